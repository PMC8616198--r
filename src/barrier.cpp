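// Log-barrier interior-point solver for the convex stage problems of
// lexicographic fluence-map optimization:
//
//   minimize    f(x)
//   subject to  A x <= b,   x >= 0,   g_j(x) <= u_j  (j = 1..J)
//
// where f is either linear (c'x) or the log of an LTCP-type objective
// (log-sum-exp of an affine map, convex), and each g_j is a log-sum-exp
// constraint of the same form.  All stage problems of the planner reduce to
// this shape: Mean objectives are linear, Max objectives are linearized with
// an auxiliary bound variable on the R side, and LTCP is minimized in log
// space (same minimizer, far better conditioning than the raw sum of
// exponentials).
//
// Classic path-following scheme: damped Newton centering on
//   phi_t(x) = t f(x) - sum log(b - Ax) - sum log(x) - sum log(u_j - g_j(x)),
// with t increased by a factor mu until m_total / t < gap_tol, which bounds
// the suboptimality of the returned point by gap_tol.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct LseTerm {
  arma::mat D;      // rows x n affine map
  double alpha;     // decay per Gy
  double ref;       // reference dose (Gy)
  double bound;     // upper bound on g (log scale); +inf for the objective
};

// g(x) = logsumexp(-alpha * (D x - ref)) - log(nrow(D));
// fills grad and (optionally) hess, returns g.
static double lse_eval(const LseTerm& term, const arma::vec& x,
                       arma::vec& grad, arma::mat* hess) {
  arma::vec z = -term.alpha * (term.D * x - term.ref);
  double zmax = z.max();
  arma::vec w = arma::exp(z - zmax);
  double s = arma::accu(w);
  arma::vec p = w / s;
  double g = zmax + std::log(s) - std::log((double)z.n_elem);
  arma::vec Dtp = term.D.t() * p;
  grad = -term.alpha * Dtp;
  if (hess) {
    arma::mat DtPD = term.D.t() * (term.D.each_col() % p);
    *hess = term.alpha * term.alpha * (DtPD - Dtp * Dtp.t());
  }
  return g;
}

struct Problem {
  arma::vec c;             // linear part of objective
  bool has_lse_obj;
  LseTerm obj;             // objective LSE term (if any)
  arma::mat A;             // linear inequality lhs
  arma::vec b;             // linear inequality rhs
  std::vector<LseTerm> cons;  // LSE constraints
};

// objective value (on the solver's scale: g for LSE, c'x otherwise)
static double obj_val(const Problem& P, const arma::vec& x) {
  if (P.has_lse_obj) {
    arma::vec grad;
    return lse_eval(P.obj, x, grad, nullptr);
  }
  return arma::dot(P.c, x);
}

// barrier value; returns +inf when x is not strictly feasible
static double phi_val(const Problem& P, const arma::vec& x, double t) {
  if (x.min() <= 0.0) return arma::datum::inf;
  double val = t * obj_val(P, x);
  if (P.A.n_rows > 0) {
    arma::vec s = P.b - P.A * x;
    if (s.min() <= 0.0) return arma::datum::inf;
    val -= arma::accu(arma::log(s));
  }
  val -= arma::accu(arma::log(x));
  for (const auto& term : P.cons) {
    arma::vec grad;
    double slack = term.bound - lse_eval(term, x, grad, nullptr);
    if (slack <= 0.0) return arma::datum::inf;
    val -= std::log(slack);
  }
  return val;
}

// [[Rcpp::export(name = ".barrier_solve_cpp")]]
List barrier_solve_cpp(arma::vec c, bool has_lse_obj, List lse_obj,
                       arma::mat A, arma::vec b, List lse_cons,
                       arma::vec x0, double t0, double mu,
                       double gap_tol, int max_newton) {
  Problem P;
  P.c = c;
  P.has_lse_obj = has_lse_obj;
  if (has_lse_obj) {
    P.obj.D = as<arma::mat>(lse_obj["D"]);
    P.obj.alpha = as<double>(lse_obj["alpha"]);
    P.obj.ref = as<double>(lse_obj["ref"]);
    P.obj.bound = arma::datum::inf;
  }
  P.A = A;
  P.b = b;
  for (int j = 0; j < lse_cons.size(); ++j) {
    List lc = lse_cons[j];
    LseTerm term;
    term.D = as<arma::mat>(lc["D"]);
    term.alpha = as<double>(lc["alpha"]);
    term.ref = as<double>(lc["ref"]);
    term.bound = as<double>(lc["bound"]);
    P.cons.push_back(term);
  }

  const arma::uword n = x0.n_elem;
  const double m_total = (double)P.A.n_rows + (double)n + (double)P.cons.size();
  arma::vec x = arma::clamp(x0, 1e-14, arma::datum::inf);

  // warm starts from a previous stage sit on that stage's active set up to
  // round-off; absorb round-off-level violations into the bounds (solution
  // perturbation is at machine precision, far below solver tolerance)
  if (P.A.n_rows > 0) {
    arma::vec Ax = P.A * x;
    for (arma::uword i = 0; i < P.b.n_elem; ++i) {
      double floor_i = Ax(i) + 1e-12 * (1.0 + std::abs(P.b(i)));
      if (P.b(i) < floor_i && Ax(i) - P.b(i) < 1e-7 * (1.0 + std::abs(P.b(i))))
        P.b(i) = floor_i;
    }
  }
  for (auto& term : P.cons) {
    arma::vec gg;
    double g0 = lse_eval(term, x, gg, nullptr);
    double floor_b = g0 + 1e-12 * (1.0 + std::abs(term.bound));
    if (term.bound < floor_b && g0 - term.bound < 1e-7 * (1.0 + std::abs(term.bound)))
      term.bound = floor_b;
  }

  // strict feasibility of the (possibly repaired) start point
  if (!std::isfinite(phi_val(P, x, 1.0))) {
    return List::create(_["status"] = "infeasible_start", _["x"] = x);
  }

  double t = t0;
  int newton_used = 0;
  std::string status = "optimal";
  std::vector<int> per_outer;
  double f_prev = obj_val(P, x);

  while (true) {
    // Newton centering at parameter t
    int it_used = 0;
    bool centered = false;
    for (int it = 0; it < max_newton; ++it) {
      ++it_used;
      arma::vec grad(n, arma::fill::zeros);
      arma::mat H(n, n, arma::fill::zeros);

      if (P.has_lse_obj) {
        arma::vec g_obj;
        arma::mat H_obj;
        lse_eval(P.obj, x, g_obj, &H_obj);
        grad += t * g_obj;
        H += t * H_obj;
      } else {
        grad += t * P.c;
      }
      if (P.A.n_rows > 0) {
        arma::vec s = P.b - P.A * x;
        arma::vec inv_s = 1.0 / s;
        grad += P.A.t() * inv_s;
        H += P.A.t() * (P.A.each_col() % (inv_s % inv_s));
      }
      grad -= 1.0 / x;
      H.diag() += 1.0 / (x % x);
      for (const auto& term : P.cons) {
        arma::vec gg;
        arma::mat Hg;
        double slack = term.bound - lse_eval(term, x, gg, &Hg);
        grad += gg / slack;
        H += Hg / slack + (gg * gg.t()) / (slack * slack);
      }

      arma::vec dx;
      bool ok = false;
      double ridge = 0.0;
      for (int tries = 0; tries < 6 && !ok; ++tries) {
        arma::mat Hr = H;
        if (ridge > 0.0) Hr.diag() += ridge;
        ok = arma::solve(dx, Hr, -grad,
                         arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
        if (!ok) ridge = (ridge == 0.0) ? 1e-10 * arma::trace(H) / n : ridge * 100.0;
      }
      if (!ok) { status = "singular_hessian"; break; }

      double phi0 = phi_val(P, x, t);
      double decrement = -arma::dot(grad, dx);  // lambda^2 (affine-invariant)
      if (decrement < 0) { dx = -grad; decrement = arma::dot(grad, grad); }
      // re-centering to a modest Newton decrement suffices: the duality gap
      // bound m/t holds up to an O(lambda) correction that is negligible at
      // lambda ~ 1e-3, and decrements much below this are float-cancellation
      // noise at large t
      if (decrement / 2.0 < 1e-6) { centered = true; break; }

      // analytic fraction-to-boundary cap for the linear constraints and
      // the nonnegativity bounds, so backtracking never wastes halvings on
      // infeasible trial points
      double step_max = 1.0;
      if (P.A.n_rows > 0) {
        arma::vec s = P.b - P.A * x;
        arma::vec Adx = P.A * dx;
        for (arma::uword i = 0; i < s.n_elem; ++i)
          if (Adx(i) > 0) step_max = std::min(step_max, 0.99 * s(i) / Adx(i));
      }
      for (arma::uword i = 0; i < n; ++i)
        if (dx(i) < 0) step_max = std::min(step_max, 0.99 * x(i) / (-dx(i)));

      double step = step_max;
      bool moved = false;
      for (int ls = 0; ls < 60; ++ls) {
        arma::vec xn = x + step * dx;
        double phin = phi_val(P, xn, t);
        if (std::isfinite(phin) && phin <= phi0 - 1e-4 * step * decrement) {
          x = xn; moved = true; break;
        }
        step *= 0.5;
      }
      if (!moved) {
        // Newton direction unusable (ill-conditioned solve); retry once with
        // a strongly ridged system, which interpolates toward gradient descent
        arma::mat Hr = H;
        Hr.diag() += 1e-6 * arma::trace(H) / n;
        if (arma::solve(dx, Hr, -grad, arma::solve_opts::likely_sympd)) {
          step_max = 1.0;
          if (P.A.n_rows > 0) {
            arma::vec s = P.b - P.A * x;
            arma::vec Adx = P.A * dx;
            for (arma::uword i = 0; i < s.n_elem; ++i)
              if (Adx(i) > 0) step_max = std::min(step_max, 0.99 * s(i) / Adx(i));
          }
          for (arma::uword i = 0; i < n; ++i)
            if (dx(i) < 0) step_max = std::min(step_max, 0.99 * x(i) / (-dx(i)));
          step = step_max;
          for (int ls = 0; ls < 60; ++ls) {
            arma::vec xn = x + step * dx;
            double phin = phi_val(P, xn, t);
            if (std::isfinite(phin) && phin < phi0) { x = xn; moved = true; break; }
            step *= 0.5;
          }
        }
      }
      ++newton_used;
      if (!moved) break;  // stalled at numerical precision
    }
    per_outer.push_back(it_used);
    if (status != "optimal") break;
    if (m_total / t < gap_tol) break;
    // at large t double precision limits how well Newton can re-center; once
    // the certified gap m/t is already small relative to the objective AND
    // the value has stopped moving, further path-following is numerical noise
    double f_now = obj_val(P, x);
    bool gap_ok = m_total / t < 1e-7 * (1.0 + std::abs(f_now));
    if (!centered && gap_ok &&
        std::abs(f_now - f_prev) < 1e-9 * (1.0 + std::abs(f_now)))
      break;
    f_prev = f_now;
    t *= mu;
    if (t > 1e300 || (int)per_outer.size() > 60) { status = "t_overflow"; break; }
  }

  double fval = obj_val(P, x);
  if (P.has_lse_obj) fval = std::exp(fval);  // report LTCP itself, not its log
  return List::create(_["status"] = status, _["x"] = x, _["value"] = fval,
                      _["gap"] = m_total / t, _["newton_iters"] = newton_used,
                      _["per_outer"] = wrap(per_outer));
}
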