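# Shared fixtures: compact phantoms and influence matrices sized for fast,
# exact testing. Built once per test run and memoized.

compact_config <- function(laterality = "right", D_p = 66) {
  phantom_config(grid = c(32, 32), spacing_mm = 7, anatomy_scale = 0.85,
                 laterality = laterality, prescription_Gy = D_p)
}

default_config <- function(laterality = "right", D_p = 66) {
  phantom_config(grid = c(40, 40), spacing_mm = 6, anatomy_scale = 0.9,
                 laterality = laterality, prescription_Gy = D_p)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

fixture_phantom <- function(seed = 17) {
  memo(paste0("ph", seed), generate_phantom(default_config(), seed))
}

fixture_derived <- function(seed = 17) {
  memo(paste0("der", seed),
       suppressMessages(derive_structures(fixture_phantom(seed))))
}

fixture_influence <- function(seed = 17, angles = template_angles("right")) {
  memo(paste0("inf", seed, paste(round(angles), collapse = "_")),
       compute_influence(fixture_phantom(seed), angles,
                         beam_geometry(beamlet_width_mm = 6)))
}

fixture_plan <- function(seed = 17) {
  memo(paste0("plan", seed), suppressMessages(
    lexicographic_solve(fixture_influence(seed), build_wishlist(66),
                        fixture_phantom(seed), fixture_derived(seed))))
}

# brute-force distance from every voxel to the nearest TRUE voxel of a mask
brute_distance_to_mask <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    d2 <- (idx[, 1] - i)^2 + (idx[, 2] - j)^2
    out[i, j] <- sqrt(min(d2)) * spacing
  }
  out
}

# brute-force influence: per-voxel per-beamlet evaluation with scalar loops
brute_influence <- function(phantom, angles, geometry) {
  step <- geometry$step_mm %||% (phantom$spacing_mm / 2)
  sp <- phantom$spacing_mm
  grid <- phantom$grid
  dens <- phantom$masks$body * 1
  dens[phantom$masks$lungs] <- geometry$lung_density
  dens[phantom$masks$PTV] <- 1
  xs <- (seq_len(grid[1]) - (grid[1] + 1) / 2) * sp
  ys <- (seq_len(grid[2]) - (grid[2] + 1) / 2) * sp
  ptv <- which(phantom$masks$PTV, arr.ind = TRUE)
  w <- geometry$beamlet_width_mm; sig <- geometry$penumbra_sigma_mm
  reach <- w / 2 + 4 * sig
  cols <- list()
  for (ang in angles) {
    th <- ang * pi / 180
    dirx <- -sin(th); diry <- cos(th)
    tx <- cos(th); ty <- sin(th)
    lptv <- xs[ptv[, 1]] * tx + ys[ptv[, 2]] * ty
    lmin <- min(lptv) - geometry$margin_mm
    lmax <- max(lptv) + geometry$margin_mm
    nb <- max(1L, as.integer(ceiling((lmax - lmin) / w)))
    centers <- (lmin + lmax) / 2 + (seq_len(nb) - (nb + 1) / 2) * w
    L <- sqrt(sum((grid * sp)^2)) + 2 * sp
    K <- ceiling(L / step)
    for (ct in centers) {
      col <- numeric(prod(grid))
      for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
        if (!phantom$masks$body[i, j]) next
        lat <- xs[i] * tx + ys[j] * ty - ct
        if (abs(lat) > reach) next
        depth <- 0
        for (k in seq_len(K)) {
          s <- (k - 0.5) * step
          qx <- xs[i] - s * dirx; qy <- ys[j] - s * diry
          ii <- round(qx / sp + (grid[1] + 1) / 2)
          jj <- round(qy / sp + (grid[2] + 1) / 2)
          if (ii >= 1 && ii <= grid[1] && jj >= 1 && jj <= grid[2])
            depth <- depth + dens[ii, jj] * step
        }
        prof <- pnorm((lat + w / 2) / sig) - pnorm((lat - w / 2) / sig)
        col[(j - 1) * grid[1] + i] <- exp(-geometry$mu_per_mm * depth) * prof
      }
      cols[[length(cols) + 1]] <- col
    }
  }
  do.call(cbind, cols)
}
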