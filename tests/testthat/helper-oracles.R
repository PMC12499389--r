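# Independent oracles kept deliberately naive: direct loops and textbook
# formulas, never sharing code with the implementation they check.

# Valid-pair autocovariance by explicit pair enumeration.
brute_force_acv <- function(x, valid, tr, max_lag) {
  xd <- x - mean(x[valid])
  n <- length(x)
  out <- data.frame(lag = seq_len(max_lag), adjusted = NA_real_,
                    n_pairs = NA_real_)
  for (m in seq_len(max_lag)) {
    rs <- 0
    np <- 0
    for (t in seq_len(n - m + 1)) {
      if (valid[t] && valid[t + m - 1]) {
        rs <- rs + xd[t] * xd[t + m - 1]
        np <- np + 1
      }
    }
    q <- (m - 1) * tr / 30
    out$adjusted[m] <- if (np >= 1) rs * exp(-0.5 * q^2) / np else 0
    out$n_pairs[m] <- np
  }
  out
}

# Spectrum of a symmetric two-sided ACV via complex exponentials.
direct_dft_psd <- function(adjusted, tr, freq) {
  m <- seq_along(adjusted) - 1
  vapply(freq, function(f) {
    s <- sum(adjusted * exp(-2i * pi * f * m * tr)) +
      sum(adjusted[-1] * exp(2i * pi * f * m[-1] * tr))
    tr * Re(s)
  }, numeric(1))
}

# Closed-form one-sided PSD of a unit-variance AR(1) process.
ar1_psd <- function(phi, tr, freq) {
  2 * tr * (1 - phi^2) / (1 - 2 * phi * cos(2 * pi * freq * tr) + phi^2)
}

# Adjusted Rand index from the contingency table.
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Small power spectrum object built directly from a power function.
make_spectrum <- function(powfun, tr = 1.97, n_freq = 256) {
  freq <- (0:n_freq) / (2 * n_freq * tr)
  structure(list(freq = freq, power = powfun(freq),
                 floored = rep(FALSE, n_freq + 1), tr = tr),
            class = "power_spectrum")
}

# Mirror-symmetric smooth map on the geometry sphere plus iid noise, for
# spin-test nulls. Degree-1 and degree-2 real spherical harmonics with iid
# coefficients in an equal-variance basis, so the random field is
# isotropic and rotation leaves its distribution invariant.
smooth_sphere_map <- function(geometry, noise_sd = 0.3) {
  cf <- rnorm(8)
  s <- ifelse(geometry$hemisphere == "L", 1, -1)
  x <- s * geometry$x
  y <- geometry$y
  z <- geometry$z
  cf[1] * x + cf[2] * y + cf[3] * z +
    cf[4] * x * y + cf[5] * y * z + cf[6] * z * x +
    cf[7] * (x^2 - y^2) / 2 + cf[8] * (3 * z^2 - 1) / (2 * sqrt(3)) +
    rnorm(nrow(geometry), 0, noise_sd)
}

# Two planted trajectory families on an age grid, as the generator
# plants them: continuous decline from 20 vs onset at 50, amplitudes
# tied to the baseline topography.
planted_trajectories <- function(n_parcels = 80, noise_sd = 0.05,
                                 seed = 1) {
  set.seed(seed)
  spec <- cohort_spec(n_parcels = n_parcels, seed = seed)
  geo <- generate_parcel_geometry(spec)
  traj <- generate_trajectories(geo, spec)
  grid <- seq(20, 85, length.out = 66)
  x <- t(vapply(seq_len(nrow(traj)), function(i)
    target_slope(traj[i, ], grid, spec), numeric(length(grid))))
  x <- x + rnorm(length(x), 0, noise_sd)
  list(x = x - rowMeans(x), cluster = traj$cluster, grid = grid)
}
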