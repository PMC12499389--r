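#' Cohort specification for the synthetic study generator
#'
#' Bundles and validates every parameter of the synthetic cohort: sample
#' size, age range, parcellation size, run length, planted trajectory
#' structure, planted topographic outliers, and the T2w lesion effect.
#' Defaults mirror the acquisition this pipeline targets (261 frames at
#' TR = 1.97 s, ages 18-88) and plant an age effect inside the 0-0.12
#' explained-variance range the lifespan models are designed to detect.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two-element numeric, years, `lo < hi`.
#' @param n_parcels Number of cortical parcels (split across hemispheres).
#' @param n_frames Frames per run (>= 64).
#' @param tr Sampling interval, seconds.
#' @param seed Integer master seed; every generator draws from streams
#'   derived from it, so identical specs give byte-identical cohorts.
#' @param frac_cluster2 Fraction of parcels assigned the delayed-onset
#'   trajectory family.
#' @param onset_age Onset age (years) of decline for the delayed family.
#' @param outlier_frac Fraction of subjects older than 45 y whose spectral
#'   slope topography is rank-permuted (planted divergent subjects).
#' @param noise_floor Flat additive PSD floor (power units), >= 0.
#' @param slope_effect_frac Target fraction of slope variance explained by
#'   age; between-subject slope dispersion is set from this.
#' @param lesion_effect T2w intensity shift inside the frontal white matter
#'   ROI for divergent subjects (same units as the voxel noise sd).
#' @param t2w_noise_sd Voxelwise T2w noise sd (default 1).
#' @param censor_rate Expected fraction of invalid (censored) frames.
#' @param censor_mode `"iid"` (Bernoulli per frame, default) or `"block"`
#'   (one contiguous censored run of expected length).
#' @param decline_rate1,decline_rate2 Slope-units-per-year decline for the
#'   continuous (onset 20 y) and delayed (onset `onset_age`) families.
#' @param decline_exponent Shape exponent of the post-onset decline
#'   (`1` = linear; `>1` accelerating).
#' @param baseline_mean,baseline_z,baseline_y,baseline_harm Coefficients
#'   of the smooth baseline-slope topography
#'   `b = mean + z_coef*z + y_coef*y + harm*(2z^2-1) + harm*2yz` over the
#'   unit-sphere centroids (log10-power per Hz at age 20); the
#'   second-order terms give the map realistic mid-scale structure.
#' @param log_power_intercept log10 power at 0 Hz of the synthesized
#'   in-band spectrum.
#' @param glc_noise,cmro2_noise,cbf_noise Additive map noise (sd) for the
#'   three synthetic metabolic/hemodynamic maps; larger noise gives weaker
#'   spatial correlation with the young slope map.
#' @param t2w_dim Edge length of the cubic T2w volume grid.
#' @param rsn_names Names of the resting-state networks used for the
#'   probabilistic parcel weights.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_subjects = 200,
                        age_range = c(18, 88),
                        n_parcels = 100,
                        n_frames = 261,
                        tr = 1.97,
                        seed = 1L,
                        frac_cluster2 = 0.25,
                        onset_age = 50,
                        outlier_frac = 0.10,
                        noise_floor = 1,
                        slope_effect_frac = 0.10,
                        lesion_effect = 3,
                        t2w_noise_sd = 1,
                        censor_rate = 0.10,
                        censor_mode = c("iid", "block"),
                        decline_rate1 = 0.02,
                        decline_rate2 = 0.045,
                        decline_exponent = 1,
                        baseline_mean = 6.5,
                        baseline_z = 2.0,
                        baseline_y = 0.8,
                        baseline_harm = 1.2,
                        log_power_intercept = 4,
                        glc_noise = 2,
                        cmro2_noise = 4,
                        cbf_noise = 6,
                        t2w_dim = 24,
                        rsn_names = c("Vis", "SomMot", "DorsAttn", "VentAttn",
                                      "Limbic", "Cont", "Default")) {
  censor_mode <- match.arg(censor_mode)
  spec <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
               n_parcels = as.integer(n_parcels), n_frames = as.integer(n_frames),
               tr = tr, seed = as.integer(seed), frac_cluster2 = frac_cluster2,
               onset_age = onset_age, outlier_frac = outlier_frac,
               noise_floor = noise_floor, slope_effect_frac = slope_effect_frac,
               lesion_effect = lesion_effect, t2w_noise_sd = t2w_noise_sd,
               censor_rate = censor_rate,
               censor_mode = censor_mode, decline_rate1 = decline_rate1,
               decline_rate2 = decline_rate2, decline_exponent = decline_exponent,
               baseline_mean = baseline_mean, baseline_z = baseline_z,
               baseline_y = baseline_y, baseline_harm = baseline_harm,
               log_power_intercept = log_power_intercept,
               glc_noise = glc_noise, cmro2_noise = cmro2_noise,
               cbf_noise = cbf_noise, t2w_dim = as.integer(t2w_dim),
               rsn_names = rsn_names)
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort spec field '%s': %s", field, why), call. = FALSE)
  }
  if (spec$n_subjects < 1) fail("n_subjects", "must be >= 1")
  if (length(spec$age_range) != 2 || spec$age_range[1] >= spec$age_range[2])
    fail("age_range", "must be [lo, hi] with lo < hi")
  if (spec$n_frames < 64) fail("n_frames", "must be >= 64")
  if (spec$tr <= 0) fail("tr", "must be > 0")
  for (f in c("frac_cluster2", "outlier_frac", "censor_rate", "slope_effect_frac")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must lie in [0, 1]")
  }
  if (spec$noise_floor < 0) fail("noise_floor", "must be >= 0")
  if (spec$t2w_noise_sd < 0) fail("t2w_noise_sd", "must be >= 0")
  if (spec$t2w_dim < 8) fail("t2w_dim", "must be >= 8")
  invisible(spec)
}

# Independent RNG streams per generator, all derived from the master seed.
# Offsets keep the streams apart; everything stays below .Machine$integer.max.
.stream_seed <- function(spec, offset) {
  (spec$seed %% 1000003L) * 1009L + offset
}

#' Generate the subject covariate table
#'
#' Ages are uniform over the spec's range, sex is Bernoulli(0.5), head
#' motion log-normal and grey-matter volume Gaussian, all independent of
#' the planted divergence flag so covariate regressions have a true null.
#' Subjects older than 45 y are flagged `outlier` (topography to be
#' rank-permuted downstream) at rate `outlier_frac`.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns subject_id, age, sex (`"F"`/`"M"`),
#'   head_motion (mm), gmv (voxel count), outlier (logical).
#' @export
generate_subject_table <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(.stream_seed(spec, 1L))
  n <- spec$n_subjects
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  head_motion <- rlnorm(n, meanlog = -2, sdlog = 0.5)
  gmv <- round(rnorm(n, mean = 45000, sd = 4000))
  outlier <- age > 45 & runif(n) < spec$outlier_frac
  data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
             age = age, sex = sex, head_motion = head_motion,
             gmv = gmv, outlier = outlier, stringsAsFactors = FALSE)
}

# Fibonacci lattice: k quasi-uniform points on the unit sphere.
.fibonacci_sphere <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

#' Generate spherical parcel geometry
#'
#' Each hemisphere gets a Fibonacci lattice on its own unit sphere (the
#' right hemisphere mirrored through the x = 0 plane so the two maps are
#' symmetric). Parcels whose centroid falls within a fixed cap around the
#' medial pole are flagged `medial_wall` and excluded from analysis.
#' Probabilistic network weights are von-Mises-Fisher-like kernels around
#' seeded network centres, normalized to sum to one per parcel.
#'
#' @param spec A [cohort_spec()]; requires `n_parcels >= 10`.
#' @return A data.frame: parcel_id (1-based), x, y, z (unit centroid),
#'   hemisphere (`"L"`/`"R"`), medial_wall (logical), and one `rsn_<name>`
#'   column per network.
#' @export
generate_parcel_geometry <- function(spec) {
  validate_cohort_spec(spec)
  if (spec$n_parcels < 10) stop("n_parcels must be >= 10", call. = FALSE)
  set.seed(.stream_seed(spec, 2L))
  n_l <- ceiling(spec$n_parcels / 2)
  n_r <- spec$n_parcels - n_l
  cl <- .fibonacci_sphere(n_l)
  cr <- .fibonacci_sphere(max(n_r, 1))[seq_len(n_r), , drop = FALSE]
  cr[, "x"] <- -cr[, "x"]  # mirror so left/right topographies correspond
  centroids <- rbind(cl, cr)
  hemisphere <- c(rep("L", n_l), rep("R", n_r))
  # medial pole: +x for L, -x for R; cap with cos(angle) > 0.85 (~7.5%)
  medial_dot <- ifelse(hemisphere == "L", centroids[, "x"], -centroids[, "x"])
  medial_wall <- medial_dot > 0.85
  # RSN kernels: fixed centres per network, mirrored across hemispheres
  k_rsn <- length(spec$rsn_names)
  ctr <- matrix(rnorm(3 * k_rsn), ncol = 3)
  ctr <- ctr / sqrt(rowSums(ctr^2))
  probs <- matrix(NA_real_, nrow = spec$n_parcels, ncol = k_rsn)
  for (r in seq_len(k_rsn)) {
    cc <- ctr[r, ]
    d <- ifelse(hemisphere == "L",
                centroids %*% cc,
                centroids %*% (cc * c(-1, 1, 1)))
    probs[, r] <- exp(3 * d)
  }
  probs <- probs / rowSums(probs)
  colnames(probs) <- paste0("rsn_", spec$rsn_names)
  out <- data.frame(parcel_id = seq_len(spec$n_parcels),
                    x = centroids[, "x"], y = centroids[, "y"],
                    z = centroids[, "z"], hemisphere = hemisphere,
                    medial_wall = medial_wall, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' Assign a lifespan trajectory to each parcel
#'
#' Baseline slope (value at age 20) is a smooth function of the centroid,
#' giving a reproducible spatial topography; a contiguous cap of parcels
#' (fraction `frac_cluster2`, nearest the superior pole) gets the
#' delayed-onset family, all others the continuous-decline family.
#'
#' @param geometry Output of [generate_parcel_geometry()].
#' @param spec A [cohort_spec()].
#' @return A data.frame: parcel_id, cluster (1 continuous / 2 delayed),
#'   baseline_slope, decline_rate, onset_age.
#' @export
generate_trajectories <- function(geometry, spec) {
  validate_cohort_spec(spec)
  baseline <- spec$baseline_mean + spec$baseline_z * geometry$z +
    spec$baseline_y * geometry$y +
    spec$baseline_harm * (2 * geometry$z^2 - 1) +
    spec$baseline_harm * 2 * geometry$y * geometry$z
  # delayed-onset family: the frac_cluster2 parcels closest to the +z pole
  n2 <- round(spec$frac_cluster2 * nrow(geometry))
  cluster <- rep(1L, nrow(geometry))
  if (n2 > 0) cluster[order(geometry$z, decreasing = TRUE)[seq_len(n2)]] <- 2L
  # decline amplitude scales with baseline slope: parcels with steeper
  # young-age slopes (higher metabolic demand) age more, so the
  # explained-variance topography tracks the metabolic maps
  amp <- sqrt(baseline / mean(baseline))
  data.frame(parcel_id = geometry$parcel_id,
             cluster = cluster,
             baseline_slope = baseline,
             decline_rate = amp * ifelse(cluster == 2L, spec$decline_rate2,
                                         spec$decline_rate1),
             onset_age = ifelse(cluster == 2L, spec$onset_age, 20))
}

#' Target spectral slope of a parcel at a given age
#'
#' Flat at `baseline_slope` until `onset_age`, then declining as
#' `decline_rate * (age - onset)^decline_exponent`, floored at 0.5 so the
#' synthesized spectrum always has in-band structure.
#'
#' @param traj One row (or vectorized rows) of [generate_trajectories()].
#' @param age Age(s) in years.
#' @param spec A [cohort_spec()] (supplies the decline exponent).
#' @return Numeric target slope(s), log10-power per Hz.
#' @export
target_slope <- function(traj, age, spec) {
  drop <- traj$decline_rate * pmax(age - traj$onset_age, 0)^spec$decline_exponent
  pmax(traj$baseline_slope - drop, 0.5)
}

# Between-subject slope dispersion implied by slope_effect_frac: the
# target fraction of realized slope variance attributable to age. The
# residual variance of an estimated slope already contains the spectral
# estimator's own sampling variance (~2.0 slope-units^2 for the default
# acquisition: 261 frames, TR 1.97 s, 10% censoring, Gaussian lag taper);
# the between-subject offset only supplies whatever residual variance is
# still missing. At the defaults this is ~0, which also keeps every
# target slope inside the estimator's stable range.
.estimator_noise_var <- 2.0

.subject_sd_from_effect_frac <- function(traj, spec) {
  f <- spec$slope_effect_frac
  if (f <= 0) return(1)
  ages <- seq(spec$age_range[1], spec$age_range[2], length.out = 201)
  va <- mean(vapply(seq_len(nrow(traj)), function(i) {
    stats::var(target_slope(traj[i, ], ages, spec))
  }, numeric(1)))
  sqrt(max(va * (1 / f - 1) - .estimator_noise_var, 0))
}

# Spectral synthesis: a Gaussian series whose expected one-sided PSD is
# 10^(a - s f) + noise_floor, via random-phase inverse DFT.
.synth_series <- function(s, spec) {
  n <- spec$n_frames
  tr <- spec$tr
  k <- seq_len(floor((n - 1) / 2))
  fk <- k / (n * tr)
  target <- 10^(spec$log_power_intercept - s * fk) + spec$noise_floor
  amp <- sqrt(target * n / (2 * tr))
  z <- complex(real = rnorm(length(k), sd = sqrt(0.5)),
               imaginary = rnorm(length(k), sd = sqrt(0.5)))
  coef <- complex(real = rep(0, n))
  coef[1 + k] <- amp * z
  coef[n + 1 - k] <- Conj(coef[1 + k])
  if (n %% 2 == 0) {
    fn <- 0.5 / tr
    tn <- 10^(spec$log_power_intercept - s * fn) + spec$noise_floor
    coef[n / 2 + 1] <- sqrt(tn * n / tr) * rnorm(1)
  }
  Re(fft(coef, inverse = TRUE)) / n
}

.censor_mask <- function(spec) {
  n <- spec$n_frames
  if (spec$censor_rate <= 0) return(rep(TRUE, n))
  if (spec$censor_mode == "block") {
    len <- min(n - 2L, max(1L, round(spec$censor_rate * n)))
    start <- sample.int(n - len + 1L, 1L)
    valid <- rep(TRUE, n)
    valid[start:(start + len - 1L)] <- FALSE
    valid
  } else {
    runif(n) >= spec$censor_rate
  }
}

#' Generate one parcel timeseries
#'
#' Synthesizes a Gaussian series whose expected PSD is
#' `10^(a - s f) + noise_floor`, with `s` the subject-and-age-dependent
#' target slope from the parcel's trajectory, plus a valid-frame mask with
#' expected validity rate `1 - censor_rate`.
#'
#' @param subject One row of [generate_subject_table()].
#' @param traj One row of [generate_trajectories()].
#' @param spec A [cohort_spec()].
#' @param slope_offset Optional additive subject-level slope offset.
#' @return A [frame_series()].
#' @export
generate_timeseries <- function(subject, traj, spec, slope_offset = 0) {
  validate_cohort_spec(spec)
  s <- target_slope(traj, subject$age, spec) + slope_offset
  frame_series(.synth_series(max(s, 0), spec), tr = spec$tr,
               valid = .censor_mask(spec))
}

#' Generate all parcel timeseries for one subject
#'
#' All parcels share the subject's valid-frame mask (censoring reflects
#' head motion, which is frame-wide). A subject-level slope offset (sd set
#' from `slope_effect_frac`) shifts all parcels together, preserving the
#' across-parcel rank order; for planted divergent subjects the
#' across-parcel slope profile is randomly permuted instead, destroying
#' the topography while preserving the marginal slope values.
#'
#' @param subject One row of the subject table.
#' @param traj Full trajectory table.
#' @param spec A [cohort_spec()].
#' @param subject_sd Between-subject slope sd (precomputed by
#'   [generate_cohort()]; defaults to the value implied by the spec).
#' @return A list: `series` (frames x parcels matrix), `tr`, `valid`
#'   (shared mask), `slopes` (the per-parcel target slopes used).
#' @export
generate_subject_timeseries <- function(subject, traj, spec,
                                        subject_sd = NULL) {
  validate_cohort_spec(spec)
  if (is.null(subject_sd)) subject_sd <- .subject_sd_from_effect_frac(traj, spec)
  delta <- rnorm(1, 0, subject_sd)
  s <- pmax(target_slope(traj, subject$age, spec) + delta, 0)
  if (isTRUE(subject$outlier)) s <- sample(s)
  valid <- .censor_mask(spec)
  series <- vapply(s, function(si) .synth_series(si, spec),
                   numeric(spec$n_frames))
  colnames(series) <- as.character(traj$parcel_id)
  list(series = series, tr = spec$tr, valid = valid, slopes = s)
}

#' Generate synthetic parcel-level metabolic and hemodynamic maps
#'
#' CMRGlc is a monotone (logistic) transform of the young-age target slope
#' topography plus additive noise, so its rank correlation with the young
#' slope map is high by construction; CMRO2 and CBF use progressively
#' larger noise and correlate more weakly.
#'
#' @param geometry Parcel geometry.
#' @param traj Trajectory table (supplies the young slope topography).
#' @param spec A [cohort_spec()].
#' @return A data.frame: parcel_id, cmrglc, cmro2, cbf.
#' @export
generate_metabolic_maps <- function(geometry, traj, spec) {
  validate_cohort_spec(spec)
  set.seed(.stream_seed(spec, 3L))
  s20 <- traj$baseline_slope
  base <- (s20 - mean(s20)) / max(stats::sd(s20), 1e-12)
  shape <- stats::plogis(1.2 * base)            # monotone, bounded
  shape <- (shape - mean(shape)) / max(stats::sd(shape), 1e-12)
  n <- nrow(geometry)
  # signal sd fixed at 3 map units; noise sds from the spec, so the rank
  # correlation with the young slope map is ~ 3/sqrt(9 + noise^2)
  data.frame(parcel_id = geometry$parcel_id,
             cmrglc = 25 + 3 * shape + rnorm(n, 0, spec$glc_noise),
             cmro2 = 120 + 3 * shape + rnorm(n, 0, spec$cmro2_noise),
             cbf = 45 + 3 * shape + rnorm(n, 0, spec$cbf_noise))
}

#' Generate synthetic T2w-like volumes with a frontal white matter effect
#'
#' Each subject gets a cubic intensity volume of unit-sd Gaussian noise
#' around a constant baseline; planted divergent subjects additionally
#' carry `lesion_effect` extra intensity inside a contiguous frontal-
#' white-matter ROI. A voxelwise reference atlas (mean, sd) is computed
#' from subjects younger than `atlas_cutoff`.
#'
#' @param subjects Subject table.
#' @param spec A [cohort_spec()].
#' @param atlas_cutoff Age below which subjects enter the reference atlas.
#' @return A list: `volumes` (list of 3-D arrays, one per subject),
#'   `roi_mask` (logical array), `atlas_mean`, `atlas_sd`, `dim`.
#' @export
generate_t2w_volumes <- function(subjects, spec, atlas_cutoff = 40) {
  validate_cohort_spec(spec)
  set.seed(.stream_seed(spec, 4L))
  d <- spec$t2w_dim
  roi <- array(FALSE, dim = c(d, d, d))
  # contiguous frontal (high-y), superior block
  xr <- seq(round(d * 0.3), round(d * 0.55))
  yr <- seq(round(d * 0.65), round(d * 0.9))
  zr <- seq(round(d * 0.5), round(d * 0.75))
  roi[xr, yr, zr] <- TRUE
  if (!any(roi)) stop("FLWM ROI is empty", call. = FALSE)
  volumes <- lapply(seq_len(nrow(subjects)), function(i) {
    v <- array(50 + rnorm(d^3, 0, spec$t2w_noise_sd), dim = c(d, d, d))
    if (isTRUE(subjects$outlier[i])) v[roi] <- v[roi] + spec$lesion_effect
    v
  })
  names(volumes) <- subjects$subject_id
  young <- which(subjects$age < atlas_cutoff)
  if (length(young) < 2)
    stop("need at least 2 subjects below the atlas cutoff", call. = FALSE)
  stack <- vapply(volumes[young], as.vector, numeric(d^3))
  atlas_mean <- array(rowMeans(stack), dim = c(d, d, d))
  atlas_sd <- array(apply(stack, 1, stats::sd), dim = c(d, d, d))
  list(volumes = volumes, roi_mask = roi, atlas_mean = atlas_mean,
       atlas_sd = atlas_sd, dim = c(d, d, d))
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator off the spec's seed streams and returns the whole
#' study in memory: subjects, geometry, trajectories, per-subject
#' timeseries, metabolic maps and T2w volumes.
#'
#' @param spec A [cohort_spec()].
#' @param timeseries Generate the (largest) timeseries component; set
#'   FALSE to skip it.
#' @param t2w Generate T2w volumes.
#' @return A list of class `cohort` with components `spec`, `subjects`,
#'   `geometry`, `trajectories`, `metabolic`, `timeseries` (list per
#'   subject, see [generate_subject_timeseries()]) and `t2w`.
#' @export
generate_cohort <- function(spec, timeseries = TRUE, t2w = TRUE) {
  validate_cohort_spec(spec)
  subjects <- generate_subject_table(spec)
  geometry <- generate_parcel_geometry(spec)
  traj <- generate_trajectories(geometry, spec)
  metabolic <- generate_metabolic_maps(geometry, traj, spec)
  ts <- NULL
  if (timeseries) {
    set.seed(.stream_seed(spec, 5L))
    ssd <- .subject_sd_from_effect_frac(traj, spec)
    ts <- lapply(seq_len(nrow(subjects)), function(i) {
      generate_subject_timeseries(subjects[i, ], traj, spec, subject_sd = ssd)
    })
    names(ts) <- subjects$subject_id
  }
  vol <- if (t2w) generate_t2w_volumes(subjects, spec) else NULL
  structure(list(spec = spec, subjects = subjects, geometry = geometry,
                 trajectories = traj, metabolic = metabolic,
                 timeseries = ts, t2w = vol),
            class = "cohort")
}
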