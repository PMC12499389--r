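#' Young-group reference spectral slope map
#'
#' Parcel-wise arithmetic mean of the SS maps of subjects strictly
#' younger than the cutoff.
#'
#' @param ss SS matrix, parcels x subjects (colnames = subject ids).
#' @param subjects Subject table aligned to the SS columns.
#' @param cutoff Age cutoff in years (default 45).
#' @return Named numeric vector (one mean SS per parcel) with attributes
#'   `n_reference` and `age_cutoff`.
#' @export
young_reference_map <- function(ss, subjects, cutoff = 45) {
  young <- which(subjects$age < cutoff)
  if (length(young) < 10)
    stop(sprintf("need >= 10 subjects below %g years, found %d",
                 cutoff, length(young)), call. = FALSE)
  ref <- rowMeans(ss[, young, drop = FALSE])
  attr(ref, "n_reference") <- length(young)
  attr(ref, "age_cutoff") <- cutoff
  ref
}

#' Spectral Slope Youthful Index of one subject
#'
#' Spearman correlation (average ranks on ties) between the subject's SS
#' map and the young-group reference map.
#'
#' @param subject_map Numeric vector of parcel SS values.
#' @param reference Reference map from [young_reference_map()].
#' @return Spearman rho in `[-1, 1]`.
#' @export
compute_ssyi <- function(subject_map, reference) {
  spearman_map_correlation(as.numeric(subject_map), as.numeric(reference))
}

#' Robust outlier flags by scaled median absolute deviation
#'
#' Flags values more than `k` scaled MADs from the median, where the
#' scaled MAD is `1.4826 * median(|x - median(x)|)` (Gaussian-consistent
#' scaling). A zero MAD (all values equal at the median) flags nothing.
#'
#' @param x Numeric vector, length >= 5.
#' @param k Threshold in scaled-MAD units (default 3).
#' @return Logical vector of flags.
#' @export
mad_outliers <- function(x, k = 3) {
  if (length(x) < 5) stop("need at least 5 values", call. = FALSE)
  med <- stats::median(x)
  smad <- 1.4826 * stats::median(abs(x - med))
  if (smad == 0) return(rep(FALSE, length(x)))
  abs(x - med) > k * smad
}

#' Normalize a T2w volume against a young-subject reference atlas
#'
#' Voxelwise z-score: `(intensity - atlas mean) / atlas sd`, with the sd
#' floored at a small epsilon.
#'
#' @param volume 3-D numeric array.
#' @param atlas_mean,atlas_sd Arrays on the same grid.
#' @param eps Floor for the atlas sd (default 1e-6).
#' @return Normalized 3-D array.
#' @export
normalize_t2w <- function(volume, atlas_mean, atlas_sd, eps = 1e-6) {
  if (!identical(dim(volume), dim(atlas_mean)) ||
      !identical(dim(volume), dim(atlas_sd)))
    stop("volume and atlas grids do not match", call. = FALSE)
  (volume - atlas_mean) / pmax(atlas_sd, eps)
}

#' Voxelwise correlation of T2w intensity with the SS Youthful Index
#'
#' Pearson correlation across subjects at every voxel, with a two-sided
#' p-value; the significance mask keeps voxels with p < alpha regardless
#' of sign (exploratory, no multiplicity correction). Zero-variance
#' voxels are excluded from the mask and flagged NA.
#'
#' @param volumes List of (normalized) 3-D arrays, one per subject.
#' @param ssyi Numeric vector of SSYI values, one per subject.
#' @param alpha Significance level (default 0.05).
#' @return list(r = array, p = array, mask = logical array, n).
#' @export
voxelwise_ssyi_correlation <- function(volumes, ssyi, alpha = 0.05) {
  n <- length(volumes)
  if (n != length(ssyi)) stop("one SSYI value per volume required",
                              call. = FALSE)
  if (n < 20) stop("need at least 20 subjects", call. = FALSE)
  dm <- dim(volumes[[1]])
  x <- vapply(volumes, as.vector, numeric(prod(dm)))  # voxels x subjects
  xc <- x - rowMeans(x)
  yc <- ssyi - mean(ssyi)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(xc %*% yc) / (sx * sy)
  r[sx == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  mask <- !is.na(p) & p < alpha
  list(r = array(r, dm), p = array(p, dm), mask = array(mask, dm), n = n)
}

#' Mean normalized intensity inside an ROI
#'
#' @param volume 3-D array.
#' @param mask Logical array on the same grid, at least one TRUE voxel.
#' @return Scalar mean intensity.
#' @export
roi_mean_intensity <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask grids do not match", call. = FALSE)
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  mean(volume[mask])
}

#' Linear regression of youthful-pattern status on covariates
#'
#' Ordinary least squares of the binarized index (1 = retains the
#' youthful topography, 0 = outlier) on age, grey-matter volume, head
#' motion, sex and FLWM T2w intensity, over subjects older than
#' `min_age`. A linear probability model is fit (not logistic), as is
#' conventional for this analysis; under this coding an association of
#' outlier status with higher FLWM intensity yields a negative FLWM
#' coefficient.
#'
#' @param records data.frame with columns youthful (0/1), age, gmv,
#'   motion, sex (0/1 or factor), flwm_t2w.
#' @param min_age Only subjects with age > min_age enter (default 45).
#' @return list(coefficients = matrix with Estimate/SE/t/p rows per term,
#'   n_used, fit).
#' @export
outlier_regression <- function(records, min_age = 45) {
  d <- records[records$age > min_age, , drop = FALSE]
  if (nrow(d) < 30) stop("need at least 30 subjects above min_age",
                         call. = FALSE)
  if (is.factor(d$sex)) d$sex <- as.character(d$sex)
  if (is.character(d$sex)) d$sex <- as.numeric(d$sex == "M")
  d$sex <- as.numeric(d$sex)
  if (stats::var(d$youthful) == 0)
    stop("response has no variance (all subjects in one group)",
         call. = FALSE)
  for (v in c("age", "gmv", "motion", "sex", "flwm_t2w")) {
    if (stats::var(d[[v]]) == 0)
      stop(sprintf("predictor '%s' is constant", v), call. = FALSE)
  }
  fit <- stats::lm(youthful ~ age + gmv + motion + sex + flwm_t2w, data = d)
  list(coefficients = summary(fit)$coefficients, n_used = nrow(d), fit = fit)
}
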