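#' Spearman correlation between two parcellated maps
#'
#' Rank correlation (average ranks on ties) over the jointly non-missing
#' parcels.
#'
#' @param a,b Numeric vectors (one value per parcel), NA = missing.
#' @return Spearman rho.
#' @export
spearman_map_correlation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10)
    stop("need at least 10 jointly non-missing parcels", call. = FALSE)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0)
    stop("rho undefined for a constant map", call. = FALSE)
  stats::cor(a[ok], b[ok], method = "spearman")
}

#' Draw a uniform random 3-D rotation (quaternion method)
#'
#' Normalizes a 4-D standard Gaussian draw to a unit quaternion and
#' converts it to a rotation matrix; this is uniform over SO(3).
#'
#' @return A 3x3 rotation matrix (determinant +1).
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Mirror a rotation through the x = 0 plane (for the opposite hemisphere).
.mirror_rotation <- function(r) {
  m <- diag(c(-1, 1, 1))
  m %*% r %*% m
}

#' Spin permutation test for the association of two parcel maps
#'
#' Builds a spatial null by rotating the parcel centroids of map `a` on
#' each hemisphere's sphere (the mirrored rotation is applied to the
#' right hemisphere), reassigning each original parcel position the value
#' of the nearest rotated source parcel (great-circle / maximal dot
#' product), dropping positions whose nearest source is a medial-wall
#' parcel, and recomputing the Spearman correlation with `b`. The
#' one-sided p-value counts null correlations strictly greater than the
#' observed one, with the finite-sample `(count + 1)/(R + 1)` correction.
#'
#' @param a,b Numeric vectors aligned to the rows of `geometry`
#'   (NA = missing; medial-wall parcels are ignored for the observed
#'   correlation).
#' @param geometry Parcel geometry (columns x, y, z, hemisphere,
#'   medial_wall).
#' @param n_rotations Number of random rotations (default 10000).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default, as printed) or
#'   `"two.sided"` (counts |null| >= |observed|).
#' @return list(rho_obs, p_spin, null_corrs, n_rotations, seed).
#' @export
spin_pvalue <- function(a, b, geometry, n_rotations = 10000, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == nrow(geometry), length(b) == nrow(geometry))
  med <- geometry$medial_wall
  usable_b <- is.finite(b) & !med
  if (mean(!is.finite(b[!med])) > 0.5)
    stop("map b is missing for more than half of the parcels", call. = FALSE)
  amask <- ifelse(med, NA_real_, a)
  bmask <- ifelse(med, NA_real_, b)
  rho_obs <- spearman_map_correlation(amask, bmask)
  if (!is.null(seed)) set.seed(seed)
  hems <- split(seq_len(nrow(geometry)), geometry$hemisphere)
  cent <- as.matrix(geometry[, c("x", "y", "z")])
  null_corrs <- numeric(n_rotations)
  for (r in seq_len(n_rotations)) {
    rot <- random_rotation()
    src <- integer(nrow(geometry))
    for (h in names(hems)) {
      idx <- hems[[h]]
      rh <- if (h == "R") .mirror_rotation(rot) else rot
      ch <- cent[idx, , drop = FALSE]
      dots <- ch %*% t(ch %*% t(rh))   # <orig_i, R orig_j>
      src[idx] <- idx[max.col(dots, ties.method = "first")]
    }
    rot_a <- a[src]
    rot_a[med[src] | !is.finite(rot_a)] <- NA_real_
    ok <- !med & is.finite(rot_a) & is.finite(b)
    null_corrs[r] <- if (sum(ok) >= 10 &&
                         stats::var(rot_a[ok]) > 0 && stats::var(b[ok]) > 0)
      stats::cor(rot_a[ok], b[ok], method = "spearman") else NA_real_
  }
  valid_null <- null_corrs[is.finite(null_corrs)]
  exceed <- if (alternative == "greater") sum(valid_null > rho_obs)
            else sum(abs(valid_null) >= abs(rho_obs))
  p_spin <- (exceed + 1) / (length(valid_null) + 1)
  list(rho_obs = rho_obs, p_spin = p_spin, null_corrs = null_corrs,
       n_rotations = n_rotations, seed = seed)
}
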