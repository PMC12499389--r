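#' A single parcel timeseries with sampling interval and frame mask
#'
#' The unit of spectral estimation: signal values per frame, the sampling
#' interval (TR) and a logical valid-frame mask marking the motion-free
#' frames that enter the autocovariance.
#'
#' @param values Numeric vector, one value per frame.
#' @param tr Sampling interval in seconds, > 0.
#' @param valid Logical vector, same length as `values` (default all TRUE).
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(values, tr, valid = rep(TRUE, length(values))) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (length(valid) != length(values))
    stop("valid mask and values must have the same length", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("tr must be a single positive number", call. = FALSE)
  structure(list(values = as.numeric(values), tr = tr,
                 valid = as.logical(valid)),
            class = "frame_series")
}

#' Default maximum lag for the tapered autocovariance
#'
#' Lags are Gaussian-tapered with `exp(-q^2/2)`, `q = (m-1)*tr/30`; beyond
#' the lag where the taper drops below 1e-3 (q ~ 3.72, about 112 s)
#' nothing survives, so the default stops there, capped at one less than
#' the series length.
#'
#' @param n_frames Series length.
#' @param tr Sampling interval, seconds.
#' @return Integer maximum lag index (1-based; lag 1 is zero shift).
#' @export
default_max_lag <- function(n_frames, tr) {
  qcrit <- sqrt(-2 * log(1e-3))
  min(as.integer(floor(qcrit * 30 / tr)) + 1L, n_frames - 1L)
}

#' Censored (valid-pair) autocovariance with Gaussian lag taper
#'
#' Demeans the series over valid frames, then for each lag `m` (1-based;
#' `m = 1` is zero shift) sums products over frame pairs where both frames
#' are valid, counts those pairs (`n`), and adjusts by the decay factor
#' `exp(-q^2/2)/n` with scaled lag `q = (m-1)*tr/30`. Lags with no valid
#' pair get adjusted value 0 and are flagged.
#'
#' @param ts A [frame_series()] with at least 2 valid frames.
#' @param max_lag Maximum lag index; must be < series length. Defaults to
#'   [default_max_lag()].
#' @return A data.frame with columns lag, q, raw_sum, n_pairs, adjusted,
#'   empty; `tr` attached as an attribute.
#' @export
censored_autocovariance <- function(ts, max_lag = NULL) {
  stopifnot(inherits(ts, "frame_series"))
  n <- length(ts$values)
  if (sum(ts$valid) < 2)
    stop("need at least 2 valid frames", call. = FALSE)
  if (is.null(max_lag)) max_lag <- default_max_lag(n, ts$tr)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n)
    stop("max_lag must be smaller than the series length", call. = FALSE)
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  x <- ts$values - mean(ts$values[ts$valid])
  x[!ts$valid] <- 0
  v <- as.numeric(ts$valid)
  lag <- seq_len(max_lag)
  raw_sum <- n_pairs <- numeric(max_lag)
  for (m in lag) {
    i <- seq_len(n - m + 1L)
    j <- i + m - 1L
    raw_sum[m] <- sum(x[i] * x[j])
    n_pairs[m] <- sum(v[i] * v[j])
  }
  q <- (lag - 1) * ts$tr / 30
  adjusted <- ifelse(n_pairs >= 1, raw_sum * exp(-0.5 * q^2) / n_pairs, 0)
  out <- data.frame(lag = lag, q = q, raw_sum = raw_sum,
                    n_pairs = n_pairs, adjusted = adjusted,
                    empty = n_pairs == 0)
  attr(out, "tr") <- ts$tr
  out
}

#' PSD via cosine transform of the adjusted autocovariance
#'
#' Wiener-Khinchin route: evaluates
#' `S(f_j) = tr * sum_m w_m * acv_m * cos(2*pi*f_j*(m-1)*tr)` on the grid
#' `f_j = j / (2*n_freq*tr)`, `j = 0..n_freq` (DC to Nyquist), with
#' endpoint weight `w_1 = 1` and `w_m = 2` otherwise. Estimates can dip
#' negative (lag-window estimators are not positivity-preserving); values
#' are floored at `1e-12 * max(power)` before any logging and the floored
#' points flagged.
#'
#' @param acv Output of [censored_autocovariance()].
#' @param tr Sampling interval, seconds; defaults to the one attached to
#'   `acv`.
#' @param n_freq Number of positive-frequency grid steps (default 256,
#'   giving at least 5 in-band points for any tr <= 4 s).
#' @return An object of class `power_spectrum`: list(freq, power, floored,
#'   tr).
#' @export
psd_via_cosine_transform <- function(acv, tr = attr(acv, "tr"), n_freq = 256) {
  if (is.null(acv) || nrow(acv) == 0)
    stop("empty autocovariance", call. = FALSE)
  if (is.null(tr) || tr <= 0) stop("tr must be > 0", call. = FALSE)
  freq <- (0:n_freq) / (2 * n_freq * tr)
  w <- c(1, rep(2, nrow(acv) - 1L))
  cosmat <- cos(2 * pi * outer(freq, (acv$lag - 1) * tr))
  power <- as.vector(tr * (cosmat %*% (w * acv$adjusted)))
  floor_at <- 1e-12 * max(abs(power), 1e-300)
  floored <- power < floor_at
  power[floored] <- floor_at
  structure(list(freq = freq, power = power, floored = floored, tr = tr),
            class = "power_spectrum")
}

.inband <- function(ps, band) {
  which(ps$freq >= band[1] & ps$freq <= band[2])
}

#' Fit the spectral slope in the analysis band
#'
#' Ordinary least squares of log10 power on raw frequency over in-band
#' grid points (semilog fit). The spectral slope SS is the negative of the
#' fitted slope, so positive SS means power declines with frequency.
#'
#' @param ps A [psd_via_cosine_transform()] spectrum.
#' @param band Frequency band in Hz (default 0.015-0.145).
#' @return An object of class `slope_fit`: list(ss, intercept, r2, band,
#'   n_inband). `r2` is 0 for a perfectly flat in-band spectrum.
#' @export
fit_spectral_slope <- function(ps, band = c(0.015, 0.145)) {
  idx <- .inband(ps, band)
  if (length(idx) < 5)
    stop(sprintf(paste0("need >= 5 in-band grid points, found %d ",
                        "(grid resolution %.5f Hz; increase n_freq)"),
                 length(idx), ps$freq[2] - ps$freq[1]), call. = FALSE)
  f <- ps$freq[idx]
  y <- log10(ps$power[idx])
  fx <- f - mean(f)
  slope <- sum(fx * y) / sum(fx^2)
  intercept <- mean(y) - slope * mean(f)
  res <- y - (intercept + slope * f)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-300) 0 else max(0, min(1, 1 - sum(res^2) / tss))
  structure(list(ss = -slope, intercept = intercept, r2 = r2,
                 band = band, n_inband = length(idx)),
            class = "slope_fit")
}

#' Compare semilog and log-log spectral fits
#'
#' Fits log10 power against raw frequency (semilog) and against log10
#' frequency (log-log / power law) on the same in-band points and returns
#' both R^2 values, supporting the choice of spectral model.
#'
#' @inheritParams fit_spectral_slope
#' @return list(r2_semilog, r2_loglog, n_inband).
#' @export
compare_spectral_models <- function(ps, band = c(0.015, 0.145)) {
  idx <- .inband(ps, band)
  if (length(idx) < 5)
    stop("need >= 5 in-band grid points", call. = FALSE)
  y <- log10(ps$power[idx])
  r2_of <- function(x) {
    xc <- x - mean(x)
    tss <- sum((y - mean(y))^2)
    if (tss < 1e-300) return(0)
    b <- sum(xc * y) / sum(xc^2)
    res <- y - mean(y) - b * xc
    max(0, min(1, 1 - sum(res^2) / tss))
  }
  f <- ps$freq[idx]
  list(r2_semilog = r2_of(f), r2_loglog = r2_of(log10(f)),
       n_inband = length(idx))
}

#' Per-subject spectral slope map
#'
#' Runs the censored-autocovariance / cosine-transform / semilog-slope
#' chain on every parcel of one subject. Accepts either a named list of
#' [frame_series()] or a frames-x-parcels matrix with a shared mask.
#' Medial-wall parcels (if geometry is supplied) are dropped from the map.
#'
#' @param series Named list of `frame_series`, or a numeric matrix
#'   (frames x parcels, column names = parcel ids).
#' @param tr,valid Sampling interval and shared mask; required when
#'   `series` is a matrix.
#' @param geometry Optional parcel geometry; its `medial_wall` parcels are
#'   excluded.
#' @param band Analysis band, Hz.
#' @param n_freq Frequency grid size.
#' @return An object of class `ss_map`: data.frame(parcel_id, ss, r2,
#'   n_inband).
#' @export
subject_ss_map <- function(series, tr = NULL, valid = NULL, geometry = NULL,
                           band = c(0.015, 0.145), n_freq = 256) {
  if (is.matrix(series)) {
    if (is.null(tr)) stop("tr is required with matrix input", call. = FALSE)
    if (is.null(valid)) valid <- rep(TRUE, nrow(series))
    ids <- colnames(series)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(series)))
    series <- lapply(seq_len(ncol(series)), function(j)
      frame_series(series[, j], tr = tr, valid = valid))
    names(series) <- ids
  }
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  if (!is.null(geometry)) {
    keep <- !ids %in% as.character(geometry$parcel_id[geometry$medial_wall])
    series <- series[keep]
    ids <- ids[keep]
  }
  trs <- vapply(series, function(s) s$tr, numeric(1))
  if (length(unique(trs)) > 1)
    stop("all parcels must share the same tr", call. = FALSE)
  rows <- lapply(seq_along(series), function(j) {
    fit <- tryCatch({
      acv <- censored_autocovariance(series[[j]])
      ps <- psd_via_cosine_transform(acv, n_freq = n_freq)
      fit_spectral_slope(ps, band = band)
    }, error = function(e) {
      stop(sprintf("parcel %s: %s", ids[j], conditionMessage(e)),
           call. = FALSE)
    })
    data.frame(parcel_id = ids[j], ss = fit$ss, r2 = fit$r2,
               n_inband = fit$n_inband, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ss_map", class(out))
  out
}
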