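#' Validate a per-parcel design table
#'
#' @param design data.frame with numeric columns ss, age, sex (0/1) and
#'   motion across subjects for one parcel.
#' @return The design, invisibly.
#' @keywords internal
.check_design <- function(design) {
  need <- c("ss", "age", "sex", "motion")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(design$ss)) stop("design has missing ss values", call. = FALSE)
  if (nrow(design) < 50)
    stop("need >= 50 rows to fit a lifespan model", call. = FALSE)
  for (v in c("age", "sex", "motion")) {
    if (stats::var(as.numeric(design[[v]])) == 0)
      stop(sprintf("covariate '%s' is constant", v), call. = FALSE)
  }
  invisible(design)
}

#' Fit the full lifespan GAM for one parcel
#'
#' Penalized thin-plate spline smooth of age (basis dimension k = 4,
#' REML-selected smoothing) with sex and head motion as linear covariates.
#'
#' @param design data.frame(ss, age, sex, motion); >= 50 rows, no constant
#'   covariate.
#' @param k Maximum basis complexity of the age smooth.
#' @return A fitted `mgcv::gam` object.
#' @export
fit_full_gam <- function(design, k = 4) {
  .check_design(design)
  mgcv::gam(ss ~ s(age, k = k, bs = "tp") + sex + motion,
            data = design, method = "REML")
}

#' Fit the covariates-only reduced model
#'
#' Linear model of slope on sex and motion only (no age term), the
#' baseline against which the age effect is measured.
#'
#' @inheritParams fit_full_gam
#' @return A fitted `mgcv::gam` object (no smooth terms, i.e. an ordinary
#'   linear fit).
#' @export
fit_reduced_model <- function(design) {
  .check_design(design)
  mgcv::gam(ss ~ sex + motion, data = design, method = "REML")
}

.model_r2 <- function(fit) {
  y <- fit$y
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Test the age effect of one parcel
#'
#' Returns the p-value of the age smooth (mgcv's standard approximate
#' test for penalized smooths, well calibrated under the null), the
#' chi-square deviance comparison of full against reduced model, and the
#' age-specific explained-variance difference
#' `delta_r2 = R2(full) - R2(reduced)` with `R2 = 1 - RSS/TSS`.
#'
#' @param full,reduced Fits from [fit_full_gam()] and
#'   [fit_reduced_model()] on identical rows.
#' @return list(p_age, delta_r2, r2_full, r2_reduced, chisq, df, edf).
#' @export
age_effect_test <- function(full, reduced) {
  if (length(full$y) != length(reduced$y) ||
      any(abs(full$y - reduced$y) > 0))
    stop("full and reduced models must be fit on identical rows",
         call. = FALSE)
  st <- summary(full)$s.table
  p_age <- unname(st[1, "p-value"])
  dev_diff <- stats::deviance(reduced) - stats::deviance(full)
  edf <- unname(st[1, "edf"])
  df <- max(sum(full$edf) - sum(reduced$edf), 1e-8)
  r2f <- .model_r2(full)
  r2r <- .model_r2(reduced)
  list(p_age = p_age, delta_r2 = r2f - r2r, r2_full = r2f, r2_reduced = r2r,
       chisq = dev_diff / max(full$sig2, 1e-300), df = df, edf = edf)
}

#' Fitted lifespan trajectory of one parcel
#'
#' Evaluates the full model's age smooth on a grid with sex and motion
#' held at their column means (reference levels for plotting and
#' clustering).
#'
#' @param full A [fit_full_gam()] fit.
#' @param age_grid Ages (years) at which to evaluate.
#' @return Numeric vector of fitted slope values on the grid.
#' @export
gam_trajectory <- function(full, age_grid) {
  mf <- full$model
  nd <- data.frame(age = age_grid, sex = mean(as.numeric(mf$sex)),
                   motion = mean(mf$motion))
  as.vector(stats::predict(full, newdata = nd))
}

#' Fit lifespan GAMs across all parcels
#'
#' For each parcel column of an SS matrix, fits the full and reduced
#' models, tests the age effect and evaluates the fitted trajectory.
#'
#' @param ss SS matrix, parcels x subjects (rownames = parcel ids).
#' @param subjects Subject table with age, sex, head_motion columns
#'   aligned to the SS columns.
#' @param age_grid Grid for trajectory evaluation (default 66 ages,
#'   20-85 y).
#' @param exclude Parcel ids to drop (e.g. low-SNR exclusion list).
#' @param k Basis dimension of the age smooth.
#' @return list: `table` = data.frame(parcel_id, p_age, q, significant,
#'   delta_r2, r2_full, r2_reduced, edf) with BH-adjusted q;
#'   `trajectories` = parcels x grid matrix; `age_grid`.
#' @export
parcel_gam_table <- function(ss, subjects, age_grid = seq(20, 85, length.out = 66),
                             exclude = NULL, k = 4) {
  ids <- rownames(ss)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ss)))
  keep <- !ids %in% as.character(exclude)
  ids <- ids[keep]
  ss <- ss[keep, , drop = FALSE]
  sex01 <- as.integer(subjects$sex == "M")
  rows <- vector("list", nrow(ss))
  traj <- matrix(NA_real_, nrow = nrow(ss), ncol = length(age_grid),
                 dimnames = list(ids, NULL))
  for (i in seq_len(nrow(ss))) {
    design <- data.frame(ss = ss[i, ], age = subjects$age, sex = sex01,
                         motion = subjects$head_motion)
    full <- fit_full_gam(design, k = k)
    reduced <- fit_reduced_model(design)
    tst <- age_effect_test(full, reduced)
    traj[i, ] <- gam_trajectory(full, age_grid)
    rows[[i]] <- data.frame(parcel_id = ids[i], p_age = tst$p_age,
                            delta_r2 = tst$delta_r2, r2_full = tst$r2_full,
                            r2_reduced = tst$r2_reduced, edf = tst$edf,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  fdr <- fdr_correct(tab$p_age)
  tab$q <- fdr$q
  tab$significant <- fdr$significant
  list(table = tab, trajectories = traj, age_grid = age_grid)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment across parcels; significance at q < alpha.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame(p, q, significant).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = q < alpha)
}

#' Trajectory matrix for clustering
#'
#' Selects the rows of a fitted-trajectory matrix (typically the parcels
#' surviving FDR) and mean-centers each row, so decline shape rather than
#' overall slope amplitude drives the clustering.
#'
#' @param trajectories Parcels x grid matrix from [parcel_gam_table()].
#' @param select Logical or id vector of rows to keep (default all).
#' @param center Mean-center rows (default TRUE).
#' @return The selected (centered) matrix.
#' @export
trajectory_curves <- function(trajectories, select = NULL, center = TRUE) {
  if (is.null(select)) select <- rep(TRUE, nrow(trajectories))
  out <- trajectories[select, , drop = FALSE]
  if (nrow(out) == 0) stop("no trajectories selected", call. = FALSE)
  if (center) out <- out - rowMeans(out)
  out
}
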