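#' Default pipeline configuration
#'
#' Every stage parameter at its reference default: analysis band
#' 0.015-0.145 Hz, smooth basis k = 4, fuzzifier 5, max 10000 iterations
#' at tolerance 1e-5, cluster candidates 2-15, 10000 spin rotations,
#' alpha = 0.05, MAD k = 3, SS reference cutoff 45 y, T2w atlas cutoff
#' 40 y.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, slopes = TRUE, gam = TRUE,
                  cluster = TRUE, spin = TRUE, ssyi = TRUE),
    cohort = list(),               # overrides for cohort_spec()
    band = c(0.015, 0.145),
    n_freq = 256,
    gam = list(k = 4, age_grid_lo = 20, age_grid_hi = 85, age_grid_n = 66),
    cluster = list(fuzzifier = 5, max_iter = 10000, tol = 1e-5,
                   candidates_lo = 2, candidates_hi = 15),
    spin = list(n_rotations = 10000),
    ssyi = list(mad_k = 3, ref_cutoff = 45, atlas_cutoff = 40,
                alpha = 0.05, min_age = 45),
    exclude_parcels = integer(0)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; fields present in the file override the defaults,
#' missing fields keep them.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @param seed Optional seed override applied after reading.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, seed = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be .yaml, .yml or .json", call. = FALSE)
  cfg <- utils::modifyList(unclass(default_config()), raw)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage_fail <- function(stage, id, e) {
  stop(sprintf("stage '%s' failed at '%s': %s", stage, id,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, slopes, gam, cluster, spin and ssyi in order (each
#' stage can be toggled in the config), writing every stage's outputs in
#' the documented TSV/JSON/NIfTI formats under `out_dir` plus a manifest
#' recording the config hash, seed and the md5 of every output file.
#' Outputs are byte-identical across reruns of the same config.
#'
#' @param config A [default_config()] / [read_config()] configuration.
#' @param out_dir Output run directory (created if missing).
#' @return The run directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_used.yaml"))
  st <- config$stages
  spec <- do.call(cohort_spec,
                  utils::modifyList(list(seed = config$seed), config$cohort))

  cohort <- NULL
  if (isTRUE(st$simulate)) {
    cohort <- tryCatch(generate_cohort(spec),
                       error = function(e) .stage_fail("simulate", "cohort", e))
    .write_tsv(cohort$subjects, file.path(out_dir, "subjects.tsv"))
    .write_tsv(cohort$geometry, file.path(out_dir, "geometry.tsv"))
    .write_tsv(cohort$trajectories, file.path(out_dir, "trajectories_true.tsv"))
    .write_tsv(cohort$metabolic, file.path(out_dir, "metabolic.tsv"))
    tsdir <- file.path(out_dir, "timeseries")
    dir.create(tsdir, showWarnings = FALSE)
    for (sid in names(cohort$timeseries)) {
      ts <- cohort$timeseries[[sid]]
      .write_tsv(as.data.frame(ts$series, check.names = FALSE),
                 file.path(tsdir, paste0(sid, "_timeseries.tsv")))
      .write_json(list(tr_seconds = ts$tr, valid_mask = as.integer(ts$valid)),
                  file.path(tsdir, paste0(sid, ".json")))
    }
    voldir <- file.path(out_dir, "t2w")
    dir.create(voldir, showWarnings = FALSE)
    for (sid in names(cohort$t2w$volumes))
      RNifti::writeNifti(RNifti::asNifti(cohort$t2w$volumes[[sid]]),
                         file.path(voldir, paste0(sid, "_t2w.nii")))
    RNifti::writeNifti(RNifti::asNifti(cohort$t2w$atlas_mean),
                       file.path(voldir, "atlas_mean.nii"))
    RNifti::writeNifti(RNifti::asNifti(cohort$t2w$atlas_sd),
                       file.path(voldir, "atlas_sd.nii"))
    RNifti::writeNifti(RNifti::asNifti(cohort$t2w$roi_mask + 0),
                       file.path(voldir, "flwm_roi.nii"))
  }

  subjects <- if (!is.null(cohort)) cohort$subjects
              else .read_tsv(file.path(out_dir, "subjects.tsv"))
  geometry <- if (!is.null(cohort)) cohort$geometry
              else .read_tsv(file.path(out_dir, "geometry.tsv"))

  ss_mat <- NULL
  if (isTRUE(st$slopes)) {
    ssdir <- file.path(out_dir, "ss")
    dir.create(ssdir, showWarnings = FALSE)
    maps <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[i]
      ts <- if (!is.null(cohort)) cohort$timeseries[[sid]]
            else read_subject_timeseries(file.path(out_dir, "timeseries"), sid)
      m <- tryCatch(
        subject_ss_map(ts$series, tr = ts$tr, valid = ts$valid,
                       geometry = geometry, band = config$band,
                       n_freq = config$n_freq),
        error = function(e) .stage_fail("slopes", sid, e))
      .write_tsv(m, file.path(ssdir, paste0(sid, "_ss.tsv")))
      maps[[i]] <- m
    }
    ss_mat <- do.call(cbind, lapply(maps, function(m) m$ss))
    rownames(ss_mat) <- maps[[1]]$parcel_id
    colnames(ss_mat) <- subjects$subject_id
    .write_tsv(data.frame(parcel_id = rownames(ss_mat), ss_mat,
                          check.names = FALSE),
               file.path(out_dir, "ss_matrix.tsv"))
  } else if (file.exists(file.path(out_dir, "ss_matrix.tsv"))) {
    ssd <- .read_tsv(file.path(out_dir, "ss_matrix.tsv"))
    ss_mat <- as.matrix(ssd[, -1, drop = FALSE])
    rownames(ss_mat) <- ssd$parcel_id
  }

  gam_res <- NULL
  if (isTRUE(st$gam)) {
    if (is.null(ss_mat)) stop("gam stage requires slope maps", call. = FALSE)
    grid <- seq(config$gam$age_grid_lo, config$gam$age_grid_hi,
                length.out = config$gam$age_grid_n)
    gam_res <- tryCatch(
      parcel_gam_table(ss_mat, subjects, age_grid = grid,
                       exclude = config$exclude_parcels, k = config$gam$k),
      error = function(e) .stage_fail("gam", "parcel_gam_table", e))
    .write_tsv(gam_res$table, file.path(out_dir, "parcel_gam.tsv"))
    .write_tsv(data.frame(parcel_id = rownames(gam_res$trajectories),
                          gam_res$trajectories, check.names = FALSE),
               file.path(out_dir, "trajectory_matrix.tsv"))
    .write_json(list(age_grid = grid), file.path(out_dir, "age_grid.json"))
  } else if (file.exists(file.path(out_dir, "parcel_gam.tsv"))) {
    tab <- .read_tsv(file.path(out_dir, "parcel_gam.tsv"))
    tj <- .read_tsv(file.path(out_dir, "trajectory_matrix.tsv"))
    tm <- as.matrix(tj[, -1, drop = FALSE])
    rownames(tm) <- tj$parcel_id
    gam_res <- list(table = tab, trajectories = tm)
  }

  if (isTRUE(st$cluster)) {
    if (is.null(gam_res)) stop("cluster stage requires gam outputs",
                               call. = FALSE)
    sel_rows <- gam_res$table$significant
    traj <- tryCatch(trajectory_curves(gam_res$trajectories, sel_rows),
                     error = function(e) .stage_fail("cluster", "selection", e))
    cands <- seq(config$cluster$candidates_lo, config$cluster$candidates_hi)
    sel <- tryCatch(
      silhouette_select(traj, candidates = cands,
                        fuzzifier = config$cluster$fuzzifier,
                        max_iter = config$cluster$max_iter,
                        tol = config$cluster$tol, seed = config$seed + 101L),
      error = function(e) .stage_fail("cluster", "silhouette_select", e))
    fit <- sel$memberships[[as.character(sel$chosen_n)]]
    memb <- data.frame(parcel_id = rownames(traj), fit$u,
                       label = fit$labels, tie = fit$tie, check.names = FALSE)
    names(memb)[2:(1 + ncol(fit$u))] <- paste0("u_", seq_len(ncol(fit$u)))
    .write_tsv(memb, file.path(out_dir, "membership.tsv"))
    .write_json(list(candidate_n = sel$candidate_n,
                     silhouette = sel$silhouette, chosen_n = sel$chosen_n),
                file.path(out_dir, "cluster_selection.json"))
    rsn_cols <- grep("^rsn_", names(geometry), value = TRUE)
    gidx <- match(as.integer(rownames(traj)), geometry$parcel_id)
    idxm <- rsn_correspondence_index(fit$u,
                                     as.matrix(geometry[gidx, rsn_cols]))
    .write_tsv(data.frame(rsn = sub("^rsn_", "", rsn_cols), idxm,
                          check.names = FALSE),
               file.path(out_dir, "rsn_index.tsv"))
  }

  if (isTRUE(st$spin)) {
    if (is.null(gam_res)) stop("spin stage requires gam outputs", call. = FALSE)
    metabolic <- if (!is.null(cohort)) cohort$metabolic
                 else .read_tsv(file.path(out_dir, "metabolic.tsv"))
    amap <- rep(NA_real_, nrow(geometry))
    amap[match(as.integer(gam_res$table$parcel_id), geometry$parcel_id)] <-
      gam_res$table$delta_r2
    bmap <- metabolic$cmrglc[match(geometry$parcel_id, metabolic$parcel_id)]
    sp <- tryCatch(
      spin_pvalue(amap, bmap, geometry,
                  n_rotations = config$spin$n_rotations,
                  seed = config$seed + 202L),
      error = function(e) .stage_fail("spin", "cmrglc", e))
    aok <- !geometry$medial_wall
    .write_json(list(rho = sp$rho_obs, p_spin = sp$p_spin,
                     n_rotations = sp$n_rotations, seed = sp$seed,
                     rho_cmro2 = spearman_map_correlation(
                       ifelse(aok, amap, NA), ifelse(aok, metabolic$cmro2, NA)),
                     rho_cbf = spearman_map_correlation(
                       ifelse(aok, amap, NA), ifelse(aok, metabolic$cbf, NA))),
                file.path(out_dir, "spin.json"))
    .write_tsv(data.frame(rotation = seq_along(sp$null_corrs),
                          rho = sp$null_corrs),
               file.path(out_dir, "spin_null.tsv"))
  }

  if (isTRUE(st$ssyi)) {
    if (is.null(ss_mat)) stop("ssyi stage requires slope maps", call. = FALSE)
    t2w <- if (!is.null(cohort)) cohort$t2w
           else read_t2w_dir(file.path(out_dir, "t2w"), subjects$subject_id)
    ref <- tryCatch(
      young_reference_map(ss_mat, subjects, cutoff = config$ssyi$ref_cutoff),
      error = function(e) .stage_fail("ssyi", "reference", e))
    ssyi <- vapply(seq_len(ncol(ss_mat)), function(j)
      compute_ssyi(ss_mat[, j], ref), numeric(1))
    flags <- mad_outliers(ssyi, k = config$ssyi$mad_k)
    norm <- lapply(t2w$volumes, normalize_t2w,
                   atlas_mean = t2w$atlas_mean, atlas_sd = t2w$atlas_sd)
    vx <- tryCatch(voxelwise_ssyi_correlation(norm, ssyi,
                                              alpha = config$ssyi$alpha),
                   error = function(e) .stage_fail("ssyi", "voxelwise", e))
    RNifti::writeNifti(RNifti::asNifti(vx$r),
                       file.path(out_dir, "ssyi_corr.nii"))
    RNifti::writeNifti(RNifti::asNifti(vx$mask + 0),
                       file.path(out_dir, "ssyi_mask.nii"))
    flwm <- vapply(norm, roi_mean_intensity, numeric(1), mask = vx$mask)
    recs <- data.frame(subject_id = subjects$subject_id, ssyi = ssyi,
                       outlier = flags, youthful = as.numeric(!flags),
                       age = subjects$age, gmv = subjects$gmv,
                       motion = subjects$head_motion, sex = subjects$sex,
                       flwm_t2w = flwm, stringsAsFactors = FALSE)
    .write_tsv(recs[, c("subject_id", "ssyi", "outlier", "flwm_t2w")],
               file.path(out_dir, "ssyi.tsv"))
    reg <- tryCatch(outlier_regression(recs, min_age = config$ssyi$min_age),
                    error = function(e) .stage_fail("ssyi", "regression", e))
    cf <- reg$coefficients
    .write_json(list(terms = rownames(cf), estimate = unname(cf[, 1]),
                     se = unname(cf[, 2]), t = unname(cf[, 3]),
                     p = unname(cf[, 4]), n_used = reg$n_used),
                file.path(out_dir, "regression.json"))
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    config_hash = .config_hash(config),
    seed = config$seed,
    stages = config$stages,
    n_subjects = nrow(subjects),
    n_parcels = nrow(geometry),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Read one subject's timeseries TSV + JSON sidecar
#'
#' @param dir Directory holding `<sid>_timeseries.tsv` and `<sid>.json`.
#' @param sid Subject id.
#' @return list(series, tr, valid) as produced by the generator.
#' @export
read_subject_timeseries <- function(dir, sid) {
  ser <- as.matrix(.read_tsv(file.path(dir, paste0(sid, "_timeseries.tsv"))))
  side <- jsonlite::read_json(file.path(dir, paste0(sid, ".json")),
                              simplifyVector = TRUE)
  list(series = ser, tr = side$tr_seconds,
       valid = as.logical(side$valid_mask))
}

#' Read the T2w volume directory written by the simulate stage
#'
#' @param dir The `t2w/` run subdirectory.
#' @param subject_ids Subject ids to load.
#' @return list(volumes, roi_mask, atlas_mean, atlas_sd) of plain arrays.
#' @export
read_t2w_dir <- function(dir, subject_ids) {
  rd <- function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(v), dim = dim(v))
  }
  volumes <- lapply(subject_ids, function(sid) rd(paste0(sid, "_t2w.nii")))
  names(volumes) <- subject_ids
  list(volumes = volumes, roi_mask = rd("flwm_roi.nii") > 0.5,
       atlas_mean = rd("atlas_mean.nii"), atlas_sd = rd("atlas_sd.nii"))
}

#' Summarize a completed run
#'
#' Collects the headline quantities of every completed stage into one
#' machine-readable JSON: significant-parcel fraction and explained-
#' variance range, chosen cluster count, CMRGlc association and its spin
#' p-value, outlier count, and the covariate regression table.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return The summary list, invisibly; written to `summary.json`.
#' @export
write_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path))
    stop("not a completed run: manifest.json missing", call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  enabled <- names(Filter(isTRUE, as.list(man$stages)))
  expect_file <- c(simulate = "subjects.tsv", slopes = "ss_matrix.tsv",
                   gam = "parcel_gam.tsv", cluster = "cluster_selection.json",
                   spin = "spin.json", ssyi = "ssyi.tsv")
  missing <- enabled[!file.exists(file.path(run_dir, expect_file[enabled]))]
  if (length(missing))
    stop("incomplete run; missing stage output(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- list(seed = man$seed, n_subjects = man$n_subjects,
              n_parcels = man$n_parcels)
  if ("gam" %in% enabled) {
    tab <- .read_tsv(file.path(run_dir, "parcel_gam.tsv"))
    out$n_parcels_tested <- nrow(tab)
    out$n_significant <- sum(tab$significant)
    out$frac_significant <- mean(tab$significant)
    out$delta_r2_min <- min(tab$delta_r2)
    out$delta_r2_max <- max(tab$delta_r2)
  }
  if ("cluster" %in% enabled) {
    sel <- jsonlite::read_json(file.path(run_dir, "cluster_selection.json"),
                               simplifyVector = TRUE)
    out$chosen_n <- sel$chosen_n
    out$silhouette <- sel$silhouette
  }
  if ("spin" %in% enabled) {
    sp <- jsonlite::read_json(file.path(run_dir, "spin.json"),
                              simplifyVector = TRUE)
    out$rho_cmrglc <- sp$rho
    out$p_spin <- sp$p_spin
    out$rho_cmro2 <- sp$rho_cmro2
    out$rho_cbf <- sp$rho_cbf
  }
  if ("ssyi" %in% enabled) {
    sy <- .read_tsv(file.path(run_dir, "ssyi.tsv"))
    out$n_outliers <- sum(sy$outlier)
    reg <- jsonlite::read_json(file.path(run_dir, "regression.json"),
                               simplifyVector = TRUE)
    out$regression <- reg
  }
  .write_json(out, file.path(run_dir, "summary.json"))
  invisible(out)
}
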