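test_that("subject table is deterministic, respects ranges and outlier rates", {
  spec <- cohort_spec(seed = 7)
  t1 <- generate_subject_table(spec)
  t2 <- generate_subject_table(spec)
  expect_identical(t1, t2)
  expect_true(all(t1$age >= 18 & t1$age <= 88))
  expect_true(all(t1$head_motion >= 0))
  expect_true(all(t1$outlier[t1$age <= 45] == FALSE))

  none <- generate_subject_table(cohort_spec(n_subjects = 100,
                                             outlier_frac = 0, seed = 3))
  expect_identical(sum(none$outlier), 0L)

  big <- generate_subject_table(cohort_spec(n_subjects = 400,
                                            outlier_frac = 0.1, seed = 11))
  n_old <- sum(big$age > 45)
  bounds <- qbinom(c(0.005, 0.995), n_old, 0.1)
  expect_gte(sum(big$outlier), bounds[1])
  expect_lte(sum(big$outlier), bounds[2])
})

test_that("invalid cohort spec fields raise errors naming the field", {
  expect_error(cohort_spec(n_frames = 32), "n_frames")
  expect_error(cohort_spec(tr = 0), "tr")
  expect_error(cohort_spec(age_range = c(80, 30)), "age_range")
  expect_error(cohort_spec(censor_rate = 1.2), "censor_rate")
  expect_error(cohort_spec(outlier_frac = -0.1), "outlier_frac")
  expect_error(cohort_spec(noise_floor = -1), "noise_floor")
})

test_that("parcel geometry: unit centroids, normalized RSN rows, even spacing", {
  spec <- cohort_spec(n_parcels = 120, seed = 2)
  geo <- generate_parcel_geometry(spec)
  norms <- sqrt(geo$x^2 + geo$y^2 + geo$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  rsn <- as.matrix(geo[, grep("^rsn_", names(geo))])
  expect_true(all(abs(rowSums(rsn) - 1) < 1e-9))
  expect_true(any(geo$medial_wall))
  expect_lt(mean(geo$medial_wall), 0.2)
  # quasi-uniform lattice: nearest-neighbour spacing within 3x the median
  for (h in c("L", "R")) {
    cc <- as.matrix(geo[geo$hemisphere == h, c("x", "y", "z")])
    d <- as.matrix(dist(cc))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    expect_true(all(nn < 3 * median(nn)))
    expect_true(all(nn > median(nn) / 3))
  }
  expect_error(generate_parcel_geometry(cohort_spec(n_parcels = 8)),
               "n_parcels")
})

test_that("timeseries: censoring mask, flat white case, determinism", {
  spec0 <- cohort_spec(censor_rate = 0, seed = 4)
  subj <- generate_subject_table(spec0)[1, ]
  traj <- data.frame(parcel_id = 1, cluster = 1, baseline_slope = 5,
                     decline_rate = 0, onset_age = 20)
  fs <- generate_timeseries(subj, traj, spec0)
  expect_true(all(fs$valid))
  expect_length(fs$values, spec0$n_frames)

  # flat expected spectrum when s -> 0 and no floor: in-band periodogram
  # level should be close to 10^intercept at both band edges
  specw <- cohort_spec(censor_rate = 0, noise_floor = 0, seed = 9)
  trajw <- data.frame(parcel_id = 1, cluster = 1, baseline_slope = 0.5,
                      decline_rate = 0, onset_age = 20)
  set.seed(1)
  ss <- replicate(100, {
    f <- generate_timeseries(subj, trajw, specw, slope_offset = -0.5)
    fit_spectral_slope(psd_via_cosine_transform(censored_autocovariance(f)))$ss
  })
  expect_lt(abs(mean(ss)), 3 * sd(ss) / sqrt(length(ss)) + 0.05)

  expect_error(generate_timeseries(subj, traj, cohort_spec(noise_floor = -1)),
               "noise_floor")
})

test_that("whole-cohort generation is byte-deterministic given the seed", {
  spec <- cohort_spec(n_subjects = 5, n_parcels = 12, t2w_dim = 10, seed = 21)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
})

test_that("outlier permutation preserves the marginal slope distribution", {
  spec <- cohort_spec(n_parcels = 40, seed = 13)
  geo <- generate_parcel_geometry(spec)
  traj <- generate_trajectories(geo, spec)
  subj <- data.frame(subject_id = "a", age = 70, sex = "F",
                     head_motion = 0.1, gmv = 40000, outlier = TRUE)
  set.seed(5)
  out <- generate_subject_timeseries(subj, traj, spec, subject_sd = 0)
  expected <- target_slope(traj, 70, spec)
  expect_equal(sort(out$slopes), sort(pmax(expected, 0.5)), tolerance = 1e-12)
  # ranks actually move for a permuted subject
  expect_false(isTRUE(all.equal(out$slopes, pmax(expected, 0.5))))
})

test_that("covariates are generated independently of outlier status", {
  spec <- cohort_spec(n_subjects = 2000, outlier_frac = 0.5, seed = 17)
  tab <- generate_subject_table(spec)
  old <- tab[tab$age > 45, ]
  expect_gt(t.test(head_motion ~ outlier, data = old)$p.value, 0.01)
  expect_gt(t.test(gmv ~ outlier, data = old)$p.value, 0.01)
  expect_gt(chisq.test(table(old$sex, old$outlier))$p.value, 0.01)
})

test_that("metabolic maps track the young slope topography as designed", {
  spec0 <- cohort_spec(glc_noise = 0, seed = 3)
  geo <- generate_parcel_geometry(spec0)
  traj <- generate_trajectories(geo, spec0)
  maps0 <- generate_metabolic_maps(geo, traj, spec0)
  expect_equal(cor(maps0$cmrglc, traj$baseline_slope, method = "spearman"), 1)

  # default noise: correlation in (0.5, 0.9); CBF weaker than CMRGlc
  rho_glc <- rho_cbf <- numeric(25)
  for (i in seq_len(25)) {
    sp <- cohort_spec(seed = 100 + i)
    g <- generate_parcel_geometry(sp)
    tr <- generate_trajectories(g, sp)
    m <- generate_metabolic_maps(g, tr, sp)
    rho_glc[i] <- cor(m$cmrglc, tr$baseline_slope, method = "spearman")
    rho_cbf[i] <- cor(m$cbf, tr$baseline_slope, method = "spearman")
  }
  expect_gt(mean(rho_glc), 0.5)
  expect_lt(mean(rho_glc), 0.9)
  expect_lt(mean(rho_cbf), mean(rho_glc))
})

test_that("T2w volumes carry the planted FLWM effect and a young atlas", {
  spec <- cohort_spec(n_subjects = 60, t2w_dim = 12, seed = 19)
  tab <- generate_subject_table(spec)
  tab$outlier <- rep(c(TRUE, FALSE), length.out = 60)

  # zero noise: ROI mean differs by exactly lesion_effect
  spec0 <- cohort_spec(n_subjects = 60, t2w_dim = 12, t2w_noise_sd = 0,
                       seed = 19)
  v0 <- generate_t2w_volumes(tab, spec0)
  d0 <- mean(v0$volumes[[1]][v0$roi_mask]) - mean(v0$volumes[[2]][v0$roi_mask])
  expect_equal(d0, spec0$lesion_effect, tolerance = 1e-12)

  # zero lesion effect: ROI and background indistinguishable
  specnull <- cohort_spec(n_subjects = 60, t2w_dim = 12, lesion_effect = 0,
                          seed = 19)
  vn <- generate_t2w_volumes(tab, specnull)
  roi_vals <- unlist(lapply(vn$volumes[tab$outlier], function(v) v[vn$roi_mask]))
  bg_vals <- unlist(lapply(vn$volumes[tab$outlier], function(v) v[!vn$roi_mask]))
  expect_gt(t.test(roi_vals, bg_vals)$p.value, 0.01)

  # default effect detectable
  v <- generate_t2w_volumes(tab, spec)
  roi_means <- vapply(v$volumes, function(x) mean(x[v$roi_mask]), numeric(1))
  expect_lt(t.test(roi_means[tab$outlier], roi_means[!tab$outlier])$p.value,
            0.01)
  expect_identical(dim(v$atlas_mean), dim(v$volumes[[1]]))
})
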