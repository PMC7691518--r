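test_that("hormone curves peak in the right cycle windows with realistic dynamic range", {
  for (s in 1:5) {
    p <- generate_hormone_cycle(n_days = 30, seed = s)
    expect_true(p$day[which.max(p$estradiol)] %in% 10:14)
    expect_true(p$day[which.max(p$progesterone)] %in% 19:27)
    e_ratio <- max(p$estradiol) / min(p$estradiol)
    p_ratio <- max(p$progesterone) / min(p$progesterone)
    expect_true(e_ratio > 8 * 0.75 && e_ratio < 8 * 1.25)
    expect_true(p_ratio > 80 * 0.75 && p_ratio < 80 * 1.25)
    expect_gt(max(p$progesterone), 5) # ovulatory luteal rise
    expect_true(all(p$estradiol >= 0 & p$progesterone >= 0 & p$lh >= 0 & p$fsh >= 0))
  }
})

test_that("hormone generation is deterministic and noiseless curves are periodic", {
  expect_identical(generate_hormone_cycle(seed = 7), generate_hormone_cycle(seed = 7))
  p <- generate_hormone_cycle(n_days = 54, cycle_length = 27, noise_sd = 0, seed = 1)
  peaks1 <- which.max(p$estradiol[1:27])
  peaks2 <- which.max(p$estradiol[28:54])
  expect_lte(abs(peaks2 - peaks1), 1)
  expect_equal(p$progesterone[1:27], p$progesterone[28:54], tolerance = 1e-12)
})

test_that("hormone generator rejects degenerate parameters", {
  expect_error(generate_hormone_cycle(n_days = 2), class = "cyclecoh_parameter_error")
  bad <- default_peak_params()
  bad$estradiol$amps[1] <- -5
  expect_error(generate_hormone_cycle(peak_params = bad), class = "cyclecoh_parameter_error")
})

test_that("motion tracks progesterone at the target rank correlation on average", {
  rhos <- vapply(1:200, function(s) {
    p <- generate_hormone_cycle(seed = s)
    p <- generate_motion_series(p, target_rho = 0.42, mean_level = 0.13, seed = s + 5000)
    cor(p$mean_fwd, p$progesterone, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.32)
  expect_lte(mean(rhos), 0.52)
})

test_that("motion is positive, low on average, and decorrelated when asked", {
  p <- generate_motion_series(generate_hormone_cycle(seed = 3), seed = 4)
  expect_true(all(p$mean_fwd > 0))
  expect_lt(mean(p$mean_fwd), 0.13)
  rhos0 <- vapply(1:100, function(s) {
    p <- generate_motion_series(generate_hormone_cycle(seed = s), target_rho = 0, seed = s)
    cor(p$mean_fwd, p$progesterone, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos0)), 0.1)
  expect_error(generate_motion_series(p, target_rho = 1), class = "cyclecoh_parameter_error")
})

test_that("atlas fixture covers the requested networks and is deterministic", {
  atlas <- generate_atlas_fixture(seed = 5)
  expect_equal(nrow(atlas$partition), 99)
  expect_equal(sort(unique(atlas$partition$network)),
               sort(c("FCN", "DMN", "VAN", "DAN", "SMN", "Limbic")))
  expect_identical(atlas$partition, generate_atlas_fixture(seed = 5)$partition)
  one_each <- generate_atlas_fixture(n_nodes = 6, seed = 1)
  expect_true(all(table(one_each$partition$network) == 1))
  expect_error(generate_atlas_fixture(n_nodes = 3), class = "cyclecoh_parameter_error")
})

test_that("atlas voxel counts reproduce the labels under winner-take-all", {
  atlas <- generate_atlas_fixture(n_nodes = 30, seed = 9)
  recovered <- assign_parcel_networks(atlas$voxel_counts)
  expect_equal(recovered$network, atlas$partition$network)
})

test_that("realized coupling is symmetric, zero-diagonal and inside [0,1)", {
  study <- small_study(seed = 41)
  for (Cd in study$coupling) {
    expect_equal(Cd, t(Cd))
    expect_equal(unname(diag(Cd)), rep(0, nrow(Cd)))
    off <- Cd[upper.tri(Cd)]
    expect_true(all(off >= 0 & off < 1))
  }
})

test_that("coupling leaving [0,1) is reported as a parameter error with the edge", {
  atlas <- generate_atlas_fixture(n_nodes = 8, seed = 2)
  truth <- default_ground_truth(atlas$partition, n_designated = 0)
  truth <- plant_edge_effect(truth, cbind(1, 2), "progesterone", beta = -0.9, base = 0.3)
  panel <- generate_motion_series(generate_hormone_cycle(seed = 1), seed = 2)
  expect_error(
    generate_daily_timeseries(panel, truth, n_samples = 128, seed = 3),
    "edge",
    class = "cyclecoh_parameter_error"
  )
})

test_that("study generation is deterministic in the seed", {
  a <- small_study(seed = 77, n_days = 4, n_nodes = 8, n_samples = 128)
  b <- small_study(seed = 77, n_days = 4, n_nodes = 8, n_samples = 128)
  expect_identical(a$panel, b$panel)
  expect_identical(a$sessions[[3]]$signals, b$sessions[[3]]$signals)
  c <- small_study(seed = 78, n_days = 4, n_nodes = 8, n_samples = 128)
  expect_false(identical(a$sessions[[1]]$signals, c$sessions[[1]]$signals))
})

test_that("without planted effects, edgewise slopes on hormones center at zero", {
  study <- small_study(seed = 51, n_days = 12, n_nodes = 10, n_samples = 400,
                       n_designated = 0)
  stack <- coherence_stack(study$sessions, q = NA)
  fit <- edgewise_regression(stack, study$panel$progesterone)
  expect_lt(abs(mean(fit$beta)), 0.25)
  expect_gt(mean(abs(fit$stat) < 3), 0.9)
})

test_that("a strong negative planted effect produces anti-correlated coherence", {
  signs <- vapply(1:20, function(s) {
    atlas <- generate_atlas_fixture(n_nodes = 10, seed = s)
    truth <- default_ground_truth(atlas$partition, n_designated = 0)
    truth <- plant_edge_effect(truth, cbind(1, 2), "progesterone",
                               beta = -0.12, base = 0.55)
    panel <- generate_motion_series(generate_hormone_cycle(seed = s), seed = s)
    study <- generate_daily_timeseries(panel, truth, n_samples = 256, seed = s + 100)
    stack <- coherence_stack(study$sessions, q = NA)
    series <- vapply(stack, function(cm) cm$values[1, 2], numeric(1))
    cor(series, panel$progesterone)
  }, numeric(1))
  expect_gte(mean(signs < 0), 0.9)
})
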