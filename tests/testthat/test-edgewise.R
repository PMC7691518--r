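test_that("Z-scoring gives mean 0, SD 1 and is idempotent", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_series(z), z, tolerance = 1e-12)
  withr::with_seed(71, {
    x <- rnorm(40, 5, 3)
    expect_equal(zscore_series(x), (x - mean(x)) / sd(x), tolerance = 1e-12)
  })
  expect_error(zscore_series(rep(2, 10)), class = "cyclecoh_data_error")
})

test_that("edgewise regression recovers exact linear relationships", {
  n_days <- 12
  withr::with_seed(72, {
    h <- rnorm(n_days)
    stack <- lapply(seq_len(n_days), function(d) {
      M <- matrix(0, 3, 3)
      M[1, 2] <- M[2, 1] <- h[d] # edge equal to the hormone
      M[1, 3] <- M[3, 1] <- -h[d] # edge equal to minus the hormone
      M[2, 3] <- M[3, 2] <- rnorm(1)
      diag(M) <- 1
      list(day = d, values = M)
    })
    fit <- edgewise_regression(stack, h)
    expect_equal(fit$beta[fit$i == 1 & fit$j == 2], 1, tolerance = 1e-10)
    expect_equal(fit$beta[fit$i == 1 & fit$j == 3], -1, tolerance = 1e-10)
  })
})

test_that("edgewise regression matches the closed-form OLS oracle per edge", {
  withr::with_seed(73, {
    stack <- null_stack(15, 6, seed = 101)
    h <- rnorm(15)
    fit <- edgewise_regression(stack, h)
    x <- (h - mean(h)) / sd(h)
    xc <- x - mean(x)
    for (r in sample(nrow(fit), 8)) {
      y <- vapply(stack, function(m) m$values[fit$i[r], fit$j[r]], numeric(1))
      y <- (y - mean(y)) / sd(y)
      beta_hat <- sum(xc * (y - mean(y))) / sum(xc^2)
      res <- y - mean(y) - beta_hat * xc
      se_hat <- sqrt(sum(res^2) / (15 - 2) / sum(xc^2))
      expect_equal(fit$beta[r], beta_hat, tolerance = 1e-10)
      expect_equal(fit$se[r], se_hat, tolerance = 1e-10)
    }
  })
})

test_that("an exact hormone-tracking edge attains the minimum empirical p", {
  withr::with_seed(74, {
    n_days <- 10
    h <- rnorm(n_days)
    stack <- lapply(seq_len(n_days), function(d) {
      M <- matrix(runif(16), 4, 4)
      M <- (M + t(M)) / 2
      M[1, 2] <- M[2, 1] <- h[d]
      diag(M) <- 1
      list(day = d, values = M)
    })
    map <- permutation_null(stack, h, n_perm = 999, p_threshold = 0.01, seed = 5)
    expect_equal(map$emp_p[1, 2], 1 / 1000)
    expect_true(map$mask[1, 2])
  })
})

test_that("empirical p is invariant to monotone rescaling of the hormone", {
  stack <- null_stack(12, 5, seed = 102)
  h <- withr::with_seed(75, rnorm(12, 50, 9))
  a <- permutation_null(stack, h, n_perm = 200, p_threshold = 0.05, seed = 6)
  b <- permutation_null(stack, 3 * h - 100, n_perm = 200, p_threshold = 0.05, seed = 6)
  expect_equal(a$emp_p, b$emp_p, tolerance = 1e-12)
})

test_that("shrinking the threshold never adds edges to the mask", {
  stack <- null_stack(12, 6, seed = 103)
  h <- withr::with_seed(76, rnorm(12))
  loose <- permutation_null(stack, h, n_perm = 400, p_threshold = 0.05, seed = 7)
  strict <- permutation_null(stack, h, n_perm = 400, p_threshold = 0.01, seed = 7)
  expect_true(all(loose$mask[strict$mask]))
})

test_that("unattainable thresholds and degenerate hormones are parameter errors", {
  stack <- null_stack(8, 4, seed = 104)
  expect_error(permutation_null(stack, rnorm(8), n_perm = 500, p_threshold = 0.001),
               class = "cyclecoh_parameter_error")
  expect_error(permutation_null(stack, rep(1, 8), n_perm = 1000, p_threshold = 0.01),
               class = "cyclecoh_parameter_error")
})

test_that("nodal strengths sum signed suprathreshold statistics per node", {
  stat <- matrix(0, 4, 4)
  stat[1, 2] <- stat[2, 1] <- 2.0
  stat[1, 3] <- stat[3, 1] <- 3.0
  stat[1, 4] <- stat[4, 1] <- -1.5
  mask <- stat != 0
  map <- structure(list(stat = stat, mask = mask), class = "edgewise_map")
  s <- nodal_association_strength(map)
  expect_equal(s$positive_strength[1], 5.0)
  expect_equal(s$negative_strength[1], 1.5)
  expect_equal(s$positive_strength[4], 0)
  expect_equal(s$negative_strength[4], 1.5)
  # nodes with no masked incident edges score (0, 0)
  map$mask[] <- FALSE
  s0 <- nodal_association_strength(map)
  expect_true(all(s0$positive_strength == 0 & s0$negative_strength == 0))
})

test_that("node strength totals double-count each masked edge once per endpoint", {
  stack <- null_stack(14, 8, seed = 105)
  h <- withr::with_seed(77, rnorm(14))
  map <- permutation_null(stack, h, n_perm = 200, p_threshold = 0.2, seed = 8)
  s <- nodal_association_strength(map)
  up <- upper.tri(map$stat)
  pos_edges <- sum(pmax(map$stat, 0)[up & map$mask])
  neg_edges <- sum(pmax(-map$stat, 0)[up & map$mask])
  expect_equal(sum(s$positive_strength), 2 * pos_edges, tolerance = 1e-10)
  expect_equal(sum(s$negative_strength), 2 * neg_edges, tolerance = 1e-10)
})

test_that("network strength summaries match a direct t-interval oracle", {
  withr::with_seed(78, {
    part <- new_partition_for_test(tibble::tibble(
      node_id = 1:10,
      network = rep(c("DMN", "DAN"), each = 5)
    ))
    strengths <- tibble::tibble(
      node_id = 1:10,
      positive_strength = abs(rnorm(10, 3)),
      negative_strength = abs(rnorm(10, 5))
    )
    summ <- network_strength_summary(strengths, part)
    x <- strengths$negative_strength[1:5] # DMN members
    row <- summ[summ$network == "DMN" & summ$direction == "negative", ]
    expect_equal(row$mean, mean(x), tolerance = 1e-12)
    half <- qt(0.975, 4) * sd(x) / sqrt(5)
    expect_equal(row$ci_low, mean(x) - half, tolerance = 1e-12)
    expect_equal(row$ci_high, mean(x) + half, tolerance = 1e-12)
  })
})

test_that("degenerate network summaries: equal strengths and singletons", {
  part <- new_partition_for_test(tibble::tibble(
    node_id = 1:4, network = c("DMN", "DMN", "DMN", "VAN")
  ))
  strengths <- tibble::tibble(
    node_id = 1:4,
    positive_strength = c(2, 2, 2, 7),
    negative_strength = c(1, 1, 1, 0)
  )
  summ <- network_strength_summary(strengths, part)
  dmn <- summ[summ$network == "DMN" & summ$direction == "positive", ]
  expect_equal(dmn$ci_low, dmn$ci_high) # zero-width interval
  van <- summ[summ$network == "VAN" & summ$direction == "positive", ]
  expect_true(is.na(van$ci_low)) # singleton: undefined CI
  expect_equal(van$mean, 7)
})
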