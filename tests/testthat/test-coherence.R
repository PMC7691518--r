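test_that("eigenvariate reduces to the (rescaled) series for degenerate inputs", {
  withr::with_seed(21, {
    x <- rnorm(100)
    one <- extract_eigenvariate(matrix(x, 1))
    expect_equal(abs(cor(one, x)), 1, tolerance = 1e-12)
    expect_equal(sd(one), 1, tolerance = 1e-12)
    dup <- extract_eigenvariate(rbind(x, x, x))
    expect_equal(abs(cor(dup, x)), 1, tolerance = 1e-12)
    expect_gt(cor(dup, x), 0) # sign-aligned with the voxel mean
  })
  expect_error(extract_eigenvariate(matrix(0, 3, 10)), class = "cyclecoh_data_error")
})

test_that("eigenvariate matches a power-iteration principal component oracle", {
  withr::with_seed(22, {
    X <- matrix(rnorm(5 * 200), 5, 200)
    ev <- extract_eigenvariate(X)
    Xc <- sweep(X, 1, rowMeans(X))
    # independent oracle: power iteration on the sample covariance of time courses
    v <- rnorm(200)
    for (i in 1:500) {
      v <- crossprod(Xc, Xc %*% v)
      v <- v / sqrt(sum(v^2))
    }
    expect_gte(abs(cor(ev, as.numeric(v))), 0.999)
  })
})

test_that("coherence is 1 for identical series and invariant to scale and offset", {
  withr::with_seed(23, {
    x <- rnorm(600)
    expect_equal(magnitude_squared_coherence(x, x, dt = 1, band = c(0.02, 0.4),
                                             segment_len = 64)$coherence, 1,
                 tolerance = 1e-10)
    expect_equal(magnitude_squared_coherence(x, -2 * x, dt = 1, band = c(0.02, 0.4),
                                             segment_len = 64)$coherence, 1,
                 tolerance = 1e-10)
    y <- rnorm(600)
    c0 <- magnitude_squared_coherence(x, y, dt = 1, band = c(0.02, 0.4),
                                      segment_len = 64)$coherence
    c1 <- magnitude_squared_coherence(5 * x + 3, y, dt = 1, band = c(0.02, 0.4),
                                      segment_len = 64)$coherence
    expect_equal(c0, c1, tolerance = 1e-10)
  })
  expect_error(magnitude_squared_coherence(rep(1, 100), rnorm(100), segment_len = 32),
               class = "cyclecoh_data_error")
})

test_that("pairwise and matrix coherence estimators agree", {
  withr::with_seed(24, {
    X <- matrix(rnorm(4 * 500), 4, 500)
    cm <- coherence_matrix(X, dt = 1, band = c(0.02, 0.4), segment_len = 64)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        cij <- magnitude_squared_coherence(X[i, ], X[j, ], dt = 1,
                                           band = c(0.02, 0.4), segment_len = 64)
        expect_equal(cm$C[i, j], cij$coherence, tolerance = 1e-10)
      }
    }
  })
})

test_that("BH mask matches examples and is monotone in q", {
  expect_equal(fdr_bh(c(0.001, 0.02, 0.03, 0.8), 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_true(fdr_bh(0.04, 0.05))
  withr::with_seed(25, {
    p <- runif(50)^2
    m1 <- fdr_bh(p, 0.01)
    m2 <- fdr_bh(p, 0.10)
    expect_true(all(m2[m1])) # everything rejected at the stricter level survives the looser
  })
  expect_error(fdr_bh(c(0.5, 1.2), 0.05), class = "cyclecoh_data_error")
})

test_that("daily coherence matrix is symmetric with unit diagonal and [0,1] entries", {
  study <- small_study(seed = 31)
  cm <- daily_coherence_matrix(study$sessions[[1]])
  expect_equal(cm$values, t(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, 12))
  off <- cm$values[upper.tri(cm$values)]
  expect_true(all(off >= 0 & off <= 1))
})

test_that("duplicated node signals keep a surviving near-unit edge", {
  study <- small_study(seed = 32)
  s <- study$sessions[[1]]
  s$signals[2, ] <- s$signals[1, ]
  cm <- daily_coherence_matrix(s)
  expect_gt(cm$values[1, 2], 0.99)
})

test_that("thresholding never increases an entry and zeroes sub-threshold edges", {
  study <- small_study(seed = 33)
  raw <- daily_coherence_matrix(study$sessions[[3]], q = NA)
  thr <- daily_coherence_matrix(study$sessions[[3]], q = 0.05)
  expect_true(all(thr$values <= raw$values + 1e-12))
  off <- thr$values[upper.tri(thr$values)]
  expect_true(all(off == 0 | off > 0)) # entries are either removed or untouched
  kept <- off > 0
  expect_equal(off[kept], raw$values[upper.tri(raw$values)][kept], tolerance = 1e-12)
})

test_that("coherence is invariant to per-node affine rescaling through the full stage", {
  study <- small_study(seed = 34)
  s <- study$sessions[[1]]
  s2 <- s
  s2$signals[4, ] <- -3.7 * s2$signals[4, ] + 11
  a <- daily_coherence_matrix(s, q = NA)
  b <- daily_coherence_matrix(s2, q = NA)
  expect_lt(max(abs(a$values - b$values)), 1e-10)
})

test_that("an independent-noise session keeps few edges at q = .05", {
  withr::with_seed(35, {
    X <- matrix(rnorm(25 * 833), 25, 833)
    cm <- daily_coherence_matrix(list(signals = X, dt = 0.72, day = 1), q = 0.05)
    frac <- mean(cm$values[upper.tri(cm$values)] > 0)
    expect_lte(frac, 0.05 + 0.03)
  })
})
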