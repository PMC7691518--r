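#' Generate a cyclic daily hormone panel
#'
#' Emulates the serum endocrinology of a complete ovulatory menstrual
#' cycle sampled once per day: estradiol is lowest during menses, rises to
#' a tall late-follicular peak (with a smaller secondary luteal rise), and
#' progesterone stays near baseline until ovulation before climbing to a
#' late-luteal maximum that exceeds 5 ng/mL. Curves are sums of Gaussian
#' bumps on the day axis, repeated with period `cycle_length`, with
#' multiplicative log-normal day-to-day noise. The default parameters give
#' roughly an eightfold dynamic range for estradiol and an eightyfold range
#' for progesterone across the cycle, with LH/FSH surging at ovulation.
#'
#' @param n_days Number of consecutive study days (>= 3).
#' @param cycle_length Cycle period in days.
#' @param peak_params Named list of per-hormone curve parameters; each entry
#'   has `baseline` (concentration at menses), `amps`, `days` and `widths`
#'   (vectors, one per Gaussian bump). See `default_peak_params()`.
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   noise, as a fraction of the noiseless value.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `hormone_panel` tibble with columns `day`, `estradiol`
#'   (pg/mL), `progesterone` (ng/mL), `lh` (mIU/mL), `fsh` (mIU/mL), and
#'   `mean_fwd` (mm, `NA` until filled by [generate_motion_series()]).
#' @export
#' @examples
#' panel <- generate_hormone_cycle(n_days = 30, seed = 1)
#' panel$day[which.max(panel$progesterone)]
generate_hormone_cycle <- function(n_days = 30, cycle_length = 27,
                                   peak_params = default_peak_params(),
                                   noise_sd = 0.05, seed = 1) {
  if (n_days < 3) abort_param("n_days must be >= 3")
  if (cycle_length <= 0) abort_param("cycle_length must be positive")
  for (h in names(peak_params)) {
    if (any(peak_params[[h]]$amps <= 0)) abort_param(sprintf("non-positive amplitude for %s", h))
  }
  day <- seq_len(n_days)
  phase <- ((day - 1) %% cycle_length) + 1
  curve <- function(p) {
    v <- rep(p$baseline, length(phase))
    for (k in seq_along(p$amps)) {
      v <- v + p$amps[k] * exp(-(phase - p$days[k])^2 / (2 * p$widths[k]^2))
    }
    v
  }
  seeds <- split_seed(seed, length(peak_params))
  vals <- purrr::imap(peak_params, function(p, nm) {
    v <- curve(p)
    if (noise_sd > 0) {
      i <- match(nm, names(peak_params))
      v <- with_seed(seeds[i], v * exp(rnorm(length(v), 0, noise_sd) - noise_sd^2 / 2))
    }
    pmax(v, 0)
  })
  panel <- tibble::tibble(
    day = day,
    estradiol = vals$estradiol,
    progesterone = vals$progesterone,
    lh = vals$lh,
    fsh = vals$fsh,
    mean_fwd = NA_real_
  )
  class(panel) <- c("hormone_panel", class(panel))
  panel
}

#' Default hormone curve parameters
#'
#' Calibrated to a 27-day ovulatory cycle: late-follicular estradiol peak
#' near day 12 (max ~240 pg/mL over a ~30 pg/mL menses baseline, an
#' approximately eightfold range) with a smaller luteal rise, a single
#' late-luteal progesterone peak near day 22 (max ~8.8 ng/mL over a
#' 0.11 ng/mL baseline, approximately eightyfold), and sharp midcycle LH
#' and FSH surges.
#'
#' @return Named list of curve parameters, one entry per hormone.
#' @export
default_peak_params <- function() {
  list(
    estradiol = list(baseline = 30, amps = c(210, 90), days = c(12, 21), widths = c(2, 3)),
    progesterone = list(baseline = 0.11, amps = 8.7, days = 22, widths = 3),
    lh = list(baseline = 4, amps = 40, days = 13, widths = 1),
    fsh = list(baseline = 5, amps = 8, days = 13, widths = 1.5)
  )
}

#' Fill the motion covariate as a rank-correlated copy of progesterone
#'
#' Head motion (per-session mean framewise displacement) is generated as a
#' log-normal series whose latent Gaussian is a noisy copy of the normal
#' scores of progesterone, giving a target Spearman rank correlation with
#' progesterone while keeping motion strictly positive with mean
#' `mean_level`. This reproduces the motion-progesterone confound structure
#' the residualization step is designed to remove.
#'
#' @param panel A `hormone_panel` (see [generate_hormone_cycle()]).
#' @param target_rho Target Spearman correlation with progesterone,
#'   |rho| < 1.
#' @param mean_level Expected mean framewise displacement in mm.
#' @param seed Integer seed.
#' @return The panel with `mean_fwd` filled.
#' @export
generate_motion_series <- function(panel, target_rho = 0.42,
                                   mean_level = 0.115, seed = 1) {
  if (abs(target_rho) >= 1) abort_param("|target_rho| must be < 1")
  if (mean_level <= 0) abort_param("mean_level must be positive")
  n <- nrow(panel)
  # Gaussian-copula construction: the Pearson correlation on the latent
  # scale that yields the requested Spearman correlation
  rho_p <- 2 * sin(pi * target_rho / 6)
  zr <- stats::qnorm((rank(panel$progesterone, ties.method = "average") - 0.5) / n)
  zr <- zr / sd(zr)
  latent <- with_seed(seed, rho_p * zr + sqrt(1 - rho_p^2) * rnorm(n))
  sig <- 0.25 # log-scale spread of daily motion
  panel$mean_fwd <- mean_level * exp(sig * latent - sig^2 / 2)
  panel
}

#' Generate a node-to-network atlas fixture
#'
#' Builds a parcel label table for `n_nodes` nodes spread across the named
#' networks (every network non-empty), together with per-parcel voxel label
#' counts in which the assigned network holds a strict plurality — a
#' self-consistent fixture for exercising winner-take-all assignment.
#'
#' @param n_nodes Number of parcels (>= number of networks).
#' @param network_names Networks to represent; the default is the six
#'   cerebral networks represented in the cerebellum.
#' @param voxels_per_parcel Total voxel count per parcel.
#' @param seed Integer seed.
#' @return A list with `partition` (a `network_partition` tibble of
#'   `node_id`, `network`) and `voxel_counts` (tibble of `parcel_id`,
#'   `network`, `voxels`).
#' @export
generate_atlas_fixture <- function(n_nodes = 99,
                                   network_names = c("FCN", "DMN", "VAN", "DAN", "SMN", "Limbic"),
                                   voxels_per_parcel = 40, seed = 1) {
  k <- length(network_names)
  if (n_nodes < k) abort_param("need at least one node per network")
  labels <- with_seed(split_seed(seed, 2)[1], {
    base <- rep(network_names, length.out = n_nodes)
    sample(base, n_nodes, replace = FALSE)
  })
  counts <- with_seed(split_seed(seed, 2)[2], {
    purrr::map_dfr(seq_len(n_nodes), function(i) {
      win <- labels[i]
      others <- setdiff(network_names, win)
      n_win <- ceiling(voxels_per_parcel * 0.6)
      rest <- voxels_per_parcel - n_win
      alloc <- if (rest > 0) {
        tabulate(sample(seq_along(others), rest, replace = TRUE), nbins = length(others))
      } else {
        rep(0L, length(others))
      }
      tibble::tibble(
        parcel_id = i,
        network = c(win, others),
        voxels = c(n_win, alloc)
      )
    })
  })
  partition <- new_network_partition(
    tibble::tibble(node_id = seq_len(n_nodes), network = labels)
  )
  list(partition = partition, voxel_counts = counts)
}

#' Default ground-truth coupling structure for a synthetic study
#'
#' Baseline inter-node coupling is block-structured on the network
#' partition (stronger within networks than between), and hormone effects
#' are planted on a designated set of edges: each designated edge's
#' coupling moves linearly with the standardized hormone. Designated edges
#' have their baseline recentred so the realized coupling stays inside
#' [0, 1) over the hormone's range.
#'
#' @param partition A `network_partition`.
#' @param base_within,base_between Baseline coupling for within- and
#'   between-network edges.
#' @param n_designated Number of edges carrying a planted effect.
#' @param effect_size Absolute coupling change per SD of hormone on
#'   designated edges; signs alternate across edges.
#' @param hormone Which hormone drives the designated edges
#'   (`"progesterone"` or `"estradiol"`).
#' @param designated_base Baseline coupling used on designated edges.
#' @param seed Integer seed (selects the designated edges).
#' @return A `ground_truth` list: `base_coupling`,
#'   `edge_beta_progesterone`, `edge_beta_estradiol` (symmetric
#'   zero-diagonal matrices), `designated` (tibble of edge, sign), and
#'   `network_labels`.
#' @export
default_ground_truth <- function(partition, base_within = 0.75, base_between = 0.50,
                                 n_designated = 20, effect_size = 0.12,
                                 hormone = "progesterone",
                                 designated_base = 0.55, seed = 1) {
  n <- nrow(partition)
  same <- outer(partition$network, partition$network, `==`)
  base <- ifelse(same, base_within, base_between)
  diag(base) <- 0
  bP <- matrix(0, n, n)
  bE <- matrix(0, n, n)
  designated <- NULL
  if (n_designated > 0) {
    eidx <- edge_index(n)
    n_designated <- min(n_designated, nrow(eidx))
    pick <- with_seed(seed, sample(nrow(eidx), n_designated))
    signs <- rep(c(-1, 1), length.out = n_designated)
    designated <- dplyr::mutate(eidx[pick, ], sign = signs, beta = signs * effect_size)
    B <- matrix(0, n, n)
    B[cbind(designated$i, designated$j)] <- designated$beta
    B <- B + t(B)
    if (hormone == "progesterone") bP <- B else bE <- B
    base[cbind(designated$i, designated$j)] <- designated_base
    base[cbind(designated$j, designated$i)] <- designated_base
  }
  structure(
    list(
      base_coupling = base,
      edge_beta_progesterone = bP,
      edge_beta_estradiol = bE,
      designated = designated,
      designated_hormone = if (n_designated > 0) hormone else NULL,
      network_labels = partition
    ),
    class = "ground_truth"
  )
}

#' Plant a hormone effect on a set of edges
#'
#' Adds `beta` (coupling change per SD of the hormone) to the chosen edges'
#' slope matrix, recentring their baseline coupling to `base` so the
#' realized coupling keeps inside [0, 1).
#'
#' @param truth A `ground_truth` object.
#' @param edges Two-column matrix or data frame of node index pairs.
#' @param hormone `"progesterone"` or `"estradiol"`.
#' @param beta Signed coupling change per SD of hormone (recycled).
#' @param base Baseline coupling for the affected edges.
#' @return The modified `ground_truth`.
#' @export
plant_edge_effect <- function(truth, edges, hormone, beta, base = 0.55) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) abort_param("edges must have two columns")
  edges <- edges[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  beta <- rep_len(beta, nrow(edges))
  slot <- paste0("edge_beta_", hormone)
  B <- truth[[slot]]
  B[edges] <- beta
  B[edges[, 2:1, drop = FALSE]] <- beta
  truth[[slot]] <- B
  truth$base_coupling[edges] <- base
  truth$base_coupling[edges[, 2:1, drop = FALSE]] <- base
  truth
}

#' Realized coupling matrix for one day
#'
#' @param truth A `ground_truth`.
#' @param zP,zE Standardized progesterone and estradiol for the day.
#' @return Symmetric zero-diagonal coupling matrix in [0, 1).
#' @export
realized_coupling <- function(truth, zP, zE) {
  C <- truth$base_coupling +
    truth$edge_beta_progesterone * zP +
    truth$edge_beta_estradiol * zE
  bad <- which(upper.tri(C) & (C < 0 | C >= 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_param(sprintf(
      "realized coupling leaves [0, 1) at edge (%d, %d): %.3f",
      bad[1, 1], bad[1, 2], C[bad[1, , drop = FALSE]]
    ))
  }
  diag(C) <- 0
  C
}

#' Generate daily node timeseries for a synthetic study
#'
#' For each day the panel's standardized hormones set a realized coupling
#' matrix `base + beta_P * z(P_d) + beta_E * z(E_d)`; node signals are then
#' drawn as a correlated low-frequency process — Gaussian innovations with
#' that correlation structure passed through a common AR(1) filter — plus
#' white measurement noise. Band-averaged coherence between two nodes
#' increases monotonically with their realized coupling (the mapping is
#' validated empirically, not analytically).
#'
#' @param panel A complete `hormone_panel` (motion filled).
#' @param truth A `ground_truth`.
#' @param n_samples Samples per session (>= 64); default 833, a 10-minute
#'   session at `dt = 0.72` s.
#' @param dt Sampling interval in seconds.
#' @param ar_phi AR(1) coefficient of the latent low-frequency sources.
#' @param noise_sd SD of additive white measurement noise (signal SD ~ 1).
#' @param seed Integer seed.
#' @return A `synthetic_study`: list with `panel`, `sessions` (per-day
#'   lists of `day`, `signals` node x sample matrix, `dt`), `truth`,
#'   `coupling` (per-day realized coupling matrices) and `seed`.
#' @export
generate_daily_timeseries <- function(panel, truth, n_samples = 833, dt = 0.72,
                                      ar_phi = 0.92, noise_sd = 0.15, seed = 1) {
  if (n_samples < 64) abort_param("n_samples must be >= 64")
  if (dt <= 0) abort_param("dt must be positive")
  n_days <- nrow(panel)
  n <- nrow(truth$base_coupling)
  zP <- zscore_series(panel$progesterone)
  zE <- zscore_series(panel$estradiol)
  seeds <- split_seed(seed, n_days)
  sessions <- vector("list", n_days)
  coupling <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    Cd <- realized_coupling(truth, zP[d], zE[d])
    Sigma <- Cd
    diag(Sigma) <- 1
    # On extreme hormone days the target coupling pattern may not be a
    # valid correlation matrix; project it to the nearest feasible one by
    # eigenvalue clipping (part of the empirical coupling-to-coherence
    # mapping, which is monotone but not exact by design).
    R <- tryCatch(chol(Sigma), error = function(e) {
      ed <- eigen(Sigma, symmetric = TRUE)
      lam <- pmax(ed$values, 1e-3)
      S <- ed$vectors %*% (lam * t(ed$vectors))
      D <- 1 / sqrt(diag(S))
      chol(S * outer(D, D) + diag(1e-10, n))
    })
    sessions[[d]] <- with_seed(seeds[d], {
      innov <- matrix(rnorm(n_samples * n), n_samples, n) %*% R
      s <- apply(innov, 2, function(e) {
        as.numeric(stats::filter(e * sqrt(1 - ar_phi^2), ar_phi, method = "recursive"))
      })
      x <- s + noise_sd * matrix(rnorm(n_samples * n), n_samples, n)
      list(day = panel$day[d], signals = t(x), dt = dt)
    })
    coupling[[d]] <- Cd
  }
  structure(
    list(panel = panel, sessions = sessions, truth = truth,
         coupling = coupling, seed = seed),
    class = "synthetic_study"
  )
}

#' Simulate a complete dense-sampling study
#'
#' One call wiring together the hormone cycle, the motion confound, the
#' atlas fixture, the ground-truth coupling structure and the daily
#' timeseries. All randomness derives from `seed`.
#'
#' @param n_days,n_nodes Study size; defaults emulate a 30-day, 99-node
#'   protocol.
#' @param seed Integer seed.
#' @param truth Optional `ground_truth` to use instead of
#'   [default_ground_truth()].
#' @param n_samples,dt Session length and sampling interval.
#' @param ... Passed to [default_ground_truth()].
#' @return A `synthetic_study` with an additional `partition` element.
#' @export
#' @examples
#' study <- simulate_study(n_days = 8, n_nodes = 12, n_samples = 128, seed = 1)
#' length(study$sessions)
simulate_study <- function(n_days = 30, n_nodes = 99, seed = 1, truth = NULL,
                           n_samples = 833, dt = 0.72, ...) {
  seeds <- split_seed(seed, 4)
  panel <- generate_hormone_cycle(n_days = n_days, seed = seeds[1])
  panel <- generate_motion_series(panel, seed = seeds[2])
  atlas <- generate_atlas_fixture(n_nodes = n_nodes, seed = seeds[3])
  if (is.null(truth)) {
    truth <- default_ground_truth(atlas$partition, seed = seeds[3], ...)
  }
  study <- generate_daily_timeseries(panel, truth, n_samples = n_samples,
                                     dt = dt, seed = seeds[4])
  study$partition <- atlas$partition
  study$seed <- seed
  study
}
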