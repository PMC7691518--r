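#' Z-transform a series
#'
#' @param values Numeric vector with at least 2 values and nonzero variance.
#' @return The vector standardized to mean 0 and sample SD 1.
#' @export
zscore_series <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2) abort_data("need at least 2 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort_data("zero-variance series cannot be Z-scored")
  (x - mean(x)) / s
}

# Day x edge matrix of upper-triangle coherence values from a stack of
# coherence matrices (coherence_matrix objects or plain matrices).
stack_to_edges <- function(stack) {
  mats <- lapply(stack, function(m) if (is.list(m)) m$values else m)
  n <- nrow(mats[[1]])
  Y <- do.call(rbind, lapply(mats, edges_from_mat))
  list(Y = Y, n_nodes = n, days = vapply(seq_along(stack), function(i) {
    d <- if (is.list(stack[[i]]) && !is.null(stack[[i]]$day)) stack[[i]]$day else i
    as.integer(if (is.na(d)) i else d)
  }, integer(1)))
}

#' Edgewise regression of day-by-day coherence on a hormone series
#'
#' For every unique node pair, the across-day coherence series is Z-scored
#' and regressed (ordinary least squares) on the standardized hormone
#' series, yielding a slope, its standard error, and the standardized test
#' statistic beta/SE. Edges whose coherence is constant across days (e.g.
#' always sub-threshold) cannot be standardized and are excluded (`NA`).
#'
#' @param coherence_stack List of per-day coherence matrices
#'   ([daily_coherence_matrix()] objects or plain symmetric matrices), in
#'   day order.
#' @param hormone Numeric per-day hormone vector (standardized internally).
#' @param rescore_edges Z-score each edge's across-day series before
#'   fitting (default `TRUE`).
#' @return A tibble with one row per unique edge: `i`, `j`, `beta`, `se`,
#'   `stat` (= beta/se).
#' @export
edgewise_regression <- function(coherence_stack, hormone, rescore_edges = TRUE) {
  st <- stack_to_edges(coherence_stack)
  n_days <- nrow(st$Y)
  if (n_days < 3) abort_param("need at least 3 days")
  if (length(hormone) != n_days) abort_param("hormone length must equal number of days")
  x <- zscore_series(hormone)
  fit <- edge_ols(st$Y, x, rescore_edges)
  ei <- edge_index(st$n_nodes)
  tibble::tibble(i = ei$i, j = ei$j, beta = fit$beta, se = fit$se, stat = fit$stat)
}

# Vectorized per-edge simple OLS on (optionally Z-scored) edge series.
edge_ols <- function(Y, x, rescore_edges = TRUE) {
  n <- nrow(Y)
  sds <- apply(Y, 2, sd)
  ok <- is.finite(sds) & sds > 0
  Yc <- sweep(Y, 2, colMeans(Y))
  if (rescore_edges) Yc[, ok] <- sweep(Yc[, ok, drop = FALSE], 2, sds[ok], `/`)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  beta <- as.numeric(xc %*% Yc) / Sxx
  rss <- pmax(colSums(Yc^2) - beta^2 * Sxx, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  stat <- beta / se
  beta[!ok] <- NA_real_
  se[!ok] <- NA_real_
  stat[!ok] <- NA_real_
  list(beta = beta, se = se, stat = stat, ok = ok, Yc = Yc, xc = xc, Sxx = Sxx)
}

#' Permutation-thresholded edgewise statistic map
#'
#' Fits [edgewise_regression()] and builds per-edge empirical null
#' distributions of the standardized statistic (beta/SE) by refitting all
#' edges under random permutations of the hormone's day labels (one shared
#' permutation per iteration, preserving cross-edge dependence). The
#' two-tailed empirical p-value uses the add-one correction
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, so the smallest
#' attainable p is `1/(n_perm + 1)`; `n_perm` must make `p_threshold`
#' attainable.
#'
#' @inheritParams edgewise_regression
#' @param n_perm Number of permutations (default 10000).
#' @param p_threshold Two-tailed empirical significance threshold
#'   (default 0.001).
#' @param seed Integer seed for the permutation stream.
#' @param hormone_name Label stored on the result.
#' @return An `edgewise_map`: list with node x node matrices `stat`,
#'   `emp_p`, `mask` (logical, `emp_p < p_threshold`), plus `hormone`,
#'   `n_perm`, `p_threshold`, and the per-edge tibble `edges`.
#' @export
permutation_null <- function(coherence_stack, hormone, n_perm = 10000,
                             p_threshold = 0.001, seed = 1,
                             rescore_edges = TRUE, hormone_name = "hormone") {
  if (n_perm < 1 / p_threshold - 1) {
    abort_param(sprintf(
      "p_threshold %.4g unattainable with %d permutations (need >= %d)",
      p_threshold, n_perm, ceiling(1 / p_threshold - 1)
    ))
  }
  if (sd(hormone) == 0) abort_param("constant hormone vector")
  st <- stack_to_edges(coherence_stack)
  n_days <- nrow(st$Y)
  if (length(hormone) != n_days) abort_param("hormone length must equal number of days")
  x <- zscore_series(hormone)
  fit <- edge_ols(st$Y, x, rescore_edges)
  t_obs <- abs(fit$stat)
  n_edges <- length(t_obs)
  exceed <- integer(n_edges)
  Yc <- fit$Yc
  ss_y <- colSums(Yc^2)
  xc <- fit$xc
  Sxx <- fit$Sxx
  chunk <- 500L
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      P <- t(vapply(seq_len(m), function(k) sample(xc), numeric(n_days)))
      B <- (P %*% Yc) / Sxx
      RSS <- pmax(sweep(-B^2 * Sxx, 2, ss_y, `+`), 0)
      Tp <- abs(B / sqrt(RSS / (n_days - 2) / Sxx))
      cmp <- sweep(Tp, 2, t_obs, `>=`)
      exceed <- exceed + colSums(cmp, na.rm = TRUE)
      done <- done + m
    }
  })
  emp_p <- (1 + exceed) / (n_perm + 1)
  emp_p[!fit$ok] <- NA_real_
  mask <- !is.na(emp_p) & emp_p < p_threshold
  ei <- edge_index(st$n_nodes)
  structure(
    list(
      hormone = hormone_name,
      stat = mat_from_edges(ifelse(fit$ok, fit$stat, 0), st$n_nodes),
      emp_p = mat_from_edges(ifelse(fit$ok, emp_p, 1), st$n_nodes, diag_value = 1),
      mask = mat_from_edges(mask, st$n_nodes) > 0,
      n_perm = n_perm,
      p_threshold = p_threshold,
      edges = tibble::tibble(
        i = ei$i, j = ei$j, beta = fit$beta, se = fit$se,
        stat = fit$stat, emp_p = emp_p, mask = mask
      )
    ),
    class = "edgewise_map"
  )
}

#' Signed nodal association strengths
#'
#' Per node, the sum of suprathreshold positive statistics and the sum of
#' absolute suprathreshold negative statistics over its incident masked
#' edges — the standard signed-strength summary of a thresholded statistic
#' map.
#'
#' @param map An `edgewise_map` from [permutation_null()].
#' @param partition Optional `network_partition`; when given, its network
#'   labels are attached to the output.
#' @return A tibble with `node_id`, `positive_strength`,
#'   `negative_strength` (and `network` when a partition is supplied).
#' @export
nodal_association_strength <- function(map, partition = NULL) {
  S <- map$stat * map$mask
  pos <- rowSums(pmax(S, 0))
  neg <- rowSums(pmax(-S, 0))
  out <- tibble::tibble(
    node_id = seq_len(nrow(S)),
    positive_strength = pos,
    negative_strength = neg
  )
  if (!is.null(partition)) out$network <- partition$network
  out
}

#' Network-level summary of nodal strengths
#'
#' Mean positive and negative nodal association strength per network with
#' 95% t-based confidence intervals across member nodes; single-node
#' networks report an undefined (NA) interval, empty networks are skipped
#' with a warning.
#'
#' @param strengths Output of [nodal_association_strength()].
#' @param partition A `network_partition` (ignored if `strengths` already
#'   carries a `network` column).
#' @return A tibble with `network`, `direction`, `mean`, `ci_low`,
#'   `ci_high`, `n_nodes`.
#' @export
network_strength_summary <- function(strengths, partition = NULL) {
  if (!"network" %in% names(strengths)) {
    if (is.null(partition)) abort_param("a partition is required")
    strengths <- dplyr::left_join(
      strengths, tibble::as_tibble(partition), by = "node_id"
    )
  }
  nets <- unique(strengths$network)
  long <- tidyr::pivot_longer(
    strengths,
    cols = c("positive_strength", "negative_strength"),
    names_to = "direction", values_to = "strength"
  ) |>
    dplyr::mutate(direction = sub("_strength$", "", .data$direction))
  empty <- setdiff(nets, unique(long$network[!is.na(long$strength)]))
  if (length(empty) > 0) warning("skipping empty networks: ", paste(empty, collapse = ", "))
  long |>
    dplyr::group_by(.data$network, .data$direction) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      mean = mean(.data$strength),
      .half = ci_half_width(.data$strength),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_low = .data$mean - .data$.half,
                  ci_high = .data$mean + .data$.half) |>
    dplyr::select(-".half")
}

ci_half_width <- function(x, level = 0.95) {
  m <- length(x)
  if (m < 2) return(NA_real_)
  qt(1 - (1 - level) / 2, df = m - 1) * sd(x) / sqrt(m)
}
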