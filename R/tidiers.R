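#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted topology model
#'
#' One row per model term in broom convention: the standardized hormone
#' slope with its SE, t statistic and p-values.
#'
#' @param x A `topology_model` from [fit_topology_model()].
#' @param ... Unused.
#' @return A tibble with columns `network`, `metric`, `hormone`, `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `p.value.fdr`.
#' @exportS3Method generics::tidy
tidy.topology_model <- function(x, ...) {
  tibble::tibble(
    network = x$network, metric = x$metric, hormone = x$hormone,
    term = x$hormone, estimate = x$beta, std.error = x$se,
    statistic = x$t, p.value = x$p_raw, p.value.fdr = x$p_fdr
  )
}

#' Model-level summary of a fitted topology model
#'
#' @param x A `topology_model`.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `adj.r.squared`,
#'   `statistic` (F), `df`, `df.residual`, `p.value`, `nobs`,
#'   `n.removed`.
#' @exportS3Method generics::glance
glance.topology_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, adj.r.squared = x$r2_adj,
    statistic = x$F, df = x$df1, df.residual = x$df2,
    p.value = x$p_raw, nobs = x$n_obs, n.removed = length(x$removed_days)
  )
}

#' @exportS3Method generics::tidy
tidy.topology_model_set <- function(x, ...) {
  res <- x$results
  res$removed_days <- NULL
  res
}

#' @exportS3Method generics::glance
glance.topology_model_set <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$results),
    n_significant_fdr = sum(x$results$p_fdr <= x$q),
    q = x$q
  )
}

#' @export
print.topology_model <- function(x, ...) {
  cat(sprintf(
    "<topology_model> %s %s ~ %s\n  beta = %.3f (SE %.3f), t = %.2f, F(%d, %d) = %.2f, p = %.4g, adj R^2 = %.2f\n  days removed: %s\n",
    x$network, x$metric, x$hormone, x$beta, x$se, x$t, x$df1, x$df2, x$F,
    x$p_raw, x$r2_adj,
    if (length(x$removed_days) == 0) "none" else paste(x$removed_days, collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d days x %d nodes, %d samples/session (dt = %.2f s), seed %s\n",
    length(x$sessions), nrow(x$sessions[[1]]$signals),
    ncol(x$sessions[[1]]$signals), x$sessions[[1]]$dt, format(x$seed)
  ))
  invisible(x)
}

#' @export
print.edgewise_map <- function(x, ...) {
  cat(sprintf(
    "<edgewise_map> hormone %s: %d/%d edges suprathreshold (p < %g, %d permutations)\n",
    x$hormone, sum(x$mask[upper.tri(x$mask)]), sum(upper.tri(x$mask)),
    x$p_threshold, x$n_perm
  ))
  invisible(x)
}

#' Plot daily hormone concentrations
#'
#' @param object A `hormone_panel`.
#' @param ... Unused.
#' @return A ggplot: one faceted panel per hormone (free y scales) plus
#'   motion, against study day.
#' @exportS3Method ggplot2::autoplot
autoplot.hormone_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"day",
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Study day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-network topology trajectories
#'
#' @param topology Output of [daily_topology()].
#' @return A ggplot of participation and efficiency by day, one colour per
#'   network.
#' @export
plot_topology <- function(topology) {
  long <- tidyr::pivot_longer(topology, c("participation", "efficiency"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value, colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Study day", y = NULL, colour = "Network") +
    ggplot2::theme_minimal()
}

#' Heatmap of an edgewise statistic map
#'
#' @param map An `edgewise_map`.
#' @param masked_only Show only suprathreshold edges.
#' @return A ggplot tile heatmap of beta/SE.
#' @export
plot_stat_map <- function(map, masked_only = TRUE) {
  S <- map$stat
  if (masked_only) S[!map$mask] <- NA
  df <- tibble::tibble(
    i = rep(seq_len(nrow(S)), times = ncol(S)),
    j = rep(seq_len(ncol(S)), each = nrow(S)),
    stat = as.vector(S)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$stat)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey95") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Node", y = "Node",
                  fill = expression(beta / SE),
                  title = sprintf("Edgewise associations: %s", map$hormone)) +
    ggplot2::theme_minimal()
}

#' Plot network strength summaries
#'
#' @param summary Output of [network_strength_summary()] (optionally with a
#'   `hormone` column, as produced by [run_pipeline()]).
#' @return A ggplot bar chart with 95% CI error bars.
#' @export
plot_network_strengths <- function(summary) {
  p <- ggplot2::ggplot(
    summary,
    ggplot2::aes(.data$network, .data$mean, fill = .data$direction)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "Mean nodal association strength",
                  fill = "Direction") +
    ggplot2::theme_minimal()
  if ("hormone" %in% names(summary)) p <- p + ggplot2::facet_wrap(~hormone, scales = "free_y")
  p
}
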