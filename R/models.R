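#' Flag outlier days by median absolute deviation of residuals
#'
#' Flags days whose residual lies more than `threshold` (normalized) MADs
#' from the median residual: `|r - median(r)| / (1.4826 * MAD) > threshold`
#' with the 1.4826 factor making the scale consistent with the SD under
#' normality (`normalized = FALSE` uses raw MAD multiples). When the MAD is
#' zero nothing is flagged.
#'
#' @param residuals Numeric per-day residual vector (>= 3 days).
#' @param threshold Number of MADs beyond which a day is flagged.
#' @param normalized Use the 1.4826 normal-consistency factor.
#' @return Integer vector of flagged day positions (possibly empty).
#' @export
#' @examples
#' mad_outlier_days(c(0.1, -0.1, 0.05, 8.0))
mad_outlier_days <- function(residuals, threshold = 3, normalized = TRUE) {
  r <- as.numeric(residuals)
  if (length(r) < 3) abort_param("need at least 3 days")
  scale <- mad(r, constant = if (normalized) 1.4826 else 1)
  if (scale == 0) return(integer(0))
  which(abs(r - median(r)) / scale > threshold)
}

#' Residualize a per-day metric on motion
#'
#' OLS residuals of the metric on an intercept plus the per-day mean
#' framewise displacement, removing the motion confound before hormone
#' models are fit. Constant motion carries no information: the centered
#' metric is returned with a warning.
#'
#' @param metric Numeric per-day metric vector.
#' @param motion Numeric per-day mean FWD vector, same length.
#' @return Numeric residual vector.
#' @export
residualize_on_motion <- function(metric, motion) {
  if (length(metric) != length(motion)) abort_param("metric and motion lengths differ")
  if (length(metric) < 3) abort_param("need at least 3 days")
  if (sd(motion) == 0) {
    warning("constant motion; returning centered metric")
    return(metric - mean(metric))
  }
  stats::residuals(lm(metric ~ motion))
}

#' Fit a network-topology hormone model
#'
#' The per-network model pipeline: (1) an initial fit of the metric on the
#' hormone is inspected for outlier days by the MAD rule
#' ([mad_outlier_days()]); (2) flagged days are removed; (3) remaining
#' metric and hormone values are Z-scored; (4) the metric is residualized
#' on motion ([residualize_on_motion()]); (5) a simple OLS regression of
#' the residualized metric on the standardized hormone is fit. Reported
#' are the standardized slope, its SE, t (= beta/SE), the two-sided p, the
#' model F (= t^2 for a single predictor) with its degrees of freedom, and
#' the adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - 2)`.
#'
#' @param metric,hormone,motion Numeric per-day vectors of equal length.
#' @param mad_threshold MAD multiples for the outlier screen; `NA` skips
#'   screening.
#' @param network,metric_name,hormone_name Labels stored on the result.
#' @return A `topology_model` object; see [tidy.topology_model()] and
#'   [glance.topology_model()].
#' @export
fit_topology_model <- function(metric, hormone, motion,
                               mad_threshold = 3,
                               network = NA_character_,
                               metric_name = NA_character_,
                               hormone_name = NA_character_) {
  n0 <- length(metric)
  if (length(hormone) != n0 || length(motion) != n0) abort_param("input lengths differ")
  if (n0 < 4) abort_data("need at least 4 days")
  removed <- integer(0)
  if (!is.na(mad_threshold)) {
    init <- lm(zscore_series(metric) ~ zscore_series(hormone))
    removed <- mad_outlier_days(stats::residuals(init), threshold = mad_threshold)
  }
  keep <- setdiff(seq_len(n0), removed)
  if (length(keep) < 4) abort_data("too few days left after outlier removal")
  y <- zscore_series(metric[keep])
  x <- zscore_series(hormone[keep])
  yr <- residualize_on_motion(y, motion[keep])
  fit <- lm(yr ~ x)
  sm <- summary(fit)
  n <- length(keep)
  beta <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tval <- beta / se
  r2 <- sm$r.squared
  structure(
    list(
      network = network, metric = metric_name, hormone = hormone_name,
      beta = beta, se = se, t = tval,
      p_raw = sm$coefficients[2, 4], p_fdr = NA_real_,
      F = tval^2, df1 = 1, df2 = n - 2,
      r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
      n_obs = n, removed_days = removed, fit = fit
    ),
    class = "topology_model"
  )
}

#' Adjusted R-squared from a single-predictor F statistic
#'
#' For a one-predictor model, `R^2 = F / (F + df2)` and adjusted
#' `R^2 = 1 - (1 - R^2)(n - 1)/(n - 2)` with `n = df2 + 2` — the identity
#' that lets a reported F(1, df2) be converted to the adjusted coefficient
#' of determination.
#'
#' @param f F statistic of the model.
#' @param df2 Denominator degrees of freedom.
#' @return Adjusted R-squared.
#' @export
#' @examples
#' adj_r2_from_f(10.82, 28) # ~0.25
adj_r2_from_f <- function(f, df2) {
  r2 <- f / (f + df2)
  n <- df2 + 2
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' Fit all network x metric x hormone topology models
#'
#' Runs [fit_topology_model()] for every combination of network, metric
#' (participation, efficiency) and hormone (estradiol, progesterone) in a
#' [daily_topology()] table, then fills BH-FDR-adjusted p-values across
#' the whole model family.
#'
#' @param topology Output of [daily_topology()].
#' @param panel A complete `hormone_panel` (days aligned with `topology`).
#' @param hormones Hormone columns of the panel to model.
#' @param mad_threshold Passed to [fit_topology_model()].
#' @param q FDR level across models.
#' @return A `topology_model_set`: list with `models` (named list of
#'   `topology_model`) and `results` (tidy tibble, one row per model,
#'   with `p_fdr` filled).
#' @export
fit_hormone_models <- function(topology, panel,
                               hormones = c("estradiol", "progesterone"),
                               mad_threshold = 3, q = 0.05) {
  stopifnot(all(c("day", "network", "participation", "efficiency") %in% names(topology)))
  panel <- dplyr::arrange(tibble::as_tibble(panel), .data$day)
  combos <- tidyr::expand_grid(
    network = unique(topology$network),
    metric = c("participation", "efficiency"),
    hormone = hormones
  )
  models <- purrr::pmap(combos, function(network, metric, hormone) {
    sub <- dplyr::arrange(topology[topology$network == network, ], .data$day)
    stopifnot(all(sub$day == panel$day))
    tryCatch(
      fit_topology_model(
        metric = sub[[metric]], hormone = panel[[hormone]],
        motion = panel$mean_fwd, mad_threshold = mad_threshold,
        network = network, metric_name = metric, hormone_name = hormone
      ),
      cyclecoh_data_error = function(e) {
        warning(sprintf("%s %s ~ %s not fit: %s", network, metric, hormone,
                        conditionMessage(e)), call. = FALSE)
        structure(
          list(network = network, metric = metric, hormone = hormone,
               beta = NA_real_, se = NA_real_, t = NA_real_,
               p_raw = NA_real_, p_fdr = NA_real_, F = NA_real_,
               df1 = 1, df2 = NA_integer_, r2 = NA_real_, r2_adj = NA_real_,
               n_obs = NA_integer_, removed_days = integer(0), fit = NULL),
          class = "topology_model"
        )
      }
    )
  })
  names(models) <- paste(combos$network, combos$metric, combos$hormone, sep = ".")
  set <- structure(list(models = models, q = q), class = "topology_model_set")
  set$results <- fdr_correct_models(purrr::map_dfr(models, tidy_model_row), q = q)
  set
}

tidy_model_row <- function(m) {
  tibble::tibble(
    network = m$network, metric = m$metric, hormone = m$hormone,
    beta = m$beta, se = m$se, t = m$t, p_raw = m$p_raw, p_fdr = m$p_fdr,
    F = m$F, df1 = m$df1, df2 = m$df2, r2_adj = m$r2_adj, n_obs = m$n_obs,
    removed_days = list(m$removed_days)
  )
}

#' BH-FDR correction across a family of fitted models
#'
#' @param results Tibble with a `p_raw` column (e.g. the `results` of
#'   [fit_hormone_models()]).
#' @param q FDR level recorded on the result (adjusted p-values do not
#'   depend on it).
#' @return The tibble with `p_fdr` filled with BH-adjusted p-values.
#' @export
fdr_correct_models <- function(results, q = 0.05) {
  if (nrow(results) == 0) abort_param("empty results")
  results$p_fdr <- p.adjust(results$p_raw, method = "BH")
  attr(results, "q") <- q
  results
}
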