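#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults used
#' throughout: the dyadic wavelet levels and the matching frequency band,
#' Welch parameters, the per-day edge FDR level, the permutation budget and
#' edgewise threshold, the MAD outlier rule, and the model-family FDR
#' level.
#'
#' @param scales MODWT levels retained (default 3:6).
#' @param dt Sampling interval in seconds.
#' @param band Frequency band in Hz; default derived from `scales`.
#' @param segment_len,overlap Welch parameters.
#' @param q_edge Per-day edge FDR level.
#' @param n_perm Permutations for the edgewise null.
#' @param p_threshold Edgewise empirical significance threshold.
#' @param mad_threshold MAD multiples for outlier screening.
#' @param q_models FDR level across topology models.
#' @param hormones Hormones modelled.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scales = 3:6, dt = 0.72, band = NULL,
                            segment_len = NULL, overlap = 0.5,
                            q_edge = 0.05, n_perm = 10000, p_threshold = 0.001,
                            mad_threshold = 3, q_models = 0.05,
                            hormones = c("estradiol", "progesterone"),
                            seed = 1) {
  for (lev in c(q_edge, p_threshold, q_models)) {
    if (lev <= 0 || lev >= 1) abort_param("significance levels must lie in (0, 1)")
  }
  if (length(scales) == 0) abort_param("scales must be non-empty")
  if (is.null(band)) band <- modwt_band_hz(scales, dt)
  structure(
    list(
      scales = scales, dt = dt, band = band, segment_len = segment_len,
      overlap = overlap, q_edge = q_edge, n_perm = n_perm,
      p_threshold = p_threshold, mad_threshold = mad_threshold,
      q_models = q_models, hormones = hormones, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a study — per-day FDR-thresholded coherence
#' matrices, per-hormone edgewise permutation maps and nodal strengths,
#' the per-day network topology table, and the motion-corrected hormone
#' models with family-wise FDR — and, when `out_dir` is given, writes all
#' stage artifacts plus a machine-readable run manifest.
#'
#' @param study A study list with `panel`, `sessions`, `partition` (from
#'   [simulate_study()] or [read_study()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for stage artifacts.
#' @param verbose Log stage progress to stderr.
#' @return A `pipeline_result`: list with `coherence` (per-day stack),
#'   `edgewise` (per-hormone `edgewise_map`), `strengths`,
#'   `network_strengths`, `topology`, `models` (a `topology_model_set`),
#'   `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  log_msg <- function(...) if (verbose) message(sprintf("[cyclecoh] %s", sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  panel <- study$panel
  partition <- study$partition

  log_msg("coherence: %d sessions, scales %s", length(study$sessions),
          paste(range(config$scales), collapse = "-"))
  stack <- stage("coherence", coherence_stack(
    study$sessions, dt = config$dt, scales = config$scales, band = config$band,
    segment_len = config$segment_len, overlap = config$overlap, q = config$q_edge
  ))

  seeds <- split_seed(config$seed, length(config$hormones))
  edgewise <- list()
  strengths <- list()
  net_strengths <- list()
  for (i in seq_along(config$hormones)) {
    h <- config$hormones[i]
    log_msg("edgewise: %s, %d permutations", h, config$n_perm)
    map <- stage("edgewise", permutation_null(
      stack, panel[[h]], n_perm = config$n_perm,
      p_threshold = config$p_threshold, seed = seeds[i], hormone_name = h
    ))
    edgewise[[h]] <- map
    strengths[[h]] <- nodal_association_strength(map, partition)
    net_strengths[[h]] <- dplyr::mutate(
      network_strength_summary(strengths[[h]]), hormone = h, .before = 1
    )
  }

  log_msg("topology: %d networks", length(unique(partition$network)))
  topology <- stage("topology", daily_topology(stack, partition))

  log_msg("models: %d combinations",
          length(unique(partition$network)) * 2 * length(config$hormones))
  models <- stage("models", fit_hormone_models(
    topology, panel, hormones = config$hormones,
    mad_threshold = config$mad_threshold, q = config$q_models
  ))

  result <- structure(
    list(
      coherence = stack, edgewise = edgewise, strengths = strengths,
      network_strengths = dplyr::bind_rows(net_strengths),
      topology = topology, models = models, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir, study)
  result
}

write_pipeline_result <- function(result, out_dir, study) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cdir <- file.path(out_dir, "coherence")
  dir.create(cdir, showWarnings = FALSE)
  for (cm in result$coherence) {
    write_tsv_matrix(cm$values, file.path(cdir, sprintf("coherence_%03d.tsv", cm$day)))
    jsonlite::write_json(
      list(day = cm$day, q = cm$qvalue_threshold, n_segments = cm$n_segments,
           band = cm$band),
      file.path(cdir, sprintf("coherence_%03d.json", cm$day)),
      auto_unbox = TRUE, digits = NA
    )
  }
  for (h in names(result$edgewise)) {
    map <- result$edgewise[[h]]
    write_tsv_matrix(map$stat, file.path(out_dir, sprintf("edgewise_stat_%s.tsv", h)))
    write_tsv_matrix(map$emp_p, file.path(out_dir, sprintf("edgewise_p_%s.tsv", h)))
    write_tsv_matrix(map$mask + 0, file.path(out_dir, sprintf("edgewise_mask_%s.tsv", h)))
    write_tsv_table(result$strengths[[h]], file.path(out_dir, sprintf("strengths_%s.tsv", h)))
  }
  write_tsv_table(result$network_strengths, file.path(out_dir, "network_strengths.tsv"))
  write_tsv_table(result$topology, file.path(out_dir, "topology.tsv"))
  res <- result$models$results
  res$removed_days <- vapply(res$removed_days, function(d) paste(d, collapse = ","), character(1))
  write_tsv_table(res, file.path(out_dir, "model_results.tsv"))
  jsonlite::write_json(
    purrr::discard(as.list(result$models$results), is.list),
    file.path(out_dir, "model_results.json"),
    digits = NA
  )
  manifest <- c(
    unclass(result$config),
    list(
      package_version = as.character(utils::packageVersion("cyclecoh")),
      r_version = R.version.string,
      n_days = length(result$coherence),
      n_nodes = nrow(result$coherence[[1]]$values),
      study_seed = if (is.null(study$seed)) NA else study$seed
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
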