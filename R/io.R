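# All tabular/matrix artifacts are written as TSV with a fixed
# 10-significant-digit float format so files are text-stable across
# platforms; configs and manifests are JSON.

fmt_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  out
}

write_tsv_matrix <- function(M, path) {
  lines <- apply(M, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  M <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(M) <- NULL
  M
}

write_tsv_table <- function(tbl, path) {
  tbl <- as.data.frame(tbl)
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], fmt_num)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hormone panel to TSV
#'
#' @param panel A `hormone_panel`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hormone_panel <- function(panel, path) {
  write_tsv_table(panel[, c("day", "estradiol", "progesterone", "lh", "fsh", "mean_fwd")], path)
}

#' Read a hormone panel from TSV
#'
#' @param path TSV file with columns day, estradiol, progesterone, lh,
#'   fsh, mean_fwd.
#' @return A `hormone_panel` tibble sorted by day.
#' @export
read_hormone_panel <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("day", "estradiol", "progesterone", "lh", "fsh", "mean_fwd")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort_data(sprintf("%s: missing columns %s", path, paste(missing, collapse = ", ")))
  }
  for (cc in setdiff(need, "mean_fwd")) {
    if (!is.numeric(tbl[[cc]]) || anyNA(tbl[[cc]])) {
      abort_data(sprintf("%s: non-numeric or missing values in column %s", path, cc))
    }
  }
  tbl <- dplyr::arrange(tbl[, need], .data$day)
  if (any(duplicated(tbl$day))) abort_data(sprintf("%s: duplicated days", path))
  class(tbl) <- c("hormone_panel", class(tbl))
  tbl
}

#' Write network labels to TSV
#'
#' @param partition A `network_partition`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_network_labels <- function(partition, path) {
  write_tsv_table(tibble::as_tibble(partition)[, c("node_id", "network")], path)
}

#' Read network labels from TSV
#'
#' @param path TSV file with columns node_id, network.
#' @return A `network_partition`.
#' @export
read_network_labels <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("node_id", "network") %in% names(tbl))) {
    abort_data(sprintf("%s: expected columns node_id, network", path))
  }
  new_network_partition(dplyr::arrange(tbl, .data$node_id))
}

#' Write a synthetic study to a directory
#'
#' Lays out a study the way [read_study()] expects it: `hormones.tsv`,
#' `labels.tsv`, one headerless node x sample `session_###.tsv` per day,
#' and (for synthetic studies) `ground_truth.json`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hormone_panel(study$panel, file.path(dir, "hormones.tsv"))
  if (!is.null(study$partition)) {
    write_network_labels(study$partition, file.path(dir, "labels.tsv"))
  }
  for (s in study$sessions) {
    write_tsv_matrix(s$signals, file.path(dir, sprintf("session_%03d.tsv", s$day)))
  }
  if (!is.null(study$truth)) {
    truth <- study$truth
    jsonlite::write_json(
      list(
        base_coupling = truth$base_coupling,
        edge_beta_progesterone = truth$edge_beta_progesterone,
        edge_beta_estradiol = truth$edge_beta_estradiol,
        designated = truth$designated
      ),
      file.path(dir, "ground_truth.json"),
      digits = NA
    )
  }
  jsonlite::write_json(
    list(dt = study$sessions[[1]]$dt, seed = study$seed,
         n_days = length(study$sessions),
         n_nodes = nrow(study$sessions[[1]]$signals)),
    file.path(dir, "study.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a study from a directory
#'
#' Loads the hormone panel, the per-session node x sample matrices and the
#' node-to-network labels, verifying that every panel day has a session,
#' that all sessions share the labels' node count, and that all values are
#' numeric. Sessions are returned sorted by day regardless of on-disk
#' order.
#'
#' @param dir Study directory (see [write_study()]).
#' @param dt Sampling interval in seconds, used when the directory has no
#'   `study.json` sidecar.
#' @return A list with `panel`, `sessions` and `partition`.
#' @export
read_study <- function(dir, dt = 0.72) {
  panel <- read_hormone_panel(file.path(dir, "hormones.tsv"))
  partition <- read_network_labels(file.path(dir, "labels.tsv"))
  meta_path <- file.path(dir, "study.json")
  if (file.exists(meta_path)) {
    dt <- jsonlite::read_json(meta_path)$dt
  }
  files <- list.files(dir, pattern = "^session_[0-9]+\\.tsv$", full.names = TRUE)
  days <- as.integer(sub("^session_0*([0-9]+)\\.tsv$", "\\1", basename(files)))
  missing <- setdiff(panel$day, days)
  if (length(missing) > 0) {
    abort_data(sprintf("%s: no session file for day(s) %s", dir, paste(missing, collapse = ", ")))
  }
  ord <- order(days)
  files <- files[ord]
  days <- days[ord]
  keep <- days %in% panel$day
  files <- files[keep]
  days <- days[keep]
  n_nodes <- nrow(partition)
  sessions <- purrr::map2(files, days, function(f, d) {
    M <- read_tsv_matrix(f)
    if (nrow(M) != n_nodes) {
      abort_data(sprintf("%s: %d rows but %d nodes in labels", f, nrow(M), n_nodes))
    }
    if (!is.numeric(M) || anyNA(M)) abort_data(sprintf("%s: non-numeric cells", f))
    list(day = d, signals = M, dt = dt)
  })
  list(panel = panel, sessions = sessions, partition = partition)
}
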