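#' Canonical seven-network order
#'
#' The fixed network order used for deterministic tie-breaking in
#' winner-take-all assignment (standard seven-network atlas numbering).
#'
#' @return Character vector of network names.
#' @export
canonical_networks <- function() {
  c("Visual", "SMN", "DAN", "VAN", "Limbic", "FCN", "DMN")
}

#' Winner-take-all network assignment of parcels
#'
#' Assigns each parcel to the functional network holding the plurality of
#' its voxel labels. Ties are broken deterministically by the canonical
#' network order ([canonical_networks()]), earliest wins.
#'
#' @param counts A data frame with columns `parcel_id`, `network`, and
#'   `voxels` (one row per parcel x network), or a named list of per-parcel
#'   named count vectors.
#' @return A `network_partition`: tibble with columns `node_id` and
#'   `network`, one row per parcel, ordered by `parcel_id`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   parcel_id = c(1, 1, 2), network = c("DMN", "VAN", "DAN"),
#'   voxels = c(10, 5, 50)
#' )
#' assign_parcel_networks(counts)
assign_parcel_networks <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- purrr::imap_dfr(counts, function(v, id) {
      tibble::tibble(parcel_id = as.integer(id), network = names(v), voxels = as.numeric(v))
    })
  }
  stopifnot(all(c("parcel_id", "network", "voxels") %in% names(counts)))
  if (nrow(counts) == 0) abort_data("empty voxel-count table")
  if (any(counts$voxels < 0)) abort_data("negative voxel counts")
  rank_tbl <- tibble::tibble(
    network = canonical_networks(),
    .tie_rank = seq_along(canonical_networks())
  )
  out <- counts |>
    dplyr::group_by(.data$parcel_id) |>
    dplyr::group_modify(function(df, key) {
      if (sum(df$voxels) == 0) {
        abort_data(sprintf("parcel %s has all-zero voxel counts", key$parcel_id))
      }
      df <- dplyr::left_join(df, rank_tbl, by = "network")
      df$.tie_rank[is.na(df$.tie_rank)] <- Inf
      df <- df[order(-df$voxels, df$.tie_rank), ]
      tibble::tibble(network = df$network[1])
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$parcel_id) |>
    dplyr::rename(node_id = "parcel_id")
  new_network_partition(out)
}

new_network_partition <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)[, c("node_id", "network")]
  ord <- canonical_networks()
  nets <- unique(tbl$network)
  nets <- c(intersect(ord, nets), setdiff(nets, ord))
  structure(tbl, networks = nets,
            class = c("network_partition", class(tbl)))
}

#' Group node indices by network
#'
#' @param partition A `network_partition` (see [assign_parcel_networks()])
#'   or any data frame with `node_id` and `network` columns.
#' @return Named list mapping each network to the integer positions (row
#'   indices in node order) of its member nodes; the lists are disjoint and
#'   jointly cover all nodes.
#' @export
group_nodes_by_network <- function(partition) {
  stopifnot(all(c("node_id", "network") %in% names(partition)))
  nets <- attr(partition, "networks")
  if (is.null(nets)) {
    ord <- canonical_networks()
    nets <- unique(partition$network)
    nets <- c(intersect(ord, nets), setdiff(nets, ord))
  }
  lapply(setNames(nets, nets), function(nm) which(partition$network == nm))
}
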