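#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats sd median mad fft lm coef pf pt qt rnorm runif setNames
#'   cor p.adjust quantile var complete.cases
#' @importFrom utils head tail
NULL

# Deterministic seed splitting: every stochastic routine takes one integer
# seed and derives independent substream seeds through this LCG step, so a
# single top-level seed reproduces a whole study.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.double(seed)) %% m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (48271 * s + 1) %% m
    out[i] <- s
  }
  as.integer(out)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

abort_param <- function(msg) stop(errorCondition(msg, class = c("cyclecoh_parameter_error", "cyclecoh_error")))
abort_data <- function(msg) stop(errorCondition(msg, class = c("cyclecoh_data_error", "cyclecoh_error")))

check_symmetric <- function(W, tol = 1e-8, what = "matrix") {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    abort_data(sprintf("%s must be a square matrix", what))
  }
  if (max(abs(W - t(W))) > tol) {
    abort_data(sprintf("%s must be symmetric", what))
  }
  invisible(TRUE)
}

# Unique upper-triangle edge index table for an n-node graph (i < j).
edge_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2])
}

# Rebuild a symmetric matrix from its upper-triangle values (column-major,
# the same order edges_from_mat extracts).
mat_from_edges <- function(values, n, diag_value = 0) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- values
  M <- M + t(M)
  diag(M) <- diag_value
  M
}

edges_from_mat <- function(M) M[upper.tri(M)]
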