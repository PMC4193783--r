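#' Tidy a simulation trace into a long per-cell table
#'
#' One row per (record, cell): time, cell identity, fate, misspecified
#' flag, area and centroid.
#'
#' @param x A `potts_trace`.
#' @param ... Unused.
#' @return A tibble with columns `mcs`, `cell`, `type`, `misspecified`
#'   (when available), `area`, `x`, `y`.
#' @export
tidy.potts_trace <- function(x, ...) {
  nrec <- nrow(x$summary)
  N <- ncol(x$area)
  cx <- as.vector(x$cx)
  cy <- as.vector(x$cy)
  out <- tibble::tibble(
    mcs = rep(x$summary$mcs, N),
    cell = rep(seq_len(N), each = nrec),
    area = as.vector(x$area),
    x = cx,
    y = cy
  )
  dplyr::left_join(out, x$cells0, by = "cell")[
    , c("mcs", "cell", intersect(c("type", "region", "misspecified"),
                                 names(x$cells0)), "area", "x", "y")]
}

#' One-row summary of a simulation trace
#'
#' @param x A `potts_trace`.
#' @param ... Unused.
#' @return A tibble: run length, number of records, initial and final
#'   cluster count, acceptance rate.
#' @export
glance.potts_trace <- function(x, ...) {
  tibble::tibble(
    n_mcs = x$n_mcs, cadence = x$cadence, n_records = nrow(x$summary),
    initial_n_clusters = x$summary$n_clusters[1],
    final_n_clusters = utils::tail(x$summary$n_clusters, 1),
    accept_rate = x$accept_rate, crossing_mcs = x$crossing_mcs
  )
}

#' Per-run table of a scenario ensemble
#'
#' @param x A `potts_ensemble`.
#' @param ... Unused.
#' @return The per-run tibble (`x$runs`).
#' @export
tidy.potts_ensemble <- function(x, ...) x$runs

#' Per-condition summary of a scenario ensemble
#'
#' @param x A `potts_ensemble`.
#' @param ... Unused.
#' @return The per-parameter-combination summary tibble.
#' @export
glance.potts_ensemble <- function(x, ...) x$summary
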