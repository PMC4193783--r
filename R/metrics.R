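#' Count same-type clusters
#'
#' A cluster is a connected group of cells of the same type: connected
#' components of the cell-adjacency graph restricted to same-type edges,
#' where two cells are adjacent iff any of their sites are 4-neighbours.
#' Correct sorting means the count equals the number of cell types.
#'
#' @param sys A `potts_system`.
#' @return An integer cluster count.
#' @examples
#' count_clusters(make_fixture("french_flag")) # 4
#' @export
count_clusters <- function(sys) {
  cpm_count_clusters_cpp(sys$labels, as.integer(sys$cells$type))
}

#' Classify a run as correct / stable and extract its sorting time
#'
#' A run is *correct* if the recorded cluster count reaches `n_t` at some
#' time after `t_gate` (0 for standard runs; 500 MCS for delayed-adhesion
#' runs, so transient pre-onset coincidences are not credited); the
#' *sorting time* `t_s` is the first such time. A correct run is *stable*
#' if every recorded count from `t_s` to the end equals `n_t`. Breakups
#' shorter than the recording cadence are invisible, so subsampling can
#' only overstate stability and understate correctness.
#'
#' @param trace A `potts_trace` from [run_mcs()].
#' @param n_t Number of cell types.
#' @param t_gate Times `<= t_gate` are ignored when looking for `n_t`
#'   clusters.
#' @return A one-row tibble: `correct`, `stable`, `t_s`, `t_end`,
#'   `initial_n_clusters`.
#' @export
classify_run <- function(trace, n_t = 4, t_gate = 0) {
  s <- if (inherits(trace, "potts_trace")) trace$summary else trace
  if (is.null(s$mcs) || is.null(s$n_clusters) || nrow(s) == 0)
    stop("empty trace: need records with `mcs` and `n_clusters`")
  hit <- s$mcs > t_gate & s$n_clusters == n_t
  correct <- any(hit)
  t_s <- if (correct) min(s$mcs[hit]) else NA_real_
  stable <- correct && all(s$n_clusters[s$mcs >= t_s] == n_t)
  tibble::tibble(correct = correct, stable = stable, t_s = t_s,
                 t_end = max(s$mcs), initial_n_clusters = s$n_clusters[1])
}

#' Summarize an ensemble of runs
#'
#' Fraction of correct runs `F_C`, fraction of stable runs among correct
#' `F_S` (undefined, and flagged, when no run is correct), and the mean and
#' standard error of the sorting time over correct runs.
#'
#' @param runs Either a data frame with logical columns `correct`, `stable`
#'   and numeric `t_s` (one row per run, as from [classify_run()]), or a
#'   list of `potts_trace` objects.
#' @param n_t,t_gate Used to classify traces when `runs` is a list.
#' @return A one-row tibble: `n_runs`, `n_correct`, `f_correct`,
#'   `f_stable`, `f_stable_defined`, `mean_t_s`, `se_t_s`.
#' @examples
#' summarize_ensemble(tibble::tibble(
#'   correct = rep(TRUE, 10), stable = rep(c(TRUE, FALSE), c(2, 8)),
#'   t_s = rep(1000, 10)))
#' @export
summarize_ensemble <- function(runs, n_t = 4, t_gate = 0) {
  if (is.list(runs) && !is.data.frame(runs))
    runs <- dplyr::bind_rows(lapply(runs, classify_run, n_t = n_t,
                                    t_gate = t_gate))
  if (nrow(runs) == 0) stop("need at least one run")
  nc <- sum(runs$correct)
  ts <- runs$t_s[runs$correct]
  tibble::tibble(
    n_runs = nrow(runs), n_correct = nc,
    f_correct = nc / nrow(runs),
    f_stable = if (nc > 0) sum(runs$stable) / nc else NA_real_,
    f_stable_defined = nc > 0,
    mean_t_s = if (nc > 0) mean(ts) else NA_real_,
    se_t_s = if (nc > 1) sd(ts) / sqrt(nc) else NA_real_
  )
}

#' Cell-size variation across types
#'
#' Ratio of the standard deviation to the mean of the per-type mean cell
#' areas (population standard deviation over the `n_t` type means by
#' default). Zero when all types share the same mean area; grows when one
#' type is squeezed, e.g. near the morphogen source at strong chemotaxis.
#'
#' @param cells A cell table with columns `type` and `area` (e.g.
#'   `sys$cells`, or one time slice of [tidy()] on a trace).
#' @param n_t Number of types expected; a missing type is flagged with a
#'   warning and `NA` is returned.
#' @param population Use the population (divide by `n_t`) rather than the
#'   sample standard deviation.
#' @return The size-variation ratio (a single number).
#' @export
size_variation <- function(cells, n_t = 4, population = TRUE) {
  means <- dplyr::summarise(dplyr::group_by(cells, .data$type),
                            m = mean(.data$area))$m
  if (length(means) < n_t) {
    warning("not all ", n_t, " types are present; size variation undefined")
    return(NA_real_)
  }
  s <- if (population) sqrt(mean((means - mean(means))^2)) else sd(means)
  s / mean(means)
}

#' Per-cell mean speeds from a trace
#'
#' Speed is the mean Euclidean centroid displacement per `window` MCS,
#' estimated from trace records spaced `window` apart; reported with each
#' cell's type and misspecified flag so correctly- and wrongly-specified
#' populations can be compared.
#'
#' @param trace A `potts_trace`.
#' @param window Displacement window in MCS; must be a multiple of the
#'   trace cadence.
#' @return A tibble: `cell`, `type`, `misspecified` (if available),
#'   `speed` (sites per window), `n_steps`.
#' @export
cell_speeds <- function(trace, window = 100) {
  stopifnot(inherits(trace, "potts_trace"))
  if (window %% trace$cadence != 0)
    stop("`window` must be a multiple of the trace cadence (",
         trace$cadence, ")")
  keep <- which(trace$summary$mcs %% window == 0)
  if (length(keep) < 2) stop("trace too short for this window")
  cx <- trace$cx[keep, , drop = FALSE]
  cy <- trace$cy[keep, , drop = FALSE]
  disp <- sqrt(diff(cx)^2 + diff(cy)^2)
  out <- trace$cells0
  out$speed <- colMeans(disp)
  out$n_steps <- nrow(disp)
  out[, intersect(c("cell", "type", "misspecified", "speed", "n_steps"),
                  names(out))]
}

#' Lifetimes of the correctly sorted state
#'
#' Durations of the maximal recorded intervals during which the cluster
#' count equals `n_t`; a single-record visit counts one cadence.
#'
#' @param trace A `potts_trace`.
#' @param n_t Number of cell types.
#' @return A tibble with columns `start`, `end`, `lifetime` (MCS); zero
#'   rows if the sorted state is never reached.
#' @export
cluster_lifetimes <- function(trace, n_t = 4) {
  s <- trace$summary
  runs <- rle(s$n_clusters == n_t)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- runs$values
  tibble::tibble(start = s$mcs[starts[ok]], end = s$mcs[ends[ok]],
                 lifetime = s$mcs[ends[ok]] - s$mcs[starts[ok]] +
                   trace$cadence)
}

#' Boundary-crossing (merging) time in the 16-cell fixture
#'
#' The 16-cell system (4 x 4 cells; 7 of type 1, 9 of type 2, with the
#' marked type-2 cell inside the type-1 block next to the straight
#' interface) probes how fast a cell in contact with both like and unlike
#' cells integrates into its own type's region: the first MCS at which the
#' marked cell's centroid crosses the initial interface column, averaged
#' over independent runs. This time decreases with the adhesion magnitude
#' `j`. Runs that never cross within `horizon` are capped there, flagged,
#' and excluded from the mean.
#'
#' @param j Differential-adhesion magnitude.
#' @param n_runs Number of independent runs.
#' @param horizon Cap in MCS per run.
#' @param ... Extra arguments to [potts_params()] (e.g. `temp`).
#' @return A one-row tibble: `j`, `n_runs`, `n_crossed`, `mean_crossing`,
#'   `se_crossing`; per-run times in the `runs` list-column.
#' @export
merging_time <- function(j, n_runs = 100, horizon = 5000, ...) {
  times <- vapply(seq_len(n_runs), function(i) {
    sys <- make_fixture("merge16", j = j, ...)
    tr <- run_mcs(sys, horizon, cadence = 0,
                  monitor = list(cell = attr(sys, "marked_cell"),
                                 x = attr(sys, "boundary_x"), stop = TRUE))
    if (is.na(tr$crossing_mcs)) NA_real_ else as.numeric(tr$crossing_mcs)
  }, numeric(1))
  crossed <- !is.na(times)
  tibble::tibble(
    j = j, n_runs = n_runs, n_crossed = sum(crossed),
    mean_crossing = if (any(crossed)) mean(times[crossed]) else NA_real_,
    se_crossing = if (sum(crossed) > 1)
      sd(times[crossed]) / sqrt(sum(crossed)) else NA_real_,
    runs = list(tibble::tibble(
      run = seq_len(n_runs), crossed = crossed,
      crossing_mcs = ifelse(crossed, times, horizon)))
  )
}

#' Does the initial cluster count influence the sorting outcome?
#'
#' Per parameter combination: a two-sample t-test (pooled variance)
#' comparing the initial cluster counts of correct vs incorrect runs
#' (requires at least two runs in each group), and a Spearman correlation
#' test of initial cluster count against sorting time over correct runs
#' (requires at least three correct runs). Combinations failing a gate are
#' flagged untestable for that test.
#'
#' @param runs A data frame with one row per run: grouping columns `mu0`
#'   and `j`, plus `initial_n_clusters`, `correct`, `t_s`.
#' @return A tibble keyed by (`mu0`, `j`) with test p-values and
#'   testability flags.
#' @export
initial_cluster_stats <- function(runs) {
  need <- c("mu0", "j", "initial_n_clusters", "correct", "t_s")
  if (!all(need %in% names(runs)))
    stop("`runs` needs columns ", paste(need, collapse = ", "))
  one <- function(d) {
    a <- d$initial_n_clusters[d$correct]
    b <- d$initial_n_clusters[!d$correct]
    t_testable <- length(a) >= 2 && length(b) >= 2
    t_p <- if (t_testable)
      t.test(a, b, var.equal = TRUE)$p.value else NA_real_
    ts <- d$t_s[d$correct]
    s_testable <- length(a) >= 3
    if (s_testable) {
      ct <- suppressWarnings(cor.test(a, ts, method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); s_p <- ct$p.value
    } else {
      rho <- NA_real_; s_p <- NA_real_
    }
    tibble::tibble(n_correct = length(a), n_incorrect = length(b),
                   t_testable = t_testable, t_p = t_p,
                   spearman_testable = s_testable, spearman_rho = rho,
                   spearman_p = s_p)
  }
  dplyr::reframe(dplyr::group_by(runs, .data$mu0, .data$j),
                 one(dplyr::pick(dplyr::everything())))
}
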