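#' Small deterministic test systems
#'
#' Hand-checkable configurations used throughout the tests and the merging
#' experiment:
#' * `"two_cell"`: two like-type 7x7 cells side by side (membrane
#'   fluctuation / detailed-balance checks);
#' * `"merge16"`: 16 cells in a 4x4 arrangement, 7 of type 1 and 9 of type
#'   2 - the left two cell columns are type 1 except the marked cell
#'   (column 2, row 2), a type-2 cell sitting against the straight type
#'   interface; attributes `marked_cell` and `boundary_x` give the marked
#'   identity and the interface column;
#' * `"french_flag"`: the standard 100-cell grid with perfect fates (four
#'   bands, 4 clusters);
#' * `"random100"`: the standard grid with uniform-random fates (error ratio 1).
#'
#' @param kind One of `"two_cell"`, `"merge16"`, `"french_flag"`,
#'   `"random100"`.
#' @param ... Arguments passed to [potts_params()] (e.g. `j`, `mu0`).
#' @return A `potts_system`.
#' @examples
#' count_clusters(make_fixture("french_flag"))
#' @export
make_fixture <- function(kind = c("two_cell", "merge16", "french_flag",
                                  "random100"), ...) {
  kind <- match.arg(kind)
  switch(kind,
    two_cell = {
      g <- grid_spec(2, 1)
      lay <- cell_layout(g, n_t = 2)
      lay$type <- c(1L, 1L)
      lay$misspecified <- FALSE
      init_cells(g, potts_params(n_t = 2, ...), fates = lay)
    },
    merge16 = {
      g <- grid_spec(4, 4)
      lay <- cell_layout(g, n_t = 2)
      lay$type <- ifelse(lay$col <= 2, 1L, 2L)
      marked <- which(lay$col == 2 & lay$row == 2)
      lay$type[marked] <- 2L
      lay$misspecified <- lay$cell == marked
      sys <- init_cells(g, potts_params(n_t = 2, ...), fates = lay,
                        field = matrix(0, g$width, g$height))
      attr(sys, "marked_cell") <- marked
      # interface between tile columns 2 and 3: last site of column 2 + 1/2
      attr(sys, "boundary_x") <- 1 + 2 * g$cell_size + 0.5
      sys
    },
    french_flag = init_cells(grid_spec(), potts_params(...), r = 0),
    random100 = init_cells(grid_spec(), potts_params(...), r = 1)
  )
}

#' Named experiment scenarios
#'
#' Pre-registered scenario definitions covering the in-silico experiments:
#' chemotaxis-only sweeps (`"chemotaxis"`, plus `"chemo_attract"` /
#' `"chemo_repel"` for one-signed responses and `"chemotaxis_large"` for
#' the 210-cell grid), differential-adhesion-only sweeps (`"adhesion"`,
#' `"adhesion_uniform"` for the equal-dislike contact matrix), the combined
#' two-mechanism phase sweep (`"combined"`), the 16-cell merging experiment
#' (`"merging"`), noisy-gradient sweeps (`"noise_eta"`, `"noise_j"`), and
#' chemotaxis with delayed adhesion onset under noise (`"delayed"`). The
#' `"full"` profile runs the published scale; `"smoke"` is a reduced
#' profile (fewer, shorter runs) with the same conditions.
#'
#' @param name Scenario name (see [scenario_names()]).
#' @param profile `"full"` or `"smoke"`.
#' @return A `potts_scenario` list understood by [run_scenario()].
#' @export
scenario <- function(name = scenario_names(), profile = c("full", "smoke")) {
  name <- match.arg(name)
  profile <- match.arg(profile)
  smoke <- profile == "smoke"
  base <- list(name = name, profile = profile, grid = grid_spec(), r = 1,
               mu0 = 0, j = 0, mu_mode = "bipolar", j_mode = "graded",
               eta = 0, burn_in = 50000, n_mcs = 100000, n_runs = 10,
               cadence = 100, t_gate = 0, schedule_fun = NULL,
               kind = "sorting", horizon = NA, require_unsorted = FALSE)
  sweep_mu <- c(0.25, 0.5, 0.75, 1, 1.5)
  sweep_j <- c(0.25, 0.5, 1, 2, 4)
  s <- switch(name,
    chemotaxis = within_list(base, {
      mu0 <- if (smoke) c(0.75, 1.5) else sweep_mu
      if (smoke) { n_runs <- 5; n_mcs <- 30000 }
    }),
    chemo_attract = within_list(base, {
      mu_mode <- "attract_only"
      mu0 <- if (smoke) c(0.75, 1.5) else sweep_mu
      if (smoke) { n_runs <- 5; n_mcs <- 30000 }
    }),
    chemo_repel = within_list(base, {
      mu_mode <- "repel_only"
      mu0 <- if (smoke) c(0.75, 1.5) else sweep_mu
      if (smoke) { n_runs <- 5; n_mcs <- 30000 }
    }),
    chemotaxis_large = within_list(base, {
      grid <- grid_spec(30, 7)
      mu0 <- if (smoke) c(0.75, 1.5) else sweep_mu
      if (smoke) { n_runs <- 3; n_mcs <- 30000 }
    }),
    adhesion = within_list(base, {
      r <- default_error_ratio()
      require_unsorted <- TRUE
      j <- if (smoke) c(0.25, 1, 4) else sweep_j
      n_mcs <- if (smoke) 100000 else 200000
      n_runs <- if (smoke) 10 else 30
    }),
    adhesion_uniform = within_list(base, {
      r <- default_error_ratio()
      require_unsorted <- TRUE
      j_mode <- "uniform"
      j <- if (smoke) c(0.25, 1, 4) else c(0.25, 1, 4)
      n_mcs <- if (smoke) 100000 else 200000
      n_runs <- if (smoke) 10 else 30
    }),
    combined = within_list(base, {
      mu0 <- if (smoke) c(0.25, 0.75, 1.5) else c(0, 0.25, 0.5, 0.75, 1.5)
      j <- if (smoke) c(0, 0.25) else c(0, 0.25, 0.5, 1, 1.5)
      if (smoke) { n_runs <- 3; n_mcs <- 20000 }
    }),
    merging = within_list(base, {
      kind <- "merging"
      j <- c(0.25, 1, 4)
      n_runs <- if (smoke) 30 else 100
      horizon <- 5000
    }),
    noise_eta = within_list(base, {
      mu0 <- 0.75; j <- 0.25
      eta <- c(1, 3, 10, 30)
      if (smoke) { n_runs <- 2; n_mcs <- 5000; burn_in <- 2000 }
    }),
    noise_j = within_list(base, {
      mu0 <- 0.75; eta <- 10
      j <- c(0.25, 0.5, 1, 1.5)
      if (smoke) { n_runs <- 2; n_mcs <- 5000; burn_in <- 2000 }
    }),
    delayed = within_list(base, {
      mu0 <- 0.75
      eta <- c(1, 3, 10, 30)
      n_mcs <- 2000
      t_gate <- 500
      schedule_fun <- function() data.frame(mcs = 500, j = 1.5)
      if (smoke) { n_runs <- 3; burn_in <- 2000 }
    })
  )
  structure(s, class = "potts_scenario")
}

within_list <- function(base, expr) {
  env <- list2env(base, parent = parent.frame())
  eval(substitute(expr), env)
  as.list(env)[names(base)]
}

#' @rdname scenario
#' @export
scenario_names <- function() c("chemotaxis", "chemo_attract", "chemo_repel",
                               "chemotaxis_large", "adhesion",
                               "adhesion_uniform", "combined", "merging",
                               "noise_eta", "noise_j", "delayed")

#' Run a scenario ensemble
#'
#' Executes `n_runs` independently seeded runs for every parameter
#' combination of the scenario, classifies each run, and summarizes the
#' ensemble per combination. Per-run seeds are derived deterministically
#' from `seed_base`, so re-running with the same seed reproduces every
#' trace bit-identically. If `out_dir` is given, per-run results are
#' appended to `runs.csv` there and already-persisted runs are skipped on
#' resume.
#'
#' @param scn A [scenario()].
#' @param seed_base Integer base seed.
#' @param out_dir Optional output directory for persisted results.
#' @param keep_traces Keep the full `potts_trace` objects (memory!).
#' @return A `potts_ensemble` list: `runs` (one row per run), `summary`
#'   (per parameter combination, via [summarize_ensemble()]), `scenario`,
#'   and optionally `traces`.
#' @examples
#' \donttest{
#' scn <- scenario("merging", "smoke")
#' ens <- run_scenario(scn, seed_base = 1)
#' ens$summary
#' }
#' @export
run_scenario <- function(scn, seed_base = 1, out_dir = NULL,
                         keep_traces = FALSE) {
  stopifnot(inherits(scn, "potts_scenario"))
  combos <- expand.grid(mu0 = scn$mu0, j = scn$j, eta = scn$eta,
                        KEEP.OUT.ATTRS = FALSE)
  runs_file <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "runs.csv")
  }
  done <- if (!is.null(runs_file) && file.exists(runs_file))
    utils::read.csv(runs_file) else NULL
  rows <- list()
  traces <- list()
  for (ci in seq_len(nrow(combos))) {
    cb <- combos[ci, ]
    for (run in seq_len(scn$n_runs)) {
      seed <- run_seed(seed_base, ci, run)
      if (!is.null(done) && any(done$seed == seed)) {
        rows[[length(rows) + 1L]] <- done[done$seed == seed, ][1, ]
        next
      }
      t0 <- proc.time()[["elapsed"]]
      set.seed(seed)
      if (scn$kind == "merging") {
        mt <- merging_time(j = cb$j, n_runs = 1, horizon = scn$horizon)
        row <- tibble::tibble(
          scenario = scn$name, mu0 = cb$mu0, j = cb$j, eta = cb$eta,
          run = run, seed = seed, correct = NA, stable = NA, t_s = NA_real_,
          initial_n_clusters = NA_integer_,
          crossing_mcs = mt$runs[[1]]$crossing_mcs[1],
          crossed = mt$runs[[1]]$crossed[1],
          accept_rate = NA_real_,
          wall_s = proc.time()[["elapsed"]] - t0)
      } else {
        par <- potts_params(j = cb$j, j_mode = scn$j_mode, mu0 = cb$mu0,
                            mu_mode = scn$mu_mode)
        gp <- gradient_params(eta = cb$eta)
        field <- if (cb$eta > 0) {
          f <- noisy_gradient(scn$grid, gp)
          evolve_noisy(f, scn$burn_in)
        } else closed_form_gradient(scn$grid, gp)
        sched <- if (!is.null(scn$schedule_fun)) scn$schedule_fun()
        sys <- init_cells(scn$grid, par, r = scn$r, field = field,
                          require_unsorted = scn$require_unsorted)
        tr <- run_mcs(sys, scn$n_mcs, cadence = scn$cadence,
                      schedule = sched)
        cls <- classify_run(tr, n_t = par$n_t, t_gate = scn$t_gate)
        row <- tibble::tibble(
          scenario = scn$name, mu0 = cb$mu0, j = cb$j, eta = cb$eta,
          run = run, seed = seed, correct = cls$correct,
          stable = cls$stable, t_s = cls$t_s,
          initial_n_clusters = cls$initial_n_clusters,
          crossing_mcs = NA_real_, crossed = NA,
          accept_rate = tr$accept_rate,
          wall_s = proc.time()[["elapsed"]] - t0)
        if (keep_traces) traces[[length(traces) + 1L]] <- tr
      }
      rows[[length(rows) + 1L]] <- row
      if (!is.null(runs_file)) {
        new_file <- !file.exists(runs_file)
        utils::write.table(row, runs_file, sep = ",", row.names = FALSE,
                           col.names = new_file, append = !new_file)
      }
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- if (scn$kind == "merging") {
    dplyr::summarise(dplyr::group_by(runs, .data$j),
      n_runs = dplyr::n(), n_crossed = sum(.data$crossed),
      mean_crossing = mean(.data$crossing_mcs[.data$crossed]),
      .groups = "drop")
  } else {
    dplyr::reframe(dplyr::group_by(runs, .data$mu0, .data$j, .data$eta),
                   summarize_ensemble(dplyr::pick(dplyr::everything())))
  }
  structure(list(runs = runs, summary = summary, scenario = scn,
                 traces = if (keep_traces) traces),
            class = "potts_ensemble")
}

run_seed <- function(seed_base, combo, run) {
  (as.integer(seed_base) %% 1000L) * 1000003L + combo * 4096L + run
}

#' @exportS3Method base::print
print.potts_ensemble <- function(x, ...) {
  cat("<potts_ensemble> scenario '", x$scenario$name, "' (",
      x$scenario$profile, "), ", nrow(x$runs), " runs\n", sep = "")
  print(x$summary)
  invisible(x)
}
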