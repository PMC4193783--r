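#' Lattice geometry for a tiled cell sheet
#'
#' The accessible interior is an exact tiling of `n_cell_x` by `n_cell_y`
#' square cells of `cell_size` sites, wrapped in a one-site inaccessible
#' boundary ring. The default (20 x 5 cells of 7 x 7 sites) gives 100 cells
#' on a 142 x 37 bounded grid whose rightmost accessible sites sit next to
#' the morphogen source column at `x = 142`; `grid_spec(30, 7)` gives the
#' 210-cell variant on a 212 x 51 grid.
#'
#' @param n_cell_x,n_cell_y Number of cell tiles along x and y.
#' @param cell_size Side of each square tile, in sites.
#' @return A `grid_spec` list with `width`, `height` (site counts including
#'   the ring), `n_cells`, and the tiling fields.
#' @examples
#' grid_spec()          # 100 cells, 142 x 37
#' grid_spec(30, 7)     # 210 cells, 212 x 51
#' @export
grid_spec <- function(n_cell_x = 20, n_cell_y = 5, cell_size = 7) {
  if (n_cell_x < 1 || n_cell_y < 1 || cell_size < 1)
    stop("grid dimensions must be positive integers")
  if (any(c(n_cell_x, n_cell_y, cell_size) %% 1 != 0))
    stop("the interior cannot be tiled exactly: ",
         "`n_cell_x`, `n_cell_y` and `cell_size` must be whole numbers")
  n_cell_x <- as.integer(n_cell_x)
  n_cell_y <- as.integer(n_cell_y)
  cell_size <- as.integer(cell_size)
  structure(list(
    n_cell_x = n_cell_x, n_cell_y = n_cell_y, cell_size = cell_size,
    width = n_cell_x * cell_size + 2L, height = n_cell_y * cell_size + 2L,
    interior_width = n_cell_x * cell_size,
    interior_height = n_cell_y * cell_size,
    n_cells = n_cell_x * n_cell_y
  ), class = "grid_spec")
}

#' Initial cell layout on a grid
#'
#' One row per cell: identity (row-major over tiles), tile column/row,
#' centroid in site coordinates, and the home region `region` - the index
#' of the equal-width fate band (along x, the gradient direction) that
#' contains the centroid. Region `n_t` is nearest the morphogen source.
#'
#' @param grid A [grid_spec()].
#' @param n_t Number of fate regions.
#' @return A tibble with columns `cell`, `col`, `row`, `x`, `y`, `region`.
#' @export
cell_layout <- function(grid, n_t = 4) {
  stopifnot(inherits(grid, "grid_spec"))
  cs <- grid$cell_size
  idx <- tibble::tibble(
    cell = seq_len(grid$n_cells),
    col = (cell - 1L) %% grid$n_cell_x + 1L,
    row = (cell - 1L) %/% grid$n_cell_x + 1L
  )
  band <- grid$interior_width / n_t
  dplyr::mutate(idx,
    x = 2 + (.data$col - 1) * cs + (cs - 1) / 2,
    y = 2 + (.data$row - 1) * cs + (cs - 1) / 2,
    region = pmin(n_t, ceiling((.data$x - 1) / band))
  )
}

#' Initialize a Potts system
#'
#' Tiles the interior with equal square cell domains, assigns identities
#' row-major, and attaches cell fates: either an explicit fate table from
#' [assign_fates()] or one drawn internally with error ratio `r`.
#'
#' @param grid A [grid_spec()].
#' @param params A [potts_params()] object.
#' @param fates Optional fate table (from [assign_fates()]); when `NULL`,
#'   fates are drawn with [assign_fates()] at error ratio `r`.
#' @param r Fate-specification error ratio used when `fates` is `NULL`
#'   (0 = perfect positional specification, 1 = uniform random).
#' @param field Optional morphogen field ([closed_form_gradient()],
#'   [noisy_gradient()], or a numeric matrix); defaults to the closed-form
#'   exponential gradient with source at the right edge.
#' @param require_unsorted Redraw fates (when `fates` is `NULL`) until the
#'   initial cluster count exceeds the number of types, so the run starts
#'   from a visibly unsorted state; used by the differential-adhesion
#'   ensembles, which measure sorting of misplaced cells.
#' @return A `potts_system` list: `labels` (width x height integer matrix,
#'   0 on the ring), `cells` (tibble with type, region, misspecified, area,
#'   centroid), `grid`, `params`, `field`.
#' @examples
#' sys <- init_cells(grid_spec(), potts_params(mu0 = 0.75), r = 1)
#' sys
#' @export
init_cells <- function(grid = grid_spec(), params = potts_params(),
                       fates = NULL, r = 0, field = NULL,
                       require_unsorted = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "potts_params"))
  n_t <- params$n_t
  if (is.null(fates)) fates <- assign_fates(cell_layout(grid, n_t), r, n_t)
  if (!all(c("cell", "type", "region") %in% names(fates)))
    stop("`fates` must have columns cell, type, region (see assign_fates())")
  if (nrow(fates) != grid$n_cells)
    stop("`fates` has ", nrow(fates), " rows but the grid holds ",
         grid$n_cells, " cells")
  cs <- grid$cell_size
  labels <- matrix(0L, grid$width, grid$height)
  for (i in seq_len(grid$n_cells)) {
    cx <- (i - 1L) %% grid$n_cell_x
    cy <- (i - 1L) %/% grid$n_cell_x
    labels[2 + cx * cs + 0:(cs - 1), 2 + cy * cs + 0:(cs - 1)] <- i
  }
  if (is.null(field)) field <- closed_form_gradient(grid)
  field <- as_field(field, grid)
  cells <- dplyr::arrange(fates, .data$cell)
  cells$area <- as.integer(cs^2)
  sys <- structure(list(labels = labels, cells = cells, grid = grid,
                        params = params, field = field),
                   class = "potts_system")
  sys <- refresh_cells(sys)
  if (require_unsorted && count_clusters(sys) <= n_t) {
    # redraw fates until the start is visibly unsorted: an ensemble that
    # probes sorting must not begin in the sorted state (possible at small
    # r when every error lands next to its own type's band, or none occur)
    for (i in 1:1000) {
      fates <- assign_fates(cell_layout(grid, n_t), r, n_t)
      sys$cells[c("type", "misspecified")] <-
        fates[order(fates$cell), c("type", "misspecified")]
      if (count_clusters(sys) > n_t) return(sys)
    }
    stop("could not draw an unsorted initial fate assignment")
  }
  sys
}

# Recompute area and centroid columns of sys$cells from the label field.
refresh_cells <- function(sys) {
  N <- nrow(sys$cells)
  st <- cell_geometry(sys$labels, N)
  sys$cells$area <- st$area
  sys$cells$x <- st$x
  sys$cells$y <- st$y
  sys
}

cell_geometry <- function(labels, N) {
  W <- nrow(labels)
  occ <- which(labels > 0)
  lab <- labels[occ]
  xs <- (occ - 1) %% W + 1
  ys <- (occ - 1) %/% W + 1
  area <- tabulate(lab, nbins = N)
  list(area = as.integer(area),
       x = as.numeric(rowsum(xs, lab, reorder = TRUE)) / pmax(area, 1),
       y = as.numeric(rowsum(ys, lab, reorder = TRUE)) / pmax(area, 1))
}

# Fail loudly if incremental bookkeeping has drifted from the label field.
check_consistency <- function(sys, tol = 1e-9) {
  st <- cell_geometry(sys$labels, nrow(sys$cells))
  if (!identical(as.integer(sys$cells$area), st$area))
    stop("inconsistent area bookkeeping: cell table does not match lattice")
  if (max(abs(sys$cells$x - st$x), abs(sys$cells$y - st$y)) > tol)
    stop("inconsistent centroid bookkeeping: cell table does not match lattice")
  invisible(TRUE)
}

#' @exportS3Method base::print
print.potts_system <- function(x, ...) {
  cat("<potts_system> ", x$grid$n_cells, " cells on a ", x$grid$width, " x ",
      x$grid$height, " grid (", sum(x$cells$misspecified %||% FALSE),
      " misspecified)\n", sep = "")
  print(x$params)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

field_matrix <- function(field) {
  if (is.matrix(field)) field else field$conc
}

#' Total energy of a configuration
#'
#' Sums the three energy terms: type-pair contact energy over unlike
#' 4-neighbour site pairs (counted once, boundary contacts via the boundary
#' row of `J`), the quadratic area constraint
#' `lambda * (a_i - A_tau)^2` per cell, and the chemotactic coupling
#' `-mu(tau) * C(x)` per occupied site (positive-`mu` types lower their
#' energy in high concentration).
#'
#' @param sys A `potts_system`.
#' @return The energy (a single number).
#' @export
total_energy <- function(sys) {
  check_consistency(sys)
  p <- sys$params
  cpm_total_energy_cpp(sys$labels, as.integer(sys$cells$type),
                       field_matrix(sys$field), p$J, p$mu, p$lambda,
                       p$a_target)
}

#' Energy change of a single copy attempt
#'
#' Energy difference for copying the label at neighbour `neighbor` onto the
#' interior site `site`, computed locally in O(1); equals the difference of
#' [total_energy()] before/after to floating precision.
#'
#' @param sys A `potts_system`.
#' @param site Integer `c(x, y)` of an interior site.
#' @param neighbor Integer `c(x, y)` of one of its four neighbours.
#' @return The energy change (a single number).
#' @export
delta_energy <- function(sys, site, neighbor) {
  p <- sys$params
  cpm_delta_energy_cpp(sys$labels, as.integer(sys$cells$type),
                       field_matrix(sys$field), p$J, p$mu, p$lambda,
                       p$a_target, site[1], site[2], neighbor[1], neighbor[2])
}

#' One elementary Metropolis attempt
#'
#' Picks a uniform random interior site and a uniform random 4-neighbour,
#' and accepts the copy with the Metropolis probability
#' `min(1, exp(-dH / T))`. Copies from the boundary ring, and flips that
#' would annihilate a cell when `allow_vanish` is off, are rejected.
#' Intended for inspection and testing; whole sweeps run in compiled code
#' via [run_mcs()].
#'
#' @param sys A `potts_system`.
#' @return A list `(system, accepted, delta, site, neighbor)`.
#' @export
metropolis_step <- function(sys) {
  g <- sys$grid
  x <- sample.int(g$width - 2L, 1L) + 1L
  y <- sample.int(g$height - 2L, 1L) + 1L
  d <- sample.int(4L, 1L)
  nx <- x + c(1L, -1L, 0L, 0L)[d]
  ny <- y + c(0L, 0L, 1L, -1L)[d]
  p <- sys$params
  labels <- sys$labels + 0L # private copy: the kernel flips in place
  res <- cpm_attempt_cpp(labels, as.integer(sys$cells$type),
                         field_matrix(sys$field), p$J, p$mu, p$lambda,
                         p$temp, p$a_target, x, y, nx, ny, p$allow_vanish,
                         apply = TRUE)
  if (isTRUE(res$changed)) {
    sys$labels <- labels
    sys <- refresh_cells(sys)
  }
  list(system = sys, accepted = res$accepted, delta = res$delta,
       site = c(x, y), neighbor = c(nx, ny))
}

#' Run Monte Carlo sweeps and record a trace
#'
#' Performs `n_mcs` Monte Carlo steps (one MCS = as many elementary copy
#' attempts as there are interior sites), recording the cluster count and
#' per-cell area/centroid snapshot every `cadence` MCS. A parameter
#' schedule lets `j` and/or `mu0` change at given times (e.g. delayed
#' differential adhesion). If the field is a stochastic reaction-diffusion
#' field (from [noisy_gradient()]) it is advanced by one integration step
#' per MCS.
#'
#' @param sys A `potts_system`.
#' @param n_mcs Number of sweeps (>= 0).
#' @param cadence Recording interval in MCS (the standard read-out uses 100).
#' @param schedule Optional data frame with column `mcs` and any of `j`,
#'   `mu0`: at each listed time the parameters are rebuilt with the new
#'   magnitudes. Times must lie in `[0, n_mcs]`.
#' @param monitor Optional list `(cell, x)`: report the first MCS at which
#'   that cell's centroid x-coordinate exceeds `x` (checked every MCS); with
#'   `stop = TRUE` the run ends at the crossing.
#' @return A `potts_trace`: `summary` tibble (`mcs`, `n_clusters`), snapshot
#'   matrices `area`, `cx`, `cy` (records x cells), the initial cell table
#'   `cells0`, acceptance rate, `crossing_mcs`, and the final `system`.
#' @examples
#' sys <- make_fixture("french_flag")
#' tr <- run_mcs(sys, 5, cadence = 1)
#' tr$summary
#' @export
run_mcs <- function(sys, n_mcs, cadence = 100, schedule = NULL,
                    monitor = NULL) {
  stopifnot(inherits(sys, "potts_system"), n_mcs >= 0)
  if (!is.null(schedule)) {
    if (!("mcs" %in% names(schedule)))
      stop("`schedule` needs an `mcs` column")
    if (any(schedule$mcs < 0 | schedule$mcs > n_mcs))
      stop("schedule times must lie in [0, n_mcs]")
    schedule <- schedule[order(schedule$mcs), , drop = FALSE]
  }
  mon_stop <- isTRUE(monitor$stop)
  noisy <- inherits(sys$field, "morphogen_field") &&
    !is.null(sys$field$solver) && sys$field$params$eta > 0
  mon_cell <- if (is.null(monitor)) -1L else as.integer(monitor$cell)
  mon_x <- if (is.null(monitor)) 0 else monitor$x

  segments <- segment_times(n_mcs, schedule)
  types <- as.integer(sys$cells$type)
  recs <- list()
  crossing <- NA_integer_
  acc <- 0; att <- 0
  t0 <- 0
  for (s in seq_len(nrow(segments))) {
    seg <- segments[s, ]
    if (!is.null(schedule) && !is.na(seg$isched)) {
      row <- schedule[seg$isched, ]
      sys$params <- update_params(sys$params,
                                  j = if ("j" %in% names(row)) row$j,
                                  mu0 = if ("mu0" %in% names(row)) row$mu0)
    }
    len <- seg$to - seg$from
    if (len == 0 && s > 1) next
    p <- sys$params
    if (!noisy) {
      res <- cpm_run_cpp(sys$labels, types, field_matrix(sys$field), p$J,
                         p$mu, p$lambda, p$temp, p$a_target, len, cadence,
                         p$allow_vanish, record_initial = (s == 1),
                         mon_cell, mon_x, mon_stop, seg$from)
      sys$labels <- res$labels
      recs[[length(recs) + 1L]] <- shift_records(res, seg$from)
      if (is.na(crossing) && !is.na(res$crossing_mcs))
        crossing <- seg$from + res$crossing_mcs
      if (!is.na(crossing)) mon_cell <- -1L # stop watching once crossed
      acc <- acc + res$n_accepted; att <- att + res$n_attempts
    } else {
      if (s == 1)
        recs[[length(recs) + 1L]] <- snapshot_record(sys, types, 0L)
      for (m in seq_len(len)) {
        mcs <- seg$from + m
        sys$field <- evolve_noisy(sys$field, 1)
        res <- cpm_run_cpp(sys$labels, types, field_matrix(sys$field), p$J,
                           p$mu, p$lambda, p$temp, p$a_target, 1L, 0L,
                           p$allow_vanish, record_initial = FALSE,
                           mon_cell, mon_x, mon_stop, 0L)
        sys$labels <- res$labels
        acc <- acc + res$n_accepted; att <- att + res$n_attempts
        if (is.na(crossing) && !is.na(res$crossing_mcs)) {
          crossing <- mcs
          mon_cell <- -1L
        }
        if (cadence > 0 && mcs %% cadence == 0)
          recs[[length(recs) + 1L]] <- snapshot_record(sys, types, mcs)
      }
    }
    t0 <- seg$to
  }
  mcs_v <- unlist(lapply(recs, `[[`, "mcs"))
  trace <- structure(list(
    summary = tibble::tibble(
      mcs = mcs_v,
      n_clusters = unlist(lapply(recs, `[[`, "n_clusters"))),
    area = do.call(rbind, lapply(recs, `[[`, "area")),
    cx = do.call(rbind, lapply(recs, `[[`, "cx")),
    cy = do.call(rbind, lapply(recs, `[[`, "cy")),
    cells0 = sys$cells[, intersect(c("cell", "type", "region",
                                     "misspecified"), names(sys$cells))],
    cadence = cadence, n_mcs = n_mcs, t_end = n_mcs,
    accept_rate = if (att > 0) acc / att else NA_real_,
    crossing_mcs = crossing,
    schedule = schedule,
    system = refresh_cells(sys)
  ), class = "potts_trace")
  trace
}

segment_times <- function(n_mcs, schedule) {
  if (is.null(schedule) || nrow(schedule) == 0)
    return(data.frame(from = 0, to = n_mcs, isched = NA_integer_))
  tt <- schedule$mcs
  from <- c(0, tt)
  to <- c(tt, n_mcs)
  isched <- c(NA_integer_, seq_len(nrow(schedule)))
  keep <- from <= to
  data.frame(from = from[keep], to = to[keep], isched = isched[keep])
}

shift_records <- function(res, offset) {
  k <- length(res$rec_mcs) # can be short of nrec when a run stops early
  list(mcs = res$rec_mcs + offset, n_clusters = res$rec_n_clusters,
       area = res$rec_area[seq_len(k), , drop = FALSE],
       cx = res$rec_cx[seq_len(k), , drop = FALSE],
       cy = res$rec_cy[seq_len(k), , drop = FALSE])
}

snapshot_record <- function(sys, types, mcs) {
  ncl <- cpm_count_clusters_cpp(sys$labels, types)
  st <- cell_geometry(sys$labels, length(types))
  list(mcs = as.integer(mcs), n_clusters = ncl,
       area = matrix(st$area, nrow = 1), cx = matrix(st$x, nrow = 1),
       cy = matrix(st$y, nrow = 1))
}

#' @exportS3Method base::print
print.potts_trace <- function(x, ...) {
  cat("<potts_trace> ", x$n_mcs, " MCS, ", nrow(x$summary),
      " records (cadence ", x$cadence, "), final clusters: ",
      utils::tail(x$summary$n_clusters, 1), "\n", sep = "")
  invisible(x)
}
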