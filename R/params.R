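#' Build the type-pair contact-energy matrix
#'
#' Constructs the symmetric surface-energy-per-contact matrix `J` over cell
#' types plus the boundary ring. In `"graded"` mode the penalty for an
#' unlike-type contact grows with the distance between the two types in the
#' sorted order, `J(tau, tau') = j_same + j * |tau - tau'|`, so types that
#' end up far apart after sorting dislike each other most. In `"uniform"`
#' mode every unlike pair pays the same penalty `j_same + j`. Like-type
#' contacts between different cells cost `j_same`; contacts within a single
#' cell cost nothing.
#'
#' @param j Differential-adhesion magnitude (energy per unit contact), `>= 0`.
#' @param mode `"graded"` (distance-weighted) or `"uniform"` (equal dislike).
#' @param n_t Number of cell types (at least 2).
#' @param j_same Like-type cell-cell contact energy; sets the adhesion scale.
#' @param j_bnd Cell-boundary contact energy (the inaccessible ring).
#' @return An `(n_t + 1) x (n_t + 1)` matrix; row/column 1 is the boundary.
#' @examples
#' build_adhesion_matrix(1, "graded")
#' @export
build_adhesion_matrix <- function(j, mode = c("graded", "uniform"), n_t = 4,
                                  j_same = 1, j_bnd = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(j) || length(j) != 1 || is.na(j) || j < 0)
    stop("`j` must be a single non-negative number")
  if (n_t < 2) stop("`n_t` must be at least 2")
  tt <- seq_len(n_t)
  off <- if (mode == "graded") abs(outer(tt, tt, "-")) else
    1 * (outer(tt, tt, "!=") )
  Jcell <- j_same + j * off
  diag(Jcell) <- j_same
  J <- matrix(j_bnd, n_t + 1, n_t + 1)
  J[1, 1] <- 0 # boundary-boundary contacts never occur
  J[-1, -1] <- Jcell
  dimnames(J) <- list(c("bnd", paste0("t", tt)), c("bnd", paste0("t", tt)))
  J
}

#' Build the chemotactic-potential vector
#'
#' One potential per cell type, strictly increasing with type index so that
#' under a source on the right the sorted order reads 1|2|3|4 away from the
#' source. `"bipolar"` gives the antisymmetric, evenly spaced default
#' `mu0 * (-2, -1, +1, +2)` (types 3 and 4 attracted, 1 and 2 repelled);
#' `"attract_only"` gives `mu0 * (1, ..., n_t)` (all attracted, graded);
#' `"repel_only"` gives `mu0 * (-n_t, ..., -1)` (all repelled, graded).
#'
#' @param mu0 Chemotactic magnitude (energy per concentration unit), `>= 0`.
#' @param mode `"bipolar"`, `"attract_only"` or `"repel_only"`.
#' @param n_t Number of cell types (even for `"bipolar"`).
#' @return Numeric vector of length `n_t`.
#' @examples
#' build_chemo_vector(1.5) # c(-3, -1.5, 1.5, 3)
#' @export
build_chemo_vector <- function(mu0, mode = c("bipolar", "attract_only",
                                             "repel_only"), n_t = 4) {
  mode <- match.arg(mode)
  if (!is.numeric(mu0) || length(mu0) != 1 || is.na(mu0) || mu0 < 0)
    stop("`mu0` must be a single non-negative number")
  base <- switch(mode,
    bipolar = {
      if (n_t %% 2 != 0) stop("bipolar mode needs an even number of types")
      h <- n_t / 2
      c(-(h:1), 1:h)
    },
    attract_only = seq_len(n_t),
    repel_only = -(n_t:1)
  )
  mu0 * base
}

#' Model parameters for the Potts dynamics
#'
#' Bundles the energy-function parameters: area-constraint strength
#' `lambda`, fluctuation temperature `temp`, per-type target area, the
#' contact-energy matrix built from `j`, and the chemotactic-potential
#' vector built from `mu0`. Defaults are the standard study conditions:
#' `lambda = 0.2`, `temp = 1`, target area 49 sites, four cell types.
#'
#' @param n_t Number of cell types.
#' @param lambda Area-constraint strength (energy / site^2).
#' @param temp Fluctuation temperature (energy).
#' @param a_target Target area in sites, scalar or length `n_t`.
#' @param j,j_mode,j_same,j_bnd Passed to [build_adhesion_matrix()].
#' @param mu0,mu_mode Passed to [build_chemo_vector()].
#' @param allow_vanish If `FALSE` (default) flips that would reduce a cell
#'   to zero area are rejected, so every cell persists.
#' @return A `potts_params` list with elements `J`, `mu`, `a_target`, ...
#' @examples
#' potts_params(mu0 = 1.5)
#' @export
potts_params <- function(n_t = 4, lambda = 0.2, temp = 1, a_target = 49,
                         j = 0, j_mode = "graded", mu0 = 0,
                         mu_mode = "bipolar", j_same = 1, j_bnd = 1,
                         allow_vanish = FALSE) {
  if (temp <= 0) stop("`temp` must be positive")
  a_target <- rep_len(as.numeric(a_target), n_t)
  p <- list(
    n_t = n_t, lambda = lambda, temp = temp, a_target = a_target,
    j = j, j_mode = j_mode, mu0 = mu0, mu_mode = mu_mode,
    j_same = j_same, j_bnd = j_bnd, allow_vanish = allow_vanish,
    J = build_adhesion_matrix(j, j_mode, n_t, j_same, j_bnd),
    mu = build_chemo_vector(mu0, mu_mode, n_t)
  )
  structure(p, class = "potts_params")
}

#' Update `j` and/or `mu0` in a parameter set
#'
#' Rebuilds the derived `J` matrix and `mu` vector; used by the schedule
#' hook of [run_mcs()] (e.g. delayed differential adhesion).
#'
#' @param params A [potts_params()] object.
#' @param j,mu0 New magnitudes; `NULL` keeps the current value.
#' @return The updated `potts_params` object.
#' @export
update_params <- function(params, j = NULL, mu0 = NULL) {
  stopifnot(inherits(params, "potts_params"))
  if (!is.null(j)) params$j <- j
  if (!is.null(mu0)) params$mu0 <- mu0
  params$J <- build_adhesion_matrix(params$j, params$j_mode, params$n_t,
                                    params$j_same, params$j_bnd)
  params$mu <- build_chemo_vector(params$mu0, params$mu_mode, params$n_t)
  params
}

#' @exportS3Method base::print
print.potts_params <- function(x, ...) {
  cat("<potts_params> ", x$n_t, " types | lambda=", x$lambda, " T=", x$temp,
      " | j=", x$j, " (", x$j_mode, ") | mu0=", x$mu0, " (", x$mu_mode,
      ")\n", sep = "")
  invisible(x)
}
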