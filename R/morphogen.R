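#' Morphogen gradient parameters
#'
#' A source column of fixed concentration `c0`, diffusion away from it and
#' first-order degradation give, at steady state, the exponential profile
#' `C(x) = c0 * exp(-(x_s - x) / lambda_d)`. For the stochastic field the
#' same physics is integrated in time: diffusion coefficients `D` in x and
#' y (equal), degradation rate `k`, and per-step additive Gaussian noise of
#' magnitude `eta`.
#'
#' `D` defaults to the lattice-consistent value
#' `k / (2 * (cosh(1 / lambda_d) - 1))`, equal to `k * lambda_d^2` up to a
#' relative `1/(12 lambda_d^2)` correction, so the closed-form exponential
#' is an exact fixed point of the discrete operator.
#'
#' @param c0 Source concentration (concentration units).
#' @param lambda_d Characteristic decay length (sites).
#' @param k Degradation rate (1/step).
#' @param eta Noise magnitude (concentration / step^(1/2)).
#' @param dt Integration step (1 step per MCS).
#' @param x_s Source column index; `NULL` means the grid's rightmost column.
#' @param D Diffusion coefficient (sites^2/step); `NULL` for the default.
#' @return A `gradient_params` list.
#' @export
gradient_params <- function(c0 = 5, lambda_d = 140, k = 1e-3, eta = 0,
                            dt = 1, x_s = NULL, D = NULL) {
  if (c0 <= 0 || lambda_d <= 0 || k <= 0 || eta < 0 || dt <= 0)
    stop("need c0 > 0, lambda_d > 0, k > 0, eta >= 0, dt > 0")
  if (is.null(D)) D <- k / (2 * (cosh(1 / lambda_d) - 1))
  structure(list(c0 = c0, lambda_d = lambda_d, k = k, eta = eta, dt = dt,
                 x_s = x_s, D = D), class = "gradient_params")
}

#' Closed-form exponential morphogen gradient
#'
#' The steady-state profile `C(x, y) = c0 * exp(-(x_s - x) / lambda_d)` for
#' `x <= x_s`, uniform in y.
#'
#' @param grid A [grid_spec()].
#' @param params A [gradient_params()].
#' @return A static `morphogen_field` (no stochastic solver attached).
#' @examples
#' f <- closed_form_gradient(grid_spec())
#' f$conc[142, 1]             # c0 at the source
#' @export
closed_form_gradient <- function(grid, params = gradient_params()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "gradient_params"))
  if (is.null(params$x_s)) params$x_s <- grid$width
  conc <- closed_form_matrix(grid, params)
  structure(list(conc = conc, params = params, grid = grid, solver = NULL,
                 step = 0L), class = "morphogen_field")
}

closed_form_matrix <- function(grid, params) {
  x <- seq_len(grid$width)
  prof <- params$c0 * exp(-(params$x_s - x) / params$lambda_d)
  prof[x > params$x_s] <- params$c0
  matrix(prof, grid$width, grid$height)
}

as_field <- function(field, grid) {
  if (inherits(field, "morphogen_field")) {
    if (!identical(dim(field$conc), c(grid$width, grid$height)))
      stop("field grid does not match the lattice grid")
    return(field)
  }
  if (is.matrix(field)) {
    if (!identical(dim(field), c(grid$width, grid$height)))
      stop("field matrix must be width x height")
    return(structure(list(conc = field, params = NULL, grid = grid,
                          solver = NULL, step = 0L),
                     class = "morphogen_field"))
  }
  stop("`field` must be a morphogen_field or a numeric matrix")
}

#' Stochastic reaction-diffusion morphogen field
#'
#' Sets up the time-evolving field
#' `dC/dt = D (d2C/dx2 + d2C/dy2) - k C + eta * xi`, with `xi` i.i.d.
#' standard Gaussian per site and step, integrated by implicit Euler for
#' the deterministic operator (unconditionally stable; the sparse system is
#' factorized once by Cholesky) with the noise increment added explicitly.
#' Boundary conditions: fixed concentration `c0` on the source column
#' `x_s`; exponential-outflow (Robin) ghost at the far x edge, the discrete
#' analogue of the semi-infinite exponential tail, so that with `eta = 0`
#' the closed-form gradient is the exact steady state; zero flux on the two
#' y edges. Negative excursions are clipped to zero.
#'
#' @param grid A [grid_spec()].
#' @param params A [gradient_params()] (set `eta > 0` for noise).
#' @param init `"closed_form"` (default) or `"zero"` initial concentration.
#' @return A `morphogen_field` with an attached implicit-Euler solver.
#' @export
noisy_gradient <- function(grid, params = gradient_params(eta = 1),
                           init = c("closed_form", "zero")) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "gradient_params"))
  init <- match.arg(init)
  if (is.null(params$x_s)) params$x_s <- grid$width
  W <- grid$width; H <- grid$height
  nx <- params$x_s - 1L  # unknown columns 1..x_s-1; the source is pinned
  if (nx < 1) stop("the source column must leave at least one free column")
  n <- nx * H
  id <- function(x, y) x + nx * (y - 1)
  D <- params$D; k <- params$k; dt <- params$dt
  xs <- rep(seq_len(nx), H)
  ys <- rep(seq_len(H), each = nx)
  # diagonal: 1 + dt*k + dt*D * (number of non-mirror neighbours), with the
  # far-x Robin ghost contributing dt*D*(1 - exp(-1/lambda_d))
  ndiag <- (xs > 1) + 1 + (ys > 1) + (ys < H)  # x_s side always couples
  diag_v <- 1 + dt * k + dt * D * ndiag
  diag_v[xs == 1] <- diag_v[xs == 1] + dt * D * (1 - exp(-1 / params$lambda_d))
  ii <- seq_len(n); jj <- ii; vv <- diag_v
  add <- function(from, to) {
    ii <<- c(ii, from); jj <<- c(jj, to); vv <<- c(vv, rep(-dt * D,
                                                           length(from)))
  }
  h <- which(xs < nx); add(id(xs[h], ys[h]), id(xs[h] + 1L, ys[h]))
  h <- which(xs > 1);  add(id(xs[h], ys[h]), id(xs[h] - 1L, ys[h]))
  h <- which(ys < H);  add(id(xs[h], ys[h]), id(xs[h], ys[h] + 1L))
  h <- which(ys > 1);  add(id(xs[h], ys[h]), id(xs[h], ys[h] - 1L))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  chol <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"))
  rhs0 <- numeric(n)
  rhs0[id(rep(nx, H), seq_len(H))] <- dt * D * params$c0
  conc <- if (init == "closed_form") closed_form_matrix(grid, params) else {
    m <- matrix(0, W, H); m[params$x_s:W, ] <- params$c0; m
  }
  structure(list(conc = conc, params = params, grid = grid,
                 solver = list(chol = chol, rhs0 = rhs0, nx = nx, H = H),
                 step = 0L), class = "morphogen_field")
}

#' Advance the stochastic morphogen field
#'
#' Performs `n_steps` implicit-Euler steps (deterministic operator solved
#' implicitly via the cached Cholesky factor, Gaussian noise `eta * xi`
#' added explicitly, negatives clipped to zero). With `eta = 0` the map is
#' a contraction towards the closed-form exponential profile.
#'
#' @param field A `morphogen_field` from [noisy_gradient()].
#' @param n_steps Number of integration steps.
#' @param eta Optional noise-magnitude override for these steps.
#' @return The advanced `morphogen_field`.
#' @export
evolve_noisy <- function(field, n_steps = 1, eta = NULL) {
  stopifnot(inherits(field, "morphogen_field"))
  if (is.null(field$solver))
    stop("this field has no stochastic solver; build it with noisy_gradient()")
  s <- field$solver
  p <- field$params
  if (is.null(eta)) eta <- p$eta
  v <- as.vector(field$conc[seq_len(s$nx), ])
  for (i in seq_len(n_steps)) {
    b <- v + s$rhs0
    if (eta > 0) b <- b + p$dt * eta * rnorm(length(v))
    v <- as.numeric(Matrix::solve(s$chol, b, system = "A"))
    v[v < 0] <- 0
  }
  field$conc[seq_len(s$nx), ] <- v
  field$step <- field$step + n_steps
  field
}

#' Fractional deviation of a field from a reference gradient
#'
#' Spatial mean of `|C(x) - C_ref(x)| / C_ref(x)` over the free (non-source)
#' columns; sites where the reference is zero are excluded with a warning.
#'
#' @param field A `morphogen_field` or concentration matrix.
#' @param reference The deterministic reference (`morphogen_field` or
#'   matrix) on the same grid.
#' @return The mean fractional deviation (a single number).
#' @export
fractional_noise <- function(field, reference) {
  C <- field_matrix(field)
  R <- field_matrix(reference)
  if (!identical(dim(C), dim(R))) stop("field and reference grids differ")
  ok <- R > 0
  if (!all(ok)) {
    warning(sum(!ok), " sites with zero reference concentration excluded")
    if (!any(ok)) return(NA_real_)
  }
  mean(abs(C[ok] - R[ok]) / R[ok])
}

#' Calibrate noise magnitude against fractional deviation
#'
#' For each `eta`, evolves the stochastic field and averages the
#' fractional deviation from the deterministic gradient over snapshots
#' taken every `spacing` steps after a burn-in, giving the
#' `eta` -> fractional-deviation calibration table.
#'
#' @param eta Noise magnitudes to sweep.
#' @param grid A [grid_spec()].
#' @param params Base [gradient_params()] (its `eta` is overridden).
#' @param n_snapshots Snapshots averaged per `eta`.
#' @param spacing Steps between snapshots.
#' @param burn_in Steps evolved before the first snapshot.
#' @return A tibble with columns `eta`, `fractional_deviation`.
#' @export
calibrate_noise <- function(eta, grid = grid_spec(),
                            params = gradient_params(), n_snapshots = 10,
                            spacing = 200, burn_in = 1000) {
  ref <- closed_form_gradient(grid, params)
  dev <- vapply(eta, function(e) {
    p <- params; p$eta <- e
    f <- noisy_gradient(grid, p)
    f <- evolve_noisy(f, burn_in)
    mean(vapply(seq_len(n_snapshots), function(i) {
      f <<- evolve_noisy(f, spacing)
      fractional_noise(f, ref)
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(eta = eta, fractional_deviation = dev)
}
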