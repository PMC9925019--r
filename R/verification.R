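#' Fully developed power-law channel profile (closed form)
#'
#' Exact solution of the dimensionless fully developed momentum balance
#' with no magnetic body force: driven by a constant pressure gradient
#' `G = -dp/dx`,
#' `u(y) = (n/(n+1)) (G Re)^(1/n) ((1/2)^((n+1)/n) - |y|^((n+1)/n))`.
#' At n = 1 and `G Re = 12` this is the parabolic inlet profile
#' `1.5 (1 - 4 y^2)`.
#'
#' @param y transverse coordinate(s), `|y| <= 1/2`
#' @param n power-law index
#' @param G driving pressure gradient (`-dp/dx > 0`)
#' @param Re Reynolds number
#' @return axial velocity u(y)
#' @export
power_law_poiseuille <- function(y, n, G, Re) {
  if (G <= 0) stop("pressure gradient G must be positive", call. = FALSE)
  stopifnot(n > 0, all(abs(y) <= 0.5 + 1e-12))
  k <- (n + 1) / n
  n / (n + 1) * (G * Re)^(1 / n) * (0.5^k - pmin(abs(y), 0.5)^k)
}

## pressure gradient that gives the power-law profile a unit centreline
## velocity scaled to u0
power_law_gradient <- function(n, Re, u0 = 1.5) {
  k <- (n + 1) / n
  ((u0 * (n + 1) / n) / (0.5^k))^n / Re
}

#' Fully developed Hartmann channel profile (closed form)
#'
#' Exact solution of `(1/Re) u'' - (M^2/Re) u = -G` with no-slip walls
#' at `y = +/- 1/2`:
#' `u(y) = (Re G / M^2) (1 - cosh(M y)/cosh(M/2))`.
#'
#' @param y transverse coordinate(s), `|y| <= 1/2`
#' @param M Hartmann number (> 0)
#' @param Re Reynolds number
#' @param G driving pressure gradient
#' @return axial velocity u(y)
#' @export
hartmann_profile <- function(y, M, Re, G) {
  stopifnot(M > 0, all(abs(y) <= 0.5 + 1e-12))
  (Re * G / M^2) * (1 - cosh(M * y) / cosh(M / 2))
}

#' Finite-difference Jacobian verification
#'
#' Column-by-column comparison of the analytic Jacobian with central
#' differences of the residual (the stabilization parameter frozen at
#' the base iterate, matching the analytic convention).  Intended for
#' meshes with at most a few dozen unknowns.
#'
#' @param mesh a small `tri_mesh`
#' @param Re,M,n flow parameters
#' @param U state vector at which to compare (random-ish states are the
#'   sharpest test)
#' @param eps_scale central-difference step scale
#' @return maximum entrywise error relative to the largest Jacobian
#'   entry
#' @export
finite_difference_residual_check <- function(mesh, Re, M, n, U,
                                             eps_scale = 1e-7) {
  fp <- fem_precompute(mesh)
  if (3L * fp$nn > 600)
    stop("finite-difference check is restricted to small meshes", call. = FALSE)
  phys <- make_phys(Re, M, n)
  Ja <- as.matrix(assemble_system(fp, phys, U, jacobian = "analytic")$J)
  Jfd <- fd_jacobian(fp, phys, U, eps_scale = eps_scale)
  max(abs(Ja - Jfd)) / max(abs(Jfd))
}
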