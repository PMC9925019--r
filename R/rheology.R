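#' Generalized power-law fluid model
#'
#' Dimensional fluid description: power-law index `n` (n < 1
#' shear-thinning, n = 1 Newtonian, n > 1 shear-thickening), consistency
#' `m` (equal to the Newtonian viscosity `mu` when n = 1), density `rho`,
#' electrical conductivity `sigma`, magnetic flux density `B0`, and the
#' reference (mean inflow) velocity `u_ref`.  Defaults are the blood
#' properties of the study conditions.
#'
#' @param n power-law index (dimensionless)
#' @param m consistency (kg m^-1 s^(n-2))
#' @param mu Newtonian viscosity (kg m^-1 s^-1); used as `m` when n = 1
#' @param rho density (kg m^-3)
#' @param sigma electrical conductivity (S m^-1)
#' @param B0 magnetic flux density (T)
#' @param u_ref reference mean inflow velocity (m s^-1)
#' @return an object of class `fluid_model`
#' @export
fluid_model <- function(n = 1, m = 0.0035, mu = 0.0035, rho = 1050,
                        sigma = 0.8, B0 = 0, u_ref = 0.066667) {
  stopifnot(n > 0, m > 0, rho > 0, sigma >= 0, u_ref > 0)
  f <- list(n = n, m = m, mu = mu, rho = rho, sigma = sigma, B0 = B0,
            u_ref = u_ref)
  class(f) <- "fluid_model"
  f
}

#' Reynolds and Hartmann numbers of a power-law MHD flow
#'
#' `Re = rho hbar^n u_ref^(2-n) / m` and
#' `M = B0 sqrt(sigma hbar^(n+1) / (m u_ref^(n-1)))`, the power-law
#' generalizations of the classical groups (they reduce to
#' `rho hbar u_ref / mu` and `B0 hbar sqrt(sigma/mu)` at n = 1).
#'
#' @param fluid a [fluid_model()] object
#' @param hbar characteristic length (m)
#' @return list of class `dimensionless_groups` with `Re` and `M`
#' @export
dimensionless_groups <- function(fluid, hbar) {
  if (!is.numeric(hbar) || hbar <= 0)
    stop("characteristic length hbar must be positive", call. = FALSE)
  n <- fluid$n
  m <- if (n == 1) fluid$mu else fluid$m
  Re <- fluid$rho * hbar^n * fluid$u_ref^(2 - n) / m
  M <- fluid$B0 * sqrt(fluid$sigma * hbar^(n + 1) / (m * fluid$u_ref^(n - 1)))
  g <- list(Re = Re, M = M)
  class(g) <- "dimensionless_groups"
  g
}

#' Second invariant of the strain-rate tensor
#'
#' `I2 = 2 (du/dx)^2 + 2 (dv/dy)^2 + (du/dy + dv/dx)^2` for a planar
#' velocity gradient; the squared shear-rate magnitude
#' `gamma_dot^2 = 2 D:D`.
#'
#' @param dudx,dudy,dvdx,dvdy velocity-gradient entries (vectorized)
#' @return `I2 >= 0`
#' @export
shear_rate_invariant <- function(dudx, dudy, dvdx, dvdy) {
  2 * dudx^2 + 2 * dvdy^2 + (dudy + dvdx)^2
}

#' Dimensionless apparent viscosity of the power-law model
#'
#' `eta = |max(I2, floor^2)|^((n-1)/2)`, identically 1 for n = 1.  For
#' n < 1 the power law diverges as the shear rate vanishes; a shear-rate
#' floor (`gamma_floor`, default 1e-6 dimensionless) regularizes the
#' stagnant limit.
#'
#' @param I2 second strain-rate invariant (>= 0, vectorized)
#' @param n power-law index
#' @param gamma_floor shear-rate regularization floor
#' @return apparent viscosity, strictly positive
#' @export
apparent_viscosity <- function(I2, n, gamma_floor = 1e-6) {
  stopifnot(n > 0)
  if (n == 1) return(rep(1, length(I2)))
  abs(pmax(I2, gamma_floor^2))^((n - 1) / 2)
}

#' Fully developed inlet velocity profile
#'
#' `u(y) = (3/2) (1 - (|y| / 0.5)^((n+1)/n))`, `v = 0`, on the
#' dimensionless inlet `y` in `[-1/2, 1/2]`.  The 3/2 prefactor is the
#' printed profile for all n; it normalizes the mean inflow to 1 exactly
#' at n = 1.
#'
#' @param y dimensionless transverse coordinate(s) in `[-1/2, 1/2]`
#' @param n power-law index
#' @return axial velocity u at `y`
#' @export
inlet_velocity <- function(y, n = 1) {
  if (any(abs(y) > 0.5 + 1e-12))
    stop("inlet profile: |y| > 1/2", call. = FALSE)
  1.5 * (1 - (pmin(abs(y) / 0.5, 1))^((n + 1) / n))
}
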