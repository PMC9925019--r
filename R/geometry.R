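#' Parametric geometry of a stenosed bifurcated artery
#'
#' Container for the dimensional parameters that define the bifurcated
#' channel with an overlapping (two-throat) stenosis in the mother artery.
#' All lengths are in metres; `beta` is the branch half-angle in radians.
#' Defaults are the values used throughout the study conditions:
#' a = 0.0075 m mother-artery radius, stenosis of length l0 = 0.015 m
#' starting at d = 0.005 m, lateral junction onset x1 = 0.025 m, domain
#' length x_max = 0.06 m, beta = 30 degrees, junction compatibility offset
#' q = 0.0002 m, daughter radius r1 = 0.51 a, and characteristic length
#' hbar = 2a (the inlet height).
#'
#' @param a mother-artery radius (m)
#' @param l0 stenosis length (m)
#' @param d stenosis onset distance from the inlet (m)
#' @param x_max domain length (m)
#' @param x1 lateral-junction onset (m)
#' @param beta branch half-angle (radians)
#' @param q junction compatibility offset (m), in [1e-4, 5e-4]
#' @param r1 daughter-artery radius (m)
#' @param tau_m maximum stenosis height (m); 0.4*a gives a 40 % occlusion
#' @param hbar characteristic length (m), the inlet height 2a
#' @return an object of class `artery_params`
#' @export
artery_params <- function(a = 0.0075, l0 = 0.015, d = 0.005, x_max = 0.06,
                          x1 = 0.025, beta = pi / 6, q = 2e-4, r1 = 0.51 * a,
                          tau_m = 0.4 * a, hbar = 2 * a) {
  p <- list(a = a, l0 = l0, d = d, x_max = x_max, x1 = x1, beta = beta,
            q = q, r1 = r1, tau_m = tau_m, hbar = hbar)
  class(p) <- "artery_params"
  validate_artery_params(p)
  p
}

validate_artery_params <- function(p) {
  stopifnot(is.list(p))
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("invalid artery geometry: ", what, call. = FALSE)
  }
  chk(p$a > 0, "mother radius a must be positive")
  chk(p$d > 0, "stenosis onset d must be positive")
  chk(p$l0 > 0, "stenosis length l0 must be positive")
  chk(p$d + p$l0 <= p$x1, "stenosis must end before the lateral junction (d + l0 <= x1)")
  chk(p$tau_m >= 0 && p$tau_m < p$a, "stenosis height tau_m must satisfy 0 <= tau_m < a")
  chk(p$q >= 1e-4 && p$q <= 5e-4, "compatibility offset q must lie in [0.0001, 0.0005] m")
  chk(p$beta > 0 && p$beta < pi / 2, "half-angle beta must lie in (0, pi/2)")
  chk(p$r1 > 0, "daughter radius r1 must be positive")
  chk(p$hbar > 0, "characteristic length hbar must be positive")
  invisible(p)
}

#' Derived junction parameters of the bifurcation
#'
#' Computes the quantities implied by the closed-form wall equations:
#' the lateral-junction curvature radius `r0 = (a - 2 r1 sec(beta)) /
#' (cos(beta) - 1)`, the junction offset `x2 = x1 + r0 sin(beta)`, the
#' flow-divider apex `x3 = x2 + q`, the divider curvature radius
#' `r0p = (x3 - x2) sin(beta) / (1 - sin(beta))`, the outer-wall
#' shortening `s = 2 r1 sin(beta)` and the divider-curvature offset
#' `x4 = x3 + r0p (1 - sin(beta))`.
#'
#' @param params an [artery_params()] object
#' @return a list of class `junction_derived` with fields
#'   `x2, x3, x4, r0, r0p, s` (metres)
#' @export
derive_junction_parameters <- function(params) {
  validate_artery_params(params)
  b <- params$beta
  if (abs(cos(b) - 1) < .Machine$double.eps * 8)
    stop("invalid artery geometry: beta = 0 makes the junction curvature singular",
         call. = FALSE)
  r0 <- (params$a - 2 * params$r1 / cos(b)) / (cos(b) - 1)
  x2 <- params$x1 + r0 * sin(b)
  x3 <- x2 + params$q
  r0p <- (x3 - x2) * sin(b) / (1 - sin(b))
  s <- 2 * params$r1 * sin(b)
  x4 <- x3 + r0p * (1 - sin(b))
  d <- list(x2 = x2, x3 = x3, x4 = x4, r0 = r0, r0p = r0p, s = s)
  class(d) <- "junction_derived"
  if (r0 <= 0) stop("invalid artery geometry: r0 <= 0", call. = FALSE)
  if (r0p <= 0) stop("invalid artery geometry: r0' <= 0", call. = FALSE)
  if (!(params$x1 < x2 && x2 < x3 && x3 < x4 && x4 < params$x_max))
    stop("invalid artery geometry: junction ordering x1 < x2 < x3 < x4 < x_max violated",
         call. = FALSE)
  if (params$x_max - s <= x4)
    stop("invalid artery geometry: outer wall ends before the divider curvature (x_max - s <= x4)",
         call. = FALSE)
  d
}

#' Outer wall radius of the bifurcated artery
#'
#' Piecewise closed form: constant radius `a` up- and downstream of the
#' stenosis, the quartic overlapping-stenosis profile
#' `a - (3 tau_m / 2) (11 t - 47 t^2 + 72 t^3 - 36 t^4)` with
#' `t = (x - d)/l0` over the stenosis, a circular lateral-junction arc of
#' radius `r0` over `[x1, x2]`, and the straight diverging branch wall
#' `2 r1 sec(beta) + (x - x2) tan(beta)` up to `x_max - s`.
#'
#' @param x axial coordinate(s), same units as `params` (metres)
#' @param params an [artery_params()] object
#' @param derived optional [derive_junction_parameters()] result
#' @return wall radius at `x` (metres)
#' @export
outer_wall_radius <- function(x, params, derived = derive_junction_parameters(params)) {
  xs_end <- params$x_max - derived$s
  if (any(x < -1e-12 | x > xs_end + 1e-12))
    stop("outer wall: x outside [0, x_max - s]", call. = FALSE)
  a <- params$a; d <- params$d; l0 <- params$l0; tm <- params$tau_m
  b <- params$beta
  t <- (x - d) / l0
  r <- rep(a, length(x))
  in_sten <- x > d & x < d + l0
  r[in_sten] <- a - 1.5 * tm *
    (11 * t[in_sten] - 47 * t[in_sten]^2 + 72 * t[in_sten]^3 - 36 * t[in_sten]^4)
  in_arc <- x >= params$x1 & x < derived$x2
  r[in_arc] <- a + derived$r0 - sqrt(pmax(derived$r0^2 - (x[in_arc] - params$x1)^2, 0))
  in_branch <- x >= derived$x2
  r[in_branch] <- 2 * params$r1 / cos(b) + (x[in_branch] - derived$x2) * tan(b)
  r
}

#' Inner wall radius of the bifurcated artery
#'
#' Zero upstream of the flow-divider apex `x3`, the divider curvature arc
#' `sqrt(r0p^2 - (x - (x3 + r0p))^2)` over `[x3, x4]`, and the straight
#' inner branch wall `r0p cos(beta) + (x - x4) tan(beta)` up to `x_max`.
#'
#' @inheritParams outer_wall_radius
#' @return wall radius at `x` (metres)
#' @export
inner_wall_radius <- function(x, params, derived = derive_junction_parameters(params)) {
  if (any(x < -1e-12 | x > params$x_max + 1e-12))
    stop("inner wall: x outside [0, x_max]", call. = FALSE)
  b <- params$beta
  r <- numeric(length(x))
  in_arc <- x > derived$x3 & x < derived$x4
  r[in_arc] <- sqrt(pmax(derived$r0p^2 - (x[in_arc] - (derived$x3 + derived$r0p))^2, 0))
  in_branch <- x >= derived$x4
  r[in_branch] <- derived$r0p * cos(b) + (x[in_branch] - derived$x4) * tan(b)
  r
}

## chord-error-bounded sampling of a wall function on [xa, xb] (dimensionless)
sample_wall <- function(f, xa, xb, chord_tol = 1e-3, n_min = 16) {
  x <- seq(xa, xb, length.out = n_min + 1)
  repeat {
    xm <- (x[-1] + x[-length(x)]) / 2
    err <- abs(f(xm) - (f(x[-1]) + f(x[-length(x)])) / 2)
    bad <- which(err > chord_tol)
    if (!length(bad) || length(x) > 4096) break
    x <- sort(c(x, xm[bad]))
  }
  x
}

#' Closed, tagged boundary polyline of the bifurcated domain
#'
#' Builds the dimensionless computational boundary: upper outer wall
#' `+R1(x)` with its mirror image below the axis, inner walls `+/-R2(x)`
#' meeting at the flow-divider apex, the inflow face at `x = 0` spanning
#' `y` in `[-1/2, 1/2]`, and each daughter outlet closed by the straight
#' segment joining the outer-wall endpoint `(x_max - s, +/-R1)` to the
#' inner-wall endpoint `(x_max, +/-R2)`.  All coordinates are divided by
#' the characteristic length `hbar`.  The two pressure-pin points sit at
#' the outlet/wall corners (printed values (4, 1.1556) and
#' (3.745, -1.5973) under the default parameters).
#'
#' @param params an [artery_params()] object
#' @param chord_tol chord-error bound (dimensionless) for sampling the
#'   curved wall segments of the polyline
#' @return an object of class `domain_boundary` with elements `polyline`
#'   (data.frame x, y, tag), `pins` (2 x 2 matrix), `params`, `derived`,
#'   and dimensionless wall functions `R1`, `R2`, `y_top`
#' @export
build_domain_boundary <- function(params, chord_tol = 1e-3) {
  validate_artery_params(params)
  der <- derive_junction_parameters(params)
  h <- params$hbar
  ## dimensionless wall functions
  R1 <- function(x) outer_wall_radius(x * h, params, der) / h
  R2 <- function(x) inner_wall_radius(x * h, params, der) / h
  xs <- (params$x_max - der$s) / h   # outer-wall terminus
  xm <- params$x_max / h             # inner-wall terminus
  x3 <- der$x3 / h
  y_out <- R1(xs)                    # outlet corner on the outer wall
  y_in <- R2(xm)                     # outlet corner on the inner wall
  ## straight outlet closure between the two corners (upper branch)
  y_top <- function(x) ifelse(x <= xs, R1(x),
                              y_out + (x - xs) * (y_in - y_out) / (xm - xs))
  if (params$tau_m >= params$a)
    stop("invalid artery geometry: stenosis closes the lumen", call. = FALSE)

  xo <- sample_wall(R1, 0, xs, chord_tol)
  xi <- sample_wall(R2, x3, xm, chord_tol)
  seg <- function(x, y, tag) data.frame(x = x, y = y, tag = tag)
  poly <- rbind(
    seg(c(0, 0), c(-0.5, 0.5), "inflow"),
    seg(xo[-1], R1(xo[-1]), "outer_wall"),
    seg(xm, y_in, "outlet_upper"),
    seg(rev(xi)[-1], R2(rev(xi)[-1]), "inner_wall"),
    seg(xi[-1], -R2(xi[-1]), "inner_wall"),
    seg(xs, -y_out, "outlet_lower"),
    seg(rev(xo)[-c(1, length(xo))], -R1(rev(xo)[-c(1, length(xo))]), "outer_wall")
  )
  bd <- list(type = "bifurcated", polyline = poly,
             pins = rbind(c(xm, y_in), c(xs, -y_out)),
             params = params, derived = der,
             R1 = R1, R2 = R2, y_top = y_top,
             x_breaks = c(d = params$d / h, d_l0 = (params$d + params$l0) / h,
                          x1 = params$x1 / h, x2 = der$x2 / h, x3 = x3,
                          x4 = der$x4 / h, xs = xs, xm = xm))
  class(bd) <- "domain_boundary"
  if (!polygon_is_simple(poly$x, poly$y))
    stop("invalid artery geometry: boundary polyline self-intersects", call. = FALSE)
  bd
}

## crude but reliable simple-polygon test on a decimated copy of the loop
polygon_is_simple <- function(x, y, n_keep = 256) {
  n <- length(x)
  if (n > n_keep) {
    idx <- unique(round(seq(1, n, length.out = n_keep)))
    x <- x[idx]; y <- y[idx]; n <- length(x)
  }
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)]           # skip segments sharing an endpoint
    if (!length(j)) next
    d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j]) *
          cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    d2 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i]) *
          cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
    if (any(d1 < 0 & d2 < 0)) return(FALSE)
  }
  TRUE
}

#' Straight stenosed channel domain
#'
#' A rectangle of the given length and half-height with a user-supplied
#' symmetric constriction profile subtracted from both walls; used for
#' verification against closed-form channel solutions.  The default has
#' no bump.  `cosine_bump()` builds the documented default constriction.
#'
#' @param length channel length (dimensionless)
#' @param half_height channel half-height (dimensionless; inlet spans
#'   `[-half_height, half_height]`)
#' @param bump_profile `NULL` or a vectorized function of x returning the
#'   local constriction height (>= 0, < half_height)
#' @return an object of class `domain_boundary` with `type = "channel"`
#' @export
straight_channel_domain <- function(length = 4, half_height = 0.5,
                                    bump_profile = NULL) {
  stopifnot(length > 0, half_height > 0)
  bump <- if (is.null(bump_profile)) function(x) numeric(base::length(x)) else bump_profile
  xs <- seq(0, length, length.out = 257)
  bmax <- max(bump(xs))
  if (bmax >= half_height)
    stop("invalid channel geometry: bump height >= half height", call. = FALSE)
  wall <- function(x) half_height - bump(x)
  xw <- sample_wall(wall, 0, length, 1e-3)
  seg <- function(x, y, tag) data.frame(x = x, y = y, tag = tag)
  poly <- rbind(
    seg(c(0, 0), c(-half_height, half_height), "inflow"),
    seg(xw[-1], wall(xw[-1]), "wall"),
    seg(length, -wall(length), "outflow"),
    seg(rev(xw)[-c(1, length(xw))], -wall(rev(xw)[-c(1, length(xw))]), "wall")
  )
  bd <- list(type = "channel", polyline = poly, pins = NULL,
             params = list(length = length, half_height = half_height),
             bump = bump, wall = wall)
  class(bd) <- "domain_boundary"
  bd
}

#' Cosine constriction profile
#'
#' @param height maximum bump height
#' @param centre bump centre along x
#' @param width full support width of the bump
#' @return a vectorized function of x
#' @export
cosine_bump <- function(height, centre, width) {
  function(x) ifelse(abs(x - centre) <= width / 2,
                     height / 2 * (1 + cos(2 * pi * (x - centre) / width)),
                     0)
}

#' Export a boundary polyline as tagged CSV
#'
#' @param boundary a `domain_boundary` object
#' @param file output path
#' @return the file path, invisibly
#' @export
write_boundary_csv <- function(boundary, file) {
  utils::write.csv(boundary$polyline, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
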