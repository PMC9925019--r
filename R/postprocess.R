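## ---- field interpolation -------------------------------------------------

## locate points in the mesh and evaluate P1 fields; returns NA outside
interp_fields <- function(sol, px, py) {
  mesh <- sol$mesh
  tri <- mesh$tri
  x <- matrix(mesh$nodes[tri, 1], ncol = 3)
  y <- matrix(mesh$nodes[tri, 2], ncol = 3)
  np <- length(px)
  out <- data.frame(x = px, y = py, u = NA_real_, v = NA_real_, p = NA_real_)
  xmin <- pmin(x[, 1], x[, 2], x[, 3]); xmax <- pmax(x[, 1], x[, 2], x[, 3])
  ymin <- pmin(y[, 1], y[, 2], y[, 3]); ymax <- pmax(y[, 1], y[, 2], y[, 3])
  tol <- 1e-9
  for (k in seq_len(np)) {
    cand <- which(px[k] >= xmin - tol & px[k] <= xmax + tol &
                  py[k] >= ymin - tol & py[k] <= ymax + tol)
    if (!length(cand)) next
    x1 <- x[cand, 1]; x2 <- x[cand, 2]; x3 <- x[cand, 3]
    y1 <- y[cand, 1]; y2 <- y[cand, 2]; y3 <- y[cand, 3]
    d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (px[k] - x3) + (x3 - x2) * (py[k] - y3)) / d
    l2 <- ((y3 - y1) * (px[k] - x3) + (x1 - x3) * (py[k] - y3)) / d
    l3 <- 1 - l1 - l2
    inside <- which(l1 >= -1e-8 & l2 >= -1e-8 & l3 >= -1e-8)
    if (!length(inside)) next
    e <- cand[inside[1]]
    lam <- c(l1[inside[1]], l2[inside[1]], l3[inside[1]])
    nodes <- tri[e, ]
    out$u[k] <- sum(lam * sol$u[nodes])
    out$v[k] <- sum(lam * sol$v[nodes])
    out$p[k] <- sum(lam * sol$p[nodes])
  }
  out
}

## ---- wall traces ---------------------------------------------------------

## order the boundary edges of a tag (and side) into arc-length chains
wall_chain <- function(mesh, wall_tag, side = c("upper", "lower")) {
  side <- match.arg(side)
  ed <- mesh$boundary[mesh$boundary$tag == wall_tag, , drop = FALSE]
  if (!nrow(ed))
    stop("configuration error: unknown or empty wall tag '", wall_tag, "'",
         call. = FALSE)
  ymid <- (mesh$nodes[ed$n1, 2] + mesh$nodes[ed$n2, 2]) / 2
  keep <- if (side == "upper") ymid >= 0 else ymid <= 0
  ed <- ed[keep, , drop = FALSE]
  if (!nrow(ed))
    stop("configuration error: no '", wall_tag, "' edges on the ", side,
         " side", call. = FALSE)
  ## edges were emitted in chain order by the mesher
  nodes <- c(ed$n1[1], ed$n2)
  xy <- mesh$nodes[nodes, , drop = FALSE]
  s <- c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
  list(nodes = nodes, x = xy[, 1], y = xy[, 2], s = s, edges = ed)
}

#' Wall shear stress trace along a tagged wall
#'
#' `tau_w = m_coef * eta * (du/dy + dv/dx)` evaluated on the
#' wall-adjacent element of each boundary edge (P1 gradients are
#' elementwise constant); node values average the two adjacent edges.
#' The consistency prefactor defaults to 1 for dimensionless output.
#'
#' @param sol a `flow_solution`
#' @param wall_tag boundary tag (`"outer_wall"`, `"inner_wall"`,
#'   `"wall"`)
#' @param side `"upper"` or `"lower"` chain of that tag
#' @param m_coef consistency prefactor (1 = dimensionless)
#' @return data.frame (class `wall_trace`): `s` (arc length), `x`, `y`,
#'   `tau_w`
#' @export
wall_shear_stress <- function(sol, wall_tag, side = "upper", m_coef = 1) {
  mesh <- sol$mesh
  ch <- wall_chain(mesh, wall_tag, side)
  fp <- fem_precompute(mesh)
  G12 <- rowSums(fp$c * matrix(sol$u[fp$tri], ncol = 3))
  G21 <- rowSums(fp$b * matrix(sol$v[fp$tri], ncol = 3))
  I2 <- shear_rate_invariant(rowSums(fp$b * matrix(sol$u[fp$tri], ncol = 3)),
                             G12, G21,
                             rowSums(fp$c * matrix(sol$v[fp$tri], ncol = 3)))
  eta <- apparent_viscosity(I2, sol$n, sol$gamma_floor)
  tau_el <- m_coef * eta * (G12 + G21)
  ## adjacent element of each boundary edge
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- c(key(fp$tri[, 1], fp$tri[, 2]), key(fp$tri[, 2], fp$tri[, 3]),
          key(fp$tri[, 3], fp$tri[, 1]))
  eid <- rep(seq_len(fp$ne), 3)
  adj <- eid[match(key(ch$edges$n1, ch$edges$n2), ek)]
  tw_edge <- tau_el[adj]
  nn <- length(ch$nodes)
  tw <- numeric(nn)
  tw[1] <- tw_edge[1]; tw[nn] <- tw_edge[length(tw_edge)]
  if (nn > 2) tw[2:(nn - 1)] <- (tw_edge[-length(tw_edge)] + tw_edge[-1]) / 2
  out <- data.frame(s = ch$s, x = ch$x, y = ch$y, tau_w = tw)
  class(out) <- c("wall_trace", class(out))
  out
}

#' Wall pressure trace along a tagged wall
#'
#' Nodal pressure sampled along the tagged wall in arc-length order.
#'
#' @inheritParams wall_shear_stress
#' @return data.frame (class `wall_trace`): `s`, `x`, `y`, `p`
#' @export
wall_pressure <- function(sol, wall_tag, side = "upper") {
  ch <- wall_chain(sol$mesh, wall_tag, side)
  out <- data.frame(s = ch$s, x = ch$x, y = ch$y, p = sol$p[ch$nodes])
  class(out) <- c("wall_trace", class(out))
  out
}

## ---- cross sections ------------------------------------------------------

## transverse extent of the domain at station x
section_range <- function(domain, x, region = "auto") {
  if (domain$type == "channel") {
    w <- domain$wall(x)
    return(c(-w, w))
  }
  xb <- domain$x_breaks
  if (x < 0 || x > xb["xm"])
    stop("configuration error: station x = ", x, " outside the domain",
         call. = FALSE)
  in_branch <- x > xb["x3"]
  if (region == "auto") region <- if (in_branch) "upper" else "parent"
  if (region == "parent") {
    if (in_branch)
      stop("configuration error: station x = ", x,
           " is past the flow divider; pick region 'upper' or 'lower'",
           call. = FALSE)
    r <- domain$R1(x)
    return(c(-r, r))
  }
  lo <- domain$R2(x); hi <- domain$y_top(x)
  if (region == "upper") c(lo, hi) else c(-hi, -lo)
}

#' Cross-section profile at a vertical station
#'
#' Interpolates `(y, u, v, p)` along the chord `x = x_station` and
#' reports the trapezoidal mean of the axial velocity over the section.
#'
#' @param sol a `flow_solution`
#' @param x_station station abscissa (dimensionless)
#' @param region `"auto"`, `"parent"`, `"upper"` or `"lower"` (branch)
#' @param n_samples number of sampling points across the chord
#' @return list of class `cross_section` with `samples` (data.frame) and
#'   `mean_u`
#' @export
cross_section <- function(sol, x_station, region = "auto", n_samples = 201) {
  rng <- section_range(sol$mesh$domain, x_station, region)
  eps <- 1e-8 * max(1, abs(diff(rng)))
  yy <- seq(rng[1] + eps, rng[2] - eps, length.out = n_samples)
  f <- interp_fields(sol, rep(x_station, n_samples), yy)
  ok <- is.finite(f$u)
  if (sum(ok) < 2)
    stop("configuration error: station x = ", x_station,
         " does not intersect the mesh", call. = FALSE)
  ys <- yy[ok]; us <- f$u[ok]
  mean_u <- sum(diff(ys) * (us[-1] + us[-length(us)]) / 2) / (max(ys) - min(ys))
  out <- list(x = x_station, region = region, samples = f[ok, ],
              mean_u = mean_u)
  class(out) <- "cross_section"
  out
}

#' Section-averaged pressure drop between two stations
#'
#' @param sol a `flow_solution`
#' @param from_station,to_station station abscissae
#' @param region section region passed to [cross_section()]
#' @return scalar `mean p(from) - mean p(to)`
#' @export
pressure_drop <- function(sol, from_station, to_station, region = "auto") {
  pmean <- function(xs) {
    cs <- cross_section(sol, xs, region)
    s <- cs$samples
    sum(diff(s$y) * (s$p[-1] + s$p[-nrow(s)]) / 2) / (max(s$y) - min(s$y))
  }
  pmean(from_station) - pmean(to_station)
}

## ---- recirculation -------------------------------------------------------

## exact area of {field < 0} inside one triangle with nodal values a
neg_area_tri <- function(a1, a2, a3, A) {
  v <- cbind(a1, a2, a3)
  nneg <- rowSums(v < 0)
  out <- numeric(length(A))
  out[nneg == 3] <- A[nneg == 3]
  one <- which(nneg == 1)
  if (length(one)) {
    vn <- v[one, , drop = FALSE]
    an <- apply(vn, 1, min)                     # the negative vertex
    rest <- t(apply(vn, 1, sort))[, 2:3, drop = FALSE]
    out[one] <- A[one] * an^2 / ((an - rest[, 1]) * (an - rest[, 2]))
  }
  two <- which(nneg == 2)
  if (length(two)) {
    vn <- v[two, , drop = FALSE]
    ap <- apply(vn, 1, max)                     # the positive vertex
    rest <- t(apply(vn, 1, sort))[, 1:2, drop = FALSE]
    out[two] <- A[two] * (1 - ap^2 / ((ap - rest[, 1]) * (ap - rest[, 2])))
  }
  out
}

#' Recirculation (flow-reversal) area
#'
#' Area of the region where the axial velocity is negative, restricted
#' to elements whose centroid lies in the given axial window (default:
#' downstream of the stenosis offset).  The linear-in-element velocity
#' makes the per-element negative-area computation exact.
#'
#' @param sol a `flow_solution`
#' @param x_min,x_max axial window (dimensionless); defaults to
#'   downstream of the stenosis (`x > d + l0`) with no upper bound
#' @return total area (scalar) with per-pocket info in attributes
#' @export
recirculation_area <- function(sol, x_min = NULL, x_max = Inf) {
  mesh <- sol$mesh
  if (is.null(x_min)) {
    x_min <- if (mesh$domain$type == "bifurcated")
      unname(mesh$domain$x_breaks["d_l0"]) else 0
  }
  cx <- rowMeans(matrix(mesh$nodes[mesh$tri, 1], ncol = 3))
  sel <- cx > x_min & cx < x_max
  ue <- matrix(sol$u[mesh$tri], ncol = 3)
  a <- neg_area_tri(ue[, 1], ue[, 2], ue[, 3], mesh$area)
  sum(a[sel])
}

#' Recirculation-change metrics between two solutions
#'
#' Percent reduction `100 (A_ref - A_new) / A_ref` of the
#' negative-axial-velocity area between a reference and a comparison
#' solution on the same domain.
#'
#' @param sol_ref,sol_new `flow_solution`s on meshes of the same domain
#' @param x_min,x_max axial window (see [recirculation_area()])
#' @return list with `area_ref`, `area_new`, `percent_reduction`
#' @export
recirculation_metrics <- function(sol_ref, sol_new, x_min = NULL, x_max = Inf) {
  a0 <- recirculation_area(sol_ref, x_min, x_max)
  a1 <- recirculation_area(sol_new, x_min, x_max)
  pr <- if (a0 > 0) 100 * (a0 - a1) / a0 else NA_real_
  if (a0 == 0) warning("reference recirculation area is zero; reduction undefined")
  list(area_ref = a0, area_new = a1, percent_reduction = pr)
}

## ---- streamfunction ------------------------------------------------------

#' Streamfunction reconstruction
#'
#' Solves the Poisson problem `-lap(psi) = omega` (`omega = dv/dx -
#' du/dy`) with Dirichlet values on the whole boundary accumulated from
#' the normal flux of the solution (psi = 0 at the start of the lower
#' outer wall); contours of `psi` are the streamlines.
#'
#' @param sol a `flow_solution`
#' @return nodal `psi` vector
#' @export
streamfunction <- function(sol) {
  mesh <- sol$mesh
  fp <- fem_precompute(mesh)
  nn <- fp$nn
  ue <- matrix(sol$u[fp$tri], ncol = 3); ve <- matrix(sol$v[fp$tri], ncol = 3)
  omega <- rowSums(fp$b * ve) - rowSums(fp$c * ue)
  ## stiffness and load (P1, exact)
  idx9 <- cbind(rep(1:3, times = 3), rep(1:3, each = 3))
  ii <- jj <- xx <- vector("list", 9)
  for (m in 1:9) {
    i <- idx9[m, 1]; k <- idx9[m, 2]
    ii[[m]] <- fp$tri[, i]; jj[[m]] <- fp$tri[, k]
    xx[[m]] <- fp$A * (fp$b[, i] * fp$b[, k] + fp$c[, i] * fp$c[, k])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nn, nn))
  Fv <- numeric(nn)
  for (i in 1:3) {
    contrib <- rowsum(omega * fp$A / 3, fp$tri[, i])
    Fv[as.integer(rownames(contrib))] <-
      Fv[as.integer(rownames(contrib))] + contrib
  }
  ## boundary loop: accumulate psi from the normal flux
  loop <- boundary_loop(mesh)
  xy <- mesh$nodes[loop, , drop = FALSE]
  um <- (sol$u[loop][-1] + sol$u[loop][-length(loop)]) / 2
  vm <- (sol$v[loop][-1] + sol$v[loop][-length(loop)]) / 2
  dpsi <- um * diff(xy[, 2]) - vm * diff(xy[, 1])
  psi_b <- c(0, cumsum(dpsi))
  bnodes <- loop[-length(loop)]
  psi_bv <- psi_b[-length(psi_b)]
  ## Dirichlet rows
  isb <- logical(nn); isb[bnodes] <- TRUE
  trip <- Matrix::summary(K)
  keep <- !isb[trip$i]
  K2 <- Matrix::sparseMatrix(i = c(trip$i[keep], bnodes),
                             j = c(trip$j[keep], bnodes),
                             x = c(trip$x[keep], rep(1, length(bnodes))),
                             dims = c(nn, nn))
  Fv[bnodes] <- psi_bv
  as.numeric(Matrix::solve(K2, Fv))
}

## ordered closed counter-clockwise loop of boundary nodes (first node
## repeated at the end); stored edge chains are not consistently oriented,
## so walk the undirected adjacency and fix the orientation by signed area
boundary_loop <- function(mesh) {
  ed <- mesh$boundary
  nb <- list()
  addn <- function(a, b) {
    ka <- as.character(a)
    nb[[ka]] <<- c(nb[[ka]], b)
  }
  for (r in seq_len(nrow(ed))) { addn(ed$n1[r], ed$n2[r]); addn(ed$n2[r], ed$n1[r]) }
  start <- ed$n1[1]
  loop <- c(start)
  prev <- -1L
  cur <- start
  for (k in seq_len(nrow(ed))) {
    cand <- nb[[as.character(cur)]]
    nxt <- cand[cand != prev][1]
    loop <- c(loop, nxt)
    prev <- cur; cur <- nxt
    if (cur == start) break
  }
  xy <- mesh$nodes[loop, , drop = FALSE]
  a2 <- sum(xy[-nrow(xy), 1] * xy[-1, 2] - xy[-1, 1] * xy[-nrow(xy), 2])
  if (a2 < 0) loop <- rev(loop)
  loop
}

#' Net flux through a tagged boundary
#'
#' Line integral of `u . n` (outward normal) over all edges of a tag.
#'
#' @param sol a `flow_solution`
#' @param tag boundary tag
#' @return scalar flux (positive outward)
#' @export
boundary_flux <- function(sol, tag) {
  mesh <- sol$mesh
  ed <- mesh$boundary[mesh$boundary$tag == tag, , drop = FALSE]
  if (!nrow(ed)) stop("configuration error: unknown tag '", tag, "'",
                      call. = FALSE)
  x1 <- mesh$nodes[ed$n1, 1]; y1 <- mesh$nodes[ed$n1, 2]
  x2 <- mesh$nodes[ed$n2, 1]; y2 <- mesh$nodes[ed$n2, 2]
  um <- (sol$u[ed$n1] + sol$u[ed$n2]) / 2
  vm <- (sol$v[ed$n1] + sol$v[ed$n2]) / 2
  ## orient each edge normal outward using the adjacent element centroid
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tri <- mesh$tri
  ek <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]), key(tri[, 3], tri[, 1]))
  eid <- rep(seq_len(nrow(tri)), 3)
  adj <- eid[match(key(ed$n1, ed$n2), ek)]
  cx <- rowMeans(matrix(mesh$nodes[tri[adj, ], 1], ncol = 3))
  cy <- rowMeans(matrix(mesh$nodes[tri[adj, ], 2], ncol = 3))
  nx <- y2 - y1; ny <- -(x2 - x1)
  outward <- sign(nx * ((x1 + x2) / 2 - cx) + ny * ((y1 + y2) / 2 - cy))
  sum(outward * (um * nx + vm * ny))
}

#' Mass-conservation audit
#'
#' @param sol a `flow_solution`
#' @return list with per-tag fluxes and the net imbalance relative to
#'   the inflow flux
#' @export
mass_audit <- function(sol) {
  tags <- unique(sol$mesh$boundary$tag)
  fl <- vapply(tags, function(tg) boundary_flux(sol, tg), numeric(1))
  qin <- abs(fl[["inflow"]])
  list(fluxes = fl, net = sum(fl), imbalance_rel = abs(sum(fl)) / qin)
}
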