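#' Six-point Gaussian quadrature on the reference triangle
#'
#' Degree-4 exact rule on the unit reference triangle with vertices
#' (0,0), (1,0), (0,1).  Weights are positive and sum to the reference
#' area 1/2.
#'
#' @return list with `points` (6 x 2 reference coordinates), `weights`
#'   (length 6, summing to 1/2), and `bary` (6 x 3 barycentric
#'   coordinates, equal to the P1 shape-function values at each point)
#' @export
triangle_quadrature <- function() {
  a1 <- 0.108103018168070; b1 <- 0.445948490915965; w1 <- 0.223381589678011
  a2 <- 0.816847572980459; b2 <- 0.091576213509771; w2 <- 0.109951743655322
  bary <- rbind(c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
                c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(w1, w1, w1, w2, w2, w2) / 2    # reference-triangle area 1/2
  list(points = bary[, 2:3], weights = w, bary = bary)
}

## per-mesh constant FEM data: P1 gradients, areas, quadrature
fem_precompute <- function(mesh) {
  tri <- mesh$tri
  x <- matrix(mesh$nodes[tri, 1], ncol = 3)
  y <- matrix(mesh$nodes[tri, 2], ncol = 3)
  A2 <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) - (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])
  qr <- triangle_quadrature()
  list(mesh = mesh, tri = tri,
       b = cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / A2,
       c = cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / A2,
       A = A2 / 2, h = mesh$h_K,
       N = qr$bary, w = 2 * qr$weights,   # w * A integrates over the element
       nn = nrow(mesh$nodes), ne = nrow(tri),
       gdof = cbind(tri, nrow(mesh$nodes) + tri, 2L * nrow(mesh$nodes) + tri))
}

#' GLS stabilization parameter
#'
#' Element stabilization `tau(Re_K) = (h_K / (2 |u|_p)) xi(Re_K)` with
#' the element Reynolds number `Re_K = m_K |u|_p h_K Re / (4 eta)` (the
#' dimensionless transcription; the printed dimensional form with the
#' density prefactor is available as `form = "dimensional"`), the capped
#' function `xi = min(Re_K, 1)`, and `m_K = 1/3` for linear elements.
#' In the diffusive branch `Re_K < 1` the algebraically equivalent form
#' `tau = m_K h_K^2 Re / (8 eta)` is used, which is well defined as
#' `|u|_p -> 0`.
#'
#' @param h_K element size(s)
#' @param u_elem,v_elem element-centroid velocity components
#' @param eta element apparent viscosity
#' @param Re_global global Reynolds number
#' @param m_K element constant (1/3 for P1)
#' @param form `"dimensionless"` (default) or `"dimensional"`
#' @return list with `tau`, `Re_K` and `xi` (vectors)
#' @export
stabilization_parameter <- function(h_K, u_elem, v_elem, eta, Re_global,
                                    m_K = 1 / 3, form = "dimensionless") {
  speed <- sqrt(u_elem^2 + v_elem^2)
  scl <- if (identical(form, "dimensional")) 1 else Re_global
  Re_K <- m_K * speed * h_K * scl / (4 * eta)
  xi <- pmin(Re_K, 1)
  tau <- ifelse(Re_K < 1, m_K * h_K^2 * scl / (8 * eta), h_K / (2 * speed))
  list(tau = tau, Re_K = Re_K, xi = xi)
}

#' Dirichlet/pin boundary conditions for a flow problem
#'
#' Walls (tags `outer_wall`, `inner_wall`, `wall`) carry `u = v = 0`;
#' inflow nodes carry the fully developed inlet profile (or a supplied
#' profile); pressure pins are `p = 0` constraints at the boundary nodes
#' nearest the pin coordinates (default: the domain's own pins, if any).
#' Outflow/outlet segments are natural (traction-free) and need no
#' constraint.
#'
#' @param mesh a `tri_mesh`
#' @param n_inlet power-law index used in the inlet profile
#' @param inflow_profile optional function of y overriding the inlet
#'   axial-velocity profile
#' @param pins 2-column matrix of pin coordinates, `NULL` for the
#'   domain default, or `FALSE` for none
#' @return list with `dof`, `val` and the node index sets
#' @export
flow_bcs <- function(mesh, n_inlet = 1, inflow_profile = NULL, pins = NULL) {
  nn <- nrow(mesh$nodes)
  bnd <- mesh$boundary
  wall_tags <- c("outer_wall", "inner_wall", "wall")
  wall_nodes <- sort(unique(c(bnd$n1[bnd$tag %in% wall_tags],
                              bnd$n2[bnd$tag %in% wall_tags])))
  inflow_nodes <- sort(unique(c(bnd$n1[bnd$tag == "inflow"],
                                bnd$n2[bnd$tag == "inflow"])))
  prof <- if (is.null(inflow_profile)) function(y) inlet_velocity(y, n_inlet)
          else inflow_profile
  if (is.null(pins)) pins <- mesh$domain$pins
  pin_nodes <- integer(0)
  if (!isFALSE(pins) && !is.null(pins)) {
    bn <- sort(unique(c(bnd$n1, bnd$n2)))
    hloc <- max(mesh$h_K)
    for (kp in seq_len(nrow(pins))) {
      d2 <- (mesh$nodes[bn, 1] - pins[kp, 1])^2 + (mesh$nodes[bn, 2] - pins[kp, 2])^2
      jm <- which.min(d2)
      if (sqrt(d2[jm]) > hloc)
        stop("configuration error: pressure pin (", pins[kp, 1], ", ",
             pins[kp, 2], ") farther than one element size from the boundary",
             call. = FALSE)
      pin_nodes <- c(pin_nodes, bn[jm])
    }
  }
  ## walls first, inflow overrides (corner nodes get the profile value, 0)
  uval <- rep(NA_real_, nn)
  uval[wall_nodes] <- 0
  uval[inflow_nodes] <- prof(mesh$nodes[inflow_nodes, 2])
  vnodes <- sort(unique(c(wall_nodes, inflow_nodes)))
  unodes <- vnodes
  dof <- c(unodes, nn + vnodes, 2L * nn + pin_nodes)
  val <- c(uval[unodes], rep(0, length(vnodes)), rep(0, length(pin_nodes)))
  list(dof = dof, val = val, wall_nodes = wall_nodes,
       inflow_nodes = inflow_nodes, pin_nodes = pin_nodes)
}

## Nonlinear GLS residual and (optionally) its Jacobian.
##
## U = [u(1..nn), v, p].  The stabilization parameter tau is evaluated
## from the current iterate (or taken from tau_fixed) and held constant
## under differentiation; the apparent-viscosity derivative terms are
## included in "analytic" mode and dropped in "frozen" mode.
assemble_system <- function(fp, phys, U, bc = NULL,
                            jacobian = c("analytic", "frozen", "none"),
                            tau_fixed = NULL) {
  jacobian <- match.arg(jacobian)
  nn <- fp$nn; ne <- fp$ne
  tri <- fp$tri; b <- fp$b; cc <- fp$c; A <- fp$A
  ue <- matrix(U[tri], ncol = 3)
  ve <- matrix(U[nn + tri], ncol = 3)
  pe <- matrix(U[2L * nn + tri], ncol = 3)

  G11 <- rowSums(b * ue); G12 <- rowSums(cc * ue)
  G21 <- rowSums(b * ve); G22 <- rowSums(cc * ve)
  D12 <- (G12 + G21) / 2
  dxp <- rowSums(b * pe); dyp <- rowSums(cc * pe)

  n <- phys$n
  I2 <- shear_rate_invariant(G11, G12, G21, G22)
  fl2 <- phys$gamma_floor^2
  if (n == 1) {
    eta <- rep(1, ne); detadI2 <- numeric(ne)
  } else {
    I2f <- pmax(I2, fl2)
    eta <- I2f^((n - 1) / 2)
    detadI2 <- ifelse(I2 > fl2, (n - 1) / 2 * eta / I2f, 0)
  }
  if (jacobian == "frozen") detadI2 <- numeric(ne)

  tau <- if (is.null(tau_fixed)) {
    stabilization_parameter(fp$h, rowMeans(ue), rowMeans(ve), eta, phys$Re,
                            phys$m_K, phys$tau_form)$tau
  } else tau_fixed

  MMRe <- phys$M^2 / phys$Re
  Rl <- matrix(0, ne, 9)
  want_J <- jacobian != "none"
  if (want_J) Jl <- array(0, c(ne, 9, 9))

  for (q in seq_len(nrow(fp$N))) {
    Nq <- fp$N[q, ]
    w2A <- fp$w[q] * A
    uq <- drop(ue %*% Nq); vq <- drop(ve %*% Nq); pq <- drop(pe %*% Nq)
    advr1 <- uq * G11 + vq * G12
    advr2 <- uq * G21 + vq * G22
    S1 <- advr1 + dxp + MMRe * uq
    S2 <- advr2 + dyp
    for (i in 1:3) {
      Pi <- uq * b[, i] + vq * cc[, i]
      Rl[, i] <- Rl[, i] + w2A * (Nq[i] * (advr1 + MMRe * uq) - pq * b[, i] +
                                  tau * S1 * Pi)
      Rl[, 3 + i] <- Rl[, 3 + i] + w2A * (Nq[i] * advr2 - pq * cc[, i] +
                                          tau * S2 * Pi)
      Rl[, 6 + i] <- Rl[, 6 + i] + w2A * (-Nq[i] * (G11 + G22) -
                                          tau * (S1 * b[, i] + S2 * cc[, i]))
      if (want_J) {
        for (k in 1:3) {
          Pk <- uq * b[, k] + vq * cc[, k]
          dS1du <- Nq[k] * G11 + Pk + MMRe * Nq[k]
          dS1dv <- Nq[k] * G12
          dS2du <- Nq[k] * G21
          dS2dv <- Nq[k] * G22 + Pk
          Jl[, i, k] <- Jl[, i, k] + w2A *
            (Nq[i] * dS1du + tau * (dS1du * Pi + S1 * Nq[k] * b[, i]))
          Jl[, i, 3 + k] <- Jl[, i, 3 + k] + w2A *
            (Nq[i] * dS1dv + tau * (dS1dv * Pi + S1 * Nq[k] * cc[, i]))
          Jl[, i, 6 + k] <- Jl[, i, 6 + k] + w2A *
            (-Nq[k] * b[, i] + tau * b[, k] * Pi)
          Jl[, 3 + i, k] <- Jl[, 3 + i, k] + w2A *
            (Nq[i] * dS2du + tau * (dS2du * Pi + S2 * Nq[k] * b[, i]))
          Jl[, 3 + i, 3 + k] <- Jl[, 3 + i, 3 + k] + w2A *
            (Nq[i] * dS2dv + tau * (dS2dv * Pi + S2 * Nq[k] * cc[, i]))
          Jl[, 3 + i, 6 + k] <- Jl[, 3 + i, 6 + k] + w2A *
            (-Nq[k] * cc[, i] + tau * cc[, k] * Pi)
          Jl[, 6 + i, k] <- Jl[, 6 + i, k] + w2A *
            (-Nq[i] * b[, k] - tau * (dS1du * b[, i] + dS2du * cc[, i]))
          Jl[, 6 + i, 3 + k] <- Jl[, 6 + i, 3 + k] + w2A *
            (-Nq[i] * cc[, k] - tau * (dS1dv * b[, i] + dS2dv * cc[, i]))
          Jl[, 6 + i, 6 + k] <- Jl[, 6 + i, 6 + k] + w2A *
            (-tau * (b[, k] * b[, i] + cc[, k] * cc[, i]))
        }
      }
    }
  }

  ## viscous (elementwise-constant) contributions and eta derivatives
  twoARe <- 2 * A / phys$Re
  for (i in 1:3) {
    v1 <- G11 * b[, i] + D12 * cc[, i]
    v2 <- G22 * cc[, i] + D12 * b[, i]
    Rl[, i] <- Rl[, i] + twoARe * eta * v1
    Rl[, 3 + i] <- Rl[, 3 + i] + twoARe * eta * v2
    if (want_J) {
      for (k in 1:3) {
        detadu <- detadI2 * (4 * G11 * b[, k] + 2 * (G12 + G21) * cc[, k])
        detadv <- detadI2 * (4 * G22 * cc[, k] + 2 * (G12 + G21) * b[, k])
        Jl[, i, k] <- Jl[, i, k] + twoARe *
          (eta * (b[, k] * b[, i] + 0.5 * cc[, k] * cc[, i]) + v1 * detadu)
        Jl[, i, 3 + k] <- Jl[, i, 3 + k] + twoARe *
          (eta * 0.5 * b[, k] * cc[, i] + v1 * detadv)
        Jl[, 3 + i, k] <- Jl[, 3 + i, k] + twoARe *
          (eta * 0.5 * cc[, k] * b[, i] + v2 * detadu)
        Jl[, 3 + i, 3 + k] <- Jl[, 3 + i, 3 + k] + twoARe *
          (eta * (cc[, k] * cc[, i] + 0.5 * b[, k] * b[, i]) + v2 * detadv)
      }
    }
  }

  ## scatter to the global residual
  R <- numeric(3L * nn)
  rs <- rowsum(as.vector(Rl), as.vector(fp$gdof))
  R[as.integer(rownames(rs))] <- rs

  J <- NULL
  if (want_J) {
    ii <- as.vector(fp$gdof[, rep(1:9, times = 9)])
    jj <- as.vector(fp$gdof[, rep(1:9, each = 9)])
    xx <- as.vector(Jl)
    if (!is.null(bc)) {
      isdir <- logical(3L * nn); isdir[bc$dof] <- TRUE
      keep <- !isdir[ii]
      J <- Matrix::sparseMatrix(i = c(ii[keep], bc$dof),
                                j = c(jj[keep], bc$dof),
                                x = c(xx[keep], rep(1, length(bc$dof))),
                                dims = c(3L * nn, 3L * nn))
    } else {
      J <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(3L * nn, 3L * nn))
    }
  }
  if (!is.null(bc)) R[bc$dof] <- U[bc$dof] - bc$val
  list(R = R, J = J, tau = tau, eta = eta, res2 = sum(R^2))
}
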