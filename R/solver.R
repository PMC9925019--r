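#' Solver configuration
#'
#' @param tol convergence threshold on the sum of squared residual
#'   entries (default 1e-4).  A case is declared converged once the sum
#'   falls to or below this value
#' @param tol_stop iteration-stopping threshold (default 1e-12): once
#'   declared converged, Newton keeps iterating until the residual
#'   reaches this level or stagnates, so post-processed quantities do
#'   not depend on where inside the convergence basin the iteration
#'   happened to stop
#' @param max_iter Newton iteration cap per continuation stage
#' @param damping initial step factor in (0, 1]; steps are halved
#'   automatically while the residual grows
#' @param jacobian `"analytic"` (includes the apparent-viscosity
#'   derivative terms), `"frozen"` (Picard-like, viscosity frozen) or
#'   `"fd"` (dense finite differences; tiny meshes only)
#' @param quiet suppress per-iteration residual messages
#' @return list of class `solver_config`
#' @export
solver_config <- function(tol = 1e-4, max_iter = 25, damping = 1,
                          jacobian = "analytic", tol_stop = 1e-12,
                          quiet = TRUE) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1, tol_stop <= tol)
  cfg <- list(tol = tol, max_iter = max_iter, damping = damping,
              jacobian = jacobian, tol_stop = tol_stop, quiet = quiet)
  class(cfg) <- "solver_config"
  cfg
}

make_phys <- function(Re, M, n, gamma_floor = 1e-6, m_K = 1 / 3,
                      tau_form = "dimensionless") {
  stopifnot(Re > 0, M >= 0, n > 0)
  list(Re = Re, M = M, n = n, gamma_floor = gamma_floor, m_K = m_K,
       tau_form = tau_form)
}

#' Stokes initial guess
#'
#' Solves the linear Stokes problem (advective terms absent, n = 1, the
#' linear Lorentz term retained) under the same boundary conditions;
#' this is the initial iterate for the Newton solve.
#'
#' @param mesh a `tri_mesh`
#' @param Re,M Reynolds and Hartmann numbers
#' @param bc boundary conditions from [flow_bcs()]
#' @return the stacked solution vector `U0 = [u, v, p]`
#' @export
initial_guess <- function(mesh, Re, M = 0, bc = flow_bcs(mesh)) {
  fp <- fem_precompute(mesh)
  stokes_guess(fp, make_phys(Re, M, 1), bc)
}

stokes_guess <- function(fp, phys, bc) {
  phys$n <- 1
  U0 <- numeric(3L * fp$nn)
  asm <- assemble_system(fp, phys, U0, bc = bc, jacobian = "analytic")
  as.numeric(Matrix::solve(asm$J, -asm$R))
}

## finite-difference Jacobian of the full residual (tau frozen at U)
fd_jacobian <- function(fp, phys, U, bc = NULL, eps_scale = 1e-7) {
  base <- assemble_system(fp, phys, U, bc = bc, jacobian = "none")
  tau0 <- base$tau
  nd <- length(U)
  J <- matrix(0, nd, nd)
  for (j in seq_len(nd)) {
    eps <- eps_scale * (1 + abs(U[j]))
    Up <- U; Up[j] <- U[j] + eps
    Um <- U; Um[j] <- U[j] - eps
    Rp <- assemble_system(fp, phys, Up, bc = bc, jacobian = "none",
                          tau_fixed = tau0)$R
    Rm <- assemble_system(fp, phys, Um, bc = bc, jacobian = "none",
                          tau_fixed = tau0)$R
    J[, j] <- (Rp - Rm) / (2 * eps)
  }
  J
}

#' Newton-Raphson solve of the nonlinear GLS system
#'
#' Iterates `U <- U - J^-1 R(U)` (with automatic step halving while the
#' residual grows) until the sum of squared residual entries falls to or
#' below `config$tol`, the printed stopping rule.  When the analytic
#' Newton step stalls, one frozen-viscosity (Picard-like) step is tried
#' before declaring divergence.
#'
#' @param mesh a `tri_mesh`
#' @param phys list with `Re`, `M`, `n` (see internals of
#'   [solve_flow()]); built by the higher-level drivers
#' @param bc boundary conditions from [flow_bcs()]
#' @param U0 initial iterate (e.g. [initial_guess()])
#' @param config a [solver_config()]
#' @return list with `U`, `converged`, `residual_history`, `iterations`
#' @export
newton_solve <- function(mesh, phys, bc, U0, config = solver_config()) {
  fp <- if (!is.null(mesh$gdof)) mesh else fem_precompute(mesh)
  U <- U0
  hist <- numeric(0)
  bad_streak <- 0L
  mode <- config$jacobian
  tol_stop <- if (is.null(config$tol_stop)) config$tol else config$tol_stop
  for (it in seq_len(config$max_iter)) {
    asm <- assemble_system(fp, phys, U, bc = bc, jacobian = mode)
    prev <- if (it > 1L) hist[it - 1L] else Inf
    hist <- c(hist, asm$res2)
    if (!config$quiet)
      message(sprintf("  newton %2d: sum R^2 = %.3e", it, asm$res2))
    if (asm$res2 <= tol_stop ||
        (asm$res2 <= config$tol && asm$res2 > 0.2 * prev))
      return(list(U = U, converged = TRUE, residual_history = hist,
                  iterations = it - 1L))
    delta <- as.numeric(Matrix::solve(asm$J, -asm$R))
    alpha <- config$damping
    improved <- FALSE
    for (h in 0:5) {
      res2_new <- assemble_system(fp, phys, U + alpha * delta, bc = bc,
                                  jacobian = "none")$res2
      if (is.finite(res2_new) && res2_new < asm$res2) { improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved && mode == "analytic") {
      ## frozen-viscosity fallback step
      asm2 <- assemble_system(fp, phys, U, bc = bc, jacobian = "frozen")
      delta <- as.numeric(Matrix::solve(asm2$J, -asm2$R))
      alpha <- config$damping
      for (h in 0:5) {
        res2_new <- assemble_system(fp, phys, U + alpha * delta, bc = bc,
                                    jacobian = "none")$res2
        if (is.finite(res2_new) && res2_new < asm$res2) { improved <- TRUE; break }
        alpha <- alpha / 2
      }
    }
    U <- U + alpha * delta
    bad_streak <- if (improved) 0L else bad_streak + 1L
    if (bad_streak >= 3L) {
      err <- simpleError("newton_solve: residual grew over 3 consecutive damped iterations")
      err$residual_history <- hist
      stop(err)
    }
  }
  asm <- assemble_system(fp, phys, U, bc = bc, jacobian = "none")
  hist <- c(hist, asm$res2)
  list(U = U, converged = asm$res2 <= config$tol, residual_history = hist,
       iterations = config$max_iter)
}

## default continuation schedule towards (n, M): Newtonian Navier-Stokes
## first, then the rheology, then the Hartmann number in steps of <= 4
continuation_stages <- function(n, M, M_step = 4) {
  stages <- list(list(n = 1, M = 0))
  if (n != 1) stages <- c(stages, list(list(n = n, M = 0)))
  if (M > 0) {
    Ms <- seq(min(M_step, M), M, by = M_step)
    if (Ms[length(Ms)] < M) Ms <- c(Ms, M)
    for (m in Ms) stages <- c(stages, list(list(n = n, M = m)))
  }
  stages
}

#' Solve a flow case (or a Hartmann-number ladder of cases)
#'
#' Full pipeline on a given mesh: Stokes initialization, then
#' Newton-Raphson continuation through the default schedule (Newtonian
#' Navier-Stokes at the target Re, then the target power-law index, then
#' the Hartmann number ramped in steps of at most 4).  With `M_values`,
#' all listed Hartmann numbers are solved in one continuation sweep and
#' a named list of solutions is returned.
#'
#' @param mesh a `tri_mesh`
#' @param Re Reynolds number
#' @param n power-law index
#' @param M Hartmann number (ignored when `M_values` is given)
#' @param M_values optional increasing vector of Hartmann numbers
#' @param config a [solver_config()]
#' @param gamma_floor shear-rate regularization floor
#' @param tau_form stabilization form, `"dimensionless"` or
#'   `"dimensional"`
#' @param bc optional [flow_bcs()] override
#' @return a `flow_solution` (list with `u`, `v`, `p`, `U`, `history`,
#'   `converged`, `mesh`, parameters), or a named list of them for
#'   `M_values`
#' @export
solve_flow <- function(mesh, Re = 300, n = 1, M = 0, M_values = NULL,
                       config = solver_config(), gamma_floor = 1e-6,
                       tau_form = "dimensionless", bc = NULL) {
  fp <- fem_precompute(mesh)
  if (is.null(bc)) bc <- flow_bcs(mesh, n_inlet = n)
  ladder <- !is.null(M_values)
  Mtar <- if (ladder) max(M_values) else M
  stages <- continuation_stages(n, Mtar)
  phys0 <- make_phys(Re, 0, 1, gamma_floor, tau_form = tau_form)
  ## the Newtonian stages use the Newtonian inlet profile; the target
  ## rheology stages use the target profile
  bc1 <- if (n != 1) flow_bcs(mesh, n_inlet = 1,
                              pins = if (length(bc$pin_nodes)) NULL else FALSE)
         else bc
  U <- stokes_guess(fp, phys0, bc1)
  history <- list()
  out <- list()
  capture <- function(U, hist, stage, conv) {
    sol <- list(mesh = mesh, Re = Re, n = stage$n, M = stage$M,
                u = U[seq_len(fp$nn)], v = U[fp$nn + seq_len(fp$nn)],
                p = U[2L * fp$nn + seq_len(fp$nn)], U = U,
                history = hist, converged = conv,
                gamma_floor = gamma_floor, tau_form = tau_form)
    class(sol) <- "flow_solution"
    sol
  }
  for (s in stages) {
    phys <- make_phys(Re, s$M, s$n, gamma_floor, tau_form = tau_form)
    bcs <- if (s$n == phys0$n && n != 1) bc1 else bc
    res <- newton_solve(fp, phys, bcs, U, config)
    U <- res$U
    history[[length(history) + 1L]] <-
      data.frame(n = s$n, M = s$M, iter = seq_along(res$residual_history),
                 res2 = res$residual_history)
    if (!res$converged)
      warning(sprintf("stage (n=%g, M=%g) did not meet the residual tolerance",
                      s$n, s$M))
    if (ladder && s$n == n && s$M %in% M_values)
      out[[paste0("M", s$M)]] <- capture(U, do.call(rbind, history), s,
                                         res$converged)
  }
  hist <- do.call(rbind, history)
  if (ladder) return(out)
  capture(U, hist, list(n = n, M = Mtar), res$converged)
}
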