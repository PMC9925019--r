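test_that("the Stokes initial guess matches the Poiseuille oracle on a channel", {
  mesh <- channel_mesh()
  U0 <- initial_guess(mesh, Re = 300)
  idx <- which(abs(mesh$nodes[, 1] - 2) < 1e-9)
  y <- mesh$nodes[idx, 2]
  uex <- power_law_poiseuille(y, 1, 12 / 300, 300)
  expect_lt(sqrt(sum((U0[idx] - uex)^2) / sum(uex^2)), 0.01)
  ## walls exact
  bc <- flow_bcs(mesh)
  expect_equal(max(abs(U0[bc$wall_nodes])), 0)
})

test_that("Newton converges quadratically and meets the residual rule", {
  mesh <- channel_mesh()
  sol <- solve_flow(mesh, Re = 300, n = 1, M = 0)
  expect_true(sol$converged)
  h <- sol$history$res2
  expect_lte(min(h), 1e-4)
  ## monotone decrease within each stage after at most 3 steps
  for (stage in split(sol$history, sol$history$M)) {
    r <- stage$res2
    if (length(r) > 3) expect_true(all(diff(r[-(1:3)]) <= 0))
  }
  ## superlinear tail: successive ratios shrink once below 1
  r <- h[h < 1]
  if (length(r) > 2) expect_lt(r[length(r)] / r[length(r) - 1],
                               r[length(r) - 1] / r[length(r) - 2] + 1e-12)
})

test_that("converged channel flow matches the power-law and Hartmann oracles", {
  mesh <- channel_mesh()
  idx <- which(abs(mesh$nodes[, 1] - 2) < 1e-9)
  y <- mesh$nodes[idx, 2]
  ## power-law Poiseuille, shear-thinning: the inlet profile is the
  ## fully developed state, so the interior must reproduce it
  n <- 0.639
  sol <- solve_flow(mesh, Re = 300, n = n, M = 0)
  uex <- inlet_velocity(y, n)
  expect_lt(sqrt(sum((sol$u[idx] - uex)^2) / sum(uex^2)), 0.01)
  ## flatter than the Newtonian profile at |y| = 0.25
  expect_gt(inlet_velocity(0.25, n) / 1.5, 1.125 / 1.5)
  ## Hartmann flow at M = 6 under a matched pressure gradient
  M <- 6; G <- 12 / 300
  bc <- flow_bcs(mesh, inflow_profile = function(yy)
    hartmann_profile(yy, M, 300, G))
  solH <- solve_flow(mesh, Re = 300, n = 1, M = M, bc = bc)
  uH <- hartmann_profile(y, M, 300, G)
  expect_lt(sqrt(sum((solH$u[idx] - uH)^2) / sum(uH^2)), 0.01)
})

test_that("centreline velocity decreases monotonically with the Hartmann number", {
  mesh <- channel_mesh(0.1, length = 2)
  sols <- solve_flow(mesh, Re = 300, n = 1, M_values = c(0, 4, 8, 12))
  ic <- which.min((mesh$nodes[, 1] - 1)^2 + mesh$nodes[, 2]^2)
  uc <- vapply(sols, function(s) s$u[ic], numeric(1))
  expect_true(all(diff(uc) < 0))
  ## and the closed-form oracle shows the same ordering
  uo <- vapply(c(4, 8, 12), function(M)
    hartmann_profile(0, M, 300, 12 / 300), numeric(1))
  expect_true(all(diff(uo) < 0))
})

test_that("continuation through intermediate stages lands on the same state", {
  mesh <- bif_mesh_coarse()
  cfg <- solver_config()
  direct <- solve_flow(mesh, Re = 300, n = 0.639, M = 8, config = cfg)
  staged <- solve_flow(mesh, Re = 300, n = 0.639, M_values = c(4, 8),
                       config = cfg)$M8
  ## same converged state within a residual-scale tolerance
  expect_lt(max(abs(direct$U - staged$U)) / max(abs(direct$U)), 1e-6)
})

test_that("a frozen-viscosity Jacobian equals the analytic one at n = 1", {
  m <- tiny_mesh(3, 2)
  fp <- stenofem:::fem_precompute(m)
  set.seed(7)
  U <- rnorm(3 * fp$nn, 0, 0.4)
  phys <- stenofem:::make_phys(100, 2, 1)
  Ja <- as.matrix(stenofem:::assemble_system(fp, phys, U, jacobian = "analytic")$J)
  Jf <- as.matrix(stenofem:::assemble_system(fp, phys, U, jacobian = "frozen")$J)
  expect_equal(Ja, Jf)
  ## and differs for shear-thinning rheology
  phys2 <- stenofem:::make_phys(100, 2, 0.639)
  Ja2 <- as.matrix(stenofem:::assemble_system(fp, phys2, U, jacobian = "analytic")$J)
  Jf2 <- as.matrix(stenofem:::assemble_system(fp, phys2, U, jacobian = "frozen")$J)
  expect_gt(max(abs(Ja2 - Jf2)), 1e-8)
})

test_that("a missing pressure pin on an enclosed problem raises a solver error", {
  ## all-Dirichlet cavity with no pin: the Stokes matrix is singular
  mesh <- generate_mesh(straight_channel_domain(1, 0.5),
                        list(global_max = 0.25))
  fp <- stenofem:::fem_precompute(mesh)
  nn <- fp$nn
  bn <- sort(unique(c(mesh$boundary$n1, mesh$boundary$n2)))
  bc <- list(dof = c(bn, nn + bn), val = rep(0, 2 * length(bn)),
             pin_nodes = integer(0))
  expect_error(stenofem:::stokes_guess(fp, stenofem:::make_phys(1, 0, 1), bc))
})
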