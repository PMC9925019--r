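## closed-form reference-triangle moments: int x^a y^b = a! b! / (a+b+2)!
ref_moment <- function(a, b) factorial(a) * factorial(b) / factorial(a + b + 2)

test_that("six-point quadrature is exact through total degree 4", {
  qr <- triangle_quadrature()
  expect_true(all(qr$weights > 0))
  expect_equal(sum(qr$weights), 0.5)          # reference-triangle area
  for (a in 0:4) for (b in 0:(4 - a)) {
    got <- sum(qr$weights * qr$points[, 1]^a * qr$points[, 2]^b)
    expect_equal(got, ref_moment(a, b), tolerance = 1e-14,
                 label = sprintf("moment x^%d y^%d", a, b))
  }
  ## spot values: int 1 = 1/2, int x = 1/6, int x^4 = 1/30
  expect_equal(sum(qr$weights), 1 / 2)
  expect_equal(sum(qr$weights * qr$points[, 1]), 1 / 6)
  expect_equal(sum(qr$weights * qr$points[, 1]^4), 1 / 30)
  ## barycentric rows are the P1 partition of unity
  expect_equal(rowSums(qr$bary), rep(1, 6))
})

test_that("stabilization parameter reproduces the capped element Reynolds form", {
  ## advective branch: Re_K >= 1 gives xi = 1, tau = h / (2 |u|)
  s <- stabilization_parameter(0.1, 1, 0, eta = 1, Re_global = 300)
  expect_equal(s$xi, 1)
  expect_equal(s$tau, 0.05)
  ## diffusive branch: xi = Re_K < 1 and the |u|-free equivalent form
  s2 <- stabilization_parameter(0.01, 0.1, 0, eta = 1, Re_global = 300)
  expect_lt(s2$Re_K, 1)
  expect_equal(s2$xi, s2$Re_K)
  expect_equal(s2$tau, (1 / 3) * 0.01^2 * 300 / 8)
  ## |u|_p is the Euclidean norm: (3,4) behaves as speed 5
  expect_equal(stabilization_parameter(0.1, 3, 4, 1, 300)$tau,
               stabilization_parameter(0.1, 5, 0, 1, 300)$tau)
  ## zero-velocity limit is finite (diffusive form)
  s0 <- stabilization_parameter(0.05, 0, 0, 1, 300)
  expect_true(is.finite(s0$tau) && s0$tau > 0)
  ## xi branch values as printed
  expect_equal(stabilization_parameter(1, 0.5 * 4 * 3 / 300, 0, 1, 300)$xi,
               0.5, tolerance = 1e-12)
})

test_that("element systems vanish on constant fields and without a magnetic field", {
  m <- tiny_mesh(3, 2)
  fp <- stenofem:::fem_precompute(m)
  nn <- fp$nn
  ## spatially constant velocity, zero pressure: all residual blocks vanish
  U <- c(rep(0.8, nn), rep(-0.3, nn), rep(0, nn))
  asm <- stenofem:::assemble_system(fp, stenofem:::make_phys(100, 0, 1), U)
  expect_lt(max(abs(asm$R)), 1e-12)
  ## U = 0 with no traction and no body force: residual is exactly zero
  asm0 <- stenofem:::assemble_system(fp, stenofem:::make_phys(100, 5, 0.8),
                                     numeric(3 * nn))
  expect_equal(max(abs(asm0$R)), 0)
  ## M = 0 removes the Lorentz contribution entirely
  U2 <- c(rep(0.8, nn), rep(0, nn), rep(0, nn))
  r_M0 <- stenofem:::assemble_system(fp, stenofem:::make_phys(100, 0, 1), U2)$R
  r_M5 <- stenofem:::assemble_system(fp, stenofem:::make_phys(100, 5, 1), U2)$R
  dif <- r_M5 - r_M0
  expect_gt(max(abs(dif)), 0)
  ## the Lorentz force has zero second component: v-rows are unaffected
  expect_lt(max(abs(dif[nn + seq_len(nn)])), 1e-15)
})

test_that("element matrices are translation invariant", {
  mk <- function(shift) {
    nodes <- rbind(c(0, 0), c(1, 0), c(0.6, 0.9), c(1.4, 1)) +
      matrix(shift, 4, 2, byrow = TRUE)
    m <- list(nodes = nodes, tri = rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
    met <- element_metrics(m)
    m$h_K <- met$h_K; m$area <- met$area
    m
  }
  U <- c(0.3, -0.2, 0.9, 0.4, 0.1, 0.5, -0.3, 0.2, 0.05, -0.4, 0.6, 0.15)
  phys <- stenofem:::make_phys(80, 2, 0.8)
  a1 <- stenofem:::assemble_system(stenofem:::fem_precompute(mk(c(0, 0))), phys, U)
  a2 <- stenofem:::assemble_system(stenofem:::fem_precompute(mk(c(2.7, -1.3))), phys, U)
  expect_equal(a1$R, a2$R, tolerance = 1e-12)
  expect_equal(as.matrix(a1$J), as.matrix(a2$J), tolerance = 1e-12)
})

test_that("Dirichlet rows impose walls, inflow and pins exactly", {
  m <- bif_mesh_coarse()
  bc <- flow_bcs(m, n_inlet = 1)
  U0 <- initial_guess(m, Re = 300, bc = bc)
  nn <- nrow(m$nodes)
  expect_equal(max(abs(U0[bc$wall_nodes])), 0)
  expect_equal(max(abs(U0[nn + c(bc$wall_nodes, bc$inflow_nodes)])), 0)
  expect_equal(U0[bc$inflow_nodes],
               inlet_velocity(m$nodes[bc$inflow_nodes, 2], 1))
  expect_length(bc$pin_nodes, 2)
  expect_equal(U0[2 * nn + bc$pin_nodes], c(0, 0))
  ## pins snap to the printed outlet corners
  expect_equal(m$nodes[bc$pin_nodes[1], ], c(4, 1.1556), tolerance = 1e-4)
  expect_equal(m$nodes[bc$pin_nodes[2], ], c(3.745, -1.5973), tolerance = 1e-4)
  ## a pin far from the boundary is a configuration error
  expect_error(flow_bcs(m, pins = rbind(c(2, 3))), "pin")
})

test_that("GLS stabilization suppresses the equal-order pressure modes", {
  ## lid-driven-style Stokes solve; with tau forced to ~0 the P1/P1 pair
  ## produces an oscillatory pressure, with tau per the Re_K formula it
  ## does not
  mesh <- generate_mesh(straight_channel_domain(1, 0.5),
                        list(global_max = 0.125))
  fp <- stenofem:::fem_precompute(mesh)
  nn <- fp$nn
  bnd <- mesh$boundary
  bn <- sort(unique(c(bnd$n1, bnd$n2)))
  top <- bn[abs(mesh$nodes[bn, 2] - 0.5) < 1e-9 &
            abs(mesh$nodes[bn, 1] - 0.5) < 0.5 - 1e-9]
  bc <- list(dof = c(bn, nn + bn, 2 * nn + bn[1]),
             val = c(ifelse(bn %in% top, 1, 0), rep(0, length(bn)), 0))
  phys <- stenofem:::make_phys(1, 0, 1)
  pspread <- function(tau_fixed) {
    asm <- stenofem:::assemble_system(fp, phys, numeric(3 * nn), bc = bc,
                                      jacobian = "analytic",
                                      tau_fixed = tau_fixed)
    p <- tryCatch(as.numeric(Matrix::solve(asm$J, -asm$R))[2 * nn + seq_len(nn)],
                  error = function(e) NULL)
    if (is.null(p)) return(Inf)      # singular: spurious modes present
    stats::sd(p)
  }
  ## the unstabilized equal-order pair is (near-)singular: its pressure
  ## blows up along the spurious modes; the stabilized one stays bounded
  expect_gt(pspread(rep(1e-14, fp$ne)), 100 * pspread(NULL))
})

test_that("assembled residual at a converged state meets the printed criterion", {
  sol <- poiseuille_channel_sol()
  expect_true(sol$converged)
  expect_lte(min(sol$history$res2), 1e-4)
  ## momentum residual of the interpolated exact solution decreases
  ## under refinement (consistency against the analytic oracle)
  resnorm <- function(gm) {
    mesh <- channel_mesh(gm)
    fp <- stenofem:::fem_precompute(mesh)
    nn <- fp$nn
    G <- 12 / 300
    U <- c(power_law_poiseuille(mesh$nodes[, 2], 1, G, 300), rep(0, nn),
           G * (4 - mesh$nodes[, 1]))
    bc <- flow_bcs(mesh)
    r <- stenofem:::assemble_system(fp, stenofem:::make_phys(300, 0, 1), U,
                                    bc = bc, jacobian = "none")$R
    sqrt(sum(r[seq_len(2 * nn)]^2))
  }
  expect_lt(resnorm(0.05), resnorm(0.1))
})
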