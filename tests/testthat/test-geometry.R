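test_that("junction parameters follow the closed-form expressions", {
  p <- artery_params()
  d <- derive_junction_parameters(p)
  ## frozen values evaluated directly from the printed formulas
  expect_equal(d$r0, (p$a - 2 * p$r1 / cos(p$beta)) / (cos(p$beta) - 1))
  expect_equal(d$r0, 0.009953, tolerance = 1e-4)
  expect_equal(d$s, 0.51 * p$a)          # 2 * 0.51 a * sin(30 deg)
  expect_equal(d$s / p$hbar, 0.255)
  expect_equal(d$r0p, 2e-4)              # sin(b)/(1 - sin(b)) = 1 at 30 deg
  expect_equal(d$x2, p$x1 + d$r0 * sin(p$beta))
  expect_equal(d$x4, d$x3 + d$r0p * (1 - sin(p$beta)))
  expect_true(p$x1 < d$x2 && d$x2 < d$x3 && d$x3 < d$x4 && d$x4 < p$x_max)
})

test_that("invalid geometries are rejected with a named constraint", {
  expect_error(artery_params(tau_m = 0.0075), "tau_m")
  expect_error(artery_params(q = 1e-3), "q")
  expect_error(artery_params(d = 0.02, l0 = 0.015), "d \\+ l0")
  p <- artery_params()
  p$beta <- 0
  expect_error(derive_junction_parameters(p), "beta")
})

test_that("overlapping stenosis profile has the exact throat and bridge values", {
  p <- artery_params()
  ## the two throats at d + l0/3 and d + 2 l0/3 reach a - tau_m exactly;
  ## the interior bridge at mid-stenosis is a - 3 tau_m / 4
  expect_equal(outer_wall_radius(p$d + p$l0 / 3, p), p$a - p$tau_m,
               tolerance = 1e-12)
  expect_equal(outer_wall_radius(p$d + 2 * p$l0 / 3, p), p$a - p$tau_m,
               tolerance = 1e-12)
  expect_equal(outer_wall_radius(p$d + p$l0 / 2, p), p$a - 0.75 * p$tau_m,
               tolerance = 1e-12)
  expect_equal(outer_wall_radius(p$d, p), p$a)
  expect_equal(outer_wall_radius(p$d + p$l0, p), p$a)
  expect_equal(outer_wall_radius(0.001, p), p$a)
})

test_that("wall radii are continuous at every breakpoint", {
  p <- artery_params()
  der <- derive_junction_parameters(p)
  eps <- 1e-9
  for (xb in c(p$d, p$d + p$l0, p$x1, der$x2)) {
    lo <- outer_wall_radius(xb - eps, p, der)
    hi <- outer_wall_radius(xb + eps, p, der)
    ## difference bounded by slope * 2 eps (slope <= ~4 dimensional)
    expect_lt(abs(hi - lo), 1e-7)
  }
  ## inner wall: value continuity at x3 and x4
  expect_equal(inner_wall_radius(der$x3, p, der), 0, tolerance = 1e-12)
  expect_equal(inner_wall_radius(der$x4, p, der), der$r0p * cos(p$beta),
               tolerance = 1e-12)
  expect_error(outer_wall_radius(p$x_max, p, der), "x outside")
  expect_error(inner_wall_radius(-0.01, p, der), "x outside")
})

test_that("terminal wall coordinates reproduce the pressure-pin points", {
  p <- artery_params()
  der <- derive_junction_parameters(p)
  ## dimensionless outlet corners, printed as (4, 1.1556) / (3.745, -1.5973)
  expect_equal(inner_wall_radius(p$x_max, p, der) / p$hbar, 1.1556,
               tolerance = 5e-5)
  expect_equal(outer_wall_radius(p$x_max - der$s, p, der) / p$hbar, 1.5973,
               tolerance = 5e-5)
  expect_equal((p$x_max - der$s) / p$hbar, 3.745)
})

test_that("the domain boundary is a closed, mirror-symmetric, tagged loop", {
  bd <- build_domain_boundary(artery_params())
  poly <- bd$polyline
  ## closed: last point connects back to the first (inflow foot)
  expect_equal(poly$x[1], 0)
  expect_equal(poly$y[1], -0.5)
  expect_setequal(unique(poly$tag),
                  c("inflow", "outer_wall", "inner_wall",
                    "outlet_upper", "outlet_lower"))
  ## inflow spans [-1/2, 1/2] at x = 0, domain length 4
  expect_equal(range(poly$y[poly$x == 0]), c(-0.5, 0.5))
  expect_equal(max(poly$x), 4)
  ## mirror symmetry: every lower outer-wall vertex is the reflection of
  ## an upper one
  up <- poly[poly$tag == "outer_wall" & poly$y > 0, ]
  lo <- poly[poly$tag == "outer_wall" & poly$y < 0, ]
  expect_true(all(round(lo$x, 10) %in% round(up$x, 10)))
  expect_equal(-lo$y, bd$R1(lo$x))
  ## pins sit on the two outlet corners
  expect_equal(unname(bd$pins[1, ]), c(4, bd$R2(4)))
  expect_equal(unname(bd$pins[2, ]), c(3.745, -bd$R1(3.745)))
  ## heavily stenosed but valid geometry still closes
  expect_s3_class(build_domain_boundary(artery_params(tau_m = 0.4 * 0.0075)),
                  "domain_boundary")
})

test_that("straight channel domains validate their constriction", {
  ch <- straight_channel_domain(4, 0.5)
  expect_equal(nrow(ch$polyline[ch$polyline$tag == "outflow", , drop = FALSE]), 1)
  bump <- cosine_bump(0.125, 2, 1)
  chb <- straight_channel_domain(4, 0.5, bump)
  ## minimum gap: 2 * (half_height - height) at the bump centre
  expect_equal(2 * chb$wall(2), 2 * (0.5 - 0.125))
  ## symmetric walls by construction
  xs <- seq(0, 4, by = 0.1)
  expect_equal(chb$wall(xs), chb$wall(xs))
  expect_error(straight_channel_domain(4, 0.5, cosine_bump(0.6, 2, 1)),
               "bump height")
})
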