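## shared fixtures, built once per session and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

channel_mesh <- function(global_max = 0.05, length = 4) {
  fixture(sprintf("channel_%g_%g", global_max, length), function()
    generate_mesh(straight_channel_domain(length, 0.5),
                  list(global_max = global_max)))
}

bif_mesh <- function() {
  fixture("bif_default", function()
    generate_mesh(build_domain_boundary(artery_params())))
}

bif_mesh_coarse <- function() {
  fixture("bif_coarse", function()
    generate_mesh(build_domain_boundary(artery_params()),
                  list(global_max = 0.05)))
}

## the full study grid: three rheologies x four Hartmann numbers on the
## default mesh, solved by continuation ladders
study_grid <- function() {
  fixture("study_grid", function() {
    m <- bif_mesh()
    lapply(stats::setNames(c(0.639, 1, 1.2), c("n0.639", "n1", "n1.2")),
           function(n) solve_flow(m, Re = 300, n = n, M_values = c(0, 4, 8, 12)))
  })
}

poiseuille_channel_sol <- function() {
  fixture("poiseuille_sol", function()
    solve_flow(channel_mesh(), Re = 300, n = 1, M = 0))
}

## tiny two-element single-strip mesh for Jacobian checks
tiny_mesh <- function(nx = 2, ny = 1, length = 1) {
  fixture(sprintf("tiny_%d_%d", nx, ny), function()
    generate_mesh(straight_channel_domain(length, 0.5),
                  list(global_max = length / nx, row_factor = 0.5 / (ny * (length / nx)))))
}

expect_rel_error <- function(got, want, tol) {
  expect_lt(abs(got - want) / max(abs(want), .Machine$double.eps), tol)
}
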