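#' Read a run configuration (YAML or JSON)
#'
#' A configuration has sections `geometry` (either
#' `type: bifurcated` with [artery_params()] keys in SI units, or
#' `type: channel` with `length`, `half_height` and optional cosine-bump
#' keys `bump_height`, `bump_centre`, `bump_width`), `fluid` (either
#' `Re`, `M`, `n` directly or the dimensional keys of [fluid_model()]
#' from which the groups are derived), `mesh` (sizing controls of
#' [generate_mesh()]), `solver` ([solver_config()] keys) and `post`
#' (`stations`, `recirc_x_min`).
#'
#' @param file path to a YAML or JSON configuration file
#' @return a validated configuration list of class `run_config`
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  as_run_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg a plain list with the sections described in
#'   [read_config()]
#' @return the completed configuration, class `run_config`
#' @export
as_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  geo <- cfg$geometry %||% list(type = "bifurcated")
  if (is.null(geo$type)) geo$type <- "bifurcated"
  fl <- cfg$fluid %||% list()
  if (is.null(fl$n)) fl$n <- 1
  if (is.null(fl$Re)) {
    fm <- fluid_model(n = fl$n, m = fl$m %||% 0.0035, mu = fl$mu %||% 0.0035,
                      rho = fl$rho %||% 1050, sigma = fl$sigma %||% 0.8,
                      B0 = fl$B0 %||% 0, u_ref = fl$u_ref %||% 0.066667)
    hbar <- geo$hbar %||% (2 * (geo$a %||% 0.0075))
    gr <- dimensionless_groups(fm, hbar)
    fl$Re <- gr$Re
    if (is.null(fl$M)) fl$M <- gr$M
    fl$derived_from <- "dimensional"
  } else fl$derived_from <- "direct"
  if (is.null(fl$M)) fl$M <- 0
  out <- list(geometry = geo, fluid = fl, mesh = cfg$mesh %||% list(),
              solver = cfg$solver %||% list(), post = cfg$post %||% list(),
              output = cfg$output)
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a configuration to YAML
#'
#' @param cfg a `run_config`
#' @param file output path
#' @return the file path, invisibly
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

config_domain <- function(cfg) {
  geo <- cfg$geometry
  if (identical(geo$type, "channel")) {
    bump <- if (!is.null(geo$bump_height) && geo$bump_height > 0)
      cosine_bump(geo$bump_height, geo$bump_centre %||% (geo$length / 2),
                  geo$bump_width %||% 1)
    else NULL
    straight_channel_domain(geo$length %||% 4, geo$half_height %||% 0.5, bump)
  } else {
    keys <- c("a", "l0", "d", "x_max", "x1", "beta", "q", "r1", "tau_m", "hbar")
    args <- geo[names(geo) %in% keys]
    p <- do.call(artery_params, args)
    build_domain_boundary(p)
  }
}

#' Run a complete case
#'
#' Executes geometry -> mesh -> solve -> post-process in order and
#' (optionally) writes the artifacts: solution fields as VTU, wall
#' traces and cross-sections as CSV, and a JSON manifest with the
#' resolved configuration, mesh summary, residual history and the
#' post-processing summary values.
#'
#' @param cfg a `run_config` (or a plain list, or a path to a config
#'   file)
#' @param outdir output directory (`NULL` to skip writing)
#' @return list of class `case_manifest` with `manifest` and `solution`
#' @export
run_case <- function(cfg, outdir = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  bd <- config_domain(cfg)
  mesh <- generate_mesh(bd, cfg$mesh)
  scfg <- do.call(solver_config, cfg$solver[names(cfg$solver) %in%
    c("tol", "max_iter", "damping", "jacobian", "tol_stop", "quiet")])
  sol <- solve_flow(mesh, Re = cfg$fluid$Re, n = cfg$fluid$n, M = cfg$fluid$M,
                    config = scfg)
  ms <- mesh_summary(mesh)
  stations <- cfg$post$stations %||%
    (if (bd$type == "bifurcated") c(1, 1.5, 3.0118) else numeric(0))
  secs <- lapply(stations, function(xs) {
    cs <- cross_section(sol, xs)
    list(x = xs, region = cs$region, mean_u = cs$mean_u)
  })
  post <- list(sections = secs,
               mass = mass_audit(sol)[c("net", "imbalance_rel")])
  if (bd$type == "bifurcated") {
    post$recirculation_area <-
      recirculation_area(sol, cfg$post$recirc_x_min %||% NULL)
    tw <- wall_shear_stress(sol, "outer_wall", "upper")
    post$tau_w_max <- max(abs(tw$tau_w))
    wp <- wall_pressure(sol, "outer_wall", "upper")
    post$wall_p_range <- range(wp$p)
  }
  manifest <- list(config = unclass(cfg), mesh = ms,
                   residual_final = utils::tail(sol$history$res2, 1),
                   iterations = nrow(sol$history),
                   converged = sol$converged, post = post)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_vtu(sol, file.path(outdir, "solution.vtu"))
    write_mesh_text(mesh, file.path(outdir, "mesh.txt"))
    if (bd$type == "bifurcated") {
      utils::write.csv(wall_shear_stress(sol, "outer_wall", "upper"),
                       file.path(outdir, "wss_outer_upper.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(wall_pressure(sol, "outer_wall", "upper"),
                       file.path(outdir, "wallp_outer_upper.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    for (cs in lapply(stations, function(xs) cross_section(sol, xs)))
      utils::write.csv(cs$samples,
                       file.path(outdir, sprintf("section_x%g.csv", cs$x)),
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out <- list(manifest = manifest, solution = sol)
  class(out) <- "case_manifest"
  invisible(out)
}

#' Run a sweep of related cases and tabulate the comparison
#'
#' All configurations must share the same geometry section.  Returns a
#' table of section means, recirculation areas and wall extrema per
#' case, with deltas and percent reductions against the first case.
#'
#' @param configs list of `run_config`s (or plain lists)
#' @return data.frame, one row per case
#' @export
sweep_cases <- function(configs) {
  if (!length(configs)) return(data.frame())
  configs <- lapply(configs, function(cf)
    if (inherits(cf, "run_config")) cf else as_run_config(cf))
  g1 <- configs[[1]]$geometry
  for (cf in configs)
    if (!identical(cf$geometry, g1))
      stop("configuration error: sweep cases must share a domain", call. = FALSE)
  rows <- lapply(seq_along(configs), function(i) {
    rc <- run_case(configs[[i]])
    man <- rc$manifest
    secs <- man$post$sections
    row <- data.frame(case = i, n = configs[[i]]$fluid$n,
                      M = configs[[i]]$fluid$M,
                      converged = man$converged)
    for (s in secs) row[[sprintf("mean_u_x%g", s$x)]] <- s$mean_u
    row$recirc_area <- man$post$recirculation_area %||% NA_real_
    row$tau_w_max <- man$post$tau_w_max %||% NA_real_
    row
  })
  tab <- do.call(rbind, rows)
  if (nrow(tab) > 1) {
    num <- setdiff(names(tab), c("case", "n", "M", "converged"))
    for (cn in num) {
      tab[[paste0("d_", cn)]] <- tab[[cn]][1] - tab[[cn]]
      if (cn == "recirc_area")
        tab$recirc_pct_reduction <-
          ifelse(tab[[cn]][1] > 0, 100 * (tab[[cn]][1] - tab[[cn]]) / tab[[cn]][1],
                 NA_real_)
    }
  }
  tab
}

#' Write solution fields as an ASCII VTU (unstructured grid) file
#'
#' Nodal `u`, `v`, `p` (and optionally the streamfunction) on the
#' triangle mesh, readable by ParaView/VisIt.
#'
#' @param sol a `flow_solution`
#' @param file output path
#' @param psi optional nodal streamfunction to include
#' @return the file path, invisibly
#' @export
write_vtu <- function(sol, file, psi = NULL) {
  mesh <- sol$mesh
  np <- nrow(mesh$nodes); ne <- nrow(mesh$tri)
  con <- file(file, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', np,
    '" NumberOfCells="', ne, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(cbind(mesh$nodes, 0)))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$tri - 1L)), collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(ne) * 3L, collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(5L, ne), collapse = " "))
  w('</DataArray></Cells>')
  w('<PointData Scalars="p" Vectors="velocity">')
  w('<DataArray type="Float64" Name="velocity" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(cbind(sol$u, sol$v, 0)))))
  w('</DataArray>')
  w('<DataArray type="Float64" Name="p" format="ascii">')
  w(num(sol$p))
  w('</DataArray>')
  w('<DataArray type="Float64" Name="reversed" format="ascii">')
  w(num(as.numeric(sol$u < 0)))
  w('</DataArray>')
  if (!is.null(psi)) {
    w('<DataArray type="Float64" Name="psi" format="ascii">')
    w(num(psi))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}
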