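#' Triangulate a tagged domain boundary
#'
#' Generates a conforming linear-triangle (P1) mesh of a
#' `domain_boundary` by mapped column-wise triangulation: nodes are laid
#' out on vertical stations that follow the parametric walls, strips
#' between consecutive stations are triangulated with a shortest-diagonal
#' two-pointer rule (which also handles stations with unequal node
#' counts, as in the tapering outlet wedges), and boundary edges inherit
#' the tags of the wall segments they lie on.  The axial station spacing
#' is `global_max` away from the stenosis and `global_max *
#' stenosis_factor` over the stenotic zone plus one stenosis length
#' downstream of it.
#'
#' @param boundary a `domain_boundary` from [build_domain_boundary()] or
#'   [straight_channel_domain()]
#' @param size list of sizing controls: `global_max` (default 0.03,
#'   dimensionless axial station spacing away from the stenosis; element
#'   longest edges reach at most about 1.4x this on strip diagonals),
#'   `stenosis_factor` (default 0.6, refinement ratio in the stenotic
#'   zone), `row_factor` (default 1.2, transverse-to-axial spacing ratio)
#' @return an object of class `tri_mesh` with `nodes` (N x 2), `tri`
#'   (Ne x 3, counter-clockwise), `boundary` (data.frame n1, n2, tag),
#'   per-element `h_K` and `area`, and the generating `domain`
#' @export
generate_mesh <- function(boundary, size = list()) {
  stopifnot(inherits(boundary, "domain_boundary"))
  sz <- utils::modifyList(list(global_max = 0.03, stenosis_factor = 0.6,
                               row_factor = 1.2), size)
  stopifnot(sz$global_max > 0, sz$stenosis_factor > 0, sz$stenosis_factor <= 1)
  mesh <- switch(boundary$type,
                 bifurcated = mesh_bifurcated(boundary, sz),
                 channel = mesh_channel(boundary, sz),
                 stop("unknown domain type: ", boundary$type, call. = FALSE))
  mesh$domain <- boundary
  mesh$size <- sz
  finalize_mesh(mesh)
}

## stations over consecutive intervals [breaks[i], breaks[i+1]] with target
## spacing dxs[i]; breakpoints are always included exactly
mesh_stations <- function(breaks, dxs) {
  out <- breaks[1]
  for (i in seq_along(dxs)) {
    a <- breaks[i]; b <- breaks[i + 1]
    if (b - a < 1e-12) next
    n <- max(1L, round((b - a) / dxs[i]))
    out <- c(out, seq(a, b, length.out = n + 1)[-1])
  }
  out
}

## strip triangulation between two node columns (ascending y); returns an
## integer matrix of CCW triangles.  Equal-count columns are paired row by
## row with the quad diagonal chosen by the sign of the quad centre, which
## makes meshes of mirror-symmetric domains exactly mirror symmetric;
## unequal counts (the tapering outlet wedge) fall back to a two-pointer
## shortest-diagonal sweep.
strip_triangulate <- function(ia, ya, xa, ib, yb, xb) {
  na <- length(ia); nb <- length(ib)
  if (na == nb && na > 1L) {
    k <- seq_len(na - 1L)
    dx2 <- (xa - xb)^2
    d_dn <- dx2 + (ya[k + 1L] - yb[k])^2      # diagonal A_{k+1} -- B_k
    d_up <- dx2 + (ya[k] - yb[k + 1L])^2      # diagonal A_k -- B_{k+1}
    tie <- abs(d_up - d_dn) <= 1e-12 * (d_up + d_dn)
    ## on ties (symmetric quads) break by the quad-centre side of the
    ## axis, which keeps mirror-symmetric domains mirror-symmetric
    up <- ifelse(tie, (ya[k] + ya[k + 1L] + yb[k] + yb[k + 1L]) >= 0,
                 d_up < d_dn)
    t_up <- rbind(cbind(ia[k[up]], ib[k[up]], ib[k[up] + 1L]),
                  cbind(ia[k[up]], ib[k[up] + 1L], ia[k[up] + 1L]))
    dn <- !up
    t_dn <- rbind(cbind(ia[k[dn]], ib[k[dn]], ia[k[dn] + 1L]),
                  cbind(ia[k[dn] + 1L], ib[k[dn]], ib[k[dn] + 1L]))
    return(rbind(t_up, t_dn))
  }
  tris <- matrix(0L, na + nb - 2, 3)
  i <- 1L; j <- 1L; k <- 0L
  while (i < na || j < nb) {
    adv_a <- if (i >= na) FALSE else if (j >= nb) TRUE else {
      d1 <- (xa - xb)^2 + (ya[i + 1] - yb[j])^2
      d2 <- (xa - xb)^2 + (ya[i] - yb[j + 1])^2
      d1 <= d2
    }
    k <- k + 1L
    if (adv_a) {
      tris[k, ] <- c(ia[i], ib[j], ia[i + 1])
      i <- i + 1L
    } else {
      tris[k, ] <- c(ia[i], ib[j], ib[j + 1])
      j <- j + 1L
    }
  }
  tris
}

mesh_bifurcated <- function(bd, sz) {
  xb <- bd$x_breaks
  dx0 <- sz$global_max
  dxs <- dx0 * sz$stenosis_factor
  l0d <- unname(xb["d_l0"] - xb["d"])
  ref_end <- min(unname(xb["d_l0"]) + l0d, unname(xb["xs"]))
  x3 <- unname(xb["x3"]); xs <- unname(xb["xs"]); xm <- unname(xb["xm"])

  ## the quartic profile is steepest just inside the stenosis ends; grade
  ## the axial spacing down there so wall-following edges stay short
  d0 <- unname(xb["d"]); d1 <- unname(xb["d_l0"])
  st1 <- mesh_stations(c(0, d0, d0 + 0.12 * l0d, d1 - 0.12 * l0d, d1,
                         min(ref_end, x3), x3),
                       c(dx0, 0.6 * dxs, dxs, 0.6 * dxs, dxs, dx0))
  stb <- mesh_stations(c(x3, max(x3, min(ref_end, xs)), xs), c(dxs, dx0))
  ## geometric stations through the tapering outlet wedge
  xw <- numeric(0); x <- xs
  while (xm - x > 1.1 * dxs) {
    x <- x + min(0.5 * dx0, max(0.35 * (xm - x), dxs))
    if (xm - x < 0.6 * dxs) break
    xw <- c(xw, x)
  }

  W3 <- bd$R1(x3)
  nyb <- max(4L, round(W3 / (dx0 * sz$row_factor)))
  dyb <- (bd$y_top(xs) - bd$R2(xs)) / nyb

  nodes <- vector("list", 0); nid <- 0L
  new_col <- function(x, y) {
    ids <- nid + seq_along(y)
    nid <<- nid + length(y)
    nodes[[length(nodes) + 1L]] <<- cbind(rep(x, length(y)), y)
    list(x = x, y = y, ids = ids)
  }
  ## trunk: full columns, symmetric about the axis
  cols1 <- lapply(st1, function(x)
    new_col(x, bd$R1(x) * seq(-1, 1, length.out = 2L * nyb + 1L)))
  last1 <- cols1[[length(cols1)]]
  shared_up <- list(x = x3, y = last1$y[(nyb + 1L):(2L * nyb + 1L)],
                    ids = last1$ids[(nyb + 1L):(2L * nyb + 1L)])
  shared_lo <- list(x = x3, y = last1$y[1L:(nyb + 1L)],
                    ids = last1$ids[1L:(nyb + 1L)])

  branch_col <- function(x, lower) {
    yb0 <- bd$R2(x); yt <- bd$y_top(x)
    nr <- if (x <= xs + 1e-12) nyb else
      max(2L, min(nyb, round((yt - yb0) / dyb)))
    y <- seq(yb0, yt, length.out = nr + 1L)
    if (lower) y <- rev(-y)
    new_col(x, y)
  }
  xup <- c(stb[-1], xw)
  cols_up <- c(list(shared_up), lapply(xup, branch_col, lower = FALSE),
               list(new_col(xm, bd$R2(xm))))
  cols_lo <- c(list(shared_lo), lapply(xup, branch_col, lower = TRUE),
               list(new_col(xm, -bd$R2(xm))))

  nodes <- do.call(rbind, nodes)
  strip_all <- function(cols) do.call(rbind, lapply(seq_len(length(cols) - 1L),
    function(i) strip_triangulate(cols[[i]]$ids, cols[[i]]$y, cols[[i]]$x,
                                  cols[[i + 1L]]$ids, cols[[i + 1L]]$y,
                                  cols[[i + 1L]]$x)))
  tri <- rbind(strip_all(cols1), strip_all(cols_up), strip_all(cols_lo))

  chain_edges <- function(ids, tag)
    data.frame(n1 = ids[-length(ids)], n2 = ids[-1], tag = tag)
  top_of <- function(col) col$ids[length(col$ids)]
  bot_of <- function(col) col$ids[1L]
  colx <- function(cols) vapply(cols, `[[`, numeric(1), "x")
  up_x <- colx(cols_up)
  pre <- up_x <= xs + 1e-12
  edges <- rbind(
    chain_edges(cols1[[1L]]$ids, "inflow"),
    chain_edges(c(vapply(cols1, top_of, 0L), vapply(cols_up[-1L][pre[-1L]], top_of, 0L)),
                "outer_wall"),
    chain_edges(c(vapply(cols1, bot_of, 0L), vapply(cols_lo[-1L][pre[-1L]], bot_of, 0L)),
                "outer_wall"),
    chain_edges(vapply(cols_up[up_x >= xs - 1e-12], top_of, 0L), "outlet_upper"),
    chain_edges(vapply(cols_lo[up_x >= xs - 1e-12], bot_of, 0L), "outlet_lower"),
    chain_edges(vapply(cols_up, bot_of, 0L), "inner_wall"),
    chain_edges(vapply(cols_lo, top_of, 0L), "inner_wall")
  )
  list(nodes = nodes, tri = tri, boundary = edges)
}

mesh_channel <- function(bd, sz) {
  L <- bd$params$length; H <- bd$params$half_height
  dx0 <- sz$global_max * (2 * H)  # scale sizing with the channel height
  dxs <- dx0 * sz$stenosis_factor
  xg <- seq(0, L, length.out = 513)
  bumped <- bd$bump(xg) > 1e-12
  if (any(bumped)) {
    supp <- range(xg[bumped])
    ref_hi <- min(L, supp[2] + (supp[2] - supp[1]))
    st <- mesh_stations(c(0, supp[1], ref_hi, L),
                        c(dx0, dxs, dx0))
  } else {
    st <- mesh_stations(c(0, L), dx0)
  }
  nyh <- max(3L, round(H / (dx0 * sz$row_factor)))
  nodes <- vector("list", 0); nid <- 0L
  cols <- lapply(st, function(x) {
    w <- bd$wall(x)
    y <- w * seq(-1, 1, length.out = 2L * nyh + 1L)
    ids <- nid + seq_along(y)
    nid <<- nid + length(y)
    nodes[[length(nodes) + 1L]] <<- cbind(rep(x, length(y)), y)
    list(x = x, y = y, ids = ids)
  })
  nodes <- do.call(rbind, nodes)
  tri <- do.call(rbind, lapply(seq_len(length(cols) - 1L), function(i)
    strip_triangulate(cols[[i]]$ids, cols[[i]]$y, cols[[i]]$x,
                      cols[[i + 1L]]$ids, cols[[i + 1L]]$y, cols[[i + 1L]]$x)))
  chain_edges <- function(ids, tag)
    data.frame(n1 = ids[-length(ids)], n2 = ids[-1], tag = tag)
  top <- vapply(cols, function(cc) cc$ids[length(cc$ids)], 0L)
  bot <- vapply(cols, function(cc) cc$ids[1L], 0L)
  edges <- rbind(chain_edges(cols[[1L]]$ids, "inflow"),
                 chain_edges(cols[[length(cols)]]$ids, "outflow"),
                 chain_edges(top, "wall"),
                 chain_edges(bot, "wall"))
  list(nodes = nodes, tri = tri, boundary = edges)
}

finalize_mesh <- function(mesh) {
  dimnames(mesh$nodes) <- NULL
  rownames(mesh$boundary) <- NULL
  mesh$tri <- fix_orientation(mesh$nodes, mesh$tri)
  met <- element_metrics(mesh)
  if (any(met$area <= 0))
    stop("mesh error: degenerate (non-positive area) element", call. = FALSE)
  mesh$h_K <- met$h_K
  mesh$area <- met$area
  class(mesh) <- "tri_mesh"
  mesh
}

fix_orientation <- function(nodes, tri) {
  x <- matrix(nodes[tri, 1], ncol = 3); y <- matrix(nodes[tri, 2], ncol = 3)
  a2 <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) - (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])
  flip <- a2 < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  tri
}

#' Per-element size and area
#'
#' `h_K` is the longest edge of the element (the definition used by the
#' stabilization parameter); the area comes from the shoelace formula.
#'
#' @param mesh a `tri_mesh` (or a list with `nodes` and `tri`)
#' @return list with numeric vectors `h_K`, `area`, and `min_angle`
#'   (degrees)
#' @export
element_metrics <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$tri, 1], ncol = 3)
  y <- matrix(mesh$nodes[mesh$tri, 2], ncol = 3)
  area <- 0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                 (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
  e1 <- sqrt((x[, 2] - x[, 3])^2 + (y[, 2] - y[, 3])^2)
  e2 <- sqrt((x[, 1] - x[, 3])^2 + (y[, 1] - y[, 3])^2)
  e3 <- sqrt((x[, 1] - x[, 2])^2 + (y[, 1] - y[, 2])^2)
  h_K <- pmax(e1, e2, e3)
  ang <- function(a, b, c) acos(pmin(pmax((b^2 + c^2 - a^2) / (2 * b * c), -1), 1))
  min_angle <- pmin(ang(e1, e2, e3), ang(e2, e1, e3), ang(e3, e1, e2)) * 180 / pi
  if (any(area == 0)) stop("mesh error: zero-area element", call. = FALSE)
  list(h_K = h_K, area = area, min_angle = min_angle)
}

#' Mesh summary statistics
#'
#' @param mesh a `tri_mesh`
#' @return list with node/element/edge counts, h statistics, minimum
#'   interior angle and Euler characteristic
#' @export
mesh_summary <- function(mesh) {
  met <- element_metrics(mesh)
  ed <- rbind(mesh$tri[, c(1, 2)], mesh$tri[, c(2, 3)], mesh$tri[, c(3, 1)])
  ed <- unique(t(apply(ed, 1, sort)))
  list(n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$tri),
       n_boundary_edges = nrow(mesh$boundary),
       h_max = max(met$h_K), h_min = min(met$h_K), h_mean = mean(met$h_K),
       min_angle_deg = min(met$min_angle),
       euler = nrow(mesh$nodes) - nrow(ed) + nrow(mesh$tri),
       area_total = sum(met$area))
}

#' Write a mesh in a plain-text node/element/edge format
#'
#' Three whitespace-separated sections with counts in a header line each:
#' nodes (x y), elements (three 1-based node ids), boundary edges
#' (two node ids and a tag).
#'
#' @param mesh a `tri_mesh`
#' @param file output path
#' @return the file path, invisibly
#' @export
write_mesh_text <- function(mesh, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("nodes %d", nrow(mesh$nodes)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("elements %d", nrow(mesh$tri)), con)
  utils::write.table(mesh$tri, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("edges %d", nrow(mesh$boundary)), con)
  utils::write.table(mesh$boundary, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
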