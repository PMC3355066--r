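# Reference tilings and patch extraction.

#' Toroidal honeycomb lattice
#'
#' A periodic regular hexagonal tiling, built as the Voronoi diagram of a
#' triangular seed lattice: `nx * ny` hexagonal cells with `V = 2 nx ny`,
#' `E = 3 nx ny`. With uniform tensions it is an exact equilibrium of the
#' tension-only energy, which makes it the canonical stationary fixture.
#'
#' @param nx,ny Cells per row / number of rows (`ny` must be even).
#' @param a Seed spacing (hexagon area `a^2 sqrt(3)/2`).
#' @return A toroidal [cell_array()].
#' @export
hex_lattice <- function(nx = 8L, ny = 8L, a = 1) {
  stopifnot(nx >= 2, ny >= 2, ny %% 2 == 0)
  box <- c(nx * a, ny * a * sqrt(3) / 2)
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  seeds <- cbind(ij$i * a + (ij$j %% 2) * a / 2, ij$j * a * sqrt(3) / 2)
  periodic_voronoi(seeds, box)
}

#' Cut a patch out of a toroidal tissue
#'
#' Extracts the cells whose centroid lies within `radius` of `center` and
#' re-expresses them as a planar array, either:
#' * `"closed"`: a free-standing island of cells - each boundary cell's
#'   outer boundary is replaced by a single perimeter interface (a chord)
#'   bordering the exterior region (`cell -1`), so every vertex stays
#'   three-valent and the array satisfies the closed Euler relation;
#' * `"open"`: the same construction labelled as a field-of-view patch:
#'   perimeter edges still border the exterior, but only vertices whose
#'   cells are all in view are balanced by the inverse.
#'
#' Cells that would keep fewer than three vertices are pruned iteratively.
#' The patch must be simply connected and smaller than half the box;
#' degenerate selections fail validation.
#'
#' @param array A toroidal [cell_array()] (three-valent).
#' @param center Numeric length-2 point.
#' @param radius Selection radius (must be at most a quarter of the box).
#' @param topology `"closed"` or `"open"`.
#' @return A planar [cell_array()].
#' @export
extract_patch <- function(array, center = NULL, radius = NULL,
                          topology = c("closed", "open")) {
  topology <- match.arg(topology)
  stopifnot(array$topology == "toroidal")
  box <- array$box
  if (is.null(center)) center <- box / 2
  if (is.null(radius)) radius <- min(box) / 4
  if (radius > min(box) / 4 + 1e-9) {
    stop_epiforce("patch radius must be at most a quarter of the box for unambiguous unwrapping",
                  "epiforce_invalid")
  }
  pos <- vertex_matrix(array)

  cent <- t(vapply(seq_len(nrow(array$cells)), function(k) {
    p <- unwrap_loop(array, array$cells$vertices[[k]], pos)
    d <- colMeans(p) - center
    center + c(wrap_min_image(d[[1]], box[[1]]), wrap_min_image(d[[2]], box[[2]]))
  }, c(0, 0)))
  keep <- array$cells$id[row_norms(sweep(cent, 2, center)) <= radius]
  if (length(keep) < 3) stop_epiforce("patch selection keeps fewer than 3 cells", "epiforce_invalid")

  e <- array$edges
  repeat {
    interior <- e$cell_left %in% keep & e$cell_right %in% keep
    marked <- unique(c(e$v1[interior], e$v2[interior]))
    n_marked <- vapply(match(keep, array$cells$id), function(k) {
      sum(array$cells$vertices[[k]] %in% marked)
    }, 1L)
    if (all(n_marked >= 3)) break
    keep <- keep[n_marked >= 3]
    if (length(keep) < 3) stop_epiforce("patch pruning removed almost all cells", "epiforce_invalid")
  }
  interior <- e$cell_left %in% keep & e$cell_right %in% keep
  marked <- unique(c(e$v1[interior], e$v2[interior]))

  # Unwrapped coordinates relative to the patch center.
  vk <- match(marked, array$vertices$id)
  d <- sweep(pos[vk, , drop = FALSE], 2, center)
  d[, 1] <- wrap_min_image(d[, 1], box[[1]]); d[, 2] <- wrap_min_image(d[, 2], box[[2]])
  vertices <- tibble::tibble(id = marked, x = center[[1]] + d[, 1], y = center[[2]] + d[, 2])

  edges <- e[interior, ]
  next_eid <- max(e$id) + 1L

  cells_out <- vector("list", length(keep))
  boundary <- logical(length(keep))
  perim <- list()
  for (kk in seq_along(keep)) {
    cid <- keep[[kk]]
    loop <- array$cells$vertices[[match(cid, array$cells$id)]]
    inloop <- loop[loop %in% marked]
    if (length(inloop) < 3) stop_epiforce("patch cell degenerated during chordification", "epiforce_topology")
    cells_out[[kk]] <- inloop
    # A perimeter chord replaces each run of dropped vertices: between
    # consecutive kept vertices that are not already joined by an interior
    # edge of this cell.
    nxt <- c(inloop[-1], inloop[[1]])
    ekey <- paste(pmin(edges$v1, edges$v2), pmax(edges$v1, edges$v2))
    pair_key <- paste(pmin(inloop, nxt), pmax(inloop, nxt))
    missing <- !(pair_key %in% ekey)
    boundary[[kk]] <- any(missing) ||
      any(!(c(e$cell_left[e$cell_right == cid], e$cell_right[e$cell_left == cid]) %in% keep))
    for (m in which(missing)) {
      # walking CCW around the cell: the cell is on the left, exterior right
      perim[[length(perim) + 1L]] <- tibble::tibble(
        id = next_eid, v1 = inloop[[m]], v2 = nxt[[m]],
        cell_left = cid, cell_right = -1L, curvature = NA_real_
      )
      next_eid <- next_eid + 1L
    }
  }
  edges <- dplyr::bind_rows(edges, perim)

  cells <- tibble::tibble(id = keep, vertices = cells_out,
                          boundary = boundary, label = NA_character_)
  cell_array(vertices, edges, cells, topology = topology, box = NULL)
}
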