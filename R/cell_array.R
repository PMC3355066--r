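#' Build a polygonal cell array
#'
#' A `cell_array` is the package's representation of a segmented epithelial
#' sheet: a planar (or toroidal) polygonal tiling given by vertex positions,
#' edges (cell-cell interfaces, each knowing the two cells it separates) and
#' cells (counter-clockwise vertex loops). It is the geometric input to both
#' the forward vertex model and the mechanical inverse.
#'
#' Conventions:
#' * Edges are directed `v1 -> v2` with `cell_left` the cell lying to the
#'   left of that direction (y axis pointing up). The exterior / out-of-view
#'   region is denoted by cell id `-1`.
#' * Cell loops are stored counter-clockwise, so planar cells have positive
#'   signed (shoelace) area.
#' * `topology` is one of `"closed"` (a finite island of cells surrounded by
#'   a tension-free exterior; the exterior counts as one extra face in the
#'   Euler relation), `"open"` (a patch cut out of a larger tissue by the
#'   field of view; only vertices whose incident cells are all in view can be
#'   balanced), or `"toroidal"` (periodic box, used by the simulator).
#' * Optional per-edge signed `curvature` (1/length) is positive when the
#'   interface bows away from `cell_left`; it is carried as data for the
#'   Young-Laplace cross-check and never used by the inverse itself.
#'
#' @param vertices Data frame with columns `id`, `x`, `y`.
#' @param edges Data frame with columns `id`, `v1`, `v2`, `cell_left`,
#'   `cell_right` and optionally `curvature`.
#' @param cells Data frame with columns `id`, `vertices` (list-column of
#'   integer vertex ids, counter-clockwise) and optionally `boundary`
#'   (logical) and `label` (character).
#' @param topology One of `"closed"`, `"open"`, `"toroidal"`.
#' @param box Numeric length-2 period `(Lx, Ly)`; required iff toroidal.
#' @param validate Run the full consistency checks (default `TRUE`).
#'
#' @return An object of class `cell_array`.
#' @seealso [read_cell_array()], [cell_areas()], [edge_table()],
#'   [count_expected_zero_modes()]
#' @export
cell_array <- function(vertices, edges, cells, topology = c("closed", "open", "toroidal"),
                       box = NULL, validate = TRUE) {
  topology <- match.arg(topology)
  vertices <- tibble::as_tibble(vertices)
  edges <- tibble::as_tibble(edges)
  cells <- tibble::as_tibble(cells)

  vertices$id <- as.integer(vertices$id)
  vertices$x <- as.double(vertices$x)
  vertices$y <- as.double(vertices$y)
  for (col in c("id", "v1", "v2", "cell_left", "cell_right")) {
    edges[[col]] <- as.integer(edges[[col]])
  }
  if (!"curvature" %in% names(edges)) edges$curvature <- NA_real_
  edges$curvature <- as.double(edges$curvature)
  cells$id <- as.integer(cells$id)
  cells$vertices <- lapply(cells$vertices, as.integer)
  if (!"boundary" %in% names(cells)) cells$boundary <- FALSE
  cells$boundary <- as.logical(cells$boundary)
  if (!"label" %in% names(cells)) cells$label <- NA_character_
  cells$label <- as.character(cells$label)

  arr <- structure(
    list(vertices = vertices, edges = edges, cells = cells,
         topology = topology, box = if (!is.null(box)) as.double(box) else NULL),
    class = "cell_array"
  )
  arr$vertices$interior <- vertex_is_interior(arr)
  if (validate) validate_cell_array(arr)
  arr
}

#' @export
print.cell_array <- function(x, ...) {
  cat(sprintf("<cell_array: %s> V = %d, E = %d, C = %d\n",
              x$topology, nrow(x$vertices), nrow(x$edges), nrow(x$cells)))
  if (!is.null(x$box)) {
    cat(sprintf("  box: %.6g x %.6g\n", x$box[[1]], x$box[[2]]))
  }
  nb <- sum(x$cells$boundary)
  if (nb > 0) cat(sprintf("  boundary cells: %d\n", nb))
  invisible(x)
}

# TRUE for vertices none of whose incident edges borders the exterior (-1).
vertex_is_interior <- function(array) {
  ext_edges <- array$edges$cell_left < 0 | array$edges$cell_right < 0
  touched <- unique(c(array$edges$v1[ext_edges], array$edges$v2[ext_edges]))
  !(array$vertices$id %in% touched)
}

vertex_degrees <- function(array) {
  tab <- table(factor(c(array$edges$v1, array$edges$v2), levels = array$vertices$id))
  as.integer(tab)
}

#' Validate a cell array
#'
#' Checks referential integrity (every edge/cell id resolves), manifoldness
#' (no interface claimed by three or more cells), loop/edge consistency,
#' minimum vertex degree, edge non-degeneracy, cell orientation and the
#' Euler relation appropriate to the topology (`V - E + (C + 1) = 2` for
#' closed arrays counting the exterior as a face; `V - E + C = 0` for
#' toroidal arrays).
#'
#' @param array A [cell_array()].
#' @return `array`, invisibly; errors with a descriptive condition class on
#'   the first violation found.
#' @export
validate_cell_array <- function(array) {
  v <- array$vertices; e <- array$edges; cl <- array$cells

  if (anyDuplicated(v$id)) stop_epiforce("duplicate vertex ids", "epiforce_invalid")
  if (anyDuplicated(e$id)) stop_epiforce("duplicate edge ids", "epiforce_invalid")
  if (anyDuplicated(cl$id)) stop_epiforce("duplicate cell ids", "epiforce_invalid")
  if (any(cl$id < 0)) stop_epiforce("cell ids must be >= 0 (-1 is reserved for the exterior)", "epiforce_invalid")
  if (!all(is.finite(v$x)) || !all(is.finite(v$y))) {
    stop_epiforce("non-finite vertex coordinates", "epiforce_invalid")
  }

  if (array$topology == "toroidal") {
    if (is.null(array$box) || length(array$box) != 2 || !all(is.finite(array$box)) || any(array$box <= 0)) {
      stop_epiforce("toroidal arrays require a positive box = c(Lx, Ly)", "epiforce_invalid")
    }
  }

  # Cross references.
  miss <- setdiff(c(e$v1, e$v2), v$id)
  if (length(miss) > 0) {
    stop_epiforce(sprintf("dangling id: edge references unknown vertex %d", miss[[1]]), "epiforce_dangling_id")
  }
  ref_cells <- c(e$cell_left, e$cell_right)
  miss <- setdiff(ref_cells[ref_cells >= 0], cl$id)
  if (length(miss) > 0) {
    stop_epiforce(sprintf("dangling id: edge references unknown cell %d", miss[[1]]), "epiforce_dangling_id")
  }
  miss <- setdiff(unlist(cl$vertices), v$id)
  if (length(miss) > 0) {
    stop_epiforce(sprintf("dangling id: cell loop references unknown vertex %d", miss[[1]]), "epiforce_dangling_id")
  }

  if (any(e$v1 == e$v2)) stop_epiforce("edge with coincident endpoint ids", "epiforce_invalid")
  if (any(e$cell_left == e$cell_right)) stop_epiforce("edge with identical cells on both sides", "epiforce_invalid")
  key <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
  if (anyDuplicated(key)) stop_epiforce("duplicate edge (same unordered vertex pair listed twice)", "epiforce_invalid")

  # Loop sanity.
  len <- lengths(cl$vertices)
  if (any(len < 3)) stop_epiforce("cell loop with fewer than 3 vertices", "epiforce_invalid")
  if (any(vapply(cl$vertices, anyDuplicated, 1L) > 0)) {
    stop_epiforce("cell loop with repeated vertices", "epiforce_invalid")
  }

  # Loop/edge consistency + manifoldness: every consecutive loop pair must be
  # a declared edge, and each edge must be claimed by exactly the (real)
  # cells it names.
  idx <- stats::setNames(seq_len(nrow(e)), key)
  claims <- integer(nrow(e))
  for (k in seq_len(nrow(cl))) {
    loop <- cl$vertices[[k]]
    nxt <- c(loop[-1], loop[[1]])
    ek <- paste(pmin(loop, nxt), pmax(loop, nxt))
    hit <- idx[ek]
    if (anyNA(hit)) {
      stop_epiforce(sprintf("cell %d loop uses vertex pair (%d,%d) that is not a declared edge",
                            cl$id[[k]], loop[[which(is.na(hit))[[1]]]], nxt[[which(is.na(hit))[[1]]]]),
                    "epiforce_topology")
    }
    claims[hit] <- claims[hit] + 1L
    ok_side <- e$cell_left[hit] == cl$id[[k]] | e$cell_right[hit] == cl$id[[k]]
    if (!all(ok_side)) {
      stop_epiforce(sprintf("cell %d traverses edge %d but is not one of its two cells",
                            cl$id[[k]], e$id[[hit[!ok_side][[1]]]]), "epiforce_topology")
    }
  }
  expected <- (e$cell_left >= 0) + (e$cell_right >= 0)
  if (any(claims > 2)) {
    stop_epiforce(sprintf("non-manifold edge %d claimed by %d cells",
                          e$id[[which(claims > 2)[[1]]]], max(claims)), "epiforce_topology")
  }
  if (any(claims != expected)) {
    bad <- which(claims != expected)[[1]]
    stop_epiforce(sprintf("edge %d is claimed by %d cell loops but names %d real cells",
                          e$id[[bad]], claims[[bad]], expected[[bad]]), "epiforce_topology")
  }

  # Geometry: degenerate edges.
  et <- edge_table(array)
  mean_len <- mean(et$length)
  if (any(et$length < 1e-9 * mean_len)) {
    stop_epiforce(sprintf("degenerate edge %d (length %.3g, < 1e-9 x mean edge length)",
                          et$edge[[which.min(et$length)]], min(et$length)), "epiforce_degenerate")
  }
  if (array$topology == "toroidal" && min(array$box) < 3 * mean_len) {
    stop_epiforce("toroidal box must be at least 3 x the mean edge length", "epiforce_invalid")
  }

  # Interior vertex degree.
  deg <- vertex_degrees(array)
  low <- array$vertices$interior & deg < 3
  if (any(low)) {
    stop_epiforce(sprintf("interior vertex %d has degree %d (< 3)",
                          array$vertices$id[[which(low)[[1]]]], deg[[which(low)[[1]]]]), "epiforce_topology")
  }

  # Orientation (planar arrays only; a toroidal cell may wrap the box).
  if (array$topology != "toroidal") {
    areas <- cell_areas(array, check = FALSE)$area
    if (any(areas <= 0)) {
      stop_epiforce(sprintf("cell %d loop is not counter-clockwise (signed area %.3g)",
                            cl$id[[which(areas <= 0)[[1]]]], min(areas)), "epiforce_invalid")
    }
  }

  # Euler relation.
  V <- nrow(v); E <- nrow(e); C <- nrow(cl)
  if (array$topology == "closed" && (V - E + C + 1) != 2) {
    stop_epiforce(sprintf("closed array violates Euler relation: V - E + (C+1) = %d, expected 2",
                          V - E + C + 1), "epiforce_topology")
  }
  if (array$topology == "toroidal" && (V - E + C) != 0) {
    stop_epiforce(sprintf("toroidal array violates Euler relation: V - E + C = %d, expected 0",
                          V - E + C), "epiforce_topology")
  }
  invisible(array)
}

#' Edge chord vectors and lengths
#'
#' Returns one row per edge with the chord vector from `v1` to `v2`
#' (minimum-image convention on toroidal arrays) and its Euclidean length.
#'
#' @param array A [cell_array()].
#' @return Tibble with columns `edge`, `v1`, `v2`, `cell_left`, `cell_right`,
#'   `dx`, `dy`, `length`, `angle` (chord angle in `(-pi/2, pi/2]`, i.e. of
#'   the undirected edge) and `curvature`.
#' @export
edge_table <- function(array) {
  pos <- vertex_matrix(array)
  i <- match(array$edges$v1, array$vertices$id)
  j <- match(array$edges$v2, array$vertices$id)
  d <- displacements(pos, i, j, array$box)
  ang <- atan2(d[, 2], d[, 1])
  ang <- ifelse(ang > pi / 2, ang - pi, ifelse(ang <= -pi / 2, ang + pi, ang))
  tibble::tibble(
    edge = array$edges$id,
    v1 = array$edges$v1, v2 = array$edges$v2,
    cell_left = array$edges$cell_left, cell_right = array$edges$cell_right,
    dx = d[, 1], dy = d[, 2], length = row_norms(d),
    angle = ang,
    curvature = array$edges$curvature
  )
}

#' Chord vector of a single edge
#'
#' The vector from the edge's first to its second vertex, using the
#' minimum-image convention on toroidal arrays. Reversing the stored
#' orientation negates the vector.
#'
#' @param array A [cell_array()].
#' @param edge An edge id.
#' @return Numeric length-2 vector `(dx, dy)`.
#' @export
edge_vector <- function(array, edge) {
  k <- match(edge, array$edges$id)
  if (is.na(k)) stop_epiforce(sprintf("unknown edge id %s", format(edge)), "epiforce_dangling_id")
  pos <- vertex_matrix(array)
  i <- match(array$edges$v1[[k]], array$vertices$id)
  j <- match(array$edges$v2[[k]], array$vertices$id)
  drop(displacements(pos, i, j, array$box))
}

#' @rdname edge_vector
#' @export
edge_length <- function(array, edge) {
  v <- edge_vector(array, edge)
  len <- sqrt(sum(v^2))
  if (len == 0) stop_epiforce(sprintf("degenerate edge %s: coincident endpoints", format(edge)), "epiforce_degenerate")
  len
}

mean_edge_length <- function(array) mean(edge_table(array)$length)

# Unwrap a cell loop into contiguous planar coordinates (toroidal arrays may
# wrap the box; successive vertices are placed by minimum-image steps).
unwrap_loop <- function(array, loop_ids, pos = vertex_matrix(array)) {
  k <- match(loop_ids, array$vertices$id)
  p <- pos[k, , drop = FALSE]
  if (!is.null(array$box)) {
    d <- diff(p)
    d[, 1] <- wrap_min_image(d[, 1], array$box[[1]])
    d[, 2] <- wrap_min_image(d[, 2], array$box[[2]])
    steps <- matrix(c(cumsum(d[, 1]), cumsum(d[, 2])), ncol = 2)
    p <- rbind(p[1, , drop = FALSE], sweep(steps, 2, p[1, ], "+"))
  }
  p
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[[1]]); yn <- c(y[-1], y[[1]])
  sum(x * yn - xn * y) / 2
}

# TRUE if any two non-adjacent sides of the polygon cross.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    for (j in js) {
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

#' Cell areas
#'
#' Signed (shoelace) polygon area per cell, positive for counter-clockwise
#' loops. Toroidal loops are unwrapped by minimum-image steps before the
#' shoelace sum, so cells wrapping the box are handled correctly.
#'
#' @param array A [cell_array()].
#' @param cells Cell ids to compute (default all).
#' @param check Error on self-intersecting loops (default `TRUE`).
#' @return Tibble with columns `cell`, `area`.
#' @export
cell_areas <- function(array, cells = NULL, check = TRUE) {
  ids <- if (is.null(cells)) array$cells$id else as.integer(cells)
  k <- match(ids, array$cells$id)
  if (anyNA(k)) stop_epiforce(sprintf("unknown cell id %d", ids[[which(is.na(k))[[1]]]]), "epiforce_dangling_id")
  pos <- vertex_matrix(array)
  area <- vapply(k, function(kk) {
    p <- unwrap_loop(array, array$cells$vertices[[kk]], pos)
    if (check && polygon_self_intersects(p)) {
      stop_epiforce(sprintf("cell %d has a self-intersecting loop", array$cells$id[[kk]]), "epiforce_geometry")
    }
    shoelace(p)
  }, 1.0)
  tibble::tibble(cell = ids, area = area)
}

#' @rdname cell_areas
#' @param cell A single cell id.
#' @export
cell_area <- function(array, cell, check = TRUE) {
  cell_areas(array, cells = cell, check = check)$area[[1]]
}

#' Expected number of zero modes of the force-balance system
#'
#' The mechanical inverse determines tensions and pressures only up to a
#' finite number of free constants: the null-space dimension of the
#' homogeneous force-balance system. Counting parameters against independent
#' constraints gives, for generic geometry:
#' * closed arrays: `(E + C) - (2V - 3)` (all vertices balanced; translation
#'   and rotation make three rows redundant), which is 4 for three-valent
#'   arrays — overall scale plus three boundary constants;
#' * toroidal arrays: `(E + C) - (2V - 2)` (two translational redundancies),
#'   which is 2 for three-valent arrays — scale plus a uniform pressure
#'   shift;
#' * open arrays: `E_int + C - 2 V_int`, counting only interfaces between
#'   two in-view cells and only interior-vertex balance rows; for a nice
#'   three-valent patch this equals the number of boundary cells plus one
#'   (scale plus per-boundary-cell pressure freedom).
#'
#' Rosettes (vertices of degree above three) are accounted for automatically
#' since the formulas use the actual vertex/edge counts: each fusion of two
#' three-fold vertices removes one vertex and one edge and so adds one free
#' constant.
#'
#' The returned value is the generic count. Special local geometries add
#' exact soft modes on top: most importantly every three-sided cell is one
#' (its pressure and three tensions can be adjusted with no net force
#' anywhere, whatever its shape), so on a generic toroidal geometry the
#' measured null-space dimension is `max(2, 1 + #three-sided cells)`.
#' Exactly equilibrated geometry is itself non-generic and can carry
#' further self-stresses. See the methods vignette.
#'
#' @param array A [cell_array()].
#' @return Integer expected null-space dimension.
#' @seealso [null_space_dimension()] for the numerical (SVD) measurement.
#' @export
count_expected_zero_modes <- function(array) {
  V <- nrow(array$vertices); E <- nrow(array$edges); C <- nrow(array$cells)
  switch(array$topology,
    closed = (E + C) - (2L * V - 3L),
    toroidal = (E + C) - (2L * V - 2L),
    open = {
      e_int <- sum(array$edges$cell_left >= 0 & array$edges$cell_right >= 0)
      v_int <- sum(array$vertices$interior)
      (e_int + C) - 2L * v_int
    }
  )
}
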