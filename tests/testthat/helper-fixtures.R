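# Shared fixtures, built in code. Expensive simulated tissues are memoized
# so several test files can reuse them.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

fixture_tissue <- function(n_cells, seed, ...) {
  key <- paste("tissue", n_cells, seed, paste(c(...), collapse = "_"))
  memo(key, generate_voronoi_tissue(simulation_config(n_cells = n_cells, seed = seed, ...)))
}

fixture_hex <- function(nx = 8, ny = 8) {
  memo(paste("hex", nx, ny), hex_lattice(nx, ny))
}

# Smallest two-cell tiling: two triangles sharing one edge, with the four
# perimeter interfaces bordering the exterior (-1).
two_triangle_array <- function() {
  vertices <- tibble::tibble(id = 1:4, x = c(0, 1, 0.5, 0.5), y = c(0, 0, 1, -1))
  edges <- tibble::tibble(
    id = 1:5,
    v1 = c(1L, 2L, 3L, 1L, 4L),
    v2 = c(2L, 3L, 1L, 4L, 2L),
    cell_left = c(10L, 10L, 10L, 20L, 20L),
    cell_right = c(20L, -1L, -1L, -1L, -1L),
    curvature = NA_real_
  )
  cells <- tibble::tibble(
    id = c(10L, 20L),
    vertices = list(c(1L, 2L, 3L), c(1L, 4L, 2L)),
    boundary = TRUE, label = NA_character_
  )
  cell_array(vertices, edges, cells, topology = "open")
}

# A single unit-square cell (closed array with 4 perimeter interfaces).
unit_square_array <- function() {
  vertices <- tibble::tibble(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  edges <- tibble::tibble(
    id = 1:4, v1 = 1:4, v2 = c(2:4, 1L),
    cell_left = 1L, cell_right = -1L, curvature = NA_real_
  )
  cells <- tibble::tibble(id = 1L, vertices = list(1:4), boundary = TRUE, label = NA_character_)
  # V - E + C + 1 = 4 - 4 + 1 + 1 = 2: valid closed array
  cell_array(vertices, edges, cells, topology = "closed")
}

random_state <- function(array, seed, tension_sd = 0.3, pressure_sd = 0.3) {
  withr::with_seed(seed, mechanical_state(
    tibble::tibble(edge = array$edges$id,
                   tension = 1 + tension_sd * stats::rnorm(nrow(array$edges))),
    tibble::tibble(cell = array$cells$id,
                   pressure = pressure_sd * stats::rnorm(nrow(array$cells)))
  ))
}

# Independent oracle for polygon area: fan triangulation from the first
# vertex, summing cross products.
fan_area <- function(p) {
  s <- 0
  for (k in 2:(nrow(p) - 1)) {
    a <- p[k, ] - p[1, ]; b <- p[k + 1, ] - p[1, ]
    s <- s + (a[[1]] * b[[2]] - a[[2]] * b[[1]]) / 2
  }
  s
}

# Independent oracle for intercellular traction: solve the corner
# cortical-tension continuity system at each endpoint of the edge and take
# the difference of the shared cell's corner values.
traction_oracle <- function(array, state, edge_id) {
  e <- array$edges[match(edge_id, array$edges$id), ]
  Tv <- stats::setNames(state$tensions$tension, state$tensions$edge)
  corner_value <- function(v, want_cell) {
    inc <- array$edges[array$edges$v1 == v | array$edges$v2 == v, ]
    stopifnot(nrow(inc) == 3)
    cells <- unique(c(inc$cell_left, inc$cell_right))
    stopifnot(length(cells) == 3)
    # rows: one equation per interface, t_x + t_y = T_xy
    A <- t(vapply(seq_len(3), function(r) as.numeric(cells %in% c(inc$cell_left[[r]], inc$cell_right[[r]])), numeric(3)))
    tt <- solve(A, Tv[as.character(inc$id)])
    tt[[match(want_cell, cells)]]
  }
  corner_value(e$v2, e$cell_left) - corner_value(e$v1, e$cell_left)
}

wrap_d <- function(d, L) d - L * round(d / L)
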