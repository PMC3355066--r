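test_that("the minimal two-triangle tiling is represented and counted correctly", {
  arr <- two_triangle_array()
  expect_equal(nrow(arr$vertices), 4)
  expect_equal(nrow(arr$edges), 5)
  expect_equal(nrow(arr$cells), 2)
  expect_false(any(arr$vertices$interior))   # every vertex touches the exterior
  # only the shared interface carries a tension parameter; no vertex is
  # balanced, so all three parameters (1 tension + 2 pressures) are free
  expect_equal(count_expected_zero_modes(arr), 3)
})

test_that("validation catches dangling references, non-manifold edges and bad loops", {
  arr <- two_triangle_array()

  bad <- arr; bad$edges$v2[[1]] <- 99L
  expect_error(validate_cell_array(bad), class = "epiforce_dangling_id")

  bad <- arr; bad$edges$cell_left[[2]] <- 77L
  expect_error(validate_cell_array(bad), class = "epiforce_dangling_id")

  # a third cell claiming an existing edge -> non-manifold
  bad <- arr
  bad$cells <- dplyr::bind_rows(bad$cells, tibble::tibble(
    id = 30L, vertices = list(c(1L, 2L, 3L)), boundary = TRUE, label = NA_character_))
  expect_error(validate_cell_array(bad), class = "epiforce_topology")

  # clockwise loop -> orientation error
  bad <- arr; bad$cells$vertices[[1]] <- rev(bad$cells$vertices[[1]])
  expect_error(validate_cell_array(bad), class = "epiforce_invalid")

  # degenerate edge
  bad <- arr; bad$vertices$x[[2]] <- 0; bad$vertices$y[[2]] <- 0
  expect_error(validate_cell_array(bad), class = "epiforce_degenerate")
})

test_that("cell areas match closed forms and an independent triangulation oracle", {
  sq <- unit_square_array()
  expect_equal(cell_area(sq, 1), 1.0)

  # regular hexagon with circumradius 1
  ang <- 2 * pi * (0:5) / 6
  vertices <- tibble::tibble(id = 1:6, x = cos(ang), y = sin(ang))
  edges <- tibble::tibble(id = 1:6, v1 = 1:6, v2 = c(2:6, 1L),
                          cell_left = 1L, cell_right = -1L, curvature = NA_real_)
  cells <- tibble::tibble(id = 1L, vertices = list(1:6), boundary = TRUE, label = NA_character_)
  hexagon <- cell_array(vertices, edges, cells, topology = "closed")
  expect_equal(cell_area(hexagon, 1), 3 * sqrt(3) / 2, tolerance = 1e-12)

  # random convex polygons against the fan-triangulation oracle
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(5:9, 1)
      th <- sort(stats::runif(n, 0, 2 * pi))
      rad <- stats::runif(1, 0.5, 2)
      p <- cbind(rad * cos(th), rad * sin(th))
      vs <- tibble::tibble(id = seq_len(n), x = p[, 1], y = p[, 2])
      es <- tibble::tibble(id = seq_len(n), v1 = seq_len(n), v2 = c(2:n, 1L),
                           cell_left = 1L, cell_right = -1L, curvature = NA_real_)
      cs <- tibble::tibble(id = 1L, vertices = list(seq_len(n)), boundary = TRUE, label = NA_character_)
      poly <- cell_array(vs, es, cs, topology = "closed")
      expect_equal(cell_area(poly, 1), fan_area(p), tolerance = 1e-12)
    }
  })
})

test_that("self-intersecting loops raise a geometry error", {
  vertices <- tibble::tibble(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  edges <- tibble::tibble(id = 1:4, v1 = c(1L, 3L, 2L, 4L), v2 = c(3L, 2L, 4L, 1L),
                          cell_left = 1L, cell_right = -1L, curvature = NA_real_)
  cells <- tibble::tibble(id = 1L, vertices = list(c(1L, 3L, 2L, 4L)), boundary = TRUE,
                          label = NA_character_)
  bowtie <- cell_array(vertices, edges, cells, topology = "open", validate = FALSE)
  expect_error(cell_area(bowtie, 1), class = "epiforce_geometry")
})

test_that("edge vectors use the minimum image and flip sign with orientation", {
  arr <- two_triangle_array()
  expect_equal(edge_vector(arr, 1), c(1, 0))
  expect_equal(edge_length(arr, 1), 1)
  # (0,0) -> (3,4) style: edge 2 of the triangle fixture
  expect_equal(edge_length(arr, 2), sqrt(0.5^2 + 1))

  hx <- fixture_hex()
  et <- edge_table(hx)
  expect_true(all(et$length > 0))
  # reversing orientation negates the chord
  rev_arr <- hx
  rev_arr$edges$v1 <- hx$edges$v2; rev_arr$edges$v2 <- hx$edges$v1
  tmp <- hx$edges$cell_left
  rev_arr$edges$cell_left <- hx$edges$cell_right; rev_arr$edges$cell_right <- tmp
  expect_equal(edge_vector(rev_arr, 5), -edge_vector(hx, 5))

  # explicit minimum image on a toroidal box
  vertices <- tibble::tibble(id = 1:2, x = c(9, 1), y = c(0, 0))
  fake <- structure(list(vertices = vertices,
                         edges = tibble::tibble(id = 1L, v1 = 1L, v2 = 2L,
                                                cell_left = 1L, cell_right = 2L, curvature = NA_real_),
                         cells = tibble::tibble(id = 1:2, vertices = list(1:2, 1:2)),
                         topology = "toroidal", box = c(10, 10)),
                    class = "cell_array")
  expect_equal(edge_vector(fake, 1), c(2, 0))
  expect_equal(edge_length(fake, 1), 2)
})

test_that("Euler relations are enforced per topology", {
  hx <- fixture_hex()
  V <- nrow(hx$vertices); E <- nrow(hx$edges); C <- nrow(hx$cells)
  expect_equal(V - E + C, 0)
  expect_equal(c(V, E, C), c(128, 192, 64))

  # removing one toroidal edge record breaks the Euler relation
  bad <- hx; bad$edges <- bad$edges[-1, ]
  expect_error(validate_cell_array(bad), class = "epiforce_topology")
})

test_that("arrays round-trip bit-identically through JSON and CSV", {
  arr <- fixture_tissue(36, 1)$array
  arr$edges$curvature[3] <- 0.123456789012345
  arr$cells$label[2] <- "hair-cell"

  json <- file.path(withr::local_tempdir(), "arr.json")
  write_cell_array(arr, json, "json")
  back <- read_cell_array(json)
  expect_identical(back$vertices$x, arr$vertices$x)
  expect_identical(back$vertices$y, arr$vertices$y)
  expect_identical(back$edges, arr$edges)
  expect_identical(lapply(back$cells$vertices, as.integer), arr$cells$vertices)
  expect_identical(back$box, arr$box)

  csvdir <- file.path(withr::local_tempdir(), "arr_csv")
  write_cell_array(arr, csvdir, "csv")
  back2 <- read_cell_array(csvdir)
  expect_identical(back2$vertices$x, arr$vertices$x)
  expect_identical(back2$edges$id, arr$edges$id)
  expect_identical(back2$cells$vertices, arr$cells$vertices)
  expect_equal(back2$topology, arr$topology)

  # mechanical state round trip
  st <- random_state(arr, 5)
  sfile <- file.path(withr::local_tempdir(), "state.json")
  write_state(st, sfile)
  st2 <- read_state(sfile)
  expect_identical(st2$tensions$tension, st$tensions$tension)
  expect_identical(st2$pressures$pressure, st$pressures$pressure)
})

test_that("reading a file with a dangling cell reference fails loudly", {
  arr <- two_triangle_array()
  arr$edges$cell_left[[2]] <- 55L
  json <- file.path(withr::local_tempdir(), "bad.json")
  # write without validation by rebuilding unchecked
  raw <- structure(arr, class = "cell_array")
  write_cell_array(raw, json, "json")
  expect_error(read_cell_array(json), class = "epiforce_dangling_id")
})

test_that("three-valent closed arrays obey the counting identities", {
  sim <- fixture_tissue(100, 4)
  cl <- extract_patch(sim$array, topology = "closed")
  V <- nrow(cl$vertices); E <- nrow(cl$edges); C <- nrow(cl$cells)
  expect_equal(3 * V, 2 * E)                 # all junctions three-valent
  expect_equal(V - E + C + 1, 2)             # sphere-like Euler count
  expect_equal((E + C) - (2 * V - 3), 4)     # parameters exceed constraints by 4
  expect_equal(count_expected_zero_modes(cl), 4)
})
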