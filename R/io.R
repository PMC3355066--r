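#' Read and write cell arrays
#'
#' Two plain-text formats are supported:
#' * `json`: a single file with keys `topology`, `box`, `vertices`
#'   (`id`, `x`, `y`), `edges` (`id`, `v1`, `v2`, `cell_left`, `cell_right`,
#'   `curvature`) and `cells` (`id`, `vertices`, `boundary`, `label`);
#'   `cell_right = -1` denotes the exterior region.
#' * `csv`: a directory containing `vertices.csv`, `edges.csv`, `cells.csv`
#'   with the same columns plus `topology.csv` holding the topology kind and
#'   box; the cell loop is encoded as a `"|"`-separated vertex-id list.
#'
#' Writing then reading reproduces the topology exactly and the coordinates
#' bit-identically (full-precision serialization in both formats).
#'
#' @param path File (json) or directory (csv) path.
#' @param format `"auto"` (directory implies csv), `"json"` or `"csv"`.
#' @param validate Validate the array after reading (default `TRUE`).
#' @return A [cell_array()].
#' @export
read_cell_array <- function(path, format = c("auto", "json", "csv"), validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "csv" else "json"
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    vertices <- tibble::as_tibble(obj$vertices)
    edges <- tibble::as_tibble(obj$edges)
    cells_df <- obj$cells
    cells <- tibble::tibble(
      id = cells_df$id,
      vertices = if (is.list(cells_df$vertices)) cells_df$vertices else list(cells_df$vertices),
      boundary = if (!is.null(cells_df$boundary)) cells_df$boundary else FALSE,
      label = if (!is.null(cells_df$label)) cells_df$label else NA_character_
    )
    box <- if (!is.null(obj$box) && length(obj$box) == 2) as.double(obj$box) else NULL
    cell_array(vertices, edges, cells, topology = obj$topology, box = box, validate = validate)
  } else {
    req <- file.path(path, c("vertices.csv", "edges.csv", "cells.csv", "topology.csv"))
    missing <- req[!file.exists(req)]
    if (length(missing) > 0) {
      stop_epiforce(sprintf("csv cell-array directory is missing %s", basename(missing)[[1]]), "epiforce_io")
    }
    # doubles come in as text and through strtod (correctly rounded), so
    # the 17-digit decimal representation round-trips bit-exactly
    vertices <- readr::read_csv(req[[1]], col_types = readr::cols(id = "i", x = "c", y = "c"),
                                progress = FALSE)
    vertices$x <- as.double(vertices$x); vertices$y <- as.double(vertices$y)
    edges <- readr::read_csv(req[[2]], col_types = readr::cols(
      id = "i", v1 = "i", v2 = "i", cell_left = "i", cell_right = "i", curvature = "c"
    ), progress = FALSE)
    edges$curvature <- as.double(edges$curvature)
    cells_raw <- readr::read_csv(req[[3]], col_types = readr::cols(
      id = "i", vertices = "c", boundary = "l", label = "c"
    ), progress = FALSE)
    cells <- tibble::tibble(
      id = cells_raw$id,
      vertices = lapply(strsplit(cells_raw$vertices, "|", fixed = TRUE), as.integer),
      boundary = cells_raw$boundary,
      label = cells_raw$label
    )
    topo <- readr::read_csv(req[[4]], col_types = readr::cols(
      topology = "c", Lx = "d", Ly = "d"
    ), progress = FALSE)
    box <- if (is.finite(topo$Lx[[1]])) c(topo$Lx[[1]], topo$Ly[[1]]) else NULL
    cell_array(vertices, edges, cells, topology = topo$topology[[1]], box = box, validate = validate)
  }
}

#' @rdname read_cell_array
#' @param array A [cell_array()] to write.
#' @export
write_cell_array <- function(array, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "json") {
    obj <- list(
      topology = array$topology,
      box = array$box,
      vertices = array$vertices[c("id", "x", "y")],
      edges = array$edges[c("id", "v1", "v2", "cell_left", "cell_right", "curvature")],
      cells = list(
        id = array$cells$id,
        vertices = array$cells$vertices,
        boundary = array$cells$boundary,
        label = array$cells$label
      )
    )
    # 17 significant digits: exact decimal round trip for doubles.
    json <- jsonlite::toJSON(obj, dataframe = "columns", digits = I(17), auto_unbox = TRUE, null = "null", na = "null")
    writeLines(json, path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    v_out <- array$vertices[c("id", "x", "y")]
    v_out$x <- fmt(v_out$x); v_out$y <- fmt(v_out$y)
    readr::write_csv(v_out, file.path(path, "vertices.csv"), progress = FALSE)
    e_out <- array$edges[c("id", "v1", "v2", "cell_left", "cell_right", "curvature")]
    e_out$curvature <- fmt(e_out$curvature)
    readr::write_csv(e_out, file.path(path, "edges.csv"), progress = FALSE)
    cells_flat <- tibble::tibble(
      id = array$cells$id,
      vertices = vapply(array$cells$vertices, paste, "", collapse = "|"),
      boundary = array$cells$boundary,
      label = array$cells$label
    )
    readr::write_csv(cells_flat, file.path(path, "cells.csv"), progress = FALSE)
    topo <- tibble::tibble(
      topology = array$topology,
      Lx = if (is.null(array$box)) NA_real_ else array$box[[1]],
      Ly = if (is.null(array$box)) NA_real_ else array$box[[2]]
    )
    readr::write_csv(topo, file.path(path, "topology.csv"), progress = FALSE)
  }
  invisible(path)
}

#' Read and write mechanical states
#'
#' A mechanical state (per-edge tensions and per-cell pressures) is stored
#' as JSON: `{"tensions": {"<edge id>": T, ...},
#' "pressures": {"<cell id>": P, ...}, "exterior_pressure": 0}`.
#'
#' @param path JSON file path.
#' @return A [mechanical_state()].
#' @export
read_state <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mechanical_state(
    tensions = tibble::tibble(
      edge = as.integer(names(obj$tensions)),
      tension = as.double(unlist(obj$tensions, use.names = FALSE))
    ),
    pressures = tibble::tibble(
      cell = as.integer(names(obj$pressures)),
      pressure = as.double(unlist(obj$pressures, use.names = FALSE))
    ),
    exterior_pressure = if (!is.null(obj$exterior_pressure)) obj$exterior_pressure else 0
  )
}

#' @rdname read_state
#' @param state A [mechanical_state()] to write.
#' @export
write_state <- function(state, path) {
  obj <- list(
    tensions = as.list(stats::setNames(state$tensions$tension, state$tensions$edge)),
    pressures = as.list(stats::setNames(state$pressures$pressure, state$pressures$cell)),
    exterior_pressure = state$exterior_pressure
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}
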