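# Periodic (toroidal) Voronoi tessellation by half-plane clipping.
#
# Each seed's cell is the intersection of bisector half-planes against the
# seeds tiled over the 3 x 3 neighbouring period images. Neighbours are
# visited in order of distance and clipping stops once the next bisector
# cannot intersect the current polygon, so only O(1) clips per cell are
# performed. Voronoi vertices are identified across cells by their defining
# seed triple plus position.

#' Periodic Voronoi diagram of a set of seeds
#'
#' Tessellates the periodic rectangle `box` into convex cells, one per seed.
#' Generic seed configurations give a three-valent tiling satisfying
#' `V - E + C = 0` and `3V = 2E`; cocircular degeneracies are resolved by
#' perturbing the seeds slightly and retrying (with a warning).
#'
#' @param seeds n x 2 matrix of seed positions (wrapped into the box).
#' @param box Numeric `(Lx, Ly)` period lengths.
#' @param max_attempts Retries on degenerate configurations.
#' @return A toroidal [cell_array()] whose cell ids `1..n` match seed rows.
#' @export
periodic_voronoi <- function(seeds, box, max_attempts = 6L) {
  seeds <- as.matrix(seeds)
  stopifnot(ncol(seeds) == 2, length(box) == 2, all(box > 0))
  n <- nrow(seeds)
  if (n < 3) stop_epiforce("periodic Voronoi needs at least 3 seeds", "epiforce_invalid")
  scale <- sqrt(box[[1]] * box[[2]] / n)
  current <- seeds
  for (attempt in seq_len(max_attempts)) {
    arr <- tryCatch(
      periodic_voronoi_once(current, box),
      error = function(e) e
    )
    if (!inherits(arr, "error")) return(arr)
    if (attempt == max_attempts) {
      stop_epiforce(sprintf("periodic Voronoi failed after %d attempts: %s",
                            max_attempts, conditionMessage(arr)), "epiforce_geometry")
    }
    rlang::warn(sprintf("degenerate Voronoi configuration (%s); perturbing seeds and retrying",
                        conditionMessage(arr)))
    jitter <- matrix(stats::rnorm(2 * n, sd = 1e-9 * 10^(attempt - 1) * scale), ncol = 2)
    current <- current + jitter
  }
}

periodic_voronoi_once <- function(seeds, box) {
  n <- nrow(seeds)
  Lx <- box[[1]]; Ly <- box[[2]]
  seeds[, 1] <- seeds[, 1] %% Lx
  seeds[, 2] <- seeds[, 2] %% Ly

  offs <- as.matrix(expand.grid(x = c(-Lx, 0, Lx), y = c(-Ly, 0, Ly)))
  n_tile <- n * nrow(offs)
  tiled <- matrix(0, n_tile, 2)
  canon <- integer(n_tile)
  for (k in seq_len(nrow(offs))) {
    rows <- ((k - 1) * n + 1):(k * n)
    tiled[rows, 1] <- seeds[, 1] + offs[k, 1]
    tiled[rows, 2] <- seeds[, 2] + offs[k, 2]
    canon[rows] <- seq_len(n)
  }

  merge_tol <- 1e-7 * min(Lx, Ly)
  vert_env <- new.env(parent = emptyenv(), hash = TRUE)
  vert_pos <- matrix(0, 0, 2)
  n_vert <- 0L

  cell_loops <- vector("list", n)
  edge_rows <- vector("list", n)

  for (i in seq_len(n)) {
    poly <- clip_voronoi_cell(i, seeds[i, ], tiled, canon)
    pts <- poly$points      # k x 2, CCW, local frame around seed i
    gens <- poly$gens       # tiled-neighbour index of side starting at each point
    k <- nrow(pts)
    if (k < 3) stop("cell polygon collapsed")

    # Identify corners: corner j joins side ending there (gens[j-1]) and side
    # starting there (gens[j]).
    prev_gen <- c(gens[k], gens[-k])
    vids <- integer(k)
    for (j in seq_len(k)) {
      trip <- sort(c(i, canon[prev_gen[j]], canon[gens[j]]))
      if (anyDuplicated(trip)) stop("degenerate corner (repeated seed in triple)")
      key <- paste(trip, collapse = "_")
      px <- pts[j, 1] %% Lx; py <- pts[j, 2] %% Ly
      hits <- vert_env[[key]]
      found <- 0L
      if (!is.null(hits)) {
        for (h in hits) {
          dx <- wrap_min_image(px - vert_pos[h, 1], Lx)
          dy <- wrap_min_image(py - vert_pos[h, 2], Ly)
          if (dx * dx + dy * dy < merge_tol^2) { found <- h; break }
        }
      }
      if (found == 0L) {
        n_vert <- n_vert + 1L
        vert_pos <- rbind(vert_pos, c(px, py))
        vert_env[[key]] <- c(hits, n_vert)
        found <- n_vert
      }
      vids[j] <- found
    }
    if (anyDuplicated(vids)) stop("merged corners within one cell (near-degenerate edge)")
    cell_loops[[i]] <- vids
    edge_rows[[i]] <- tibble::tibble(
      v1 = vids, v2 = c(vids[-1], vids[1]),
      cell_left = i, cell_right = canon[gens]
    )
  }

  all_edges <- dplyr::bind_rows(edge_rows)
  key <- paste(pmin(all_edges$v1, all_edges$v2), pmax(all_edges$v1, all_edges$v2))
  first <- !duplicated(key)
  if (sum(first) * 2L != nrow(all_edges)) stop("unpaired interface between cells")
  edges <- all_edges[first, ]
  edges$id <- seq_len(nrow(edges))
  edges$curvature <- NA_real_

  vertices <- tibble::tibble(id = seq_len(n_vert), x = vert_pos[, 1], y = vert_pos[, 2])
  cells <- tibble::tibble(
    id = seq_len(n), vertices = cell_loops, boundary = FALSE, label = NA_character_
  )
  cell_array(vertices, edges[c("id", "v1", "v2", "cell_left", "cell_right", "curvature")],
             cells, topology = "toroidal", box = box)
}

# Clip the (large) initial square around seed s against bisectors with tiled
# neighbours in distance order. Returns CCW points and, per point, the tiled
# index generating the side that starts there.
clip_voronoi_cell <- function(self, s, tiled, canon) {
  d2 <- (tiled[, 1] - s[1])^2 + (tiled[, 2] - s[2])^2
  ord <- order(d2)
  ord <- ord[d2[ord] > 0]  # drop the seed itself (its own 0-offset copy)

  R0 <- sqrt(max(d2))
  pts <- rbind(s + c(-R0, -R0), s + c(R0, -R0), s + c(R0, R0), s + c(-R0, R0))
  gens <- rep(0L, 4L)  # 0 marks a side of the initial bounding square

  for (t in ord) {
    maxd2 <- max((pts[, 1] - s[1])^2 + (pts[, 2] - s[2])^2)
    if (d2[t] >= 4 * maxd2) break
    dir <- tiled[t, ] - s
    mid <- s + dir / 2
    f <- (pts[, 1] - mid[1]) * dir[1] + (pts[, 2] - mid[2]) * dir[2]
    if (all(f <= 0)) next
    if (all(f >= 0)) stop("cell polygon collapsed")
    k <- nrow(pts)
    new_pts <- matrix(0, 0, 2); new_gens <- integer(0)
    for (a in seq_len(k)) {
      b <- if (a == k) 1L else a + 1L
      fa <- f[a]; fb <- f[b]
      if (fa <= 0) {
        # A is kept; if the side leaving A is cut right at A, it becomes the
        # new bisector side.
        g <- if (fa == 0 && fb > 0) t else gens[a]
        new_pts <- rbind(new_pts, pts[a, ]); new_gens <- c(new_gens, g)
        if (fb > 0 && fa < 0) {             # exit crossing: bisector side starts here
          x <- pts[a, ] + (pts[b, ] - pts[a, ]) * (fa / (fa - fb))
          new_pts <- rbind(new_pts, x); new_gens <- c(new_gens, t)
        }
      } else if (fb < 0) {                  # entry crossing: old side a resumes here
        x <- pts[a, ] + (pts[b, ] - pts[a, ]) * (fa / (fa - fb))
        new_pts <- rbind(new_pts, x); new_gens <- c(new_gens, gens[a])
      }
    }
    pts <- new_pts; gens <- new_gens
    if (nrow(pts) < 3) stop("cell polygon collapsed")
  }
  if (any(gens == 0L)) stop("unclipped bounding-square side (seeds too sparse)")
  list(points = pts, gens = gens)
}

# Lloyd (centroidal Voronoi) regularization: move each seed to the centroid
# of its Voronoi cell, `iters` times.
lloyd_steps <- function(seeds, box, iters) {
  for (it in seq_len(iters)) {
    arr <- periodic_voronoi(seeds, box)
    pos <- vertex_matrix(arr)
    seeds <- t(vapply(seq_len(nrow(seeds)), function(k) {
      p <- unwrap_loop(arr, arr$cells$vertices[[k]], pos)
      x <- p[, 1]; y <- p[, 2]
      xn <- c(x[-1], x[[1]]); yn <- c(y[-1], y[[1]])
      cr <- x * yn - xn * y
      c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * sum(cr) / 2)
    }, c(0, 0)))
    seeds[, 1] <- seeds[, 1] %% box[[1]]
    seeds[, 2] <- seeds[, 2] %% box[[2]]
  }
  seeds
}
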