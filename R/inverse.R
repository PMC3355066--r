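#' Assemble the force-balance linear system
#'
#' Writes the condition that the interfacial forces balance at every
#' junction as a linear system `A q = b` in the unknown mechanical
#' parameters `q`. Each balanced vertex contributes two rows (x and y); one
#' final row fixes the arbitrary overall scale by constraining the average
#' tension to 1 (its right-hand side is the only nonzero entry of `b`).
#'
#' Three parameterizations are supported:
#' * `"full"`: one tension per interface and one pressure per cell
#'   (exterior pressure pinned to 0 by omission, not by an extra row);
#' * `"constant_pressure"`: pressure variation is neglected, leaving only
#'   the tensions - the system becomes overdetermined and is solved in the
#'   least-squares sense;
#' * `"cortical"`: each interface tension is the sum of the two adjacent
#'   cells' cortical tensions, `T_ab = zeta_a + zeta_b`, giving one
#'   cortical tension plus one pressure per cell.
#'
#' Which vertices are balanced depends on the topology: all vertices for
#' closed and toroidal arrays, interior vertices only for open arrays
#' (those whose incident cells are all in view). For open arrays,
#' interfaces that border the exterior never appear in a balanced row and
#' carry no tension column.
#'
#' @param array A validated [cell_array()].
#' @param parameterization One of `"full"`, `"constant_pressure"`,
#'   `"cortical"`.
#' @param scale Right-hand side of the scale row (mean tension; default 1).
#' @return An object of class `balance_system`: a list with `matrix`, `rhs`,
#'   `column_map` (tibble: `column`, `kind`, `id`), `row_map` (tibble:
#'   `row`, `vertex`, `component`), `parameterization` and `array`.
#' @export
balance_system <- function(array, parameterization = c("full", "constant_pressure", "cortical"),
                           scale = 1) {
  parameterization <- match.arg(parameterization)
  et <- edge_table(array)

  balanced <- if (array$topology == "open") {
    array$vertices$id[array$vertices$interior]
  } else {
    array$vertices$id
  }
  if (length(balanced) == 0) {
    stop_epiforce("nothing to balance: open array has no interior vertices", "epiforce_invalid")
  }
  vrow <- stats::setNames(seq_along(balanced), balanced)  # vertex id -> row pair index

  # Parameter columns.
  tension_edges <- if (array$topology == "open") {
    et$edge[et$cell_left >= 0 & et$cell_right >= 0]
  } else {
    et$edge
  }
  cells <- array$cells$id
  column_map <- switch(parameterization,
    full = dplyr::bind_rows(
      tibble::tibble(kind = "tension", id = tension_edges),
      tibble::tibble(kind = "pressure", id = cells)
    ),
    constant_pressure = tibble::tibble(kind = "tension", id = tension_edges),
    cortical = dplyr::bind_rows(
      tibble::tibble(kind = "cortical", id = cells),
      tibble::tibble(kind = "pressure", id = cells)
    )
  )
  column_map$column <- seq_len(nrow(column_map))
  col_of <- function(kind, id) {
    m <- column_map$column[match(paste(kind, id), paste(column_map$kind, column_map$id))]
    m
  }

  n_rows <- 2L * length(balanced) + 1L
  n_cols <- nrow(column_map)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- double(0)
  add <- function(rows, cols, vals) {
    keep <- !is.na(cols)
    trip_i <<- c(trip_i, rows[keep]); trip_j <<- c(trip_j, cols[keep]); trip_x <<- c(trip_x, vals[keep])
  }

  # Per edge: tension pulls each endpoint toward the other along the unit
  # chord; the pressure difference pushes both endpoints perpendicular to
  # the chord, half each (left cell +, right cell -).
  in_t <- match(et$edge, tension_edges)
  for (k in seq_len(nrow(et))) {
    u <- c(et$dx[[k]], et$dy[[k]]) / et$length[[k]]
    perp <- c(et$dy[[k]], -et$dx[[k]]) / 2      # eps * chi / 2
    r1 <- vrow[as.character(et$v1[[k]])]
    r2 <- vrow[as.character(et$v2[[k]])]
    rows1 <- if (!is.na(r1)) c(2 * r1 - 1, 2 * r1)
    rows2 <- if (!is.na(r2)) c(2 * r2 - 1, 2 * r2)
    if (!is.na(in_t[[k]])) {
      if (parameterization == "cortical") {
        tc <- c(col_of("cortical", et$cell_left[[k]]), col_of("cortical", et$cell_right[[k]]))
        if (!is.null(rows1)) add(rep(rows1, 2), rep(tc, each = 2), rep(u, 2))
        if (!is.null(rows2)) add(rep(rows2, 2), rep(tc, each = 2), rep(-u, 2))
      } else {
        tc <- col_of("tension", et$edge[[k]])
        if (!is.null(rows1)) add(rows1, rep(tc, 2), u)
        if (!is.null(rows2)) add(rows2, rep(tc, 2), -u)
      }
    }
    if (parameterization != "constant_pressure") {
      pc_l <- if (et$cell_left[[k]] >= 0) col_of("pressure", et$cell_left[[k]]) else NA_integer_
      pc_r <- if (et$cell_right[[k]] >= 0) col_of("pressure", et$cell_right[[k]]) else NA_integer_
      for (rows in list(rows1, rows2)) {
        if (is.null(rows)) next
        add(rows, rep(pc_l, 2), perp)
        add(rows, rep(pc_r, 2), -perp)
      }
    }
  }

  # Scale row: mean implied tension equals `scale`.
  nT <- length(tension_edges)
  if (parameterization == "cortical") {
    cnt <- table(factor(c(et$cell_left, et$cell_right), levels = cells))
    add(rep(n_rows, length(cells)), col_of("cortical", cells), as.double(cnt) / nT)
  } else {
    add(rep(n_rows, nT), col_of("tension", tension_edges), rep(1 / nT, nT))
  }

  mat <- as.matrix(Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                        dims = c(n_rows, n_cols)))
  rhs <- c(rep(0, n_rows - 1L), scale)
  row_map <- tibble::tibble(
    row = seq_len(n_rows),
    vertex = c(rep(balanced, each = 2), NA_integer_),
    component = c(rep(c("x", "y"), length(balanced)), "scale")
  )
  structure(
    list(matrix = mat, rhs = rhs, column_map = column_map[c("column", "kind", "id")],
         row_map = row_map, parameterization = parameterization, array = array),
    class = "balance_system"
  )
}

#' @export
print.balance_system <- function(x, ...) {
  cat(sprintf("<balance_system: %s> %d rows (incl. scale) x %d parameters\n",
              x$parameterization, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Solve the mechanical inverse
#'
#' Solves the assembled force-balance system by singular value
#' decomposition: the returned `particular` solution is the minimum-norm
#' least-squares solution (the Moore-Penrose pseudo-inverse applied to the
#' right-hand side), `zero_modes` is an orthonormal basis of the numerical
#' null space (singular values below `rel_tol` times the largest), and any
#' combination `particular + zero_modes %*% amplitudes` solves the system
#' equally well. By construction the particular solution is orthogonal to
#' every zero mode.
#'
#' @param system A [balance_system()].
#' @param rel_tol Relative singular-value cutoff for the null space.
#' @param amplitudes Optional zero-mode amplitudes (default all 0, i.e. the
#'   minimum-norm solution).
#' @return An object of class `mi_fit` with elements `particular`,
#'   `zero_modes`, `amplitudes`, `residual_norm`, `singular_values`,
#'   `column_map`, `parameterization` and `state` (a [mechanical_state()];
#'   for the cortical parameterization the per-edge tensions are the sums of
#'   the two adjacent cortical tensions, and the per-cell cortical tensions
#'   are kept in `cortical`).
#' @export
solve_inverse <- function(system, rel_tol = 1e-8, amplitudes = NULL) {
  A <- system$matrix
  if (all(A == 0)) stop_epiforce("all-zero balance matrix", "epiforce_invalid")
  sv <- svd(A)
  keep <- sv$d > rel_tol * sv$d[[1]]
  q <- sv$v[, keep, drop = FALSE] %*% ((t(sv$u[, keep, drop = FALSE]) %*% system$rhs) / sv$d[keep])
  q <- drop(q)
  zero_modes <- sv$v[, !keep, drop = FALSE]
  if (!is.null(amplitudes)) {
    stopifnot(length(amplitudes) == ncol(zero_modes))
    q <- q + drop(zero_modes %*% amplitudes)
  } else {
    amplitudes <- rep(0, ncol(zero_modes))
  }
  residual <- sqrt(sum((A %*% q - system$rhs)^2))
  new_mi_fit(system, q, zero_modes, amplitudes, residual, sv$d)
}

new_mi_fit <- function(system, q, zero_modes, amplitudes, residual, singular_values) {
  arr <- system$array
  # The scale row enters the least-squares trade-off with finite weight, so
  # on inconsistent (noisy or reduced) systems the raw solution is shrunk;
  # rescaling to mean tension exactly 1 restores the stated normalization
  # without changing the solution direction.
  m <- mean(implied_tensions(system, q))
  if (is.finite(m) && m > 1e-12) {
    q <- q / m
    residual <- sqrt(sum((system$matrix %*% q - system$rhs)^2))
  }
  cm <- system$column_map
  cm$estimate <- q
  if (system$parameterization == "cortical") {
    zeta <- cm[cm$kind == "cortical", ]
    zl <- zeta$estimate[match(arr$edges$cell_left, zeta$id)]
    zr <- zeta$estimate[match(arr$edges$cell_right, zeta$id)]
    # the exterior region has no cortex: its share is 0
    zl[is.na(zl)] <- 0; zr[is.na(zr)] <- 0
    tensions <- tibble::tibble(edge = arr$edges$id, tension = zl + zr)
    cortical <- tibble::tibble(cell = zeta$id, cortical_tension = zeta$estimate)
  } else {
    tt <- cm[cm$kind == "tension", ]
    tensions <- tibble::tibble(edge = tt$id, tension = tt$estimate)
    cortical <- NULL
  }
  if (system$parameterization == "constant_pressure") {
    pressures <- tibble::tibble(cell = arr$cells$id, pressure = 0)
  } else {
    pp <- cm[cm$kind == "pressure", ]
    pressures <- tibble::tibble(cell = pp$id, pressure = pp$estimate)
  }
  structure(
    list(particular = q, zero_modes = zero_modes, amplitudes = amplitudes,
         residual_norm = residual, singular_values = singular_values,
         column_map = cm, parameterization = system$parameterization,
         state = mechanical_state(tensions, pressures), cortical = cortical),
    class = "mi_fit"
  )
}

# Per-edge tensions implied by a parameter vector (cortical: sum of the two
# adjacent cortical tensions, exterior contributing 0).
implied_tensions <- function(system, q) {
  cm <- system$column_map
  arr <- system$array
  if (system$parameterization == "cortical") {
    zeta <- stats::setNames(q[cm$kind == "cortical"], cm$id[cm$kind == "cortical"])
    zl <- zeta[as.character(arr$edges$cell_left)]
    zr <- zeta[as.character(arr$edges$cell_right)]
    zl[is.na(zl)] <- 0; zr[is.na(zr)] <- 0
    unname(zl + zr)
  } else {
    q[cm$kind == "tension"]
  }
}

#' @export
print.mi_fit <- function(x, ...) {
  cat(sprintf("<mi_fit: %s> %d parameters, %d zero modes, residual %.3g\n",
              x$parameterization, length(x$particular), ncol(x$zero_modes), x$residual_norm))
  invisible(x)
}

#' Solve the mechanical inverse with nonnegative tensions
#'
#' Least-squares solution of the balance system subject to nonnegativity of
#' the tension-like parameters (tensions or cortical tensions); pressures
#' remain free. Implemented by eliminating the free columns with their
#' pseudo-inverse and running Lawson-Hanson nonnegative least squares
#' ([pracma::lsqnonneg()]) on the projected problem. Compared to the plain
#' pseudo-inverse this removes the small tail of negative tensions that
#' noise can otherwise produce, at the cost of a residual that can only be
#' larger or equal.
#'
#' @inheritParams solve_inverse
#' @return An `mi_fit` (zero modes from the unconstrained system).
#' @export
solve_inverse_nonneg <- function(system, rel_tol = 1e-8) {
  A <- system$matrix
  nn <- system$column_map$kind %in% c("tension", "cortical")
  if (!any(nn)) stop_epiforce("no tension columns to constrain", "epiforce_invalid")
  A_n <- A[, nn, drop = FALSE]
  A_f <- A[, !nn, drop = FALSE]
  b <- system$rhs
  if (ncol(A_f) > 0) {
    pf <- pseudo_inverse(A_f, rel_tol)
    proj <- function(x) x - A_f %*% (pf %*% x)   # project onto complement of span(A_f)
    C <- apply(A_n, 2, proj)
    d <- drop(proj(b))
  } else {
    C <- A_n; d <- b
  }
  fit_n <- pracma::lsqnonneg(C, d)
  x_n <- fit_n$x
  x_f <- if (ncol(A_f) > 0) drop(pf %*% (b - A_n %*% x_n)) else double(0)
  q <- double(ncol(A))
  q[nn] <- x_n; q[!nn] <- x_f
  mean_T <- mean(x_n)
  if (mean_T <= 0) stop_epiforce("nonnegative solve produced zero mean tension (infeasible scale)", "epiforce_invalid")
  sv <- svd(A)
  keep <- sv$d > rel_tol * sv$d[[1]]
  residual <- sqrt(sum((A %*% q - b)^2))
  new_mi_fit(system, q, sv$v[, !keep, drop = FALSE], rep(0, sum(!keep)), residual, sv$d)
}

pseudo_inverse <- function(A, rel_tol = 1e-8) {
  sv <- svd(A)
  keep <- sv$d > rel_tol * max(sv$d, 0)
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Numerical null-space dimension of the balance system
#'
#' Counts singular values below `rel_tol` times the largest. By default the
#' scale row is excluded, so the count refers to the homogeneous
#' force-balance system and matches the theoretical free-constant counting
#' of [count_expected_zero_modes()] (the scale row removes exactly one of
#' these freedoms when included).
#'
#' @param system A [balance_system()].
#' @param rel_tol Relative singular-value cutoff.
#' @param include_scale_row Keep the scale row (default `FALSE`).
#' @return Integer null-space dimension.
#' @export
null_space_dimension <- function(system, rel_tol = 1e-8, include_scale_row = FALSE) {
  A <- system$matrix
  if (!include_scale_row) A <- A[-nrow(A), , drop = FALSE]
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d < rel_tol * d[[1]]) + max(0L, ncol(A) - length(d))
}

#' Infer tensions and pressures from geometry
#'
#' One-call interface to the mechanical inverse: assembles the balance
#' system for the requested parameterization and solves it.
#'
#' @inheritParams balance_system
#' @param nonnegative Constrain tensions to be nonnegative (default FALSE).
#' @param rel_tol Relative singular-value cutoff.
#' @return An `mi_fit`; see [solve_inverse()].
#' @examples
#' sim <- generate_voronoi_tissue(simulation_config(n_cells = 36, seed = 1))
#' fit <- infer_forces(sim$array, "constant_pressure")
#' recovery_scatter(sim$state, fit$state)$r
#' @export
infer_forces <- function(array, parameterization = c("full", "constant_pressure", "cortical"),
                         nonnegative = FALSE, rel_tol = 1e-8) {
  sys <- balance_system(array, parameterization)
  if (nonnegative) solve_inverse_nonneg(sys, rel_tol) else solve_inverse(sys, rel_tol)
}

#' @rdname tidy-mi_fit
#' @method tidy mi_fit
#' @export
tidy.mi_fit <- function(x, ...) {
  tibble::tibble(term = paste(x$column_map$kind, x$column_map$id, sep = "_"),
                 kind = x$column_map$kind, id = x$column_map$id,
                 estimate = x$column_map$estimate)
}

#' Tidy and summarize a mechanical-inverse fit
#'
#' `tidy()` returns one row per inferred parameter; `glance()` a one-row
#' summary (residual norm, null-space dimension, singular-value extremes,
#' mean inferred tension).
#'
#' @param x An `mi_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-mi_fit
#' @method glance mi_fit
#' @export
glance.mi_fit <- function(x, ...) {
  tibble::tibble(
    parameterization = x$parameterization,
    n_parameters = length(x$particular),
    n_zero_modes = ncol(x$zero_modes),
    residual_norm = x$residual_norm,
    sigma_max = max(x$singular_values),
    sigma_min = min(x$singular_values),
    mean_tension = mean(x$state$tensions$tension)
  )
}
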