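#' Error-response operator of the mechanical inverse
#'
#' First-order propagation of vertex-position error into inferred
#' parameters. Writing the balance system as `A(r) q = b` with `b`
#' independent of the geometry, a perturbation `dr` of the vertex positions
#' changes the solution by `dq = -A^+ (dA/dr . dr) q`: the matrix of this
#' linear map (parameters x vertex coordinates) is the error-response
#' operator. Its singular values, after normalizing displacements by the
#' mean edge length (tensions are already of mean 1), are dimensionless
#' amplification factors: modes with singular value above one amplify
#' positional noise into the inferred parameters.
#'
#' The derivative of `A` with respect to vertex coordinates is assembled
#' analytically (unit-chord derivatives `(I - u u^T)/l` for the tension
#' columns, the constant rotation for the pressure columns; the scale row
#' does not depend on the geometry).
#'
#' @param array A validated [cell_array()].
#' @param parameterization Parameterization of the balance system.
#' @param rel_tol Singular-value cutoff for the pseudo-inverse.
#' @param include_scale_row Keep the scale row in the operator (default
#'   `TRUE`).
#' @return List with `operator` (the matrix `M`, scaled by the mean edge
#'   length), `singular_values` (descending), `fraction_above_one`, `fit`
#'   (the underlying [solve_inverse()] fit) and `parameterization`.
#' @export
error_response <- function(array, parameterization = c("full", "constant_pressure", "cortical"),
                           rel_tol = 1e-8, include_scale_row = TRUE) {
  parameterization <- match.arg(parameterization)
  sys <- balance_system(array, parameterization)
  fit <- solve_inverse(sys, rel_tol)
  q <- fit$particular

  A <- sys$matrix
  if (!include_scale_row) {
    A <- A[-nrow(A), , drop = FALSE]
  }
  n_rows <- nrow(A)

  et <- edge_table(array)
  nV <- nrow(array$vertices)
  vcol <- stats::setNames(seq_len(nV), array$vertices$id)   # vertex id -> column pair
  balanced <- sys$row_map$vertex[!is.na(sys$row_map$vertex)]
  vrow <- stats::setNames(seq_len(length(unique(balanced))), unique(balanced))

  cm <- sys$column_map
  col_lookup <- stats::setNames(cm$column, paste(cm$kind, cm$id))

  # G[, (k, mu)] = (dA/dr_k_mu) q over the balance rows.
  G <- matrix(0, n_rows, 2L * nV)
  add_block <- function(rows, cols, block) {
    G[rows, cols] <<- G[rows, cols] + block
  }
  I2 <- diag(2)
  E2 <- matrix(c(0, -1, 1, 0), 2, 2)   # Jacobian of chi -> (chi_y, -chi_x)

  for (k in seq_len(nrow(et))) {
    u <- c(et$dx[[k]], et$dy[[k]]) / et$length[[k]]
    B <- (I2 - tcrossprod(u)) / et$length[[k]]
    ci <- vcol[as.character(et$v1[[k]])]; cj <- vcol[as.character(et$v2[[k]])]
    cols_i <- c(2 * ci - 1, 2 * ci); cols_j <- c(2 * cj - 1, 2 * cj)
    ri <- vrow[as.character(et$v1[[k]])]; rj <- vrow[as.character(et$v2[[k]])]
    rows_i <- if (!is.na(ri)) c(2 * ri - 1, 2 * ri)
    rows_j <- if (!is.na(rj)) c(2 * rj - 1, 2 * rj)

    # Tension-like coefficient at this edge.
    q_T <- if (sys$parameterization == "cortical") {
      ql <- col_lookup[paste("cortical", et$cell_left[[k]])]
      qr <- col_lookup[paste("cortical", et$cell_right[[k]])]
      sum(q[stats::na.omit(c(ql, qr))])
    } else {
      ct <- col_lookup[paste("tension", et$edge[[k]])]
      if (is.na(ct)) 0 else q[[ct]]
    }
    if (q_T != 0) {
      if (!is.null(rows_i)) { add_block(rows_i, cols_j, q_T * B); add_block(rows_i, cols_i, -q_T * B) }
      if (!is.null(rows_j)) { add_block(rows_j, cols_j, -q_T * B); add_block(rows_j, cols_i, q_T * B) }
    }

    if (sys$parameterization != "constant_pressure") {
      pl <- col_lookup[paste("pressure", et$cell_left[[k]])]
      pr <- col_lookup[paste("pressure", et$cell_right[[k]])]
      dP <- (if (is.na(pl)) 0 else q[[pl]]) - (if (is.na(pr)) 0 else q[[pr]])
      if (dP != 0) {
        blk <- (dP / 2) * E2
        for (rows in list(rows_i, rows_j)) {
          if (is.null(rows)) next
          add_block(rows, cols_j, blk); add_block(rows, cols_i, -blk)
        }
      }
    }
  }

  M <- -pseudo_inverse(A, rel_tol) %*% G
  M <- M * mean(et$length)            # displacements in units of mean edge length
  d <- svd(M, nu = 0, nv = 0)$d
  list(operator = M, singular_values = sort(d, decreasing = TRUE),
       fraction_above_one = mean(d > 1), fit = fit,
       parameterization = parameterization)
}

#' Compare error sensitivity before and after parameter reduction
#'
#' Computes the error-response spectra of the full inverse (tensions and
#' pressures) and of the reduced, constant-pressure inverse on the same
#' array. Parameter reduction makes the system overdetermined and
#' suppresses the large-amplification modes: the reduced problem's largest
#' singular value and its fraction of singular values above one are both
#' smaller.
#'
#' @inheritParams error_response
#' @param reduced Parameterization of the reduced problem (default
#'   `"constant_pressure"`).
#' @return Object of class `sensitivity_report`: list with
#'   `singular_values_full`, `singular_values_reduced`,
#'   `fraction_above_one_full`, `fraction_above_one_reduced`.
#' @export
sensitivity_report <- function(array, reduced = "constant_pressure",
                               rel_tol = 1e-8, include_scale_row = TRUE) {
  full <- error_response(array, "full", rel_tol, include_scale_row)
  red <- error_response(array, reduced, rel_tol, include_scale_row)
  structure(
    list(singular_values_full = full$singular_values,
         singular_values_reduced = red$singular_values,
         fraction_above_one_full = full$fraction_above_one,
         fraction_above_one_reduced = red$fraction_above_one,
         reduced = reduced),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<sensitivity_report>\n",
    "  full:    sigma_max = %.3g, fraction > 1 = %.3f (%d values)\n",
    "  reduced: sigma_max = %.3g, fraction > 1 = %.3f (%d values)\n"),
    max(x$singular_values_full), x$fraction_above_one_full, length(x$singular_values_full),
    max(x$singular_values_reduced), x$fraction_above_one_reduced, length(x$singular_values_reduced)))
  invisible(x)
}

#' @rdname tidy-mi_fit
#' @method tidy sensitivity_report
#' @export
tidy.sensitivity_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(problem = "full", singular_value = x$singular_values_full),
    tibble::tibble(problem = "reduced", singular_value = x$singular_values_reduced)
  )
}

#' Empirical noise-robustness curve of the partial inverse
#'
#' The in-silico benchmark: for each noise level, generate an equilibrium
#' tissue, displace every vertex by isotropic Gaussian noise of the given
#' r.m.s. magnitude (as a fraction of the mean edge length), run the
#' constant-pressure inverse and record the Pearson correlation between
#' true and inferred tensions; replicated over independent seeds.
#'
#' @param config A [simulation_config()]; its `seed` seeds the whole
#'   experiment and per-replicate seeds are derived from it.
#' @param noise_levels Numeric vector of r.m.s. noise fractions.
#' @param n_replicates Replicates (fresh tissue + noise) per level.
#' @return Tibble with one row per (level, replicate): `noise_level`,
#'   `replicate`, `r`, `n_edges`; summarize with e.g.
#'   `dplyr::summarise(mean_r = mean(r), sd_r = sd(r))`.
#' @export
noise_curve <- function(config = simulation_config(), noise_levels = c(0, 0.05, 0.10),
                        n_replicates = 10L) {
  stopifnot(all(noise_levels >= 0))
  grid <- tidyr::expand_grid(replicate = seq_len(n_replicates), noise_level = noise_levels)
  tissues <- lapply(seq_len(n_replicates), function(rep) {
    generate_voronoi_tissue(config, seed = derive_seed(config$seed, rep))
  })
  purrr::pmap_dfr(grid, function(replicate, noise_level) {
    sim <- tissues[[replicate]]
    arr <- corrupt_vertices(sim$array, noise_level,
                            seed = derive_seed(config$seed, 1000L * replicate + round(1e4 * noise_level)))
    fit <- infer_forces(arr, "constant_pressure")
    sc <- recovery_scatter(sim$state, fit$state)
    tibble::tibble(noise_level = noise_level, replicate = replicate,
                   r = sc$r, n_edges = nrow(sc$pairs))
  })
}
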