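#' Intercellular traction forces
#'
#' The tension of an interface is carried by the two actomyosin cortices on
#' either side; because cortical tension is continuous around each cell
#' corner, the two cortical shares can be expressed in terms of the
#' interfacial tensions meeting at the interface's endpoints. The net shear
#' (traction) force transmitted across the interface between cells `a`
#' (left) and `b` (right), with third cells `c` at the first endpoint and
#' `d` at the second, is
#' `tau_ab = (T_ad + T_bc - T_ac - T_bd) / 2`.
#' It is antisymmetric under exchanging the roles of `a` and `b`, vanishes
#' when all tensions are equal, and scales linearly with the tensions. This
#' shear is the load borne by the adhesion molecules bridging the two
#' cortices.
#'
#' Records are produced for interior edges (both cells real) whose
#' endpoints are three-fold junctions; edges ending at rosettes get `NA`
#' traction.
#'
#' @param array A [cell_array()].
#' @param state A [mechanical_state()] (inferred or true).
#' @return Tibble with columns `edge`, `cell_left`, `cell_right`,
#'   `third_v1`, `third_v2`, `traction`.
#' @export
edge_tractions <- function(array, state) {
  Tv <- state$tensions$tension[match(array$edges$id, state$tensions$edge)]
  if (anyNA(Tv)) stop_epiforce("state is missing a tension for some edge", "epiforce_state")
  e <- array$edges
  interior <- e$cell_left >= 0 & e$cell_right >= 0

  # tension lookup by unordered cell pair at a given vertex
  find_T <- function(v, x, y) {
    hit <- which((e$v1 == v | e$v2 == v) &
                   ((e$cell_left == x & e$cell_right == y) | (e$cell_left == y & e$cell_right == x)))
    if (length(hit) != 1) NA_real_ else Tv[[hit]]
  }
  third_cell <- function(v, a, b, self) {
    inc <- which((e$v1 == v | e$v2 == v) & e$id != self)
    cand <- setdiff(unique(c(e$cell_left[inc], e$cell_right[inc])), c(a, b))
    if (length(inc) != 2 || length(cand) != 1) NA_integer_ else cand
  }

  rows <- lapply(which(interior), function(k) {
    a <- e$cell_left[[k]]; b <- e$cell_right[[k]]
    cc <- third_cell(e$v1[[k]], a, b, e$id[[k]])
    dd <- third_cell(e$v2[[k]], a, b, e$id[[k]])
    tau <- if (is.na(cc) || is.na(dd)) NA_real_ else {
      (find_T(e$v2[[k]], a, dd) + find_T(e$v1[[k]], b, cc) -
         find_T(e$v1[[k]], a, cc) - find_T(e$v2[[k]], b, dd)) / 2
    }
    tibble::tibble(edge = e$id[[k]], cell_left = a, cell_right = b,
                   third_v1 = cc, third_v2 = dd, traction = tau)
  })
  dplyr::bind_rows(rows)
}

#' Young-Laplace cross-check
#'
#' The inverse uses only vertex positions, never the interface curvatures,
#' so measured curvatures provide an independent validation: the Laplace
#' law predicts that the pressure jump across an interface equals its
#' tension times its curvature, `P_left - P_right = T * kappa`, with
#' curvature signed positive when the interface bows away from the left
#' cell (towards the right cell). The check regresses the inferred pressure
#' differential on `T * kappa` across edges: perfect agreement gives
#' Pearson `r = 1` and slope 1.
#'
#' @param array A [cell_array()] with `curvature` set on at least one edge.
#' @param state A [mechanical_state()].
#' @return Object of class `laplace_check`: list with `pairs` (tibble:
#'   `edge`, `dp`, `t_kappa`), `r` (Pearson correlation; `NA` with a
#'   message in `degenerate` when either column has zero variance) and
#'   `slope` (through-origin regression coefficient).
#' @export
laplace_check <- function(array, state) {
  st <- state_on_array(array, state)
  has <- !is.na(array$edges$curvature)
  if (!any(has)) {
    stop_epiforce("no edge carries a curvature value; supply measured curvatures to run the Laplace check",
                  "epiforce_invalid")
  }
  dp <- (st$P_left - st$P_right)[has]
  tk <- (st$T * array$edges$curvature)[has]
  degenerate <- (stats::sd(dp) == 0 || stats::sd(tk) == 0)
  r <- if (degenerate) NA_real_ else stats::cor(dp, tk)
  slope <- if (sum(tk^2) == 0) NA_real_ else sum(dp * tk) / sum(tk^2)
  structure(
    list(pairs = tibble::tibble(edge = array$edges$id[has], dp = dp, t_kappa = tk),
         r = r, slope = slope, degenerate = degenerate),
    class = "laplace_check"
  )
}

#' @export
print.laplace_check <- function(x, ...) {
  if (x$degenerate) {
    cat("<laplace_check> degenerate (zero variance); correlation undefined\n")
  } else {
    cat(sprintf("<laplace_check> %d edges: r = %.4f, slope = %.4f\n",
                nrow(x$pairs), x$r, x$slope))
  }
  invisible(x)
}

#' Tension anisotropy relative to a tissue axis
#'
#' Splits the interfaces into two groups by the acute angle between their
#' chord and a caller-supplied tissue axis (for example the
#' anterior-posterior axis of an embryo): `"along"` for angles below the
#' threshold, `"across"` for angles at or above it (a tie at exactly the
#' threshold goes to `"across"`). Reports group means and counts of the
#' tension, their ratio, the empirical CDFs, and a rank-based two-sample
#' location test (Wilcoxon).
#'
#' @param array A [cell_array()].
#' @param state A [mechanical_state()].
#' @param axis_angle Axis direction in radians (0 = x axis).
#' @param threshold_angle Grouping threshold in radians (default `pi/4`,
#'   which splits the quadrant symmetrically).
#' @return Object of class `anisotropy_report`: list with `edges` (tibble:
#'   `edge`, `angle_to_axis`, `group`, `tension`), `group_stats`,
#'   `mean_ratio` (along / across), `test` (the `htest`), `ecdf_along`,
#'   `ecdf_across`.
#' @export
anisotropy_report <- function(array, state, axis_angle = 0, threshold_angle = pi / 4) {
  st <- state_on_array(array, state)
  et <- edge_table(array)
  delta <- abs(et$angle - axis_angle) %% pi
  delta <- pmin(delta, pi - delta)             # acute angle in [0, pi/2]
  group <- ifelse(delta < threshold_angle, "along", "across")
  if (length(unique(group)) < 2) {
    stop_epiforce("one anisotropy group is empty; adjust the threshold angle", "epiforce_invalid")
  }
  edges <- tibble::tibble(edge = et$edge, angle_to_axis = delta, group = group,
                          tension = st$T)
  gs <- dplyr::summarise(dplyr::group_by(edges, .data$group),
                         n = dplyr::n(), mean_tension = mean(.data$tension),
                         sd_tension = stats::sd(.data$tension), .groups = "drop")
  t_along <- edges$tension[edges$group == "along"]
  t_across <- edges$tension[edges$group == "across"]
  structure(
    list(edges = edges, group_stats = gs,
         axis_angle = axis_angle, threshold_angle = threshold_angle,
         mean_ratio = mean(t_along) / mean(t_across),
         test = stats::wilcox.test(t_along, t_across, exact = FALSE),
         ecdf_along = stats::ecdf(t_along), ecdf_across = stats::ecdf(t_across)),
    class = "anisotropy_report"
  )
}

#' @export
print.anisotropy_report <- function(x, ...) {
  cat(sprintf("<anisotropy_report> axis %.3f rad, threshold %.3f rad\n",
              x$axis_angle, x$threshold_angle))
  print(x$group_stats)
  cat(sprintf("  along/across mean ratio: %.4f (Wilcoxon p = %.3g)\n",
              x$mean_ratio, x$test$p.value))
  invisible(x)
}

#' Recovery scatter between two mechanical states
#'
#' Pairs the tensions of a reference (true) state with those of an inferred
#' state on the same interfaces, rescales both to mean 1, and reports the
#' Pearson correlation together with the paired table - the numerical
#' summary of the benchmark scatter plot.
#'
#' @param true_state,inferred_state [mechanical_state()] objects over the
#'   same edge set.
#' @return List with `r` and `pairs` (tibble: `edge`, `true`, `inferred`,
#'   both rescaled to mean 1).
#' @export
recovery_scatter <- function(true_state, inferred_state) {
  te <- true_state$tensions
  ie <- inferred_state$tensions
  if (!setequal(te$edge, ie$edge)) {
    stop_epiforce(sprintf("edge sets differ (%d true vs %d inferred tensions)",
                          nrow(te), nrow(ie)), "epiforce_invalid")
  }
  m <- match(te$edge, ie$edge)
  pairs <- tibble::tibble(
    edge = te$edge,
    true = te$tension / mean(te$tension),
    inferred = ie$tension[m] / mean(ie$tension)
  )
  list(r = stats::cor(pairs$true, pairs$inferred), pairs = pairs)
}
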