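#' Mechanical state of a cell array
#'
#' Holds the per-interface tensions and per-cell (two-dimensional) pressures
#' that, together with the geometry, determine every junctional force. Only
#' pressure differences exert force, so pressures are defined up to an
#' additive constant; the exterior pressure is conventionally 0.
#'
#' @param tensions Tibble with columns `edge`, `tension` (force units; any
#'   sign unless positivity is imposed at inference time).
#' @param pressures Tibble with columns `cell`, `pressure` (force/length:
#'   a 2D pressure conjugate to cell area).
#' @param exterior_pressure Pressure of the exterior region (default 0).
#' @return Object of class `mechanical_state`.
#' @export
mechanical_state <- function(tensions, pressures, exterior_pressure = 0) {
  tensions <- tibble::as_tibble(tensions)
  pressures <- tibble::as_tibble(pressures)
  stopifnot(all(c("edge", "tension") %in% names(tensions)),
            all(c("cell", "pressure") %in% names(pressures)))
  structure(
    list(tensions = tensions[c("edge", "tension")],
         pressures = pressures[c("cell", "pressure")],
         exterior_pressure = as.double(exterior_pressure)),
    class = "mechanical_state"
  )
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat(sprintf("<mechanical_state> %d tensions (mean %.4g), %d pressures (mean %.4g)\n",
              nrow(x$tensions), mean(x$tensions$tension),
              nrow(x$pressures), mean(x$pressures$pressure)))
  invisible(x)
}

#' Uniform mechanical state
#'
#' Convenience constructor: every edge gets `tension`, every cell `pressure`.
#'
#' @param array A [cell_array()].
#' @param tension,pressure Scalar values (defaults 1 and 0).
#' @return A [mechanical_state()].
#' @export
uniform_state <- function(array, tension = 1, pressure = 0) {
  mechanical_state(
    tibble::tibble(edge = array$edges$id, tension = tension),
    tibble::tibble(cell = array$cells$id, pressure = pressure)
  )
}

# Match a state's tensions/pressures onto the array's edge/cell order.
# Returns list(T = per-edge tension, P_left, P_right = per-edge pressures).
state_on_array <- function(array, state) {
  Tv <- state$tensions$tension[match(array$edges$id, state$tensions$edge)]
  if (anyNA(Tv)) stop_epiforce("state is missing a tension for some edge", "epiforce_state")
  press <- function(cid) {
    p <- ifelse(cid < 0, state$exterior_pressure,
                state$pressures$pressure[match(cid, state$pressures$cell)])
    if (anyNA(p)) stop_epiforce("state is missing a pressure for some cell", "epiforce_state")
    p
  }
  list(T = Tv, P_left = press(array$edges$cell_left), P_right = press(array$edges$cell_right))
}

#' Force exerted by one interface on one of its vertices
#'
#' The interface pulls the vertex toward the opposite endpoint with its
#' tension, and the pressure differential across the interface pushes
#' perpendicular to the chord: with chord vector `chi` directed away from
#' the vertex and `a` the cell to the left of that direction,
#' `F = T * chi/|chi| + (P_a - P_b)/2 * eps %*% chi`, where `eps` is the
#' antisymmetric tensor (`eps_xy = 1`). Each endpoint carries half of the
#' total Young-Laplace pressure load `(P_a - P_b) * |chi|`.
#'
#' @param array A [cell_array()].
#' @param state A [mechanical_state()].
#' @param edge Edge id.
#' @param at_vertex Vertex id; must be an endpoint of `edge`.
#' @return Numeric length-2 force vector.
#' @export
interface_force <- function(array, state, edge, at_vertex) {
  k <- match(edge, array$edges$id)
  if (is.na(k)) stop_epiforce(sprintf("unknown edge id %s", format(edge)), "epiforce_dangling_id")
  e <- array$edges[k, ]
  if (!at_vertex %in% c(e$v1, e$v2)) {
    stop_epiforce(sprintf("vertex %d is not an endpoint of edge %d", at_vertex, edge), "epiforce_invalid")
  }
  chi <- edge_vector(array, edge)            # v1 -> v2, cell_left on the left
  len <- sqrt(sum(chi^2))
  if (len == 0) stop_epiforce(sprintf("degenerate edge %d", edge), "epiforce_degenerate")
  st <- state_on_array(array, state)
  Tv <- st$T[[k]]; dP <- st$P_left[[k]] - st$P_right[[k]]
  away <- if (at_vertex == e$v1) chi else -chi
  # The pressure term is orientation-covariant: flipping the chord also flips
  # which cell is on the left, so it is the same vector at both endpoints.
  Tv * away / len + (dP / 2) * c(chi[[2]], -chi[[1]])
}

#' Mechanical energy of a state on an array
#'
#' `H = - sum_cells P * A + sum_edges T * l`: pressures are conjugate to
#' cell areas and tensions to interface lengths. Junctional forces are
#' exactly minus the gradient of `H` in the vertex positions. Adding a
#' constant to every pressure changes `H` by a constant (minus that constant
#' times the total tiled area) without changing any force.
#'
#' @inheritParams interface_force
#' @return Scalar energy.
#' @export
tissue_energy <- function(array, state) {
  st <- state_on_array(array, state)
  areas <- cell_areas(array, check = FALSE)
  p <- state$pressures$pressure[match(areas$cell, state$pressures$cell)]
  lens <- edge_table(array)$length
  -sum(p * areas$area) + sum(st$T * lens)
}

#' Net force on vertices
#'
#' Sums [interface_force()] over all interfaces incident to each vertex.
#' At mechanical equilibrium every interior net force vanishes; the residual
#' magnitude relative to the mean tension is the package's convergence and
#' equilibrium measure.
#'
#' @inheritParams interface_force
#' @return Tibble with columns `vertex`, `fx`, `fy`, `norm`.
#' @export
net_vertex_forces <- function(array, state) {
  st <- state_on_array(array, state)
  pos <- vertex_matrix(array)
  i <- match(array$edges$v1, array$vertices$id)
  j <- match(array$edges$v2, array$vertices$id)
  chi <- displacements(pos, i, j, array$box)
  len <- row_norms(chi)
  if (any(len == 0)) stop_epiforce("degenerate edge during force evaluation", "epiforce_degenerate")
  u <- chi / len
  press <- (st$P_left - st$P_right) / 2 * rotate_cw(chi)   # same at both endpoints
  f_i <- st$T * u + press
  f_j <- -st$T * u + press
  acc <- rowsum(rbind(f_i, f_j), group = c(i, j))
  out <- matrix(0, nrow(pos), 2)
  out[as.integer(rownames(acc)), ] <- acc
  tibble::tibble(
    vertex = array$vertices$id,
    fx = out[, 1], fy = out[, 2],
    norm = sqrt(out[, 1]^2 + out[, 2]^2)
  )
}

#' @rdname net_vertex_forces
#' @param vertex A single vertex id.
#' @return `net_vertex_force()`: numeric length-2 vector.
#' @export
net_vertex_force <- function(array, state, vertex) {
  nf <- net_vertex_forces(array, state)
  k <- match(vertex, nf$vertex)
  if (is.na(k)) stop_epiforce(sprintf("unknown vertex id %s", format(vertex)), "epiforce_dangling_id")
  c(nf$fx[[k]], nf$fy[[k]])
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-tissue generator. The defaults are the
#' package's in-silico benchmark conditions: a toroidal random tissue in
#' exact mechanical equilibrium under heterogeneous interface tensions of
#' mean 1.
#'
#' @param n_cells Number of cells (at least 16).
#' @param tension_distribution Either `NULL` (default) or a length-2
#'   `(low, high)` of a uniform law. With `NULL` the generator uses the
#'   reciprocal tension set `T = |s_a - s_b|` (distance between the two
#'   seed points generating the interface, normalized to mean 1), which is
#'   the tension assignment for which the Voronoi geometry is an exact
#'   equilibrium of the tension-only energy. With explicit bounds, tensions
#'   are drawn i.i.d. uniform and relaxation with topological event handling
#'   is attempted; a tension quench drawn independently of the topology is
#'   generically incompatible with a straight-edge equilibrium, so this path
#'   usually aborts after extensive rearrangement and is retained for
#'   experimentation only (see the methods vignette).
#' @param lloyd_iterations Lloyd (centroidal Voronoi) regularization steps
#'   applied to the seed points before tessellating (default 0: the plain
#'   Voronoi diagram of the uniform random seeds). With 0 the realized
#'   tension coefficient of variation is about 0.48; each Lloyd step makes
#'   the tiling more regular and narrows the tension spread.
#' @param seed Integer RNG seed.
#' @param convergence_tol Relaxation stops when the maximum net vertex force
#'   falls below `convergence_tol` times the mean tension.
#' @param max_iterations Iteration budget for the relaxation.
#' @param box_aspect Lx/Ly of the periodic box (area fixed at `n_cells`,
#'   i.e. mean cell area 1).
#' @param stretch Anisotropy factor `lambda`: seeds and box are mapped by
#'   `diag(lambda, 1/lambda)` before tessellating, which under the
#'   reciprocal tension set raises the tension of interfaces oriented along
#'   the y axis relative to those along x (default 1: isotropic).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 400L, tension_distribution = NULL,
                              lloyd_iterations = 0L, seed = 1L,
                              convergence_tol = 1e-7,
                              max_iterations = 500000L, box_aspect = 1,
                              stretch = 1) {
  if (!is.null(tension_distribution)) {
    stopifnot(tension_distribution[[1]] > 0,
              tension_distribution[[2]] >= tension_distribution[[1]])
  }
  stopifnot(convergence_tol > 0, n_cells >= 16)
  structure(list(
    n_cells = as.integer(n_cells),
    tension_distribution = if (!is.null(tension_distribution)) as.double(tension_distribution),
    lloyd_iterations = as.integer(lloyd_iterations),
    seed = as.integer(seed),
    convergence_tol = convergence_tol,
    max_iterations = as.integer(max_iterations),
    box_aspect = box_aspect,
    stretch = as.double(stretch)
  ), class = "simulation_config")
}

#' Generate a relaxed synthetic tissue
#'
#' Draws `n_cells` uniform random seed points in a periodic box of area
#' `n_cells` (optionally regularized by a few Lloyd steps), builds their
#' periodic Voronoi tessellation, assigns interface tensions, and returns
#' the tissue in mechanical equilibrium under the tension-only energy
#' `sum T * l` (toroidal wrap prevents collapse to the zero-tension ground
#' state). Since the energy has no area term the equilibrium has uniform
#' cell pressure, recorded as 0 for every cell.
#'
#' By default tensions are the reciprocal set `T_ab = |s_a - s_b|`
#' (normalized to mean 1), for which the Voronoi geometry is already an
#' exact equilibrium: the relaxation then terminates immediately with a
#' residual at rounding level. If `tension_distribution` is given, i.i.d.
#' uniform tensions are drawn instead and relaxation with topological event
#' handling (rosette fusion, cell extinction) is attempted; such quenches
#' are generically incompatible with a straight-edge equilibrium and the
#' attempt usually aborts (see the methods vignette).
#'
#' @param config A [simulation_config()].
#' @param ... Used to override `config` fields, e.g. `n_cells = 64`.
#' @return List with elements `array` (equilibrated toroidal
#'   [cell_array()]), `state` (the true [mechanical_state()]), and
#'   `relaxation` (diagnostics from [relax_tissue()]).
#' @export
generate_voronoi_tissue <- function(config = simulation_config(), ...) {
  dots <- list(...)
  if (length(dots) > 0) config <- do.call(simulation_config, modifyList(unclass(config), dots))
  n <- config$n_cells
  Ly <- sqrt(n / config$box_aspect)
  box <- c(config$box_aspect * Ly, Ly)
  res <- withr::with_seed(config$seed, {
    seeds <- cbind(stats::runif(n, 0, box[[1]]), stats::runif(n, 0, box[[2]]))
    seeds <- lloyd_steps(seeds, box, config$lloyd_iterations)
    if (config$stretch != 1) {
      seeds[, 1] <- seeds[, 1] * config$stretch
      seeds[, 2] <- seeds[, 2] / config$stretch
      box <- c(box[[1]] * config$stretch, box[[2]] / config$stretch)
    }
    arr <- periodic_voronoi(seeds, box)
    tensions <- if (is.null(config$tension_distribution)) {
      # Reciprocal tension = distance between the two generating seeds,
      # taking the periodic copies nearest the interface midpoint (for
      # small boxes the raw minimum-image seed separation can pick the
      # wrong copy).
      pos <- vertex_matrix(arr)
      i <- match(arr$edges$v1, arr$vertices$id)
      j <- match(arr$edges$v2, arr$vertices$id)
      mid <- pos[i, , drop = FALSE] + displacements(pos, i, j, box) / 2
      da <- seeds[arr$edges$cell_left, , drop = FALSE] - mid
      db <- seeds[arr$edges$cell_right, , drop = FALSE] - mid
      da[, 1] <- wrap_min_image(da[, 1], box[[1]]); da[, 2] <- wrap_min_image(da[, 2], box[[2]])
      db[, 1] <- wrap_min_image(db[, 1], box[[1]]); db[, 2] <- wrap_min_image(db[, 2], box[[2]])
      len <- row_norms(da - db)
      len / mean(len)
    } else {
      stats::runif(nrow(arr$edges), config$tension_distribution[[1]],
                   config$tension_distribution[[2]])
    }
    list(arr = arr, tensions = tensions)
  })
  state <- mechanical_state(
    tibble::tibble(edge = res$arr$edges$id, tension = res$tensions),
    tibble::tibble(cell = res$arr$cells$id, pressure = 0)
  )
  rel <- relax_tissue(res$arr, state, tol = config$convergence_tol,
                      max_iterations = config$max_iterations)
  list(array = rel$array, state = rel$state,
       relaxation = rel[c("residual", "iterations", "energy", "n_merge", "n_t2")])
}

#' Relax a tissue to mechanical equilibrium
#'
#' Minimizes the tension-only energy `sum_edges T * l` over vertex positions
#' by capped Barzilai-Borwein gradient descent with the analytic gradient,
#' until the maximum net vertex force is below `tol` times the mean tension.
#' The step is capped so that no vertex moves further than a fraction of the
#' shortest live edge per iteration, which prevents vertices from tunnelling
#' across interfaces and tangling the mesh. Pressure terms are not part of
#' the descent (the benchmark energy has no area term); the relaxed geometry
#' therefore carries uniform pressure.
#'
#' With quenched tension disorder a few junctions are generically frustrated
#' (for instance when one tension exceeds the sum of the other two at a
#' junction, no three-fold equilibrium exists there): descent drives the
#' corresponding interface to zero length and then stalls with a localized
#' residual. When progress stalls, any interface pinned below
#' `collapse_frac` times the mean edge length is resolved by a topological
#' move: its endpoints are fused into a rosette vertex (the interface and
#' its tension are removed - the counting move of the rosette
#' generalization), or, if it belongs to a three-sided cell, the cell is
#' removed entirely (T2 extinction). Moves are performed only at stalls,
#' never on transient dips, and are irreversible, so the event sequence
#' terminates; the result is an equilibrium of the final topology. Because
#' moves remove edges (and possibly cells), the paired state is updated
#' alongside and both are returned.
#'
#' @param array A toroidal [cell_array()]. (Open/closed arrays would slide
#'   into the zero-tension ground state without pinned boundaries and are
#'   rejected.)
#' @param state A [mechanical_state()] supplying the quenched tensions.
#' @param tol Convergence tolerance on `max |net force| / mean tension`.
#' @param max_iterations Total descent-step budget.
#' @param collapse_frac Edge length (as a fraction of the current mean edge
#'   length) below which a stalled interface is considered collapsed.
#' @return List with `array` (relaxed), `state` (tensions/pressures of the
#'   surviving interfaces and cells), `residual` (final force measure),
#'   `iterations`, `energy`, `n_merge` and `n_t2` (numbers of topological
#'   moves) and `residual_history`.
#' @export
relax_tissue <- function(array, state, tol = 1e-7, max_iterations = 500000L,
                         collapse_frac = 0.02) {
  if (array$topology != "toroidal") {
    stop_epiforce("relaxation requires toroidal topology (open arrays would collapse)", "epiforce_invalid")
  }
  arr <- array
  box <- arr$box
  mean_T <- mean(abs(state$tensions$tension))
  total_steps <- 0L
  n_merge <- 0L; n_t2 <- 0L
  soft_stalls <- 0L
  patience <- 3000L
  resid_hist <- double(0)

  repeat {
    # Provably doomed interfaces first: a junction where one tension exceeds
    # the sum of the others can never balance, so its strong interface must
    # collapse. Resolving these before (and between) descent phases avoids
    # waiting for the dynamics to pin them at zero length.
    fr <- frustrated_edge(arr, state)
    if (!is.na(fr)) {
      surgery <- resolve_collapse(arr, state, fr)
      arr <- surgery$array; state <- surgery$state
      n_merge <- n_merge + surgery$merged; n_t2 <- n_t2 + surgery$t2
      next
    }

    st <- state_on_array(arr, state)
    Tv <- st$T
    pos <- vertex_matrix(arr)
    nV <- nrow(pos)
    i <- match(arr$edges$v1, arr$vertices$id)
    j <- match(arr$edges$v2, arr$vertices$id)
    grp <- c(i, j)
    ll <- mean(row_norms(displacements(pos, i, j, box)))
    thr <- collapse_frac * ll
    geom <- function(p) {
      d <- displacements(p, i, j, box)
      list(d = d, len = pmax(row_norms(d), 1e-300))
    }
    force <- function(g) {
      u <- g$d / g$len
      acc <- rowsum(rbind(Tv * u, -Tv * u), group = grp)  # -dE/dr
      out <- matrix(0, nV, 2)
      out[as.integer(rownames(acc)), ] <- acc
      out
    }
    energy <- function(g) sum(Tv * g$len)

    p <- pos
    g <- geom(p)
    f <- force(g)
    alpha <- 0.01 * ll / max(max(row_norms(f)), 1e-300)
    status <- "running"
    e_best <- energy(g)
    last_improve <- total_steps
    check_every <- 100L
    steps_this_round <- 0L

    # Cell loops as vertex row indices, for inversion (tangling) checks.
    loop_rows <- lapply(arr$cells$vertices, function(lp) match(lp, arr$vertices$id))
    any_inverted <- function(p) {
      for (lr in loop_rows) {
        q <- p[lr, , drop = FALSE]
        d <- diff(q)
        d[, 1] <- wrap_min_image(d[, 1], box[[1]]); d[, 2] <- wrap_min_image(d[, 2], box[[2]])
        x <- c(0, cumsum(d[, 1])); y <- c(0, cumsum(d[, 2]))
        xn <- c(x[-1], x[[1]]); yn <- c(y[-1], y[[1]])
        if (sum(x * yn - xn * y) <= 0) return(TRUE)
      }
      FALSE
    }

    # Phase 1: capped Barzilai-Borwein warmup through the rough transient.
    # The cap keeps vertices from tunnelling across interfaces while the
    # geometry is far from equilibrium.
    while (TRUE) {
      resid <- max(row_norms(f)) / mean_T
      if (resid <= tol) { status <- "converged"; break }
      if (total_steps >= max_iterations) { status <- "budget"; break }
      if (steps_this_round >= 3000L && resid < 1) { status <- "handoff"; break }
      if (steps_this_round %% check_every == 0L && steps_this_round > 0L) {
        e_now <- energy(g)
        if (e_now < e_best - 1e-8 * (abs(e_now) + 1)) {
          e_best <- e_now
          last_improve <- total_steps
        } else if (total_steps - last_improve >= patience) {
          status <- "stalled"; break
        }
      }
      steps_this_round <- steps_this_round + 1L
      total_steps <- total_steps + 1L
      live <- g$len[g$len >= thr]
      cap <- min(max(0.3 * if (length(live)) min(live) else thr, 1e-4 * ll), 0.2 * ll)
      stepv <- alpha * f
      mx <- max(row_norms(stepv))
      if (mx > cap) stepv <- stepv * (cap / mx)
      p_new <- p + stepv
      g_new <- geom(p_new)
      f_new <- force(g_new)
      dx <- p_new - p; df <- f_new - f
      denom <- sum(df * df)
      alpha <- if (denom > 0) abs(sum(dx * df)) / denom else alpha
      p <- p_new; g <- g_new; f <- f_new
    }

    # Phase 2: limited-memory quasi-Newton finish, with a revert-on-tangle
    # safeguard (a cell turning inside out means the line search tunnelled a
    # vertex across an interface).
    if (status == "handoff") {
      fn <- function(x) sum(Tv * geom(matrix(x, nV, 2))$len)
      gr <- function(x) -as.vector(force(geom(matrix(x, nV, 2))))
      x <- as.vector(p)
      repeat {
        e_before <- fn(x)
        opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                            control = list(maxit = 2000L, factr = 10,
                                           pgtol = tol * mean_T / 10))
        total_steps <- total_steps + opt$counts[["function"]]
        p_try <- matrix(opt$par, nV, 2)
        if (any_inverted(p_try)) { status <- "stalled"; break }
        progressed <- opt$value < e_before - 1e-12 * (abs(opt$value) + 1)
        x <- opt$par
        p <- p_try; g <- geom(p); f <- force(g)
        resid <- max(row_norms(f)) / mean_T
        if (resid <= tol) { status <- "converged"; break }
        if (!progressed) { status <- "stalled"; break }
        if (total_steps >= max_iterations) { status <- "budget"; break }
      }
    }

    arr$vertices$x <- p[, 1]; arr$vertices$y <- p[, 2]
    resid_hist <- c(resid_hist, resid)
    if (status == "converged") break

    # A sub-threshold interface counts as stuck only when the unresolved
    # force actually sits on it: one of its endpoints must carry a net force
    # comparable to the worst in the network. Otherwise short interfaces are
    # legitimate equilibrium features and are left alone.
    stuck <- integer(0)
    if (resid > 100 * tol) {
      fnorm <- row_norms(f)
      short <- which(g$len < thr)
      hot <- fnorm >= 0.3 * max(fnorm)
      stuck <- short[hot[i[short]] | hot[j[short]]]
    }
    if (length(stuck) == 0 && status == "stalled" && soft_stalls < 6L) {
      # Slow-progress stall without any pinned interface: give the descent
      # more patience rather than acting.
      soft_stalls <- soft_stalls + 1L
      patience <- patience * 2L
      next
    }
    if (length(stuck) == 0 || status == "budget") {
      stop(rlang::error_cnd(
        class = c("epiforce_no_convergence", "epiforce_error"),
        message = sprintf("relaxation did not converge: residual %.3g after %d steps (tol %.3g)",
                          resid, total_steps, tol),
        residual_history = resid_hist
      ))
    }
    k <- stuck[which.min(g$len[stuck])]
    surgery <- resolve_collapse(arr, state, arr$edges$id[[k]])
    arr <- surgery$array; state <- surgery$state
    n_merge <- n_merge + surgery$merged; n_t2 <- n_t2 + surgery$t2
  }

  arr$vertices$x <- arr$vertices$x %% box[[1]]
  arr$vertices$y <- arr$vertices$y %% box[[2]]
  list(array = arr, state = state, residual = resid,
       iterations = total_steps, energy = tissue_energy(arr, state),
       n_merge = n_merge, n_t2 = n_t2, residual_history = resid_hist)
}

# The first interface (by edge id order) whose tension exceeds the sum of
# the other tensions at one of its endpoints, or NA if every junction
# satisfies the polygon inequality. Such an interface cannot be balanced at
# any positive length.
frustrated_edge <- function(arr, state, slack = 1e-9) {
  Tv <- state$tensions$tension[match(arr$edges$id, state$tensions$edge)]
  for (v in arr$vertices$id) {
    inc <- which(arr$edges$v1 == v | arr$edges$v2 == v)
    if (length(inc) < 2) next
    Ts <- Tv[inc]
    k <- which.max(Ts)
    if (Ts[[k]] > sum(Ts[-k]) + slack) return(arr$edges$id[[inc[[k]]]])
  }
  NA_integer_
}

# Resolve a collapsing interface: T2 extinction if it belongs to a
# three-sided cell, rosette fusion otherwise.
resolve_collapse <- function(arr, state, edge_id) {
  k <- match(edge_id, arr$edges$id)
  sides <- lengths(arr$cells$vertices)[match(c(arr$edges$cell_left[[k]], arr$edges$cell_right[[k]]),
                                             arr$cells$id)]
  if (any(sides == 3)) {
    tri <- c(arr$edges$cell_left[[k]], arr$edges$cell_right[[k]])[sides == 3][[1]]
    surgery <- t2_transition(arr, state, tri)
    surgery$merged <- 0L; surgery$t2 <- 1L
  } else {
    surgery <- rosette_merge(arr, state, edge_id)
    surgery$merged <- 1L; surgery$t2 <- 0L
  }
  surgery
}

# Fuse the endpoints of edge `edge_id` into a single (rosette) vertex at the
# edge midpoint. The interface and its tension disappear; V and E each drop
# by one, which is exactly the counting move that grants the inverse one
# extra zero mode per rosette. Works for endpoints of any degree.
rosette_merge <- function(arr, state, edge_id) {
  k <- match(edge_id, arr$edges$id)
  e <- arr$edges[k, ]
  i <- e$v1; j <- e$v2
  pos <- vertex_matrix(arr)
  ii <- match(i, arr$vertices$id); jj <- match(j, arr$vertices$id)
  chi <- drop(displacements(pos, ii, jj, arr$box))
  arr$vertices$x[[ii]] <- pos[ii, 1] + chi[[1]] / 2
  arr$vertices$y[[ii]] <- pos[ii, 2] + chi[[2]] / 2

  arr$edges <- arr$edges[-k, ]
  other <- (arr$edges$v1 == i & arr$edges$v2 == j) | (arr$edges$v1 == j & arr$edges$v2 == i)
  if (any(other)) {
    stop_epiforce("vertex fusion would degenerate a parallel interface (two-sided cell)", "epiforce_collapse")
  }
  arr$edges$v1[arr$edges$v1 == j] <- i
  arr$edges$v2[arr$edges$v2 == j] <- i

  touched <- which(vapply(arr$cells$vertices, function(lp) j %in% lp || i %in% lp, TRUE))
  for (kk in touched) {
    loop <- arr$cells$vertices[[kk]]
    loop[loop == j] <- i
    loop <- loop[c(TRUE, diff(loop) != 0)]
    if (length(loop) > 1 && loop[[1]] == loop[[length(loop)]]) loop <- loop[-length(loop)]
    if (length(loop) < 3) {
      stop_epiforce("vertex fusion left a cell with fewer than three sides", "epiforce_collapse")
    }
    arr$cells$vertices[[kk]] <- loop
  }
  arr$vertices <- arr$vertices[arr$vertices$id != j, ]
  state$tensions <- state$tensions[state$tensions$edge != edge_id, ]
  list(array = arr, state = state)
}

# T2 extinction: collapse a dying cell to a single vertex. If removing the
# cell would leave a neighbour with fewer than three sides (adjacent dying
# triangles), the neighbour joins the collapsing cluster, so the whole
# degenerate region contracts to one rosette vertex in a single move.
t2_transition <- function(arr, state, cell_id, max_cluster = 6L) {
  region <- cell_id
  repeat {
    vset <- unique(unlist(arr$cells$vertices[match(region, arr$cells$id)]))
    both_in <- arr$edges$v1 %in% vset & arr$edges$v2 %in% vset
    # Side counts after collapse: each surviving cell keeps its loop with all
    # vset entries fused into one.
    grow <- integer(0)
    for (kk in seq_len(nrow(arr$cells))) {
      if (arr$cells$id[[kk]] %in% region) next
      loop <- arr$cells$vertices[[kk]]
      if (!any(loop %in% vset)) next
      newloop <- collapse_loop(loop, vset, -1L)
      if (length(newloop) < 3) grow <- c(grow, arr$cells$id[[kk]])
    }
    if (length(grow) == 0) break
    region <- c(region, grow)
    if (length(region) > max_cluster) {
      stop_epiforce(sprintf("cell extinction cascade exceeds %d cells", max_cluster), "epiforce_collapse")
    }
  }

  keep_v <- min(vset)
  # Position: mean of the first region cell's unwrapped loop.
  pos <- vertex_matrix(arr)
  p0 <- unwrap_loop(arr, arr$cells$vertices[[match(region[[1]], arr$cells$id)]], pos)
  centroid <- colMeans(p0)
  pk <- match(keep_v, arr$vertices$id)
  arr$vertices$x[[pk]] <- centroid[[1]]; arr$vertices$y[[pk]] <- centroid[[2]]

  dead_edges <- arr$edges$id[both_in]
  arr$edges <- arr$edges[!both_in, ]
  arr$edges$v1[arr$edges$v1 %in% vset] <- keep_v
  arr$edges$v2[arr$edges$v2 %in% vset] <- keep_v

  survive <- !arr$cells$id %in% region
  arr$cells <- arr$cells[survive, ]
  for (kk in seq_len(nrow(arr$cells))) {
    loop <- arr$cells$vertices[[kk]]
    if (!any(loop %in% vset)) next
    arr$cells$vertices[[kk]] <- collapse_loop(loop, vset, keep_v)
  }
  arr$vertices <- arr$vertices[!(arr$vertices$id %in% setdiff(vset, keep_v)), ]
  state$tensions <- state$tensions[!state$tensions$edge %in% dead_edges, ]
  state$pressures <- state$pressures[!state$pressures$cell %in% region, ]
  list(array = arr, state = state)
}

# Replace every loop entry in `vset` by `keep` and collapse the resulting
# consecutive (cyclic) duplicates.
collapse_loop <- function(loop, vset, keep) {
  loop[loop %in% vset] <- keep
  loop <- loop[c(TRUE, diff(loop) != 0)]
  if (length(loop) > 1 && loop[[1]] == loop[[length(loop)]]) loop <- loop[-length(loop)]
  loop
}

#' Corrupt vertex positions with isotropic noise
#'
#' Displaces every vertex by i.i.d. isotropic Gaussian noise whose r.m.s.
#' displacement magnitude equals `rms_fraction` times the mean edge length
#' (per-coordinate standard deviation `rms_fraction * mean_edge_length /
#' sqrt(2)`). Topology is unchanged. This emulates segmentation and
#' biological positional error in the in-silico benchmark.
#'
#' @param array A [cell_array()].
#' @param rms_fraction Nonnegative noise magnitude, as a fraction of the
#'   mean edge length.
#' @param seed Optional integer seed for reproducible noise.
#' @return The corrupted [cell_array()].
#' @export
corrupt_vertices <- function(array, rms_fraction, seed = NULL) {
  stopifnot(rms_fraction >= 0)
  if (rms_fraction == 0) return(array)
  nV <- nrow(array$vertices)
  sigma <- rms_fraction * mean_edge_length(array) / sqrt(2)
  noise <- if (is.null(seed)) {
    matrix(stats::rnorm(2 * nV, sd = sigma), nV, 2)
  } else {
    withr::with_seed(as.integer(seed), matrix(stats::rnorm(2 * nV, sd = sigma), nV, 2))
  }
  array$vertices$x <- array$vertices$x + noise[, 1]
  array$vertices$y <- array$vertices$y + noise[, 2]
  if (!is.null(array$box)) {
    array$vertices$x <- array$vertices$x %% array$box[[1]]
    array$vertices$y <- array$vertices$y %% array$box[[2]]
  }
  array
}

#' Fuse sub-resolution interfaces into rosettes
#'
#' Interfaces shorter than `min_length` cannot be oriented reliably from
#' observed vertex positions (for instance when positional error is
#' comparable to the interface length); in segmented images such junction
#' pairs effectively appear as single higher-order junctions. This helper
#' fuses them into rosette vertices, removing the interface. Edges of
#' three-sided cells are left untouched (fusing them would degenerate the
#' cell).
#'
#' @param array A [cell_array()].
#' @param min_length Length threshold (same units as the coordinates).
#' @return The array with all sub-threshold interfaces fused.
#' @export
fuse_short_edges <- function(array, min_length) {
  dummy <- uniform_state(array)
  repeat {
    et <- edge_table(array)
    sides_l <- lengths(array$cells$vertices)[match(et$cell_left, array$cells$id)]
    sides_r <- lengths(array$cells$vertices)[match(et$cell_right, array$cells$id)]
    ok <- et$length < min_length & (is.na(sides_l) | sides_l > 3) & (is.na(sides_r) | sides_r > 3) &
      et$cell_left >= 0 & et$cell_right >= 0
    if (!any(ok)) break
    k <- which(ok)[which.min(et$length[ok])]
    array <- rosette_merge(array, dummy, et$edge[[k]])$array
    dummy <- uniform_state(array)
  }
  array
}
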