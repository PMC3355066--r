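test_that("the balance system has the documented shape in each parameterization", {
  sim <- fixture_tissue(64, 2)
  arr <- sim$array
  V <- nrow(arr$vertices); E <- nrow(arr$edges); C <- nrow(arr$cells)

  full <- balance_system(arr, "full")
  expect_equal(dim(full$matrix), c(2 * V + 1, E + C))
  cp <- balance_system(arr, "constant_pressure")
  expect_equal(dim(cp$matrix), c(2 * V + 1, E))
  expect_gt(nrow(cp$matrix), ncol(cp$matrix))        # overdetermined
  co <- balance_system(arr, "cortical")
  expect_equal(dim(co$matrix), c(2 * V + 1, 2 * C))

  # closed three-valent array: E + C = 2V + 1, a square system plus scale row
  cl <- extract_patch(fixture_tissue(100, 4)$array, topology = "closed")
  Vc <- nrow(cl$vertices); Ec <- nrow(cl$edges); Cc <- nrow(cl$cells)
  expect_equal(Ec + Cc, 2 * Vc + 1)
  expect_equal(dim(balance_system(cl, "full")$matrix), c(2 * Vc + 1, Ec + Cc))

  # right-hand side: zeros except the scale entry
  expect_equal(full$rhs[seq_len(2 * V)], rep(0, 2 * V))
  expect_equal(full$rhs[[2 * V + 1]], 1)
})

test_that("a rosette vertex contributes two rows summing all incident interface forces", {
  sim <- fixture_tissue(64, 2)
  ll <- mean(edge_table(sim$array)$length)
  fused <- fuse_short_edges(sim$array, 0.05 * ll)
  deg <- table(c(fused$edges$v1, fused$edges$v2))
  rosettes <- as.integer(names(deg)[deg > 3])
  expect_gt(length(rosettes), 0)
  sys <- balance_system(fused, "constant_pressure")
  rid <- sys$row_map$row[which(sys$row_map$vertex == rosettes[[1]])]
  # the x-row of the rosette has one entry per incident interface
  expect_equal(sum(sys$matrix[rid[[1]], ] != 0), deg[[as.character(rosettes[[1]])]])
})

test_that("the uniform honeycomb yields exactly unit tensions", {
  hx <- fixture_hex()
  fit <- infer_forces(hx, "constant_pressure")
  expect_equal(fit$state$tensions$tension, rep(1, nrow(hx$edges)), tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-9)
})

test_that("noiseless constant-pressure inference recovers the true tensions exactly", {
  sim <- fixture_tissue(100, 4)
  fit <- infer_forces(sim$array, "constant_pressure")
  sc <- recovery_scatter(sim$state, fit$state)
  expect_gte(sc$r, 0.999)
  expect_equal(mean(fit$state$tensions$tension), 1, tolerance = 1e-9)
})

test_that("zero-mode counts match the theoretical counting in every topology", {
  # toroidal, full parameterization, generic (observed/noisy) geometry:
  # the generic count is 2 (overall scale + uniform pressure shift), and
  # every three-sided cell adds one exact soft mode whatever its shape
  # (the inscribed-circle degeneracy), so the measured dimension is
  # max(2, 1 + #triangles).
  for (seed in c(2, 4)) {
    sim <- fixture_tissue(64, seed)
    ntri <- sum(lengths(sim$array$cells$vertices) == 3)
    observed <- corrupt_vertices(sim$array, 0.05, seed = seed)
    expect_equal(null_space_dimension(balance_system(observed, "full")),
                 max(2, 1 + ntri))
    expect_equal(count_expected_zero_modes(sim$array), 2)
  }
  # the exactly equilibrated geometry is itself non-generic and can carry
  # further self-stresses on top
  sim <- fixture_tissue(64, 2)
  expect_gte(null_space_dimension(balance_system(sim$array, "full")), 2)

  # closed planar: the four free constants
  cl <- extract_patch(fixture_tissue(100, 4)$array, topology = "closed")
  expect_equal(null_space_dimension(balance_system(cl, "full")), 4)

  # open patch: overall scale plus one freedom per boundary cell
  op <- extract_patch(fixture_tissue(100, 4)$array, topology = "open")
  nd <- null_space_dimension(balance_system(op, "full"))
  expect_equal(nd, count_expected_zero_modes(op))
  expect_equal(nd, sum(op$cells$boundary) + 1)

  # the scale row removes exactly one freedom
  expect_equal(null_space_dimension(balance_system(cl, "full"), include_scale_row = TRUE), 3)
})

test_that("the particular solution is minimum-norm and respects the scale row", {
  cl <- extract_patch(fixture_tissue(100, 4)$array, topology = "closed")
  fit <- solve_inverse(balance_system(cl, "full"))
  expect_equal(ncol(fit$zero_modes), 3)
  # orthogonal to every zero mode
  expect_lt(max(abs(t(fit$zero_modes) %*% fit$particular)), 1e-9)
  tt <- fit$column_map[fit$column_map$kind == "tension", ]
  expect_equal(mean(tt$estimate), 1, tolerance = 1e-6)
})

test_that("inference is invariant under rigid motions and scale of the geometry", {
  sim <- fixture_tissue(100, 4)
  cl <- extract_patch(sim$array, topology = "closed")
  base <- infer_forces(cl, "constant_pressure")$state$tensions$tension

  th <- 0.71
  rot <- cl
  xy <- cbind(cl$vertices$x, cl$vertices$y) %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
  rot$vertices$x <- xy[, 1] + 13.7; rot$vertices$y <- xy[, 2] - 4.2
  expect_equal(infer_forces(rot, "constant_pressure")$state$tensions$tension, base,
               tolerance = 1e-8)

  big <- cl
  big$vertices$x <- cl$vertices$x * 37; big$vertices$y <- cl$vertices$y * 37
  fit_big <- infer_forces(big, "constant_pressure")
  expect_equal(fit_big$state$tensions$tension, base, tolerance = 1e-8)
  expect_equal(mean(fit_big$state$tensions$tension), 1, tolerance = 1e-9)
})

test_that("the constant-pressure solution nests inside the full system", {
  sim <- fixture_tissue(64, 2)
  cp <- balance_system(sim$array, "constant_pressure")
  full <- balance_system(sim$array, "full")
  fit <- solve_inverse(cp)
  # pad with equal pressures (zero): same residual on the balance rows
  q_pad <- c(fit$particular, rep(0, nrow(sim$array$cells)))
  n_bal <- nrow(full$matrix) - 1
  r_full <- full$matrix[seq_len(n_bal), ] %*% q_pad
  r_cp <- cp$matrix[seq_len(n_bal), ] %*% fit$particular
  expect_equal(drop(r_full), drop(r_cp), tolerance = 1e-12)
})

test_that("nonnegative least squares removes the negative-tension tail", {
  sim <- fixture_tissue(64, 3)
  # noiseless: the constraint is inactive and both solvers agree
  plain0 <- infer_forces(sim$array, "constant_pressure")
  nneg0 <- infer_forces(sim$array, "constant_pressure", nonnegative = TRUE)
  expect_equal(nneg0$state$tensions$tension, plain0$state$tensions$tension, tolerance = 1e-9)

  # heavy corruption: the plain pseudo-inverse develops negative tensions
  noisy <- corrupt_vertices(sim$array, 0.15, seed = 42)
  plain <- infer_forces(noisy, "constant_pressure")
  nneg <- infer_forces(noisy, "constant_pressure", nonnegative = TRUE)
  expect_gt(sum(plain$state$tensions$tension < 0), 0)
  expect_true(all(nneg$state$tensions$tension >= -1e-12))
  expect_gte(nneg$residual_norm, plain$residual_norm)
})

test_that("the cortical reduction infers one tension and one pressure per cell", {
  cl <- extract_patch(fixture_tissue(100, 4)$array, topology = "closed")
  fit <- infer_forces(cl, "cortical")
  expect_equal(length(fit$particular), 2 * nrow(cl$cells))
  expect_equal(nrow(fit$cortical), nrow(cl$cells))
  expect_equal(mean(fit$state$tensions$tension), 1, tolerance = 0.05)
  expect_true(all(is.finite(fit$state$pressures$pressure)))
  td <- tidy(fit)
  expect_setequal(unique(td$kind), c("cortical", "pressure"))
})

test_that("degenerate systems raise errors", {
  op <- two_triangle_array()
  expect_error(balance_system(op, "full"), class = "epiforce_invalid")  # no interior vertex
})
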