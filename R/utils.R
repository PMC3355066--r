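# Internal numerical helpers shared across modules.

# Minimum-image displacement for periodic (toroidal) domains.
# d: numeric vector/matrix of raw coordinate differences, len: period(s).
wrap_min_image <- function(d, len) {
  d - len * round(d / len)
}

# Displacement vectors r[to,] - r[from,] with minimum-image wrapping when the
# array is toroidal. pos is a V x 2 matrix, from/to are row indices.
displacements <- function(pos, from, to, box = NULL) {
  d <- pos[to, , drop = FALSE] - pos[from, , drop = FALSE]
  if (!is.null(box)) {
    d[, 1] <- wrap_min_image(d[, 1], box[[1]])
    d[, 2] <- wrap_min_image(d[, 2], box[[2]])
  }
  d
}

# 90-degree rotation by the antisymmetric tensor (eps_xy = 1, eps_yx = -1):
# (x, y) -> (y, -x). Acts rowwise on an n x 2 matrix.
rotate_cw <- function(v) {
  cbind(v[, 2], -v[, 1], deparse.level = 0)
}

row_norms <- function(m) sqrt(rowSums(m^2))

# Positions as a plain matrix in vertex-table order.
vertex_matrix <- function(array) {
  cbind(array$vertices$x, array$vertices$y, deparse.level = 0)
}

stop_epiforce <- function(msg, class) {
  rlang::abort(msg, class = c(class, "epiforce_error"))
}

# Derive a child RNG seed from a base seed and a stream index, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1009) %% 2147483647)
}
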