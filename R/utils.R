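# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_acf <- function(...) stop(..., call. = FALSE)

#' Coerce a mask argument to a logical 3D array
#'
#' Accepts a `volume_map` (its mask slot), a logical array, or a numeric
#' array (non-zero and finite = in mask).
#' @param x mask-like object
#' @return logical array
#' @keywords internal
as_mask <- function(x) {
  if (inherits(x, "volume_map")) return(x$mask)
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(is.finite(x) & x != 0)
  stop_acf("cannot interpret object of class '", class(x)[1], "' as a mask")
}

# Evaluate `code` under a deterministic private RNG stream without
# disturbing the caller's .Random.seed (used for Monte-Carlo critical
# values that must not consume user randomness).
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-subject seed from a master seed
#'
#' Deterministic splitting rule: `(master * 100003 + index * 7919) mod
#' (2^31 - 1)`, kept within the 32-bit integer range R requires of
#' `set.seed()`.
#' @param master integer master seed
#' @param index integer stream index (subject number, covariate stream, ...)
#' @return integer seed
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 100003 + as.double(index) * 7919) %% 2147483647)
}

# Linear index <-> (i,j,k) conversions for 3D arrays (R 1-based indices).
lin_to_ijk <- function(idx, dm) {
  idx0 <- idx - 1L
  i <- idx0 %% dm[1]
  j <- (idx0 %/% dm[1]) %% dm[2]
  k <- idx0 %/% (dm[1] * dm[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_lin <- function(ijk, dm) {
  (ijk[, 1] - 1L) + (ijk[, 2] - 1L) * dm[1] + (ijk[, 3] - 1L) * dm[1] * dm[2] + 1L
}

#' Convert voxel indices to world (mm) coordinates
#'
#' Voxel indices are R-style 1-based array indices; they are shifted to the
#' 0-based convention of the NIfTI affine before multiplication, so world
#' coordinates always come from the affine alone.
#'
#' @param affine 4x4 voxel-to-world matrix
#' @param ijk integer vector of length 3, or an n x 3 matrix of indices
#' @return numeric vector (or n x 3 matrix) of mm coordinates
#' @export
voxel_to_world <- function(affine, ijk) {
  if (is.vector(ijk)) ijk <- matrix(ijk, nrow = 1)
  xyz1 <- affine %*% rbind(t(ijk) - 1, 1)
  out <- t(xyz1[1:3, , drop = FALSE])
  if (nrow(out) == 1L) drop(out) else out
}

#' Convert world (mm) coordinates to voxel indices
#'
#' Inverse of [voxel_to_world()]; returns 1-based indices rounded to the
#' nearest voxel.
#' @param affine 4x4 voxel-to-world matrix
#' @param xyz numeric vector of length 3, or an n x 3 matrix of mm coordinates
#' @return integer vector (or matrix) of voxel indices
#' @export
world_to_voxel <- function(affine, xyz) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  ijk0 <- solve(affine) %*% rbind(t(xyz), 1)
  out <- round(t(ijk0[1:3, , drop = FALSE])) + 1
  storage.mode(out) <- "integer"
  if (nrow(out) == 1L) drop(out) else out
}

# Extract the T x V matrix of time series at `idx` (linear voxel indices)
# from a bold_image data array.
bold_matrix <- function(bold, idx) {
  dm <- dim(bold$data)
  nv <- prod(dm[1:3])
  flat <- matrix(bold$data, nrow = nv, ncol = dm[4])
  t(flat[idx, , drop = FALSE])
}
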