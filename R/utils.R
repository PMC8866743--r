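#' Derive reproducible child seeds from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds through this helper
#' so that a single master seed reproduces every stage.  Child seeds are kept
#' below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param k number of child seeds.
#' @return integer vector of length `k`.
#' @export
derive_seeds <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L, k >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, k)
}

# save/restore .Random.seed so library internals do not disturb user RNG state
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Logistic transform used by selection objectives
#'
#' Maps a raw statistic to (0, 1).  `increasing = TRUE` rewards large values
#' (e.g. CFI), `FALSE` rewards small values (e.g. RMSEA).
#'
#' @param x raw statistic.
#' @param b midpoint (value mapped to 0.5).
#' @param a slope.
#' @param increasing orientation.
#' @return value in (0, 1).
#' @export
logistic_component <- function(x, b, a, increasing = TRUE) {
  s <- if (increasing) 1 else -1
  1 / (1 + exp(-s * a * (x - b)))
}

# lower-triangle index helper (column-major pairs j < k as in combn)
.lt_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

.lt_vec <- function(M) M[lower.tri(M)]

.vec_lt <- function(v, p, diag = 1) {
  M <- matrix(0, p, p)
  M[lower.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- diag
  M
}

#' Nearest positive-semidefinite correlation matrix by eigenvalue clipping
#'
#' Eigenvalues below `eps` are raised to `eps`, the matrix is reassembled and
#' rescaled back to unit diagonal.
#'
#' @param R symmetric matrix.
#' @param eps clipping floor.
#' @return list with `mat` and logical `clipped`.
#' @export
psd_clip <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(mat = R, clipped = FALSE))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  list(mat = M, clipped = TRUE)
}
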