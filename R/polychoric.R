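# Two-step polychoric estimation: thresholds fixed at the probit of the
# cumulative margins, then a one-dimensional bounded likelihood search for
# each pair's latent correlation.  Zero-frequency categories are collapsed
# into the adjacent lower category (first category collapses upward) with a
# loud log, so downstream estimation always proceeds.

#' Probit thresholds from category counts
#'
#' @param counts vector of category counts for one item (category order).
#' @return strictly increasing thresholds; empty boundary categories are
#'   collapsed (their threshold dropped) and recorded in the `collapsed`
#'   attribute.
#' @export
thresholds_from_margins <- function(counts) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (sum(counts > 0) < 2) stop("fewer than 2 nonempty categories")
  cum <- cumsum(counts)[-length(counts)] / n
  keep <- cum > 0 & cum < 1
  tau <- qnorm(cum[keep])
  attr(tau, "collapsed") <- any(!keep)
  tau
}

#' Polychoric correlation of one two-way contingency table
#'
#' Two-step maximum likelihood: thresholds from the margins, then the
#' bivariate-normal cell likelihood maximized over the correlation in
#' (-0.999, 0.999) by bounded one-dimensional search; the estimate is
#' clamped to +/- 0.999.
#'
#' @param table a category x category count matrix.
#' @return estimated correlation.  Attributes: `collapsed` (were empty
#'   categories merged).  Degenerate tables (one category left on a margin
#'   after collapse) are an error.
#' @export
polychoric_pair <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("negative counts")
  res <- .polychoric_table_cpp(tab)
  if (res$degenerate) stop("degenerate table: one category left after collapse")
  structure(res$rho, collapsed = res$collapsed)
}

#' Bivariate standard normal CDF
#'
#' `P(X <= a, Y <= b)` for correlation `rho`; vectorized over its arguments.
#' @param a,b upper limits.
#' @param rho correlation in (-1, 1).
#' @return probabilities.
#' @export
bvn_cdf <- function(a, b, rho) {
  k <- max(length(a), length(b), length(rho))
  .bvn_cdf_cpp(rep_len(as.numeric(a), k), rep_len(as.numeric(b), k),
               rep_len(as.numeric(rho), k))
}

#' Pairwise polychoric correlation matrix
#'
#' Pairwise-complete observations; if the resulting matrix is not positive
#' semidefinite it is eigenvalue-clipped to the nearest PSD matrix (floor
#' 1e-6, rescaled to unit diagonal) and this is logged in the result.
#'
#' @param resp response data frame or integer matrix (categories 0..K-1).
#' @param spec an [instrument_spec()]; its items select and order columns.
#' @param items optional subset of items.
#' @return object of class `polychoric_result`: `R` (correlations), `tau`
#'   (per-item thresholds from the full margins), `npair` (pairwise n),
#'   `n` (respondents), `collapse_log` (items/pairs with category collapse),
#'   `psd_clipped`.
#' @export
polychoric_matrix <- function(resp, spec, items = NULL) {
  items <- items %||% spec$items
  X <- as.matrix(as.data.frame(resp)[, items, drop = FALSE])
  storage.mode(X) <- "integer"
  K <- spec$n_categories
  ncat_obs <- apply(X, 2, function(v) length(unique(v[!is.na(v)])))
  if (any(ncat_obs < 2))
    stop("item with fewer than 2 observed categories: ",
         paste(items[ncat_obs < 2], collapse = ", "))
  res <- .polychoric_matrix_cpp(X, K)
  R <- res$R
  dimnames(R) <- list(items, items)
  tau <- .item_thresholds_cpp(X, K)
  names(tau) <- items
  clip <- psd_clip(R)
  collapse_pairs <- which(res$collapse & upper.tri(res$collapse), arr.ind = TRUE)
  structure(list(R = clip$mat, tau = tau, npair = res$npair, n = nrow(X),
                 collapse_log = if (nrow(collapse_pairs))
                   data.frame(item1 = items[collapse_pairs[, 1]],
                              item2 = items[collapse_pairs[, 2]])
                 else NULL,
                 psd_clipped = clip$clipped),
            class = "polychoric_result")
}

#' @export
print.polychoric_result <- function(x, ...) {
  cat(sprintf("polychoric_result: %d items, n = %d%s%s\n", ncol(x$R), x$n,
              if (x$psd_clipped) ", PSD-clipped" else "",
              if (!is.null(x$collapse_log))
                sprintf(", %d pairs with collapsed categories", nrow(x$collapse_log))
              else ""))
  invisible(x)
}

#' Diagonal asymptotic variances of the polychoric correlations
#'
#' Delete-one-group jackknife over respondents: rows are partitioned into
#' `groups` consecutive blocks, the polychoric matrix is recomputed with each
#' block deleted, and the jackknife variance estimates `Var(rho_hat)` at the
#' full sample size.  Floored at 1e-8.  With fewer than 50 respondents, unit
#' weights are substituted with a warning.
#'
#' @param resp response data (same rows used for the point estimates).
#' @param spec an [instrument_spec()].
#' @param items optional subset of items.
#' @param groups number of jackknife blocks (default 30).
#' @param return_replicates attach the jackknife replicate correlations
#'   (G x n-pairs matrix of lower-triangle vectors) as attribute
#'   `"replicates"`; [fit_dwls()] uses them to estimate the full asymptotic
#'   covariance needed by the mean-scaled chi-square.
#' @return symmetric matrix of variance estimates (diagonal set to `NA`), or
#'   unit weights for tiny samples.
#' @export
acov_diag <- function(resp, spec, items = NULL, groups = 30L,
                      return_replicates = FALSE) {
  items <- items %||% spec$items
  X <- as.matrix(as.data.frame(resp)[, items, drop = FALSE])
  storage.mode(X) <- "integer"
  n <- nrow(X)
  p <- length(items)
  if (n < 50) {
    warning("n < 50: unit weights substituted for the asymptotic variances")
    W <- matrix(1, p, p, dimnames = list(items, items))
    diag(W) <- NA_real_
    return(W)
  }
  G <- as.integer(groups)
  gidx <- rep(seq_len(G), length.out = n)   # deterministic consecutive blocks
  K <- spec$n_categories
  est <- array(NA_real_, c(p, p, G))
  for (g in seq_len(G)) {
    Rg <- .polychoric_matrix_cpp(X[gidx != g, , drop = FALSE], K)$R
    est[, , g] <- Rg
  }
  m <- apply(est, c(1, 2), mean)
  V <- apply(sweep(est, c(1, 2), m)^2, c(1, 2), sum) * (G - 1) / G
  V <- pmax(V, 1e-8)
  dimnames(V) <- list(items, items)
  diag(V) <- NA_real_
  if (return_replicates) {
    lt <- lower.tri(diag(p))
    attr(V, "replicates") <- t(apply(est, 3, function(M) M[lt]))
    attr(V, "rep_items") <- items
  }
  V
}
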