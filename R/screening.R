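# Careless-responding indices and the inclusion rule: <10% missing items and
# every index within 2.5 SD of a designated reference sample's average.

#' Average longstring of a response vector
#'
#' Mean length of maximal runs of identical consecutive responses; missing
#' entries break runs and are excluded.  Depends on the declared item order.
#'
#' @param row ordinal response vector (with possible `NA`s).
#' @return mean maximal-run length; errors if nothing is observed.
#' @export
longstring_avg <- function(row) {
  x <- as.vector(row)
  if (all(is.na(x))) stop("all-missing row")
  # split at missings, rle within each observed segment
  seg <- split(x[!is.na(x)], cumsum(is.na(x))[!is.na(x)])
  runs <- unlist(lapply(seg, function(s) rle(s)$lengths))
  mean(runs)
}

#' Squared Mahalanobis distances of item-response vectors
#'
#' Distance to the sample centroid under the ridge-regularized sample
#' covariance of the item responses (`ridge * trace/p` added to the
#' diagonal); near-singular covariances are common with few categories.
#' Missing cells are replaced by the item mean (their contribution to the
#' distance is then zero in the corresponding direction).
#'
#' @param resp response data frame or matrix.
#' @param spec an [instrument_spec()].
#' @param ridge regularization factor (default 1e-6).
#' @return numeric vector of squared distances.
#' @export
mahalanobis_sq <- function(resp, spec, ridge = 1e-6) {
  X <- as.matrix(as.data.frame(resp)[, spec$items])
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  S <- cov(X)
  p <- ncol(X)
  S <- S + diag(ridge * sum(diag(S)) / p, p)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("singular covariance despite regularization")
  stats::mahalanobis(X, mu, S)
}

#' Even-odd consistency of one respondent
#'
#' Splits each facet's items by within-facet position into an odd half
#' (1st, 3rd, ...) and an even half (2nd, 4th, ...), correlates the two
#' half-scores across facets, and applies the Spearman-Brown correction
#' `2r / (1 + r)`, clamped to \[-1, 1\].
#'
#' @param row one respondent's responses (named by item ID).
#' @param spec an [instrument_spec()].
#' @return corrected consistency; errors if fewer than 3 facets have both
#'   halves observed.
#' @export
even_odd_consistency <- function(row, spec) {
  fi <- facet_items(spec)
  halves <- vapply(fi, function(its) {
    v <- as.numeric(row[its])
    odd <- v[seq(1, length(v), 2)]
    even <- if (length(v) >= 2) v[seq(2, length(v), 2)] else NA_real_
    c(mean(odd, na.rm = TRUE), mean(even, na.rm = TRUE))
  }, numeric(2))
  ok <- is.finite(halves[1, ]) & is.finite(halves[2, ])
  if (sum(ok) < 3) stop("fewer than 3 facets with both halves observed")
  o <- halves[1, ok]; e <- halves[2, ok]
  if (sd(o) == 0 && sd(e) == 0) return(1)      # identical constant halves
  if (sd(o) == 0 || sd(e) == 0) return(0)
  r <- cor(o, e)
  max(-1, min(1, 2 * r / (1 + r)))
}

#' Per-respondent screening indices
#'
#' @param resp response data frame.
#' @param spec an [instrument_spec()].
#' @return data frame: `missing_frac`, `longstring`, `mahalanobis_sq`,
#'   `even_odd`.
#' @export
screening_report <- function(resp, spec) {
  X <- as.matrix(as.data.frame(resp)[, spec$items])
  storage.mode(X) <- "double"
  miss <- rowMeans(is.na(X))
  ls <- apply(X, 1, function(r) if (all(is.na(r))) NA_real_ else longstring_avg(r))
  md <- mahalanobis_sq(resp, spec)
  eo <- apply(X, 1, function(r) {
    tryCatch(even_odd_consistency(r, spec), error = function(e) NA_real_)
  })
  data.frame(missing_frac = miss, longstring = ls,
             mahalanobis_sq = md, even_odd = eo)
}

#' Reference statistics for the inclusion rule
#'
#' Means and SDs of the three indices computed on a designated reference
#' (community) sample.
#'
#' @param resp reference sample response data frame.
#' @param spec an [instrument_spec()].
#' @return list of per-index `mean` and `sd`.
#' @export
screening_reference <- function(resp, spec) {
  rep_ <- screening_report(resp, spec)
  idx <- c("longstring", "mahalanobis_sq", "even_odd")
  out <- lapply(idx, function(k) list(mean = mean(rep_[[k]], na.rm = TRUE),
                                      sd = sd(rep_[[k]], na.rm = TRUE)))
  names(out) <- idx
  out
}

#' Apply the inclusion rule
#'
#' A respondent is included iff missingness is below `max_missing` and each
#' of the three indices lies within `z_limit` reference SDs of the reference
#' mean.  An unobservable index (e.g. even-odd for an all-missing row) fails
#' the rule.
#'
#' @param resp response data frame.
#' @param spec an [instrument_spec()].
#' @param reference a [screening_reference()] (defaults to the sample itself).
#' @param max_missing missingness cap (default 0.10).
#' @param z_limit index tolerance in reference SDs (default 2.5).
#' @return list with logical `include` and the `report` (screening indices
#'   plus the flag).
#' @export
apply_inclusion <- function(resp, spec, reference = NULL,
                            max_missing = 0.10, z_limit = 2.5) {
  report <- screening_report(resp, spec)
  if (is.null(reference)) {
    idx <- c("longstring", "mahalanobis_sq", "even_odd")
    reference <- lapply(idx, function(k) list(mean = mean(report[[k]], na.rm = TRUE),
                                              sd = sd(report[[k]], na.rm = TRUE)))
    names(reference) <- idx
  }
  inc <- report$missing_frac < max_missing
  for (k in c("longstring", "mahalanobis_sq", "even_odd")) {
    ref <- reference[[k]]
    if (!is.finite(ref$sd) || ref$sd <= 0) stop("zero reference SD for ", k)
    z <- (report[[k]] - ref$mean) / ref$sd
    inc <- inc & !is.na(z) & abs(z) <= z_limit
  }
  report$include <- inc
  list(include = inc, report = report)
}
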