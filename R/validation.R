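# Criterion-validity and group-contrast statistics: Fisher-averaged pooled
# correlations, confidence intervals for differences between overlapping
# dependent correlations, Cohen's d with noncentral-t intervals, and
# z-profile tables contrasting groups on short and long forms.

#' Fisher-z pooled correlation
#'
#' Correlations are transformed with `atanh`, averaged (unweighted by
#' default; `(n - 3)`-weighted when sizes are supplied and
#' `weighted = TRUE`), and transformed back.
#'
#' @param rs correlations (each strictly inside (-1, 1)).
#' @param ns optional sample sizes.
#' @param weighted use `(n - 3)` weights (requires `ns`).
#' @return pooled correlation.
#' @export
fisher_avg <- function(rs, ns = NULL, weighted = FALSE) {
  if (any(abs(rs) >= 1)) stop("|r| = 1 cannot be Fisher-averaged")
  z <- atanh(rs)
  if (weighted) {
    if (is.null(ns)) stop("weighted averaging needs sample sizes")
    w <- ns - 3
    tanh(sum(w * z) / sum(w))
  } else tanh(mean(z))
}

#' Confidence interval for the difference of two overlapping dependent
#' correlations
#'
#' Zou's (2007) method: individual Fisher-based confidence limits for `r1 =
#' cor(x, y1)` and `r2 = cor(x, y2)` are combined using the estimated
#' correlation between the two estimates, which depends on `r12 =
#' cor(y1, y2)`.
#'
#' @param r1,r2 the two correlations sharing variable x.
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @param level confidence level (default 0.95).
#' @return vector `c(lower, upper)` for `r1 - r2`.
#' @export
zou_ci_dependent <- function(r1, r2, r12, n, level = 0.95) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, abs(r12) < 1, n > 3)
  Rm <- matrix(c(1, r1, r2, r1, 1, r12, r2, r12, 1), 3, 3)
  if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("infeasible correlation triple (not positive semidefinite)")
  zcrit <- qnorm(1 - (1 - level) / 2)
  se <- 1 / sqrt(n - 3)
  l1 <- tanh(atanh(r1) - zcrit * se); u1 <- tanh(atanh(r1) + zcrit * se)
  l2 <- tanh(atanh(r2) - zcrit * se); u2 <- tanh(atanh(r2) + zcrit * se)
  num <- r12 * (1 - r1^2 - r2^2) - (r1 * r2 / 2) * (1 - r1^2 - r2^2 - r12^2)
  c12 <- num / ((1 - r1^2) * (1 - r2^2))
  d <- r1 - r2
  L <- d - sqrt(pmax((r1 - l1)^2 + (u2 - r2)^2 - 2 * c12 * (r1 - l1) * (u2 - r2), 0))
  U <- d + sqrt(pmax((u1 - r1)^2 + (r2 - l2)^2 - 2 * c12 * (u1 - r1) * (r2 - l2), 0))
  c(L, U)
}

#' Cohen's d with a noncentral-t confidence interval
#'
#' Classical pooled-SD d; the CI inverts the noncentral t distribution of
#' `t = d * sqrt(n1 n2 / (n1 + n2))`.
#'
#' @param x1,x2 the two groups' values (`NA`s dropped).
#' @param level confidence level (default 0.95).
#' @return list `d`, `ci`, `n1`, `n2`.
#' @export
cohens_d <- function(x1, x2, level = 0.95) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  if (sp <= 0) stop("zero pooled SD")
  d <- (mean(x1) - mean(x2)) / sp
  mult <- sqrt(n1 * n2 / (n1 + n2))
  tobs <- d * mult
  df <- n1 + n2 - 2
  a <- (1 - level) / 2
  ncp_bound <- function(q) {
    # the noncentral-t CDF emits spurious full-precision warnings far out in
    # the tails; accuracy there is far beyond what the interval needs
    f <- function(ncp) suppressWarnings(pt(tobs, df, ncp = ncp)) - q
    lo <- tobs - 10 * (abs(tobs) + 2); hi <- tobs + 10 * (abs(tobs) + 2)
    uniroot(f, c(lo, hi), tol = 1e-8, extendInt = "yes")$root
  }
  ci <- c(ncp_bound(1 - a), ncp_bound(a)) / mult
  list(d = d, ci = ci, n1 = n1, n2 = n2)
}

#' Convergent/discriminant matrix between short and long forms
#'
#' Pearson correlations between the short-form and full-form facet (and
#' domain) scores, optionally Fisher-pooled over samples.  Note that when
#' the short form's items are a subset of the long form's, the shared items
#' inflate the convergent correlations; the report carries this caveat.
#'
#' @param scores_short,scores_long [score_scales()] results on the same
#'   respondents.
#' @param sample optional sample labels to pool over.
#' @return list `facet` (matrix short x long), `domain`, `convergent_facet`
#'   (diagonal, pooled), `convergent_domain`, `discriminant_facet`
#'   (mean absolute off-diagonal), `discriminant_domain`, `note`.
#' @export
convergence_matrix <- function(scores_short, scores_long, sample = NULL) {
  pool_cor <- function(A, B) {
    if (is.null(sample)) return(cor(A, B, use = "pairwise.complete.obs"))
    labs <- unique(sample)
    mats <- lapply(labs, function(s) cor(A[sample == s, , drop = FALSE],
                                         B[sample == s, , drop = FALSE],
                                         use = "pairwise.complete.obs"))
    out <- mats[[1]]
    for (i in seq_along(out)) out[i] <- fisher_avg(pmin(pmax(
      vapply(mats, `[`, numeric(1), i), -0.999), 0.999))
    out
  }
  Mf <- pool_cor(scores_short$facet, scores_long$facet)
  Md <- pool_cor(scores_short$domain, scores_long$domain)
  list(facet = Mf, domain = Md,
       convergent_facet = diag(Mf), convergent_domain = diag(Md),
       discriminant_facet = mean(abs(Mf[row(Mf) != col(Mf)])),
       discriminant_domain = mean(abs(Md[row(Md) != col(Md)])),
       note = "overlapping items inflate short-vs-long convergent correlations")
}

#' Group contrast and z-profile table
#'
#' Per scale and group: z-mean and quartiles against reference norms;
#' between-group Cohen's d (with CI) on the short form for each adjacent
#' pair of the supplied group ordering; within-group short-vs-long d.
#'
#' @param scores_short,scores_long `scale_scores` for the same respondents.
#' @param groups group labels per respondent.
#' @param reference a [scale_reference()] from the norm sample (applied to
#'   both forms).
#' @param group_order optional ordering of group labels for the adjacent
#'   contrasts.
#' @return object of class `profile_table`: `z_profile` (per group x scale),
#'   `between` (data frame of adjacent-group d on the short form),
#'   `within` (short-vs-long d per group and scale).
#' @export
profile_table <- function(scores_short, scores_long, groups, reference,
                          group_order = NULL) {
  zs <- z_standardize(scores_short, reference)
  zl <- z_standardize(scores_long, reference)
  labs <- group_order %||% sort(unique(groups))
  if (any(!labs %in% groups)) stop("empty group among: ", paste(labs, collapse = ", "))
  scales <- colnames(zs$domain)
  zp <- lapply(labs, function(g) {
    M <- zs$domain[groups == g, , drop = FALSE]
    data.frame(group = g, scale = scales,
               z_mean = colMeans(M, na.rm = TRUE),
               q25 = apply(M, 2, quantile, 0.25, na.rm = TRUE),
               q75 = apply(M, 2, quantile, 0.75, na.rm = TRUE),
               row.names = NULL)
  })
  between <- list()
  if (length(labs) >= 2) {
    for (k in seq_len(length(labs) - 1)) {
      g1 <- labs[k + 1]; g2 <- labs[k]
      for (s in scales) {
        dd <- cohens_d(zs$domain[groups == g1, s], zs$domain[groups == g2, s])
        between[[length(between) + 1]] <-
          data.frame(contrast = paste(g1, "vs", g2), scale = s, d = dd$d,
                     lower = dd$ci[1], upper = dd$ci[2])
      }
    }
  }
  within <- list()
  for (g in labs) {
    for (s in scales) {
      a <- zs$domain[groups == g, s]; b <- zl$domain[groups == g, s]
      dd <- cohens_d(a, b)
      within[[length(within) + 1]] <-
        data.frame(group = g, scale = s, d_short_vs_long = dd$d,
                   lower = dd$ci[1], upper = dd$ci[2])
    }
  }
  structure(list(z_profile = do.call(rbind, zp),
                 between = do.call(rbind, between),
                 within = do.call(rbind, within)),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat("profile_table\n$z_profile:\n"); print(head(x$z_profile, 12))
  invisible(x)
}
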