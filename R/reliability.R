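# Model-based reliability on the latent-response (polychoric) metric,
# consistent with how the measurement model is estimated.  A raw-score
# (Pearson) variant is available behind a flag since published omegas are
# sometimes computed on observed scores.

#' McDonald's omega of a composite
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))` for
#' standardized loadings; uniquenesses may be supplied explicitly.
#'
#' @param loadings standardized loadings of the composite's indicators.
#' @param uniquenesses defaults to `1 - loadings^2`.
#' @return omega in \[0, 1\].
#' @export
omega_composite <- function(loadings, uniquenesses = NULL) {
  if (any(abs(loadings) > 1)) stop("|loading| > 1")
  u <- uniquenesses %||% (1 - loadings^2)
  s <- sum(loadings)^2
  s / (s + sum(u))
}

#' Facet and domain omegas from a fitted model
#'
#' Facet omega uses the standardized item-facet loadings.  For a domain,
#' item loadings on the domain factor are `lambda_i * gamma_f`;
#' `omega_hierarchical` counts only domain-factor variance as true score,
#' while `omega_total` additionally counts facet-specific variance (the
#' `lambda_i` vs `lambda_i * gamma_f` decomposition).  Both are evaluated as
#' variance ratios of the implied correlation matrix, so they agree with the
#' closed forms to machine precision.  `omega_total` is the headline domain
#' value.
#'
#' @param fit a [fit_dwls()] result.
#' @return object of class `omega_report`: `facet` (omega per facet),
#'   `domain_total`, `domain_hierarchical`, `mean_facet`, `mean_domain`.
#'   Heywood-flagged parameters make the affected entries `NA`.
#' @export
omega_report <- function(fit) {
  model <- fit$model; spec <- model$spec
  std <- fit$std
  li <- std$loading_item
  gf <- std$loading_facet
  fi <- facet_items(spec)
  om_f <- vapply(spec$facets, function(f) {
    l <- li[fi[[f]]]
    if (anyNA(l)) return(NA_real_)
    omega_composite(l)
  }, numeric(1))
  Sig <- fit$implied
  uni <- std$uniqueness
  fd <- split(spec$facets, factor(spec$facet_to_domain, levels = spec$domains))
  om_t <- om_h <- setNames(numeric(length(spec$domains)), spec$domains)
  for (d in spec$domains) {
    its <- unlist(fi[fd[[d]]], use.names = FALSE)
    if (anyNA(li[its]) || anyNA(gf[fd[[d]]])) {
      om_t[d] <- om_h[d] <- NA_real_
      next
    }
    tot <- sum(Sig[its, its])
    gload <- li[its] * gf[spec$item_to_facet[its]]
    om_h[d] <- sum(gload)^2 / tot
    om_t[d] <- (tot - sum(uni[its])) / tot
  }
  structure(list(facet = om_f, domain_total = om_t, domain_hierarchical = om_h,
                 mean_facet = mean(om_f, na.rm = TRUE),
                 mean_domain = mean(om_t, na.rm = TRUE)),
            class = "omega_report")
}

#' @export
print.omega_report <- function(x, ...) {
  cat(sprintf("omega_report: mean facet omega = %.3f, mean domain omega (total) = %.3f\n",
              x$mean_facet, x$mean_domain))
  invisible(x)
}

#' Raw-score omega per facet from Pearson correlations
#'
#' Observed-score variant: a one-factor loading vector is taken as the
#' square root of the average inter-item Pearson correlation within the
#' facet (exact for tau-equivalent 2-item facets).
#'
#' @param resp response data.
#' @param spec an [instrument_spec()].
#' @return named vector of facet omegas.
#' @export
omega_raw <- function(resp, spec) {
  X <- as.matrix(as.data.frame(resp)[, spec$items])
  storage.mode(X) <- "double"
  fi <- facet_items(spec)
  vapply(spec$facets, function(f) {
    R <- cor(X[, fi[[f]], drop = FALSE], use = "pairwise.complete.obs")
    rbar <- mean(R[lower.tri(R)])
    if (rbar <= 0) return(0)
    omega_composite(rep(sqrt(rbar), length(fi[[f]])))
  }, numeric(1))
}

#' Mean within-domain facet-score correlations
#'
#' @param scores a [score_scales()] result.
#' @param spec an [instrument_spec()].
#' @return named vector: mean pairwise Pearson correlation of facet scores
#'   within each domain.
#' @export
within_domain_corr <- function(scores, spec) {
  fd <- split(spec$facets, factor(spec$facet_to_domain, levels = spec$domains))
  vapply(spec$domains, function(d) {
    fs <- scores$facet[, fd[[d]], drop = FALSE]
    if (ncol(fs) < 2) return(NA_real_)
    sds <- apply(fs, 2, sd, na.rm = TRUE)
    if (any(sds == 0)) stop("zero-variance facet score in domain ", d)
    R <- cor(fs, use = "pairwise.complete.obs")
    mean(R[lower.tri(R)])
  }, numeric(1))
}
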