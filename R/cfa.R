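# DWLS estimation of hierarchical ordinal factor models on the polychoric
# correlation metric.  Thresholds are fixed in step 1 (polychoric module);
# the fit function is F = sum_j (s_j - sigma_j(theta))^2 / w_j over the
# non-redundant correlations, with w_j proportional to the asymptotic
# variance of s_j.  Both model modes have closed-form gradients, which is
# what makes the ant-colony search affordable.

#' Specify a hierarchical measurement model
#'
#' @param spec an [instrument_spec()] (possibly a subset, see
#'   [subset_instrument()]).
#' @param mode `"tau_equivalent"`: all unstandardized first- and second-order
#'   loadings fixed to 1; free parameters are the facet total variances and
#'   the domain covariance matrix.  `"congeneric"`: standardized loadings
#'   free at both levels with unit latent variances, domain correlations
#'   free.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(spec, mode = c("tau_equivalent", "congeneric")) {
  mode <- match.arg(mode)
  fidx <- match(spec$item_to_facet, spec$facets)
  didx <- match(spec$facet_to_domain, spec$domains)
  structure(list(spec = spec, mode = mode, fidx = fidx, didx = didx,
                 p = length(spec$items), nf = length(spec$facets),
                 nd = length(spec$domains)),
            class = "model_spec")
}

.npar_model <- function(model) {
  if (model$mode == "tau_equivalent")
    model$nf + model$nd * (model$nd + 1) / 2
  else
    model$p + model$nf + model$nd * (model$nd - 1) / 2
}

#' Model-implied correlation matrix
#'
#' Path-tracing over the second-order structure.  For `tau_equivalent`
#' parameters are `v` (facet total variances, named) and `Psi` (domain
#' covariance matrix); implied r within a facet is `v_f`, across facets it
#' is the relevant entry of `Psi`.  For `congeneric` parameters are
#' `lambda`, `gamma`, `Phi` (standardized; implied r =
#' `lambda_j lambda_k * corr(facet_j, facet_k)`).
#'
#' Item uniqueness is `1 - communality` by construction; a communality above
#' 1 is flagged in the `heywood` attribute, never silently clipped.
#'
#' @param params named list of parameters (see above).
#' @param model a [model_spec()].
#' @return implied correlation matrix with unit diagonal.
#' @export
implied_corr <- function(params, model) {
  p <- model$p
  if (model$mode == "tau_equivalent") {
    A <- params$Psi[model$didx, model$didx, drop = FALSE]
    diag(A) <- params$v
    Sig <- A[model$fidx, model$fidx, drop = FALSE]
    comm <- params$v[model$fidx]
  } else {
    Cf <- tcrossprod(params$gamma) * params$Phi[model$didx, model$didx, drop = FALSE]
    diag(Cf) <- 1
    Sig <- tcrossprod(params$lambda) * Cf[model$fidx, model$fidx, drop = FALSE]
    comm <- params$lambda^2
  }
  diag(Sig) <- 1
  dimnames(Sig) <- list(model$spec$items, model$spec$items)
  attr(Sig, "heywood") <- model$spec$items[comm > 1 + 1e-12]
  Sig
}

# pack/unpack parameter vectors -------------------------------------------

.pack_start <- function(model, loading_start = 0.7) {
  nd <- model$nd
  if (model$mode == "tau_equivalent") {
    list(par = c(rep(0.5, model$nf), rep(0.5, nd),
                 rep(0.1, nd * (nd - 1) / 2)),
         lower = c(rep(1e-6, model$nf), rep(1e-6, nd),
                   rep(-1.999, nd * (nd - 1) / 2)),
         upper = c(rep(2, model$nf), rep(2, nd), rep(1.999, nd * (nd - 1) / 2)))
  } else {
    list(par = c(rep(loading_start, model$p), rep(loading_start, model$nf),
                 rep(0.2, nd * (nd - 1) / 2)),
         lower = c(rep(-1.5, model$p), rep(-1.5, model$nf),
                   rep(-0.999, nd * (nd - 1) / 2)),
         upper = c(rep(1.5, model$p), rep(1.5, model$nf),
                   rep(0.999, nd * (nd - 1) / 2)))
  }
}

.unpack <- function(par, model) {
  nd <- model$nd
  if (model$mode == "tau_equivalent") {
    v <- par[seq_len(model$nf)]
    pd <- par[model$nf + seq_len(nd)]
    po <- par[model$nf + nd + seq_len(nd * (nd - 1) / 2)]
    Psi <- .vec_lt(po, nd, diag = pd)
    names(v) <- model$spec$facets
    dimnames(Psi) <- list(model$spec$domains, model$spec$domains)
    list(v = v, Psi = Psi)
  } else {
    lambda <- setNames(par[seq_len(model$p)], model$spec$items)
    gamma <- setNames(par[model$p + seq_len(model$nf)], model$spec$facets)
    po <- par[model$p + model$nf + seq_len(nd * (nd - 1) / 2)]
    Phi <- .vec_lt(po, nd, diag = 1)
    dimnames(Phi) <- list(model$spec$domains, model$spec$domains)
    list(lambda = lambda, gamma = gamma, Phi = Phi)
  }
}

# objective + analytic gradient over the correlation residuals.  All matrix
# expansions go through precomputed flat index vectors; the ant-colony
# search calls these thousands of times.
.dwls_fns <- function(model, S, Wt) {
  p <- model$p; nf <- model$nf; nd <- model$nd
  fidx <- model$fidx; didx <- model$didx
  P <- matrix(0, p, nf); P[cbind(seq_len(p), fidx)] <- 1
  Q <- matrix(0, nf, nd); Q[cbind(seq_len(nf), didx)] <- 1
  iW <- 1 / Wt; diag(iW) <- 0
  lt_ij <- which(lower.tri(diag(nd)), arr.ind = TRUE)
  lt_ij <- lt_ij[order(lt_ij[, 2], lt_ij[, 1]), , drop = FALSE]
  ctx <- list(
    p = p, nf = nf, nd = nd, ndo = nrow(lt_ij),
    P = P, Q = Q,
    iWv = as.vector(iW), Sv = as.vector(S),
    lt = which(lower.tri(diag(nd))),
    IA = as.vector(outer(didx, didx, function(i, j) i + (j - 1L) * nd)),
    IF_ = as.vector(outer(fidx, fidx, function(i, j) i + (j - 1L) * nf)),
    dgF = seq(1L, nf * nf, by = nf + 1L),
    dgP = seq(1L, p * p, by = p + 1L),
    dgD = seq(1L, nd * nd, by = nd + 1L),
    sym1 = lt_ij[, 1] + (lt_ij[, 2] - 1L) * nd,
    sym2 = lt_ij[, 2] + (lt_ij[, 1] - 1L) * nd,
    psi_tmpl = numeric(nd * nd)
  )
  if (model$mode == "tau_equivalent")
    list(fn = .dwls_fn_te, gr = .dwls_gr_te, ctx = ctx)
  else
    list(fn = .dwls_fn_cg, gr = .dwls_gr_cg, ctx = ctx)
}

# the four hot functions live at top level so they are byte-compiled once
.dwls_sig_te <- function(par, ctx) {
  psi <- ctx$psi_tmpl
  psi[ctx$sym1] <- psi[ctx$sym2] <- par[ctx$nf + ctx$nd + seq_len(ctx$ndo)]
  psi[ctx$dgD] <- par[ctx$nf + seq_len(ctx$nd)]
  A <- psi[ctx$IA]; A[ctx$dgF] <- par[seq_len(ctx$nf)]
  Sig <- A[ctx$IF_]; Sig[ctx$dgP] <- 1
  Sig
}

.dwls_fn_te <- function(par, ctx) {
  r <- ctx$Sv - .dwls_sig_te(par, ctx)
  sum(r * r * ctx$iWv) / 2
}

.dwls_gr_te <- function(par, ctx) {
  Rsd <- matrix((ctx$Sv - .dwls_sig_te(par, ctx)) * ctx$iWv, ctx$p, ctx$p)
  B <- crossprod(ctx$P, Rsd) %*% ctx$P
  Gd <- crossprod(ctx$Q, B) %*% ctx$Q
  within <- as.vector(crossprod(ctx$Q, diag(B)))  # sum of B_ff per domain
  c(-diag(B), -(diag(Gd) - within), -2 * Gd[ctx$lt])
}

.dwls_fn_cg <- function(par, ctx) {
  lam <- par[seq_len(ctx$p)]; gam <- par[ctx$p + seq_len(ctx$nf)]
  psi <- ctx$psi_tmpl
  psi[ctx$sym1] <- psi[ctx$sym2] <- par[ctx$p + ctx$nf + seq_len(ctx$ndo)]
  psi[ctx$dgD] <- 1
  Cf <- tcrossprod(gam) * psi[ctx$IA]; Cf[ctx$dgF] <- 1
  Sig <- tcrossprod(lam) * Cf[ctx$IF_]; Sig[ctx$dgP] <- 1
  r <- ctx$Sv - as.vector(Sig)
  sum(r * r * ctx$iWv) / 2
}

.dwls_gr_cg <- function(par, ctx) {
  lam <- par[seq_len(ctx$p)]; gam <- par[ctx$p + seq_len(ctx$nf)]
  psi <- ctx$psi_tmpl
  psi[ctx$sym1] <- psi[ctx$sym2] <- par[ctx$p + ctx$nf + seq_len(ctx$ndo)]
  psi[ctx$dgD] <- 1
  PhiF <- matrix(psi[ctx$IA], ctx$nf, ctx$nf)
  Cf <- tcrossprod(gam) * PhiF; Cf[ctx$dgF] <- 1
  A <- matrix(as.vector(Cf)[ctx$IF_], ctx$p, ctx$p)
  Sig <- tcrossprod(lam) * A; Sig[ctx$dgP] <- 1
  Rsd <- matrix((ctx$Sv - as.vector(Sig)) * ctx$iWv, ctx$p, ctx$p)
  g_lam <- -2 * as.vector((Rsd * A) %*% lam)
  B <- crossprod(ctx$P, Rsd * tcrossprod(lam)) %*% ctx$P
  M <- B * PhiF; diag(M) <- 0
  g_gam <- -2 * as.vector(M %*% gam)
  Gd <- crossprod(ctx$Q, B * tcrossprod(gam)) %*% ctx$Q
  c(g_lam, g_gam, -2 * Gd[ctx$lt])
}

# Jacobian of the implied lower-triangle correlations with respect to the
# free parameters, rows in which(lower.tri) (column-major) order.  Needed
# only for the mean-scaling factor, so it is built once per reported fit.
.dwls_jacobian <- function(model, params) {
  p <- model$p
  idx <- which(lower.tri(diag(p)), arr.ind = TRUE)
  j <- idx[, 1]; k <- idx[, 2]
  fj <- model$fidx[j]; fk <- model$fidx[k]
  dj <- model$didx[fj]; dk <- model$didx[fk]
  nd <- model$nd; nf <- model$nf; ndo <- nd * (nd - 1) / 2
  pos <- matrix(0L, nd, nd)
  pos[lower.tri(pos)] <- seq_len(ndo)
  pos <- pos + t(pos)
  N <- nrow(idx)
  if (model$mode == "tau_equivalent") {
    D <- matrix(0, N, nf + nd + ndo)
    same_f <- fj == fk
    D[cbind(which(same_f), fj[same_f])] <- 1
    samed <- !same_f & dj == dk
    D[cbind(which(samed), nf + dj[samed])] <- 1
    diffd <- !same_f & dj != dk
    D[cbind(which(diffd), nf + nd + pos[cbind(dj[diffd], dk[diffd])])] <- 1
  } else {
    lam <- params$lambda; gam <- params$gamma; Phi <- params$Phi
    D <- matrix(0, N, p + nf + ndo)
    Arow <- ifelse(fj == fk, 1, gam[fj] * gam[fk] * Phi[cbind(dj, dk)])
    D[cbind(seq_len(N), j)] <- lam[k] * Arow
    D[cbind(seq_len(N), k)] <- lam[j] * Arow
    cr <- which(fj != fk)
    ll <- lam[j[cr]] * lam[k[cr]]
    D[cbind(cr, p + fj[cr])] <- ll * gam[fk[cr]] * Phi[cbind(dj[cr], dk[cr])]
    D[cbind(cr, p + fk[cr])] <- ll * gam[fj[cr]] * Phi[cbind(dj[cr], dk[cr])]
    dd <- which(fj != fk & dj != dk)
    D[cbind(dd, p + nf + pos[cbind(dj[dd], dk[dd])])] <-
      lam[j[dd]] * lam[k[dd]] * gam[fj[dd]] * gam[fk[dd]]
  }
  D
}

# mean-scaling ingredients from jackknife replicates: tr(U Gamma_hat) with
# U = V - V D (D'VD)^-1 D'V, V = diag(1/w), Gamma_hat the jackknife
# covariance of the lower-triangle correlations.
.scaling_trace <- function(model, params, W, reps) {
  wlt <- W[lower.tri(W)]
  Vd <- 1 / pmax(wlt, 1e-8)
  Dm <- sweep(reps, 2, colMeans(reps))
  G <- nrow(reps)
  kap <- (G - 1) / G
  trVG <- sum(kap * colSums(Dm^2) * Vd)
  Dj <- .dwls_jacobian(model, params)
  A <- crossprod(Dj, Vd * Dj)
  Z <- Dm %*% (Vd * Dj)
  corr <- kap * sum(diag(solve(A, crossprod(Z))))
  list(trUG = trVG - corr, trVG = trVG)
}

#' Fit a model by diagonally weighted least squares
#'
#' Minimizes the weighted squared difference between the sample polychoric
#' correlations and the model-implied correlations with a bounded
#' quasi-Newton optimizer and analytic gradients.  Starting values are fixed
#' (loadings 0.7, variances 0.5, domain correlations 0.2) so fits are
#' deterministic; one fallback restart at loadings 0.4 is tried on
#' non-convergence.  Non-convergence yields a flagged result, not an error.
#'
#' @param poly a [polychoric_matrix()] result (or a list with `R` and `n`).
#' @param model a [model_spec()]; its items must be present in `poly$R`.
#' @param weights matrix of asymptotic variances of the correlations, as
#'   from [acov_diag()]; `NULL` uses the Pearson-style plug-in
#'   `(1 - r^2)^2 / n`.
#' @param compute_indices also compute scaled chi-square and fit indices
#'   (default TRUE).
#' @param rmsea_ci compute the RMSEA 90% confidence interval (two root
#'   finds; skipped by the selection search, which only needs the point
#'   statistics).
#' @return object of class `fit_result`: parameter estimates, discrepancy
#'   `F`, `chisq`/`df`/`scaling`/`scaled_chisq`, `cfi`, `rmsea` (+ 90% CI),
#'   `srmr`, standardized solution, Heywood flags, convergence record.
#' @export
fit_dwls <- function(poly, model, weights = NULL, compute_indices = TRUE,
                     rmsea_ci = TRUE) {
  items <- model$spec$items
  S <- poly$R[items, items, drop = FALSE]
  n <- poly$n
  if (is.null(weights)) {
    W <- (1 - S^2)^2 / n
  } else {
    W <- weights[items, items, drop = FALSE]
  }
  W <- pmax(W, 1e-8)
  Wt <- (n - 1) * W             # order-1 weights: (n-1) * Var(s)
  diag(Wt) <- Inf
  fns <- .dwls_fns(model, S, Wt)
  st <- .pack_start(model)
  opt <- optim(st$par, fns$fn, fns$gr, ctx = fns$ctx, method = "L-BFGS-B",
               lower = st$lower, upper = st$upper,
               control = list(maxit = 500, factr = 1e7))
  if (opt$convergence != 0) {
    st2 <- .pack_start(model, loading_start = 0.4)
    opt2 <- optim(st2$par, fns$fn, fns$gr, ctx = fns$ctx, method = "L-BFGS-B",
                  lower = st$lower, upper = st$upper,
                  control = list(maxit = 500, factr = 1e7))
    if (opt2$value < opt$value || opt2$convergence == 0) opt <- opt2
  }
  if (opt$value < 1e-6) {
    # near-exact fit: polish to machine precision so the perfect-fit
    # contract (F ~ 0 on model-implied input) holds sharply
    opt3 <- optim(opt$par, fns$fn, fns$gr, ctx = fns$ctx, method = "L-BFGS-B",
                  lower = st$lower, upper = st$upper,
                  control = list(maxit = 200, factr = 10))
    if (opt3$value < opt$value) opt3 -> opt
  }
  params <- .unpack(opt$par, model)
  Sig <- implied_corr(params, model)
  nstat <- model$p * (model$p - 1) / 2
  npar <- .npar_model(model)
  df <- nstat - npar
  heywood <- detect_heywood(params, model)
  std <- standardized_solution(params, model)
  out <- list(params = params, model = model, F = opt$value,
              n = n, nstat = nstat, npar = npar, df = df,
              implied = Sig, S = S, W = W,
              converged = opt$convergence == 0,
              heywood = heywood, std = std)
  if (compute_indices) {
    reps <- attr(weights, "replicates")
    if (!is.null(reps) && !identical(attr(weights, "rep_items"), items))
      reps <- NULL                       # replicates from a different item set
    Fb <- fns$fn(.null_par(model), fns$ctx)
    chisq_b <- (n - 1) * Fb
    df_b <- nstat
    if (!is.null(reps) && df > 0) {
      tr_ <- .scaling_trace(model, params, W, reps)
      sc <- scaled_chisq(opt$value, n, df, trUG = tr_$trUG)
      chisq_b <- chisq_b / (tr_$trVG / nstat)   # baseline scaled by its own factor
    } else {
      sc <- scaled_chisq(opt$value, n, df)
    }
    fi <- fit_indices(sc$scaled, df, chisq_b, df_b, n, S, Sig, ci = rmsea_ci)
    out <- c(out, sc, fi, list(chisq_baseline = chisq_b, df_baseline = df_b))
  }
  structure(out, class = "fit_result")
}

# parameter vector for the independence (zero-correlation) baseline model
.null_par <- function(model) {
  if (model$mode == "tau_equivalent") {
    nd <- model$nd
    c(rep(0, model$nf), rep(0, nd), rep(0, nd * (nd - 1) / 2))
  } else {
    rep(0, .npar_model(model))
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): chisq(%d) = %.2f, CFI = %.3f, RMSEA = %.3f [%.3f, %.3f], SRMR = %.3f%s%s\n",
              x$model$mode, x$df, x$scaled_chisq %||% NA, x$cfi %||% NA,
              x$rmsea %||% NA, x$rmsea_ci[1] %||% NA, x$rmsea_ci[2] %||% NA,
              x$srmr %||% NA,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (length(x$heywood)) paste0(" [Heywood: ",
                                            paste(x$heywood, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Mean-scaled chi-square statistic
#'
#' `T = (n - 1) F` with scaling factor `c = tr(U Gamma) / df`, `Gamma` the
#' asymptotic covariance of the correlations and `U` the residual-weight
#' projection.  Under the diagonal `Gamma` consistent with the fitting
#' weights the factor is exactly 1 and the mean-scaled statistic equals the
#' unscaled one; calibration (mean `T/df` near 1 for well-specified models)
#' is checked by simulation in the test suite.  A saturated model
#' (`df = 0`) has scaled chi-square 0 by convention.
#'
#' @param F minimized discrepancy.
#' @param n sample size.
#' @param df model degrees of freedom.
#' @param trUG optional `tr(U Gamma)` for a non-default `Gamma`.
#' @return list `chisq`, `scaling`, `scaled_chisq`.
#' @export
scaled_chisq <- function(F, n, df, trUG = NULL) {
  T_ <- (n - 1) * F
  if (df <= 0) return(list(chisq = T_, scaling = 1, scaled_chisq = 0))
  c_ <- if (is.null(trUG)) 1 else trUG / df
  list(chisq = T_, scaling = c_, scaled_chisq = T_ / c_)
}

#' Fit indices from scaled chi-squares
#'
#' CFI from the independence baseline, RMSEA with 90% CI by inversion of the
#' noncentral chi-square distribution, SRMR as the root mean squared
#' correlation residual over the non-redundant entries.
#'
#' @param chisq scaled chi-square of the target model.
#' @param df its degrees of freedom.
#' @param chisq_b,df_b baseline (independence) model values.
#' @param n sample size.
#' @param S sample correlation matrix.
#' @param Sigma implied correlation matrix.
#' @param ci compute the RMSEA confidence interval (default TRUE).
#' @return list `cfi`, `rmsea`, `rmsea_ci`, `srmr`.
#' @export
fit_indices <- function(chisq, df, chisq_b, df_b, n, S, Sigma, ci = TRUE) {
  if (df_b < df) stop("baseline df smaller than model df")
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- sqrt(num / (df * (n - 1)))
  ci <- if (ci) .rmsea_ci(chisq, df, n) else c(NA_real_, NA_real_)
  resid <- (S - Sigma)[lower.tri(S)]
  srmr <- sqrt(mean(resid^2))
  list(cfi = cfi, rmsea = rmsea, rmsea_ci = ci, srmr = srmr)
}

.rmsea_ci <- function(T_, df, n, level = 0.90) {
  a <- (1 - level) / 2
  f <- function(ncp, q) pchisq(T_, df, ncp = ncp) - q
  up <- max(T_ * 2, df + 10)
  lo <- if (f(0, 1 - a) < 0) 0 else
    uniroot(f, c(0, up), q = 1 - a, tol = 1e-8, extendInt = "downX")$root
  hi <- if (f(0, a) < 0) 0 else
    uniroot(f, c(0, up), q = a, tol = 1e-8, extendInt = "downX")$root
  c(sqrt(max(lo, 0) / (df * (n - 1))), sqrt(max(hi, 0) / (df * (n - 1))))
}

#' Standardized solution
#'
#' In `tau_equivalent` mode the standardized item loading on its facet is
#' `sqrt(v_f)` and the standardized facet loading on its domain is
#' `sqrt(Psi_dd / v_f)`, i.e. the rescaling that sets all latent variances
#' to 1; domain correlations are `cov2cor(Psi)`.  In `congeneric` mode the
#' parameterization is already standardized.  Parameters implying a negative
#' variance are flagged and their standardized value set `NA`.
#'
#' @param params parameter list (see [implied_corr()]).
#' @param model a [model_spec()].
#' @return list `loading_item` (per item), `loading_facet` (per facet),
#'   `domain_corr`, `uniqueness` (per item), `disturbance` (per facet).
#' @export
standardized_solution <- function(params, model) {
  spec <- model$spec
  if (model$mode == "tau_equivalent") {
    v <- params$v
    psi_d <- diag(params$Psi)
    li <- sqrt(pmax(v, 0))[model$fidx]
    lf <- sqrt(pmax(psi_d[model$didx], 0) / v)
    uni <- 1 - v[model$fidx]
    dist <- v - psi_d[model$didx]
    dc <- params$Psi / tcrossprod(sqrt(pmax(psi_d, 1e-12)))
    li[v[model$fidx] < 0] <- NA
    lf[dist < 0] <- NA            # negative disturbance: no admissible value
  } else {
    li <- params$lambda
    lf <- params$gamma
    uni <- 1 - params$lambda^2
    dist <- 1 - params$gamma^2
    dc <- params$Phi
  }
  list(loading_item = setNames(as.numeric(li), spec$items),
       loading_facet = setNames(as.numeric(lf), spec$facets),
       domain_corr = dc,
       uniqueness = setNames(as.numeric(uni), spec$items),
       disturbance = setNames(as.numeric(dist), spec$facets))
}

#' Detect Heywood cases
#'
#' Flags negative implied variances (item uniqueness, facet disturbance,
#' domain variance), standardized loadings above 1, and latent correlations
#' outside \[-1, 1\].
#'
#' @param params parameter list.
#' @param model a [model_spec()].
#' @return character vector naming the offending parameters (empty if none).
#' @export
detect_heywood <- function(params, model) {
  spec <- model$spec
  flags <- character(0)
  if (model$mode == "tau_equivalent") {
    v <- params$v; psi_d <- diag(params$Psi)
    bad_u <- spec$facets[v > 1 + 1e-8]
    if (length(bad_u)) flags <- c(flags, paste0("uniqueness<0:", bad_u))
    dist <- v - psi_d[model$didx]
    bad_z <- spec$facets[dist < -1e-8]
    if (length(bad_z)) flags <- c(flags, paste0("disturbance<0:", bad_z))
    bad_pd <- spec$domains[psi_d <= 0]
    if (length(bad_pd)) flags <- c(flags, paste0("domain_var<=0:", bad_pd))
    dc <- params$Psi / tcrossprod(sqrt(pmax(psi_d, 1e-12)))
    diag(dc) <- 0
    if (any(abs(dc) > 1 + 1e-8)) {
      ij <- which(abs(dc) > 1 + 1e-8, arr.ind = TRUE)
      ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
      flags <- c(flags, paste0("latent_corr>1:", spec$domains[ij[, 1]], "-",
                               spec$domains[ij[, 2]]))
    }
  } else {
    bad_l <- spec$items[abs(params$lambda) > 1 + 1e-8]
    if (length(bad_l)) flags <- c(flags, paste0("loading>1:", bad_l))
    bad_g <- spec$facets[abs(params$gamma) > 1 + 1e-8]
    if (length(bad_g)) flags <- c(flags, paste0("loading>1:", bad_g))
    dc <- params$Phi; diag(dc) <- 0
    if (any(abs(dc) > 1 + 1e-8)) flags <- c(flags, "latent_corr>1")
  }
  flags
}

#' Polychorics, weights, and DWLS fit in one call
#'
#' @param resp response data.
#' @param spec instrument spec of the items to fit.
#' @param mode model mode (see [model_spec()]).
#' @param jackknife_groups blocks for [acov_diag()]; `0` uses the plug-in
#'   weights.
#' @return a `fit_result`.
#' @export
fit_cfa <- function(resp, spec, mode = "congeneric", jackknife_groups = 30L) {
  poly <- polychoric_matrix(resp, spec)
  W <- if (jackknife_groups > 0)
    acov_diag(resp, spec, groups = jackknife_groups, return_replicates = TRUE)
  else NULL
  fit_dwls(poly, model_spec(spec, mode), weights = W)
}
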