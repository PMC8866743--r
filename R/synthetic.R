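# Probit graded-response generator: multivariate-normal domain factors,
# facet factors loading on domains, item latents loading on facets,
# discretized by fixed increasing thresholds.  Matches the distributional
# assumption under which polychoric/DWLS estimation is consistent, so
# parameter recovery is a self-consistency check of the whole pipeline.

.pid5_facets <- function() {
  # 17 facets in 6 domains; pool sizes of the full item pool per facet
  list(
    domains = c(
      NegativeAffectivity = "NegativeAffectivity",
      Detachment = "Detachment",
      Antagonism = "Antagonism",
      Disinhibition = "Disinhibition",
      Psychoticism = "Psychoticism",
      Anankastia = "Anankastia"
    ),
    facet_to_domain = c(
      EmotionalLability = "NegativeAffectivity",
      Anxiousness = "NegativeAffectivity",
      SeparationInsecurity = "NegativeAffectivity",
      Withdrawal = "Detachment",
      Anhedonia = "Detachment",
      IntimacyAvoidance = "Detachment",
      Manipulativeness = "Antagonism",
      Deceitfulness = "Antagonism",
      Grandiosity = "Antagonism",
      Irresponsibility = "Disinhibition",
      Impulsivity = "Disinhibition",
      Distractibility = "Disinhibition",
      UnusualBeliefs = "Psychoticism",
      Eccentricity = "Psychoticism",
      PerceptualDysregulation = "Psychoticism",
      Perseveration = "Anankastia",
      RigidPerfectionism = "Anankastia"
    ),
    pool_sizes = c(7L, 9L, 7L, 10L, 7L, 6L, 5L, 10L, 6L, 7L, 6L, 9L, 8L, 13L, 12L, 9L, 10L)
  )
}

.build_spec <- function(items_per_facet) {
  s <- .pid5_facets()
  facets <- names(s$facet_to_domain)
  i2f <- character(0)
  for (k in seq_along(facets)) {
    np <- items_per_facet[k]
    its <- paste0(facets[k], "_", seq_len(np))
    i2f <- c(i2f, setNames(rep(facets[k], np), its))
  }
  instrument_spec(i2f, s$facet_to_domain, n_categories = 4L)
}

#' Construct a generator configuration
#'
#' @param spec an [instrument_spec()].
#' @param Phi domain correlation matrix (unit diagonal, positive definite).
#' @param gamma named vector of standardized facet-on-domain loadings,
#'   one per facet, in (0, 1].
#' @param lambda named vector of standardized item-on-facet loadings in
#'   \[0, 1\].
#' @param tau matrix of probit thresholds, one row per item, strictly
#'   increasing, `n_categories - 1` columns.
#' @param n respondents in the reference group.
#' @param groups named list of additional groups; each entry a list with
#'   `n` and optional per-item `tau_shift`, per-item `lambda_scale`,
#'   per-domain `domain_shift`.
#' @param careless list with `fraction` and `kind` ("longstring" or
#'   "random"); applied by [generate_responses()] after drawing responses.
#' @param missing_rate probability that each observed cell is set missing.
#' @param criteria named list of criterion variables, each a list with a
#'   named `coef` vector over domains and `noise_sd`.
#' @return object of class `gen_config`.
#' @export
gen_config <- function(spec, Phi, gamma, lambda, tau, n,
                       groups = list(),
                       careless = list(fraction = 0, kind = "random"),
                       missing_rate = 0,
                       criteria = list()) {
  D <- length(spec$domains)
  stopifnot(is.matrix(Phi), nrow(Phi) == D, ncol(Phi) == D)
  if (max(abs(diag(Phi) - 1)) > 1e-12) stop("Phi must have unit diagonal")
  if (max(abs(Phi - t(Phi))) > 1e-12) stop("Phi must be symmetric")
  if (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Phi is not positive definite")
  dimnames(Phi) <- list(spec$domains, spec$domains)
  gamma <- gamma[spec$facets]
  lambda <- lambda[spec$items]
  if (anyNA(gamma) || any(gamma <= 0 | gamma > 1)) stop("gamma must be in (0, 1] for every facet")
  if (anyNA(lambda) || any(lambda < 0 | lambda > 1)) stop("lambda must be in [0, 1] for every item")
  tau <- as.matrix(tau)
  if (nrow(tau) == 1 && length(spec$items) > 1)
    tau <- matrix(tau, length(spec$items), ncol(tau), byrow = TRUE)
  rownames(tau) <- spec$items
  if (ncol(tau) != spec$n_categories - 1) stop("tau needs n_categories - 1 columns")
  if (any(apply(tau, 1, function(z) any(diff(z) <= 0)))) stop("thresholds must be strictly increasing")
  for (g in names(groups)) groups[[g]] <- .validate_group(groups[[g]], spec, lambda, tau)
  structure(list(spec = spec, Phi = Phi, gamma = gamma, lambda = lambda,
                 tau = tau, n = as.integer(n), groups = groups,
                 careless = careless, missing_rate = missing_rate,
                 criteria = criteria),
            class = "gen_config")
}

.validate_group <- function(g, spec, lambda, tau) {
  p <- length(spec$items)
  g$n <- as.integer(g$n %||% stop("group needs n"))
  ts <- g$tau_shift %||% 0
  if (length(ts) == 1) ts <- setNames(rep(ts, p), spec$items)
  full <- setNames(rep(0, p), spec$items)
  full[names(ts)] <- ts
  g$tau_shift <- full
  ls <- g$lambda_scale %||% 1
  if (length(ls) == 1) ls <- setNames(rep(ls, p), spec$items)
  fl <- setNames(rep(1, p), spec$items)
  fl[names(ls)] <- ls
  g$lambda_scale <- fl
  lam <- lambda * g$lambda_scale
  if (any(lam <= 0 | lam > 1)) stop("group loading outside (0, 1]")
  ds <- g$domain_shift %||% 0
  if (length(ds) == 1) ds <- setNames(rep(ds, length(spec$domains)), spec$domains)
  fd <- setNames(rep(0, length(spec$domains)), spec$domains)
  fd[names(ds)] <- ds
  g$domain_shift <- fd
  g
}

#' Default generator configurations
#'
#' `pid5bfplus` is a 34-item, 17-facet, 6-domain short-form instrument with
#' standardized loadings of .8 at both levels, mean inter-domain correlation
#' .32, 4 response categories, and mildly right-skewed thresholds
#' (-0.2, 0.6, 1.4) emulating maladaptive-trait response distributions.
#' `pid5pool` is the matching 141-item pool (facet pool sizes
#' 7,9,7,10,7,6,5,10,6,7,6,9,8,13,12,9,10) with two planted high-loading
#' items (lambda = .8) per facet among lower-loading distractors
#' (lambda = .4).  `custom` passes through a caller-supplied spec.
#'
#' @param template one of "pid5bfplus", "pid5pool", "custom".
#' @param n number of respondents.
#' @param seed default generation seed recorded in the config.
#' @param spec for `template = "custom"`, the instrument spec to use.
#' @param ... overrides forwarded to [gen_config()] (`Phi`, `gamma`,
#'   `lambda`, `tau`, `groups`, `careless`, `missing_rate`, `criteria`).
#' @return a `gen_config` (with a `seed` attribute used as the default by
#'   [generate_responses()]).
#' @export
make_default_config <- function(template = c("pid5bfplus", "pid5pool", "custom"),
                                n = 2000, seed = 1L, spec = NULL, ...) {
  template <- match.arg(template)
  if (template == "pid5bfplus") {
    spec <- .build_spec(rep(2L, 17L))
    lambda <- setNames(rep(0.8, length(spec$items)), spec$items)
  } else if (template == "pid5pool") {
    spec <- .build_spec(.pid5_facets()$pool_sizes)
    fi <- facet_items(spec)
    lambda <- setNames(rep(0.4, length(spec$items)), spec$items)
    for (f in names(fi)) lambda[fi[[f]][1:2]] <- 0.8  # planted high-loading pair
  } else {
    if (is.null(spec)) stop("template 'custom' requires a spec")
    lambda <- setNames(rep(0.8, length(spec$items)), spec$items)
  }
  D <- length(spec$domains)
  Phi <- matrix(0.32, D, D); diag(Phi) <- 1
  defaults <- list(
    spec = spec, Phi = Phi,
    gamma = setNames(rep(0.8, length(spec$facets)), spec$facets),
    lambda = lambda,
    tau = matrix(rep(c(-0.2, 0.6, 1.4), each = length(spec$items)),
                 length(spec$items), 3, dimnames = list(spec$items, NULL)),
    n = n
  )
  args <- utils::modifyList(defaults, list(...))
  cfg <- do.call(gen_config, args)
  attr(cfg, "seed") <- as.integer(seed)
  cfg
}

#' Implied latent (polychoric) item correlation matrix of a configuration
#'
#' Path-tracing on the generator's own parameters: the latent correlation of
#' items i, j equals `lambda_i * lambda_j * corr(facet_i, facet_j)` with
#' `corr(f, g) = gamma_f * gamma_g * Phi[d(f), d(g)]` for distinct facets and
#' 1 within a facet.  Serves as the population oracle in recovery tests.
#'
#' @param config a `gen_config`.
#' @param group optional group label whose overrides apply.
#' @return item x item correlation matrix.
#' @export
implied_item_corr <- function(config, group = NULL) {
  spec <- config$spec
  lam <- config$lambda
  if (!is.null(group)) lam <- lam * config$groups[[group]]$lambda_scale
  gam <- config$gamma
  fidx <- match(spec$item_to_facet, spec$facets)
  didx <- match(spec$facet_to_domain, spec$domains)
  Cf <- tcrossprod(gam) * config$Phi[didx, didx, drop = FALSE]
  diag(Cf) <- 1
  R <- tcrossprod(lam) * Cf[fidx, fidx, drop = FALSE]
  diag(R) <- 1
  dimnames(R) <- list(spec$items, spec$items)
  R
}

#' Generate ordinal responses from a configuration
#'
#' Domain factors are multivariate normal with correlation `Phi`; facet
#' factors load `gamma` on their domain with disturbance variance
#' `1 - gamma^2`; item latents load `lambda` on their facet with uniqueness
#' `1 - lambda^2`; the observed response is the count of the item's
#' thresholds lying below the latent value.  Groups are generated
#' sequentially with their overrides applied, so the same seed always yields
#' bitwise-identical output.
#'
#' @param config a `gen_config`.
#' @param seed integer seed (defaults to the seed recorded in the config).
#' @return list with `resp` (data frame: `id`, optional `group`, criterion
#'   columns `crit_*`, optional `careless` flag, then item columns) and
#'   `truth` (domain and facet factor scores plus the parameters used).
#' @export
generate_responses <- function(config, seed = attr(config, "seed")) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  spec <- config$spec
  grp_defs <- c(list(.ref = list(n = config$n,
                                 tau_shift = setNames(rep(0, length(spec$items)), spec$items),
                                 lambda_scale = setNames(rep(1, length(spec$items)), spec$items),
                                 domain_shift = setNames(rep(0, length(spec$domains)), spec$domains))),
                config$groups)
  blocks <- list(); truths <- list()
  for (gname in names(grp_defs)) {
    g <- grp_defs[[gname]]
    out <- .generate_block(config, g)
    if (length(config$groups) > 0)
      out$resp <- cbind(group = if (gname == ".ref") "reference" else gname,
                        out$resp, stringsAsFactors = FALSE)
    blocks[[gname]] <- out$resp
    truths[[gname]] <- out$truth
  }
  resp <- do.call(rbind, blocks)
  resp <- cbind(id = sprintf("r%05d", seq_len(nrow(resp))), resp,
                stringsAsFactors = FALSE)
  rownames(resp) <- NULL
  if (config$careless$fraction > 0)
    resp <- inject_careless(resp, spec, config$careless$fraction,
                            config$careless$kind,
                            seed = sample.int(.Machine$integer.max - 1L, 1))
  if (config$missing_rate > 0)
    resp <- inject_missing(resp, spec, config$missing_rate,
                           seed = sample.int(.Machine$integer.max - 1L, 1))
  list(resp = resp, truth = truths)
}

.generate_block <- function(config, g) {
  spec <- config$spec
  n <- g$n
  D <- length(spec$domains); Fn <- length(spec$facets); p <- length(spec$items)
  Z <- matrix(rnorm(n * D), n, D) %*% chol(config$Phi)
  Z <- sweep(Z, 2, g$domain_shift, "+")
  colnames(Z) <- spec$domains
  didx <- match(spec$facet_to_domain, spec$domains)
  gam <- config$gamma
  Ff <- Z[, didx, drop = FALSE] * rep(gam, each = n) +
    matrix(rnorm(n * Fn), n, Fn) * rep(sqrt(1 - gam^2), each = n)
  colnames(Ff) <- spec$facets
  fidx <- match(spec$item_to_facet, spec$facets)
  lam <- config$lambda * g$lambda_scale
  Y <- Ff[, fidx, drop = FALSE] * rep(lam, each = n) +
    matrix(rnorm(n * p), n, p) * rep(sqrt(1 - lam^2), each = n)
  tau <- config$tau + g$tau_shift
  X <- matrix(0L, n, p, dimnames = list(NULL, spec$items))
  for (j in seq_len(p)) X[, j] <- findInterval(Y[, j], tau[j, ])
  resp <- as.data.frame(X)
  for (cname in names(config$criteria)) {
    cr <- config$criteria[[cname]]
    coef <- setNames(rep(0, D), spec$domains)
    coef[names(cr$coef)] <- cr$coef
    resp[[paste0("crit_", cname)]] <- as.numeric(Z %*% coef + rnorm(n, 0, cr$noise_sd %||% 1))
  }
  resp <- resp[, c(grep("^crit_", names(resp), value = TRUE), spec$items)]
  list(resp = resp, truth = list(domain = Z, facet = Ff,
                                 lambda = lam, gamma = gam, tau = tau))
}

#' Add a non-invariant group to a configuration
#'
#' Shifts the group's thresholds by `threshold_shift` (higher thresholds push
#' responses toward lower categories) and/or scales its loadings by
#' `1 + loading_delta`, on the given items.
#'
#' @param config a `gen_config`.
#' @param group group label (created if absent).
#' @param threshold_shift added to every threshold of the affected items.
#' @param loading_delta loadings multiplied by `1 + loading_delta`.
#' @param items item IDs to affect (default: all items).
#' @param n group size (defaults to the reference group's n).
#' @return updated `gen_config`.
#' @export
inject_noninvariance <- function(config, group, threshold_shift = 0,
                                 loading_delta = 0, items = NULL,
                                 n = config$n) {
  spec <- config$spec
  items <- items %||% spec$items
  stopifnot(all(items %in% spec$items))
  g <- config$groups[[group]] %||% list(n = n)
  g$n <- g$n %||% n
  ts <- g$tau_shift %||% setNames(rep(0, length(spec$items)), spec$items)
  ts[items] <- ts[items] + threshold_shift
  g$tau_shift <- ts
  ls <- g$lambda_scale %||% setNames(rep(1, length(spec$items)), spec$items)
  ls[items] <- ls[items] * (1 + loading_delta)
  g$lambda_scale <- ls
  config$groups[[group]] <- .validate_group(g, spec, config$lambda, config$tau)
  seed_keep <- attr(config, "seed")
  cfg <- gen_config(spec, config$Phi, config$gamma, config$lambda, config$tau,
                    config$n, config$groups, config$careless,
                    config$missing_rate, config$criteria)
  attr(cfg, "seed") <- seed_keep
  cfg
}

#' Replace a random subset of respondents with careless response patterns
#'
#' `longstring` rows answer one constant category throughout; `random` rows
#' answer uniformly at random.  Affected rows are marked in a logical
#' `careless` column.
#'
#' @param resp response data frame.
#' @param spec an [instrument_spec()] (identifies item columns).
#' @param fraction proportion of respondents to replace.
#' @param kind "longstring" or "random".
#' @param seed integer seed.
#' @return modified data frame with a `careless` column.
#' @export
inject_careless <- function(resp, spec, fraction, kind = c("longstring", "random"),
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(fraction >= 0, fraction <= 1)
  if (!"careless" %in% names(resp)) resp$careless <- FALSE
  if (fraction == 0) return(resp)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(resp); p <- length(spec$items)
  k <- round(fraction * n)
  if (k == 0) return(resp)
  rows <- sample.int(n, k)
  K <- spec$n_categories
  for (r in rows) {
    vals <- if (kind == "longstring") rep(sample.int(K, 1) - 1L, p)
            else sample.int(K, p, replace = TRUE) - 1L
    resp[r, spec$items] <- as.list(vals)
  }
  resp$careless[rows] <- TRUE
  resp
}

#' Set observed cells missing completely at random
#'
#' @param resp response data frame.
#' @param spec an [instrument_spec()].
#' @param rate per-cell missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return modified data frame.
#' @export
inject_missing <- function(resp, spec, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(resp)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  X <- as.matrix(resp[, spec$items])
  drop <- matrix(runif(length(X)) < rate, nrow(X), ncol(X)) & !is.na(X)
  X[drop] <- NA
  resp[, spec$items] <- as.data.frame(X)
  resp
}
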