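# Shared fixtures, all built in code.

# 4 facets with pools {4,4,5,5} in 2 domains; two planted high-loading items
# per facet among weaker distractors.
tiny_pool <- function() {
  i2f <- c(setNames(rep("f1", 4), paste0("f1_", 1:4)),
           setNames(rep("f2", 4), paste0("f2_", 1:4)),
           setNames(rep("f3", 5), paste0("f3_", 1:5)),
           setNames(rep("f4", 5), paste0("f4_", 1:5)))
  instrument_spec(i2f, c(f1 = "d1", f2 = "d1", f3 = "d2", f4 = "d2"))
}

tiny_pool_config <- function(n = 1500, seed = 3) {
  pool <- tiny_pool()
  lam <- setNames(rep(0.4, length(pool$items)), pool$items)
  for (f in pool$facets) lam[facet_items(pool)[[f]][1:2]] <- 0.8
  make_default_config("custom", n = n, seed = seed, spec = pool, lambda = lam)
}

# 12 items, 6 two-item facets, 3 domains: the small well-specified model
small_spec <- function() {
  i2f <- setNames(rep(paste0("f", 1:6), each = 2), paste0("i", 1:12))
  f2d <- setNames(rep(paste0("d", 1:3), each = 2), paste0("f", 1:6))
  instrument_spec(i2f, f2d)
}

# enumerate all 2-per-facet selections of a pool and return their objective
# values (independent brute-force oracle for the ant search)
enumerate_selections <- function(context, objective, mode = "tau_equivalent") {
  pairs <- lapply(facet_items(context$pool), combn, m = 2, simplify = FALSE)
  grid <- expand.grid(lapply(pairs, seq_along), KEEP.OUT.ATTRS = FALSE)
  vals <- numeric(nrow(grid))
  sols <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sol <- setNames(lapply(names(pairs), function(f) pairs[[f]][[grid[i, f]]]),
                    names(pairs))
    sols[[i]] <- sol
    vals[i] <- antshort:::.evaluate_cached(sol, context, objective, mode)$value
  }
  list(values = vals, solutions = sols)
}

# bivariate-normal rectangle probability by 1-D numerical integration of
# phi(x) * [Phi((b2 - rho x)/s) - Phi((b1 - rho x)/s)] — independent of the
# package's closed-form CDF
bvn_rect_oracle <- function(a1, a2, b1, b2, rho) {
  s <- sqrt(1 - rho^2)
  integrate(function(x) dnorm(x) * (pnorm((b2 - rho * x) / s) -
                                    pnorm((b1 - rho * x) / s)),
            lower = a1, upper = a2, rel.tol = 1e-10)$value
}

# independent polychoric oracle: coarse-to-fine likelihood scan over rho
# using the numerically integrated cell probabilities
polychoric_grid_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  ta <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n)
  tb <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / n)
  abound <- c(-Inf, ta, Inf); bbound <- c(-Inf, tb, Inf)
  nll <- function(rho) {
    ll <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      pr <- bvn_rect_oracle(abound[i], abound[i + 1], bbound[j], bbound[j + 1], rho)
      ll <- ll - tab[i, j] * log(max(pr, 1e-300))
    }
    ll
  }
  lo <- -0.999; hi <- 0.999
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 21)
    vals <- vapply(grid, nll, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(21, k + 1)]
  }
  (lo + hi) / 2
}
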