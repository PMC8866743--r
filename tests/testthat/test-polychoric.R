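test_that("thresholds are probits of the cumulative margins", {
  tau <- thresholds_from_margins(c(25, 25, 25, 25))
  expect_equal(as.numeric(tau), qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-12)
  expect_false(attr(tau, "collapsed"))
  expect_equal(as.numeric(thresholds_from_margins(c(50, 50))), 0)
  tau3 <- thresholds_from_margins(c(10, 0, 10, 10))
  expect_length(tau3, 3)            # interior boundaries all remain interior
  tau4 <- thresholds_from_margins(c(0, 10, 10, 10))
  expect_length(tau4, 2)            # empty boundary category collapsed
  expect_true(attr(tau4, "collapsed"))
  expect_error(thresholds_from_margins(c(10, 0, 0, 0)), "nonempty")
})

test_that("the bivariate normal CDF agrees with numerical integration", {
  for (rho in c(-0.95, -0.5, 0, 0.3, 0.7, 0.93, 0.999)) {
    for (ab in list(c(0, 0), c(-1, 0.5), c(1.5, -2))) {
      oracle <- bvn_rect_oracle(-Inf, ab[1], -Inf, ab[2], rho)
      expect_equal(bvn_cdf(ab[1], ab[2], rho), oracle, tolerance = 1e-6)
    }
  }
})

test_that("pairwise estimation honours its boundary and symmetry contracts", {
  expect_lt(abs(polychoric_pair(matrix(25, 2, 2))), 1e-6)
  expect_equal(as.numeric(polychoric_pair(diag(c(30, 40, 30, 20)))), 0.999)
  expect_equal(as.numeric(polychoric_pair(matrix(c(40, 0, 0, 40), 2))), 0.999)

  set.seed(41)
  for (i in 1:5) {
    tab <- matrix(rpois(16, 20) + 1, 4, 4)
    expect_lt(abs(as.numeric(polychoric_pair(tab)) -
                  as.numeric(polychoric_pair(t(tab)))), 1e-6)
  }
  # moving mass from off-diagonal to diagonal cells never decreases rho
  set.seed(42)
  for (i in 1:5) {
    tab <- matrix(rpois(16, 15) + 1, 4, 4)
    r0 <- polychoric_pair(tab)
    tab2 <- tab
    tab2[2, 4] <- tab2[2, 4] - 1
    tab2[2, 2] <- tab2[2, 2] + 1
    expect_gte(polychoric_pair(tab2) + 1e-9, r0)
  }
  # zero-frequency categories collapse instead of failing
  tab <- matrix(c(30, 5, 0, 5, 30, 0, 0, 0, 0), 3, 3)
  r <- polychoric_pair(tab)
  expect_true(attr(r, "collapsed"))
  expect_error(polychoric_pair(matrix(c(10, 10, 0, 0), 2, 2)), "degenerate")
})

test_that("the two-step estimate matches a fine-grid likelihood oracle", {
  set.seed(43)
  z1 <- rnorm(2000); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(2000)
  br <- c(-0.2, 0.6, 1.4)
  tab <- table(factor(findInterval(z1, br), 0:3), factor(findInterval(z2, br), 0:3))
  expect_equal(as.numeric(polychoric_pair(tab)), polychoric_grid_oracle(tab),
               tolerance = 1e-4)
})

test_that("the matrix route is consistent, PSD-safe, and duplication-stable", {
  cfg0 <- make_default_config("pid5bfplus", n = 1500, seed = 44,
                              lambda = setNames(rep(0, 34),
                                                make_default_config("pid5bfplus", n = 5)$spec$items))
  X <- generate_responses(cfg0)$resp
  poly <- polychoric_matrix(X, cfg0$spec)
  expect_lt(mean(abs(poly$R[lower.tri(poly$R)])), 3 / sqrt(1500))

  cfg <- make_default_config("pid5bfplus", n = 400, seed = 45)
  resp <- generate_responses(cfg)$resp
  p1 <- polychoric_matrix(resp, cfg$spec)
  p2 <- polychoric_matrix(rbind(resp, resp), cfg$spec)
  expect_equal(p1$R, p2$R, tolerance = 1e-9)

  oneCat <- resp
  oneCat[, cfg$spec$items[1]] <- 2L
  expect_error(polychoric_matrix(oneCat, cfg$spec), "fewer than 2")

  M <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  clip <- psd_clip(M)
  expect_true(clip$clipped)
  expect_gte(min(eigen(clip$mat, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(clip$mat), rep(1, 3))
})

test_that("jackknife variances scale as 1/n and fall back to unit weights", {
  spec <- instrument_spec(c(x1 = "f1", x2 = "f1", x3 = "f2", x4 = "f2"),
                          c(f1 = "d1", f2 = "d1"))
  ratios <- numeric(6)
  for (r in 1:6) {
    cfg1 <- make_default_config("custom", n = 1000, seed = 50 + r, spec = spec)
    cfg2 <- make_default_config("custom", n = 2000, seed = 70 + r, spec = spec)
    W1 <- acov_diag(generate_responses(cfg1)$resp, spec, groups = 20)
    W2 <- acov_diag(generate_responses(cfg2)$resp, spec, groups = 20)
    ratios[r] <- mean(W2[lower.tri(W2)]) / mean(W1[lower.tri(W1)])
  }
  expect_equal(mean(ratios), 0.5, tolerance = 0.1)

  # independent items: variance within a factor 2 of the Pearson 1/n rate
  cfg0 <- make_default_config("custom", n = 2000, seed = 90, spec = spec,
                              lambda = setNames(rep(0, 4), spec$items))
  W0 <- acov_diag(generate_responses(cfg0)$resp, spec, groups = 20)
  w <- W0[lower.tri(W0)]
  expect_equal(mean(w) * 2000, 1, tolerance = 1)   # within a factor 2 of 1/n
  expect_true(all(w > 1 / (3 * 2000) & w < 3 / 2000))

  tiny <- generate_responses(make_default_config("custom", n = 40, seed = 91,
                                                 spec = spec))$resp
  expect_warning(Wt <- acov_diag(tiny, spec), "unit weights")
  expect_equal(unname(Wt[lower.tri(Wt)]), rep(1, 6))
})
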