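test_that("templates carry the documented structure", {
  cfg <- make_default_config("pid5bfplus", n = 50)
  expect_length(cfg$spec$items, 34)
  expect_equal(unname(cfg$lambda), rep(0.8, 34))
  expect_equal(mean(cfg$Phi[lower.tri(cfg$Phi)]), 0.32)
  expect_equal(cfg$spec$n_categories, 4L)

  pool <- make_default_config("pid5pool", n = 50)
  fi <- facet_items(pool$spec)
  for (f in names(fi)) {
    expect_equal(unname(pool$lambda[fi[[f]][1:2]]), c(0.8, 0.8))
    if (length(fi[[f]]) > 2)
      expect_equal(unname(pool$lambda[fi[[f]][-(1:2)]]),
                   rep(0.4, length(fi[[f]]) - 2))
  }
  expect_error(make_default_config("nope"), "arg")
  BadPhi <- matrix(0.99, 6, 6); diag(BadPhi) <- 1; BadPhi[1, 2] <- BadPhi[2, 1] <- -0.99
  expect_error(make_default_config("pid5bfplus", n = 10, Phi = BadPhi),
               "positive definite")
})

test_that("generation is deterministic and respects independence limits", {
  cfg <- make_default_config("pid5bfplus", n = 300, seed = 4)
  g1 <- generate_responses(cfg)
  g2 <- generate_responses(cfg)
  expect_identical(g1$resp, g2$resp)

  lam0 <- setNames(rep(0, 34), cfg$spec$items)
  cfg0 <- make_default_config("pid5bfplus", n = 2000, seed = 4, lambda = lam0)
  X <- as.matrix(generate_responses(cfg0)$resp[, cfg0$spec$items])
  R <- cor(X)
  expect_lt(mean(abs(R[lower.tri(R)])), 3 / sqrt(2000))
  expect_lt(max(abs(R[lower.tri(R)])), 5 / sqrt(2000))
})

test_that("two high-loading items on one facet give polychoric ~ lambda^2", {
  spec <- instrument_spec(c(x1 = "f1", x2 = "f1"), c(f1 = "d1"))
  cfg <- make_default_config("custom", n = 1e5, seed = 12, spec = spec)
  X <- generate_responses(cfg)$resp
  tab <- table(factor(X$x1, 0:3), factor(X$x2, 0:3))
  expect_equal(as.numeric(polychoric_pair(tab)), 0.64, tolerance = 0.02)
})

test_that("the implied-correlation contract holds at large n", {
  cfg <- make_default_config("pid5bfplus", n = 1e5, seed = 31)
  gen <- generate_responses(cfg)
  poly <- polychoric_matrix(gen$resp, cfg$spec)
  expect_lt(max(abs(poly$R - implied_item_corr(cfg))), 0.02)
})

test_that("noninvariance injection shifts thresholds and attenuates loadings", {
  cfg <- make_default_config("pid5bfplus", n = 500, seed = 6)
  cfg0 <- inject_noninvariance(cfg, "g2", threshold_shift = 0, n = 500)
  expect_equal(unname(cfg0$groups$g2$tau_shift), rep(0, 34))
  expect_equal(unname(cfg0$groups$g2$lambda_scale), rep(1, 34))

  items10 <- cfg$spec$items[1:10]
  cfgs <- inject_noninvariance(cfg, "g2", threshold_shift = 0.5,
                               items = items10, n = 4000)
  cfgs$n <- 4000L
  gen <- generate_responses(cfgs, seed = 6)
  ref <- gen$resp$group == "reference"
  m_ref <- colMeans(gen$resp[ref, items10])
  m_g2 <- colMeans(gen$resp[!ref, items10])
  expect_true(all(m_g2 < m_ref))   # mass pushed toward low categories

  # loading_delta -0.5 on one facet halves that facet's cross-block
  f1_items <- facet_items(cfg$spec)[["EmotionalLability"]]
  cfgl <- inject_noninvariance(cfg, "g3", loading_delta = -0.5,
                               items = f1_items, n = 500)
  R_ref <- implied_item_corr(cfgl)
  R_g3 <- implied_item_corr(cfgl, group = "g3")
  other <- setdiff(cfg$spec$items, f1_items)
  expect_equal(R_g3[f1_items, other], 0.5 * R_ref[f1_items, other],
               tolerance = 1e-12)
  expect_equal(R_g3[f1_items[1], f1_items[2]],
               0.25 * R_ref[f1_items[1], f1_items[2]], tolerance = 1e-12)
  expect_error(inject_noninvariance(cfg, "g4", loading_delta = 0.5, n = 100),
               "outside")
})

test_that("careless and missingness injection behave as labelled", {
  cfg <- make_default_config("pid5bfplus", n = 400, seed = 14)
  resp <- generate_responses(cfg)$resp
  expect_identical(inject_careless(resp, cfg$spec, 0, "random")$careless,
                   rep(FALSE, 400))
  long <- inject_careless(resp, cfg$spec, 0.1, "longstring", seed = 2)
  rows <- which(long$careless)
  expect_length(rows, 40)
  for (r in rows[1:5])
    expect_equal(longstring_avg(as.numeric(long[r, cfg$spec$items])), 34)

  expect_identical(inject_missing(resp, cfg$spec, 0), resp)
  cfg2 <- make_default_config("pid5bfplus", n = 1000, seed = 15)
  resp2 <- generate_responses(cfg2)$resp
  miss <- inject_missing(resp2, cfg2$spec, 0.05, seed = 3)
  frac <- mean(is.na(as.matrix(miss[, cfg2$spec$items])))
  expect_lt(abs(frac - 0.05), 0.01)
  heavy <- inject_missing(resp2, cfg2$spec, 0.5, seed = 3)
  row_miss <- rowMeans(is.na(as.matrix(heavy[, cfg2$spec$items])))
  expect_gt(mean(row_miss >= 0.10), 0.95)  # almost everyone fails the 10% rule
})

test_that("criterion variables are linear in the domain factors", {
  cfg <- make_default_config(
    "pid5bfplus", n = 5000, seed = 16,
    criteria = list(neuro = list(coef = c(NegativeAffectivity = 0.7), noise_sd = 0.5)))
  gen <- generate_responses(cfg)
  z <- gen$truth$.ref$domain[, "NegativeAffectivity"]
  expect_equal(cor(gen$resp$crit_neuro, z), 0.7 / sqrt(0.49 + 0.25),
               tolerance = 0.03)
})
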