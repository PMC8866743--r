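test_that("Fisher pooling matches its closed form and is order-invariant", {
  expect_equal(fisher_avg(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_avg(c(0.3, 0.7)),
               tanh((atanh(0.3) + atanh(0.7)) / 2), tolerance = 1e-12)
  expect_equal(round(fisher_avg(c(0.3, 0.7)), 3), 0.529)
  expect_equal(fisher_avg(0.42), 0.42)
  expect_equal(fisher_avg(c(0.1, 0.5, -0.3)), fisher_avg(c(-0.3, 0.1, 0.5)))
  expect_error(fisher_avg(c(0.5, 1)), "Fisher")
  # (n-3) weighting pulls toward the larger sample
  w <- fisher_avg(c(0.2, 0.6), ns = c(1000, 100), weighted = TRUE)
  expect_lt(w, fisher_avg(c(0.2, 0.6)))
})

test_that("dependent-correlation difference CIs are symmetric and shrink", {
  ci0 <- zou_ci_dependent(0.5, 0.5, 0.3, 200)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-10)
  expect_lt(ci0[1], 0); expect_gt(ci0[2], 0)
  # r12 -> 1 with r1 = r2: the two estimates coincide, the CI collapses
  w1 <- diff(zou_ci_dependent(0.5, 0.5, 0.1, 200))
  w2 <- diff(zou_ci_dependent(0.5, 0.5, 0.95, 200))
  expect_lt(w2, w1 / 3)
  expect_error(zou_ci_dependent(0.9, 0.9, -0.9, 200), "infeasible")
  # point estimate always inside its CI
  set.seed(151)
  for (i in 1:20) {
    r <- cor(matrix(rnorm(50 * 3), 50, 3))
    ci <- zou_ci_dependent(r[1, 2], r[1, 3], r[2, 3], 50)
    d <- r[1, 2] - r[1, 3]
    expect_true(ci[1] <= d && d <= ci[2])
  }
})

test_that("Cohen's d matches its pooled-SD definition and antisymmetry", {
  x1 <- c(-1, 0, 1); x2 <- c(0, 1, 2)
  d <- cohens_d(x1, x2)
  expect_equal(d$d, -1)
  expect_true(d$ci[1] < -1 && -1 < d$ci[2])
  d2 <- cohens_d(x2, x1)
  expect_equal(d2$d, 1)
  expect_equal(d$ci, -rev(d2$ci), tolerance = 1e-8)
  set.seed(152)
  a <- rnorm(100)
  dd <- cohens_d(a, a)          # identical groups
  expect_equal(dd$d, 0)
  expect_true(dd$ci[1] < 0 && dd$ci[2] > 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled SD")
})

test_that("convergence matrices pool by sample and carry the overlap caveat", {
  cfg <- make_default_config("pid5bfplus", n = 1200, seed = 153)
  resp <- generate_responses(cfg)$resp
  scores <- score_scales(resp, cfg$spec)
  cm <- convergence_matrix(scores, scores)
  expect_equal(unname(cm$convergent_facet), rep(1, 17))
  expect_match(cm$note, "inflate")
  sample_lab <- rep(c("s1", "s2"), 600)
  cm2 <- convergence_matrix(scores, scores, sample = sample_lab)
  # pooling clamps perfect correlations to .999 before the z transform
  expect_equal(unname(cm2$convergent_domain), rep(0.999, 6), tolerance = 1e-6)
  expect_lt(cm$discriminant_domain, 1)
})

test_that("profile tables recover injected severity shifts", {
  cfg <- make_default_config("pid5bfplus", n = 2500, seed = 154)
  cfg$groups <- list(severe = list(n = 2500, domain_shift = 0.5))
  cfg <- gen_config(cfg$spec, cfg$Phi, cfg$gamma, cfg$lambda, cfg$tau,
                    cfg$n, cfg$groups)
  gen <- generate_responses(cfg, seed = 154)
  resp <- gen$resp
  spec <- cfg$spec
  scores <- score_scales(resp, spec)
  ref_rows <- resp$group == "reference"
  ref <- scale_reference(score_scales(resp[ref_rows, ], spec))
  pt <- profile_table(scores, scores, resp$group, ref,
                      group_order = c("reference", "severe"))
  zr <- pt$z_profile[pt$z_profile$group == "reference", "z_mean"]
  expect_lt(max(abs(zr)), 0.05)
  # a latent +0.5 SD shift appears attenuated by the observed domain score's
  # correlation with its factor: expected d = 0.5 * cor(score, factor)
  truth_ref <- gen$truth$.ref$domain
  atten <- vapply(spec$domains, function(d)
    cor(scores$domain[ref_rows, d], truth_ref[, d]), numeric(1))
  expect_equal(mean(pt$between$d), 0.5 * mean(atten), tolerance = 0.05)
  expect_gt(mean(pt$between$d), 0.35)
  expect_lt(mean(pt$between$d), 0.65)
  # identical short and long forms: within-group d exactly 0
  expect_equal(pt$within$d_short_vs_long, rep(0, nrow(pt$within)))
  expect_error(profile_table(scores, scores, resp$group, ref,
                             group_order = c("reference", "missing_group")),
               "empty group")
})
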