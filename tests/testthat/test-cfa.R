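test_that("implied correlations follow path-tracing algebra", {
  spec1 <- instrument_spec(c(x1 = "f1", x2 = "f1"), c(f1 = "d1"))
  m1 <- model_spec(spec1, "tau_equivalent")
  Sig <- implied_corr(list(v = c(f1 = 0.49), Psi = matrix(1, 1, 1)), m1)
  expect_equal(Sig[1, 2], 0.49)

  m2 <- model_spec(spec1, "congeneric")
  Sig2 <- implied_corr(list(lambda = c(0.8, 0.8), gamma = c(f1 = 1),
                            Phi = matrix(1, 1, 1)), m2)
  expect_equal(Sig2[1, 2], 0.64)

  # full truth parameters reproduce the generator's implied matrix exactly
  cfg <- make_default_config("pid5bfplus", n = 10)
  mc <- model_spec(cfg$spec, "congeneric")
  Sig3 <- implied_corr(list(lambda = cfg$lambda, gamma = cfg$gamma,
                            Phi = cfg$Phi), mc)
  expect_lt(max(abs(Sig3 - implied_item_corr(cfg))), 1e-12)

  # communality above 1 is flagged, not clipped
  Sig4 <- implied_corr(list(v = c(f1 = 1.2), Psi = matrix(1, 1, 1)), m1)
  expect_identical(attr(Sig4, "heywood"), c("x1", "x2"))
})

test_that("model-implied input is recovered to machine precision", {
  cfg <- make_default_config("pid5bfplus", n = 2000)
  poly <- list(R = implied_item_corr(cfg), n = 2000)
  for (mode in c("tau_equivalent", "congeneric")) {
    fit <- fit_dwls(poly, model_spec(cfg$spec, mode))
    expect_lt(fit$F, 1e-10)
    expect_lt(fit$scaled_chisq, 1e-4)
    expect_equal(fit$cfi, 1)
    expect_equal(fit$rmsea, 0)
    expect_lt(fit$srmr, 1e-6)
    expect_true(fit$converged)
    expect_length(fit$heywood, 0)
  }
  fitc <- fit_dwls(poly, model_spec(cfg$spec, "congeneric"))
  expect_equal(unname(fitc$params$lambda), rep(0.8, 34), tolerance = 1e-5)
  expect_equal(unname(fitc$params$gamma), rep(0.8, 17), tolerance = 1e-5)
})

test_that("the optimizer finds the same minimum as a coarse-to-fine grid", {
  spec <- instrument_spec(c(x1 = "f1", x2 = "f1", y1 = "f2", y2 = "f2"),
                          c(f1 = "d1", f2 = "d1"))
  cfg <- make_default_config("custom", n = 1200, seed = 61, spec = spec)
  gen <- generate_responses(cfg)
  poly <- polychoric_matrix(gen$resp, spec)
  model <- model_spec(spec, "tau_equivalent")
  fit <- fit_dwls(poly, model)
  # independent oracle: 3-parameter grid over v1, v2, psi
  S <- poly$R; W <- (1 - S^2)^2 / poly$n
  obj <- function(v1, v2, ps) {
    Sig <- matrix(ps, 4, 4)
    Sig[1, 2] <- Sig[2, 1] <- v1; Sig[3, 4] <- Sig[4, 3] <- v2
    diag(Sig) <- 1
    sum(((S - Sig)^2 / ((poly$n - 1) * W))[lower.tri(S)])
  }
  rng <- list(c(0.2, 1), c(0.2, 1), c(0.05, 0.9))
  for (pass in 1:8) {
    grid <- expand.grid(v1 = seq(rng[[1]][1], rng[[1]][2], length.out = 11),
                        v2 = seq(rng[[2]][1], rng[[2]][2], length.out = 11),
                        ps = seq(rng[[3]][1], rng[[3]][2], length.out = 11))
    vals <- mapply(obj, grid$v1, grid$v2, grid$ps)
    b <- grid[which.min(vals), ]
    step <- vapply(rng, function(r) (r[2] - r[1]) / 10, numeric(1))
    rng <- list(c(b$v1 - step[1], b$v1 + step[1]),
                c(b$v2 - step[2], b$v2 + step[2]),
                c(b$ps - step[3], b$ps + step[3]))
  }
  expect_equal(unname(fit$params$v), c(b$v1, b$v2), tolerance = 1e-3)
  expect_equal(fit$params$Psi[1, 1], b$ps, tolerance = 1e-3)
})

test_that("scaled chi-square and fit indices follow their formulas", {
  expect_equal(scaled_chisq(0.5, 101, 10)$chisq, 50)
  expect_equal(scaled_chisq(0.5, 101, 10)$scaled_chisq, 50)  # diagonal Gamma: c = 1
  expect_equal(scaled_chisq(0.5, 101, 10, trUG = 20)$scaling, 2)
  expect_equal(scaled_chisq(0.3, 101, 0)$scaled_chisq, 0)

  S <- diag(2)
  fi <- fit_indices(100, 100, 5000, 120, 500, S, S)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  fi2 <- fit_indices(200, 100, 5000, 120, 1001, S, S)
  expect_equal(fi2$rmsea, sqrt(100 / (100 * 1000)), tolerance = 1e-12)
  expect_error(fit_indices(10, 100, 10, 50, 100, S, S), "baseline df")
})

test_that("the RMSEA interval matches a brute-force bisection of the ncp", {
  T_ <- 180; df <- 100; n <- 700
  fi <- fit_indices(T_, df, 5000, 120, n, diag(2), diag(2))
  bisect <- function(q) {
    lo <- 0; hi <- 1000
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (pchisq(T_, df, ncp = mid) > q) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(fi$rmsea_ci[1], sqrt(bisect(0.95) / (df * (n - 1))), tolerance = 1e-4)
  expect_equal(fi$rmsea_ci[2], sqrt(bisect(0.05) / (df * (n - 1))), tolerance = 1e-4)
})

test_that("standardization and Heywood detection honour their contracts", {
  spec <- instrument_spec(c(x1 = "f1", x2 = "f1", y1 = "f2", y2 = "f2"),
                          c(f1 = "d1", f2 = "d1"))
  model <- model_spec(spec, "tau_equivalent")
  ok <- list(v = c(f1 = 0.64, f2 = 0.5), Psi = matrix(0.4, 1, 1))
  std <- standardized_solution(ok, model)
  expect_equal(unname(std$loading_item), c(0.8, 0.8, sqrt(0.5), sqrt(0.5)))
  expect_equal(unname(std$loading_facet[1]), sqrt(0.4 / 0.64))
  expect_length(detect_heywood(ok, model), 0)

  neg <- list(v = c(f1 = 0.35, f2 = 0.5), Psi = matrix(0.4, 1, 1))
  flags <- detect_heywood(neg, model)
  expect_match(flags, "disturbance<0:f1", all = FALSE)
  expect_true(is.na(standardized_solution(neg, model)$loading_facet[1]))

  spec2 <- instrument_spec(c(x1 = "f1", x2 = "f1", y1 = "f2", y2 = "f2"),
                           c(f1 = "d1", f2 = "d2"))
  model2 <- model_spec(spec2, "tau_equivalent")
  hot <- list(v = c(f1 = 0.6, f2 = 0.6),
              Psi = matrix(c(0.5, 0.515, 0.515, 0.5), 2, 2))  # corr 1.03
  expect_match(detect_heywood(hot, model2), "latent_corr>1", all = FALSE)

  # standardized solution round-trips the generating parameters
  cfg <- make_default_config("pid5bfplus", n = 10)
  mc <- model_spec(cfg$spec, "congeneric")
  stdc <- standardized_solution(list(lambda = cfg$lambda, gamma = cfg$gamma,
                                     Phi = cfg$Phi), mc)
  expect_equal(stdc$loading_item, cfg$lambda)
  expect_equal(stdc$loading_facet, cfg$gamma)
})

test_that("adding equality constraints never decreases the discrepancy", {
  # tau-equivalence nests inside the congeneric model
  cfg <- make_default_config("pid5bfplus", n = 800, seed = 62)
  gen <- generate_responses(cfg)
  poly <- polychoric_matrix(gen$resp, cfg$spec)
  W <- acov_diag(gen$resp, cfg$spec, groups = 20)
  f_cg <- fit_dwls(poly, model_spec(cfg$spec, "congeneric"), weights = W)
  f_te <- fit_dwls(poly, model_spec(cfg$spec, "tau_equivalent"), weights = W)
  expect_gte(f_te$F, f_cg$F - 1e-10)
})

test_that("well-specified data meet the conventional fit thresholds", {
  hits <- 0
  for (r in 1:40) {
    cfg <- make_default_config("pid5bfplus", n = 2000, seed = 400 + r)
    gen <- generate_responses(cfg)
    poly <- polychoric_matrix(gen$resp, cfg$spec)
    fit <- fit_dwls(poly, model_spec(cfg$spec, "tau_equivalent"),
                    rmsea_ci = FALSE)
    if (fit$cfi > 0.95 && fit$rmsea < 0.05 && fit$srmr < 0.07) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})
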