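test_that("instrument specs validate hierarchy and sizes", {
  spec34 <- make_default_config("pid5bfplus", n = 10)$spec
  expect_s3_class(spec34, "instrument_spec")
  expect_length(spec34$items, 34)
  expect_length(spec34$facets, 17)
  expect_length(spec34$domains, 6)
  expect_true(all(lengths(facet_items(spec34)) == 2))

  pool <- make_default_config("pid5pool", n = 10)$spec
  expect_identical(unname(lengths(facet_items(pool))),
                   c(7L, 9L, 7L, 10L, 7L, 6L, 5L, 10L, 6L, 7L, 6L, 9L, 8L,
                     13L, 12L, 9L, 10L))
  expect_length(pool$items, 141)

  expect_error(instrument_spec(c(a = "f1", a = "f1", b = "f1"),
                               c(f1 = "d1")), "duplicate item")
  expect_error(instrument_spec(c(a = "f1", b = "f1", c = "f2"),
                               c(f1 = "d1", f2 = "d1")), "fewer than 2")
  expect_error(instrument_spec(c(a = "f1", b = "f1"), c(f1 = "d1"),
                               n_categories = 1), "n_categories")
  expect_error(instrument_spec(c(a = "f1", b = "f1"), c(f2 = "d1")),
               "without a domain|no items")
})

test_that("YAML round trip preserves the hierarchy", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c(
    "n_categories: 4",
    "domains:",
    "  d1:",
    "    f1: [a1, a2]",
    "    f2: [b1, b2, b3]",
    "  d2:",
    "    f3: [c1, c2]"), path)
  spec <- load_instrument(path)
  expect_identical(spec$items, c("a1", "a2", "b1", "b2", "b3", "c1", "c2"))
  expect_identical(unname(spec$facet_to_domain), c("d1", "d1", "d2"))
  # an item listed under two facets is rejected
  writeLines(c(
    "n_categories: 4",
    "domains:",
    "  d1:",
    "    f1: [a1, a2]",
    "    f2: [a1, b2]"), path)
  expect_error(load_instrument(path), "more than one facet")
})

test_that("scale scoring follows the mean/coverage rules", {
  spec <- instrument_spec(c(a1 = "f1", a2 = "f1", b1 = "f2", b2 = "f2"),
                          c(f1 = "d1", f2 = "d1"))
  resp <- data.frame(a1 = c(1, 0, 1), a2 = c(3, 0, NA),
                     b1 = c(2, 0, NA), b2 = c(2, 0, NA))
  sc <- score_scales(resp, spec)
  expect_equal(unname(sc$facet[1, ]), c(2, 2))
  expect_equal(unname(sc$facet[2, ]), c(0, 0))
  expect_equal(unname(sc$total[2]), 0)
  # one of two items missing at coverage 0.5: the observed item's value
  expect_equal(unname(sc$facet[3, "f1"]), 1)
  # a fully missing facet propagates, the domain uses remaining facets
  expect_true(is.na(sc$facet[3, "f2"]))
  expect_equal(unname(sc$domain[3, "d1"]), 1)
  # stricter coverage turns the half-missing facet missing
  sc2 <- score_scales(resp, spec, min_item_coverage = 0.9)
  expect_true(is.na(sc2$facet[3, "f1"]))
  expect_error(score_scales(resp[, 1:3], spec), "absent")
})

test_that("scoring is invariant to respondent and item order", {
  cfg <- make_default_config("pid5bfplus", n = 60, seed = 8)
  resp <- generate_responses(cfg)$resp
  sc <- score_scales(resp, cfg$spec)
  perm_rows <- sample(nrow(resp))
  perm_cols <- c(sample(cfg$spec$items), "id")
  sc2 <- score_scales(resp[perm_rows, perm_cols], cfg$spec)
  expect_equal(unname(sc2$facet), unname(sc$facet[perm_rows, ]))
  expect_equal(unname(sc2$total), unname(sc$total[perm_rows]))
})

test_that("z-standardization matches the reference contract", {
  spec <- instrument_spec(c(a1 = "f1", a2 = "f1"), c(f1 = "d1"))
  ref <- structure(list(
    facet = list(mean = c(f1 = 1), sd = c(f1 = 0.5)),
    domain = list(mean = c(d1 = 1), sd = c(d1 = 0.5)),
    total = list(mean = 1, sd = 0.5)), class = "scale_reference")
  sc <- score_scales(data.frame(a1 = 2, a2 = 2), spec)
  z <- z_standardize(sc, ref)
  expect_equal(unname(z$facet[1, 1]), 2)
  sc0 <- score_scales(data.frame(a1 = 1, a2 = 1), spec)
  expect_equal(unname(z_standardize(sc0, ref)$facet[1, 1]), 0)
  ref$facet$sd["f1"] <- 0
  expect_error(z_standardize(sc, ref), "zero reference SD")

  # self-reference gives mean 0, sd 1 per scale
  cfg <- make_default_config("pid5bfplus", n = 400, seed = 9)
  scores <- score_scales(generate_responses(cfg)$resp, cfg$spec)
  zz <- z_standardize(scores, scale_reference(scores))
  expect_equal(unname(colMeans(zz$facet)), rep(0, 17), tolerance = 1e-12)
  expect_equal(unname(apply(zz$facet, 2, sd)), rep(1, 17), tolerance = 1e-12)
})

test_that("a +0.5 SD latent shift appears as ~0.5 group z-mean", {
  cfg <- make_default_config("pid5bfplus", n = 4000, seed = 21)
  cfg$groups <- list(clinical = list(n = 4000, domain_shift = 0.5))
  cfg <- do.call(gen_config, c(list(spec = cfg$spec, Phi = cfg$Phi,
                                    gamma = cfg$gamma, lambda = cfg$lambda,
                                    tau = cfg$tau, n = cfg$n,
                                    groups = cfg$groups)))
  gen <- generate_responses(cfg, seed = 21)
  resp <- gen$resp
  ref_rows <- resp$group == "reference"
  scores_ref <- score_scales(resp[ref_rows, ], cfg$spec)
  scores_cl <- score_scales(resp[!ref_rows, ], cfg$spec)
  z <- z_standardize(scores_cl, scale_reference(scores_ref))
  # attenuated by imperfect reliability of observed scores, so below 0.5
  # but clearly positive and near it
  expect_gt(mean(colMeans(z$domain)), 0.3)
  expect_lt(mean(colMeans(z$domain)), 0.6)
})
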