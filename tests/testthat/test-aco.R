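test_that("solution sampling follows the pheromone distribution", {
  pool <- instrument_spec(c(a = "f1", b = "f1", c = "f1", d = "f1"),
                          c(f1 = "d1"))
  state <- pheromone_init(pool)
  set.seed(81)
  draws <- replicate(1e5, paste(sort(sample_solution(state)$f1), collapse = ""))
  freq <- table(draws) / 1e5
  expect_length(freq, 6)
  expect_true(all(abs(freq - 1 / 6) < 0.01))  # uniform pheromone: 1/6 per pair

  # one item at phi_max with phi_max/phi_min = 20 dominates the pairs
  state$phi$f1 <- c(a = 20, b = 1, c = 1, d = 1)
  p_first <- 20 / 23
  p_second <- (3 / 23) * (20 / 22)
  p_exact <- p_first + p_second
  expect_gte(p_exact, 0.9)
  set.seed(82)
  hits <- mean(replicate(2e4, "a" %in% sample_solution(state)$f1))
  expect_equal(hits, p_exact, tolerance = 0.01)

  # a fixed seed reproduces the sampling stream
  set.seed(83); s1 <- replicate(20, sample_solution(state), simplify = FALSE)
  set.seed(83); s2 <- replicate(20, sample_solution(state), simplify = FALSE)
  expect_identical(s1, s2)

  state$phi$f1 <- state$phi$f1[1:1]
  expect_error(sample_solution(state), "fewer than 2")
})

test_that("pheromone updates clamp, decay, and converge to the bounds", {
  pool <- tiny_pool()
  cfg <- aco_config(evaporation = 0.9)
  state <- pheromone_init(pool)
  best <- list(sol = lapply(facet_items(pool), `[`, 1:2), value = 2)
  state <- update_pheromones(state, best, best, cfg)
  phi_max <- 2 / (1 - 0.9)
  expect_equal(state$phi_max, phi_max)
  expect_true(all(unlist(state$phi) <= phi_max + 1e-12))
  expect_true(all(unlist(state$phi) >=
                    phi_max / (2 * max(lengths(facet_items(pool)))) - 1e-12))

  # un-deposited items decay geometrically to the floor; deposited items
  # approach phi_max as a fixed point
  for (k in 1:200) state <- update_pheromones(state, best, best, cfg)
  f1 <- state$phi$f1
  expect_equal(unname(f1[best$sol$f1]), rep(phi_max, 2), tolerance = 1e-6)
  expect_equal(unname(f1[setdiff(names(f1), best$sol$f1)]),
               rep(phi_max / (2 * 4), 2))
  # bounds hold after every single update (checked across a random stream)
  set.seed(84)
  for (k in 1:50) {
    rb <- list(sol = sample_solution(state), value = runif(1, 0.5, 3))
    gb <- if (rb$value > best$value) rb else best
    state <- update_pheromones(state, rb, gb, cfg)
    expect_true(all(unlist(state$phi) <= state$phi_max + 1e-12))
    expect_true(all(unlist(state$phi) >= state$phi_min - 1e-12))
    best <- gb
  }
})

test_that("objective evaluation transforms components as documented", {
  cfg <- tiny_pool_config(n = 600, seed = 85)
  gen <- generate_responses(cfg)
  ctx <- aco_context(gen$resp, cfg$spec, jackknife_groups = 0)
  obj <- stock_objective("B")
  sol <- lapply(facet_items(cfg$spec), `[`, 1:2)
  ev <- evaluate_objective(sol, ctx, obj)
  expect_true(ev$admissible)
  # hand recomputation of the logistic components
  byhand <- vapply(obj$components, function(cmp)
    cmp$weight * logistic_component(ev$components[[cmp$stat]], cmp$b, cmp$a,
                                    cmp$increasing), numeric(1))
  expect_equal(ev$value, sum(byhand), tolerance = 1e-12)

  # higher CFI with everything else equal gives a strictly higher objective
  o1 <- sum(vapply(stock_objective("A")$components, function(cmp)
    logistic_component(c(cfi = 0.99, rmsea = 0.04, srmr = 0.05,
                         mean_omega = 0.8)[[cmp$stat]],
                       cmp$b, cmp$a, cmp$increasing), numeric(1)))
  o2 <- sum(vapply(stock_objective("A")$components, function(cmp)
    logistic_component(c(cfi = 0.90, rmsea = 0.04, srmr = 0.05,
                         mean_omega = 0.8)[[cmp$stat]],
                       cmp$b, cmp$a, cmp$increasing), numeric(1)))
  expect_gt(o1, o2)
})

test_that("near-perfect indicators drive the objective toward its ceiling", {
  spec <- small_spec()
  lam <- setNames(rep(0.97, 12), spec$items)
  cfg <- make_default_config("custom", n = 3000, seed = 86, spec = spec,
                             lambda = lam,
                             gamma = setNames(rep(0.97, 6), spec$facets))
  gen <- generate_responses(cfg)
  ctx <- aco_context(gen$resp, spec, jackknife_groups = 0)
  obj <- stock_objective("A")
  ev <- evaluate_objective(lapply(facet_items(spec), identity), ctx, obj)
  expect_gt(ev$value, 0.9 * length(obj$components))
})

test_that("the objective is invariant to item relabelling", {
  cfg <- tiny_pool_config(n = 600, seed = 87)
  gen <- generate_responses(cfg)
  ctx <- aco_context(gen$resp, cfg$spec, jackknife_groups = 0)
  obj <- stock_objective("A")
  sol <- lapply(facet_items(cfg$spec), `[`, 1:2)
  v1 <- evaluate_objective(sol, ctx, obj)$value

  # rename every item, permute columns, rebuild the context
  map <- setNames(paste0("it", seq_along(cfg$spec$items)), cfg$spec$items)
  spec2 <- instrument_spec(setNames(unname(cfg$spec$item_to_facet), map),
                           cfg$spec$facet_to_domain)
  resp2 <- gen$resp
  names(resp2)[match(names(map), names(resp2))] <- unname(map)
  resp2 <- resp2[, c("id", sample(spec2$items))]
  ctx2 <- aco_context(resp2, spec2, jackknife_groups = 0)
  sol2 <- lapply(sol, function(it) unname(map[it]))
  v2 <- evaluate_objective(sol2, ctx2, obj)$value
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("degenerate pools return their unique selection in one iteration", {
  cfg <- make_default_config("pid5bfplus", n = 400, seed = 88)
  gen <- generate_responses(cfg)
  ctx <- aco_context(gen$resp, cfg$spec, jackknife_groups = 0)
  res <- run_aco(pool = cfg$spec, config = aco_config(seed = 5), context = ctx)
  expect_equal(nrow(res$trace), 1)
  expect_identical(lapply(res$best, sort), lapply(facet_items(cfg$spec), sort))

  # fixed seed: identical run
  ctxb <- aco_context(gen$resp, cfg$spec, jackknife_groups = 0)
  res2 <- run_aco(pool = cfg$spec, config = aco_config(seed = 5), context = ctxb)
  expect_identical(res$best, res2$best)
  expect_equal(res$best_value, res2$best_value)
})
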