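# MAX-MIN ant-system search over two-items-per-facet selections.  Pheromone
# lives on items (per facet); only the global-best ant deposits; pheromone is
# clamped to [phi_min, phi_max] with phi_max = best/(1 - retention) and
# phi_min = phi_max / (2 * facet pool size).  Solutions are cached by item
# set, so repeated sampling of the same selection costs nothing.

#' Objective specification for the selection search
#'
#' Each component is a raw model statistic passed through an increasing or
#' decreasing logistic transform (see [logistic_component()]); the objective
#' is the weighted sum of the transformed components.
#'
#' @param components list of lists with `stat` (one of `"cfi"`, `"rmsea"`,
#'   `"srmr"`, `"mean_omega"`, `"min_loading"`, `"part_whole"`), `b`
#'   (midpoint), `a` (slope), `increasing`, `weight`.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(components) {
  for (cmp in components)
    stopifnot(cmp$stat %in% c("cfi", "rmsea", "srmr", "mean_omega",
                              "min_loading", "part_whole"))
  structure(list(components = components), class = "objective_spec")
}

.component_defaults <- list(
  cfi = list(stat = "cfi", b = 0.95, a = 100, increasing = TRUE, weight = 1),
  rmsea = list(stat = "rmsea", b = 0.05, a = 100, increasing = FALSE, weight = 1),
  srmr = list(stat = "srmr", b = 0.06, a = 100, increasing = FALSE, weight = 1),
  mean_omega = list(stat = "mean_omega", b = 0.70, a = 30, increasing = TRUE, weight = 1),
  min_loading = list(stat = "min_loading", b = 0.50, a = 20, increasing = TRUE, weight = 1),
  part_whole = list(stat = "part_whole", b = 0.80, a = 30, increasing = TRUE, weight = 1)
)

#' The two stock objectives
#'
#' Objective A combines model fit (CFI, RMSEA, SRMR) with mean facet/domain
#' reliability; objective B combines CFI and RMSEA with mean reliability,
#' the minimum standardized first/second-order loading, and the mean
#' part-whole correlation between short and full facet scales.
#'
#' @param which `"A"` or `"B"`.
#' @return an [objective_spec()].
#' @export
stock_objective <- function(which = c("A", "B")) {
  which <- match.arg(which)
  stats <- if (which == "A") c("cfi", "rmsea", "srmr", "mean_omega")
           else c("cfi", "rmsea", "mean_omega", "min_loading", "part_whole")
  objective_spec(unname(.component_defaults[stats]))
}

#' Ant-system configuration
#'
#' @param n_ants solutions sampled per iteration (default 16).
#' @param max_iter iteration cap (default 300).
#' @param evaporation pheromone retention rho per iteration (default 0.95).
#' @param stagnation iterations without global-best improvement before the
#'   search is considered converged (default 30).
#' @param seed integer seed for the sampling stream.
#' @param deposit `"global"` (MAX-MIN convention) or `"iteration"`.
#' @param local_search greedily improve a new global best by single-facet
#'   pair swaps before it deposits (default TRUE).  MAX-MIN ant systems are
#'   designed to be hybridized with local search; the swap neighbourhood is
#'   cached, so repeated visits are free.
#' @return object of class `aco_config`.
#' @export
aco_config <- function(n_ants = 16L, max_iter = 300L, evaporation = 0.95,
                       stagnation = 30L, seed = 1L,
                       deposit = c("global", "iteration"), local_search = TRUE) {
  stopifnot(n_ants >= 1, evaporation > 0, evaporation < 1)
  structure(list(n_ants = as.integer(n_ants), max_iter = as.integer(max_iter),
                 evaporation = evaporation, stagnation = as.integer(stagnation),
                 seed = as.integer(seed), deposit = match.arg(deposit),
                 local_search = isTRUE(local_search)),
            class = "aco_config")
}

#' Initialize pheromone state over a pool
#'
#' Pheromone starts uniform at 1, or, when a heuristic prior is supplied
#' (item-rest correlations from [aco_context()]), proportional to it with
#' per-facet mean 1 — a cheap visibility bias for the first iterations,
#' before deposits take over.
#'
#' @param pool an [instrument_spec()] whose facets are the selection slots.
#' @param heur optional named per-item prior (positive).
#' @return object of class `pheromone_state`: per-facet pheromone vectors,
#'   bounds, iteration counter, global best.
#' @export
pheromone_init <- function(pool, heur = NULL) {
  fi <- facet_items(pool)
  phi <- lapply(fi, function(its) {
    if (is.null(heur)) return(setNames(rep(1, length(its)), its))
    h <- heur[its]
    h / mean(h)
  })
  structure(list(phi = phi, phi_max = Inf, phi_min = 0, iter = 0L,
                 best = NULL, best_value = -Inf, pool = pool),
            class = "pheromone_state")
}

#' Sample one selection proportional to pheromone
#'
#' Per facet, two distinct items: the first proportional to pheromone, the
#' second proportional to pheromone among the remaining items.
#'
#' @param state a [pheromone_init()] state.
#' @return named list facet -> character(2) of item IDs.
#' @export
sample_solution <- function(state) {
  lapply(state$phi, function(ph) {
    if (length(ph) < 2) stop("facet with fewer than 2 candidates")
    i1 <- sample(names(ph), 1, prob = ph)
    rest <- ph[setdiff(names(ph), i1)]
    i2 <- sample(names(rest), 1, prob = rest)
    c(i1, i2)
  })
}

# canonical cache key of a selection
.sol_key <- function(sol) paste(sort(unlist(sol, use.names = FALSE)), collapse = "|")

#' Build the evaluation context for a pool and training data
#'
#' Computes the pool-wide polychoric matrix, its jackknife weights, and the
#' full-pool facet scores once; every candidate evaluation then works on
#' submatrices.
#'
#' @param resp_train training responses.
#' @param pool pool [instrument_spec()].
#' @param jackknife_groups blocks for [acov_diag()] (`0` for the plug-in).
#' @param min_item_coverage forwarded to [score_scales()].
#' @return list used by [evaluate_objective()] and [run_aco()].
#' @export
aco_context <- function(resp_train, pool, jackknife_groups = 30L,
                        min_item_coverage = 0.5) {
  poly <- polychoric_matrix(resp_train, pool)
  W <- if (jackknife_groups > 0) acov_diag(resp_train, pool, groups = jackknife_groups)
       else (1 - poly$R^2)^2 / poly$n
  full_scores <- score_scales(resp_train, pool, min_item_coverage)
  X <- as.matrix(as.data.frame(resp_train)[, pool$items])
  storage.mode(X) <- "double"
  # corrected item-rest correlation within facet: the pheromone prior
  fi <- facet_items(pool)
  heur <- setNames(rep(1, length(pool$items)), pool$items)
  for (f in names(fi)) {
    its <- fi[[f]]
    for (it in its) {
      rest <- rowMeans(X[, setdiff(its, it), drop = FALSE], na.rm = TRUE)
      heur[it] <- cor(X[, it], rest, use = "pairwise.complete.obs")
    }
  }
  heur <- pmax(heur, 0.05)
  list(pool = pool, poly = poly, W = W, full_facet = full_scores$facet, X = X,
       heur = heur, cache = new.env(parent = emptyenv()))
}

#' Evaluate the objective of one selection
#'
#' Fits the essential-tau-equivalent hierarchical model on the selected
#' items (by DWLS on the pool polychorics), computes the requested component
#' statistics, and returns the weighted logistic objective.  Non-converged
#' or Heywood-flagged fits score 0 (worst), as inadmissible solutions are
#' excluded rather than ranked.
#'
#' @param sol selection (named list facet -> 2 item IDs).
#' @param context an [aco_context()].
#' @param objective an [objective_spec()].
#' @param mode model mode for the evaluation fit.
#' @return list `value`, `components` (raw statistics), `transformed`,
#'   `admissible`, `fit`.
#' @export
evaluate_objective <- function(sol, context, objective, mode = "tau_equivalent") {
  pool <- context$pool
  items <- unlist(sol, use.names = FALSE)
  sub <- subset_instrument(pool, items)
  model <- model_spec(sub, mode)
  fit <- fit_dwls(context$poly, model, weights = context$W, rmsea_ci = FALSE)
  admissible <- fit$converged && length(fit$heywood) == 0
  stats <- c(cfi = NA, rmsea = NA, srmr = NA, mean_omega = NA,
             min_loading = NA, part_whole = NA)
  facet_omega <- NULL
  if (admissible) {
    om <- omega_report(fit)
    facet_omega <- om$facet
    pw <- vapply(sub$facets, function(f) {
      short <- rowMeans(context$X[, sol[[f]], drop = FALSE], na.rm = TRUE)
      cor(short, context$full_facet[, f], use = "pairwise.complete.obs")
    }, numeric(1))
    stats <- c(cfi = fit$cfi, rmsea = fit$rmsea, srmr = fit$srmr,
               mean_omega = mean(c(om$facet, om$domain_total), na.rm = TRUE),
               min_loading = min(c(fit$std$loading_item, fit$std$loading_facet)),
               part_whole = mean(pw))
  }
  transformed <- vapply(objective$components, function(cmp) {
    if (!admissible) return(0)
    logistic_component(stats[[cmp$stat]], cmp$b, cmp$a, cmp$increasing)
  }, numeric(1))
  value <- sum(vapply(objective$components, `[[`, numeric(1), "weight") * transformed)
  if (!admissible) value <- 0
  list(value = value, components = stats, transformed = transformed,
       admissible = admissible, facet_omega = facet_omega, fit = fit)
}

.evaluate_cached <- function(sol, context, objective, mode) {
  key <- .sol_key(sol)
  hit <- context$cache[[key]]
  if (!is.null(hit)) return(hit)
  ev <- evaluate_objective(sol, context, objective, mode)
  ev$fit <- NULL     # keep the cache light
  assign(key, ev, envir = context$cache)
  ev
}

# Greedy single-facet improvement: sweep the facets, replacing each facet's
# pair with its best alternative from the pool while the other facets stay
# fixed; repeat until a full sweep improves nothing.  Then attempt one
# targeted double swap over the two facets with the lowest facet omega
# (jointly homogeneous low-loading pairs fit the tau-equivalent model well
# but cannot be escaped one facet at a time); on success, resume sweeping.
.local_improve <- function(best, context, objective, mode) {
  fi <- facet_items(context$pool)
  sweep_once <- function(best) {
    changed <- FALSE
    for (f in names(best$sol)) {
      for (pair in combn(fi[[f]], 2, simplify = FALSE)) {
        if (setequal(pair, best$sol[[f]])) next
        cand <- best$sol
        cand[[f]] <- pair
        ev <- .evaluate_cached(cand, context, objective, mode)
        if (ev$value > best$value + 1e-12) {
          best <- list(sol = cand, value = ev$value)
          changed <- TRUE
        }
      }
    }
    list(best = best, changed = changed)
  }
  repeat {
    repeat {
      sw <- sweep_once(best)
      best <- sw$best
      if (!sw$changed) break
    }
    ev <- .evaluate_cached(best$sol, context, objective, mode)
    if (is.null(ev$facet_omega) || length(ev$facet_omega) < 2) return(best)
    worst <- names(sort(ev$facet_omega))[1:2]
    # candidate pairs from each facet's top items by the heuristic prior
    cand_pairs <- lapply(worst, function(f) {
      its <- fi[[f]]
      top <- its[order(-context$heur[its])][seq_len(min(6, length(its)))]
      combn(top, 2, simplify = FALSE)
    })
    improved <- FALSE
    for (p1 in cand_pairs[[1]]) {
      for (p2 in cand_pairs[[2]]) {
        cand <- best$sol
        cand[[worst[1]]] <- p1
        cand[[worst[2]]] <- p2
        ev2 <- .evaluate_cached(cand, context, objective, mode)
        if (ev2$value > best$value + 1e-12) {
          best <- list(sol = cand, value = ev2$value)
          improved <- TRUE
        }
      }
    }
    if (!improved) return(best)
  }
}

#' MAX-MIN pheromone update
#'
#' All pheromone decays by the retention factor; the best solution deposits
#' its objective value on each of its items; levels are clamped to
#' `[phi_min, phi_max]` with `phi_max = best_value / (1 - retention)` and
#' `phi_min = phi_max / (2 * facet pool size)`.
#'
#' @param state a `pheromone_state`.
#' @param iteration_best best solution/value of the current iteration
#'   (list `sol`, `value`).
#' @param global_best global best so far (list `sol`, `value`).
#' @param config an [aco_config()].
#' @return updated state.
#' @export
update_pheromones <- function(state, iteration_best, global_best, config) {
  rho <- config$evaporation
  depositor <- if (config$deposit == "global") global_best else iteration_best
  if (global_best$value > 0) {
    state$phi_max <- global_best$value / (1 - rho)
    for (f in names(state$phi)) {
      ph <- state$phi[[f]] * rho
      ph[depositor$sol[[f]]] <- ph[depositor$sol[[f]]] + depositor$value
      pmin_f <- state$phi_max / (2 * length(ph))
      state$phi[[f]] <- pmin(pmax(ph, pmin_f), state$phi_max)
    }
    state$phi_min <- state$phi_max / (2 * max(lengths(state$phi)))
  } else {
    # no admissible solution seen yet: plain evaporation with a positive floor
    for (f in names(state$phi))
      state$phi[[f]] <- pmax(state$phi[[f]] * rho, 1e-8)
  }
  state$iter <- state$iter + 1L
  state$best <- global_best$sol
  state$best_value <- global_best$value
  state
}

#' Run the ant-colony search
#'
#' Loops sample -> evaluate -> update until the stagnation window passes
#' without improvement of the global best, or the iteration cap is reached.
#'
#' @param data_train training responses (ignored when `context` given).
#' @param pool pool [instrument_spec()].
#' @param objective an [objective_spec()] (default objective A).
#' @param config an [aco_config()].
#' @param mode evaluation model mode.
#' @param context optional precomputed [aco_context()].
#' @return list `best` (selection), `best_value`, `best_eval`, `trace`
#'   (per-iteration best and global best), `n_unique` (distinct selections
#'   fitted), `seed`.
#' @export
run_aco <- function(data_train = NULL, pool, objective = stock_objective("A"),
                    config = aco_config(), mode = "tau_equivalent",
                    context = NULL) {
  if (is.null(context)) context <- aco_context(data_train, pool)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  state <- pheromone_init(pool, heur = context$heur)
  global <- list(sol = NULL, value = -Inf)
  trace <- vector("list", config$max_iter)
  single <- all(lengths(facet_items(pool)) == 2)   # degenerate pool: one selection
  stall <- 0L
  for (it in seq_len(config$max_iter)) {
    iter_best <- list(sol = NULL, value = -Inf)
    for (a in seq_len(config$n_ants)) {
      sol <- sample_solution(state)
      ev <- .evaluate_cached(sol, context, objective, mode)
      if (ev$value > iter_best$value) iter_best <- list(sol = sol, value = ev$value)
    }
    improved <- iter_best$value > global$value + 1e-12
    if (improved) {
      if (config$local_search)
        iter_best <- .local_improve(iter_best, context, objective, mode)
      global <- iter_best
    }
    state <- update_pheromones(state, iter_best, global, config)
    trace[[it]] <- data.frame(iter = it, iter_best = iter_best$value,
                              global_best = global$value)
    stall <- if (improved) 0L else stall + 1L
    if (stall >= config$stagnation || single) break
  }
  best_eval <- .evaluate_cached(global$sol, context, objective, mode)
  list(best = global$sol, best_value = global$value, best_eval = best_eval,
       trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
       n_unique = length(ls(context$cache)), seed = config$seed)
}
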