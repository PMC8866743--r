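# End-to-end short-form construction: stratified train/test split,
# multi-algorithm multi-run ant search on the training half, consensus over
# the best solutions by test-set fit, brute-force completion of unresolved
# facets, and a Heywood-aware final ranking on the test half.

#' Size of the two-items-per-facet selection space
#'
#' Product over facets of `choose(size, 2)`, in exact integer arithmetic
#' (base-10000 long multiplication; the count overflows doubles long before
#' realistic pools do).
#'
#' @param pool_sizes per-facet candidate counts (each >= 2).
#' @return list with `count` (double approximation) and `exact` (decimal
#'   string of the exact product).
#' @export
count_solution_space <- function(pool_sizes) {
  if (any(pool_sizes < 2)) stop("facet pool smaller than 2")
  digits <- 1           # little-endian base-1e4 digits
  for (n in pool_sizes) {
    m <- choose(n, 2)
    prod <- digits * m
    carry <- 0
    for (i in seq_along(prod)) {
      prod[i] <- prod[i] + carry
      carry <- prod[i] %/% 1e4
      prod[i] <- prod[i] %% 1e4
    }
    while (carry > 0) {
      prod <- c(prod, carry %% 1e4)
      carry <- carry %/% 1e4
    }
    digits <- prod
  }
  s <- paste0(c(as.character(digits[length(digits)]),
                sprintf("%04d", rev(digits[-length(digits)]))), collapse = "")
  # the double is derived from the exact decimal string, so it is the
  # correctly rounded value (a running double product can drift by an ulp)
  list(count = as.numeric(s), exact = s)
}

#' Stratified train/test split
#'
#' Per-stratum random split preserving the stratum composition; the test
#' count per stratum follows largest-remainder allocation so the totals
#' match the requested ratio as closely as possible.
#'
#' @param resp response data frame.
#' @param ratio test fraction in (0, 1).
#' @param strata optional vector of stratum labels (e.g. sample of origin).
#' @param seed integer seed.
#' @return list of logical masks `train` and `test`.
#' @export
split_train_test <- function(resp, ratio, strata = NULL, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- nrow(resp)
  strata <- strata %||% rep("all", n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sizes <- table(strata)
  if (any(sizes < 2)) stop("stratum with fewer than 2 respondents")
  target <- round(n * ratio)
  raw <- as.numeric(sizes) * ratio
  base <- floor(raw)
  rem <- target - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  test <- logical(n)
  for (k in seq_along(sizes)) {
    idx <- which(strata == names(sizes)[k])
    test[sample(idx, base[k])] <- TRUE
  }
  list(train = !test, test = test)
}

#' One evaluated selection
#' @noRd
.selection_solution <- function(sol, train_eval, test_fit, provenance) {
  structure(list(items = sol, objective = train_eval$value,
                 components = train_eval$components,
                 admissible = train_eval$admissible,
                 test_fit = test_fit, provenance = provenance),
            class = "selection_solution")
}

#' @export
print.selection_solution <- function(x, ...) {
  cat(sprintf("selection_solution [%s]: objective %.3f, test CFI %.3f, RMSEA %.3f, SRMR %.3f\n",
              paste(unlist(x$provenance), collapse = "/"), x$objective,
              x$test_fit$cfi, x$test_fit$rmsea, x$test_fit$srmr))
  invisible(x)
}

.fit_selection_test <- function(sol, context_test, mode = "tau_equivalent") {
  sub <- subset_instrument(context_test$pool, unlist(sol, use.names = FALSE))
  fit_dwls(context_test$poly, model_spec(sub, mode), weights = context_test$W)
}

#' Multi-algorithm, multi-run search
#'
#' Runs each requested objective `runs_per_algorithm` times on the training
#' half with derived seeds, evaluates every run's best selection on the test
#' half, and sorts by test fit (CFI, then RMSEA, then SRMR).
#'
#' @param context_train,context_test [aco_context()]s of the two halves.
#' @param algorithms objectives to run: subset of `c("A", "B")`, or a named
#'   list of [objective_spec()]s.
#' @param runs_per_algorithm default 3.
#' @param seed master seed; per-run seeds are derived from it.
#' @param seeds optional explicit per-run seeds (overrides `seed`); passing
#'   identical seeds within one algorithm duplicates its runs and is flagged
#'   as a misconfiguration warning.
#' @param config base [aco_config()] (its seed is overwritten per run).
#' @param mode evaluation model mode.
#' @return list of `selection_solution`s, best test fit first.
#' @export
run_multistart <- function(context_train, context_test,
                           algorithms = c("A", "B"), runs_per_algorithm = 3L,
                           seed = 1L, seeds = NULL, config = aco_config(),
                           mode = "tau_equivalent") {
  if (!is.list(algorithms))
    algorithms <- setNames(lapply(algorithms, stock_objective), algorithms)
  nrun <- length(algorithms) * runs_per_algorithm
  seeds <- seeds %||% derive_seeds(seed, nrun)
  stopifnot(length(seeds) == nrun)
  if (anyDuplicated(seeds))
    warning("identical seeds across runs: runs will duplicate each other")
  sols <- list(); k <- 0L
  for (alg in names(algorithms)) {
    for (r in seq_len(runs_per_algorithm)) {
      k <- k + 1L
      cfg <- config; cfg$seed <- seeds[k]
      res <- run_aco(pool = context_train$pool, objective = algorithms[[alg]],
                     config = cfg, mode = mode, context = context_train)
      test_fit <- .fit_selection_test(res$best, context_test, mode)
      sols[[k]] <- .selection_solution(res$best, res$best_eval, test_fit,
                                       list(algorithm = alg, run = r,
                                            seed = seeds[k]))
    }
  }
  ord <- order(-vapply(sols, function(s) s$test_fit$cfi, numeric(1)),
               vapply(sols, function(s) s$test_fit$rmsea, numeric(1)),
               vapply(sols, function(s) s$test_fit$srmr, numeric(1)))
  sols[ord]
}

#' Consensus over the top solutions
#'
#' A facet is resolved when the same unordered item pair occurs in at least
#' two of the top solutions; otherwise the facet's candidate set is the
#' union of its items across those solutions.
#'
#' @param top_solutions list of `selection_solution`s (usually the best 3).
#' @return object of class `consensus_report`: `resolved` (facet -> item
#'   pair), `unresolved` (facet -> candidate item set).
#' @export
consensus <- function(top_solutions) {
  if (length(top_solutions) < 2) stop("need at least 2 solutions")
  facets <- names(top_solutions[[1]]$items)
  resolved <- list(); unresolved <- list()
  for (f in facets) {
    pairs <- vapply(top_solutions, function(s) paste(sort(s$items[[f]]), collapse = "|"),
                    character(1))
    tab <- sort(table(pairs), decreasing = TRUE)
    if (tab[1] >= 2) {
      resolved[[f]] <- strsplit(names(tab)[1], "|", fixed = TRUE)[[1]]
    } else {
      unresolved[[f]] <- sort(unique(unlist(lapply(top_solutions,
                                                   function(s) s$items[[f]]))))
    }
  }
  structure(list(resolved = resolved, unresolved = unresolved),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("consensus_report: %d facets resolved, %d unresolved\n",
              length(x$resolved), length(x$unresolved)))
  invisible(x)
}

#' Brute-force completion of unresolved facets
#'
#' Enumerates the Cartesian product of all candidate pairs for the
#' unresolved facets (resolved facets held fixed) and fits every resulting
#' full model on the training half.
#'
#' @param context_train an [aco_context()].
#' @param consensus_report a [consensus()] result.
#' @param objective objective used to score each candidate on the training
#'   half.
#' @param mode model mode.
#' @param cap enumeration cap (default 1e5 combinations).
#' @return list of candidates, each with `items`, `objective`, `components`,
#'   `admissible`; sorted by training objective.
#' @export
brute_force_completion <- function(context_train, consensus_report,
                                   objective = stock_objective("A"),
                                   mode = "tau_equivalent", cap = 1e5) {
  res <- consensus_report$resolved
  unres <- consensus_report$unresolved
  pair_sets <- lapply(unres, function(cand) combn(cand, 2, simplify = FALSE))
  n_comb <- prod(vapply(pair_sets, length, numeric(1)))
  if (n_comb > cap)
    stop(sprintf("enumeration of %g combinations exceeds the cap (%g); tighten the candidate sets",
                 n_comb, cap))
  grid <- if (length(pair_sets)) do.call(expand.grid,
                                         c(lapply(pair_sets, seq_along),
                                           KEEP.OUT.ATTRS = FALSE))
          else data.frame(row.names = 1)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sol <- res
    for (f in names(pair_sets)) sol[[f]] <- pair_sets[[f]][[grid[i, f]]]
    sol <- sol[context_train$pool$facets]
    ev <- .evaluate_cached(sol, context_train, objective, mode)
    out[[i]] <- list(items = sol, objective = ev$value,
                     components = ev$components, admissible = ev$admissible)
  }
  out[order(-vapply(out, `[[`, numeric(1), "objective"))]
}

#' Final ranking on the test half
#'
#' Fits every candidate on the test half, drops any candidate with a
#' test-set Heywood flag or non-convergence, and ranks the rest by test CFI,
#' then RMSEA, then mean omega.  The choice among closely ranked candidates
#' on semantic/content grounds is deliberately left to the user.
#'
#' @param candidates list from [brute_force_completion()] (each with
#'   `items`).
#' @param context_test test-half [aco_context()].
#' @param mode model mode.
#' @param test_fits optional precomputed list of test `fit_result`s
#'   (parallel to `candidates`), for re-ranking without refitting.
#' @return object of class `final_ranking`: `ranked` (list with items, test
#'   fit and omega), `dropped` (excluded candidates with reasons), `table`
#'   (summary data frame).
#' @export
final_rank <- function(candidates, context_test, mode = "tau_equivalent",
                       test_fits = NULL) {
  if (is.null(test_fits))
    test_fits <- lapply(candidates, function(cand)
      .fit_selection_test(cand$items, context_test, mode))
  keep <- logical(length(candidates)); reason <- character(length(candidates))
  omega_mean <- cfi <- rmsea <- srmr <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    ft <- test_fits[[i]]
    if (!ft$converged) { reason[i] <- "non-convergence"; next }
    if (length(ft$heywood)) { reason[i] <- paste("Heywood:", paste(ft$heywood, collapse = ";")); next }
    keep[i] <- TRUE
    om <- omega_report(ft)
    omega_mean[i] <- mean(c(om$facet, om$domain_total), na.rm = TRUE)
    cfi[i] <- ft$cfi; rmsea[i] <- ft$rmsea; srmr[i] <- ft$srmr
  }
  if (!any(keep)) {
    return(structure(list(ranked = list(),
                          dropped = Map(function(c_, r) list(items = c_$items, reason = r),
                                        candidates, reason),
                          table = NULL,
                          note = "all candidates inadmissible on the test half"),
                     class = "final_ranking"))
  }
  idx <- which(keep)
  ord <- idx[order(-cfi[idx], rmsea[idx], -omega_mean[idx])]
  ranked <- lapply(ord, function(i) list(items = candidates[[i]]$items,
                                         test_fit = test_fits[[i]],
                                         mean_omega = omega_mean[i]))
  tab <- data.frame(rank = seq_along(ord), cfi = cfi[ord], rmsea = rmsea[ord],
                    srmr = srmr[ord], mean_omega = omega_mean[ord])
  structure(list(ranked = ranked,
                 dropped = Map(function(c_, r) list(items = c_$items, reason = r),
                               candidates[!keep], reason[!keep]),
                 table = tab,
                 note = "content validity of near-tied candidates is a human judgment"),
            class = "final_ranking")
}

#' @export
print.final_ranking <- function(x, ...) {
  cat(sprintf("final_ranking: %d admissible candidates, %d dropped\n",
              length(x$ranked), length(x$dropped)))
  if (!is.null(x$table)) print(head(x$table, 5))
  invisible(x)
}

#' Full short-form construction pipeline
#'
#' Split, search (both stock objectives, `runs_per_algorithm` runs each),
#' consensus over the best three solutions by test fit, brute-force
#' completion, final ranking.
#'
#' @param resp response data frame over the pool items.
#' @param pool pool [instrument_spec()].
#' @param test_ratio test fraction (default 0.30).
#' @param strata optional stratum labels for the split.
#' @param seed master seed; all child seeds derive from it.
#' @param runs_per_algorithm default 3.
#' @param config base [aco_config()].
#' @param mode model mode.
#' @param jackknife_groups weight-estimation blocks (see [acov_diag()]).
#' @return list: `split`, `solutions` (all runs, sorted by test fit),
#'   `consensus`, `candidates`, `ranking`, and `final` (top-ranked
#'   selection).
#' @export
shorten_scale <- function(resp, pool, test_ratio = 0.30, strata = NULL,
                          seed = 1L, runs_per_algorithm = 3L,
                          config = aco_config(), mode = "tau_equivalent",
                          jackknife_groups = 30L) {
  seeds <- derive_seeds(seed, 2)
  split <- split_train_test(resp, test_ratio, strata, seed = seeds[1])
  ctx_train <- aco_context(resp[split$train, , drop = FALSE], pool, jackknife_groups)
  ctx_test <- aco_context(resp[split$test, , drop = FALSE], pool, jackknife_groups)
  sols <- run_multistart(ctx_train, ctx_test, seed = seeds[2], config = config,
                         runs_per_algorithm = runs_per_algorithm, mode = mode)
  top <- sols[seq_len(min(3, length(sols)))]
  cons <- consensus(top)
  n_comb <- prod(vapply(cons$unresolved, function(cand) choose(length(cand), 2),
                        numeric(1)))
  if (n_comb <= 1e5) {
    cands <- brute_force_completion(ctx_train, cons)
  } else {
    # near-tied runs can disagree on many facets at once; full enumeration
    # of the candidate product is then hopeless, so unresolved facets are
    # completed greedily from the best solution (coordinate-wise, which the
    # evaluation cache makes cheap) before ranking
    cands <- list(.greedy_completion(ctx_train, cons, top[[1]]$items, mode))
  }
  # the top solutions themselves always stand as candidates
  keys <- vapply(cands, function(cc) .sol_key(cc$items), character(1))
  for (s in top) {
    if (.sol_key(s$items) %in% keys) next
    ev <- .evaluate_cached(s$items, ctx_train, stock_objective("A"), mode)
    cands <- c(cands, list(list(items = s$items, objective = ev$value,
                                components = ev$components,
                                admissible = ev$admissible)))
  }
  rank <- final_rank(cands, ctx_test, mode)
  list(split = split, solutions = sols, consensus = cons,
       candidates = cands, ranking = rank,
       final = if (length(rank$ranked)) rank$ranked[[1]] else NULL)
}

# complete unresolved facets one at a time, holding the rest at the given
# base selection, then sweep until stable
.greedy_completion <- function(context, consensus_report, base, mode,
                               objective = stock_objective("A")) {
  sol <- base[context$pool$facets]
  for (f in names(consensus_report$resolved))
    sol[[f]] <- consensus_report$resolved[[f]]
  best <- .evaluate_cached(sol, context, objective, mode)$value
  repeat {
    changed <- FALSE
    for (f in names(consensus_report$unresolved)) {
      for (pair in combn(consensus_report$unresolved[[f]], 2, simplify = FALSE)) {
        cand <- sol
        cand[[f]] <- pair
        ev <- .evaluate_cached(cand, context, objective, mode)
        if (ev$value > best + 1e-12) {
          sol <- cand; best <- ev$value; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ev <- .evaluate_cached(sol, context, objective, mode)
  list(items = sol, objective = ev$value, components = ev$components,
       admissible = ev$admissible)
}
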