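#' Construct an instrument specification
#'
#' An instrument specification fixes the item -> facet -> domain hierarchy and
#' the number of ordered response categories.  Category codes are 0-based
#' (a 4-point scale is coded 0..3).
#'
#' @param item_to_facet named character vector: names are item IDs, values the
#'   facet label of each item.
#' @param facet_to_domain named character vector: names are facet labels,
#'   values the domain label of each facet.
#' @param n_categories integer >= 2; responses take values
#'   `0 .. n_categories - 1`.
#' @return object of class `instrument_spec` with components `items`,
#'   `facets`, `domains`, `item_to_facet`, `facet_to_domain`, `n_categories`.
#'   Facet and domain order follow first appearance and are stable for
#'   reporting.
#' @export
instrument_spec <- function(item_to_facet, facet_to_domain, n_categories = 4L) {
  items <- names(item_to_facet)
  if (is.null(items) || anyNA(items) || any(items == ""))
    stop("every item needs an ID (names of item_to_facet)")
  if (anyDuplicated(items)) stop("duplicate item ID: ",
                                 paste(unique(items[duplicated(items)]), collapse = ", "))
  facets <- unique(unname(item_to_facet))
  if (anyDuplicated(names(facet_to_domain))) stop("duplicate facet label in facet_to_domain")
  orphan <- setdiff(facets, names(facet_to_domain))
  if (length(orphan)) stop("facet without a domain: ", paste(orphan, collapse = ", "))
  unused <- setdiff(names(facet_to_domain), facets)
  if (length(unused)) stop("facet with no items: ", paste(unused, collapse = ", "))
  sizes <- table(factor(item_to_facet, levels = facets))
  if (any(sizes < 2)) stop("facet with fewer than 2 items: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2) stop("n_categories must be >= 2")
  domains <- unique(unname(facet_to_domain[facets]))
  structure(list(
    items = items,
    facets = facets,
    domains = domains,
    item_to_facet = setNames(unname(item_to_facet), items),
    facet_to_domain = setNames(unname(facet_to_domain[facets]), facets),
    n_categories = n_categories
  ), class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("instrument_spec: %d items, %d facets, %d domains, %d categories\n",
              length(x$items), length(x$facets), length(x$domains), x$n_categories))
  invisible(x)
}

#' Load an instrument specification from a YAML document
#'
#' Expected layout:
#' \preformatted{
#' n_categories: 4
#' domains:
#'   DomainA:
#'     Facet1: [item1, item2]
#'     Facet2: [item3, item4]
#' }
#'
#' @param spec_doc path to a YAML file, or an equivalent nested list.
#' @return validated [instrument_spec()].
#' @export
load_instrument <- function(spec_doc) {
  doc <- if (is.character(spec_doc)) yaml::read_yaml(spec_doc) else spec_doc
  if (is.null(doc$domains)) stop("spec document lacks a 'domains' section")
  i2f <- character(0)
  f2d <- character(0)
  for (dname in names(doc$domains)) {
    facets <- doc$domains[[dname]]
    for (fname in names(facets)) {
      its <- as.character(unlist(facets[[fname]]))
      i2f <- c(i2f, setNames(rep(fname, length(its)), its))
      f2d <- c(f2d, setNames(dname, fname))
    }
  }
  if (anyDuplicated(names(i2f)))
    stop("item assigned to more than one facet: ",
         paste(unique(names(i2f)[duplicated(names(i2f))]), collapse = ", "))
  instrument_spec(i2f, f2d, n_categories = doc$n_categories %||% 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Items belonging to each facet of a spec
#' @param spec an [instrument_spec()].
#' @return named list, facet -> character vector of item IDs (spec order).
#' @export
facet_items <- function(spec) {
  split(spec$items, factor(spec$item_to_facet, levels = spec$facets))
}

#' Restrict an instrument spec to a subset of its items
#'
#' @param spec an [instrument_spec()].
#' @param items character vector of item IDs to keep.
#' @return a new `instrument_spec` over the kept items (facets losing all but
#'   one item are rejected, since facets need >= 2 items).
#' @export
subset_instrument <- function(spec, items) {
  stopifnot(all(items %in% spec$items))
  keep <- spec$items[spec$items %in% items]
  i2f <- spec$item_to_facet[keep]
  instrument_spec(i2f, spec$facet_to_domain[unique(unname(i2f))],
                  n_categories = spec$n_categories)
}

#' Score facet, domain, and total scales from item responses
#'
#' Facet score = mean of the facet's observed item responses, on the category
#' scale; a facet is missing when fewer than `min_item_coverage` of its items
#' were answered.  Domain score = unweighted mean of its (non-missing) facet
#' scores; total = unweighted mean of all facet scores.  Missingness
#' propagates upward only through the coverage rule: a domain score is missing
#' iff all of its facet scores are missing.
#'
#' @param resp data frame (or matrix) holding one column per spec item;
#'   additional columns are ignored.  Values are category codes or `NA`.
#' @param spec an [instrument_spec()].
#' @param min_item_coverage minimum fraction of a facet's items that must be
#'   observed for the facet score to be computed (default 0.5).
#' @return object of class `scale_scores`: list with matrices `facet`
#'   (n x facets), `domain` (n x domains) and vector `total`.
#' @export
score_scales <- function(resp, spec, min_item_coverage = 0.5) {
  missing_items <- setdiff(spec$items, colnames(resp))
  if (length(missing_items))
    stop("spec item absent from response matrix: ",
         paste(missing_items, collapse = ", "))
  X <- as.matrix(as.data.frame(resp)[, spec$items, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  fi <- facet_items(spec)
  facet <- matrix(NA_real_, n, length(spec$facets),
                  dimnames = list(rownames(resp), spec$facets))
  for (f in spec$facets) {
    sub <- X[, fi[[f]], drop = FALSE]
    obs <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[obs < min_item_coverage * length(fi[[f]]) | obs == 0] <- NA_real_
    facet[, f] <- m
  }
  fd <- split(spec$facets, factor(spec$facet_to_domain, levels = spec$domains))
  domain <- matrix(NA_real_, n, length(spec$domains),
                   dimnames = list(rownames(resp), spec$domains))
  for (d in spec$domains) {
    sub <- facet[, fd[[d]], drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    m[rowSums(!is.na(sub)) == 0] <- NA_real_
    domain[, d] <- m
  }
  total <- rowMeans(facet, na.rm = TRUE)
  total[rowSums(!is.na(facet)) == 0] <- NA_real_
  structure(list(facet = facet, domain = domain, total = total),
            class = "scale_scores")
}

#' Per-scale reference means and SDs for z-standardization
#'
#' @param scores a [score_scales()] result from the reference (norm) sample.
#' @return list with `facet`, `domain`, `total`, each holding `mean` and `sd`.
#' @export
scale_reference <- function(scores) {
  one <- function(M) list(mean = colMeans(M, na.rm = TRUE),
                          sd = apply(M, 2, sd, na.rm = TRUE))
  out <- list(facet = one(scores$facet), domain = one(scores$domain),
              total = list(mean = mean(scores$total, na.rm = TRUE),
                           sd = sd(scores$total, na.rm = TRUE)))
  structure(out, class = "scale_reference")
}

#' z-standardize scale scores against a reference sample
#'
#' @param scores a `scale_scores` object.
#' @param reference a [scale_reference()] object (zero SDs are an error).
#' @return `scale_scores` object on the z scale.
#' @export
z_standardize <- function(scores, reference) {
  chk <- c(reference$facet$sd, reference$domain$sd, reference$total$sd)
  if (any(chk <= 0 | !is.finite(chk))) stop("zero reference SD")
  zs <- function(M, r) sweep(sweep(M, 2, r$mean), 2, r$sd, "/")
  structure(list(
    facet = zs(scores$facet, reference$facet),
    domain = zs(scores$domain, reference$domain),
    total = (scores$total - reference$total$mean) / reference$total$sd
  ), class = "scale_scores")
}

#' Read a response matrix from delimited text
#'
#' CSV with a header row; item columns carry item IDs, empty cells are
#' missing.  A column named `group` holds group labels; columns prefixed
#' `crit_` hold continuous criterion variables.
#'
#' @param file path to a CSV file.
#' @param spec optional [instrument_spec()] for validation.
#' @return data frame; item columns integer, `group` character, criteria
#'   numeric.
#' @export
read_responses <- function(file, spec = NULL) {
  d <- read.csv(file, check.names = FALSE, na.strings = c("", "NA"))
  if (!is.null(spec)) {
    miss <- setdiff(spec$items, colnames(d))
    if (length(miss)) stop("response file lacks items: ", paste(miss, collapse = ", "))
    rng <- range(as.matrix(d[, spec$items]), na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > spec$n_categories - 1)
      stop("response outside 0..", spec$n_categories - 1)
  }
  d
}

#' Write a response matrix as delimited text
#' @param resp data frame as produced by [generate_responses()].
#' @param file output path.
#' @export
write_responses <- function(resp, file) {
  write.csv(resp, file, row.names = FALSE, na = "")
}
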