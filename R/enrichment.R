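# Over-representation statistics: expected class counts under random
# duplication, fold enrichment, exact hypergeometric upper-tail p-values and
# Benjamini-Hochberg FDR control, plus composition deltas in percentage
# points.

#' Class-count quadruple for an over-representation test
#'
#' @param N_total Number of genes in the genome (background).
#' @param n_selected Number of genes in the selection (e.g. duplicated).
#' @param K_class Class size genome-wide.
#' @param k_observed Class members observed in the selection.
#' @return A `class_counts` list.
#' @export
class_counts <- function(N_total, n_selected, K_class, k_observed = 0L) {
  stopifnot(N_total >= 1, n_selected >= 0, K_class >= 0, k_observed >= 0,
            K_class <= N_total, n_selected <= N_total,
            k_observed <= min(n_selected, K_class))
  structure(list(N_total = as.integer(N_total),
                 n_selected = as.integer(n_selected),
                 K_class = as.integer(K_class),
                 k_observed = as.integer(k_observed)),
            class = "class_counts")
}

#' Expected class count under random selection
#'
#' The number of class members one would find by chance in a random
#' selection: `K_class * n_selected / N_total`.
#'
#' @param counts A [class_counts()] object.
#' @return Expected count (also the hypergeometric mean).
#' @export
expected_count <- function(counts) {
  stopifnot(inherits(counts, "class_counts"))
  counts$K_class * counts$n_selected / counts$N_total
}

#' Fold enrichment of an observation over its expectation
#'
#' Works on counts or on percentages, as long as both arguments share the
#' same scale.
#'
#' @param observed Observed count or fraction.
#' @param expected Expected count or fraction (> 0).
#' @return `observed / expected`.
#' @export
fold_enrichment <- function(observed, expected) {
  if (any(expected <= 0)) {
    stop("fold enrichment undefined for expected <= 0")
  }
  observed / expected
}

#' Exact hypergeometric upper-tail p-value
#'
#' P\[X >= k_observed\] for X ~ Hypergeometric(N_total, K_class, n_selected):
#' the probability of drawing at least as many class members when
#' `n_selected` genes are sampled without replacement. Only
#' over-representation (the upper tail) is tested.
#'
#' @param counts A [class_counts()] object.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_pvalue <- function(counts) {
  stopifnot(inherits(counts, "class_counts"))
  if (counts$k_observed == 0L) return(1)
  stats::phyper(counts$k_observed - 1L, counts$K_class,
                counts$N_total - counts$K_class, counts$n_selected,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: q for the i-th smallest p is
#' `min over j >= i of p_(j) * m / j`, capped at 1, mapped back to input
#' order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Term over-representation in a selection
#'
#' One exact hypergeometric test per term with at least one annotated
#' protein in the background; q-values by Benjamini-Hochberg over all tested
#' terms. Terms with zero observed members are part of the correction but
#' reported only with `include_zero = TRUE`.
#'
#' @param selection Character vector of selected protein ids.
#' @param annotations Annotation object from [read_annotations()], or a
#'   plain named list term -> protein ids.
#' @param background Character vector of background protein ids
#'   (the selection must be a subset).
#' @param alpha FDR significance level; `significant` means q < alpha.
#' @param include_zero Keep rows for terms with `k = 0`.
#' @return Data.frame sorted by (q, p): `term`, `k`, `K`, `n`, `N`,
#'   `expected`, `fold`, `p`, `q`, `significant`.
#' @export
term_enrichment <- function(selection, annotations, background,
                            alpha = 0.05, include_zero = FALSE) {
  term_map <- if (is.list(annotations) && !is.null(annotations$terms)) {
    annotations$terms
  } else {
    annotations
  }
  stopifnot(is.list(term_map), length(term_map) > 0L)
  selection <- unique(selection)
  background <- unique(background)
  extra <- setdiff(selection, background)
  if (length(extra) > 0L) {
    stop("selection not contained in background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  N <- length(background)
  n <- length(selection)
  rows <- lapply(names(term_map), function(term) {
    members <- intersect(term_map[[term]], background)
    K <- length(members)
    if (K == 0L) return(NULL)   # no background annotation: not tested
    k <- length(intersect(members, selection))
    cc <- class_counts(N, n, K, k)
    exp_k <- expected_count(cc)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               expected = exp_k,
               fold = if (exp_k > 0) k / exp_k else NA_real_,
               p = hypergeom_pvalue(cc),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term has an annotated protein in the background")
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < alpha
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  if (!include_zero) res <- res[res$k > 0L, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Composition difference between a selection and the background
#'
#' For each category, the percentage of the selection in that category minus
#' the percentage of the background in it, in percentage points. Proteins
#' missing from the category map fall into `"unknown"`. Deltas sum to zero
#' across categories.
#'
#' @param selection Character vector of selected protein ids.
#' @param background Character vector of background protein ids.
#' @param categories Named character vector mapping protein id -> category.
#' @return Named numeric vector of signed percentage-point deltas.
#' @export
composition_delta <- function(selection, background, categories) {
  stopifnot(length(selection) > 0L, length(background) > 0L)
  lookup <- function(ids) {
    cat <- unname(categories[ids])
    cat[is.na(cat)] <- "unknown"
    cat
  }
  sel_cat <- lookup(unique(selection))
  bg_cat <- lookup(unique(background))
  cats <- sort(unique(c(sel_cat, bg_cat)))
  sel_frac <- vapply(cats, function(cl) mean(sel_cat == cl), numeric(1))
  bg_frac <- vapply(cats, function(cl) mean(bg_cat == cl), numeric(1))
  100 * (sel_frac - bg_frac)
}
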