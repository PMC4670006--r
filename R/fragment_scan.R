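# Continuous-fragment scan: enumerate every k-gene stretch within a
# chromosome, score each by its long-disorder content, rank a query region
# against the genome-wide distribution, and pick a minimal-disorder
# duplication plan under a gene budget.

# flags (0/1 long-disorder indicator) in gene order for one chromosome
chrom_flags <- function(genome_map, calls, chromosome, T) {
  cc <- calls_for_chromosome(genome_map, calls, chromosome)
  col <- paste0("long_", T)
  if (!col %in% names(cc)) stop("no column '", col, "' in calls")
  as.integer(cc[[col]])
}

#' Enumerate all continuous k-gene windows
#'
#' Windows advance one gene at a time and never span chromosomes; a
#' chromosome with n genes contributes `n - k + 1` windows (none if n < k).
#'
#' @param genome_map Genome map data.frame, see [genome_map()].
#' @param k Window size in genes (>= 1).
#' @param calls Optional disorder calls; when given, each window is scored.
#' @param T Run-length threshold used for scoring.
#' @return Data.frame `chromosome`, `start_ordinal` (0-based), `k`, and —
#'   when `calls` is supplied — `n_flagged`, `pct_long`.
#' @export
enumerate_windows <- function(genome_map, k, calls = NULL, T = 30L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L) {
    stop("window size k must be a single integer >= 1")
  }
  k <- as.integer(k)
  chroms <- unique(genome_map$chromosome)
  pieces <- lapply(chroms, function(ch) {
    n <- sum(genome_map$chromosome == ch)
    if (n < k) return(NULL)
    out <- data.frame(chromosome = ch,
                      start_ordinal = 0:(n - k),
                      k = k, stringsAsFactors = FALSE)
    if (!is.null(calls)) {
      flags <- chrom_flags(genome_map, calls, ch, T)
      cs <- c(0L, cumsum(flags))
      out$n_flagged <- cs[out$start_ordinal + k + 1L] -
        cs[out$start_ordinal + 1L]
      out$pct_long <- 100 * out$n_flagged / k
    }
    out
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(0), start_ordinal = integer(0),
                      k = integer(0), stringsAsFactors = FALSE)
    if (!is.null(calls)) {
      out$n_flagged <- integer(0); out$pct_long <- numeric(0)
    }
  }
  rownames(out) <- NULL
  out
}

#' Protein ids inside one window
#'
#' @inheritParams enumerate_windows
#' @param chromosome Chromosome label.
#' @param start_ordinal 0-based ordinal of the first gene in the window.
#' @return Character vector of protein ids in gene order.
#' @export
window_proteins <- function(genome_map, chromosome, start_ordinal, k) {
  sel <- genome_map$chromosome == chromosome &
    genome_map$ordinal >= start_ordinal &
    genome_map$ordinal < start_ordinal + k
  ids <- genome_map$protein_id[sel]
  if (length(ids) != k) {
    stop("window [", start_ordinal, ", ", start_ordinal + k,
         ") does not fit on chromosome '", chromosome, "'")
  }
  ids
}

#' Score one window by its long-disorder content
#'
#' @inheritParams window_proteins
#' @param calls Disorder calls, see [disorder_calls()].
#' @param T Run-length threshold.
#' @return Percentage of the window's proteins flagged at threshold `T`.
#' @export
score_window <- function(genome_map, calls, chromosome, start_ordinal, k,
                         T = 30L) {
  ids <- window_proteins(genome_map, chromosome, start_ordinal, k)
  missing <- setdiff(ids, calls$protein_id)
  if (length(missing) > 0L) {
    stop("no disorder call for: ", paste(missing, collapse = ", "))
  }
  pct_long(calls[match(ids, calls$protein_id), , drop = FALSE], T)
}

# normalise a query specification: a chromosome label means the whole
# chromosome (k = its gene count); otherwise list(chromosome, start_ordinal, k)
resolve_query <- function(genome_map, query) {
  if (is.character(query) && length(query) == 1L) {
    n <- sum(genome_map$chromosome == query)
    if (n == 0L) stop("query chromosome '", query, "' not in genome map")
    list(chromosome = query, start_ordinal = 0L, k = n)
  } else if (is.list(query) &&
             all(c("chromosome", "start_ordinal", "k") %in% names(query))) {
    query
  } else {
    stop("query must be a chromosome label or ",
         "list(chromosome, start_ordinal, k)")
  }
}

#' Rank a query region against all same-size fragments genome-wide
#'
#' Enumerates every continuous window of the query's size across all
#' chromosomes and reports the fraction with long-disorder content less than
#' or equal to the query's (ties inclusive; the query's own window counts in
#' both numerator and denominator). A small percentile means few regions of
#' that size are as disorder-poor as the query.
#'
#' @inheritParams score_window
#' @param query A chromosome label (whole chromosome) or a
#'   `list(chromosome =, start_ordinal =, k =)` fragment.
#' @return Object of class `scan_result`: list with `chromosome`,
#'   `start_ordinal`, `k`, `T`, `query_pct`, `windows_total`,
#'   `windows_leq_query`, `percentile`.
#' @export
scan_percentile <- function(genome_map, calls, query, T = 30L) {
  q <- resolve_query(genome_map, query)
  windows <- enumerate_windows(genome_map, q$k, calls, T)
  if (nrow(windows) == 0L) {
    stop("no chromosome holds a window of ", q$k, " genes")
  }
  hit <- windows$chromosome == q$chromosome &
    windows$start_ordinal == q$start_ordinal
  if (!any(hit)) {
    stop("query is not a contiguous ", q$k, "-gene window on '",
         q$chromosome, "'")
  }
  q_flagged <- windows$n_flagged[hit]
  res <- list(chromosome = q$chromosome,
              start_ordinal = q$start_ordinal,
              k = q$k, T = T,
              query_pct = 100 * q_flagged / q$k,
              windows_total = nrow(windows),
              # integer flag counts, so tie comparison is exact
              windows_leq_query = sum(windows$n_flagged <= q_flagged),
              percentile = NA_real_)
  res$percentile <- res$windows_leq_query / res$windows_total
  class(res) <- "scan_result"
  res
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "fragment scan: %s[%d..%d) k=%d T=%d\n  query %%long = %.1f\n  %d of %d windows have as little disorder (percentile %.2f%%)\n",
    x$chromosome, x$start_ordinal, x$start_ordinal + x$k, x$k, x$T,
    x$query_pct, x$windows_leq_query, x$windows_total, 100 * x$percentile))
  invisible(x)
}

windows_overlap <- function(chrom1, start1, k1, chrom2, start2, k2) {
  chrom1 == chrom2 && start1 < start2 + k2 && start2 < start1 + k1
}

#' Select a minimal-disorder duplication plan under a gene budget
#'
#' Implements the selection rule "find a small enough chromosome with
#' minimal protein disorder and duplicate it, along with other fragments
#' also depleted of disorder": the primary region is the whole chromosome
#' with the lowest %long among those whose gene count fits the budget
#' (ties: fewer genes, then lexicographic label); each requested extra
#' fragment is the minimum-%long window of its size taken from any other
#' chromosome, never overlapping a previously chosen fragment (ties:
#' chromosome label, then start ordinal).
#'
#' @inheritParams score_window
#' @param budget Maximum gene count of the primary chromosome.
#' @param extra_sizes Integer vector of extra fragment sizes (genes).
#' @return Object of class `duplication_plan`: list with `primary_region`,
#'   `primary_pct`, `primary_n`, `extra_fragments` (data.frame), `budget`,
#'   `total_genes`, `total_pct_long`, `T`.
#' @export
postdict <- function(genome_map, calls, budget, T = 30L,
                     extra_sizes = integer(0)) {
  chroms <- unique(genome_map$chromosome)
  sizes <- vapply(chroms, function(ch) sum(genome_map$chromosome == ch),
                  integer(1))
  fits <- sizes <= budget
  if (!any(fits)) {
    stop("no chromosome fits the budget of ", budget, " genes (smallest: ",
         min(sizes), ")")
  }
  pcts <- vapply(chroms[fits], function(ch) {
    pct_long(calls_for_chromosome(genome_map, calls, ch), T)
  }, numeric(1))
  cand <- data.frame(chromosome = chroms[fits], n = sizes[fits], pct = pcts,
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$pct, cand$n, cand$chromosome), , drop = FALSE]
  primary <- cand[1, ]

  chosen <- data.frame(chromosome = character(0), start_ordinal = integer(0),
                       k = integer(0), pct_long = numeric(0),
                       stringsAsFactors = FALSE)
  for (s in extra_sizes) {
    windows <- enumerate_windows(genome_map, s, calls, T)
    windows <- windows[windows$chromosome != primary$chromosome, ,
                       drop = FALSE]
    if (nrow(chosen) > 0L) {
      free <- vapply(seq_len(nrow(windows)), function(i) {
        !any(vapply(seq_len(nrow(chosen)), function(j) {
          windows_overlap(windows$chromosome[i], windows$start_ordinal[i],
                          windows$k[i], chosen$chromosome[j],
                          chosen$start_ordinal[j], chosen$k[j])
        }, logical(1)))
      }, logical(1))
      windows <- windows[free, , drop = FALSE]
    }
    if (nrow(windows) == 0L) {
      stop("no non-overlapping window of ", s, " genes available for an ",
           "extra fragment")
    }
    windows <- windows[order(windows$pct_long, windows$chromosome,
                             windows$start_ordinal), , drop = FALSE]
    chosen <- rbind(chosen, windows[1, c("chromosome", "start_ordinal", "k",
                                         "pct_long")])
  }
  rownames(chosen) <- NULL

  dup_ids <- c(window_proteins(genome_map, primary$chromosome, 0L, primary$n),
               unlist(lapply(seq_len(nrow(chosen)), function(j) {
                 window_proteins(genome_map, chosen$chromosome[j],
                                 chosen$start_ordinal[j], chosen$k[j])
               })))
  plan <- list(primary_region = primary$chromosome,
               primary_pct = primary$pct,
               primary_n = primary$n,
               extra_fragments = chosen,
               budget = as.integer(budget),
               total_genes = length(dup_ids),
               total_pct_long = pct_long(
                 calls[match(dup_ids, calls$protein_id), , drop = FALSE], T),
               duplicated_ids = dup_ids,
               T = T)
  class(plan) <- "duplication_plan"
  plan
}

#' @export
print.duplication_plan <- function(x, ...) {
  cat(sprintf(
    "duplication plan (budget %d genes, T = %d):\n  primary: %s (%d genes, %%long = %.1f)\n",
    x$budget, x$T, x$primary_region, x$primary_n, x$primary_pct))
  if (nrow(x$extra_fragments) > 0L) {
    for (j in seq_len(nrow(x$extra_fragments))) {
      f <- x$extra_fragments[j, ]
      cat(sprintf("  extra:   %s[%d..%d) (%d genes, %%long = %.1f)\n",
                  f$chromosome, f$start_ordinal, f$start_ordinal + f$k, f$k,
                  f$pct_long))
    }
  }
  cat(sprintf("  total: %d genes, %%long = %.1f\n", x$total_genes,
              x$total_pct_long))
  invisible(x)
}

#' Change in proteome-wide %long if a duplication plan were executed
#'
#' Counts every duplicated gene twice and reports the %long of the enlarged
#' proteome minus the original %long. Negative values mean the duplication
#' dilutes long disorder.
#'
#' @inheritParams score_window
#' @param plan A [postdict()] plan.
#' @return Signed difference in percentage points.
#' @export
disorder_delta <- function(genome_map, calls, plan, T = 30L) {
  stopifnot(inherits(plan, "duplication_plan"))
  base <- calls[match(genome_map$protein_id, calls$protein_id), ,
                drop = FALSE]
  if (anyNA(base$protein_id)) {
    stop("some mapped genes have no disorder call")
  }
  col <- paste0("long_", T)
  p_flags <- base[[col]]
  d_flags <- base[[col]][match(plan$duplicated_ids, base$protein_id)]
  100 * (sum(p_flags) + sum(d_flags)) / (length(p_flags) + length(d_flags)) -
    100 * mean(p_flags)
}
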