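# Long-disorder calling: per-residue scores -> binary labels -> maximal runs
# -> %longT statistics per protein set and per chromosome (with bootstrap
# error bars).

#' Binarise per-residue disorder scores
#'
#' A residue is labelled disordered when its score is at or above the cutoff
#' (boundary inclusive). 0.5 is the conventional cutoff for IUPred-style
#' scores.
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param threshold Score cutoff in (0, 1).
#' @return Integer vector of 0/1 labels, 1 = disordered.
#' @export
binarize <- function(scores, threshold = 0.5) {
  stopifnot(is.numeric(scores), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  as.integer(scores >= threshold)
}

#' Longest constant run in a binary label vector
#'
#' @param labels Vector of 0/1 labels.
#' @param value The label whose longest run is sought.
#' @return Length of the longest run of `value`; 0 if `value` is absent.
#' @export
longest_run <- function(labels, value = 1L) {
  stopifnot(all(labels %in% c(0L, 1L)))
  if (length(labels) == 0L) return(0L)
  r <- rle(as.integer(labels))
  hit <- r$values == value
  if (!any(hit)) return(0L)
  as.integer(max(r$lengths[hit]))
}

#' Call long-disorder features for one protein
#'
#' A protein carries "long disorder" at threshold T when it has at least T
#' consecutive residues labelled disordered (inclusive: a run of exactly T
#' counts). A protein is "completely disordered" when no window of 30
#' consecutive residues is free of predicted disorder, i.e. its longest
#' fully-ordered run is shorter than 30; proteins shorter than 30 residues
#' satisfy this vacuously and are flagged `short_protein`.
#'
#' @param labels 0/1 label vector for one protein (1 = disordered).
#' @param protein_id Protein identifier.
#' @param thresholds Integer run-length thresholds, default c(30, 50, 80).
#' @return One-row data.frame: `protein_id`, `length`,
#'   `max_disordered_run`, `max_ordered_run`, one logical `long_<T>` column
#'   per threshold, `completely_disordered`, `short_protein`.
#' @export
call_protein <- function(labels, protein_id, thresholds = c(30L, 50L, 80L)) {
  stopifnot(length(labels) > 0L, all(thresholds >= 1))
  max_dis <- longest_run(labels, 1L)
  max_ord <- longest_run(labels, 0L)
  out <- data.frame(protein_id = protein_id,
                    length = length(labels),
                    max_disordered_run = max_dis,
                    max_ordered_run = max_ord,
                    stringsAsFactors = FALSE)
  for (T in thresholds) out[[paste0("long_", T)]] <- max_dis >= T
  out$completely_disordered <- max_ord < 30L
  out$short_protein <- length(labels) < 30L
  out
}

#' Call long-disorder features for a whole score set
#'
#' @param scores Named list of per-residue score vectors (one per protein),
#'   as returned by [read_disorder_scores()].
#' @param cutoff Binarisation cutoff, see [binarize()].
#' @param thresholds Run-length thresholds, see [call_protein()].
#' @return Data.frame with one row per protein (see [call_protein()]).
#' @export
disorder_calls <- function(scores, cutoff = 0.5,
                           thresholds = c(30L, 50L, 80L)) {
  stopifnot(is.list(scores), length(scores) > 0L,
            !is.null(names(scores)), all(nzchar(names(scores))))
  rows <- lapply(names(scores), function(id) {
    call_protein(binarize(scores[[id]], cutoff), id, thresholds)
  })
  do.call(rbind, rows)
}

#' Percentage of proteins with long disorder at threshold T
#'
#' @param calls Data.frame of disorder calls (see [disorder_calls()]).
#' @param T Run-length threshold; the column `long_<T>` must exist.
#' @return Percentage in \[0, 100\].
#' @export
pct_long <- function(calls, T = 30L) {
  col <- paste0("long_", T)
  if (!is.data.frame(calls) || nrow(calls) == 0L) {
    stop("pct_long needs a nonempty set of calls")
  }
  if (!col %in% names(calls)) stop("no column '", col, "' in calls")
  100 * mean(calls[[col]])
}

calls_for_chromosome <- function(genome_map, calls, chromosome) {
  genes <- genome_map$protein_id[genome_map$chromosome == chromosome]
  if (length(genes) == 0L) {
    stop("chromosome '", chromosome, "' has no genes in the map")
  }
  missing <- setdiff(genes, calls$protein_id)
  if (length(missing) > 0L) {
    stop("no disorder call for gene(s) on '", chromosome, "': ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  }
  calls[match(genes, calls$protein_id), , drop = FALSE]
}

#' Summarise disorder composition of one chromosome
#'
#' Computes the chromosome's %long at each threshold, the percentage of
#' completely disordered proteins, the mean protein length, and a bootstrap
#' standard error for each %long (SD over resamples of the chromosome's
#' proteins with replacement).
#'
#' @param genome_map Genome map data.frame, see [genome_map()].
#' @param calls Disorder calls, see [disorder_calls()].
#' @param chromosome Chromosome label.
#' @param thresholds Run-length thresholds to summarise.
#' @param bootstrap_reps Number of bootstrap resamples (0 skips the SE).
#' @param seed RNG seed for the bootstrap.
#' @return One-row data.frame: `chromosome`, `n_proteins`,
#'   `pct_long_<T>` and `se_<T>` per threshold,
#'   `pct_completely_disordered`, `mean_protein_length`.
#' @export
summarize_chromosome <- function(genome_map, calls, chromosome,
                                 thresholds = c(30L, 50L, 80L),
                                 bootstrap_reps = 1000L, seed = 42L) {
  cc <- calls_for_chromosome(genome_map, calls, chromosome)
  n <- nrow(cc)
  out <- data.frame(chromosome = chromosome, n_proteins = n,
                    stringsAsFactors = FALSE)
  flag_mat <- as.matrix(cc[, paste0("long_", thresholds), drop = FALSE])
  for (i in seq_along(thresholds)) {
    out[[paste0("pct_long_", thresholds[i])]] <- 100 * mean(flag_mat[, i])
  }
  if (bootstrap_reps > 0L) {
    boot <- withr::with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(r) {
        idx <- sample.int(n, n, replace = TRUE)
        100 * colMeans(flag_mat[idx, , drop = FALSE])
      }, numeric(length(thresholds)))
    })
    boot <- matrix(boot, nrow = length(thresholds))
    for (i in seq_along(thresholds)) {
      out[[paste0("se_", thresholds[i])]] <- stats::sd(boot[i, ])
    }
  }
  out$pct_completely_disordered <- 100 * mean(cc$completely_disordered)
  out$mean_protein_length <- mean(cc$length)
  out
}

#' Summarise disorder composition of every chromosome
#'
#' @inheritParams summarize_chromosome
#' @return Data.frame with one row per chromosome, in map order.
#' @export
summarize_chromosomes <- function(genome_map, calls,
                                  thresholds = c(30L, 50L, 80L),
                                  bootstrap_reps = 1000L, seed = 42L) {
  chroms <- unique(genome_map$chromosome)
  do.call(rbind, lapply(seq_along(chroms), function(i) {
    summarize_chromosome(genome_map, calls, chroms[i], thresholds,
                         bootstrap_reps, seed + i - 1L)
  }))
}

#' Proteome-wide average %long across chromosome summaries
#'
#' @param summaries Data.frame from [summarize_chromosomes()].
#' @param weighting `"by_protein"` (weights chromosomes by gene count,
#'   i.e. the plain proteome percentage) or `"by_chromosome"` (unweighted
#'   mean of the per-chromosome percentages).
#' @return Named numeric vector, one average per `pct_long_<T>` column.
#' @export
proteome_average <- function(summaries,
                             weighting = c("by_protein", "by_chromosome")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  cols <- grep("^pct_long_", names(summaries), value = TRUE)
  w <- if (weighting == "by_protein") summaries$n_proteins
       else rep(1, nrow(summaries))
  vapply(cols, function(cl) stats::weighted.mean(summaries[[cl]], w),
         numeric(1))
}
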