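# A scaled-down generator configuration for fast unit and integration
# tests: five chromosomes, shorter proteins, same planted structure as the
# default (low-disorder chromosome, enriched term, low-degree group all on
# chrC).
small_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    chromosomes = c(chrA = 60L, chrB = 50L, chrC = 45L, chrD = 70L,
                    chrE = 55L),
    protein_length_mean = 150,
    protein_length_sd = 80,
    planted_low_chrom = "chrC",
    planted_low_degree_group = "chrC",
    mean_degree = 8,
    n_null_terms = 15L)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# disorder-call table built directly from given long-disorder flags
calls_from_flags <- function(ids, flags30, flags50 = NULL, flags80 = NULL) {
  df <- data.frame(protein_id = ids, length = 100L,
                   max_disordered_run = ifelse(flags30, 40L, 10L),
                   max_ordered_run = 60L,
                   long_30 = flags30, stringsAsFactors = FALSE)
  df$long_50 <- if (is.null(flags50)) rep(FALSE, length(ids)) else flags50
  df$long_80 <- if (is.null(flags80)) rep(FALSE, length(ids)) else flags80
  df$completely_disordered <- FALSE
  df$short_protein <- FALSE
  df
}

# genome map with one chromosome per element of `sizes`
map_from_sizes <- function(sizes) {
  stopifnot(!is.null(names(sizes)))
  genome_map(do.call(rbind, lapply(names(sizes), function(ch) {
    n <- sizes[[ch]]
    data.frame(protein_id = sprintf("%s_p%03d", ch, seq_len(n)),
               chromosome = ch, start = seq_len(n) * 100L,
               stringsAsFactors = FALSE)
  })))
}
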