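# Synthetic genome generator with planted structure: chromosomes of
# configurable gene counts, per-residue disorder with run-length control and
# one planted low-disorder chromosome, planted enriched annotation terms,
# and a random interaction graph with a planted low-degree node group.
# Everything derives from one master seed through named substreams, so each
# piece can be regenerated independently and reproducibly.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# independent, reproducible substream seeds below 2^31
sub_seed <- function(seed, stream) {
  offs <- c(genome = 11L, disorder = 23L, annotations = 53L, ppi = 37L)
  if (!stream %in% names(offs)) stop("unknown substream '", stream, "'")
  as.integer((as.numeric(seed) * 257 + offs[[stream]]) %% 2147483629)
}

#' Configuration of the synthetic genome
#'
#' Defaults mimic a budding-yeast-shaped genome: 16 nuclear chromosomes with
#' 90-750 genes each (about 5900 in total), lognormal protein lengths with
#' mean 450 residues, and per-residue disorder from a two-state Markov chain
#' whose stationary disorder probability (0.15) and persistence (lag-1
#' autocorrelation 0.94) put about half of all proteins over the 30-residue
#' long-disorder threshold. One small chromosome (`chr03`, the analog of a
#' minimal-disorder duplication target) carries a stationary-probability
#' offset of -0.10, which drops its long-disorder share by roughly 30
#' percentage points. The interaction graph is Erdos-Renyi with mean degree
#' 12; genes of the planted low-degree group attach with probability scaled
#' by 0.3 per planted endpoint. One planted annotation term covers half the
#' selection but only 5% of the background.
#'
#' @param seed Master seed; all substreams derive from it.
#' @param chromosomes Named integer vector: chromosome label -> gene count.
#' @param protein_length_mean,protein_length_sd Lognormal length moments
#'   (residues); lengths are floored at 30.
#' @param disorder_base_prob Stationary probability a residue is disordered;
#'   a scalar, or a named per-chromosome vector.
#' @param disorder_persistence Lag-1 autocorrelation of the disorder chain
#'   in (0, 1); higher values make longer runs at the same stationary
#'   probability.
#' @param planted_low_chrom Label of the planted low-disorder chromosome.
#' @param planted_low_offset Additive offset to that chromosome's stationary
#'   probability.
#' @param enriched_terms Data.frame `term`, `background_rate`,
#'   `selection_rate` of planted terms.
#' @param n_null_terms,null_term_rate Unplanted terms annotating every
#'   protein at a flat rate.
#' @param graph_model `"erdos_renyi"` (the only model currently shipped).
#' @param mean_degree Target mean degree of the interaction graph.
#' @param planted_low_degree_group Chromosome whose genes get the scaled
#'   attachment probability.
#' @param degree_multiplier Attachment-probability multiplier (< 1) per
#'   planted endpoint.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             chromosomes = c(
                               chr01 = 90L,  chr02 = 410L, chr03 = 155L,
                               chr04 = 750L, chr05 = 290L, chr06 = 125L,
                               chr07 = 540L, chr08 = 280L, chr09 = 220L,
                               chr10 = 360L, chr11 = 320L, chr12 = 500L,
                               chr13 = 470L, chr14 = 400L, chr15 = 550L,
                               chr16 = 460L),
                             protein_length_mean = 450,
                             protein_length_sd = 300,
                             disorder_base_prob = 0.15,
                             disorder_persistence = 0.94,
                             planted_low_chrom = "chr03",
                             planted_low_offset = -0.10,
                             enriched_terms = data.frame(
                               term = "T:PLANTED",
                               background_rate = 0.05,
                               selection_rate = 0.5,
                               stringsAsFactors = FALSE),
                             n_null_terms = 40L,
                             null_term_rate = 0.05,
                             graph_model = "erdos_renyi",
                             mean_degree = 12,
                             planted_low_degree_group = "chr03",
                             degree_multiplier = 0.3) {
  stopifnot(all(chromosomes >= 1L), !is.null(names(chromosomes)),
            disorder_persistence > 0, disorder_persistence < 1,
            all(disorder_base_prob >= 0), all(disorder_base_prob < 1),
            degree_multiplier > 0,
            graph_model == "erdos_renyi")
  if (!planted_low_chrom %in% names(chromosomes)) {
    stop("planted_low_chrom '", planted_low_chrom,
         "' is not a configured chromosome")
  }
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 protein_length_mean = protein_length_mean,
                 protein_length_sd = protein_length_sd,
                 disorder_base_prob = disorder_base_prob,
                 disorder_persistence = disorder_persistence,
                 planted_low_chrom = planted_low_chrom,
                 planted_low_offset = planted_low_offset,
                 enriched_terms = enriched_terms,
                 n_null_terms = as.integer(n_null_terms),
                 null_term_rate = null_term_rate,
                 graph_model = graph_model,
                 mean_degree = mean_degree,
                 planted_low_degree_group = planted_low_degree_group,
                 degree_multiplier = degree_multiplier),
            class = "synthetic_config")
}

chrom_disorder_prob <- function(config, chromosome) {
  p <- config$disorder_base_prob
  p <- if (length(p) > 1L) {
    if (!chromosome %in% names(p)) {
      stop("no disorder_base_prob for chromosome '", chromosome, "'")
    }
    p[[chromosome]]
  } else {
    p
  }
  if (chromosome == config$planted_low_chrom) {
    p <- p + config$planted_low_offset
  }
  if (p < 0 || p >= 1) {
    stop("disorder probability out of [0,1) for '", chromosome, "': ", p)
  }
  p
}

#' Generate the synthetic genome (proteins and gene map)
#'
#' @param config A [synthetic_config()].
#' @param sequences Also sample amino-acid sequences (uniform residue
#'   composition); disable for speed when only lengths and the map matter.
#' @return List with `proteins` (data.frame `id`, `length` and, if
#'   requested, `sequence`) and `map` (a [genome_map()] data.frame).
#' @export
gen_genome <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(sub_seed(config$seed, "genome"), {
    m <- config$protein_length_mean
    s <- config$protein_length_sd
    sdlog <- sqrt(log(1 + (s / m)^2))
    mulog <- log(m) - sdlog^2 / 2
    rows <- lapply(names(config$chromosomes), function(ch) {
      n <- config$chromosomes[[ch]]
      data.frame(protein_id = sprintf("%s_g%04d", ch, seq_len(n)),
                 chromosome = ch,
                 start = cumsum(sample.int(2000L, n, replace = TRUE)),
                 stringsAsFactors = FALSE)
    })
    map_df <- do.call(rbind, rows)
    lens <- pmax(as.integer(round(stats::rlnorm(nrow(map_df), mulog,
                                                sdlog))), 30L)
    proteins <- data.frame(id = map_df$protein_id, length = lens,
                           stringsAsFactors = FALSE)
    if (sequences) {
      proteins$sequence <- vapply(lens, function(L) {
        paste(sample(AA20, L, replace = TRUE), collapse = "")
      }, character(1))
    }
    list(proteins = proteins, map = genome_map(map_df))
  })
}

# one protein's 0/1 disorder labels: alternating geometric run lengths of a
# two-state chain with stationary prob pi0 and autocorrelation rho
markov_labels <- function(L, pi0, rho) {
  if (pi0 <= 0) return(rep(0L, L))
  stay1 <- pi0 + rho * (1 - pi0)
  stay0 <- (1 - pi0) + rho * pi0
  st <- stats::runif(1) < pi0
  vals <- integer(0); lens <- integer(0); pos <- 0L
  while (pos < L) {
    run <- 1L + stats::rgeom(1L, 1 - if (st) stay1 else stay0)
    run <- min(run, L - pos)
    vals <- c(vals, as.integer(st)); lens <- c(lens, run)
    pos <- pos + run; st <- !st
  }
  rep(vals, lens)
}

#' Generate per-residue disorder scores for the synthetic genome
#'
#' Residue states follow the two-state Markov chain of the configuration
#' (chromosome-specific stationary probability, shared persistence); the
#' emitted score is uniform on \[0.5, 1) for disordered residues and
#' \[0, 0.5) for ordered ones, so binarisation at 0.5 recovers the states
#' exactly.
#'
#' @param config A [synthetic_config()].
#' @param genome Output of [gen_genome()].
#' @return Named list mapping protein id to its per-residue score vector.
#' @export
gen_disorder <- function(config, genome) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(sub_seed(config$seed, "disorder"), {
    chrom <- genome$map$chromosome[match(genome$proteins$id,
                                         genome$map$protein_id)]
    rho <- config$disorder_persistence
    scores <- vector("list", nrow(genome$proteins))
    names(scores) <- genome$proteins$id
    for (i in seq_along(scores)) {
      L <- genome$proteins$length[i]
      labels <- markov_labels(L, chrom_disorder_prob(config, chrom[i]), rho)
      u <- stats::runif(L)
      scores[[i]] <- 0.5 * u + 0.5 * labels
    }
    scores
  })
}

#' Generate annotation terms with planted enrichment
#'
#' Null terms annotate every protein at a flat rate; each planted term
#' annotates proteins of the selection region at its `selection_rate` and
#' all other proteins at its `background_rate`.
#'
#' @param config A [synthetic_config()].
#' @param genome Output of [gen_genome()].
#' @param selection_ids Protein ids of the selection region; defaults to the
#'   genes of the planted low-disorder chromosome.
#' @return List with `terms` (named list term -> protein ids) and `planted`
#'   (character vector of planted term names).
#' @export
gen_annotations <- function(config, genome, selection_ids = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- genome$map$protein_id
  if (is.null(selection_ids)) {
    selection_ids <- ids[genome$map$chromosome == config$planted_low_chrom]
  }
  stopifnot(all(selection_ids %in% ids))
  withr::with_seed(sub_seed(config$seed, "annotations"), {
    terms <- list()
    if (config$n_null_terms > 0L) {
      for (i in seq_len(config$n_null_terms)) {
        hit <- stats::runif(length(ids)) < config$null_term_rate
        terms[[sprintf("T:NULL%03d", i)]] <- ids[hit]
      }
    }
    et <- config$enriched_terms
    in_sel <- ids %in% selection_ids
    if (!is.null(et) && nrow(et) > 0L) {
      for (i in seq_len(nrow(et))) {
        rate <- ifelse(in_sel, et$selection_rate[i], et$background_rate[i])
        hit <- stats::runif(length(ids)) < rate
        terms[[et$term[i]]] <- ids[hit]
      }
    }
    list(terms = terms,
         planted = if (is.null(et)) character(0) else et$term)
  })
}

# draw `size` unordered pairs uniformly without replacement from the C(m,2)
# pairs over 1..m, returned as a 2-column matrix of indices
sample_pairs <- function(m, size) {
  if (size == 0L || m < 2L) return(matrix(integer(0), ncol = 2))
  npairs <- m * (m - 1) / 2
  t <- sort(sample(npairs, size))
  cum <- cumsum(seq(m - 1, 1))          # pairs with first index <= i
  i <- findInterval(t - 0.5, c(0, cum))
  j <- i + (t - c(0, cum)[i])
  cbind(i, as.integer(j))
}

#' Generate the synthetic interaction graph
#'
#' Erdos-Renyi over all genes with edge probability `mean_degree/(n-1)`,
#' scaled by `degree_multiplier` for every endpoint in the planted
#' low-degree group.
#'
#' @param config A [synthetic_config()].
#' @param genome Output of [gen_genome()].
#' @return Data.frame `a`, `b`: a canonical undirected edge list.
#' @export
gen_ppi <- function(config, genome) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- genome$map$protein_id
  n <- length(ids)
  planted <- genome$map$chromosome == config$planted_low_degree_group
  normal_ids <- ids[!planted]
  planted_ids <- ids[planted]
  p0 <- config$mean_degree / (n - 1)
  mult <- config$degree_multiplier
  withr::with_seed(sub_seed(config$seed, "ppi"), {
    na <- length(normal_ids); nb <- length(planted_ids)
    # normal-normal pairs
    nn <- sample_pairs(na, stats::rbinom(1L, na * (na - 1) / 2, p0))
    # planted-planted pairs
    pp <- sample_pairs(nb, stats::rbinom(1L, nb * (nb - 1) / 2,
                                         p0 * mult^2))
    # mixed pairs
    nmix <- stats::rbinom(1L, na * nb, p0 * mult)
    t <- if (nmix > 0L) sample(na * nb, nmix) else integer(0)
    a <- c(normal_ids[nn[, 1]], planted_ids[pp[, 1]],
           normal_ids[(t - 1) %/% nb + 1])
    b <- c(normal_ids[nn[, 2]], planted_ids[pp[, 2]],
           planted_ids[(t - 1) %% nb + 1])
    edge_list(a, b)
  })
}

#' Write a complete synthetic data set to disk
#'
#' Produces `proteome.fasta`, `genome_map.tsv`, per-chromosome score tables
#' under `scores/`, `ppi.tsv`, `annotations.gaf`, `ontology.obo` and a
#' `manifest.yaml` recording the planted truth. The interaction file
#' deliberately contains reversed duplicate lines and self-interactions so
#' that reader contracts are exercised; the manifest records how many.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_synthetic_data <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- gen_genome(config, sequences = TRUE)
  scores <- gen_disorder(config, genome)
  ann <- gen_annotations(config, genome)
  edges <- gen_ppi(config, genome)

  seqs <- Biostrings::AAStringSet(stats::setNames(genome$proteins$sequence,
                                                  genome$proteins$id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteome.fasta"))

  map_out <- genome$map[, c("protein_id", "chromosome", "start")]
  utils::write.table(map_out, file.path(dir, "genome_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  score_dir <- file.path(dir, "scores")
  dir.create(score_dir, showWarnings = FALSE)
  chrom_of <- genome$map$chromosome[match(genome$proteins$id,
                                          genome$map$protein_id)]
  for (ch in names(config$chromosomes)) {
    idx <- which(chrom_of == ch)
    blocks <- vapply(idx, function(i) {
      id <- genome$proteins$id[i]
      res <- strsplit(genome$proteins$sequence[i], "")[[1]]
      sc <- scores[[id]]
      paste0("# ", id, "\n",
             paste(sprintf("%d\t%s\t%.4f", seq_along(sc), res, sc),
                   collapse = "\n"), "\n")
    }, character(1))
    writeLines(blocks, file.path(score_dir, paste0(ch, ".txt")))
  }

  n_rev <- min(50L, nrow(edges))
  n_self <- 10L
  ppi_lines <- c("# protein_a\tprotein_b",
                 paste(edges$a, edges$b, sep = "\t"),
                 if (n_rev > 0L)
                   paste(edges$b[seq_len(n_rev)], edges$a[seq_len(n_rev)],
                         sep = "\t"),
                 paste(genome$proteins$id[seq_len(n_self)],
                       genome$proteins$id[seq_len(n_self)], sep = "\t"))
  writeLines(ppi_lines, file.path(dir, "ppi.tsv"))

  gaf_lines <- c("!gaf-version: 2.1")
  for (term in names(ann$terms)) {
    ids <- ann$terms[[term]]
    if (length(ids) > 0L) {
      gaf_lines <- c(gaf_lines,
                     paste("SYN", ids, ids, "", term, "SYN:0000001", "IDA",
                           "", "P", sep = "\t"))
    }
  }
  writeLines(gaf_lines, file.path(dir, "annotations.gaf"))

  obo_lines <- c("format-version: 1.2", "",
                 "[Term]", "id: T:ROOT", "name: synthetic root")
  for (term in names(ann$terms)) {
    obo_lines <- c(obo_lines, "", "[Term]", paste0("id: ", term),
                   paste0("name: synthetic term ", term),
                   "is_a: T:ROOT ! synthetic root")
  }
  writeLines(obo_lines, file.path(dir, "ontology.obo"))

  manifest <- list(
    seed = config$seed,
    n_proteins = nrow(genome$proteins),
    chromosomes = as.list(config$chromosomes),
    planted_low_chrom = config$planted_low_chrom,
    planted_terms = as.list(ann$planted),
    planted_low_degree_group = config$planted_low_degree_group,
    degree_multiplier = config$degree_multiplier,
    n_edges = nrow(edges),
    ppi_dirt = list(reversed_duplicates = n_rev, self_loops = n_self))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
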