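# Readers for the external formats the pipeline touches: proteome FASTA,
# per-residue disorder score tables, gene maps (TSV/GFF3), interaction edge
# lists and GAF/OBO annotation files.  All readers tolerate '#' comment lines
# and trailing whitespace, and fail loudly with located messages.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X","B","Z","U")

#' Read a proteome from a FASTA file
#'
#' Each record becomes one protein; the header token before the first
#' whitespace is taken as the protein id. Sequences must use the 20 standard
#' amino-acid letters plus the ambiguity codes X/B/Z/U.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence`, `length` (residues).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("non-amino-acid characters in '", path, "': ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(seqs) == 0L) {
    stop("no records in FASTA file '", path, "'")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  }
  sequence <- toupper(as.character(seqs))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad)) {
    stop("non-amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(sequence) == 0L)) {
    stop("empty sequence in record(s): ",
         paste(ids[nchar(sequence) == 0L], collapse = ", "))
  }
  data.frame(id = ids, sequence = sequence, length = nchar(sequence),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove redundant proteins (exact copies and exact substrings)
#'
#' Redundancy at 100% pairwise identity: a sequence identical to, or fully
#' contained in, another sequence is dropped and the longer sequence kept.
#' Length ties are broken by keeping the lexicographically smaller id.
#'
#' @param proteins A data.frame as returned by [read_fasta()].
#' @return The filtered data.frame, rows in their original input order.
#' @export
dedup_proteome <- function(proteins) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L,
            all(c("id", "sequence") %in% names(proteins)))
  # visit candidates longest-first (ties: smaller id) so a sequence can only
  # be absorbed by one that would survive it
  ord <- order(-nchar(proteins$sequence), proteins$id)
  kept_seqs <- character(0)
  haystack <- ""          # kept sequences joined by '#', rebuilt lazily
  stale <- FALSE
  keep <- logical(nrow(proteins))
  for (i in ord) {
    s <- proteins$sequence[i]
    if (stale) {
      haystack <- paste(kept_seqs, collapse = "#")
      stale <- FALSE
    }
    if (nzchar(haystack) && grepl(s, haystack, fixed = TRUE)) next
    keep[i] <- TRUE
    kept_seqs <- c(kept_seqs, s)
    stale <- TRUE
  }
  proteins[keep, , drop = FALSE]
}

#' Read per-residue disorder scores
#'
#' Accepts either a single multi-record table or a directory of per-protein
#' files. Data lines hold `position residue score` (whitespace-separated);
#' lines starting with `#` are comments, except that a comment line whose
#' first token names a protein (e.g. `# P38764`) opens a new record. In a
#' directory, each file holds one protein and the file name (without
#' extension) is the id unless a record header names one. Positions must be
#' 1-based and consecutive; scores must lie in [0, 1].
#'
#' @param path A file or directory.
#' @return Named list mapping protein id to its numeric per-residue scores.
#' @export
read_disorder_scores <- function(path) {
  stopifnot(file.exists(path))
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("no score files in directory '", path, "'")
    out <- list()
    for (f in files) {
      default_id <- sub("\\.[^.]*$", "", basename(f))
      out <- c(out, parse_score_records(readLines(f, warn = FALSE), f,
                                        default_id))
    }
  } else {
    out <- parse_score_records(readLines(path, warn = FALSE), path, NULL)
  }
  if (length(out) == 0L) stop("no score records found in '", path, "'")
  if (anyDuplicated(names(out))) {
    stop("duplicate protein id(s) in scores: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  out
}

parse_score_records <- function(lines, path, default_id) {
  lines <- sub("[ \t\r]+$", "", lines)
  records <- list()
  cur_id <- default_id
  cur_pos <- integer(0)
  cur_score <- numeric(0)
  flush <- function() {
    if (length(cur_pos) == 0L) return()
    if (is.null(cur_id)) stop("unnamed score record in '", path, "'")
    check_positions(cur_pos, cur_id, path)
    records[[cur_id]] <<- cur_score[order(cur_pos)]
    cur_pos <<- integer(0); cur_score <<- numeric(0)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) { flush(); cur_id <- default_id; next }
    if (startsWith(line, "#")) {
      tok <- strsplit(sub("^#+[ \t>]*", "", line), "[ \t]+")[[1]]
      if (length(tok) >= 1L && nzchar(tok[1])) { flush(); cur_id <- tok[1] }
      next
    }
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(tok) < 3L) {
      stop("malformed score line ", ln, " in '", path, "': '", line, "'")
    }
    pos <- suppressWarnings(as.integer(tok[1]))
    score <- suppressWarnings(as.numeric(tok[length(tok)]))
    if (is.na(pos) || is.na(score)) {
      stop("malformed score line ", ln, " in '", path, "': '", line, "'")
    }
    if (score < 0 || score > 1) {
      stop("score out of range [0,1] at line ", ln, " in '", path, "': ",
           score)
    }
    cur_pos <- c(cur_pos, pos)
    cur_score <- c(cur_score, score)
  }
  flush()
  records
}

check_positions <- function(pos, id, path) {
  expect <- seq_along(pos)
  got <- sort(pos)
  if (!identical(as.integer(got), as.integer(expect))) {
    gap <- setdiff(expect, got)[1]
    if (is.na(gap)) gap <- got[which(got != expect)[1]]
    stop("positions for '", id, "' in '", path,
         "' are not 1-based consecutive: gap at ", gap)
  }
}

#' Build a genome map from protein/chromosome/start assignments
#'
#' Assigns within each chromosome a 0-based `ordinal` by ascending start
#' coordinate (ties broken by protein id). Gene order — not base-pair
#' distance — is the coordinate system for fragment windows.
#'
#' @param df A data.frame with columns `protein_id`, `chromosome`, `start`.
#' @return A data.frame with columns `protein_id`, `chromosome`, `start`,
#'   `ordinal`, ordered by chromosome (first appearance) then ordinal.
#' @export
genome_map <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("protein_id", "chromosome", "start") %in% names(df)))
  if (anyDuplicated(df$protein_id)) {
    dup <- unique(df$protein_id[duplicated(df$protein_id)])
    on_two <- vapply(dup, function(p) {
      length(unique(df$chromosome[df$protein_id == p])) > 1L
    }, logical(1))
    if (any(on_two)) {
      stop("protein(s) mapped to more than one chromosome: ",
           paste(dup[on_two], collapse = ", "))
    }
    stop("duplicate protein id(s) in genome map: ",
         paste(dup, collapse = ", "))
  }
  chrom_order <- unique(df$chromosome)
  df$chromosome <- factor(df$chromosome, levels = chrom_order)
  df <- df[order(df$chromosome, df$start, df$protein_id), , drop = FALSE]
  df$ordinal <- unlist(lapply(split(df$protein_id, df$chromosome, drop = TRUE),
                              function(x) seq_along(x) - 1L),
                       use.names = FALSE)
  df$chromosome <- as.character(df$chromosome)
  rownames(df) <- NULL
  df[, c("protein_id", "chromosome", "start", "ordinal")]
}

#' Read a gene-to-chromosome map
#'
#' @param path Path to the map file.
#' @param format `"tsv"` (header columns `protein_id`, `chromosome`, `start`)
#'   or `"gff3"` (gene features; the protein id is taken from the
#'   `protein_id` attribute, falling back to `ID`).
#' @return A genome map data.frame, see [genome_map()].
#' @export
read_genome_map <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("protein_id", "chromosome", "start")
    if (!all(need %in% names(df))) {
      stop("genome map TSV '", path, "' must have header columns ",
           paste(need, collapse = ", "))
    }
    df <- df[, need]
  } else {
    gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
    gr <- gr[gr$type == "gene", , drop = FALSE]
    if (nrow(gr) == 0L) stop("no gene features in GFF3 '", path, "'")
    ids <- if ("protein_id" %in% names(gr)) gr$protein_id else gr$ID
    if (is.null(ids) || anyNA(ids)) {
      stop("GFF3 gene features in '", path,
           "' lack a protein_id/ID attribute")
    }
    df <- data.frame(protein_id = as.character(ids),
                     chromosome = as.character(gr$seqnames),
                     start = gr$start,
                     stringsAsFactors = FALSE)
  }
  genome_map(df)
}

#' Read an undirected interaction edge list
#'
#' Tab- (or whitespace-) delimited file; the two id columns default to the
#' first two. Reversed duplicates (`b a` after `a b`) and self-interactions
#' (`a a`) are removed, so the result is a simple undirected edge set.
#'
#' @param path Path to the edge list.
#' @param id_cols Integer vector of length 2: which columns hold the ids.
#' @return A data.frame with columns `a`, `b` (each unordered pair once,
#'   stored with `a < b`).
#' @export
read_edges <- function(path, id_cols = c(1L, 2L)) {
  stopifnot(file.exists(path), length(id_cols) == 2L)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  a <- character(0); b <- character(0)
  for (ln in which(keep)) {
    tok <- strsplit(lines[ln], "[ \t]+")[[1]]
    if (length(tok) < max(id_cols)) {
      stop("malformed edge line ", ln, " in '", path, "': '", lines[ln], "'")
    }
    a <- c(a, tok[id_cols[1]])
    b <- c(b, tok[id_cols[2]])
  }
  edge_list(a, b)
}

#' Canonicalise an undirected edge set
#'
#' @param a,b Character vectors of endpoint ids.
#' @return Data.frame `a`, `b`: self-pairs dropped, each unordered pair once.
#' @export
edge_list <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  df <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read term annotations (GAF) with optional ontology propagation
#'
#' GAF 2.x style: tab-separated, column 2 the protein id and column 5 the
#' term; lines starting with `!` or `#` are comments. If an OBO file is
#' given, its `is_a` edges are read and every annotation is propagated to
#' all ancestor terms.
#'
#' @param gaf_path Path to the annotation file.
#' @param obo_path Optional path to an OBO ontology (`is_a` edges only).
#' @return A list with `terms` (named list: term -> character vector of
#'   protein ids) and `parents` (named list: term -> parent terms, empty if
#'   no ontology was supplied).
#' @export
read_annotations <- function(gaf_path, obo_path = NULL) {
  stopifnot(file.exists(gaf_path))
  lines <- readLines(gaf_path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nzchar(lines) & !startsWith(lines, "!") & !startsWith(lines, "#")
  ids <- character(0); terms <- character(0)
  for (ln in which(keep)) {
    tok <- strsplit(lines[ln], "\t")[[1]]
    if (length(tok) < 5L) {
      stop("malformed GAF line ", ln, " in '", gaf_path, "'")
    }
    ids <- c(ids, tok[2]); terms <- c(terms, tok[5])
  }
  term_map <- lapply(split(ids, terms), unique)
  parents <- if (is.null(obo_path)) {
    setNames(vector("list", 0L), character(0))
  } else {
    read_obo_parents(obo_path)
  }
  if (length(parents) > 0L) {
    anc <- ontology_ancestors(parents)
    for (term in names(term_map)) {
      for (up in anc[[term]]) {
        term_map[[up]] <- unique(c(term_map[[up]], term_map[[term]]))
      }
    }
  }
  list(terms = term_map, parents = parents)
}

read_obo_parents <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  parents <- list()
  cur <- NULL
  for (line in lines) {
    if (line == "[Term]") { cur <- NULL; next }
    if (startsWith(line, "id:") ) {
      cur <- trimws(sub("^id:", "", line))
      if (is.null(parents[[cur]])) parents[[cur]] <- character(0)
    } else if (startsWith(line, "is_a:") && !is.null(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      parents[[cur]] <- unique(c(parents[[cur]], p))
    }
  }
  parents
}

# Transitive is_a closure per term; rejects cyclic ontologies.
ontology_ancestors <- function(parents) {
  anc <- list()
  visit <- function(term, path) {
    if (term %in% path) {
      stop("cyclic ontology: ", paste(c(path, term), collapse = " -> "))
    }
    if (!is.null(anc[[term]])) return(anc[[term]])
    ps <- parents[[term]]
    if (is.null(ps) || length(ps) == 0L) {
      anc[[term]] <<- character(0)
      return(character(0))
    }
    up <- unique(c(ps, unlist(lapply(ps, visit, path = c(path, term)))))
    anc[[term]] <<- up
    up
  }
  for (term in names(parents)) visit(term, character(0))
  anc
}
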