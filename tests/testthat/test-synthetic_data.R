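test_that("generation is deterministic for a fixed seed", {
  cfg <- small_config(seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_data(cfg, d1)
  write_synthetic_data(cfg, d2)
  for (f in c("proteome.fasta", "genome_map.tsv", "ppi.tsv",
              "annotations.gaf", "ontology.obo", "manifest.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  for (f in list.files(file.path(d1, "scores"))) {
    expect_identical(readLines(file.path(d1, "scores", f)),
                     readLines(file.path(d2, "scores", f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("genome dimensions and length distribution follow the config", {
  cfg <- synthetic_config(seed = 2,
                          chromosomes = c(c1 = 10L, c2 = 10L, c3 = 10L),
                          planted_low_chrom = "c1")
  g <- gen_genome(cfg)
  expect_equal(nrow(g$proteins), 30L)
  expect_equal(nrow(g$map), 30L)
  # starts strictly increasing within each chromosome
  for (ch in c("c1", "c2", "c3")) {
    expect_true(all(diff(g$map$start[g$map$chromosome == ch]) > 0))
  }

  cfg2 <- synthetic_config(seed = 3, chromosomes = c(c1 = 1000L),
                           planted_low_chrom = "c1",
                           protein_length_mean = 450)
  g2 <- gen_genome(cfg2, sequences = FALSE)
  expect_lt(abs(mean(g2$proteins$length) - 450) / 450, 0.10)
})

test_that("disorder scores binarise back to the planted chain states", {
  cfg <- small_config(seed = 7)
  g <- gen_genome(cfg, sequences = FALSE)
  sc <- gen_disorder(cfg, g)
  expect_named(sc, g$proteins$id)
  lens <- vapply(sc, length, integer(1))
  expect_equal(unname(lens), g$proteins$length)
  expect_true(all(unlist(sc) >= 0 & unlist(sc) < 1))
})

test_that("a zero disorder probability silences a chromosome completely", {
  cfg <- synthetic_config(seed = 4,
                          chromosomes = c(c1 = 40L, c2 = 40L),
                          disorder_base_prob = c(c1 = 0.3, c2 = 0.3),
                          planted_low_chrom = "c2",
                          planted_low_offset = -0.3)
  g <- gen_genome(cfg, sequences = FALSE)
  calls <- disorder_calls(gen_disorder(cfg, g))
  gm2 <- calls_for_ids <- g$map$protein_id[g$map$chromosome == "c2"]
  expect_equal(pct_long(calls[match(calls_for_ids, calls$protein_id), ],
                        30), 0)
})

test_that("planted low-disorder chromosome sits far below the rest", {
  cfg <- small_config(seed = 29)
  g <- gen_genome(cfg, sequences = FALSE)
  calls <- disorder_calls(gen_disorder(cfg, g))
  s <- summarize_chromosomes(g$map, calls, bootstrap_reps = 0)
  planted <- s$pct_long_30[s$chromosome == "chrC"]
  others <- s$pct_long_30[s$chromosome != "chrC"]
  expect_true(all(planted < others))
})

test_that("written files round-trip through the readers", {
  cfg <- small_config(seed = 19)
  dir <- tempfile()
  manifest <- write_synthetic_data(cfg, dir)

  g <- gen_genome(cfg, sequences = TRUE)
  prot <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_equal(prot$id, g$proteins$id)
  expect_equal(prot$sequence, g$proteins$sequence)

  gm <- read_genome_map(file.path(dir, "genome_map.tsv"))
  expect_equal(gm, g$map)

  sc_disk <- read_disorder_scores(file.path(dir, "scores"))
  sc_mem <- gen_disorder(cfg, g)
  expect_setequal(names(sc_disk), names(sc_mem))
  expect_equal(sc_disk[["chrC_g0001"]],
               round(sc_mem[["chrC_g0001"]], 4), tolerance = 1e-9)

  # the deliberate dirt collapses to exactly the generated edge set
  edges_disk <- read_edges(file.path(dir, "ppi.tsv"))
  edges_mem <- gen_ppi(cfg, g)
  expect_equal(edges_disk, edges_mem)
  raw <- readLines(file.path(dir, "ppi.tsv"))
  expect_equal(length(raw) - 1L,       # minus header comment
               nrow(edges_mem) + manifest$ppi_dirt$reversed_duplicates +
                 manifest$ppi_dirt$self_loops)

  ann_disk <- read_annotations(file.path(dir, "annotations.gaf"))
  ann_mem <- gen_annotations(cfg, g)
  nonempty <- names(ann_mem$terms)[vapply(ann_mem$terms, length,
                                          integer(1)) > 0]
  expect_setequal(names(ann_disk$terms), nonempty)
  for (term in nonempty) {
    expect_setequal(ann_disk$terms[[term]], ann_mem$terms[[term]])
  }

  # ontology propagation pools everything under the synthetic root
  ann_obo <- read_annotations(file.path(dir, "annotations.gaf"),
                              file.path(dir, "ontology.obo"))
  expect_setequal(ann_obo$terms[["T:ROOT"]],
                  unique(unlist(ann_mem$terms)))
  unlink(dir, recursive = TRUE)
})

test_that("a neutral degree multiplier leaves the planted group typical", {
  cfg <- small_config(seed = 31, degree_multiplier = 1)
  g <- gen_genome(cfg, sequences = FALSE)
  deg_gap <- vapply(1:5, function(i) {
    cfg_i <- small_config(seed = 300 + i, degree_multiplier = 1,
                          mean_degree = 10)
    gi <- gen_genome(cfg_i, sequences = FALSE)
    e <- gen_ppi(cfg_i, gi)
    deg <- igraph::degree(build_graph(e))
    chrom <- gi$map$chromosome[match(names(deg), gi$map$protein_id)]
    mean(deg[chrom == "chrC"]) - mean(deg[chrom != "chrC"])
  }, numeric(1))
  # no planted effect: group mean within 2 SE of the rest
  expect_lt(abs(mean(deg_gap)), 2 * stats::sd(deg_gap) / sqrt(5) + 1)
})

test_that("a low degree multiplier plants a low-degree group", {
  hits <- vapply(1:5, function(i) {
    cfg <- small_config(seed = 400 + i)
    g <- gen_genome(cfg, sequences = FALSE)
    e <- gen_ppi(cfg, g)
    deg <- igraph::degree(build_graph(e))
    chrom <- g$map$chromosome[match(names(deg), g$map$protein_id)]
    means <- tapply(deg, chrom, mean)
    names(which.min(means)) == "chrC"
  }, logical(1))
  expect_true(all(hits))
})
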