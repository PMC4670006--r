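test_that("enumerate_windows counts n - k + 1 windows per chromosome", {
  gm <- map_from_sizes(c(chrA = 5L, chrB = 3L))
  expect_equal(nrow(enumerate_windows(gm, 3)), 4L)
  expect_equal(nrow(enumerate_windows(gm, 6)), 0L)
  expect_equal(nrow(enumerate_windows(gm, 1)), 8L)
  expect_error(enumerate_windows(gm, 0), ">= 1")
})

test_that("window counts match the sum formula on random genomes", {
  set.seed(61)
  for (rep in 1:10) {
    sizes <- sample(1:30, sample(2:6, 1), replace = TRUE)
    names(sizes) <- paste0("c", seq_along(sizes))
    gm <- map_from_sizes(sizes)
    for (k in c(1L, 2L, 5L, 17L, 30L)) {
      expect_equal(nrow(enumerate_windows(gm, k)),
                   sum(pmax(0L, sizes - k + 1L)))
    }
  }
})

test_that("score_window computes the window's %long", {
  gm <- map_from_sizes(c(chrA = 4L))
  calls <- calls_from_flags(gm$protein_id, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(score_window(gm, calls, "chrA", 0L, 4L), 25)
  calls0 <- calls_from_flags(gm$protein_id, rep(FALSE, 4))
  expect_equal(score_window(gm, calls0, "chrA", 0L, 4L), 0)
  expect_error(score_window(gm, calls[1:2, ], "chrA", 0L, 4L),
               "no disorder call")
})

test_that("whole-chromosome windows agree with the chromosome summary", {
  cfg <- small_config(seed = 3)
  g <- gen_genome(cfg, sequences = FALSE)
  calls <- disorder_calls(gen_disorder(cfg, g))
  s <- summarize_chromosome(g$map, calls, "chrB", bootstrap_reps = 0)
  expect_equal(score_window(g$map, calls, "chrB", 0L,
                            s$n_proteins), s$pct_long_30)
})

test_that("scan_percentile counts ties inclusively with the query in both sides", {
  gm <- map_from_sizes(c(chrA = 4L, chrB = 4L))
  # k = 4: one window per chromosome; chrA strictly lower
  calls <- calls_from_flags(gm$protein_id,
                            c(rep(FALSE, 4), rep(TRUE, 4)))
  res <- scan_percentile(gm, calls, "chrA")
  expect_equal(res$windows_total, 2L)
  expect_equal(res$windows_leq_query, 1L)
  expect_equal(res$percentile, 0.5)

  # all windows identical: percentile 1
  calls <- calls_from_flags(gm$protein_id, rep(TRUE, 8))
  expect_equal(scan_percentile(gm, calls, "chrA")$percentile, 1)

  # unique minimum among n - k + 1 windows
  gm <- map_from_sizes(c(chrA = 5L))
  calls <- calls_from_flags(gm$protein_id,
                            c(TRUE, TRUE, FALSE, FALSE, TRUE))
  res <- scan_percentile(gm, calls,
                         list(chromosome = "chrA", start_ordinal = 2L,
                              k = 2L))
  expect_equal(res$windows_total, 4L)
  expect_equal(res$percentile, 0.25)
})

test_that("scan_percentile matches a brute-force recount on a synthetic genome", {
  cfg <- small_config(seed = 9)
  g <- gen_genome(cfg, sequences = FALSE)
  calls <- disorder_calls(gen_disorder(cfg, g))
  for (k in c(7L, 20L)) {
    q <- list(chromosome = "chrC", start_ordinal = 4L, k = k)
    res <- scan_percentile(g$map, calls, q)
    # independent recount: nested loops over every chromosome and start
    flags <- calls$long_30[match(g$map$protein_id, calls$protein_id)]
    qids <- g$map$protein_id[g$map$chromosome == "chrC"][(q$start_ordinal +
      1):(q$start_ordinal + k)]
    qcnt <- sum(calls$long_30[match(qids, calls$protein_id)])
    total <- 0L; leq <- 0L
    for (ch in unique(g$map$chromosome)) {
      idx <- which(g$map$chromosome == ch)
      n <- length(idx)
      if (n < k) next
      for (s in 0:(n - k)) {
        total <- total + 1L
        if (sum(flags[idx[(s + 1):(s + k)]]) <= qcnt) leq <- leq + 1L
      }
    }
    expect_equal(res$windows_total, total)
    expect_equal(res$windows_leq_query, leq)
    expect_equal(res$percentile, leq / total)
  }
})

test_that("scan_percentile is invariant under relabeling and monotone in query disorder", {
  gm <- map_from_sizes(c(chrA = 30L, chrB = 25L))
  set.seed(71)
  flags <- runif(55) < 0.5
  calls <- calls_from_flags(gm$protein_id, flags)
  q <- list(chromosome = "chrA", start_ordinal = 3L, k = 10L)
  base <- scan_percentile(gm, calls, q)

  # rename chromosomes and genes
  gm2 <- gm
  gm2$chromosome <- paste0("X_", gm$chromosome)
  gm2$protein_id <- paste0("Y_", gm$protein_id)
  calls2 <- calls
  calls2$protein_id <- paste0("Y_", calls$protein_id)
  q2 <- q; q2$chromosome <- "X_chrA"
  moved <- scan_percentile(gm2, calls2, q2)
  expect_equal(moved$percentile, base$percentile)

  # percentile never decreases as query windows get more disordered
  pcts <- vapply(0:20, function(s) {
    r <- scan_percentile(gm, calls, list(chromosome = "chrA",
                                         start_ordinal = s, k = 10L))
    c(r$query_pct, r$percentile)
  }, numeric(2))
  o <- order(pcts[1, ])
  expect_true(all(diff(pcts[2, o]) >= 0))
})

test_that("postdict picks the smallest minimal-disorder chromosome under budget", {
  gm <- map_from_sizes(c(big = 150L, small = 90L, other = 120L))
  set.seed(81)
  # equal %long for big and small, other higher
  flags <- c(rep(c(TRUE, FALSE, FALSE), 50),       # big: 1/3
             rep(c(TRUE, FALSE, FALSE), 30),       # small: 1/3
             rep(TRUE, 120))                       # other: 100%
  calls <- calls_from_flags(gm$protein_id, flags)
  plan <- postdict(gm, calls, budget = 200)
  expect_equal(plan$primary_region, "small")       # tie broken by size

  expect_error(postdict(gm, calls, budget = 50), "budget")
})

test_that("postdict extra fragments avoid the primary region and overlaps", {
  cfg <- small_config(seed = 13)
  g <- gen_genome(cfg, sequences = FALSE)
  calls <- disorder_calls(gen_disorder(cfg, g))
  plan <- postdict(g$map, calls, budget = 50, extra_sizes = c(8L, 8L, 8L))
  expect_equal(plan$primary_region, "chrC")
  ef <- plan$extra_fragments
  expect_false(any(ef$chromosome == "chrC"))
  for (i in seq_len(nrow(ef) - 1L)) {
    for (j in (i + 1L):nrow(ef)) {
      same <- ef$chromosome[i] == ef$chromosome[j]
      sep <- ef$start_ordinal[i] + ef$k[i] <= ef$start_ordinal[j] ||
        ef$start_ordinal[j] + ef$k[j] <= ef$start_ordinal[i]
      expect_true(!same || sep)
    }
  }
  expect_lte(plan$primary_n, plan$budget)
})

test_that("disorder_delta matches its closed form and dilution direction", {
  cfg <- small_config(seed = 17)
  g <- gen_genome(cfg, sequences = FALSE)
  calls <- disorder_calls(gen_disorder(cfg, g))
  plan <- postdict(g$map, calls, budget = 50, extra_sizes = 10L)
  delta <- disorder_delta(g$map, calls, plan)

  # algebraic oracle: (n p + k q) / (n + k) - p on fractions
  n <- nrow(g$map)
  p <- pct_long(calls[match(g$map$protein_id, calls$protein_id), ], 30)
  k <- plan$total_genes
  q <- plan$total_pct_long
  expect_equal(delta, (n * p + k * q) / (n + k) - p)
  expect_lt(delta, 0)      # duplicated an ordered-rich region

  # duplicating a region at exactly the proteome %long changes nothing
  gm <- map_from_sizes(c(chrA = 4L, chrB = 4L))
  calls <- calls_from_flags(gm$protein_id,
                            c(TRUE, FALSE, TRUE, FALSE,
                              TRUE, FALSE, TRUE, FALSE))
  plan0 <- postdict(gm, calls, budget = 4)
  expect_equal(disorder_delta(gm, calls, plan0), 0)
})
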