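test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_planted_known = 4, n_planted_novel = 2,
                    decoy_criteria = c(5L, 7L), n_decoy_features = 3,
                    genome_length = 60000L)
  sim1 <- generate_toy_genome(cfg)
  sim2 <- generate_toy_genome(cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$truth, sim2$truth)
  r1 <- simulate_reads(sim1)
  r2 <- simulate_reads(sim2)
  expect_identical(r1, r2)

  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_simulation(sim1, r1, d1)
  write_simulation(sim2, r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("planted loci carry the designed criteria labels", {
  cfg <- sim_config(seed = 7, n_planted_known = 2, n_planted_novel = 5,
                    decoy_criteria = c(5L, 7L), n_decoy_features = 2,
                    genome_length = 60000L)
  sim <- generate_toy_genome(cfg)
  loci <- sim$truth$loci
  expect_equal(sum(loci$category == "novel"), 5L)
  expect_equal(sort(loci$designed_fail[startsWith(loci$category, "decoy")]),
               c(5L, 7L))
  # every planted mature is a substring of its precursor
  expect_true(all(mapply(grepl, loci$mature, loci$precursor, fixed = TRUE)))
  # and occurs in the genome exactly once (strand-aware)
  for (i in seq_len(nrow(loci))) {
    expect_equal(equimir:::count_occurrences(sim$genome, loci$mature[i]), 1)
  }
})

test_that("the criteria engine reproduces the planted labels", {
  cfg <- sim_config(seed = 7, n_planted_known = 2, n_planted_novel = 2,
                    decoy_criteria = c(5L, 7L), n_decoy_features = 2,
                    genome_length = 60000L)
  sim <- generate_toy_genome(cfg)
  loci <- sim$truth$loci
  counts <- sim$truth$counts
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    hit <- data.frame(tag_id = l$name, sequence = l$mature, chrom = l$chrom,
                      start = l$start, end = l$end, strand = l$strand,
                      multiplicity = 1L,
                      total = sum(counts[counts$name == l$name, -1]),
                      stringsAsFactors = FALSE)
    lv <- locus_verdicts(call_novel_mirnas(hit, sim$genome))
    want <- if (is.na(l$designed_fail)) "" else as.character(l$designed_fail)
    expect_equal(lv$fails, want, info = l$name)
  }
})

test_that("the copy-number decoy is planted with 21 genomic copies", {
  cfg <- sim_config(seed = 7, n_planted_known = 2, n_planted_novel = 1,
                    decoy_criteria = 4L, n_decoy_features = 0,
                    genome_length = 60000L)
  sim <- generate_toy_genome(cfg)
  d4 <- sim$truth$loci[sim$truth$loci$designed_fail %in% 4L, ]
  expect_equal(equimir:::count_occurrences(sim$genome, d4$mature), 21)
})

test_that("forced counts are honoured exactly in a noiseless simulation", {
  cfg <- sim_config(seed = 7, n_planted_known = 1, n_planted_novel = 1,
                    decoy_criteria = integer(), n_decoy_features = 0,
                    genome_length = 30000L, noise = FALSE,
                    forced_counts = list("nov-mir-01" = c(muscle = 50)))
  sim <- generate_toy_genome(cfg)
  reads <- simulate_reads(sim)
  mature <- sim$truth$loci$mature[sim$truth$loci$name == "nov-mir-01"]
  n_mature <- sum(startsWith(reads$muscle$sequence, mature))
  expect_equal(n_mature, 50L)
  expect_equal(sum(startsWith(reads$colon$sequence, mature)), 0L)
})

test_that("junk classes are injected at the configured fractions", {
  cfg <- sim_config(seed = 13,
                    junk_fractions = c(polyA = 0.1, short = 0,
                                       no_adapter = 0, low_quality = 0),
                    jitter_3p = 0, base_error = 0)
  sim <- generate_toy_genome(cfg)
  reads <- simulate_reads(sim)
  for (tissue in names(reads)) {
    cl <- clean_reads(reads[[tissue]], cfg$adapter_3p, cfg$adapter_5p)
    raw <- cl$report$raw
    got <- cl$report$polyA
    expected <- 0.1 * raw
    # binomial tolerance: 4 standard deviations
    expect_lt(abs(got - expected), 4 * sqrt(raw * 0.1 * 0.9) + 1)
  }
})

test_that("a zero-plant genome yields zero novel calls downstream", {
  cfg <- sim_config(seed = 7, n_planted_known = 0, n_planted_novel = 0,
                    decoy_criteria = integer(), n_decoy_features = 3,
                    genome_length = 30000L, noise = FALSE)
  v <- suppressMessages(simulate_and_validate(cfg))
  expect_equal(v$report$novel_calls, 0L)
  expect_true(is.na(v$precision))
  expect_true(is.na(v$recall))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(decoy_criteria = 1L), "criterion 1")
  expect_error(sim_config(genome_length = 5000L), "too small")
  expect_error(sim_config(junk_fractions = c(polyA = 0.5, short = 0.5,
                                             no_adapter = 0.2,
                                             low_quality = 0)))
})
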