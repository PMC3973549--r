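ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("trim_adapters locates the 3' adapter and classifies failures", {
  insert <- "TTGACGGATCCGAGGACTGACA"   # 22 nt
  r <- trim_adapters(paste0(insert, ADAPTER3), ADAPTER3, ADAPTER5)
  expect_equal(r$insert, insert)

  # truncated adapter at the read end still matches (prefix rule)
  read36 <- substr(paste0(insert, ADAPTER3), 1, 36)
  expect_equal(trim_adapters(read36, ADAPTER3)$insert, insert)

  expect_equal(trim_adapters(ADAPTER3, ADAPTER3)$reason, "insert_null")
  expect_equal(trim_adapters(substr(ADAPTER3, 1, 12), ADAPTER3)$reason,
               "insert_null")
  expect_equal(trim_adapters(strrep("TA", 18), ADAPTER3)$reason,
               "no_3p_adapter")
  r5 <- trim_adapters(paste0("ACGT", ADAPTER5, "ACGT", ADAPTER3),
                      ADAPTER3, ADAPTER5)
  expect_equal(r5$reason, "adapter5_contaminant")
})

test_that("trim_adapters tolerates one mismatch per ten aligned bases", {
  insert <- "TTGACGGATCCGAGGACTGACA"
  mm <- ADAPTER3
  substr(mm, 15, 15) <- if (substr(mm, 15, 15) == "A") "C" else "A"
  r <- trim_adapters(paste0(insert, mm), ADAPTER3)
  expect_equal(r$insert, insert)
  # a 6-nt overlap allows no mismatches
  mm6 <- substr(ADAPTER3, 1, 6)
  substr(mm6, 3, 3) <- if (substr(mm6, 3, 3) == "A") "C" else "A"
  expect_equal(trim_adapters(paste0(insert, mm6), ADAPTER3)$reason,
               "no_3p_adapter")
})

test_that("filter_insert applies length, poly-A and quality rules", {
  expect_equal(filter_insert(strrep("C", 17)), "short")
  expect_equal(filter_insert(strrep("C", 31)), "short")
  expect_equal(filter_insert(strrep("A", 24)), "polyA")
  expect_true(is.na(filter_insert(strrep("AC", 11), rep(40L, 22))))
  expect_equal(filter_insert(strrep("AC", 11), rep(5L, 22)), "low_quality")
  # exactly half low-quality bases pass (rule is strictly more than half)
  expect_true(is.na(filter_insert(strrep("AC", 11),
                                  c(rep(5L, 11), rep(40L, 11)))))
})

test_that("collapse_to_tags merges identical inserts with exact counts", {
  one <- collapse_to_tags(list(muscle = rep("ACGTACGTACGTACGTAC", 3)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$total, 3L)

  # hand-enumerated fixture: 10 inserts, 6 distinct
  ins <- c(a = 3, b = 2, c = 1, d = 1, e = 2, f = 1)
  seqs <- setNames(vapply(seq_along(ins), function(i) {
    set.seed(i); random_dna(20)
  }, character(1)), names(ins))
  muscle <- rep(seqs[c("a", "b", "c")], times = c(2, 1, 1))
  colon <- rep(seqs[c("a", "b", "d", "e", "f")], times = c(1, 1, 1, 2, 1))
  tags <- collapse_to_tags(list(muscle = unname(muscle),
                                colon = unname(colon)))
  expect_equal(nrow(tags), 6L)
  expect_equal(sum(tags$total), 10L)
  expect_equal(tags$total[match(seqs["a"], tags$sequence)], 3L)
  expect_equal(tags$muscle[match(seqs["a"], tags$sequence)], 2L)
  expect_equal(tags$colon[match(seqs["e"], tags$sequence)], 2L)

  none <- collapse_to_tags(list(muscle = character()))
  expect_equal(nrow(none), 0L)
})

test_that("cleaning conserves reads: raw = clean + sum of removals", {
  sim <- generate_toy_genome(sim_config(seed = 3))
  reads <- simulate_reads(sim)
  for (tissue in names(reads)) {
    cl <- clean_reads(reads[[tissue]], ADAPTER3, ADAPTER5)
    rep <- cl$report
    removals <- rep[, c("low_quality", "adapter5_contaminant",
                        "no_3p_adapter", "insert_null", "short", "polyA")]
    expect_equal(rep$raw, rep$clean + sum(removals))
    expect_gte(rep$clean_fraction, 0)
    expect_lte(rep$clean_fraction, 1)
  }
})

test_that("tag length distribution is supported on [18, 30] only", {
  sim <- generate_toy_genome(sim_config(seed = 3))
  reads <- simulate_reads(sim)
  inserts <- lapply(reads, function(r) {
    clean_reads(r, ADAPTER3, ADAPTER5)$inserts
  })
  tags <- collapse_to_tags(inserts)
  lens <- nchar(tags$sequence)
  expect_gte(min(lens), 18L)
  expect_lte(max(lens), 30L)
  ld <- tag_length_distribution(tags)
  expect_equal(sum(ld$count), nrow(tags))
})
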