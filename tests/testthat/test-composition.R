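test_that("first-nucleotide bias recovers degenerate and hand-counted sets", {
  allU <- paste0("U", vapply(rep(19, 10), random_rna, character(1)))
  f <- first_nucleotide_bias(allU)
  expect_equal(f$U[is.na(f$length)], 100)

  hand <- c("UGACGAUCGAUCGAUCGAUC", "AGCCGAUCGAUCGAUCGAUC",
            "UUACGAUCGAUCGAUCGAUC", "GCCCGAUCGAUCGAUCGAUC")
  f2 <- first_nucleotide_bias(hand)
  row20 <- f2[!is.na(f2$length) & f2$length == 20, ]
  expect_equal(row20$U, 50)
  expect_equal(row20$A, 25)
  expect_equal(row20$G, 25)
  expect_equal(row20$C, 0)

  expect_error(first_nucleotide_bias(character()), "no sequences")
})

test_that("percentage rows of both profiles normalize to 100", {
  set.seed(21)
  seqs <- vapply(sample(18:30, 40, TRUE), random_rna, character(1))
  f <- first_nucleotide_bias(seqs)
  expect_true(all(abs(rowSums(f[, c("A", "C", "G", "U")]) - 100) < 0.01))
  p <- positional_composition(seqs)
  expect_true(all(abs(rowSums(p[, c("A", "C", "G", "U")]) - 100) < 0.01))
  expect_true(all(abs(p$AU + p$CG - 100) < 0.01))
})

test_that("positional composition follows the ragged-length rule", {
  p1 <- positional_composition("UUUU")
  expect_equal(p1$U, rep(100, 4))
  expect_equal(p1$AU, rep(100, 4))

  hand <- c("UGCA", "UGGA", "AGCU", "CGCU")
  p <- positional_composition(hand)
  expect_equal(p$U[1], 50)
  expect_equal(p$A[1], 25)
  expect_equal(p$G[2], 100)
  expect_equal(p$C[3], 75)
  expect_equal(p$G[3], 25)
  expect_equal(p$A[4], 50)
  expect_equal(p$U[4], 50)

  mixed <- c(random_rna(20), random_rna(20), random_rna(24))
  pm <- positional_composition(mixed)
  expect_equal(pm$n[20], 3L)
  expect_equal(pm$n[21], 1L)   # positions 21-24 use the long sequence only
  b <- strsplit(mixed[3], "")[[1]]
  expect_equal(pm[[b[24]]][24], 100)
})

test_that("the seed-region slice equals columns 2-8 of the matrix", {
  set.seed(22)
  seqs <- vapply(rep(22, 15), random_rna, character(1))
  p <- positional_composition(seqs)
  seed <- attr(p, "seed")
  sub <- p[p$position %in% 2:8, ]
  attr(sub, "seed") <- NULL
  expect_equal(seed, sub)
})

test_that("tissue presence partitions miRNAs into Venn regions", {
  counts <- data.frame(
    name = paste0("m", 1:6),
    muscle = c(5, 0, 2, 0, 1, 0),
    colon = c(3, 4, 0, 0, 1, 0),
    liver = c(1, 0, 0, 6, 1, 0))
  v <- tissue_presence_venn(counts, c("muscle", "colon", "liver"))
  r <- v$regions
  expect_equal(unname(r[["muscle&colon&liver"]]), 2L)  # m1, m5
  expect_equal(unname(r[["colon"]]), 1L)               # m2
  expect_equal(unname(r[["muscle"]]), 1L)              # m3
  expect_equal(unname(r[["liver"]]), 1L)               # m4
  expect_equal(unname(r[["muscle&colon"]]), 0L)
  # m6 absent everywhere: excluded, regions partition the detected set
  expect_equal(sum(r), 5L)
  expect_equal(nrow(v$presence), 5L)

  # threshold raises the detection bar
  v2 <- tissue_presence_venn(counts, threshold = 2)
  expect_equal(sum(v2$regions), 4L)
})

test_that("simulated all-U matures give a pure-U first-position profile", {
  cfg <- sim_config(seed = 9, n_planted_known = 3, n_planted_novel = 2,
                    decoy_criteria = integer(), n_decoy_features = 0,
                    genome_length = 40000L, noise = FALSE)
  sim <- generate_toy_genome(cfg)
  mats <- dna_to_rna(sim$truth$loci$mature)
  f <- first_nucleotide_bias(mats)
  expect_equal(f$U[is.na(f$length)], 100)
})
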