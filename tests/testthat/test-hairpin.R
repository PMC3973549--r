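test_that("candidate window arithmetic follows the criteria defaults", {
  set.seed(4)
  genome <- c(chr1 = random_dna(2000))
  hit <- list(chrom = "chr1", start = 1000L, end = 1022L, strand = "+")
  w <- excise_candidate_windows(hit, genome)
  expect_equal(length(w), 2L)
  # 22 nt tag + 10 flank + 35 space + 26 mature + 10 flank = 103 nt
  expect_equal(nchar(w[[1]]$window), 103L)
  expect_equal(nchar(w[[2]]$window), 103L)
  expect_equal(w[[1]]$mature_off, 10L)   # tag as 5' arm
  expect_equal(w[[2]]$mature_off, 71L)   # tag as 3' arm
  expect_true(all(grepl("^[ACGUN]+$", c(w[[1]]$window, w[[2]]$window))))
})

test_that("windows are clipped at contig bounds but still emitted", {
  set.seed(4)
  genome <- c(chr1 = random_dna(400))
  hit <- list(chrom = "chr1", start = 5L, end = 27L, strand = "+")
  w <- excise_candidate_windows(hit, genome)
  # window A is clipped at the contig start but emitted; window B would
  # be shorter than tag + 20 nt after clipping and is dropped
  expect_equal(length(w), 1L)
  expect_equal(w[[1]]$role, "A")
  expect_equal(w[[1]]$gstart, 0L)
  expect_equal(w[[1]]$mature_off, 5L)

  # a milder clip keeps both windows
  hit2 <- list(chrom = "chr1", start = 60L, end = 82L, strand = "+")
  w2 <- excise_candidate_windows(hit2, genome)
  expect_equal(length(w2), 2L)
  expect_lt(nchar(w2[[2]]$window), 103L)
})

test_that("minus-strand windows are the reverse complement of the slice", {
  set.seed(4)
  genome <- c(chr1 = random_dna(2000))
  hit <- list(chrom = "chr1", start = 1000L, end = 1022L, strand = "-")
  w <- excise_candidate_windows(hit, genome)[[1]]
  slice <- substr(genome[["chr1"]], w$gstart + 1, w$gend)
  expect_equal(w$window, dna_to_rna(revcomp(slice)))
  # the mature offset points at the tag in transcript orientation
  expect_equal(substr(w$window, w$mature_off + 1, w$mature_off + 22),
               dna_to_rna(revcomp(substr(genome[["chr1"]], 1001, 1022))))
})

test_that("find_duplex characterizes a perfect hairpin", {
  m <- "UGCAUGCAUGCAUGCAUGCAUG"
  # 10-nt loop, with a 3' tail so the star's 2-nt overhang has room
  hp <- paste0(perfect_hairpin(m, "ACACACACAC"), "CACA")
  f <- fold(hp)
  dx <- find_duplex(f, 0L, 22L)
  expect_false(dx$no_duplex)
  expect_equal(dx$paired, 22L)
  expect_equal(dx$max_bulge, 0L)
  expect_equal(dx$asymmetry, 0L)
  expect_equal(dx$space, 10L)
  # star interval carries the 2-nt 3' overhang
  expect_equal(dx$star[2] - dx$star_raw[2], 2L)
})

test_that("find_duplex measures an engineered mature-arm bulge", {
  # mature carries 3 extra unpaired bases mid-arm; the star pairs the
  # two flanking segments only
  s1 <- "GCGAUGCCUAG"; s2 <- "CGGAUGCCAUG"
  mature <- paste0(s1, "AAA", s2)
  star <- dna_to_rna(revcomp(rna_to_dna(paste0(s1, s2))))
  hp <- paste0(mature, "CACACACACACA", star)
  f <- fold(hp)
  dx <- find_duplex(f, 0L, nchar(mature))
  expect_equal(dx$paired, 22L)
  expect_equal(dx$max_bulge, 3L)
  expect_equal(dx$asymmetry, 3L)
  expect_equal(dx$space, 12L)
})

test_that("an unpairable mature arm yields a no-duplex result", {
  hp <- paste0(strrep("A", 22), "CACACACACACA",
               dna_to_rna(revcomp(rna_to_dna("GCGAUGCCUAGGCGAUGCCUAG"))))
  f <- fold(hp)
  dx <- find_duplex(f, 0L, 22L)
  expect_true(dx$no_duplex)
  expect_equal(dx$paired, 0L)
})

base_measures <- function() {
  list(mature_len = 22L, ref_len = 22L, cut_depth = 10L, copy_number = 1L,
       energy = -30, space = 12L, paired = 18L, bulge = 1L,
       asymmetry = 1L, flank = 10L)
}

test_that("evaluate_criteria flags exactly the violated criterion", {
  v0 <- evaluate_criteria(base_measures())
  expect_true(attr(v0, "overall"))

  m <- base_measures(); m$energy <- -17
  v <- evaluate_criteria(m)
  expect_false(attr(v, "overall"))
  expect_equal(v$criterion[!v$pass], 5L)

  m <- base_measures(); m$paired <- 13L
  v <- evaluate_criteria(m)
  expect_equal(v$criterion[!v$pass], 7L)

  m <- base_measures(); m$space <- NA
  v <- evaluate_criteria(m)
  expect_equal(v$criterion[!v$pass], 6L)   # NA measures fail
})

test_that("evaluate_criteria is monotone under threshold relaxation", {
  set.seed(77)
  relaxations <- list(
    function(cfg) { cfg$min_mirna_len <- cfg$min_mirna_len - 2L; cfg },
    function(cfg) { cfg$max_mirna_len <- cfg$max_mirna_len + 2L; cfg },
    function(cfg) { cfg$min_cut_depth <- cfg$min_cut_depth - 1L; cfg },
    function(cfg) { cfg$max_copy_number <- cfg$max_copy_number + 5L; cfg },
    function(cfg) { cfg$max_free_energy <- cfg$max_free_energy + 5; cfg },
    function(cfg) { cfg$max_space <- cfg$max_space + 10L; cfg },
    function(cfg) { cfg$min_duplex_pairs <- cfg$min_duplex_pairs - 3L; cfg },
    function(cfg) { cfg$max_bulge <- cfg$max_bulge + 2L; cfg },
    function(cfg) { cfg$max_asymmetry <- cfg$max_asymmetry + 2L; cfg },
    function(cfg) { cfg$flank_len <- cfg$flank_len - 3L; cfg })
  for (i in 1:40) {
    m <- list(mature_len = sample(15:30, 1), ref_len = sample(15:30, 1),
              cut_depth = sample(0:10, 1), copy_number = sample(1:30, 1),
              energy = -runif(1, 0, 40), space = sample(0:60, 1),
              paired = sample(0:25, 1), bulge = sample(0:8, 1),
              asymmetry = sample(0:8, 1), flank = sample(0:15, 1))
    base_pass <- evaluate_criteria(m)$pass
    relax <- relaxations[[sample(10, 1)]](criteria_config())
    relaxed_pass <- evaluate_criteria(m, relax)$pass
    expect_true(all(relaxed_pass[base_pass]))
  }
})

test_that("call_novel_mirnas returns an empty result with no hits", {
  nv <- call_novel_mirnas(
    data.frame(tag_id = character(), sequence = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), multiplicity = integer(),
               total = integer(), stringsAsFactors = FALSE),
    c(chr1 = "ACGT"))
  expect_equal(nrow(nv$calls), 0L)
  expect_equal(nrow(nv$candidates), 0L)
})

test_that("a two-window locus produces one merged, lowest-energy call", {
  set.seed(19)
  d <- equimir:::design_hairpin("pass")
  genome <- c(chr1 = paste0(random_dna(1500),
                            d$precursor, random_dna(1500)))
  m_start <- 1500L + d$mature_off
  hit <- data.frame(tag_id = "t1", sequence = d$mature, chrom = "chr1",
                    start = m_start, end = m_start + nchar(d$mature),
                    strand = "+", multiplicity = 1L, total = 40L,
                    stringsAsFactors = FALSE)
  nv <- call_novel_mirnas(hit, genome)
  expect_equal(nrow(nv$calls), 1L)
  expect_gte(nrow(nv$candidates), 2L)
  expect_equal(nv$calls$energy, min(nv$candidates$energy))
  expect_true(all(nv$candidates$overall[
    nv$candidates$energy == nv$calls$energy]))
})
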