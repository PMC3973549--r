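test_that("index lookup finds all occurrences on both strands", {
  idx <- build_exact_index(c(chrA = "ACGTACGT"))
  h <- index_lookup(idx, "ACGT")
  fwd <- h[h$strand == "+", ]
  expect_equal(fwd$start, c(0L, 4L))
  # ACGT is its own reverse complement, so the same offsets appear as
  # minus-strand hits too
  expect_equal(h$start[h$strand == "-"], c(0L, 4L))

  # query equal to the reverse complement of a genome substring
  g2 <- c(chrB = "AAGACGGATCCA")
  idx2 <- build_exact_index(g2)
  q <- revcomp(substr(g2[["chrB"]], 2, 9))   # revcomp("AGACGGAT")
  h2 <- index_lookup(idx2, q)
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$start, h2$end), c(1L, 9L))
  # strand-aware substring equals the query
  expect_equal(revcomp(substr(g2[["chrB"]], h2$start + 1, h2$end)), q)

  expect_error(build_exact_index(character()), "empty")
})

test_that("index agrees with a naive both-strand scan", {
  set.seed(31)
  genome <- c(c1 = random_dna(1200), c2 = random_dna(800))
  idx <- build_exact_index(genome)
  for (i in 1:10) {
    q <- if (i <= 5) random_dna(20) else {
      # guaranteed-present queries sampled from the genome, either strand
      chrom <- sample(names(genome), 1)
      st <- sample(nchar(genome[[chrom]]) - 20, 1)
      s <- substr(genome[[chrom]], st, st + 19)
      if (runif(1) < 0.5) s else revcomp(s)
    }
    got <- index_lookup(idx, q)
    want <- oracle_scan(genome, q)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("map_tags enforces the perfect-match rule and multiplicity", {
  set.seed(5)
  tag <- random_dna(22)
  genome <- c(g = paste0(random_dna(100), tag, random_dna(80), tag,
                         random_dna(60)))
  idx <- build_exact_index(genome)
  tags <- data.frame(tag_id = c("t1", "t2"),
                     sequence = c(tag, paste0(substr(tag, 1, 21), "N")),
                     total = c(7L, 1L), stringsAsFactors = FALSE)
  hits <- map_tags(tags, idx)
  expect_equal(unique(hits$tag_id), "t1")      # mismatch tag: no hits
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$multiplicity), 2L)
  expect_equal(hits$total, c(7L, 7L))
})

make_catalog <- function() {
  reference_catalog(
    mature = data.frame(id = "mir-a", sequence = "TTGACGGATCCGAGGACTGACA",
                        stringsAsFactors = FALSE),
    hairpin = data.frame(id = "mir-a-hp",
                         sequence = paste0("CCCCC", "TTGACGGATCCGAGGACTGACA",
                                           "AAAAA"),
                         stringsAsFactors = FALSE),
    sequences = list(
      tRNA = data.frame(id = "trna1",
                        sequence = "GGGCCCGGGTTTAAACCCGGGTTTCCCAAAGGG",
                        stringsAsFactors = FALSE),
      exon = data.frame(id = "ex1",
                        sequence = "GGGCCCGGGTTTAAACCCGGGTTTCCCAAAGGGTT",
                        stringsAsFactors = FALSE)))
}

test_that("annotation applies exact known-miRNA matching and priority", {
  cat <- make_catalog()
  tags <- data.frame(
    tag_id = paste0("t", 1:5),
    sequence = c("TTGACGGATCCGAGGACTGACA",          # = mature
                 "CCCCCTTGACGGATCCGAGGAC",          # substring of hairpin
                 "CCCGGGTTTAAACCCGGGTTTCCC",        # tRNA and exon: priority
                 revcomp("TTGACGGATCCGAGGACTGACA"), # antisense of mature
                 "TTTTTTTTTTGGGGGGGGGGAC"),         # nothing
    stringsAsFactors = FALSE)
  ann <- annotate_tags(tags, cat)
  expect_equal(ann$category,
               c("known_mirna", "known_mirna", "tRNA", "known_mirna",
                 "unannotated"))
  expect_equal(ann$ref_id[3], "trna1")
})

test_that("annotation is a partition of the tags", {
  cat <- make_catalog()
  set.seed(8)
  tags <- data.frame(tag_id = paste0("t", 1:30),
                     sequence = c(vapply(rep(20, 25), random_dna,
                                         character(1)),
                                  rep("TTGACGGATCCGAGGACTGACA", 5)),
                     total = 1L, stringsAsFactors = FALSE)
  ann <- annotate_tags(tags, cat)
  expect_equal(nrow(ann), 30L)
  summ <- annotation_summary(ann, tags)
  expect_equal(sum(summ$unique_tags), 30L)
})

test_that("feature overlap annotates tags through their genomic hits", {
  set.seed(12)
  body <- random_dna(300)
  genome <- c(chr1 = body)
  idx <- build_exact_index(genome)
  tag <- substr(body, 101, 122)
  tags <- data.frame(tag_id = "t1", sequence = tag, total = 1L,
                     stringsAsFactors = FALSE)
  hits <- map_tags(tags, idx)
  feats <- data.frame(chrom = "chr1", start = 90L, end = 140L, strand = "+",
                      category = "intron", id = "int1",
                      stringsAsFactors = FALSE)
  cat <- reference_catalog(features = feats)
  ann <- annotate_tags(tags, cat, hits = hits)
  expect_equal(ann$category, "intron")
  expect_equal(ann$ref_id, "int1")
})
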