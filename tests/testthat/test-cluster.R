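mk_loci <- function(chrom, start, end, name = NULL) {
  data.frame(name = name %||% paste0("m", seq_along(start)),
             chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the 3-kb edge-to-edge rule is applied inclusively", {
  # gap = 4019 - 1020 = 2999: within 3 kb, one cluster of two
  near <- mk_loci("chr1", c(1000L, 4019L), c(1020L, 4041L))
  cl <- cluster_loci(near)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_members, 2L)
  expect_equal(cl$clusters$members[[1]], c("m1", "m2"))

  # gap just over the threshold: two singletons, no clusters
  far <- mk_loci("chr1", c(1000L, 4022L), c(1020L, 4044L))
  cl2 <- cluster_loci(far)
  expect_equal(nrow(cl2$clusters), 0L)
  expect_equal(nrow(cl2$singletons), 2L)

  # exactly 3000 joins, per "within 3 kb"
  edge <- mk_loci("chr1", c(1000L, 4020L), c(1020L, 4040L))
  expect_equal(nrow(cluster_loci(edge)$clusters), 1L)
})

test_that("chaining is transitive across consecutive within-range pairs", {
  loci <- mk_loci("chr1", c(0L, 2500L, 5000L), c(100L, 2600L, 5100L))
  cl <- cluster_loci(loci)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_members, 3L)   # m1-m3 span > 3 kb but chain
})

test_that("clustering agrees with the O(n^2) transitive-closure oracle", {
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(c(12, 40, 100), 1)
    loci <- mk_loci(sample(c("c1", "c2"), n, TRUE),
                    start <- sample.int(60000L, n),
                    start + sample(20:120, n, TRUE),
                    name = sprintf("m%03d", 1:n))
    got <- cluster_loci(loci)
    want <- oracle_cluster(loci)
    got_keys <- sort(vapply(got$clusters$members,
                            function(m) paste(sort(m), collapse = ","),
                            character(1)))
    want_keys <- sort(vapply(want$clusters, paste, character(1),
                             collapse = ","))
    expect_equal(got_keys, want_keys)
    expect_equal(sort(got$singletons$name), want$singletons)
    # partition: every locus in exactly one place
    expect_equal(sum(got$clusters$n_members) + nrow(got$singletons), n)
  }
})

test_that("clustering is invariant to input order and translation", {
  set.seed(62)
  n <- 30
  loci <- mk_loci("c1", start <- sample.int(40000L, n),
                  start + 60L, name = sprintf("m%02d", 1:n))
  base <- cluster_loci(loci)
  shuf <- cluster_loci(loci[sample(n), ])
  expect_equal(base$clusters$members, shuf$clusters$members)
  moved <- loci
  moved$start <- moved$start + 123456L
  moved$end <- moved$end + 123456L
  expect_equal(cluster_loci(moved)$clusters$members, base$clusters$members)
})

test_that("chromosome_distribution reports explicit zeros", {
  loci <- mk_loci(rep("chr1", 3), c(1L, 10L, 20L), c(5L, 15L, 25L))
  d <- chromosome_distribution(loci, chromosomes = c("chr1", "chr2"))
  expect_equal(d$count[d$chrom == "chr1"], 3L)
  expect_equal(d$count[d$chrom == "chr2"], 0L)
  empty <- chromosome_distribution(loci[0, ], chromosomes = c("chr1", "chr2"))
  expect_equal(empty$count, c(0L, 0L))
})

test_that("cluster_summary computes the clustered percentage", {
  # the published inputs: 160 of 292 known miRNAs in 51 clusters -> 55%
  fake <- list(clusters = data.frame(
    cluster_id = sprintf("c%02d", 1:51), chrom = "x", start = 1, end = 2,
    n_members = c(rep(2L, 45), rep(14L, 5), 0L), stringsAsFactors = FALSE))
  fake$clusters$n_members <- local({
    # 51 clusters holding 160 loci in total
    v <- rep(2L, 51); v[1:29] <- 2L; extra <- 160L - sum(v)
    v[1] <- v[1] + extra; v
  })
  s <- cluster_summary(fake, 292L)
  expect_equal(s$n_clusters, 51L)
  expect_equal(s$n_clustered, 160L)
  expect_equal(s$pct_clustered, 55)

  # the shipped transcription sums to 158 members -> 54%
  expect_equal(cluster_summary(list(clusters = data.frame(
    cluster_id = "c1", chrom = "x", start = 1, end = 2, n_members = 158L)),
    292L)$pct_clustered, 54)

  s2 <- cluster_summary(list(clusters = data.frame(
    cluster_id = c("a", "b"), chrom = "x", start = 1, end = 2,
    n_members = c(3L, 3L))), 10L)
  expect_equal(s2$pct_clustered, 60)

  s0 <- cluster_summary(list(clusters = data.frame(
    cluster_id = character(), chrom = character(), start = integer(),
    end = integer(), n_members = integer())), 10L)
  expect_equal(s0$pct_clustered, 0)
  expect_error(cluster_summary(list(clusters = NULL), 0L), "positive")
})
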