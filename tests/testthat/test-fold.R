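test_that("fold handles unstructured and canonical stem inputs", {
  f <- fold("AAAAAAAAAA")
  expect_equal(f$structure, strrep(".", 10))
  expect_equal(f$energy, 0)

  # 8-bp GC stem around a 5-nt loop: 7 GC/GC stacks at -3 plus
  # 5 * 0.5 loop penalty = -18.5 (value confirmed by the enumeration
  # oracle below)
  f2 <- fold("GGGGGGGGAAAAGCCCCCCCC")
  expect_equal(f2$energy, -18.5)
  expect_equal(f2$structure, "((((((((.....))))))))")
  b <- strsplit("GGGGGGGGAAAAGCCCCCCCC", "")[[1]]
  expect_equal(oracle_min_energy("GGGGGGGGAAAAGCCCCCCCC"), -18.5)
})

test_that("fold input validation works", {
  expect_error(fold(""), "empty")
  expect_error(fold("ACGT"), "alphabet")   # T is not RNA
  expect_error(fold(strrep("A", 201)), "200")
})

test_that("reported energy equals the score of the reported structure", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_rna(sample(10:60, 1))
    f <- fold(s)
    expect_equal(f$energy, score_structure(s, f$structure))
    expect_lte(f$energy, 0)
  }
})

test_that("fold is optimal against exhaustive enumeration", {
  set.seed(23)
  for (i in 1:30) {
    s <- random_rna(sample(8:18, 1))
    f <- fold(s)
    expect_equal(f$energy, oracle_min_energy(s), tolerance = 1e-9)
  }
  # a couple of longer, structured cases
  for (s in c("GGCGCAAAAGCGCCAUAUGCA", perfect_hairpin("GCGAUGCC", "AAAA"))) {
    expect_equal(fold(s)$energy, oracle_min_energy(s), tolerance = 1e-9)
  }
})

test_that("structure_pairs inverts dot-bracket notation", {
  p <- structure_pairs("((..))")
  expect_equal(p, c(6L, 5L, NA, NA, 2L, 1L))
  expect_error(structure_pairs("(()"), "unbalanced")
  expect_error(structure_pairs("())"), "unbalanced")
  expect_error(structure_pairs("(x)"), "invalid")
})

test_that("the RNAfold engine honours the fold_result contract", {
  s <- perfect_hairpin("GCGAUGCCUAGCAUGGCAUGCA", "ACAACAAC")
  f <- fold(s, engine = "rnafold")
  expect_equal(nchar(f$structure), nchar(s))
  expect_true(grepl("^[().]+$", f$structure))
  expect_lte(f$energy, 0)
  # a strong designed hairpin is stable under the thermodynamic model too
  expect_lt(f$energy, -18)
  expect_no_error(structure_pairs(f$structure))
})
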