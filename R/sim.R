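## Synthetic small-RNA-seq data with planted ground truth.
##
## The generator builds a toy multi-chromosome genome containing:
##   * criteria-passing miRNA hairpins, split into "known" (also emitted
##     into the mock reference catalog) and "novel" (not in the catalog);
##   * one decoy hairpin per requested criterion, engineered to violate
##     exactly that criterion and verified against the package's own
##     criteria engine at build time (bounded redraws keep determinism
##     under the seed);
##   * decoy annotation features (rRNA/tRNA/.../intron) that shed
##     degradation fragments.
## Reads are the mature sequences with a fixed 5' end (Dicer-like
## precision), optional 1-nt 3' jitter, a 3' sequencing adapter, and
## configurable junk classes (poly-A, short, adapterless, low-quality).

#' Simulation configuration
#'
#' Defaults describe a small three-tissue experiment: ~22-nt mature
#' miRNAs whose read stacks have fixed 5' ends, log-normal per-miRNA
#' expression shared across tissues with tissue dropout, and a few
#' percent of each junk class. `noise = FALSE` zeroes the junk
#' fractions, the 3' jitter and the base-error rate, making recovery
#' exact.
#'
#' @param seed integer seed; every downstream draw is fixed by it.
#' @param genome_length total genome size (nt), split over
#'   `n_chromosomes`.
#' @param n_chromosomes number of contigs (`chr1`, `chr2`, ...).
#' @param n_planted_known,n_planted_novel criteria-passing hairpins with
#'   and without catalog entries.
#' @param decoy_criteria criteria (2-10) for which a single-criterion
#'   decoy hairpin is planted. No single-criterion decoy exists for
#'   criterion 1: cleaned tags are 18-30 nt, and any mature length in
#'   that range violating the 18-26 bound also violates the 20-24
#'   reference-length bound, so criterion 1 cannot fail alone.
#' @param n_decoy_features decoy annotation features (cycled over rRNA,
#'   tRNA, snRNA, snoRNA, scRNA, srpRNA, repeat, exon, intron).
#' @param tissues tissue names.
#' @param adapter_3p,adapter_5p sequencing adapters (DNA).
#' @param read_length read length (nt); reads are insert + 3' adapter
#'   truncated to this length.
#' @param count_meanlog,count_sdlog log-normal parameters of per-miRNA
#'   expression.
#' @param min_count floor on a present miRNA's per-tissue count.
#' @param presence_prob per-tissue presence probability (dropout builds
#'   the tissue-specific subsets; at least one tissue is kept).
#' @param junk_fractions named numeric: fractions of total reads for
#'   `polyA`, `short`, `no_adapter`, `low_quality`; must sum below 1.
#' @param jitter_3p probability that a read's 3' end moves by 1 nt (the
#'   5' end never moves).
#' @param base_error uniform per-base sequencing error rate.
#' @param feature_read_count degradation-fragment reads per decoy
#'   feature and tissue.
#' @param forced_counts optional named list: miRNA name -> named vector
#'   of per-tissue counts overriding the drawn expression.
#' @param noise logical master switch; `FALSE` sets `junk_fractions`,
#'   `jitter_3p` and `base_error` to zero.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 120000L, n_chromosomes = 4L,
                       n_planted_known = 8L, n_planted_novel = 6L,
                       decoy_criteria = 2:10, n_decoy_features = 9L,
                       tissues = c("muscle", "colon", "liver"),
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_length = 36L,
                       count_meanlog = log(100), count_sdlog = 0.8,
                       min_count = 5L, presence_prob = 0.7,
                       junk_fractions = c(polyA = 0.05, short = 0.05,
                                          no_adapter = 0.05,
                                          low_quality = 0.05),
                       jitter_3p = 0.15, base_error = 0.002,
                       feature_read_count = 25L,
                       forced_counts = list(), noise = TRUE) {
  if (!noise) {
    junk_fractions[] <- 0
    jitter_3p <- 0
    base_error <- 0
  }
  if (any(decoy_criteria == 1L)) {
    stopf(paste("no single-criterion decoy exists for criterion 1:",
                "within the cleaned 18-30 nt tag range any mature-length",
                "violation also violates the reference-length bound"))
  }
  stopifnot(all(decoy_criteria %in% 2:10), sum(junk_fractions) < 1,
            all(junk_fractions >= 0), length(tissues) >= 1)
  n_loci <- n_planted_known + n_planted_novel + length(decoy_criteria)
  if (genome_length < 10 * n_loci * 120) {
    stopf("genome_length %d too small for %d planted loci (need >= %d)",
          genome_length, n_loci, 10 * n_loci * 120)
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_planted_known = as.integer(n_planted_known),
                 n_planted_novel = as.integer(n_planted_novel),
                 decoy_criteria = as.integer(decoy_criteria),
                 n_decoy_features = as.integer(n_decoy_features),
                 tissues = tissues, adapter_3p = adapter_3p,
                 adapter_5p = adapter_5p,
                 read_length = as.integer(read_length),
                 count_meanlog = count_meanlog, count_sdlog = count_sdlog,
                 min_count = as.integer(min_count),
                 presence_prob = presence_prob,
                 junk_fractions = junk_fractions, jitter_3p = jitter_3p,
                 base_error = base_error,
                 feature_read_count = as.integer(feature_read_count),
                 forced_counts = forced_counts),
            class = "sim_config")
}

rand_dna <- function(n, letters = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

## hairpin designs ----------------------------------------------------------
## Each design returns list(mature, precursor, mature_off) in DNA space,
## mature on the 5' arm; the generator re-draws a design until the
## criteria engine reproduces the intended verdict.

design_hairpin <- function(kind, flank = 10L) {
  gc_rich <- function(n) rand_dna(n, c("G", "C"))
  mix <- function(n) rand_dna(n, prob = c(0.22, 0.28, 0.28, 0.22))
  loop <- function(n, letters = c("A", "C")) rand_dna(n, letters)
  # real miRNA/miRNA* duplexes are imperfect; two well-separated
  # non-pairing substitutions keep the mature's reverse complement out
  # of the genome (a planted mature maps to exactly one locus) and no
  # single sequencing error can recreate an exact antisense match
  mm_star <- function(mature) {
    star <- revcomp(mature)
    n <- nchar(star)
    for (k in c(n %/% 3L, (2L * n) %/% 3L)) {
      opp <- substr(mature, n - k + 1L, n - k + 1L)
      ok <- switch(opp, A = c("A", "C", "G"), C = c("A", "C", "T"),
                   G = c("A", "G"), T = c("C", "T"))
      ok <- setdiff(ok, substr(star, k, k))
      substr(star, k, k) <- sample(ok, 1L)
    }
    star
  }
  if (kind %in% c("pass", "decoy3", "decoy4", "decoy10")) {
    repeat {  # mixed-composition 22-mer with enough G/C for a stable stem
      mature <- paste0("T", mix(21L))
      if (lengths(regmatches(mature, gregexpr("[GC]", mature))) >= 11) break
    }
    core <- paste0(mature, loop(12L), mm_star(mature))
  } else if (kind == "decoy2") {
    repeat {
      mature <- paste0("T", mix(24L))   # 25 nt: passes 18-26, fails 20-24
      if (lengths(regmatches(mature, gregexpr("[GC]", mature))) >= 13) break
    }
    core <- paste0(mature, loop(12L), mm_star(mature))
  } else if (kind == "decoy5") {
    repeat {  # A:U-only stem folds well above the -18 kcal/mol bound;
              # cap the adenine content so the mature read is not poly-A
      mature <- paste0("T", rand_dna(19L, c("A", "T")))
      if (lengths(regmatches(mature, gregexpr("A", mature))) <= 12) break
    }
    core <- paste0(mature, loop(14L), mm_star(mature))
  } else if (kind == "decoy6") {
    # long loop with a short (16 bp) but strong stem: the arm spacing
    # overshoots 35 nt while the duplex still fits the excision window
    mature <- paste0("T", gc_rich(15L), rand_dna(6L, c("A", "C")))
    core <- paste0(mature, loop(40L, c("A", "C")),
                   revcomp(substr(mature, 1L, 16L)))
  } else if (kind == "decoy7") {
    mature <- paste0("T", gc_rich(11L), strrep("A", 10L))
    core <- paste0(mature, loop(12L, "C"), revcomp(substr(mature, 1L, 12L)))
  } else if (kind == "decoy8") {
    mature <- paste0("T", gc_rich(21L))
    s <- revcomp(mature)
    star <- paste0(substr(s, 1, 11), strrep("A", 5L), substr(s, 12, 22))
    core <- paste0(mature, loop(12L, "A"), star)
  } else if (kind == "decoy9") {
    mature <- paste0("T", gc_rich(21L))
    s <- revcomp(mature)
    star <- paste0(substr(s, 1, 6), strrep("A", 4L), substr(s, 7, 14),
                   strrep("A", 3L), substr(s, 15, 22))
    core <- paste0(mature, loop(12L, "A"), star)
  } else {
    stopf("unknown hairpin design '%s'", kind)
  }
  list(mature = mature,
       precursor = paste0(rand_dna(flank), core, rand_dna(flank)),
       mature_off = flank)
}

splice_into <- function(chrom_seq, start, insert) {
  paste0(substr(chrom_seq, 1L, start),
         insert,
         substr(chrom_seq, start + nchar(insert) + 1L, nchar(chrom_seq)))
}

slot_free <- function(occupied, start, len, margin) {
  for (iv in occupied) {
    if (start - margin < iv[2] && start + len + margin > iv[1]) return(FALSE)
  }
  TRUE
}

find_slot <- function(clen, occupied, len, margin) {
  hi <- clen - len - 2L * margin
  if (hi < 1L) return(NA_integer_)
  for (try in 1:200) {
    start <- sample.int(hi, 1L) + margin
    if (slot_free(occupied, start, len, margin)) return(start)
  }
  # deterministic fallback: systematic scan of the contig
  for (start in seq(margin + 1L, hi + margin, by = 23L)) {
    if (slot_free(occupied, start, len, margin)) return(start)
  }
  NA_integer_
}

count_occurrences <- function(genome, pattern) {
  sum(vapply(genome, function(chrom) {
    f <- gregexpr(pattern, chrom, fixed = TRUE)[[1]]
    r <- gregexpr(revcomp(pattern), chrom, fixed = TRUE)[[1]]
    sum(f > 0) + sum(r > 0)
  }, numeric(1)))
}

#' Generate a toy genome with planted miRNA ground truth
#'
#' Deterministic given `config$seed`; planted precursors satisfy all ten
#' criteria with margin (verified against [evaluate_criteria()] via the
#' caller machinery at build time), each decoy violates exactly its
#' designed criterion, and every planted mature occurs exactly once in
#' the genome (21 times for the copy-number decoy).
#'
#' @param config a [sim_config()].
#' @return object of class `mirna_sim`: list with `config`, `genome`
#'   (named character), and `truth` (loci, per-tissue counts, presence,
#'   reference mature/hairpin tables, decoy features).
#' @export
generate_toy_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  clen <- rep(config$genome_length %/% n_chrom, n_chrom)
  chroms <- paste0("chr", seq_len(n_chrom))
  genome <- setNames(vapply(clen, rand_dna, character(1)), chroms)
  occupied <- setNames(rep(list(list()), n_chrom), chroms)
  if (10L %in% config$decoy_criteria) {
    # the flank decoy is planted flush with the start of the first
    # contig; reserve that region before anything else is placed
    occupied[[chroms[1]]] <- list(c(0L, 120L))
  }
  crit_cfg <- criteria_config()

  plan <- data.frame(
    name = c(sprintf("kno-mir-%02d", seq_len(config$n_planted_known)),
             sprintf("nov-mir-%02d", seq_len(config$n_planted_novel)),
             sprintf("decoy-crit-%02d", config$decoy_criteria)),
    category = c(rep("known", config$n_planted_known),
                 rep("novel", config$n_planted_novel),
                 sprintf("decoy_fail_criterion_%d", config$decoy_criteria)),
    designed_fail = c(rep(NA_integer_,
                          config$n_planted_known + config$n_planted_novel),
                      config$decoy_criteria),
    stringsAsFactors = FALSE)
  # decoys 3/4/10 reuse the passing hairpin design: their failure comes
  # from counts, genomic copies, or placement, not from the fold
  plan$design <- ifelse(is.na(plan$designed_fail) |
                          plan$designed_fail %in% c(3L, 4L, 10L),
                        "pass", paste0("decoy", plan$designed_fail))

  ## expression plan (needed for the build-time criteria verification)
  n_loci <- nrow(plan)
  presence <- matrix(FALSE, n_loci, length(config$tissues),
                     dimnames = list(plan$name, config$tissues))
  counts <- matrix(0L, n_loci, length(config$tissues),
                   dimnames = list(plan$name, config$tissues))
  for (i in seq_len(n_loci)) {
    pres <- runif(length(config$tissues)) < config$presence_prob
    if (!any(pres)) pres[sample.int(length(pres), 1L)] <- TRUE
    presence[i, ] <- pres
    base <- pmax(config$min_count,
                 round(rlnorm(sum(pres), config$count_meanlog,
                              config$count_sdlog)))
    counts[i, pres] <- as.integer(base)
    if (!is.na(plan$designed_fail[i]) && plan$designed_fail[i] == 3L) {
      counts[i, ] <- 0L              # depth decoy: 2 reads in one tissue
      counts[i, which(pres)[1]] <- 2L
      presence[i, ] <- counts[i, ] > 0L
    }
  }
  for (nm in names(config$forced_counts)) {
    if (!nm %in% rownames(counts)) stopf("unknown miRNA in forced_counts: %s", nm)
    fc <- config$forced_counts[[nm]]
    counts[nm, ] <- 0L
    counts[nm, names(fc)] <- as.integer(fc)
    presence[nm, ] <- counts[nm, ] > 0L
  }

  ## placement: criterion-10 decoy hugs its contig start; the first two
  ## pairs of known loci sit 800 nt apart to create polycistrons
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    plen <- nchar(design_hairpin(plan$design[i])$precursor)  # stable per design
    is_d10 <- !is.na(plan$designed_fail[i]) && plan$designed_fail[i] == 10L
    paired_with_prev <- plan$category[i] == "known" && i > 1L &&
      i %% 2L == 0L && i <= 4L
    if (is_d10) {
      chrom <- chroms[1]
      start <- 0L
    } else if (paired_with_prev) {
      prev <- loci[[i - 1L]]
      chrom <- prev$chrom
      start <- prev$prec_start + nchar(prev$precursor_fwd) + 800L
    } else {
      # known/novel loci keep >3 kb apart (except the engineered pairs) so
      # the planted truth implies exactly the designed clusters; decoys
      # never become calls and only need their candidate windows disjoint
      margin <- if (plan$category[i] %in% c("known", "novel")) 3600L else 300L
      # widely spaced loci go round-robin over contigs so the wide
      # margins pack; decoys take any free spot
      chrom_try <- if (margin > 1000L) {
        chroms[1L + (i - 1L) %% length(chroms)]
      } else sample(chroms, 1L)
      start <- NA_integer_
      for (chrom in c(chrom_try, sample(chroms))) {
        start <- find_slot(clen[match(chrom, chroms)],
                           occupied[[chrom]], plen, margin)
        if (!is.na(start)) break
      }
      if (is.na(start)) stopf("insufficient genome space for planted loci")
    }
    strand <- if (plan$category[i] %in% c("known", "novel") && !is_d10 &&
                  !(plan$category[i] == "known" && i <= 4L)) {
      sample(c("+", "-"), 1L)   # pairs stay on + to keep spans simple
    } else "+"

    ## draw-verify-redraw: the criteria engine must reproduce the label
    placed <- FALSE
    for (try in 1:60) {
      d <- design_hairpin(plan$design[i])
      if (is_d10) {
        # truncate the 5' flank to 3 nt and plant at the contig start so
        # the excised window cannot supply the required 10-nt flank
        d$precursor <- substr(d$precursor, 8L, nchar(d$precursor))
        d$mature_off <- d$mature_off - 7L
      }
      prec_fwd <- if (strand == "+") d$precursor else revcomp(d$precursor)
      cand_genome <- genome
      cand_genome[chrom] <- splice_into(cand_genome[[chrom]], start, prec_fwd)
      if (strand == "+") {
        m_start <- start + d$mature_off
      } else {
        m_start <- start + nchar(prec_fwd) - d$mature_off - nchar(d$mature)
      }
      m_end <- m_start + nchar(d$mature)
      multiplicity <- count_occurrences(cand_genome, d$mature)
      if (multiplicity != 1L) next   # background or star collision: redraw
      extra <- list()
      if (!is.na(plan$designed_fail[i]) && plan$designed_fail[i] == 4L) {
        # plant 20 extra exact copies of the mature plus its two
        # following bases, so 3'-jittered read variants multi-map too
        copy_seq <- substr(d$precursor, d$mature_off + 1L,
                           d$mature_off + nchar(d$mature) + 2L)
        ok_extra <- TRUE
        occ2 <- occupied
        occ2[[chrom]] <- c(occ2[[chrom]], list(c(start, start + plen)))
        for (k in 1:20) {
          c2 <- sample(chroms, 1L)
          s2 <- find_slot(clen[match(c2, chroms)], occ2[[c2]],
                          nchar(copy_seq), 60L)
          if (is.na(s2)) { ok_extra <- FALSE; break }
          cand_genome[c2] <- splice_into(cand_genome[[c2]], s2, copy_seq)
          occ2[[c2]] <- c(occ2[[c2]], list(c(s2, s2 + nchar(copy_seq))))
          extra[[k]] <- list(chrom = c2, start = s2, len = nchar(copy_seq))
        }
        if (!ok_extra) next
        multiplicity <- count_occurrences(cand_genome, d$mature)
        if (multiplicity != 21L) next
      }
      pseudo_hit <- data.frame(tag_id = plan$name[i], sequence = d$mature,
                               chrom = chrom, start = m_start, end = m_end,
                               strand = strand, multiplicity = multiplicity,
                               total = sum(counts[i, ]),
                               stringsAsFactors = FALSE)
      nv <- call_novel_mirnas(pseudo_hit, cand_genome, crit_cfg)
      lv <- locus_verdicts(nv)
      want <- if (is.na(plan$designed_fail[i])) "" else
        as.character(plan$designed_fail[i])
      if (nrow(lv) == 1L && lv$fails == want) {
        genome <- cand_genome
        occupied[[chrom]] <- c(occupied[[chrom]],
                               list(c(start, start + plen)))
        for (e in extra) {
          occupied[[e$chrom]] <- c(occupied[[e$chrom]],
                                   list(c(e$start, e$start + e$len)))
        }
        mature_read <- d$mature                 # read orientation
        loci[[i]] <- list(name = plan$name[i], category = plan$category[i],
                          chrom = chrom, strand = strand,
                          start = m_start, end = m_end,
                          prec_start = start, prec_end = start + nchar(prec_fwd),
                          mature = mature_read,
                          precursor = d$precursor,       # read orientation
                          precursor_fwd = prec_fwd,
                          designed_fail = plan$designed_fail[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("could not realize planted locus %s (%s) after 60 draws",
            plan$name[i], plan$design[i])
    }
  }
  loci_df <- do.call(rbind, lapply(loci, function(l) {
    data.frame(l[c("name", "category", "chrom", "strand", "start", "end",
                   "prec_start", "prec_end", "mature", "precursor",
                   "designed_fail")], stringsAsFactors = FALSE)
  }))
  if (is.null(loci_df)) {
    loci_df <- data.frame(name = character(), category = character(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          prec_start = integer(), prec_end = integer(),
                          mature = character(), precursor = character(),
                          designed_fail = integer(), stringsAsFactors = FALSE)
  }

  ## decoy annotation features
  feat_cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA",
                 "repeat", "exon", "intron")
  features <- list()
  if (config$n_decoy_features > 0) {
    for (k in seq_len(config$n_decoy_features)) {
      cat <- feat_cats[(k - 1L) %% length(feat_cats) + 1L]
      flen <- sample(80:150, 1L)
      chrom <- sample(chroms, 1L)
      start <- find_slot(clen[match(chrom, chroms)], occupied[[chrom]],
                         flen, 200L)
      if (is.na(start)) stopf("insufficient genome space for decoy features")
      fseq <- rand_dna(flen)
      genome[chrom] <- splice_into(genome[[chrom]], start, fseq)
      occupied[[chrom]] <- c(occupied[[chrom]], list(c(start, start + flen)))
      features[[k]] <- data.frame(id = sprintf("%s_%02d", cat, k),
                                  category = cat, chrom = chrom,
                                  start = start, end = start + flen,
                                  strand = "+", sequence = fseq,
                                  stringsAsFactors = FALSE)
    }
  }
  features <- if (length(features)) do.call(rbind, features) else
    data.frame(id = character(), category = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               sequence = character(), stringsAsFactors = FALSE)

  known <- loci_df[loci_df$category == "known", , drop = FALSE]
  reference_mature <- data.frame(id = known$name,
                                 sequence = known$mature,
                                 stringsAsFactors = FALSE)
  reference_hairpin <- data.frame(id = if (nrow(known)) {
                                    paste0(known$name, "-hairpin")
                                  } else character(),
                                  sequence = known$precursor,
                                  stringsAsFactors = FALSE)
  counts_df <- data.frame(name = rownames(counts), counts,
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(config = config, genome = genome,
                 truth = list(loci = loci_df, counts = counts_df,
                              presence = presence,
                              reference_mature = reference_mature,
                              reference_hairpin = reference_hairpin,
                              features = features)),
            class = "mirna_sim")
}

#' @export
print.mirna_sim <- function(x, ...) {
  cat(sprintf("synthetic miRNA dataset: %d contigs (%d nt), %d planted loci (%d known, %d novel, %d decoys), %d decoy features\n",
              length(x$genome), sum(nchar(x$genome)), nrow(x$truth$loci),
              sum(x$truth$loci$category == "known"),
              sum(x$truth$loci$category == "novel"),
              sum(startsWith(x$truth$loci$category, "decoy")),
              nrow(x$truth$features)))
  invisible(x)
}

mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

#' Simulate per-tissue small-RNA reads from planted ground truth
#'
#' For each planted miRNA and tissue, emits its planned number of reads:
#' the mature sequence (5' end fixed, 3' end jittered by at most 1 nt at
#' the configured rate) followed by the 3' adapter, truncated to the
#' read length. Decoy features shed exact subfragment reads; junk
#' classes are injected at the configured fractions. Deterministic given
#' the seed.
#'
#' @param sim a `mirna_sim` from [generate_toy_genome()].
#' @return named list (one per tissue) of read data frames with columns
#'   `id`, `sequence`, `qual`.
#' @export
simulate_reads <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 131071L)
  truth <- sim$truth
  q_hi <- phred_encode(rep(40L, config$read_length))
  out <- list()
  for (tissue in config$tissues) {
    seqs <- character()
    quals <- character()
    for (i in seq_len(nrow(truth$loci))) {
      n <- truth$counts[[tissue]][match(truth$loci$name[i],
                                        truth$counts$name)]
      if (is.na(n) || n < 1L) next
      l <- truth$loci[i, ]
      # 3' context base for +1 jitter, in read orientation
      moff <- regexpr(l$mature, l$precursor, fixed = TRUE)
      nxt <- substr(l$precursor, moff + nchar(l$mature),
                    moff + nchar(l$mature))
      for (r in seq_len(n)) {
        insert <- l$mature
        if (config$jitter_3p > 0 && runif(1) < config$jitter_3p) {
          insert <- if (runif(1) < 0.5 && nzchar(nxt)) {
            paste0(insert, nxt)
          } else {
            substr(insert, 1L, nchar(insert) - 1L)
          }
        }
        insert <- mutate_bases(insert, config$base_error)
        seqs <- c(seqs, paste0(insert, config$adapter_3p))
        quals <- c(quals, q_hi)
      }
    }
    # degradation fragments from decoy features
    for (f in seq_len(nrow(truth$features))) {
      fseq <- truth$features$sequence[f]
      for (r in seq_len(config$feature_read_count)) {
        flen <- sample(18:30, 1L)
        fs <- sample.int(nchar(fseq) - flen + 1L, 1L)
        seqs <- c(seqs, paste0(substr(fseq, fs, fs + flen - 1L),
                               config$adapter_3p))
        quals <- c(quals, q_hi)
      }
    }
    n_signal <- length(seqs)
    fr <- config$junk_fractions
    if (sum(fr) > 0 && n_signal > 0) {
      n_total <- ceiling(n_signal / (1 - sum(fr)))
      n_junk <- setNames(vapply(fr, function(p) rbinom(1L, n_total, p),
                                integer(1)), names(fr))
      for (r in seq_len(n_junk[["polyA"]])) {
        seqs <- c(seqs, paste0(strrep("A", sample(20:28, 1L)),
                               config$adapter_3p))
        quals <- c(quals, q_hi)
      }
      for (r in seq_len(n_junk[["short"]])) {
        seqs <- c(seqs, paste0(rand_dna(sample(8:16, 1L)), config$adapter_3p))
        quals <- c(quals, q_hi)
      }
      for (r in seq_len(n_junk[["no_adapter"]])) {
        repeat {
          s <- rand_dna(config$read_length)
          if (!is.null(trim_adapters(s, config$adapter_3p)$reason) &&
              trim_adapters(s, config$adapter_3p)$reason == "no_3p_adapter") {
            break
          }
        }
        seqs <- c(seqs, s)
        quals <- c(quals, q_hi)
      }
      for (r in seq_len(n_junk[["low_quality"]])) {
        ins_len <- sample(20:26, 1L)
        seqs <- c(seqs, paste0(rand_dna(ins_len), config$adapter_3p))
        quals <- c(quals, phred_encode(c(rep(5L, ins_len),
                                         rep(40L, config$read_length -
                                                  ins_len))))
      }
    }
    seqs <- substr(seqs, 1L, config$read_length)
    quals <- substr(quals, 1L, config$read_length)
    quals <- substr(quals, 1L, nchar(seqs))
    ord <- sample.int(length(seqs))
    out[[tissue]] <- data.frame(
      id = sprintf("sim_%s_%06d", tissue, seq_along(ord)),
      sequence = seqs[ord], qual = quals[ord], stringsAsFactors = FALSE)
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the genome, mock reference catalog, decoy features, truth
#' tables and per-tissue FASTQ files; running the generator twice with
#' the same seed produces byte-identical files.
#'
#' @param sim a `mirna_sim` from [generate_toy_genome()].
#' @param reads result of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(sim$genome, p("genome.fa"))
  write_fasta(sim$truth$reference_mature, p("reference_mature.fa"))
  write_fasta(sim$truth$reference_hairpin, p("reference_hairpin.fa"))
  feats <- sim$truth$features
  write_gff3(feats, p("decoy_features.gff3"), type = "decoy")
  write_fasta(data.frame(id = feats$id, description = feats$category,
                         sequence = feats$sequence,
                         stringsAsFactors = FALSE), p("decoy_features.fa"))
  loci <- sim$truth$loci
  write_tsv(loci, p("truth_loci.tsv"))
  write_tsv(sim$truth$counts, p("truth_counts.tsv"))
  fq <- character()
  for (tissue in names(reads)) {
    fq[tissue] <- p(paste0(tissue, ".fastq"))
    write_fastq(reads[[tissue]], fq[tissue])
  }
  list(genome = p("genome.fa"), reference_mature = p("reference_mature.fa"),
       reference_hairpin = p("reference_hairpin.fa"),
       features_gff3 = p("decoy_features.gff3"),
       features_fasta = p("decoy_features.fa"),
       truth_loci = p("truth_loci.tsv"), truth_counts = p("truth_counts.tsv"),
       reads = fq)
}
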