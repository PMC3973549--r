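## Novel-miRNA calling: candidate window excision around unannotated
## mapped tags, folding, miRNA/miRNA* duplex characterization, and the
## ten-criteria verdict.

CRITERIA_NAMES <- c("mature_length", "reference_length", "cut_site_depth",
                    "copy_number", "free_energy", "space", "duplex_pairs",
                    "bulge", "asymmetry", "flank")

#' Thresholds for novel-miRNA candidate evaluation
#'
#' The ten criteria a candidate precursor must meet: (1) mature length
#' 18-26 nt; (2) reference (locus-representative tag) length 20-24 nt;
#' (3) read depth at the mature 5' cut site >= 3; (4) at most 20 perfect
#' genomic copies; (5) precursor free energy <= -18 kcal/mol; (6) at most
#' 35 nt between miRNA and miRNA*; (7) at least 14 miRNA/miRNA* base
#' pairs; (8) duplex bulges at most 4 nt; (9) duplex asymmetry at most
#' 5 nt; (10) at least 10 nt of flank around the duplex.
#'
#' @param min_mirna_len,max_mirna_len mature length bounds (nt).
#' @param min_ref_len,max_ref_len representative-tag length bounds (nt).
#' @param min_cut_depth minimal read depth sharing the mature 5' end.
#' @param max_copy_number maximal perfect genomic loci of the tag.
#' @param max_free_energy maximal precursor free energy (kcal/mol).
#' @param max_space maximal unpaired span between the two arms (nt).
#' @param min_duplex_pairs minimal miRNA/miRNA* base pairs.
#' @param max_bulge maximal bulge within the duplex (nt).
#' @param max_asymmetry maximal |unpaired miRNA - unpaired miRNA*| (nt).
#' @param flank_len required flank around the duplex (nt); also the
#'   flank added when excising candidate windows.
#' @return list of class `criteria_config`.
#' @export
criteria_config <- function(min_mirna_len = 18L, max_mirna_len = 26L,
                            min_ref_len = 20L, max_ref_len = 24L,
                            min_cut_depth = 3L, max_copy_number = 20L,
                            max_free_energy = -18, max_space = 35L,
                            min_duplex_pairs = 14L, max_bulge = 4L,
                            max_asymmetry = 5L, flank_len = 10L) {
  stopifnot(min_mirna_len <= max_mirna_len, min_ref_len <= max_ref_len,
            max_free_energy < 0)
  structure(list(min_mirna_len = as.integer(min_mirna_len),
                 max_mirna_len = as.integer(max_mirna_len),
                 min_ref_len = as.integer(min_ref_len),
                 max_ref_len = as.integer(max_ref_len),
                 min_cut_depth = as.integer(min_cut_depth),
                 max_copy_number = as.integer(max_copy_number),
                 max_free_energy = max_free_energy,
                 max_space = as.integer(max_space),
                 min_duplex_pairs = as.integer(min_duplex_pairs),
                 max_bulge = as.integer(max_bulge),
                 max_asymmetry = as.integer(max_asymmetry),
                 flank_len = as.integer(flank_len)),
            class = "criteria_config")
}

#' Excise candidate precursor windows around a genomic tag hit
#'
#' Window A treats the tag as the 5' arm of a hairpin (flank upstream,
#' room for loop and star downstream); window B mirrors it with the tag
#' as the 3' arm. Windows are clipped at contig bounds, minus-strand hits
#' are reverse-complemented into transcript orientation, and DNA is
#' transcribed to RNA. A window shorter than the tag plus 20 nt after
#' clipping is dropped.
#'
#' @param hit single-row data frame (or list) with `chrom`, `start`,
#'   `end`, `strand` (0-based half-open, forward coordinates).
#' @param genome named character vector of contig sequences (DNA).
#' @param config a [criteria_config()].
#' @return list of up to two candidate windows; each is a list with
#'   `role` ("A"/"B"), `chrom`, `strand`, `gstart`, `gend` (genomic span
#'   of the window), `window` (RNA string, transcript orientation),
#'   `mature_off` (0-based offset of the tag in the window) and
#'   `mature_len`.
#' @export
excise_candidate_windows <- function(hit, genome, config = criteria_config()) {
  chrom <- hit$chrom; start <- hit$start; end <- hit$end; strand <- hit$strand
  L <- nchar(genome[[chrom]])
  tlen <- end - start
  reach <- config$max_space + config$max_mirna_len + config$flank_len
  spans <- if (strand == "+") {
    list(A = c(start - config$flank_len, end + reach),
         B = c(start - reach, end + config$flank_len))
  } else {
    list(A = c(start - reach, end + config$flank_len),
         B = c(start - config$flank_len, end + reach))
  }
  out <- list()
  for (role in names(spans)) {
    gs <- max(0L, as.integer(spans[[role]][1]))
    ge <- min(L, as.integer(spans[[role]][2]))
    if (ge - gs < tlen + 20L) next
    slice <- substr(genome[[chrom]], gs + 1L, ge)
    if (strand == "+") {
      window <- dna_to_rna(slice)
      off <- start - gs
    } else {
      window <- dna_to_rna(revcomp(slice))
      off <- ge - end
    }
    out[[length(out) + 1L]] <- list(role = role, chrom = chrom,
                                    strand = strand, gstart = gs, gend = ge,
                                    window = window, mature_off = off,
                                    mature_len = tlen)
  }
  out
}

#' Characterize the miRNA/miRNA* duplex in a folded precursor
#'
#' The star arm is the interval of positions pairing with the mature arm,
#' extended by the canonical 2-nt 3' overhang. Reports the number of
#' duplex base pairs, the longest unpaired run (bulge) inside either arm
#' of the duplex, the asymmetry (|unpaired mature - unpaired star| within
#' the duplex), and the unpaired span between the two arms across the
#' loop (measured between the raw pairing extents; the overhang does not
#' count).
#'
#' @param fold a `fold_result` from [fold()].
#' @param mature_off 0-based offset of the mature arm in the sequence.
#' @param mature_len mature arm length (nt).
#' @return list with `paired`, `max_bulge`, `asymmetry`, `space`,
#'   `no_duplex`, `mature_region`, `star_raw` and `star` (1-based
#'   inclusive intervals; `star` carries the 2-nt 3' overhang).
#' @export
find_duplex <- function(fold, mature_off, mature_len) {
  n <- nchar(fold$sequence)
  partner <- structure_pairs(fold$structure)
  m1 <- mature_off + 1L
  m2 <- mature_off + mature_len
  stopifnot(m1 >= 1L, m2 <= n)
  no_duplex <- list(paired = 0L, max_bulge = NA_integer_,
                    asymmetry = NA_integer_, space = NA_integer_,
                    no_duplex = TRUE, mature_region = c(NA, NA),
                    star_raw = c(NA, NA), star = c(NA, NA))
  p <- partner[m1:m2]
  outside <- !is.na(p) & (p < m1 | p > m2)   # ignore mature self-pairing
  if (!any(outside)) return(no_duplex)
  # keep the arm side holding the majority of partners
  p_out <- p[outside]
  left <- p_out < m1
  use_left <- sum(left) > sum(!left)
  keep <- outside & (if (use_left) p < m1 else p > m2)
  if (!any(keep)) return(no_duplex)
  mpos <- (m1:m2)[keep]
  spos <- partner[mpos]
  paired <- length(mpos)
  mr <- c(min(mpos), max(mpos))
  sr <- c(min(spos), max(spos))
  run_max <- function(flags) {
    if (!length(flags)) return(0L)
    r <- rle(flags)
    mx <- r$lengths[r$values]
    if (length(mx)) max(mx) else 0L
  }
  m_un <- setdiff(mr[1]:mr[2], mpos)
  s_un <- setdiff(sr[1]:sr[2], spos)
  bulge <- max(run_max((mr[1]:mr[2]) %in% m_un),
               run_max((sr[1]:sr[2]) %in% s_un))
  asym <- abs(length(m_un) - length(s_un))
  space <- if (sr[1] > m2) sr[1] - mr[2] - 1L else mr[1] - sr[2] - 1L
  list(paired = paired, max_bulge = as.integer(bulge),
       asymmetry = as.integer(asym), space = as.integer(space),
       no_duplex = FALSE, mature_region = mr, star_raw = sr,
       star = c(sr[1], min(n, sr[2] + 2L)))
}

#' Evaluate the ten novel-miRNA criteria
#'
#' @param measures list with `mature_len`, `ref_len`, `cut_depth`,
#'   `copy_number`, `energy`, `space`, `paired`, `bulge`, `asymmetry`,
#'   `flank`. `NA` measures fail their criterion.
#' @param config a [criteria_config()].
#' @return object of class `criteria_verdict`: data frame with columns
#'   `criterion`, `name`, `value`, `pass`, and attribute `overall`
#'   (`TRUE` iff all ten pass).
#' @export
evaluate_criteria <- function(measures, config = criteria_config()) {
  chk <- function(value, ok) !is.na(value) && ok
  m <- measures
  pass <- c(
    chk(m$mature_len, m$mature_len >= config$min_mirna_len &&
                      m$mature_len <= config$max_mirna_len),
    chk(m$ref_len, m$ref_len >= config$min_ref_len &&
                   m$ref_len <= config$max_ref_len),
    chk(m$cut_depth, m$cut_depth >= config$min_cut_depth),
    chk(m$copy_number, m$copy_number <= config$max_copy_number),
    chk(m$energy, m$energy <= config$max_free_energy),
    chk(m$space, m$space >= 0 && m$space <= config$max_space),
    chk(m$paired, m$paired >= config$min_duplex_pairs),
    chk(m$bulge, m$bulge <= config$max_bulge),
    chk(m$asymmetry, m$asymmetry <= config$max_asymmetry),
    chk(m$flank, m$flank >= config$flank_len))
  vals <- c(m$mature_len, m$ref_len, m$cut_depth, m$copy_number, m$energy,
            m$space, m$paired, m$bulge, m$asymmetry, m$flank)
  out <- data.frame(criterion = 1:10, name = CRITERIA_NAMES,
                    value = as.numeric(vals), pass = pass,
                    stringsAsFactors = FALSE)
  class(out) <- c("criteria_verdict", class(out))
  attr(out, "overall") <- all(pass)
  out
}

#' @export
print.criteria_verdict <- function(x, ...) {
  cat(sprintf("criteria verdict: %s\n",
              if (attr(x, "overall")) "PASS" else
                paste("FAIL at", paste(x$criterion[!x$pass], collapse = ","))))
  print.data.frame(x)
  invisible(x)
}

## the caller ---------------------------------------------------------------

five_prime_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

cut_site_depths <- function(hits) {
  key <- paste(hits$chrom, hits$strand,
               five_prime_pos(hits$start, hits$end, hits$strand))
  # each tag contributes its total once per distinct 5' stack it sits on
  dedup <- !duplicated(paste(key, hits$tag_id))
  depth <- tapply(hits$total[dedup], key[dedup], sum)
  setNames(as.integer(depth), names(depth))
}

representative_tag_length <- function(hits, chrom, strand, gstart, gend) {
  h <- hits[hits$chrom == chrom & hits$strand == strand &
            hits$start < gend & hits$end > gstart, , drop = FALSE]
  if (!nrow(h)) return(NA_integer_)
  h <- h[!duplicated(h$tag_id), , drop = FALSE]
  best <- which.max(h$total)
  nchar(h$sequence[best])
}

#' Call novel miRNAs from unannotated genome-mapped tags
#'
#' For every hit, excises candidate windows ([excise_candidate_windows()]),
#' folds them, locates the miRNA/miRNA* duplex, refines the precursor to
#' the duplex plus flanks, refolds, and evaluates the ten criteria on the
#' refined precursor. Passing candidates overlapping at one locus are
#' merged, keeping the lowest-energy precursor (ties: higher read
#' support, then leftmost); the reported mature is the most abundant tag
#' inside the chosen precursor. Calls are ordered by chromosome and
#' start.
#'
#' @param hits data frame from [map_tags()] restricted to unannotated
#'   tags.
#' @param genome named character vector of contig sequences (DNA).
#' @param config a [criteria_config()].
#' @param params a [fold_params()] list for the baseline engine.
#' @param engine folding engine passed to [fold()].
#' @param stack_hits optional wider hit table used for 5'-stack depths
#'   and representative tags (defaults to `hits`).
#' @return object of class `novel_calls`: list with `calls` (one row per
#'   novel miRNA: id, locus, precursor, structure, energy, mature, star,
#'   read support) and `candidates` (one row per evaluated candidate
#'   window with its per-criterion failures).
#' @export
call_novel_mirnas <- function(hits, genome, config = criteria_config(),
                              params = fold_params(),
                              engine = "baseline", stack_hits = hits) {
  empty_calls <- data.frame(id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), mature = character(),
                            star = character(), precursor = character(),
                            structure = character(), energy = numeric(),
                            read_support = integer(), tag_id = character(),
                            stringsAsFactors = FALSE)
  empty_cand <- data.frame(tag_id = character(), chrom = character(),
                           strand = character(), start = integer(),
                           end = integer(), energy = numeric(),
                           read_support = integer(), n_fail = integer(),
                           fails = character(), overall = logical(),
                           stringsAsFactors = FALSE)
  if (!nrow(hits)) {
    return(structure(list(calls = empty_calls, candidates = empty_cand,
                          verdicts = list()), class = "novel_calls"))
  }
  depths <- cut_site_depths(stack_hits)
  cands <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    fp <- five_prime_pos(hit$start, hit$end, hit$strand)
    depth <- depths[[paste(hit$chrom, hit$strand, fp)]]
    windows <- excise_candidate_windows(hit, genome, config)
    for (w in windows) {
      fr <- fold(w$window, engine = engine, params = params)
      dx <- find_duplex(fr, w$mature_off, w$mature_len)
      if (dx$no_duplex) {
        measures <- list(mature_len = w$mature_len, ref_len = NA,
                         cut_depth = depth, copy_number = hit$multiplicity,
                         energy = fr$energy, space = NA, paired = 0L,
                         bulge = NA, asymmetry = NA, flank = NA)
        cands[[length(cands) + 1L]] <- list(
          hit = hit, role = w$role, chrom = w$chrom, strand = w$strand,
          gstart = w$gstart, gend = w$gend, energy = fr$energy,
          read_support = depth, verdict = evaluate_criteria(measures, config),
          precursor = w$window, structure = fr$structure,
          mature = dna_to_rna(hit$sequence), star = NA_character_)
        next
      }
      # refine the precursor to duplex (spanning the full mature arm)
      # +/- flank, refold, re-measure
      d0 <- min(w$mature_off, dx$star[1] - 1L)          # 0-based start
      d1 <- max(w$mature_off + w$mature_len, dx$star[2]) # 0-based end
      p0 <- max(0L, d0 - config$flank_len)
      p1 <- min(nchar(w$window), d1 + config$flank_len)
      prec <- substr(w$window, p0 + 1L, p1)
      fr2 <- fold(prec, engine = engine, params = params)
      dx2 <- find_duplex(fr2, w$mature_off - p0, w$mature_len)
      if (w$strand == "+") {
        g0 <- w$gstart + p0; g1 <- w$gstart + p1
      } else {
        g0 <- w$gend - p1; g1 <- w$gend - p0
      }
      ref_len <- representative_tag_length(stack_hits, w$chrom, w$strand,
                                           g0, g1)
      if (dx2$no_duplex) {
        measures <- list(mature_len = w$mature_len, ref_len = ref_len,
                         cut_depth = depth, copy_number = hit$multiplicity,
                         energy = fr2$energy, space = NA, paired = 0L,
                         bulge = NA, asymmetry = NA, flank = NA)
        star_seq <- NA_character_
      } else {
        m_off2 <- w$mature_off - p0
        dd0 <- min(m_off2, dx2$star[1] - 1L)
        dd1 <- max(m_off2 + w$mature_len, dx2$star[2])
        flank <- min(dd0, nchar(prec) - dd1)
        measures <- list(mature_len = w$mature_len, ref_len = ref_len,
                         cut_depth = depth, copy_number = hit$multiplicity,
                         energy = fr2$energy, space = dx2$space,
                         paired = dx2$paired, bulge = dx2$max_bulge,
                         asymmetry = dx2$asymmetry, flank = flank)
        star_seq <- substr(prec, dx2$star[1], dx2$star[2])
      }
      cands[[length(cands) + 1L]] <- list(
        hit = hit, role = w$role, chrom = w$chrom, strand = w$strand,
        gstart = g0, gend = g1, energy = fr2$energy, read_support = depth,
        verdict = evaluate_criteria(measures, config), precursor = prec,
        structure = fr2$structure, mature = dna_to_rna(hit$sequence),
        star = star_seq)
    }
  }
  cand_df <- do.call(rbind, lapply(cands, function(cd) {
    v <- cd$verdict
    data.frame(tag_id = cd$hit$tag_id, chrom = cd$chrom, strand = cd$strand,
               start = cd$gstart, end = cd$gend, energy = cd$energy,
               read_support = cd$read_support,
               n_fail = sum(!v$pass),
               fails = paste(v$criterion[!v$pass], collapse = ","),
               overall = attr(v, "overall"), stringsAsFactors = FALSE)
  }))
  if (is.null(cand_df)) cand_df <- empty_cand
  rownames(cand_df) <- NULL

  passing <- which(cand_df$overall)
  calls <- empty_calls
  if (length(passing)) {
    groups <- overlap_groups(cand_df[passing, , drop = FALSE])
    rows <- lapply(unique(groups), function(g) {
      idx <- passing[groups == g]
      sub <- cand_df[idx, , drop = FALSE]
      ord <- order(sub$energy, -sub$read_support, sub$start)
      cd <- cands[[idx[ord[1]]]]
      span <- c(min(sub$start), max(sub$end))
      # mature = most abundant tag inside the chosen precursor
      h <- stack_hits[stack_hits$chrom == cd$chrom &
                      stack_hits$strand == cd$strand &
                      stack_hits$start < cd$gend &
                      stack_hits$end > cd$gstart, , drop = FALSE]
      mature <- if (nrow(h)) {
        dna_to_rna(h$sequence[which.max(h$total)])
      } else cd$mature
      data.frame(chrom = cd$chrom, start = cd$gstart, end = cd$gend,
                 strand = cd$strand, mature = mature, star = cd$star,
                 precursor = cd$precursor, structure = cd$structure,
                 energy = cd$energy, read_support = cd$read_support,
                 tag_id = cd$hit$tag_id, span_start = span[1],
                 span_end = span[2], stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
    calls <- cbind(id = sprintf("novel_mir_%03d", seq_len(nrow(calls))),
                   calls, stringsAsFactors = FALSE)
    calls$span_start <- calls$span_end <- NULL
    rownames(calls) <- NULL
  }
  structure(list(calls = calls, candidates = cand_df,
                 verdicts = lapply(cands, `[[`, "verdict")),
            class = "novel_calls")
}

# single-linkage grouping of intervals by overlap (same chromosome,
# strand-agnostic so that a locus yields one call)
overlap_groups <- function(df) {
  n <- nrow(df)
  groups <- integer(n)
  gid <- 0L
  ord <- order(df$chrom, df$start)
  cur_chrom <- ""
  cur_end <- -Inf
  for (i in ord) {
    if (df$chrom[i] != cur_chrom || df$start[i] >= cur_end) {
      gid <- gid + 1L
      cur_chrom <- df$chrom[i]
      cur_end <- df$end[i]
    } else {
      cur_end <- max(cur_end, df$end[i])
    }
    groups[i] <- gid
  }
  groups
}

#' @export
print.novel_calls <- function(x, ...) {
  cat(sprintf("novel miRNA calls: %d (from %d candidate windows)\n",
              nrow(x$calls), nrow(x$candidates)))
  if (nrow(x$calls)) {
    print.data.frame(x$calls[, c("id", "chrom", "start", "end", "strand",
                                 "energy", "read_support")])
  }
  invisible(x)
}

#' Representative verdict per candidate locus
#'
#' Groups all evaluated candidate windows by genomic overlap and keeps,
#' per locus, the verdict of the most-supported read stack (ties: fewer
#' failed criteria, then lower energy, then leftmost), so the locus
#' verdict reflects its dominant tag rather than stray low-count
#' variants. Used to ask which criterion a non-called locus failed.
#'
#' @param novel a `novel_calls` object.
#' @return data frame with one row per candidate locus: `chrom`,
#'   `start`, `end`, `strand`, `n_fail`, `fails`, `overall`.
#' @export
locus_verdicts <- function(novel) {
  cd <- novel$candidates
  if (!nrow(cd)) return(cd)
  groups <- overlap_groups(cd)
  rows <- lapply(unique(groups), function(g) {
    sub <- cd[groups == g, , drop = FALSE]
    ord <- order(-sub$read_support, sub$n_fail, sub$energy, sub$start)
    best <- sub[ord[1], , drop = FALSE]
    best$start <- min(sub$start)
    best$end <- max(sub$end)
    best
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
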