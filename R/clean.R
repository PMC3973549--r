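## Read cleaning: adapter trimming, insert filtering, tag collapsing.
##
## Every raw read ends up in exactly one bucket: clean, or one of the six
## removal reasons. The per-tissue report reconciles exactly
## (raw == clean + sum of removals), which downstream tests rely on.

CLEAN_REASONS <- c("low_quality", "adapter5_contaminant", "no_3p_adapter",
                   "insert_null", "short", "polyA")

#' Cleaning thresholds
#'
#' @param min_len,max_len insert length bounds retained for analysis (nt).
#' @param polya_frac minimal adenine fraction for the poly-A removal.
#' @param lowq_phred Phred score below which a base counts as low quality.
#' @param lowq_frac fraction of low-quality bases above which the insert
#'   is removed.
#' @param min_overlap minimal 3' adapter overlap (nt).
#' @param max_mismatch_per10 allowed adapter mismatches per 10 aligned
#'   bases.
#' @return list of class `cleaning_config`.
#' @export
cleaning_config <- function(min_len = 18L, max_len = 30L, polya_frac = 0.8,
                            lowq_phred = 10L, lowq_frac = 0.5,
                            min_overlap = 6L, max_mismatch_per10 = 1L) {
  stopifnot(min_len <= max_len, polya_frac > 0, polya_frac <= 1,
            min_overlap >= 1)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 polya_frac = polya_frac, lowq_phred = as.integer(lowq_phred),
                 lowq_frac = lowq_frac, min_overlap = as.integer(min_overlap),
                 max_mismatch_per10 = as.integer(max_mismatch_per10)),
            class = "cleaning_config")
}

#' Locate the 3' adapter and extract the insert
#'
#' Scans the read left to right for the longest-prefix match of the 3'
#' adapter (minimum overlap `min_overlap`, at most `max_mismatch_per10`
#' mismatches per 10 aligned bases) and returns the insert preceding it.
#' A read that begins with the adapter has an empty insert
#' (`insert_null`); a read whose insert contains the 5' adapter is a
#' primer contaminant; a read with no adapter hit is `no_3p_adapter`.
#'
#' @param sequence read sequence (DNA string).
#' @param adapter_3p,adapter_5p adapter sequences (DNA strings).
#' @param config a [cleaning_config()].
#' @return list with either `insert` (and `insert_at`, the 1-based adapter
#'   start) or `reason` (one of `insert_null`, `adapter5_contaminant`,
#'   `no_3p_adapter`).
#' @export
trim_adapters <- function(sequence, adapter_3p, adapter_5p = "",
                          config = cleaning_config()) {
  stopifnot(nzchar(adapter_3p))
  n <- nchar(sequence)
  alen <- nchar(adapter_3p)
  hit <- NA_integer_
  # exact occurrence of the (possibly truncated) full adapter bounds the
  # mismatch scan, which only needs to look for an earlier fuzzy hit
  probe <- substr(adapter_3p, 1L, min(alen, n))
  exact <- as.integer(regexpr(probe, sequence, fixed = TRUE))
  limit <- if (exact > 0L) exact - 1L else n - config$min_overlap + 1L
  limit <- min(limit, n - config$min_overlap + 1L)
  if (limit >= 1L) {
    sbase <- strsplit(sequence, "", fixed = TRUE)[[1]]
    abase <- strsplit(adapter_3p, "", fixed = TRUE)[[1]]
    for (start in seq_len(limit)) {
      aligned <- min(n - start + 1L, alen)
      mism <- sum(sbase[start:(start + aligned - 1L)] != abase[seq_len(aligned)])
      if (mism <= (aligned %/% 10L) * config$max_mismatch_per10) {
        hit <- start
        break
      }
    }
  }
  if (is.na(hit) && exact > 0L) hit <- exact
  if (is.na(hit)) return(list(reason = "no_3p_adapter"))
  if (hit == 1L) return(list(reason = "insert_null"))
  insert <- substr(sequence, 1L, hit - 1L)
  if (nzchar(adapter_5p) &&
      grepl(adapter_5p, insert, fixed = TRUE)) {
    return(list(reason = "adapter5_contaminant"))
  }
  list(insert = insert, insert_at = hit)
}

#' Filter a trimmed insert
#'
#' Applies the length, poly-A and base-quality filters, in that order.
#' Inserts shorter than `min_len` or longer than `max_len` are removed as
#' `short` (the length class); inserts whose adenine fraction reaches
#' `polya_frac` as `polyA`; inserts with more than `lowq_frac` of bases
#' below `lowq_phred` as `low_quality`.
#'
#' @param insert insert sequence (DNA string).
#' @param qualities integer Phred scores for the insert bases (may be
#'   `NULL` to skip the quality filter).
#' @param config a [cleaning_config()].
#' @return `NA_character_` if the insert passes, otherwise the removal
#'   reason.
#' @export
filter_insert <- function(insert, qualities = NULL,
                          config = cleaning_config()) {
  n <- nchar(insert)
  if (n < config$min_len || n > config$max_len) return("short")
  a_frac <- lengths(regmatches(insert, gregexpr("A", insert, fixed = TRUE))) / n
  if (a_frac >= config$polya_frac) return("polyA")
  if (!is.null(qualities) && length(qualities)) {
    if (mean(qualities < config$lowq_phred) > config$lowq_frac) {
      return("low_quality")
    }
  }
  NA_character_
}

#' Clean one tissue's reads
#'
#' Runs [trim_adapters()] and [filter_insert()] over a set of reads and
#' tallies removals by reason.
#'
#' @param reads data frame as returned by [read_fastq()].
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param config a [cleaning_config()].
#' @return list with `inserts` (character vector of passing inserts, one
#'   per clean read) and `report` (single-row data frame: `raw`, `clean`,
#'   one column per removal reason, `clean_fraction`).
#' @export
clean_reads <- function(reads, adapter_3p, adapter_5p = "",
                        config = cleaning_config()) {
  n <- nrow(reads)
  inserts <- character(0)
  removals <- setNames(integer(length(CLEAN_REASONS)), CLEAN_REASONS)
  for (i in seq_len(n)) {
    tr <- trim_adapters(reads$sequence[i], adapter_3p, adapter_5p, config)
    if (!is.null(tr$reason)) {
      removals[tr$reason] <- removals[tr$reason] + 1L
      next
    }
    quals <- if (!is.null(reads$qualities)) {
      reads$qualities[[i]][seq_len(nchar(tr$insert))]
    } else NULL
    reason <- filter_insert(tr$insert, quals, config)
    if (is.na(reason)) {
      inserts <- c(inserts, tr$insert)
    } else {
      removals[reason] <- removals[reason] + 1L
    }
  }
  report <- data.frame(raw = n, clean = length(inserts), t(removals))
  report$clean_fraction <- if (n) report$clean / n else 0
  list(inserts = inserts, report = report)
}

#' Collapse cleaned inserts into unique tags with per-tissue counts
#'
#' @param inserts_by_tissue named list: tissue -> character vector of
#'   cleaned inserts.
#' @return data frame with columns `tag_id`, `sequence`, one count column
#'   per tissue, and `total`; ordered by decreasing total, then sequence.
#' @export
collapse_to_tags <- function(inserts_by_tissue) {
  stopifnot(is.list(inserts_by_tissue), length(names(inserts_by_tissue)) > 0)
  tissues <- names(inserts_by_tissue)
  all_seqs <- sort(unique(unlist(inserts_by_tissue, use.names = FALSE)))
  counts <- sapply(tissues, function(t) {
    tab <- table(factor(inserts_by_tissue[[t]], levels = all_seqs))
    as.integer(tab)
  })
  if (!length(all_seqs)) {
    out <- data.frame(tag_id = character(), sequence = character(),
                      stringsAsFactors = FALSE)
    for (t in tissues) out[[t]] <- integer()
    out$total <- integer()
    return(out)
  }
  counts <- matrix(counts, nrow = length(all_seqs),
                   dimnames = list(NULL, tissues))
  total <- as.integer(rowSums(counts))
  ord <- order(-total, all_seqs)
  out <- data.frame(tag_id = sprintf("tag_%05d", seq_along(ord)),
                    sequence = all_seqs[ord], stringsAsFactors = FALSE)
  for (t in tissues) out[[t]] <- counts[ord, t]
  out$total <- total[ord]
  out
}

#' Count-encoded FASTA headers for collapsed tags
#'
#' Writes tags as `tag_00001_x37` style FASTA, the conventional collapsed
#' small-RNA representation.
#'
#' @param tags data frame from [collapse_to_tags()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tag_fasta <- function(tags, path) {
  write_fasta(data.frame(id = sprintf("%s_x%d", tags$tag_id, tags$total),
                         description = "", sequence = tags$sequence,
                         stringsAsFactors = FALSE), path)
}

#' Length distribution of tags
#'
#' @param tags data frame from [collapse_to_tags()].
#' @param weighted if `TRUE`, weight lengths by total read counts rather
#'   than counting distinct tags.
#' @return data frame with columns `length` and `count`.
#' @export
tag_length_distribution <- function(tags, weighted = FALSE) {
  len <- nchar(tags$sequence)
  w <- if (weighted) tags$total else rep(1L, nrow(tags))
  if (!nrow(tags)) return(data.frame(length = integer(), count = integer()))
  rng <- seq(min(len), max(len))
  data.frame(length = rng,
             count = vapply(rng, function(l) sum(w[len == l]), numeric(1)))
}
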