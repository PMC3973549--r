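## Nucleotide-composition statistics and the tissue-presence Venn
## partition. All statistics are computed over distinct mature sequences
## (unweighted) by default; `weights` enables read-count weighting.

seq_matrix <- function(sequences) {
  sequences <- dna_to_rna(toupper(sequences))
  check_alphabet(sequences, "rna", "composition input")
  strsplit(sequences, "", fixed = TRUE)
}

#' First-nucleotide bias by sequence length
#'
#' Frequency of A/C/G/U at position 1, per sequence length and over all
#' lengths, as percentages.
#'
#' @param sequences character vector of mature miRNA sequences (RNA or
#'   DNA; T is read as U).
#' @param weights optional non-negative weights (e.g. read counts);
#'   default unweighted.
#' @return data frame with columns `length` (integer, plus `"all"` coded
#'   as `NA`), `n`, and percentage columns `A`, `C`, `G`, `U`; every
#'   percentage row sums to 100.
#' @export
first_nucleotide_bias <- function(sequences, weights = NULL) {
  if (!length(sequences)) stopf("no sequences supplied")
  if (is.null(weights)) weights <- rep(1, length(sequences))
  stopifnot(length(weights) == length(sequences))
  chars <- seq_matrix(sequences)
  first <- vapply(chars, `[`, character(1), 1L)
  lens <- lengths(chars)
  row_for <- function(sel) {
    w <- weights[sel]
    f <- first[sel]
    tot <- sum(w)
    vapply(c("A", "C", "G", "U"),
           function(b) 100 * sum(w[f == b]) / tot, numeric(1))
  }
  lengths_seen <- sort(unique(lens))
  rows <- lapply(lengths_seen, function(L) row_for(lens == L))
  out <- data.frame(length = c(lengths_seen, NA),
                    n = c(vapply(lengths_seen, function(L) sum(lens == L),
                                 integer(1)), length(sequences)))
  pct <- do.call(rbind, c(rows, list(row_for(rep(TRUE, length(first))))))
  cbind(out, as.data.frame(pct))
}

#' Positional base composition
#'
#' Percentage of A/C/G/U at each position, computed over the sequences
#' long enough to reach that position, with derived A+U and C+G tracks
#' and the seed-region slice (positions 2-8) attached as an attribute.
#'
#' @inheritParams first_nucleotide_bias
#' @return data frame with columns `position`, `n`, `A`, `C`, `G`, `U`,
#'   `AU`, `CG`; attribute `seed` holds rows 2-8.
#' @export
positional_composition <- function(sequences, weights = NULL) {
  if (!length(sequences)) stopf("no sequences supplied")
  if (is.null(weights)) weights <- rep(1, length(sequences))
  chars <- seq_matrix(sequences)
  lens <- lengths(chars)
  maxlen <- max(lens)
  rows <- lapply(seq_len(maxlen), function(p) {
    sel <- lens >= p
    w <- weights[sel]
    b <- vapply(chars[sel], `[`, character(1), p)
    tot <- sum(w)
    pct <- vapply(c("A", "C", "G", "U"),
                  function(x) 100 * sum(w[b == x]) / tot, numeric(1))
    c(n = sum(sel), pct)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(position = seq_len(maxlen), n = as.integer(m[, "n"]),
                    A = m[, "A"], C = m[, "C"], G = m[, "G"], U = m[, "U"])
  out$AU <- out$A + out$U
  out$CG <- out$C + out$G
  attr(out, "seed") <- out[out$position >= 2 & out$position <= 8, ,
                           drop = FALSE]
  out
}

#' Tissue presence and Venn-region partition
#'
#' A miRNA is present in a tissue when its count reaches `threshold`.
#' For each non-empty tissue subset, reports the number of miRNAs
#' detected in exactly that subset; the regions partition the detected
#' set.
#'
#' @param counts data frame with a `name` column (or tag/miRNA ids in
#'   the first character column) and one numeric count column per
#'   tissue.
#' @param tissues character vector naming the count columns; default all
#'   numeric columns.
#' @param threshold minimal count for presence.
#' @return list with `presence` (data frame: `name`, one logical column
#'   per tissue; rows absent everywhere are dropped) and `regions`
#'   (named integer vector over non-empty tissue subsets, names like
#'   `"muscle&colon"`).
#' @export
tissue_presence_venn <- function(counts, tissues = NULL, threshold = 1L) {
  name_col <- if ("name" %in% names(counts)) "name" else names(counts)[1]
  if (is.null(tissues)) {
    tissues <- setdiff(names(counts)[vapply(counts, is.numeric, logical(1))],
                       name_col)
  }
  if (!length(tissues)) stopf("no tissue count columns found")
  pres <- as.data.frame(lapply(counts[tissues], function(x) x >= threshold))
  names(pres) <- tissues
  keep <- rowSums(pres) > 0
  presence <- cbind(data.frame(name = counts[[name_col]][keep],
                               stringsAsFactors = FALSE),
                    pres[keep, , drop = FALSE])
  rownames(presence) <- NULL
  subsets <- unlist(lapply(seq_along(tissues), function(k) {
    apply(utils::combn(tissues, k), 2, paste, collapse = "&")
  }))
  pattern <- apply(pres[keep, , drop = FALSE], 1, function(r) {
    paste(tissues[as.logical(r)], collapse = "&")
  })
  regions <- setNames(vapply(subsets, function(s) sum(pattern == s),
                             integer(1)), subsets)
  list(presence = presence, regions = regions)
}
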