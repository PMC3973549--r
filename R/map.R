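## Perfect-match genome mapping and catalog annotation.
##
## Mapping is exact and exhaustive: every full-length zero-mismatch
## occurrence of a tag on either strand is reported, with the tag's
## genome-wide hit count as its multiplicity. Biostrings does the string
## matching; the contract (identical to a naive both-strand scan) is
## pinned by a property test against a hand-rolled oracle.

#' Build an exact-match index over a genome
#'
#' @param genome named character vector of contig sequences (DNA), or a
#'   data frame as returned by [read_fasta()].
#' @return object of class `genome_index`.
#' @export
build_exact_index <- function(genome) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  if (!length(genome) || any(!nzchar(genome))) stopf("empty genome")
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stopf("genome contigs must be named")
  }
  fwd <- Biostrings::DNAStringSet(toupper(genome))
  structure(list(fwd = fwd, rev = Biostrings::reverseComplement(fwd),
                 lengths = setNames(nchar(genome), names(genome))),
            class = "genome_index")
}

#' Find all exact occurrences of a query on both strands
#'
#' @param index a [build_exact_index()] object.
#' @param query DNA string.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates) and `strand`; the
#'   strand-aware genome substring at each locus equals the query.
#' @export
index_lookup <- function(index, query) {
  stopifnot(inherits(index, "genome_index"), nzchar(query))
  pat <- Biostrings::DNAString(toupper(query))
  qlen <- nchar(query)
  out <- list()
  for (ci in seq_along(index$fwd)) {
    chrom <- names(index$lengths)[ci]
    clen <- index$lengths[[ci]]
    f <- Biostrings::matchPattern(pat, index$fwd[[ci]])
    if (length(f)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = Biostrings::start(f) - 1L,
        end = Biostrings::end(f), strand = "+", stringsAsFactors = FALSE)
    }
    r <- Biostrings::matchPattern(pat, index$rev[[ci]])
    if (length(r)) {
      # positions on the reverse complement map back to forward coords
      rs <- Biostrings::start(r) - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = clen - (rs + qlen), end = clen - rs,
        strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Map tags to the genome by perfect full-length matching
#'
#' @param tags data frame from [collapse_to_tags()] (columns `tag_id`,
#'   `sequence`, `total`), or a character vector of tag sequences.
#' @param index a [build_exact_index()] object.
#' @return data frame of hits: `tag_id`, `sequence`, `chrom`, `start`,
#'   `end`, `strand`, `multiplicity` (genome-wide hit count of the tag),
#'   `total` (read count). Tags with zero hits are absent.
#' @export
map_tags <- function(tags, index) {
  if (is.character(tags)) {
    tags <- data.frame(tag_id = sprintf("tag_%05d", seq_along(tags)),
                       sequence = tags, total = 1L, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(tags))) {
    hits <- index_lookup(index, tags$sequence[i])
    if (!nrow(hits)) next
    hits$tag_id <- tags$tag_id[i]
    hits$sequence <- tags$sequence[i]
    hits$multiplicity <- nrow(hits)
    hits$total <- tags$total[i]
    out[[length(out) + 1L]] <- hits
  }
  if (!length(out)) {
    return(data.frame(tag_id = character(), sequence = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), multiplicity = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("tag_id", "sequence", "chrom", "start", "end", "strand",
          "multiplicity", "total")]
}

## Annotation ---------------------------------------------------------------

ANNOTATION_PRIORITY <- c("known_mirna", "rRNA", "tRNA", "snRNA", "snoRNA",
                         "scRNA", "srpRNA", "repeat", "exon", "intron")

#' Assemble a reference catalog for tag annotation
#'
#' @param mature data frame (`id`, `sequence`) of known mature miRNAs.
#' @param hairpin data frame (`id`, `sequence`) of known miRNA hairpins.
#' @param sequences named list: category -> data frame (`id`, `sequence`)
#'   of reference transcripts (categories from the fixed vocabulary:
#'   rRNA, tRNA, snRNA, snoRNA, scRNA, srpRNA, repeat, exon, intron).
#' @param features optional data frame of genomic features (`chrom`,
#'   `start`, `end`, `strand`, `category`, `id`), e.g. from
#'   [read_gff3()]; a tag whose genomic hit overlaps a feature is
#'   assigned the feature's category.
#' @return object of class `reference_catalog`.
#' @export
reference_catalog <- function(mature = NULL, hairpin = NULL,
                              sequences = list(), features = NULL) {
  known_cats <- setdiff(ANNOTATION_PRIORITY, "known_mirna")
  bad <- setdiff(names(sequences), known_cats)
  if (length(bad)) stopf("unknown catalog category: %s", bad[1])
  if (!is.null(features)) {
    badf <- setdiff(unique(features$category), known_cats)
    if (length(badf)) stopf("unknown feature category: %s", badf[1])
  }
  structure(list(mature = mature, hairpin = hairpin,
                 sequences = sequences, features = features),
            class = "reference_catalog")
}

#' Annotate tags against a reference catalog
#'
#' A tag identical to a known mature miRNA, or an exact substring of a
#' known hairpin, is `known_mirna`. Otherwise the tag gets the first
#' category, in the fixed priority order
#' known_mirna > rRNA > tRNA > snRNA > snoRNA > scRNA > srpRNA >
#' repeat > exon > intron, in which it matches a catalog sequence
#' (exact substring) or overlaps a genomic feature; otherwise
#' `unannotated`.
#'
#' @param tags data frame with columns `tag_id`, `sequence`.
#' @param catalog a [reference_catalog()].
#' @param hits optional data frame from [map_tags()], needed to resolve
#'   feature-based categories.
#' @param priority category priority order (highest first).
#' @return data frame `tag_id`, `sequence`, `category`, `ref_id`.
#' @export
annotate_tags <- function(tags, catalog, hits = NULL,
                          priority = ANNOTATION_PRIORITY) {
  stopifnot(inherits(catalog, "reference_catalog"))
  n <- nrow(tags)
  category <- rep("unannotated", n)
  ref_id <- rep(NA_character_, n)

  match_seqs <- function(tag, refs) {
    # tag identical to a reference or contained in it
    j <- which(vapply(refs$sequence, function(r) {
      nchar(r) >= nchar(tag) && grepl(tag, r, fixed = TRUE)
    }, logical(1)))
    if (length(j)) refs$id[j[1]] else NA_character_
  }

  feat <- catalog$features
  tag_feature_cat <- function(tag_id, cat) {
    if (is.null(feat) || is.null(hits)) return(NA_character_)
    h <- hits[hits$tag_id == tag_id, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    fc <- feat[feat$category == cat, , drop = FALSE]
    if (!nrow(fc)) return(NA_character_)
    for (k in seq_len(nrow(h))) {
      ov <- fc$chrom == h$chrom[k] & fc$start < h$end[k] & fc$end > h$start[k]
      if (any(ov)) return(fc$id[which(ov)[1]])
    }
    NA_character_
  }

  for (i in seq_len(n)) {
    tag <- tags$sequence[i]
    for (cat in priority) {
      rid <- NA_character_
      if (cat == "known_mirna") {
        # miRNA catalog matching is strand-insensitive: a fragment of a
        # known precursor locus is "known" whichever strand was read
        rc <- revcomp(tag)
        if (!is.null(catalog$mature)) {
          j <- which(catalog$mature$sequence == tag |
                     catalog$mature$sequence == rc)
          if (length(j)) rid <- catalog$mature$id[j[1]]
        }
        if (is.na(rid) && !is.null(catalog$hairpin)) {
          rid <- match_seqs(tag, catalog$hairpin)
          if (is.na(rid)) rid <- match_seqs(rc, catalog$hairpin)
        }
      } else {
        if (!is.null(catalog$sequences[[cat]])) {
          rid <- match_seqs(tag, catalog$sequences[[cat]])
        }
        if (is.na(rid)) rid <- tag_feature_cat(tags$tag_id[i], cat)
      }
      if (!is.na(rid)) {
        category[i] <- cat
        ref_id[i] <- rid
        break
      }
    }
  }
  data.frame(tag_id = tags$tag_id, sequence = tags$sequence,
             category = category, ref_id = ref_id, stringsAsFactors = FALSE)
}

#' Per-category annotation summary
#'
#' @param annotation data frame from [annotate_tags()].
#' @param tags optional tag table supplying read counts (`total`).
#' @return data frame `category`, `unique_tags`, `reads`; category counts
#'   sum to the number of tags (the annotation is a partition).
#' @export
annotation_summary <- function(annotation, tags = NULL) {
  cats <- c(ANNOTATION_PRIORITY, "unannotated")
  reads <- if (!is.null(tags)) {
    setNames(tags$total, tags$tag_id)[annotation$tag_id]
  } else rep(NA_integer_, nrow(annotation))
  data.frame(
    category = cats,
    unique_tags = vapply(cats, function(c) sum(annotation$category == c),
                         integer(1)),
    reads = vapply(cats, function(c) {
      if (all(is.na(reads))) NA_real_
      else sum(reads[annotation$category == c], na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
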