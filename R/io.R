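## Readers and writers for the plain-text formats the pipeline touches.
## Internal coordinates are 0-based half-open throughout the package;
## GFF3 output (and the printed cluster table) are 1-based inclusive.

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a data frame with one
#' row per record. Sequences are uppercased; record order is preserved.
#'
#' @param path path to a FASTA file (plain text or gzip).
#' @param alphabet one of `"any"`, `"dna"`, `"rna"`; when not `"any"` the
#'   sequences are validated against the corresponding alphabet
#'   (N allowed).
#' @return data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("any", "dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  lns <- lines[nonblank]
  is_hdr <- startsWith(lns, ">")
  if (!is_hdr[1]) {
    stopf("FASTA format error at line %d of %s: expected '>' header",
          nonblank[1], path)
  }
  grp <- cumsum(is_hdr)
  hdr_idx <- which(is_hdr)
  headers <- sub("^>", "", lns[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  empty_id <- which(!nzchar(ids))
  if (length(empty_id)) {
    stopf("FASTA format error at line %d of %s: empty record id",
          nonblank[hdr_idx[empty_id[1]]], path)
  }
  seq_parts <- split(lns[!is_hdr], factor(grp[!is_hdr], levels = seq_along(ids)))
  seqs <- toupper(vapply(seq_parts, paste, character(1), collapse = ""))
  empty_seq <- which(!nzchar(seqs))
  if (length(empty_seq)) {
    stopf("FASTA format error at line %d of %s: record '%s' has no sequence",
          nonblank[hdr_idx[empty_seq[1]]], path, ids[empty_seq[1]])
  }
  if (alphabet != "any") check_alphabet(seqs, alphabet, "FASTA record")
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records data frame with columns `id` and `sequence` (optional
#'   `description`), or a named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i])) {
      hdr <- paste(hdr, records$description[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Reads standard 4-line FASTQ records and decodes quality strings into
#' integer vectors.
#'
#' @param path path to a FASTQ file (plain text or gzip).
#' @return data frame with columns `id`, `sequence`, `qual` (raw quality
#'   string) and list column `qualities` (integer Phred scores).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) {
    out <- data.frame(id = character(), sequence = character(),
                      qual = character(), stringsAsFactors = FALSE)
    out$qualities <- list()
    return(out)
  }
  if (length(lines) %% 4L != 0L) {
    stopf("FASTQ format error in %s: %d lines is not a multiple of 4",
          path, length(lines))
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@"))) {
    stopf("FASTQ format error in %s: record header missing '@'", path)
  }
  if (any(!startsWith(plus, "+"))) {
    stopf("FASTQ format error in %s: separator line missing '+'", path)
  }
  ids <- sub("^@", "", ids)
  ids <- sub("\\s.*$", "", ids)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stopf("FASTQ format error in %s: sequence/quality length mismatch for record '%s'",
          path, ids[bad[1]])
  }
  out <- data.frame(id = ids, sequence = seqs, qual = quals,
                    stringsAsFactors = FALSE)
  out$qualities <- lapply(quals, phred_decode)
  out
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual a single quality string.
#' @return `phred_decode()`: integer vector of Phred scores.
#' @export
phred_decode <- function(qual) {
  if (!nzchar(qual)) return(integer())
  utf8ToInt(qual) - 33L
}

#' @rdname phred_decode
#' @param scores integer vector of Phred scores (0-60).
#' @return `phred_encode()`: a quality string.
#' @export
phred_encode <- function(scores) {
  intToUtf8(as.integer(scores) + 33L)
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `id`, `sequence`, `qual`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    txt <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$qual)
    writeLines(as.vector(txt), con)
  }
  invisible(path)
}

## GFF3 ---------------------------------------------------------------------

#' Write genomic loci to GFF3
#'
#' Loci use the package-internal 0-based half-open convention and are
#' written as 1-based inclusive GFF3. Optional columns `id`, `name` and
#' `category` become `ID=`, `Name=` and `category=` attributes;
#' [read_gff3()] restores them so that write/read round-trips are lossless.
#'
#' @param loci data frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) and optionally `id`, `name`, `category`.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @param type value for the GFF3 type column (recycled, or a `type`
#'   column in `loci`).
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(loci, path, source = "equimir", type = "miRNA") {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(loci)))
  if (nrow(loci) && any(loci$start < 0 | loci$start >= loci$end)) {
    stopf("invalid locus coordinates: need 0 <= start < end")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    typ <- if (!is.null(loci$type)) loci$type else rep(type, nrow(loci))
    attrs <- vapply(seq_len(nrow(loci)), function(i) {
      parts <- character()
      if (!is.null(loci$id)) parts <- c(parts, paste0("ID=", loci$id[i]))
      if (!is.null(loci$name)) parts <- c(parts, paste0("Name=", loci$name[i]))
      if (!is.null(loci$category)) {
        parts <- c(parts, paste0("category=", loci$category[i]))
      }
      if (!length(parts)) "." else paste(parts, collapse = ";")
    }, character(1))
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       loci$chrom, source, typ,
                       as.integer(loci$start) + 1L, as.integer(loci$end),
                       loci$strand, attrs), con)
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path path to a GFF3 file.
#' @return data frame with columns `chrom`, `type`, `start`, `end`,
#'   `strand` (0-based half-open) plus any `id`, `name`, `category`
#'   attributes found.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(chrom = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), id = character(),
                      name = character(), category = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    stopf("GFF3 format error in %s: expected 9 tab-separated columns", path)
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    hit <- grepl(paste0("(^|;)", key, "="), attrs)
    val <- sub(paste0("^(.*;)?", key, "=([^;]*).*$"), "\\2", attrs)
    ifelse(hit, val, NA_character_)
  }
  data.frame(chrom = m[, 1], type = m[, 3],
             start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
             strand = m[, 7],
             id = attr_get(m[, 9], "ID"),
             name = attr_get(m[, 9], "Name"),
             category = attr_get(m[, 9], "category"),
             stringsAsFactors = FALSE)
}

## Printed polycistron table ------------------------------------------------

#' Parse a transcribed polycistronic-miRNA cluster table
#'
#' Parses the tab-separated transcription of a printed per-chromosome
#' cluster table: columns are chromosome, comma-separated member miRNA
#' names, and the printed span as `start-end`. Rows whose member list
#' wraps onto a continuation line (empty chromosome field) are merged
#' into the preceding row. Spans are kept on the printed 1-based
#' inclusive scale but normalized to `start <= end`; a printed span with
#' start > end is recorded as strand `"-"` (the printed orientation is
#' the only strand signal the table carries).
#'
#' @param path path to the tab-separated table; a header line starting
#'   with `chrom` is skipped.
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `n_members` and list column `members`.
#' @export
parse_cluster_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^chrom\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(f) <- 3L
    f[is.na(f)] <- ""
    members <- trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    members <- members[nzchar(members)]
    if (!nzchar(trimws(f[1]))) {
      if (!length(rows)) {
        stopf("cluster table error at line %d: continuation with no preceding row", i)
      }
      rows[[length(rows)]]$members <- c(rows[[length(rows)]]$members, members)
      next
    }
    pos <- trimws(f[3])
    ends <- strsplit(pos, "[-–—]")[[1]]
    ends <- trimws(ends[nzchar(trimws(ends))])
    if (length(ends) != 2L || anyNA(suppressWarnings(as.numeric(ends)))) {
      stopf("cluster table error at line %d: non-numeric positions '%s'", i, pos)
    }
    rows[[length(rows) + 1L]] <- list(chrom = trimws(f[1]),
                                      members = members,
                                      a = as.numeric(ends[1]),
                                      b = as.numeric(ends[2]))
  }
  short <- which(vapply(rows, function(r) length(r$members), integer(1)) < 2L)
  if (length(short)) {
    stopf("cluster table error: row %d has fewer than 2 members", short[1])
  }
  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, function(r) min(r$a, r$b), numeric(1)),
    end = vapply(rows, function(r) max(r$a, r$b), numeric(1)),
    strand = vapply(rows, function(r) if (r$a > r$b) "-" else "+", character(1)),
    n_members = vapply(rows, function(r) length(r$members), integer(1)),
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  out
}
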