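#' @keywords internal
"_PACKAGE"

#' @useDynLib equimir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rlnorm rbinom runif setNames aggregate
#' @importFrom utils write.table read.table head combn
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between DNA and RNA alphabets
#'
#' `dna_to_rna()` replaces T with U; `rna_to_dna()` the reverse.
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

## alphabet validation ------------------------------------------------------

check_alphabet <- function(x, kind = c("dna", "rna"), what = "sequence") {
  kind <- match.arg(kind)
  pat <- if (kind == "dna") "^[ACGTN]*$" else "^[ACGUN]*$"
  bad <- which(!grepl(pat, x))
  if (length(bad)) {
    stopf("%s %d contains characters outside the %s alphabet",
          what, bad[1], toupper(kind))
  }
  invisible(x)
}

## tiny TSV helpers used by the pipeline stage writers ----------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
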