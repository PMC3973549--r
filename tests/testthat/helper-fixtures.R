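# Small in-code fixtures and a cache for the expensive end-to-end
# validations, shared across test files.

tmp_file <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a clean RNA hairpin: mature | loop | perfect-complement star
perfect_hairpin <- function(mature, loop) {
  paste0(mature, loop, dna_to_rna(revcomp(rna_to_dna(mature))))
}

.validation_cache <- new.env(parent = emptyenv())

cached_validation <- function(key, config) {
  if (is.null(.validation_cache[[key]])) {
    .validation_cache[[key]] <- suppressMessages(
      simulate_and_validate(config))
  }
  .validation_cache[[key]]
}

noiseless_validation <- function() {
  cached_validation("noiseless", sim_config(seed = 1, noise = FALSE))
}
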