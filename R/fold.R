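## RNA secondary-structure folding.
##
## The baseline engine is a dynamic program over nested structures under a
## nearest-neighbour stacking model (scores below). It exists so that the
## whole pipeline is self-contained and its optimum is checkable against
## exhaustive enumeration; ViennaRNA's RNAfold can be plugged in through
## the same contract when a full thermodynamic model is wanted.

#' Parameters of the baseline folding energy model
#'
#' Stack scores are per pair of adjacent base pairs, in kcal/mol:
#' `stack_gc` for two G:C pairs, `stack_gc_au` for a G:C next to an A:U,
#' `stack_au` for two A:U pairs, and `stack_gu` whenever either pair is a
#' G:U wobble. Every unpaired base enclosed by at least one pair costs
#' `loop_penalty`; hairpin loops must contain at least `min_loop`
#' unpaired bases.
#'
#' @param stack_gc,stack_gc_au,stack_au,stack_gu stack scores (kcal/mol).
#' @param loop_penalty per-nucleotide loop cost (kcal/mol).
#' @param min_loop minimal hairpin loop size (nt).
#' @return a list of class `fold_params`.
#' @export
fold_params <- function(stack_gc = -3.0, stack_gc_au = -2.0, stack_au = -1.0,
                        stack_gu = -0.5, loop_penalty = 0.5, min_loop = 3L) {
  stopifnot(stack_gc <= 0, stack_gc_au <= 0, stack_au <= 0, stack_gu <= 0,
            loop_penalty >= 0, min_loop >= 1)
  structure(list(stack_gc = stack_gc, stack_gc_au = stack_gc_au,
                 stack_au = stack_au, stack_gu = stack_gu,
                 loop_penalty = loop_penalty, min_loop = as.integer(min_loop)),
            class = "fold_params")
}

#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' @param sequence RNA string over A/C/G/U (N allowed, never pairs);
#'   at most 200 nt.
#' @param engine `"baseline"` (the package's stacking-model dynamic
#'   program) or `"rnafold"` (ViennaRNA's RNAfold, which must be on the
#'   PATH; its Turner-model energies replace the baseline scores).
#' @param params a [fold_params()] list (baseline engine only).
#' @return an object of class `fold_result`: list with `sequence`,
#'   `structure` (dot-bracket, same length) and `energy` (kcal/mol,
#'   `<= 0`).
#' @export
fold <- function(sequence, engine = c("baseline", "rnafold"),
                 params = fold_params()) {
  engine <- match.arg(engine)
  sequence <- toupper(sequence)
  check_alphabet(sequence, "rna", "fold input")
  n <- nchar(sequence)
  if (n == 0L) stopf("cannot fold an empty sequence")
  if (n > 200L) stopf("fold input longer than 200 nt (%d)", n)
  if (engine == "baseline") {
    res <- .fold_baseline_cpp(sequence, params$stack_gc, params$stack_gc_au,
                              params$stack_au, params$stack_gu,
                              params$loop_penalty, params$min_loop)
    out <- list(sequence = sequence, structure = res$structure,
                energy = res$energy)
  } else {
    out <- fold_rnafold(sequence)
  }
  class(out) <- "fold_result"
  out
}

fold_rnafold <- function(sequence) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stopf("RNAfold not found on PATH")
  raw <- system2(exe, c("--noPS"), input = sequence, stdout = TRUE)
  line <- raw[length(raw)]
  m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) stopf("could not parse RNAfold output: %s", line)
  list(sequence = sequence, structure = m[2], energy = min(0, as.numeric(m[3])))
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("energy: %.2f kcal/mol\n", x$energy), sep = "")
  invisible(x)
}

#' Base-pair partners of a dot-bracket structure
#'
#' @param structure dot-bracket string (nested, `(`/`)`/`.`).
#' @return integer vector: 1-based partner position of each base, `NA`
#'   where unpaired.
#' @export
structure_pairs <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stopf("unbalanced structure at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (chars[i] != ".") {
      stopf("invalid structure character '%s'", chars[i])
    }
  }
  if (length(stack)) stopf("unbalanced structure: %d unmatched '('", length(stack))
  partner
}

#' Score a dot-bracket structure under the baseline energy model
#'
#' Computes the energy the baseline model assigns to an explicit
#' structure: sum of stack scores over adjacent pairs plus the loop
#' penalty for every unpaired base enclosed by at least one pair.
#' `fold()`'s reported energy equals `score_structure()` of its returned
#' structure.
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string of the same length.
#' @param params a [fold_params()] list.
#' @return energy in kcal/mol.
#' @export
score_structure <- function(sequence, structure, params = fold_params()) {
  n <- nchar(sequence)
  stopifnot(nchar(structure) == n)
  partner <- structure_pairs(structure)
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  pair_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  e <- 0
  for (i in seq_len(n)) {
    j <- partner[i]
    if (!is.na(j) && j > i) {
      if (!pair_ok(bases[i], bases[j])) {
        stopf("structure pairs non-complementary bases at %d-%d", i, j)
      }
      if (j - i - 1 < params$min_loop) stopf("hairpin loop shorter than %d",
                                             params$min_loop)
      # stack with the directly nested pair, if present
      if (i + 1 <= n && !is.na(partner[i + 1]) && partner[i + 1] == j - 1) {
        gu1 <- paste0(bases[i], bases[j]) %in% c("GU", "UG")
        gu2 <- paste0(bases[i + 1], bases[j - 1]) %in% c("GU", "UG")
        gc1 <- paste0(bases[i], bases[j]) %in% c("GC", "CG")
        gc2 <- paste0(bases[i + 1], bases[j - 1]) %in% c("GC", "CG")
        e <- e + if (gu1 || gu2) params$stack_gu
                 else if (gc1 && gc2) params$stack_gc
                 else if (gc1 || gc2) params$stack_gc_au
                 else params$stack_au
      }
    }
  }
  # enclosed unpaired bases: inside the outermost pair spans
  enclosed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- partner[i]
    if (!is.na(j) && j > i && j - i > 1) {
      enclosed[(i + 1):(j - 1)] <- TRUE
    }
  }
  e + params$loop_penalty * sum(enclosed & is.na(partner))
}
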