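# Independent oracles the implementation is checked against. These stay
# deliberately naive: full enumeration for folding, O(n^2) transitive
# closure for clustering, character-level scanning for exact matching.

oracle_pair_ok <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# every nested structure over b[i..j] as a list of pair index vectors
oracle_enum_structures <- function(b, i, j, minloop = 3) {
  if (i > j) return(list(list()))
  out <- oracle_enum_structures(b, i + 1, j, minloop)
  ks <- if (i + minloop + 1 <= j) seq(i + minloop + 1, j) else integer(0)
  for (k in ks) {
    if (oracle_pair_ok(b[i], b[k])) {
      inner <- oracle_enum_structures(b, i + 1, k - 1, minloop)
      outer <- oracle_enum_structures(b, k + 1, j, minloop)
      for (ip in inner) for (op in outer) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), ip, op)
      }
    }
  }
  out
}

# direct scoring of an explicit pair set under the baseline model
oracle_score <- function(b, prs, p = list(gc = -3, gcau = -2, au = -1,
                                          gu = -0.5, loop = 0.5)) {
  n <- length(b)
  partner <- rep(NA_integer_, n)
  for (pr in prs) {
    partner[pr[1]] <- pr[2]
    partner[pr[2]] <- pr[1]
  }
  e <- 0
  enclosed <- rep(FALSE, n)
  for (pr in prs) {
    i <- pr[1]; j <- pr[2]
    if (j - i > 1) enclosed[(i + 1):(j - 1)] <- TRUE
    if (!is.na(partner[i + 1]) && partner[i + 1] == j - 1) {
      p1 <- paste0(b[i], b[j]); p2 <- paste0(b[i + 1], b[j - 1])
      gu <- p1 %in% c("GU", "UG") || p2 %in% c("GU", "UG")
      gc1 <- p1 %in% c("GC", "CG"); gc2 <- p2 %in% c("GC", "CG")
      e <- e + if (gu) p$gu else if (gc1 && gc2) p$gc else
        if (gc1 || gc2) p$gcau else p$au
    }
  }
  e + p$loop * sum(enclosed & is.na(partner))
}

# exhaustive minimum energy: enumerate every structure and score it
oracle_min_energy <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  structures <- oracle_enum_structures(b, 1L, length(b))
  min(vapply(structures, function(st) oracle_score(b, st), numeric(1)))
}

# O(n^2) transitive closure of the pairwise within-threshold relation
oracle_cluster <- function(loci, threshold = 3000) {
  n <- nrow(loci)
  comp <- seq_len(n)
  near <- function(i, j) {
    loci$chrom[i] == loci$chrom[j] &&
      max(loci$start[i], loci$start[j]) -
        min(loci$end[i], loci$end[j]) <= threshold
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && near(i, j) && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # canonical partition: sets of locus names, clusters = components >= 2
  parts <- split(loci$name, comp)
  sizes <- lengths(parts)
  list(clusters = unname(lapply(parts[sizes >= 2], sort)),
       singletons = sort(unlist(parts[sizes == 1], use.names = FALSE)))
}

# naive exact both-strand scan of a genome for a query
oracle_scan <- function(genome, query) {
  out <- list()
  qlen <- nchar(query)
  rc <- equimir::revcomp(query)
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    for (st in seq_len(nchar(s) - qlen + 1L)) {
      sub <- substr(s, st, st + qlen - 1L)
      if (sub == query) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = st - 1L, end = st - 1L + qlen,
          strand = "+", stringsAsFactors = FALSE)
      }
      if (sub == rc) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = st - 1L, end = st - 1L + qlen,
          strand = "-", stringsAsFactors = FALSE)
      }
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
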