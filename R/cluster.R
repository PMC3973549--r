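## Chromosomal distribution and 3-kb polycistron clustering of miRNA loci.

#' Per-chromosome miRNA counts
#'
#' @param loci data frame with columns `name`, `chrom`, `start`, `end`.
#' @param chromosomes optional character vector of all chromosomes in the
#'   genome; chromosomes without loci are reported with an explicit zero.
#' @return data frame `chrom`, `count`.
#' @export
chromosome_distribution <- function(loci, chromosomes = NULL) {
  chroms <- unique(c(chromosomes, loci$chrom))
  data.frame(chrom = chroms,
             count = vapply(chroms, function(c) sum(loci$chrom == c),
                            integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chain miRNA loci within a distance threshold into clusters
#'
#' Single-linkage chaining per chromosome: loci are sorted by start and
#' consecutive loci whose edge-to-edge gap is at most `threshold` join
#' the same chain; maximal chains of two or more loci become clusters.
#' Chaining is transitive (A near B and B near C puts A and C in one
#' cluster even if A and C are far apart) and strand-agnostic.
#'
#' @param loci data frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `source`.
#' @param threshold maximal edge-to-edge gap (nt) joining two loci;
#'   default 3 kb.
#' @return list with `clusters` (data frame: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_members`, list column `members` ordered by
#'   start) and `singletons` (the unclustered loci).
#' @export
cluster_loci <- function(loci, threshold = 3000L) {
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (!nrow(loci)) return(list(clusters = empty, singletons = loci))
  ord <- order(loci$chrom, loci$start, loci$end, loci$name)
  l <- loci[ord, , drop = FALSE]
  chain <- integer(nrow(l))
  cid <- 0L
  cur_chrom <- ""
  cur_end <- -Inf
  for (i in seq_len(nrow(l))) {
    if (l$chrom[i] != cur_chrom || l$start[i] - cur_end > threshold) {
      cid <- cid + 1L
      cur_chrom <- l$chrom[i]
      cur_end <- l$end[i]
    } else {
      cur_end <- max(cur_end, l$end[i])
    }
    chain[i] <- cid
  }
  sizes <- table(chain)
  keep <- as.integer(names(sizes)[sizes >= 2L])
  # chain ids are assigned along the (chrom, start) sort, so `keep` is
  # already in deterministic genomic order
  if (length(keep)) {
    rows <- lapply(keep, function(g) {
      sub <- l[chain == g, , drop = FALSE]
      data.frame(chrom = sub$chrom[1], start = min(sub$start),
                 end = max(sub$end), n_members = nrow(sub),
                 stringsAsFactors = FALSE)
    })
    clusters <- do.call(rbind, rows)
    clusters$members <- lapply(keep, function(g) l$name[chain == g])
    clusters <- cbind(cluster_id = sprintf("cluster_%03d",
                                           seq_len(nrow(clusters))),
                      clusters, stringsAsFactors = FALSE)
    rownames(clusters) <- NULL
  } else {
    clusters <- empty
  }
  singletons <- l[chain %in% as.integer(names(sizes)[sizes == 1L]), ,
                  drop = FALSE]
  rownames(singletons) <- NULL
  list(clusters = clusters, singletons = singletons)
}

#' Summarize a clustering of miRNA loci
#'
#' @param clustering result of [cluster_loci()].
#' @param known_total total number of miRNA loci the percentage is taken
#'   of (must be positive).
#' @return list of class `cluster_summary`: `n_clusters`, `n_clustered`,
#'   `pct_clustered` (rounded to the nearest integer percent) and
#'   `per_chrom` (clusters per chromosome).
#' @export
cluster_summary <- function(clustering, known_total) {
  if (known_total <= 0) stopf("known_total must be positive")
  cl <- clustering$clusters
  n_clustered <- sum(cl$n_members)
  per_chrom <- if (nrow(cl)) {
    stats::aggregate(list(clusters = cl$cluster_id), by = list(chrom = cl$chrom),
                     FUN = length)
  } else data.frame(chrom = character(), clusters = integer())
  structure(list(n_clusters = nrow(cl),
                 n_clustered = as.integer(n_clustered),
                 pct_clustered = round(100 * n_clustered / known_total),
                 known_total = as.integer(known_total),
                 per_chrom = per_chrom),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("%d clusters containing %d of %d miRNAs (%d%%)\n",
              x$n_clusters, x$n_clustered, x$known_total, x$pct_clustered))
  invisible(x)
}
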