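## End-to-end orchestration: clean -> collapse -> map -> annotate ->
## predict -> cluster -> compose, with staged outputs and a
## machine-readable report.

#' Pipeline configuration
#'
#' @param genome path to the genome FASTA.
#' @param reads named character vector: tissue -> FASTQ path.
#' @param reference_mature,reference_hairpin paths to the known-miRNA
#'   catalog FASTAs (miRBase-style mature and hairpin sets); optional.
#' @param catalog_fastas named list: category -> FASTA path of decoy
#'   reference transcripts (rRNA, tRNA, ...).
#' @param features_gff3 optional GFF3 of decoy genomic features (with
#'   `category=` attributes).
#' @param out_dir output directory for staged results.
#' @param adapter_3p,adapter_5p sequencing adapters.
#' @param cleaning a [cleaning_config()].
#' @param criteria a [criteria_config()].
#' @param fold_engine folding engine for [fold()].
#' @param cluster_threshold polycistron chaining distance (nt).
#' @param presence_threshold minimal count for tissue presence.
#' @param seed integer seed (the pipeline itself is deterministic; the
#'   seed is recorded and set for reproducibility of any downstream
#'   sampling).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, reads, reference_mature = NULL,
                            reference_hairpin = NULL, catalog_fastas = list(),
                            features_gff3 = NULL, out_dir = "equimir_out",
                            adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                            adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                            cleaning = cleaning_config(),
                            criteria = criteria_config(),
                            fold_engine = "baseline",
                            cluster_threshold = 3000L,
                            presence_threshold = 1L, seed = 1L) {
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    stopf("`reads` must be a named vector (tissue -> FASTQ path)")
  }
  structure(list(genome = genome, reads = reads,
                 reference_mature = reference_mature,
                 reference_hairpin = reference_hairpin,
                 catalog_fastas = catalog_fastas,
                 features_gff3 = features_gff3, out_dir = out_dir,
                 adapter_3p = adapter_3p, adapter_5p = adapter_5p,
                 cleaning = cleaning, criteria = criteria,
                 fold_engine = fold_engine,
                 cluster_threshold = as.integer(cluster_threshold),
                 presence_threshold = as.integer(presence_threshold),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `reads` and `catalog_fastas` mappings become named vectors/lists, and
#' `cleaning`/`criteria` mappings override the corresponding config
#' defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$reads)) args$reads <- unlist(y$reads)
  if (!is.null(y$cleaning)) args$cleaning <- do.call(cleaning_config, y$cleaning)
  if (!is.null(y$criteria)) args$criteria <- do.call(criteria_config, y$criteria)
  do.call(pipeline_config, args)
}

preflight <- function(config) {
  paths <- c(genome = config$genome, config$reads,
             unlist(config$catalog_fastas),
             reference_mature = config$reference_mature,
             reference_hairpin = config$reference_hairpin,
             features_gff3 = config$features_gff3)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full discovery pipeline
#'
#' Executes the stages in fixed order, writing each stage's tables under
#' `01_clean/` ... `06_compose/` in the output directory, and returns a
#' run report whose counts are mutually consistent (novel calls <=
#' candidate loci <= unannotated mapped tags). Reruns on identical
#' inputs produce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `equimir_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  preflight(config)
  set.seed(config$seed)
  out <- config$out_dir
  stage_dirs <- file.path(out, c("01_clean", "02_annotate", "03_map",
                                 "04_predict", "05_cluster", "06_compose"))
  for (d in stage_dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[equimir] ", fmt), ...))
  }

  ## 01 clean
  log_stage("clean: %d tissue libraries", length(config$reads))
  inserts <- list()
  reports <- list()
  for (tissue in names(config$reads)) {
    reads <- read_fastq(config$reads[[tissue]])
    cl <- clean_reads(reads, config$adapter_3p, config$adapter_5p,
                      config$cleaning)
    inserts[[tissue]] <- cl$inserts
    reports[[tissue]] <- cbind(tissue = tissue, cl$report)
  }
  clean_report <- do.call(rbind, reports)
  rownames(clean_report) <- NULL
  tags <- collapse_to_tags(inserts)
  write_tsv(clean_report, file.path(stage_dirs[1], "cleaning_report.tsv"))
  write_tag_fasta(tags, file.path(stage_dirs[1], "tags.fa"))
  write_tsv(tags[, setdiff(names(tags), character())],
            file.path(stage_dirs[1], "tags.tsv"))
  write_tsv(tag_length_distribution(tags),
            file.path(stage_dirs[1], "length_distribution.tsv"))

  ## 03 map (mapping precedes annotation so feature overlap can be used)
  log_stage("map: %d unique tags against the genome", nrow(tags))
  genome_df <- read_fasta(config$genome, alphabet = "dna")
  genome <- setNames(genome_df$sequence, genome_df$id)
  index <- build_exact_index(genome)
  hits <- map_tags(tags, index)
  write_tsv(hits, file.path(stage_dirs[3], "hits.tsv"))

  ## 02 annotate
  log_stage("annotate: building catalog")
  read_ref <- function(path) if (is.null(path)) NULL else read_fasta(path)
  seq_cats <- lapply(config$catalog_fastas, read_fasta)
  features <- if (!is.null(config$features_gff3)) {
    read_gff3(config$features_gff3)
  } else NULL
  catalog <- reference_catalog(mature = read_ref(config$reference_mature),
                               hairpin = read_ref(config$reference_hairpin),
                               sequences = seq_cats, features = features)
  annotation <- annotate_tags(tags, catalog, hits = hits)
  ann_summary <- annotation_summary(annotation, tags)
  write_tsv(annotation, file.path(stage_dirs[2], "annotation.tsv"))
  write_tsv(ann_summary, file.path(stage_dirs[2], "category_summary.tsv"))

  ## 04 predict
  unann_ids <- annotation$tag_id[annotation$category == "unannotated"]
  unann_hits <- hits[hits$tag_id %in% unann_ids, , drop = FALSE]
  log_stage("predict: %d unannotated mapped tags", length(unique(unann_hits$tag_id)))
  novel <- call_novel_mirnas(unann_hits, genome, config$criteria,
                             engine = config$fold_engine, stack_hits = hits)
  calls <- novel$calls
  write_tsv(novel$candidates, file.path(stage_dirs[4], "candidates.tsv"))
  if (nrow(calls)) {
    write_gff3(calls[, c("chrom", "start", "end", "strand", "id")],
               file.path(stage_dirs[4], "novel_mirnas.gff3"),
               type = "miRNA")
    write_fasta(data.frame(id = calls$id, description = "",
                           sequence = calls$precursor,
                           stringsAsFactors = FALSE),
                file.path(stage_dirs[4], "novel_precursors.fa"))
    writeLines(unlist(lapply(seq_len(nrow(calls)), function(i) {
      c(paste0(">", calls$id[i]), calls$precursor[i], calls$structure[i])
    })), file.path(stage_dirs[4], "novel_precursors.dotbracket"))
  } else {
    write_gff3(calls[, c("chrom", "start", "end", "strand")],
               file.path(stage_dirs[4], "novel_mirnas.gff3"))
  }

  ## 05 cluster: known loci (mapped reference matures) plus novel calls
  known_loci <- known_mirna_loci(catalog, index)
  novel_loci <- if (nrow(calls)) {
    data.frame(name = calls$id, chrom = calls$chrom, start = calls$start,
               end = calls$end, strand = calls$strand, source = "novel",
               stringsAsFactors = FALSE)
  } else NULL
  all_loci <- rbind(known_loci, novel_loci)
  if (is.null(all_loci)) {
    all_loci <- data.frame(name = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), source = character(),
                           stringsAsFactors = FALSE)
  }
  log_stage("cluster: %d miRNA loci at %d nt", NROW(all_loci),
            config$cluster_threshold)
  clustering <- cluster_loci(all_loci, config$cluster_threshold)
  summ <- cluster_summary(clustering, max(1L, NROW(all_loci)))
  cl_out <- clustering$clusters
  if (nrow(cl_out)) {
    cl_out$members <- vapply(cl_out$members, paste, character(1),
                             collapse = ",")
  }
  write_tsv(cl_out, file.path(stage_dirs[5], "clusters.tsv"))
  write_tsv(chromosome_distribution(all_loci, names(genome)),
            file.path(stage_dirs[5], "chromosome_distribution.tsv"))
  write_tsv(data.frame(n_clusters = summ$n_clusters,
                       n_clustered = summ$n_clustered,
                       total_loci = summ$known_total,
                       pct_clustered = summ$pct_clustered),
            file.path(stage_dirs[5], "cluster_summary.tsv"))

  ## 06 compose: composition over identified miRNAs (known tags + novel
  ## matures), tissue-presence Venn over the same set
  known_tag_ids <- annotation$tag_id[annotation$category == "known_mirna"]
  known_tags <- tags[tags$tag_id %in% known_tag_ids, , drop = FALSE]
  mirna_seqs <- unique(c(dna_to_rna(known_tags$sequence),
                         if (nrow(calls)) calls$mature))
  log_stage("compose: %d identified miRNA sequences", length(mirna_seqs))
  if (length(mirna_seqs)) {
    fnb <- first_nucleotide_bias(mirna_seqs)
    pc <- positional_composition(mirna_seqs)
    write_tsv(fnb, file.path(stage_dirs[6], "first_nt_profile.tsv"))
    write_tsv(pc, file.path(stage_dirs[6], "positional_composition.tsv"))
    write_tsv(attr(pc, "seed"), file.path(stage_dirs[6], "seed_region.tsv"))
  }
  venn_counts <- mirna_tissue_counts(tags, annotation, calls, hits,
                                     names(config$reads))
  venn <- tissue_presence_venn(venn_counts, names(config$reads),
                               config$presence_threshold)
  write_tsv(data.frame(region = names(venn$regions),
                       count = as.integer(venn$regions)),
            file.path(stage_dirs[6], "venn_regions.tsv"))

  report <- structure(list(
    tissues = names(config$reads),
    raw_reads = sum(clean_report$raw),
    clean_reads = sum(clean_report$clean),
    unique_tags = nrow(tags),
    mapped_tags = length(unique(hits$tag_id)),
    annotated = setNames(ann_summary$unique_tags, ann_summary$category),
    known_mirna_tags = sum(annotation$category == "known_mirna"),
    unannotated_mapped = length(unique(unann_hits$tag_id)),
    candidate_tags = length(unique(novel$candidates$tag_id)),
    candidate_loci = nrow(locus_verdicts(novel)),
    novel_calls = nrow(calls),
    known_loci = NROW(known_loci),
    n_clusters = summ$n_clusters,
    n_clustered = summ$n_clustered,
    pct_clustered = summ$pct_clustered,
    venn = venn$regions,
    seed = config$seed,
    out_dir = out), class = "equimir_report")
  json <- jsonlite::toJSON(report[setdiff(names(report), character())],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(out, "report.json"))
  report
}

# genomic loci of cataloged mature miRNAs, named by reference id
known_mirna_loci <- function(catalog, index) {
  if (is.null(catalog$mature) || !nrow(catalog$mature)) return(NULL)
  out <- list()
  for (i in seq_len(nrow(catalog$mature))) {
    h <- index_lookup(index, catalog$mature$sequence[i])
    if (!nrow(h)) next
    h$name <- catalog$mature$id[i]
    h$source <- "known"
    out[[length(out) + 1L]] <- h
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[, c("name", "chrom", "start", "end", "strand", "source")]
}

# per-miRNA per-tissue counts: known miRNAs aggregate their tags by
# reference id; novel calls aggregate tags overlapping the precursor
mirna_tissue_counts <- function(tags, annotation, calls, hits, tissues) {
  rows <- list()
  known <- annotation[annotation$category == "known_mirna", , drop = FALSE]
  if (nrow(known)) {
    for (rid in unique(known$ref_id)) {
      ids <- known$tag_id[known$ref_id == rid]
      sub <- tags[tags$tag_id %in% ids, tissues, drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(name = rid, t(colSums(sub)), stringsAsFactors = FALSE)
    }
  }
  if (NROW(calls)) {
    for (i in seq_len(nrow(calls))) {
      h <- hits[hits$chrom == calls$chrom[i] & hits$strand == calls$strand[i] &
                hits$start < calls$end[i] & hits$end > calls$start[i], ,
                drop = FALSE]
      sub <- tags[tags$tag_id %in% unique(h$tag_id), tissues, drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(name = calls$id[i], t(colSums(sub)),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(name = character(), stringsAsFactors = FALSE)
    for (t in tissues) out[[t]] <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("name", tissues)
  out
}

#' @export
print.equimir_report <- function(x, ...) {
  cat("equimir pipeline report\n")
  cat(sprintf("  tissues:            %s\n", paste(x$tissues, collapse = ", ")))
  cat(sprintf("  raw / clean reads:  %d / %d\n", x$raw_reads, x$clean_reads))
  cat(sprintf("  unique tags:        %d (%d mapped)\n", x$unique_tags,
              x$mapped_tags))
  cat(sprintf("  known miRNA tags:   %d\n", x$known_mirna_tags))
  cat(sprintf("  novel miRNA calls:  %d (of %d candidate loci)\n",
              x$novel_calls, x$candidate_loci))
  cat(sprintf("  clusters:           %d (%d loci, %d%%)\n", x$n_clusters,
              x$n_clustered, x$pct_clustered))
  invisible(x)
}

#' One-command self-test on synthetic data
#'
#' Generates a synthetic dataset, runs the full pipeline on it, and
#' compares the results with the planted ground truth: recall and
#' precision of novel-miRNA calls against the criterion-passing planted
#' loci (matched by genomic overlap), recovery of planted known miRNAs
#' through annotation, and, for every planted decoy locus, whether the
#' best candidate verdict failed exactly the designed criterion.
#'
#' @param config a [sim_config()].
#' @param dir working directory for the simulated inputs and pipeline
#'   outputs (default: a session temporary directory).
#' @return object of class `equimir_validation`: list with `precision`,
#'   `recall`, `known_recall`, `decoy_confusion` (data frame), `report`
#'   (the pipeline report) and `truth`.
#' @export
simulate_and_validate <- function(config = sim_config(),
                                  dir = tempfile("equimir_sim_")) {
  sim <- generate_toy_genome(config)
  reads <- simulate_reads(sim)
  paths <- write_simulation(sim, reads, file.path(dir, "input"))
  feat_cats <- unique(sim$truth$features$category)
  catalog_fastas <- list()
  for (cat in feat_cats) {
    sub <- sim$truth$features[sim$truth$features$category == cat, ,
                              drop = FALSE]
    p <- file.path(dir, "input", paste0("catalog_", cat, ".fa"))
    write_fasta(sub[, c("id", "sequence")], p)
    catalog_fastas[[cat]] <- p
  }
  pcfg <- pipeline_config(
    genome = paths$genome, reads = paths$reads,
    reference_mature = paths$reference_mature,
    reference_hairpin = paths$reference_hairpin,
    catalog_fastas = catalog_fastas, features_gff3 = paths$features_gff3,
    out_dir = file.path(dir, "out"),
    adapter_3p = config$adapter_3p, adapter_5p = config$adapter_5p,
    seed = config$seed)
  report <- run_pipeline(pcfg)

  truth <- sim$truth
  calls <- read_calls_gff(file.path(dir, "out", "04_predict",
                                    "novel_mirnas.gff3"))
  cands <- read_tsv(file.path(dir, "out", "04_predict", "candidates.tsv"))

  passing <- truth$loci[truth$loci$category == "novel", , drop = FALSE]
  matched_truth <- logical(nrow(passing))
  matched_call <- logical(nrow(calls))
  for (i in seq_len(nrow(passing))) {
    ov <- which(calls$chrom == passing$chrom[i] &
                calls$start < passing$prec_end[i] &
                calls$end > passing$prec_start[i])
    if (length(ov)) {
      matched_truth[i] <- TRUE
      matched_call[ov] <- TRUE
    }
  }
  recall <- if (nrow(passing)) mean(matched_truth) else NA_real_
  precision <- if (nrow(calls)) mean(matched_call) else
    if (!nrow(passing)) NA_real_ else 1
  # known recovery through annotation + expression
  ann <- read_tsv(file.path(dir, "out", "02_annotate", "annotation.tsv"))
  known <- truth$loci[truth$loci$category == "known", , drop = FALSE]
  known_found <- vapply(known$mature, function(m) {
    any(ann$sequence == m & ann$category == "known_mirna")
  }, logical(1))
  known_recall <- if (nrow(known)) mean(known_found) else NA_real_
  # decoy confusion
  decoys <- truth$loci[startsWith(truth$loci$category, "decoy"), ,
                       drop = FALSE]
  confusion <- lapply(seq_len(nrow(decoys)), function(i) {
    ov <- cands[cands$chrom == decoys$chrom[i] &
                cands$start < decoys$prec_end[i] &
                cands$end > decoys$prec_start[i], , drop = FALSE]
    fails <- if (nrow(ov)) {
      ov$fails[order(-ov$read_support, ov$n_fail, ov$energy)][1]
    } else NA_character_
    if (is.na(fails)) fails <- NA_character_
    data.frame(name = decoys$name[i],
               designed = decoys$designed_fail[i],
               observed_fails = as.character(fails),
               exact = identical(as.character(fails),
                                 as.character(decoys$designed_fail[i])),
               stringsAsFactors = FALSE)
  })
  confusion <- if (length(confusion)) do.call(rbind, confusion) else
    data.frame(name = character(), designed = integer(),
               observed_fails = character(), exact = logical(),
               stringsAsFactors = FALSE)
  structure(list(precision = precision, recall = recall,
                 known_recall = known_recall, decoy_confusion = confusion,
                 report = report, truth = truth, dir = dir),
            class = "equimir_validation")
}

read_calls_gff <- function(path) {
  read_gff3(path)
}

#' @export
print.equimir_validation <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.3f", v)
  cat("synthetic-data validation\n")
  cat(sprintf("  novel-call precision: %s\n", fmt(x$precision)))
  cat(sprintf("  novel-call recall:    %s\n", fmt(x$recall)))
  cat(sprintf("  known-miRNA recall:   %s\n", fmt(x$known_recall)))
  if (nrow(x$decoy_confusion)) {
    cat(sprintf("  decoys failing exactly as designed: %d / %d\n",
                sum(x$decoy_confusion$exact), nrow(x$decoy_confusion)))
  }
  invisible(x)
}
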