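## Orchestration: one entry point chaining simulate -> deconvolve ->
## annotate -> call -> differential -> summarize over on-disk intermediates,
## with a structured config, per-stage seeds derived from one root seed, and
## a JSON manifest with provenance.

PIPELINE_STAGES <- c("simulate", "deconvolve", "annotate", "call",
                     "differential", "summarize")

#' Build a pipeline run configuration
#'
#' Returns the default configuration, optionally overridden by a YAML file
#' and/or a named list (`overrides` wins over the file, the file over the
#' defaults). The configuration is a plain nested list and serialises
#' losslessly to YAML.
#'
#' @param file optional YAML config path.
#' @param overrides optional named list of overrides (nested lists merge by
#'   name).
#' @return a `radip_config` list.
#' @export
radip_config <- function(file = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    outdir = "radip_run",
    replicates = 2L,
    genome = list(n_chroms = 3L, lengths = c(2e6, 1.5e6, 1e6)),
    # biotype fractions kept as a named list so YAML round-trips losslessly
    annotation = list(n_genes = 120L,
                      biotype_fractions = list(protein_coding = 0.70,
                                               lncRNA = 0.25, other = 0.05)),
    peaks = list(n_peaks = 40L, width = 2000L),
    interactions = list(n_pairs = 8000L, mu0 = 2, r0 = 10,
                        decay_scale = 5e4, trans_fraction = 0.7,
                        enrichment_fold = 4, eps_trans = 0.05,
                        exonic_fraction = 0.15),
    reads = list(tag_len_min = 25L, tag_len_max = 27L, error_rate = 0),
    adaptor = list(sequence = DEFAULT_ADAPTOR, max_mismatches = 0L,
                   rna_side = "five_prime", min_tag_len = 25L,
                   max_tag_len = 27L),
    bins = list(width = 25000L),
    mapq = list(required = 37L, mode = "exact"),
    call = list(q_max = 0.1, min_bins = 10L),
    differential = list(adjp_max = 0.1, lfc_min = 0.5,
                        counts = "significant"),
    summarize = list(flank = 3000L, step = 50L,
                     depth_fractions = c(0.1, 0.25, 0.5, 0.75, 1),
                     n_seeds = 3L))
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  class(cfg) <- "radip_config"
  cfg
}

#' @noRd
merge_config <- function(base, over) {
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
      merge_config(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

#' Write a configuration to YAML
#' @param config a `radip_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of the semantically meaningful configuration fields
#'
#' Output location is excluded: two runs differing only in `outdir` are the
#' same experiment.
#'
#' @param config a `radip_config`.
#' @return an md5 string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' @noRd
rep_dirs <- function(outdir, config) {
  conds <- c("input", "ip")
  reps <- seq_len(config$replicates)
  dt <- CJ(condition = conds, rep = reps)
  dt[, dir := file.path(outdir, paste0(condition, "_rep", rep))]
  dt
}

#' @noRd
need_file <- function(path, stage) {
  assert_that(file.exists(path),
              sprintf("stage '%s' requires missing input: %s", stage, path))
  path
}

#' Run the pipeline
#'
#' Executes the requested stages in order over on-disk intermediates in
#' `config$outdir`. Every stage seed is derived deterministically from the
#' root seed, so re-running with an identical config and seed reproduces
#' identical outputs. A manifest (JSON) listing every produced file with its
#' row count, plus a provenance block (package version, timestamp, config
#' hash), is written at the end of each invocation.
#'
#' @param config a `radip_config`.
#' @param stages ordered subset of
#'   `c("simulate","deconvolve","annotate","call","differential","summarize")`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = radip_config(), stages = PIPELINE_STAGES) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  assert_that(length(unknown) == 0,
              paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rd <- rep_dirs(out, config)
  produced <- character(0)
  note <- function(...) produced <<- c(produced, ...)

  if ("simulate" %in% stages) {
    g <- sim_genome(config$genome$n_chroms, config$genome$lengths,
                    seed = stage_seed(config$seed, "genome"))
    ann <- sim_annotation(g, config$annotation$n_genes,
                          unlist(config$annotation$biotype_fractions),
                          seed = stage_seed(config$seed, "annotation"))
    pk <- sim_peaks(g, config$peaks$n_peaks, config$peaks$width,
                    seed = stage_seed(config$seed, "peaks"))
    write_genome(g, file.path(out, "genome.fa"), file.path(out, "chrom.sizes"))
    write_annotation_gtf(ann, file.path(out, "genes.gtf"))
    write_bed(pk, file.path(out, "peaks.bed"))
    note(file.path(out, c("genome.fa", "chrom.sizes", "genes.gtf", "peaks.bed")))
    bins <- genome_bins(g$chrom_sizes, config$bins$width)
    adp <- do.call(bridge_adaptor, config$adaptor)
    for (i in seq_len(nrow(rd))) {
      cond <- rd$condition[i]
      sseed <- stage_seed(config$seed, paste0("sim_", cond, rd$rep[i]))
      tr <- sim_interactions(
        ann, bins, n_pairs = config$interactions$n_pairs,
        mu0 = config$interactions$mu0, r0 = config$interactions$r0,
        decay_scale = config$interactions$decay_scale,
        trans_fraction = config$interactions$trans_fraction,
        peaks = pk, enrichment_fold = config$interactions$enrichment_fold,
        condition = cond, eps_trans = config$interactions$eps_trans,
        exonic_fraction = config$interactions$exonic_fraction, seed = sseed)
      sr <- sim_reads(tr, g, adp,
                      tag_len_range = c(config$reads$tag_len_min,
                                        config$reads$tag_len_max),
                      error_rate = config$reads$error_rate,
                      seed = stage_seed(config$seed,
                                        paste0("reads_", cond, rd$rep[i])))
      paths <- write_sim_reads(sr, g, rd$dir[i])
      fwrite(tr$pairs, file.path(rd$dir[i], "truth_interactions.tsv"),
             sep = "\t")
      note(paths, file.path(rd$dir[i], "truth_interactions.tsv"))
    }
  }

  if ("deconvolve" %in% stages) {
    adp <- do.call(bridge_adaptor, config$adaptor)
    for (i in seq_len(nrow(rd))) {
      fq <- need_file(file.path(rd$dir[i], "reads.fastq"), "deconvolve")
      tp <- deconvolve(fq, adp)
      write_tag_fastq(tp, file.path(rd$dir[i], "rna_tags.fastq"),
                      file.path(rd$dir[i], "dna_tags.fastq"))
      qc <- qc_report(tp)
      jsonlite::write_json(
        list(n_pairs = qc$n_pairs, adaptor_found_rate = qc$adaptor_found_rate,
             length_pass_rate = qc$length_pass_rate),
        file.path(rd$dir[i], "qc.json"), auto_unbox = TRUE, digits = NA)
      note(file.path(rd$dir[i], c("rna_tags.fastq", "dna_tags.fastq",
                                  "qc.json")))
    }
  }

  if ("annotate" %in% stages) {
    ann <- read_annotation_gtf(need_file(file.path(out, "genes.gtf"),
                                         "annotate"))
    bins <- genome_bins(need_file(file.path(out, "chrom.sizes"), "annotate"),
                        config$bins$width)
    for (i in seq_len(nrow(rd))) {
      rec <- annotate_interactions(
        need_file(file.path(rd$dir[i], "rna_truth.sam"), "annotate"),
        need_file(file.path(rd$dir[i], "dna_truth.sam"), "annotate"),
        ann, bins, blacklist = NULL,
        required_mapq = config$mapq$required, mapq_mode = config$mapq$mode)
      write_pairs(rec, file.path(rd$dir[i], "pairs.tsv"))
      note(file.path(rd$dir[i], "pairs.tsv"))
    }
  }

  if ("call" %in% stages) {
    for (i in seq_len(nrow(rd))) {
      rec <- read_pairs(need_file(file.path(rd$dir[i], "pairs.tsv"), "call"))
      counts <- build_pairs(rec)$counts
      sig <- call_significant(counts, q_max = config$call$q_max,
                              min_bins = config$call$min_bins)
      fwrite(sig, file.path(rd$dir[i], "significance.tsv"), sep = "\t")
      keep <- sig[significant == TRUE, .(gene_id, bin_id)]
      filt <- rec[paste(gene_id, bin_id) %in% keep[, paste(gene_id, bin_id)]]
      write_pairs(filt, file.path(rd$dir[i], "pairs_significant.tsv"))
      note(file.path(rd$dir[i], c("significance.tsv", "pairs_significant.tsv")))
    }
  }

  if ("differential" %in% stages) {
    # counted on background-filtered pairs by default; falls back to raw
    # pairs when a replicate retains no significant interaction at toy depth
    src <- if (identical(config$differential$counts, "raw"))
      "pairs.tsv" else "pairs_significant.tsv"
    load_tabs <- function(fn) {
      tabs <- lapply(seq_len(nrow(rd)), function(i)
        read_pairs(need_file(file.path(rd$dir[i], fn), "differential")))
      names(tabs) <- basename(rd$dir)
      tabs
    }
    tabs <- load_tabs(src)
    m <- rna_count_matrix(tabs)
    if (src == "pairs_significant.tsv" && any(colSums(m) == 0)) {
      warning("empty background-filtered replicate(s); using raw pair counts")
      tabs <- load_tabs("pairs.tsv")
      m <- rna_count_matrix(tabs)
    }
    diff <- differential_interactions(m, rd$condition,
                                      adjp_max = config$differential$adjp_max,
                                      lfc_min = config$differential$lfc_min)
    fwrite(diff, file.path(out, "differential.tsv"), sep = "\t")
    captured <- lapply(split(seq_len(nrow(rd)), rd$condition), function(ii)
      unique(unlist(lapply(tabs[ii], function(tb)
        unique(tb[!is.na(gene_id), gene_id])))))
    sp <- build_special_sets(captured$input, captured$ip, diff)
    membership <- rbindlist(lapply(c("input", "ip"), function(cc)
      data.table(condition = cc,
                 gene_id = sp[[cc]]$special,
                 unique = sp[[cc]]$special %in% sp[[cc]]$unique,
                 enriched = sp[[cc]]$special %in% sp[[cc]]$enriched)))
    fwrite(membership, file.path(out, "special_sets.tsv"), sep = "\t")
    note(file.path(out, c("differential.tsv", "special_sets.tsv")))
  }

  if ("summarize" %in% stages) {
    pk <- as.data.table(read.table(
      need_file(file.path(out, "peaks.bed"), "summarize"),
      col.names = c("chrom", "start", "end")))
    sizes <- read_chrom_sizes(need_file(file.path(out, "chrom.sizes"),
                                        "summarize"))
    for (i in seq_len(nrow(rd))) {
      rec <- read_pairs(need_file(file.path(rd$dir[i], "pairs.tsv"),
                                  "summarize"))
      fwrite(cis_trans_summary(rec),
             file.path(rd$dir[i], "distance_classes.tsv"), sep = "\t")
      mp <- metaprofile(rec, pk, config$summarize$flank,
                        config$summarize$step, sizes)
      fwrite(mp$profile, file.path(rd$dir[i], "metaprofile.tsv"), sep = "\t")
      depths <- unique(pmax(1L, as.integer(
        config$summarize$depth_fractions * nrow(rec))))
      sat <- saturation_curves(rec, depths, config$summarize$n_seeds,
                               seed = stage_seed(config$seed,
                                                 paste0("sat", i)))
      fwrite(sat$summary, file.path(rd$dir[i], "saturation.tsv"), sep = "\t")
      bk <- biotype_region_breakdown(rec)
      fwrite(bk$composition, file.path(rd$dir[i], "composition.tsv"),
             sep = "\t")
      note(file.path(rd$dir[i], c("distance_classes.tsv", "metaprofile.tsv",
                                  "saturation.tsv", "composition.tsv")))
    }
  }

  manifest <- list(
    package = "radipr",
    version = as.character(utils::packageVersion("radipr")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    files = lapply(setNames(nm = produced), function(p)
      list(rows = count_rows(p))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(config, file.path(out, "config_used.yaml"))
  invisible(manifest)
}

#' @noRd
count_rows <- function(path) {
  if (!file.exists(path)) return(NA_integer_)
  if (grepl("\\.tsv$", path)) return(nrow(fread(path)))
  length(readLines(path, warn = FALSE))
}
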