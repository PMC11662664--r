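## Synthetic-data generator: toy genomes, gene annotations, peak sets,
## ground-truth interaction tables and chimeric reads with the statistical
## structure the pipeline assumes (distance-decayed cis contacts, a trans
## fraction, IP enrichment concentrated at designated peak bins).

#' Simulate a toy genome
#'
#' Draws i.i.d. uniform A/C/G/T sequence for each chromosome. The result is
#' FASTA-serialisable and deterministic under `seed`.
#'
#' @param n_chroms number of chromosomes.
#' @param lengths integer vector of chromosome lengths (bp), one per
#'   chromosome; all must be positive.
#' @param seed integer seed.
#' @param prefix chromosome name prefix (default `"chr"`).
#' @return an object of class `sim_genome`: list with `chrom_sizes` (named
#'   integer vector) and `seq` (a [Biostrings::DNAStringSet]).
#' @examples
#' g <- sim_genome(2, c(60000, 40000), seed = 1)
#' g$chrom_sizes
#' @export
sim_genome <- function(n_chroms, lengths, seed, prefix = "chr") {
  assert_that(is_count(n_chroms) && n_chroms >= 1, "n_chroms must be a positive count")
  assert_that(length(lengths) == n_chroms, "n_chroms must equal length(lengths)")
  assert_that(all(is.finite(lengths)) && all(lengths >= 1) &&
                all(lengths == floor(lengths)),
              "chromosome lengths must be positive integers")
  lengths <- as.integer(lengths)
  names(lengths) <- paste0(prefix, seq_len(n_chroms))
  seqs <- with_seed(seed, {
    vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
  out <- list(chrom_sizes = lengths,
              seq = Biostrings::DNAStringSet(seqs),
              seed = seed)
  names(out$seq) <- names(lengths)
  class(out) <- "sim_genome"
  out
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$chrom_sizes), "chromosome(s),",
      sum(as.numeric(x$chrom_sizes)), "bp total\n")
  invisible(x)
}

#' Write a simulated genome to FASTA and a chromosome-sizes table
#'
#' @param genome a `sim_genome`.
#' @param fasta output FASTA path.
#' @param chrom_sizes output two-column (name, length) TSV path, or `NULL`.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta, chrom_sizes = NULL) {
  Biostrings::writeXStringSet(genome$seq, filepath = fasta)
  if (!is.null(chrom_sizes)) {
    write.table(data.frame(names(genome$chrom_sizes),
                           as.integer(genome$chrom_sizes)),
                chrom_sizes, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta = fasta, chrom_sizes = chrom_sizes))
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name and length, no header.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "size"),
                  colClasses = c("character", "integer"))
  setNames(x$size, x$chrom)
}

#' Simulate a gene annotation on a toy genome
#'
#' Places `n_genes` non-identical gene intervals with strand, biotype and an
#' exon/intron structure (>= 1 exon per gene, intronic gaps between exons of
#' multi-exon genes). Coordinates are 0-based half-open.
#'
#' @param genome a `sim_genome`.
#' @param n_genes number of genes to place.
#' @param biotype_fractions named proportions over
#'   `{protein_coding, lncRNA, other}`; must sum to 1.
#' @param gene_len_range min/max gene length in bp.
#' @param max_exons maximum exon count per gene.
#' @param seed integer seed.
#' @return class `gene_annotation`: list with `genes` and `exons`
#'   data.tables (0-based half-open coordinates).
#' @export
sim_annotation <- function(genome, n_genes,
                           biotype_fractions = c(protein_coding = 0.70,
                                                 lncRNA = 0.25, other = 0.05),
                           gene_len_range = c(2000L, 10000L),
                           max_exons = 6L, seed = 1L) {
  assert_that(abs(sum(biotype_fractions) - 1) < 1e-8,
              "biotype_fractions must sum to 1")
  assert_that(is_count(n_genes) && n_genes >= 1, "n_genes must be positive")
  sizes <- genome$chrom_sizes
  assert_that(max(gene_len_range) <= max(sizes),
              "genes do not fit in any chromosome")
  with_seed(seed, {
    biotype <- sample(names(biotype_fractions), n_genes, replace = TRUE,
                      prob = biotype_fractions)
    len <- sample(seq(gene_len_range[1], gene_len_range[2]), n_genes,
                  replace = TRUE)
    fit <- sizes[sizes >= max(gene_len_range)]
    assert_that(length(fit) > 0, "no chromosome can hold a gene")
    chrom <- sample(names(fit), n_genes, replace = TRUE,
                    prob = as.numeric(fit) / sum(as.numeric(fit)))
    start <- vapply(seq_len(n_genes), function(i)
      sample.int(sizes[[chrom[i]]] - len[i] + 1L, 1L) - 1L, integer(1))
    genes <- data.table(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom, start = start, end = start + len,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = biotype)
    # de-duplicate identical intervals by a 1-bp nudge
    dup <- duplicated(genes[, .(chrom, start, end)])
    while (any(dup)) {
      genes[dup & start > 0, start := start - 1L]
      genes[dup & start == 0, end := end + 1L]
      dup <- duplicated(genes[, .(chrom, start, end)])
    }
    exons <- genes[, sim_exons(start, end, max_exons), by = gene_id]
    exons <- merge(exons, genes[, .(gene_id, chrom)], by = "gene_id")
    setcolorder(exons, c("gene_id", "chrom", "start", "end"))
    structure(list(genes = genes[], exons = exons[]),
              class = "gene_annotation")
  })
}

# Exon/intron structure for one gene [start,end): short exons (100-400 bp)
# at the gene ends and at random internal positions, introns filling the
# rest, so gene bodies are intron-dominated as in real annotations. A small
# fraction of genes are single-exon (fully exonic).
#' @noRd
sim_exons <- function(start, end, max_exons, p_single = 0.1) {
  len <- end - start
  n_exon <- if (runif(1) < p_single || max_exons < 2L) 1L
            else sample(2:max_exons, 1L)
  if (n_exon == 1L) return(data.table(start = start, end = end))
  ex_len <- pmin(sample(100:400, n_exon, replace = TRUE),
                 len %/% (2L * n_exon))
  R <- len - sum(ex_len)  # total intron length over n_exon - 1 gaps
  cuts <- if (n_exon > 2L) sort(sample.int(R - 1L, n_exon - 2L)) else integer(0)
  gaps <- diff(c(0L, cuts, R))
  starts <- start + cumsum(c(0L, ex_len[-n_exon] + gaps))
  data.table(start = starts, end = starts + ex_len)
}

#' Write a gene annotation as GTF
#'
#' Emits `gene` and `exon` features with `gene_id` and `gene_type`
#' attributes (GENCODE-style keys). Internal 0-based half-open coordinates
#' are converted to GTF's 1-based inclusive convention.
#'
#' @param annotation a `gene_annotation`.
#' @param path output GTF path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  g <- annotation$genes
  e <- merge(annotation$exons,
             g[, .(gene_id, strand, biotype)], by = "gene_id")
  gr_gene <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$start + 1L, g$end),
                                    strand = g$strand, type = "gene",
                                    gene_id = g$gene_id, gene_type = g$biotype)
  gr_exon <- GenomicRanges::GRanges(e$chrom,
                                    IRanges::IRanges(e$start + 1L, e$end),
                                    strand = e$strand, type = "exon",
                                    gene_id = e$gene_id, gene_type = e$biotype)
  rtracklayer::export(c(gr_gene, gr_exon), path, format = "gtf")
  invisible(path)
}

#' Read a GTF gene annotation
#'
#' Keeps `gene` and `exon` features and the `gene_id`/`gene_type` attribute
#' keys; converts to the package's 0-based half-open convention.
#'
#' @param path GTF file.
#' @return a `gene_annotation`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.table(as.data.frame(gr))
  assert_that(all(c("type", "gene_id") %in% names(df)),
              "GTF lacks type/gene_id attributes")
  if (!"gene_type" %in% names(df)) df[, gene_type := "other"]
  genes <- df[type == "gene",
              .(gene_id, chrom = as.character(seqnames),
                start = start - 1L, end = end,
                strand = as.character(strand), biotype = gene_type)]
  exons <- df[type == "exon",
              .(gene_id, chrom = as.character(seqnames),
                start = start - 1L, end = end)]
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' Simulate a peak interval set (e.g. ChIP-seq peaks)
#'
#' @param genome a `sim_genome`.
#' @param n_peaks number of peaks.
#' @param width peak width in bp.
#' @param seed integer seed.
#' @return data.table (chrom, start, end), 0-based half-open.
#' @export
sim_peaks <- function(genome, n_peaks = 50L, width = 2000L, seed = 1L) {
  sizes <- genome$chrom_sizes
  with_seed(seed, {
    chrom <- sample(names(sizes), n_peaks, replace = TRUE,
                    prob = as.numeric(sizes) / sum(as.numeric(sizes)))
    start <- vapply(chrom, function(cc)
      sample.int(max(sizes[[cc]] - width, 1L), 1L) - 1L, integer(1))
    unique(data.table(chrom = chrom, start = start,
                      end = pmin(start + width, sizes[chrom])))
  })
}

#' Write intervals as BED
#' @param intervals data.table/data.frame with chrom, start, end
#'   (0-based half-open, BED-native).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  write.table(as.data.frame(intervals)[, c("chrom", "start", "end")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate ground-truth RNA-DNA interactions
#'
#' Samples `n_pairs` candidate (gene, bin) pairs and draws an interaction
#' count for each from NB(mu, `r0`), where for a cis pair
#' `mu = mu0 * exp(-d / decay_scale)` (`d` = planned RNA-to-DNA tag distance)
#' and for a trans pair `mu = mu0 * eps_trans`. Bins overlapping `peaks` have
#' their mean multiplied by `enrichment_fold` when `condition = "ip"`; such
#' pairs are flagged `enriched` (the planted-truth set). Zero-count pairs are
#' retained in the truth table (they emit no reads).
#'
#' @param annotation a `gene_annotation`.
#' @param bins a [genome_bins()] table.
#' @param n_pairs number of candidate (gene, bin) pairs.
#' @param mu0 background mean count at distance 0.
#' @param r0 NB dispersion (size) parameter; variance is `mu + mu^2/r0`.
#' @param decay_scale exponential decay length of the cis contact mean (bp).
#' @param trans_fraction proportion of candidate pairs placed on another
#'   chromosome.
#' @param peaks optional peak table (chrom,start,end) for IP enrichment.
#' @param enrichment_fold mean multiplier at peak bins in the IP condition
#'   (>= 1).
#' @param condition `"input"` or `"ip"`; enrichment applies only to `"ip"`.
#' @param eps_trans trans mean suppression factor.
#' @param exonic_fraction probability that an RNA tag is placed inside an
#'   exon (the remainder fall in introns of multi-exon genes).
#' @param seed integer seed.
#' @return class `sim_truth`: list with `pairs` (one row per candidate pair,
#'   including count-0 rows) and the generating parameters.
#' @export
sim_interactions <- function(annotation, bins, n_pairs,
                             mu0 = 2, r0 = 10, decay_scale = 5e4,
                             trans_fraction = 0.7, peaks = NULL,
                             enrichment_fold = 1,
                             condition = c("input", "ip"),
                             eps_trans = 0.05, exonic_fraction = 0.15,
                             seed = 1L) {
  condition <- match.arg(condition)
  assert_that(nrow(annotation$genes) > 0, "empty gene set")
  assert_that(enrichment_fold >= 1, "enrichment_fold must be >= 1")
  assert_that(trans_fraction >= 0 && trans_fraction <= 1,
              "trans_fraction must lie in [0,1]")
  genes <- annotation$genes
  exons <- annotation$exons
  chroms <- unique(bins$chrom)
  if (length(chroms) < 2L && trans_fraction > 0) {
    warning("single chromosome: forcing trans_fraction = 0")
    trans_fraction <- 0
  }
  tag_max <- 27L  # widest tag the emitter will draw; anchors leave room for it

  with_seed(seed, {
    gi <- sample.int(nrow(genes), n_pairs, replace = TRUE)
    g <- genes[gi]
    # RNA tag anchor: a start such that a 27-nt tag stays inside the gene;
    # placed inside an exon with probability exonic_fraction (where an exon
    # is wide enough), otherwise uniformly in the gene body with one retry
    # away from exons; the realised region is recorded either way.
    exw <- exons[end - start >= tag_max, .(gene_id, start, w = end - start)]
    ex_split <- split(exw, by = "gene_id")
    want_exon <- runif(n_pairs) < exonic_fraction & g$gene_id %in% names(ex_split)
    body_draw <- function(idx) g$start[idx] + as.integer(
      floor(runif(length(idx)) * (g$end[idx] - g$start[idx] - tag_max + 1L)))
    rna_start <- body_draw(seq_len(n_pairs))
    for (gid in unique(g$gene_id[want_exon])) {
      ii <- which(want_exon & g$gene_id == gid)
      exl <- ex_split[[gid]]
      j <- sample.int(nrow(exl), length(ii), replace = TRUE)
      rna_start[ii] <- exl$start[j] + as.integer(
        floor(runif(length(ii)) * (exl$w[j] - tag_max + 1L)))
    }
    in_exon <- function(ctr) {
      pts <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(ctr + 1L, ctr + 1L))
      exg <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start + 1L, exons$end))
      ov <- GenomicRanges::findOverlaps(pts, exg)
      same <- exons$gene_id[S4Vectors::subjectHits(ov)] ==
        g$gene_id[S4Vectors::queryHits(ov)]
      seq_len(n_pairs) %in% S4Vectors::queryHits(ov)[same]
    }
    for (pass in 1:5) {  # steer non-exonic draws away from exons
      retry <- which(!want_exon & in_exon(rna_start + tag_max %/% 2L))
      if (!length(retry)) break
      rna_start[retry] <- body_draw(retry)
    }
    rna_region <- ifelse(in_exon(rna_start + tag_max %/% 2L), "exon", "intron")
    rna_center <- rna_start + tag_max %/% 2L

    # DNA side: trans pairs draw a bin uniformly on another chromosome,
    # cis pairs a bin uniformly on the same chromosome.
    is_trans <- runif(n_pairs) < trans_fraction
    dna_bin <- integer(n_pairs)
    for (cc in unique(g$chrom)) {
      same <- which(bins$chrom == cc); other <- which(bins$chrom != cc)
      i_cis <- which(!is_trans & g$chrom == cc)
      i_tr <- which(is_trans & g$chrom == cc)
      if (length(i_cis))
        dna_bin[i_cis] <- same[sample.int(length(same), length(i_cis),
                                          replace = TRUE)]
      if (length(i_tr))
        dna_bin[i_tr] <- other[sample.int(length(other), length(i_tr),
                                          replace = TRUE)]
    }
    b <- bins[dna_bin]
    dna_start <- b$start + as.integer(
      floor(runif(n_pairs) * pmax(b$end - b$start - tag_max + 1L, 1L)))
    dna_center <- dna_start + tag_max %/% 2L

    d <- ifelse(is_trans, NA_integer_, abs(dna_center - rna_center))
    mu <- ifelse(is_trans, mu0 * eps_trans, mu0 * exp(-d / decay_scale))

    enriched <- rep(FALSE, n_pairs)
    if (!is.null(peaks) && nrow(peaks) > 0) {
      pk <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(peaks$start + 1L, peaks$end))
      bn <- GenomicRanges::GRanges(b$chrom,
                                   IRanges::IRanges(b$start + 1L, b$end))
      at_peak <- IRanges::overlapsAny(bn, pk)
      if (condition == "ip") {
        mu[at_peak] <- mu[at_peak] * enrichment_fold
        enriched <- at_peak & enrichment_fold > 1
      }
    }

    pairs <- data.table(
      gene_id = g$gene_id,
      rna_chrom = g$chrom, rna_start = rna_start,
      rna_strand = g$strand, rna_region = rna_region,
      dna_chrom = b$chrom, dna_start = dna_start,
      bin_id = b$bin_id, distance = d, trans = is_trans,
      mu = mu, enriched = enriched)
    pairs <- unique(pairs, by = c("gene_id", "bin_id"))
    pairs[, count := rnbinom(.N, size = r0, mu = mu)]

    structure(list(pairs = pairs[],
                   params = list(mu0 = mu0, r0 = r0,
                                 decay_scale = decay_scale,
                                 trans_fraction = trans_fraction,
                                 eps_trans = eps_trans,
                                 enrichment_fold = enrichment_fold,
                                 condition = condition, seed = seed)),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$pairs), "candidate (gene,bin) pairs;",
      sum(x$pairs$count), "interaction reads;",
      sum(x$pairs$enriched), "planted enriched pairs\n")
  invisible(x)
}

#' Emit chimeric reads and truth alignments from simulated interactions
#'
#' Expands each truth pair into `count` reads. Every read is the
#' concatenation RNA tag + full bridge adaptor + DNA tag (tag on the
#' adaptor's `rna_side`), with tag lengths drawn uniformly from
#' `tag_len_range` and per-base substitution errors at `error_rate`.
#' Minus-strand RNA tags are emitted reverse-complemented, as sequenced.
#'
#' @param truth a `sim_truth`.
#' @param genome the `sim_genome` used for the simulation.
#' @param adaptor a [bridge_adaptor()] spec.
#' @param tag_len_range inclusive tag-length range in nt (default 25-27, the
#'   fragment sizes left by EcoP15I digestion).
#' @param error_rate per-base substitution probability over the whole read.
#' @param qual constant Phred+33 quality character for emitted bases.
#' @param seed integer seed.
#' @return class `sim_reads`: list with `reads` (read_id, seq, qual),
#'   `rna_aln` and `dna_aln` truth alignments (0-based half-open, MAPQ 37)
#'   and `pairs` (read_id, gene_id, bin_id).
#' @export
sim_reads <- function(truth, genome, adaptor = bridge_adaptor(),
                      tag_len_range = c(25L, 27L), error_rate = 0,
                      qual = "I", seed = 1L) {
  assert_that(tag_len_range[1] >= 1 && tag_len_range[1] <= tag_len_range[2],
              "invalid tag_len_range")
  assert_that(tag_len_range[2] <= 27L,
              "tag_len_range exceeds the 27-nt truth anchors")
  tp <- truth$pairs[count > 0]
  idx <- rep(seq_len(nrow(tp)), tp$count)
  n <- length(idx)
  assert_that(n > 0, "truth contains no nonzero-count pairs")
  chrom_seq <- setNames(as.character(genome$seq), names(genome$seq))

  with_seed(seed, {
    lens <- seq(tag_len_range[1], tag_len_range[2])
    l_rna <- lens[sample.int(length(lens), n, replace = TRUE)]
    l_dna <- lens[sample.int(length(lens), n, replace = TRUE)]
    tpx <- tp[idx]
    rna_fwd <- substring(chrom_seq[tpx$rna_chrom],
                         tpx$rna_start + 1L, tpx$rna_start + l_rna)
    dna_fwd <- substring(chrom_seq[tpx$dna_chrom],
                         tpx$dna_start + 1L, tpx$dna_start + l_dna)
    rna_read <- ifelse(tpx$rna_strand == "-",
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(rna_fwd))),
                       rna_fwd)
    seq <- if (adaptor$rna_side == "five_prime")
      paste0(rna_read, adaptor$sequence, dna_fwd)
    else paste0(dna_fwd, adaptor$sequence, rna_read)
    if (error_rate > 0) seq <- mutate_bases(seq, error_rate)
    read_id <- sprintf("read%07d", seq_len(n))
    reads <- data.table(read_id = read_id, seq = seq,
                        qual = strrep(qual, nchar(seq)))
    rna_aln <- data.table(read_id = read_id, chrom = tpx$rna_chrom,
                          start = tpx$rna_start, end = tpx$rna_start + l_rna,
                          strand = tpx$rna_strand, mapq = 37L)
    dna_aln <- data.table(read_id = read_id, chrom = tpx$dna_chrom,
                          start = tpx$dna_start, end = tpx$dna_start + l_dna,
                          strand = "+", mapq = 37L)
    pairs <- data.table(read_id = read_id, gene_id = tpx$gene_id,
                        bin_id = tpx$bin_id)
    structure(list(reads = reads, rna_aln = rna_aln, dna_aln = dna_aln,
                   pairs = pairs, adaptor = adaptor),
              class = "sim_reads")
  })
}

# Vectorised random substitutions at rate per base.
#' @noRd
mutate_bases <- function(seq, rate) {
  nc <- nchar(seq)
  n_mut <- rbinom(length(seq), nc, rate)
  hit <- which(n_mut > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nc[i], n_mut[i])
    s <- strsplit(seq[i], "")[[1]]
    s[pos] <- vapply(s[pos], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    seq[i] <- paste(s, collapse = "")
  }
  seq
}

#' Write simulated reads to FASTQ plus truth SAM and pairs TSV
#'
#' @param sim a `sim_reads` object.
#' @param genome the `sim_genome` (for SAM headers).
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of paths
#'   (`fastq`, `rna_sam`, `dna_sam`, `pairs`).
#' @export
write_sim_reads <- function(sim, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, "reads.fastq")
  dss <- Biostrings::DNAStringSet(sim$reads$seq)
  names(dss) <- sim$reads$read_id
  Biostrings::writeXStringSet(
    dss, fq, format = "fastq",
    qualities = Biostrings::BStringSet(sim$reads$qual))
  chrom_seq <- setNames(as.character(genome$seq), names(genome$seq))
  paths <- c(fastq = fq,
             rna_sam = file.path(dir, "rna_truth.sam"),
             dna_sam = file.path(dir, "dna_truth.sam"),
             pairs = file.path(dir, "truth_pairs.tsv"))
  write_truth_sam(sim$rna_aln, genome, chrom_seq, paths[["rna_sam"]])
  write_truth_sam(sim$dna_aln, genome, chrom_seq, paths[["dna_sam"]])
  fwrite(sim$pairs, paths[["pairs"]], sep = "\t")
  invisible(paths)
}

# Truth SAM: ungapped alignments at the true coordinates, MAPQ 37. SEQ is the
# forward-genome sequence (SAM stores minus-strand reads reverse-complemented
# back to the reference strand).
#' @noRd
write_truth_sam <- function(aln, genome, chrom_seq, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chrom_sizes),
                   as.integer(genome$chrom_sizes)))
  len <- aln$end - aln$start
  seqs <- substring(chrom_seq[aln$chrom], aln$start + 1L, aln$end)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                 aln$read_id, ifelse(aln$strand == "-", 16L, 0L),
                 aln$chrom, aln$start + 1L, aln$mapq, len, seqs,
                 strrep("I", len))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
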