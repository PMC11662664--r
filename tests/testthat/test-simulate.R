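test_that("simulated genomes have declared lengths, a DNA alphabet and are seed-deterministic", {
  g <- sim_genome(2, c(60000, 40000), seed = 1)
  expect_equal(unname(g$chrom_sizes), c(60000L, 40000L))
  expect_equal(unname(Biostrings::width(g$seq)), c(60000L, 40000L))
  expect_true(all(grepl("^[ACGT]+$", as.character(g$seq))))
  g2 <- sim_genome(2, c(60000, 40000), seed = 1)
  expect_identical(as.character(g$seq), as.character(g2$seq))
  g3 <- sim_genome(2, c(60000, 40000), seed = 2)
  expect_false(identical(as.character(g$seq), as.character(g3$seq)))
  expect_error(sim_genome(1, c(0), seed = 1), "positive")
  expect_error(sim_genome(2, c(100), seed = 1), "length")
})

test_that("genome FASTA and chrom.sizes round-trip", {
  g <- sim_genome(2, c(50000, 30000), seed = 3)
  fa <- tempfile(fileext = ".fa"); cs <- tempfile()
  write_genome(g, fa, cs)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back), as.character(g$seq))
  expect_identical(read_chrom_sizes(cs), g$chrom_sizes)
})

test_that("simulated annotations respect biotype fractions and exon structure", {
  g <- sim_genome(2, c(5e5, 5e5), seed = 4)
  fr <- c(protein_coding = 0.8, lncRNA = 0.2)
  ann <- sim_annotation(g, 200, biotype_fractions = fr, seed = 5)
  n_pc <- sum(ann$genes$biotype == "protein_coding")
  # 80% +/- 4 binomial sd
  expect_lt(abs(n_pc - 160), 4 * sqrt(200 * 0.8 * 0.2) + 1)
  expect_error(sim_annotation(g, 10, biotype_fractions = c(pc = 0.5),
                              seed = 1), "sum to 1")
  # exons lie within their gene and tile without overlap
  ex <- merge(ann$exons, ann$genes, by = c("gene_id", "chrom"),
              suffixes = c("", ".gene"))
  expect_true(all(ex$start >= ex$start.gene & ex$end <= ex$end.gene))
  data.table::setorder(ex, gene_id, start)
  ov <- ex[, any(start[-1] < end[-.N]), by = gene_id]
  expect_false(any(ov$V1[ex[, .N, by = gene_id]$N > 1]))
  # single-exon genes have zero intronic bases
  n_ex <- ann$exons[, .N, by = gene_id]
  single <- n_ex[N == 1, gene_id]
  one <- merge(ann$exons[gene_id %in% single],
               ann$genes[gene_id %in% single, .(gene_id, gstart = start,
                                                gend = end)], by = "gene_id")
  expect_true(all(one$start == one$gstart & one$end == one$gend))
  # strand is recorded, exons stored in genomic coordinates on both strands
  expect_true(all(ann$genes$strand %in% c("+", "-")))
})

test_that("annotation GTF export/import round-trips", {
  g <- sim_genome(2, c(2e5, 2e5), seed = 6)
  ann <- sim_annotation(g, 30, seed = 7)
  f <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, f)
  back <- read_annotation_gtf(f)
  data.table::setorder(back$genes, gene_id)
  data.table::setorder(back$exons, gene_id, start)
  ex <- data.table::copy(ann$exons); data.table::setorder(ex, gene_id, start)
  expect_equal(back$genes[, .(gene_id, chrom, start, end, strand, biotype)],
               ann$genes[, .(gene_id, chrom, start, end, strand, biotype)],
               ignore_attr = TRUE)
  expect_equal(back$exons[, .(gene_id, chrom, start, end)],
               ex[, .(gene_id, chrom, start, end)], ignore_attr = TRUE)
})

test_that("interaction truth obeys the generating law", {
  w <- toy_world()
  expect_error(sim_interactions(structure(list(genes = w$annotation$genes[0],
                                               exons = w$annotation$exons),
                                          class = "gene_annotation"),
                                w$bins, 100, seed = 1), "empty gene set")
  expect_error(sim_interactions(w$annotation, w$bins, 100,
                                enrichment_fold = 0.5, seed = 1), ">= 1")

  # trans fraction of candidate pairs within binomial error (genome large
  # enough that deduplication does not saturate either bin pool)
  gw <- sim_genome(3, c(2e6, 1.5e6, 1e6), seed = 80)
  aw <- sim_annotation(gw, 100, seed = 81)
  bw <- genome_bins(gw$chrom_sizes, 25000L)
  trf <- sim_interactions(aw, bw, 4000, trans_fraction = 0.6, seed = 82)
  expect_lt(abs(mean(trf$pairs$trans) - 0.6),
            4 * sqrt(0.6 * 0.4 / nrow(trf$pairs)))
  tr <- sim_interactions(w$annotation, w$bins, 4000, trans_fraction = 0.6,
                         seed = 8)
  # every truth interval lies within its chromosome
  sizes <- w$genome$chrom_sizes
  expect_true(all(tr$pairs$rna_start >= 0 &
                    tr$pairs$rna_start + 27 <= sizes[tr$pairs$rna_chrom]))
  expect_true(all(tr$pairs$dna_start >= 0 &
                    tr$pairs$dna_start + 27 <= sizes[tr$pairs$dna_chrom]))

  # flat-mean limit: decay_scale -> Inf, no trans: cis counts independent of
  # distance, empirical mean near mu0 (spec's d = 0 Monte-Carlo check)
  tr2 <- sim_interactions(w$annotation, w$bins, 10000, mu0 = 2, r0 = 1,
                          decay_scale = 1e18, trans_fraction = 0, seed = 9)
  x <- tr2$pairs$count
  expect_lt(abs(mean(x) - 2), 3 * sd(x) / sqrt(length(x)))
  near <- tr2$pairs[distance <= quantile(distance, 0.2)]
  far <- tr2$pairs[distance > quantile(distance, 0.8)]
  se <- sqrt(var(near$count) / nrow(near) + var(far$count) / nrow(far))
  expect_lt(abs(mean(near$count) - mean(far$count)), 4 * se)

  # enrichment marks only peak bins in the IP condition
  tr_ip <- sim_interactions(w$annotation, w$bins, 2000, peaks = w$peaks,
                            enrichment_fold = 5, condition = "ip", seed = 10)
  tr_in <- sim_interactions(w$annotation, w$bins, 2000, peaks = w$peaks,
                            enrichment_fold = 5, condition = "input", seed = 10)
  expect_gt(sum(tr_ip$pairs$enriched), 0)
  expect_equal(sum(tr_in$pairs$enriched), 0)
})

test_that("emitted reads match the genome exactly at error rate zero", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 800, mu0 = 5,
                         trans_fraction = 0.2, seed = 12)
  sr <- sim_reads(tr, w$genome, error_rate = 0, seed = 13)
  expect_equal(nrow(sr$reads), sum(tr$pairs$count))
  chrom_seq <- stats::setNames(as.character(w$genome$seq),
                               names(w$genome$chrom_sizes))
  # every DNA tag is the genome substring at its truth coordinates
  dna_true <- substring(chrom_seq[sr$dna_aln$chrom], sr$dna_aln$start + 1L,
                        sr$dna_aln$end)
  adaptor <- bridge_adaptor()
  dna_emit <- substring(sr$reads$seq,
                        nchar(sr$reads$seq) - nchar(dna_true) + 1L)
  expect_identical(dna_emit, unname(dna_true))
  # RNA tag: forward genome sequence, reverse-complemented on minus strand
  rna_true <- substring(chrom_seq[sr$rna_aln$chrom], sr$rna_aln$start + 1L,
                        sr$rna_aln$end)
  neg <- sr$rna_aln$strand == "-"
  rna_true[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rna_true[neg])))
  rna_emit <- substring(sr$reads$seq, 1L, nchar(rna_true))
  expect_identical(rna_emit, unname(rna_true))
  expect_true(all(sr$rna_aln$mapq == 37L))
})

test_that("tag length range and FASTQ determinism hold", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 400, mu0 = 5,
                         trans_fraction = 0.2, seed = 14)
  sr27 <- sim_reads(tr, w$genome, tag_len_range = c(27L, 27L), seed = 15)
  expect_true(all(sr27$rna_aln$end - sr27$rna_aln$start == 27L))
  expect_true(all(sr27$dna_aln$end - sr27$dna_aln$start == 27L))
  expect_error(sim_reads(tr, w$genome, tag_len_range = c(25L, 30L), seed = 1),
               "27")

  sr <- sim_reads(tr, w$genome, seed = 16)
  lens <- sr$rna_aln$end - sr$rna_aln$start
  expect_true(all(lens >= 25L & lens <= 27L))
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_reads(sr, w$genome, d1)
  write_sim_reads(sim_reads(tr, w$genome, seed = 16), w$genome, d2)
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
})

test_that("substitution errors appear at roughly the requested rate", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 400, mu0 = 5,
                         trans_fraction = 0, seed = 17)
  sr0 <- sim_reads(tr, w$genome, error_rate = 0, seed = 18)
  sr1 <- sim_reads(tr, w$genome, error_rate = 0.05, seed = 18)
  n_tot <- sum(nchar(sr0$reads$seq))
  mm <- sum(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                   sr0$reads$seq, sr1$reads$seq))
  expect_lt(abs(mm / n_tot - 0.05), 4 * sqrt(0.05 * 0.95 / n_tot))
})
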