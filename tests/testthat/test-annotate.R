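test_that("center-point reduction uses the floor midpoint", {
  expect_equal(center_coord(100L, 127L), 113L)  # 27 nt
  expect_equal(center_coord(100L, 126L), 113L)  # 26 nt, floor convention
  expect_equal(center_coord(0L, 1L), 0L)
  expect_error(center_coord(10L, 10L), "start must be <")
})

test_that("bins tile chromosomes with a short final bin and half-open borders", {
  bins <- genome_bins(c(chrA = 60000L), 25000L)
  expect_equal(bins$start, c(0L, 25000L, 50000L))
  expect_equal(bins$end, c(25000L, 50000L, 60000L))
  expect_equal(assign_dna_to_bin("chrA", 24999L, bins), "chrA:0")
  expect_equal(assign_dna_to_bin("chrA", 25000L, bins), "chrA:1")
  expect_error(assign_dna_to_bin("chrB", 10L, bins), "unknown chromosome")
  expect_error(assign_dna_to_bin("chrA", 99999L, bins), "outside")
})

test_that("the unique-mapping filter keeps MAPQ 37 and supports a minimum mode", {
  tags <- tag_table(c("a", "b", "c"), "chr1", c(0L, 100L, 200L),
                    c(27L, 127L, 227L), mapq = c(37L, 20L, 42L))
  expect_equal(filter_unique(tags)$read_id, "a")
  expect_equal(filter_unique(tags, mapq_mode = "min")$read_id, c("a", "c"))
  expect_equal(nrow(filter_unique(tags[0])), 0L)
})

test_that("a read survives only if both of its tags survive", {
  ann <- structure(list(
    genes = data.table::data.table(gene_id = "gX", chrom = "chr1",
                                   start = 0L, end = 10000L, strand = "+",
                                   biotype = "protein_coding"),
    exons = data.table::data.table(gene_id = "gX", chrom = "chr1",
                                   start = 0L, end = 10000L)),
    class = "gene_annotation")
  bins <- genome_bins(c(chr1 = 50000L), 25000L)
  rna <- tag_table(c("a", "b"), "chr1", c(100L, 200L), c(127L, 227L),
                   mapq = c(37L, 37L))
  dna <- tag_table(c("a", "b"), "chr1", c(5000L, 6000L), c(5027L, 6027L),
                   mapq = c(37L, 20L))
  rec <- annotate_interactions(rna, dna, ann, bins)
  expect_equal(rec$read_id, "a")
  drops <- attr(rec, "drop_counts")
  expect_equal(unname(drops["input"]), 2)
  expect_equal(unname(drops["mapq_or_unpaired"]), 1)
  expect_equal(unname(drops["kept"]), 1)
})

test_that("RNA tags are assigned to genes strand-aware and unambiguously", {
  genes <- data.table::data.table(
    gene_id = c("A", "B", "C", "D"),
    chrom = "chr1",
    start = c(1000L, 1000L, 8000L, 8000L),
    end = c(5000L, 5000L, 9000L, 9000L),
    strand = c("+", "-", "+", "+"),
    biotype = "protein_coding")
  exons <- data.table::data.table(gene_id = c("A", "B", "C", "D"),
                                  chrom = "chr1",
                                  start = c(1000L, 1000L, 8000L, 8000L),
                                  end = c(1200L, 5000L, 9000L, 9000L))
  ann <- structure(list(genes = genes, exons = exons),
                   class = "gene_annotation")
  res <- assign_rna_to_gene(rep("chr1", 4), c(2000L, 2000L, 8500L, 6000L),
                            c("+", "-", "+", "+"), ann)
  # strand disambiguates overlapping A(+)/B(-)
  expect_equal(res$gene_id[1:2], c("A", "B"))
  expect_equal(res$status[3], "ambiguous")   # C and D overlap, same strand
  expect_equal(res$status[4], "unassigned")  # in no gene
  # exon/intron region from the assigned gene's exons
  expect_equal(res$region[1], "intron")  # A's exon ends at 1200
  expect_equal(res$region[2], "exon")    # B is single-exon
})

test_that("blacklist removal uses >=1 bp overlap of the DNA tag interval", {
  rec <- data.table::data.table(dna_chrom = "chr1",
                                dna_start = c(100L, 100L),
                                dna_end = c(127L, 127L),
                                id = c("hit", "hit2"))
  bl1 <- data.table::data.table(chrom = "chr1", start = 120L, end = 200L)
  expect_equal(nrow(blacklist_filter(rec, bl1)), 0L)  # 7 bp overlap
  bl2 <- data.table::data.table(chrom = "chr1", start = 127L, end = 200L)
  expect_equal(nrow(blacklist_filter(rec, bl2)), 2L)  # half-open adjacency
  expect_identical(blacklist_filter(rec, NULL), rec)
  expect_equal(nrow(blacklist_filter(rec, bl1[0])), 2L)
  # BED path input
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t120\t200", bed)
  expect_equal(nrow(blacklist_filter(rec, bed)), 0L)
})

test_that("pair aggregation conserves gene-assigned record counts", {
  rec <- data.table::data.table(
    read_id = sprintf("r%d", 1:5),
    gene_id = c("gX", "gX", "gX", NA, "gY"),
    bin_id = c("chr1:5", "chr1:5", "chr1:5", "chr1:1", "chr1:2"))
  bp <- build_pairs(rec)
  expect_equal(bp$counts[gene_id == "gX" & bin_id == "chr1:5", count], 3L)
  expect_equal(sum(bp$counts$count), sum(!is.na(rec$gene_id)))
  expect_equal(nrow(bp$records), 5L)  # unassigned kept at record level
})

test_that("truth SAM files are read back with exact coordinates", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 300, mu0 = 5,
                         trans_fraction = 0.2, seed = 31)
  sr <- sim_reads(tr, w$genome, seed = 32)
  d <- tempfile()
  paths <- write_sim_reads(sr, w$genome, d)
  back <- read_aligned_tags(paths[["rna_sam"]])
  data.table::setorder(back, read_id)
  truth <- data.table::copy(sr$rna_aln); data.table::setorder(truth, read_id)
  expect_equal(back[, .(read_id, chrom, start, end, strand, mapq)],
               truth[, .(read_id, chrom, start, end, strand, mapq)])
})

test_that("annotation recovers simulated truth for unambiguous records", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 1200, mu0 = 5,
                         trans_fraction = 0.3, seed = 33)
  sr <- sim_reads(tr, w$genome, error_rate = 0, seed = 34)
  d <- tempfile()
  paths <- write_sim_reads(sr, w$genome, d)
  rec <- annotate_interactions(paths[["rna_sam"]], paths[["dna_sam"]],
                               w$annotation, w$bins)
  truth <- data.table::fread(paths[["pairs"]])
  m <- merge(rec, truth, by = "read_id", suffixes = c("", ".truth"))
  assigned <- !is.na(m$gene_id)
  expect_equal(mean(m$gene_id[assigned] == m$gene_id.truth[assigned]), 1)
  expect_equal(mean(m$bin_id == m$bin_id.truth), 1)
  # conservation across the chain
  drops <- attr(rec, "drop_counts")
  expect_equal(unname(drops["input"]),
               unname(drops["mapq_or_unpaired"] + drops["ambiguous_gene"] +
                        drops["blacklisted"] + drops["kept"]))
  # distance classes are consistent with coordinates
  cis <- rec[!is.na(distance)]
  expect_true(all(cis$class[cis$distance <= 1e5] == "cis_lt100kb"))
  expect_true(all(rec[rna_chrom != dna_chrom, class] == "trans"))
})

test_that("pairs TSV round-trips through write_pairs/read_pairs", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 200, mu0 = 5,
                         trans_fraction = 0.3, seed = 35)
  sr <- sim_reads(tr, w$genome, seed = 36)
  d <- tempfile(); paths <- write_sim_reads(sr, w$genome, d)
  rec <- annotate_interactions(paths[["rna_sam"]], paths[["dna_sam"]],
                               w$annotation, w$bins)
  f <- tempfile(fileext = ".tsv")
  write_pairs(rec, f)
  back <- read_pairs(f)
  expect_equal(back, rec, ignore_attr = TRUE)
})
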