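test_that("distance classes follow the 100 kb / 1 Mb boundaries", {
  expect_equal(classify_distance_vec("chr1", "chr1", 50000L), "cis_lt100kb")
  expect_equal(classify_distance_vec("chr1", "chr1", 150000L), "cis_100kb_1Mb")
  expect_equal(classify_distance_vec("chr1", "chr1", 2e6), "cis_gt1Mb")
  expect_equal(classify_distance_vec("chr1", "chr2", NA), "trans")
  # boundary placement: <= is lower-inclusive
  expect_equal(classify_distance_vec("chr1", "chr1", 100000L), "cis_lt100kb")
  expect_equal(classify_distance_vec("chr1", "chr1", 100001L), "cis_100kb_1Mb")
  expect_equal(classify_distance_vec("chr1", "chr1", 1000000L), "cis_100kb_1Mb")
  expect_equal(classify_distance(list(rna_chrom = "chr1", dna_chrom = "chr1",
                                      distance = 5e5)), "cis_100kb_1Mb")
})

test_that("cis/trans summaries count every class and sum to one", {
  rec <- data.table::data.table(
    rna_chrom = c("chr1", "chr1", "chr1", "chr1"),
    dna_chrom = c("chr2", "chr3", "chr2", "chr1"),
    distance = c(NA, NA, NA, 1000L))
  s <- cis_trans_summary(rec)
  expect_equal(s[class == "trans", fraction], 0.75)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(s$n), nrow(rec))
  # permutation invariance
  expect_equal(cis_trans_summary(rec[c(3, 1, 4, 2)]), s)
  expect_warning(s0 <- cis_trans_summary(rec[0]), "empty")
  expect_true(all(is.na(s0$fraction)))
})

test_that("the bin-bin matrix conserves records and re-bins additively", {
  w <- toy_world()
  tr <- sim_interactions(w$annotation, w$bins, 900, mu0 = 5,
                         trans_fraction = 0.3, seed = 61)
  sr <- sim_reads(tr, w$genome, seed = 62)
  d <- tempfile(); paths <- write_sim_reads(sr, w$genome, d)
  rec <- annotate_interactions(paths[["rna_sam"]], paths[["dna_sam"]],
                               w$annotation, w$bins)
  m25 <- bin_bin_matrix(rec, w$bins)
  expect_equal(sum(m25), nrow(rec))
  # single cis record lands once on the diagonal
  one <- rec[rna_chrom == dna_chrom][1]
  m1 <- bin_bin_matrix(one, w$bins)
  expect_equal(sum(m1), 1)
  if (one$rna_center %/% 25000L == one$dna_center %/% 25000L &&
      one$rna_chrom == one$dna_chrom)
    expect_equal(sum(Matrix::diag(m1)), 1)
  # oracle: a direct recount at 50 kb equals the package's 50-kb matrix
  bins50 <- genome_bins(w$genome$chrom_sizes, 50000L)
  m50 <- bin_bin_matrix(rec, bins50)
  oracle <- table(paste0(rec$rna_chrom, ":", rec$rna_center %/% 50000L),
                  paste0(rec$dna_chrom, ":", rec$dna_center %/% 50000L))
  for (i in rownames(oracle)) for (j in colnames(oracle)) {
    if (oracle[i, j] > 0) expect_equal(unname(m50[i, j]), unname(oracle[i, j]))
  }
  expect_equal(sum(m50), sum(oracle))
})

test_that("meta-profiles peak at the center for center-planted tags and stay flat for noise", {
  sizes <- c(chr1 = 1e6)
  peaks <- data.table::data.table(chrom = "chr1",
                                  start = seq(100000L, 900000L, by = 40000L))
  peaks[, end := start + 2000L]
  centers <- center_coord(peaks$start, peaks$end)
  planted <- data.table::data.table(chrom = "chr1", center = centers)
  mp <- metaprofile(planted, peaks, chrom_sizes = sizes)
  expect_equal(nrow(mp$profile), 2L * 3000L / 50L)
  expect_equal(mp$profile[which.max(density), offset], 0L)
  expect_equal(max(mp$profile$density), 1)  # one tag per peak at the center

  set.seed(63)
  unif <- data.table::data.table(chrom = "chr1",
                                 center = sample.int(1e6, 60000L) - 1L)
  mpu <- metaprofile(unif, peaks, chrom_sizes = sizes)
  dens <- mpu$profile$density
  p_bin <- 50 / 1e6
  expected <- 60000 * p_bin
  expect_true(all(abs(dens - expected) < 4 * sqrt(60000 * p_bin * (1 - p_bin)) /
                    mpu$n_peaks + expected))
  # mirror-symmetric tags give a symmetric profile
  sym <- data.table::data.table(chrom = "chr1",
                                center = c(centers - 1000L, centers + 1000L))
  mps <- metaprofile(sym, peaks, chrom_sizes = sizes)
  prof <- mps$profile
  left <- prof[offset == -1000L, count]
  right <- prof[offset == 1000L, count]
  expect_equal(left, right)
})

test_that("windows are clipped at chromosome edges with adjusted coverage", {
  sizes <- c(chr1 = 10000)
  peaks <- data.table::data.table(chrom = "chr1", start = 0L, end = 2000L)
  tags <- data.table::data.table(chrom = "chr1", center = c(10L, 1500L))
  mp <- metaprofile(tags, peaks, flank = 3000L, step = 50L,
                    chrom_sizes = sizes)
  off_left <- mp$profile[offset < -1000L]
  expect_true(all(off_left$coverage == 0))  # window clipped below position 0
  expect_true(all(is.na(off_left$density)))
  expect_equal(sum(mp$profile$count), 2L)
})

test_that("peak overlap fractions use half-open interval semantics", {
  peaks <- data.table::data.table(chrom = "chr1", start = 1000L, end = 2000L)
  tags <- data.table::data.table(
    chrom = "chr1",
    start = c(1500L, 2000L, 973L, 5000L),
    end = c(1527L, 2027L, 1001L, 5027L))
  ov <- peak_overlap_fraction(tags, peaks)
  # inside; adjacent (no overlap); 1-bp overlap; far away
  expect_equal(ov$tag_fraction, 2 / 4)
  expect_equal(ov$peak_fraction, 1)
  none <- peak_overlap_fraction(tags[4], peaks)
  expect_equal(none$tag_fraction, 0)
  all_in <- peak_overlap_fraction(tags[1], peaks)
  expect_equal(all_in$tag_fraction, 1)
})

test_that("saturation curves are monotone and exact at the endpoints", {
  rec <- data.table::data.table(
    gene_id = sample(sprintf("g%02d", 1:30), 500, replace = TRUE),
    bin_id = sample(sprintf("b%02d", 1:40), 500, replace = TRUE))
  sat <- saturation_curves(rec, depths = c(0L, 50L, 200L, 500L),
                           n_seeds = 4L, seed = 64)
  expect_equal(sat$summary[depth == 0, bins_mean], 0)
  expect_equal(sat$summary[depth == 0, species_mean], 0)
  expect_equal(sat$summary[depth == 500, bins_mean],
               length(unique(rec$bin_id)))
  expect_equal(sat$summary[depth == 500, bins_sd], 0)
  # monotone non-decreasing within every seed
  mono <- sat$draws[order(depth),
                    .(ok = all(diff(n_bins) >= 0) & all(diff(n_species) >= 0)),
                    by = seed]
  expect_true(all(mono$ok))
  expect_warning(saturation_curves(rec, depths = 1000L, seed = 1), "capped")
})

test_that("biotype/region breakdowns are normalised per stratum", {
  rec <- data.table::data.table(
    gene_id = c("a", "a", "b", "c", NA),
    gene_biotype = c("protein_coding", "protein_coding", "protein_coding",
                     "lncRNA", NA),
    rna_region = c("intron", "intron", "exon", "exon", NA),
    class = c("cis_lt100kb", "trans", "trans", "cis_lt100kb", "trans"))
  bk <- biotype_region_breakdown(rec)
  expect_equal(sum(bk$composition$fraction), 1, tolerance = 1e-12)
  expect_equal(bk$composition[biotype == "protein_coding" &
                                region == "intron", fraction], 0.5)
  sums <- bk$by_class[, sum(fraction), by = .(biotype, region)]
  expect_true(all(abs(sums$V1 - 1) < 1e-12))
  all_pc_intron <- data.table::data.table(
    gene_id = "a", gene_biotype = "protein_coding", rna_region = "intron",
    class = "trans")
  expect_equal(biotype_region_breakdown(all_pc_intron)$composition$fraction, 1)
})

test_that("the Monte-Carlo chi-square p-value has the 1/(B+1) floor", {
  a <- c(alpha = 1000, beta = 0)
  b <- c(alpha = 0, beta = 1000)
  r <- mc_chisq_similarity(a, b, B = 2000L, seed = 65)
  expect_equal(r$p, 1 / 2001, tolerance = 1e-12)
  same <- mc_chisq_similarity(c(x = 500, y = 500), c(x = 500, y = 500),
                              B = 500L, seed = 66)
  expect_gt(same$p, 0.9)
  expect_gte(r$p, 1 / (r$B + 1))
  expect_warning(mc_chisq_similarity(c(x = 5, y = 0, z = 3),
                                     c(x = 2, y = 0, z = 1), B = 99L,
                                     seed = 1), "zero-margin")
})

test_that("the Monte-Carlo chi-square p-value is valid under the null", {
  set.seed(67)
  probs <- c(0.4, 0.3, 0.2, 0.1)
  hits <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    a <- stats::rmultinom(1, 300, probs)[, 1]
    b <- stats::rmultinom(1, 300, probs)[, 1]
    names(a) <- names(b) <- letters[1:4]
    p <- mc_chisq_similarity(a, b, B = 99L, seed = i)$p
    if (p <= 0.05) hits <- hits + 1L
  }
  # P(p <= 0.05) <= 0.05 + Monte-Carlo slack
  expect_lte(hits / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
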