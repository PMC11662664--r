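## Figure-style summary analytics: distance classes and cis/trans fractions,
## genome-wide bin-bin contact matrices, peak-centred meta-profiles, overlap
## fractions, saturation curves, biotype/region breakdowns, and a Monte-Carlo
## chi-square test of sample similarity.

DISTANCE_CLASSES <- c("cis_lt100kb", "cis_100kb_1Mb", "cis_gt1Mb", "trans")

#' Classify an RNA-DNA interaction by genomic distance
#'
#' Interactions are `trans` when the tags lie on different chromosomes;
#' otherwise the center-to-center distance `d` classifies them as
#' `cis_lt100kb` (d <= 100 kb), `cis_100kb_1Mb` (100 kb < d <= 1 Mb) or
#' `cis_gt1Mb` (d > 1 Mb).
#'
#' @param rna_chrom,dna_chrom chromosomes of the two tags.
#' @param distance center-to-center distance in bp (ignored for trans).
#' @return character vector of class labels.
#' @export
classify_distance_vec <- function(rna_chrom, dna_chrom, distance) {
  fifelse(rna_chrom != dna_chrom, "trans",
    fifelse(distance <= 1e5, "cis_lt100kb",
      fifelse(distance <= 1e6, "cis_100kb_1Mb", "cis_gt1Mb")))
}

#' @rdname classify_distance_vec
#' @param record a one-row interaction record (list or data.frame with
#'   `rna_chrom`, `dna_chrom`, `distance`).
#' @export
classify_distance <- function(record) {
  classify_distance_vec(record$rna_chrom, record$dna_chrom, record$distance)
}

#' Distance-class summary of interaction records
#'
#' @param records interaction records with `class` (or the columns needed by
#'   [classify_distance_vec()]).
#' @return data.table with `class`, `n`, `fraction` over the four distance
#'   classes; fractions sum to 1 (all-NA when the input is empty).
#' @export
cis_trans_summary <- function(records) {
  records <- as.data.table(records)
  if (!"class" %in% names(records))
    records[, class := classify_distance_vec(rna_chrom, dna_chrom, distance)]
  out <- data.table(class = DISTANCE_CLASSES)
  tab <- records[, .N, by = class]
  out <- merge(out, tab, by = "class", all.x = TRUE, sort = FALSE)
  out[is.na(N), N := 0L]
  setnames(out, "N", "n")
  if (nrow(records) == 0L) {
    warning("empty record table: fractions undefined")
    out[, fraction := NA_real_]
  } else out[, fraction := n / sum(n)]
  out[match(DISTANCE_CLASSES, class)]
}

#' Genome-wide bin-bin interaction matrix
#'
#' Assigns every record to a (RNA bin, DNA bin) cell over a global bin index
#' concatenating chromosomes. The matrix total equals the record count.
#'
#' @param records interaction records (`rna_chrom`, `rna_center`,
#'   `dna_chrom`, `dna_center`).
#' @param bins a [genome_bins()] table defining the resolution.
#' @return a sparse [Matrix::sparseMatrix] (RNA bin x DNA bin) with
#'   `dimnames` the global `bin_id`s.
#' @export
bin_bin_matrix <- function(records, bins) {
  w <- attr(bins, "width")
  n <- nrow(bins)
  key <- setNames(bins$gbin, bins$bin_id)
  gb <- function(chrom, center) {
    id <- paste0(chrom, ":", as.integer(center %/% w))
    v <- key[id]
    assert_that(!anyNA(v), "record center outside the binned genome")
    v
  }
  i <- gb(records$rna_chrom, records$rna_center)
  j <- gb(records$dna_chrom, records$dna_center)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                       dimnames = list(bins$bin_id, bins$bin_id))
}

#' Peak-centred meta-profile of DNA tag density
#'
#' Histograms tag centers by offset from each peak center within
#' `[-flank, +flank)` in `step`-bp sub-bins and averages across peaks. Each
#' offset bin is normalised by the number of peaks whose (possibly
#' chromosome-clipped) window covers it.
#'
#' @param tags interaction records (uses `dna_chrom`/`dna_center`) or a
#'   table with `chrom` and `center`.
#' @param peaks peak intervals (chrom, start, end; 0-based half-open).
#' @param flank half-window in bp (default 3000).
#' @param step sub-bin width in bp (default 50).
#' @param chrom_sizes optional named lengths used to clip windows at
#'   chromosome edges.
#' @return class `meta_profile`: list with `profile` (data.table `offset`,
#'   `count`, `coverage`, `density`), `n_peaks`, `flank`, `step`.
#' @export
metaprofile <- function(tags, peaks, flank = 3000L, step = 50L,
                        chrom_sizes = NULL) {
  tags <- as.data.table(tags)
  if ("dna_center" %in% names(tags))
    tags <- tags[, .(chrom = dna_chrom, center = dna_center)]
  peaks <- as.data.table(peaks)
  pk_center <- center_coord(peaks$start, peaks$end)
  n_off <- as.integer(2L * flank / step)
  offsets <- (seq_len(n_off) - 1L) * step - flank

  win <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(pk_center - flank + 1L,
                                                 pk_center + flank))
  pts <- GenomicRanges::GRanges(tags$chrom,
                                IRanges::IRanges(tags$center + 1L,
                                                 tags$center + 1L))
  ov <- GenomicRanges::findOverlaps(pts, win, ignore.strand = TRUE)
  off <- tags$center[S4Vectors::queryHits(ov)] -
    pk_center[S4Vectors::subjectHits(ov)]
  bin <- as.integer((off + flank) %/% step) + 1L
  counts <- tabulate(bin, nbins = n_off)

  # per-offset coverage: how many peak windows actually reach this offset
  lo <- pmax(-flank, -pk_center)
  hi <- if (is.null(chrom_sizes)) rep(flank, length(pk_center))
        else pmin(flank, chrom_sizes[peaks$chrom] - pk_center)
  coverage <- vapply(offsets, function(o)
    sum(lo <= o & hi >= o + step), numeric(1))
  density <- ifelse(coverage > 0, counts / coverage, NA_real_)
  structure(list(profile = data.table(offset = offsets, count = counts,
                                      coverage = coverage, density = density),
                 n_peaks = nrow(peaks), flank = flank, step = step),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: %d peaks, +/-%d bp in %d-bp steps; center density %.3f\n",
              x$n_peaks, x$flank, x$step,
              x$profile$density[which.min(abs(x$profile$offset))]))
  invisible(x)
}

#' Fraction of DNA tags overlapping peaks (and the converse)
#'
#' Overlap means >= 1 shared bp between the DNA tag interval and a peak;
#' half-open adjacency does not count.
#'
#' @param dna_tags intervals (`dna_chrom`/`dna_start`/`dna_end`, or
#'   `chrom`/`start`/`end`).
#' @param peaks peak intervals (chrom, start, end).
#' @return list with `tag_fraction` (tags touching >= 1 peak) and
#'   `peak_fraction` (peaks touched by >= 1 tag).
#' @export
peak_overlap_fraction <- function(dna_tags, peaks) {
  dna_tags <- as.data.table(dna_tags)
  if ("dna_chrom" %in% names(dna_tags))
    dna_tags <- dna_tags[, .(chrom = dna_chrom, start = dna_start,
                             end = dna_end)]
  peaks <- as.data.table(peaks)
  tg <- GenomicRanges::GRanges(dna_tags$chrom,
                               IRanges::IRanges(dna_tags$start + 1L,
                                                dna_tags$end))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  list(tag_fraction = mean(IRanges::overlapsAny(tg, pk)),
       peak_fraction = mean(IRanges::overlapsAny(pk, tg)))
}

#' Saturation curves of genomic coverage and RNA species
#'
#' Subsamples records without replacement at each depth and counts distinct
#' DNA bins and distinct RNA species, repeated over seeds.
#'
#' @param records interaction records (`bin_id`, `gene_id`).
#' @param depths subsampling depths (record counts); values above the record
#'   count are capped with a warning.
#' @param n_seeds number of subsampling repetitions per depth.
#' @param seed root seed.
#' @return class `saturation_curve`: list with `draws` (per depth x seed)
#'   and `summary` (mean and sd per depth).
#' @export
saturation_curves <- function(records, depths, n_seeds = 3L, seed = 1L) {
  records <- as.data.table(records)
  n <- nrow(records)
  if (any(depths > n)) {
    warning("depths above the record count are capped at ", n)
    depths <- pmin(depths, n)
  }
  depths <- sort(unique(as.integer(depths)))
  draws <- rbindlist(lapply(seq_len(n_seeds), function(sd_i) {
    with_seed(stage_seed(seed, sd_i), {
      perm <- sample.int(n)  # one permutation: depths are nested per seed
      rbindlist(lapply(depths, function(d) {
        idx <- perm[seq_len(d)]
        data.table(depth = d, seed = sd_i,
                   n_bins = uniqueN(records$bin_id[idx]),
                   n_species = uniqueN(records$gene_id[idx][
                     !is.na(records$gene_id[idx])]))
      }))
    })
  }))
  summary <- draws[, .(bins_mean = mean(n_bins), bins_sd = sd(n_bins),
                       species_mean = mean(n_species),
                       species_sd = sd(n_species)), by = depth]
  structure(list(draws = draws, summary = summary),
            class = "saturation_curve")
}

#' Biotype x region composition of interaction records
#'
#' Fractions of gene-assigned records by (biotype, RNA region), and the
#' distance-class composition within each (biotype, region) stratum.
#'
#' @param records interaction records with `gene_biotype`, `rna_region`,
#'   `class`.
#' @return list with `composition` (fractions over all gene-assigned
#'   records) and `by_class` (distance-class fractions within each stratum).
#' @export
biotype_region_breakdown <- function(records) {
  r <- as.data.table(records)[!is.na(gene_id)]
  comp <- r[, .(n = .N), by = .(biotype = gene_biotype, region = rna_region)]
  comp[, fraction := n / sum(n)]
  byc <- r[, .(n = .N), by = .(biotype = gene_biotype, region = rna_region,
                               class = class)]
  byc[, fraction := n / sum(n), by = .(biotype, region)]
  setorder(comp, -n); setorder(byc, biotype, region, class)
  list(composition = comp[], by_class = byc[])
}

#' Monte-Carlo chi-square test of sample similarity
#'
#' Compares two per-category interaction-count profiles with the Pearson
#' chi-square statistic on the 2 x K table, and computes the p-value by
#' randomising the table under fixed row and column margins; the estimator's
#' floor is `1 / (B + 1)`.
#'
#' @param tableA,tableB named per-category counts over the same category
#'   universe.
#' @param B number of Monte-Carlo replicates (default 2000).
#' @param seed integer seed.
#' @return list with `p`, `statistic`, `df`, `B`.
#' @export
mc_chisq_similarity <- function(tableA, tableB, B = 2000L, seed = 1L) {
  assert_that(B >= 1, "B must be >= 1")
  cats <- union(names(tableA), names(tableB))
  assert_that(length(cats) >= 2 && !is.null(names(tableA)) &&
                !is.null(names(tableB)), "named category counts required")
  a <- setNames(rep(0, length(cats)), cats); a[names(tableA)] <- tableA
  b <- setNames(rep(0, length(cats)), cats); b[names(tableB)] <- tableB
  keep <- (a + b) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-margin categories dropped")
    a <- a[keep]; b <- b[keep]
  }
  tab <- rbind(A = a, B = b)
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  obs <- stat(tab)
  sims <- with_seed(seed, r2dtable(B, rowSums(tab), colSums(tab)))
  sim_stats <- vapply(sims, stat, numeric(1))
  list(p = (1 + sum(sim_stats >= obs)) / (B + 1),
       statistic = obs, df = ncol(tab) - 1L, B = as.integer(B))
}
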