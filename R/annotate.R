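## Annotation of aligned RNA/DNA tags: unique-mapping filter, center-point
## reduction, strand-aware gene assignment, fixed-width genomic binning and
## blacklist removal. All coordinates are 0-based half-open.

#' Tile a genome into fixed-width bins
#'
#' Bins tile each chromosome from 0; the final bin of a chromosome may be
#' short. The default 25-kb width matches the standard resolution used for
#' RNA-DNA contact maps.
#'
#' @param chrom_sizes named integer vector of chromosome lengths, or a path
#'   to a two-column chrom.sizes TSV.
#' @param width bin width in bp (default 25000).
#' @return data.table with `chrom`, `bin_index` (0-based within chromosome),
#'   `start`, `end`, `bin_id` (`"chrom:index"`), `gbin` (global 1-based
#'   index). Attribute `width` records the bin width.
#' @export
genome_bins <- function(chrom_sizes, width = 25000L) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  assert_that(is_count(width) && width >= 1, "width must be a positive count")
  width <- as.integer(width)
  bins <- rbindlist(lapply(names(chrom_sizes), function(cc) {
    L <- chrom_sizes[[cc]]
    n <- ceiling(L / width)
    idx <- seq_len(n) - 1L
    data.table(chrom = cc, bin_index = idx,
               start = idx * width,
               end = pmin((idx + 1L) * width, L))
  }))
  bins[, bin_id := paste0(chrom, ":", bin_index)]
  bins[, gbin := .I]
  setattr(bins, "width", width)
  bins[]
}

#' Read aligned tags from SAM or BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] and read with
#' [GenomicAlignments::readGAlignments()]. Unmapped records are dropped.
#'
#' @param path SAM or BAM file of single-end tag alignments.
#' @return data.table with `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open reference span), `strand`, `mapq`.
#' @export
read_aligned_tags <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq")))
  data.table(read_id = S4Vectors::mcols(aln)$qname,
             chrom = as.character(GenomicAlignments::seqnames(aln)),
             start = GenomicAlignments::start(aln) - 1L,
             end = GenomicAlignments::end(aln),
             strand = as.character(GenomicAlignments::strand(aln)),
             mapq = S4Vectors::mcols(aln)$mapq)
}

#' Keep uniquely mapped tags
#'
#' The unique-mapping convention follows BWA, where MAPQ 37 marks a uniquely
#' mapped read; `mapq_mode = "min"` relaxes the test to `mapq >=
#' required_mapq` for aligners with different conventions.
#'
#' @param tags an aligned-tag table ([read_aligned_tags()]).
#' @param required_mapq required mapping quality (default 37).
#' @param mapq_mode `"exact"` (`mapq == required_mapq`) or `"min"`.
#' @return the filtered table.
#' @export
filter_unique <- function(tags, required_mapq = 37L,
                          mapq_mode = c("exact", "min")) {
  mapq_mode <- match.arg(mapq_mode)
  if (mapq_mode == "exact") tags[mapq == required_mapq]
  else tags[mapq >= required_mapq]
}

#' Center coordinate of an interval
#'
#' Reduces a tag's interval to a single-nucleotide position (its floor
#' midpoint) so that a fragment cannot overlap several genes or bins.
#'
#' @param start,end 0-based half-open interval bounds (vectorised).
#' @return integer center positions, `floor((start + end) / 2)`.
#' @export
center_coord <- function(start, end) {
  assert_that(all(start < end), "invalid interval: start must be < end")
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Assign DNA tag centers to genomic bins
#'
#' @param chrom,center chromosome and 0-based center position (vectorised).
#' @param bins a [genome_bins()] table.
#' @return character vector of `bin_id`s.
#' @export
assign_dna_to_bin <- function(chrom, center, bins) {
  w <- attr(bins, "width")
  maxidx <- bins[, .(mx = max(bin_index)), by = chrom]
  mx <- setNames(maxidx$mx, maxidx$chrom)
  assert_that(all(chrom %in% names(mx)), "unknown chromosome in DNA tags")
  idx <- as.integer(center %/% w)
  assert_that(all(idx >= 0 & idx <= mx[chrom]),
              "DNA tag center outside chromosome")
  paste0(chrom, ":", idx)
}

#' Assign RNA tag centers to genes (strand-aware, unambiguous only)
#'
#' A candidate gene must contain the tag center and lie on the tag's strand.
#' Exactly one candidate gives an assignment (region = exon if the center
#' falls in any exon of that gene, else intron); zero candidates are
#' `unassigned`; several same-strand candidates are `ambiguous`.
#'
#' @param chrom,center,strand vectors describing the tag centers.
#' @param annotation a `gene_annotation`.
#' @return data.table with `gene_id`, `biotype`, `region`, `status`
#'   (`assigned` / `unassigned` / `ambiguous`), aligned with the input.
#' @export
assign_rna_to_gene <- function(chrom, center, strand, annotation) {
  genes <- annotation$genes
  pts <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(center + 1L, center + 1L),
                                strand = strand)
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(pts, gg, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  nhit <- tabulate(qh, nbins = length(pts))
  out <- data.table(gene_id = NA_character_, biotype = NA_character_,
                    region = NA_character_,
                    status = ifelse(nhit == 0L, "unassigned",
                                    ifelse(nhit > 1L, "ambiguous", "assigned")))
  one <- which(nhit == 1L)
  hit1 <- sh[match(one, qh)]
  out[one, `:=`(gene_id = genes$gene_id[hit1],
                biotype = genes$biotype[hit1])]
  # exon/intron call for assigned tags
  ex <- annotation$exons
  if (length(one)) {
    exg <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start + 1L, ex$end))
    p1 <- GenomicRanges::GRanges(chrom[one],
                                 IRanges::IRanges(center[one] + 1L,
                                                  center[one] + 1L))
    ove <- GenomicRanges::findOverlaps(p1, exg, ignore.strand = TRUE)
    same_gene <- ex$gene_id[S4Vectors::subjectHits(ove)] ==
      out$gene_id[one][S4Vectors::queryHits(ove)]
    in_exon <- unique(S4Vectors::queryHits(ove)[same_gene])
    reg <- rep("intron", length(one))
    reg[in_exon] <- "exon"
    out[one, region := reg]
  }
  out[]
}

#' Remove records whose DNA tag overlaps a blacklist region
#'
#' A record is removed when its DNA tag interval overlaps any blacklist
#' interval by at least 1 bp (half-open adjacency is not an overlap).
#'
#' @param records an interaction-record table with `dna_chrom`, `dna_start`,
#'   `dna_end`.
#' @param blacklist data.frame/data.table (chrom, start, end; 0-based
#'   half-open), a GRanges, or a BED path.
#' @return the filtered record table; attribute `n_blacklisted` counts the
#'   removed records.
#' @export
blacklist_filter <- function(records, blacklist) {
  if (is.null(blacklist)) return(records)
  if (is.character(blacklist) && length(blacklist) == 1L)
    blacklist <- rtracklayer::import(blacklist, format = "bed")
  if (methods::is(blacklist, "GRanges")) {
    bl <- blacklist
  } else {
    blacklist <- as.data.table(blacklist)
    if (nrow(blacklist) == 0L) return(records)
    bl <- GenomicRanges::GRanges(blacklist$chrom,
                                 IRanges::IRanges(blacklist$start + 1L,
                                                  blacklist$end))
  }
  if (length(bl) == 0L || nrow(records) == 0L) return(records)
  tags <- GenomicRanges::GRanges(records$dna_chrom,
                                 IRanges::IRanges(records$dna_start + 1L,
                                                  records$dna_end))
  hit <- IRanges::overlapsAny(tags, bl, ignore.strand = TRUE)
  out <- records[!hit]
  setattr(out, "n_blacklisted", sum(hit))
  out
}

#' Annotate aligned tag pairs into interaction records
#'
#' Runs the full annotation chain: unique-mapping filter on both sides (a
#' read survives only if both its RNA and DNA tags survive), center-point
#' reduction, strand-aware gene assignment for RNA tags, bin assignment for
#' DNA tags (strand discarded), optional blacklist removal, and distance
#' classification. Ambiguous (multi-gene) RNA tags are dropped from the pair
#' table; unassigned-gene records are retained (they still contribute to
#' coordinate-level outputs) but are excluded from gene-level statistics.
#'
#' @param rna_tags,dna_tags aligned-tag tables or SAM/BAM paths.
#' @param annotation a `gene_annotation`.
#' @param bins a [genome_bins()] table.
#' @param blacklist optional blacklist (see [blacklist_filter()]).
#' @param required_mapq,mapq_mode unique-mapping filter settings.
#' @return interaction-record data.table with one row per surviving read:
#'   `read_id`, `rna_chrom`, `rna_center`, `rna_strand`, `gene_id`,
#'   `gene_biotype`, `rna_region`, `dna_chrom`, `dna_start`, `dna_end`,
#'   `dna_center`, `bin_id`, `distance` (NA for trans), `class`. Attribute
#'   `drop_counts` logs per-reason drops.
#' @export
annotate_interactions <- function(rna_tags, dna_tags, annotation, bins,
                                  blacklist = NULL, required_mapq = 37L,
                                  mapq_mode = c("exact", "min")) {
  mapq_mode <- match.arg(mapq_mode)
  if (is.character(rna_tags)) rna_tags <- read_aligned_tags(rna_tags)
  if (is.character(dna_tags)) dna_tags <- read_aligned_tags(dna_tags)
  rna_tags <- as.data.table(rna_tags); dna_tags <- as.data.table(dna_tags)
  n_in <- length(union(rna_tags$read_id, dna_tags$read_id))

  rna <- filter_unique(rna_tags, required_mapq, mapq_mode)
  dna <- filter_unique(dna_tags, required_mapq, mapq_mode)
  m <- merge(rna[, .(read_id, rna_chrom = chrom, rna_start = start,
                     rna_end = end, rna_strand = strand)],
             dna[, .(read_id, dna_chrom = chrom, dna_start = start,
                     dna_end = end)],
             by = "read_id")
  n_mapq <- n_in - nrow(m)

  if (nrow(m) == 0L) {
    out <- empty_records()
    setattr(out, "drop_counts",
            c(input = n_in, mapq_or_unpaired = n_mapq, ambiguous_gene = 0L,
              blacklisted = 0L, kept = 0L))
    return(out)
  }

  m[, rna_center := center_coord(rna_start, rna_end)]
  m[, dna_center := center_coord(dna_start, dna_end)]
  m[, bin_id := assign_dna_to_bin(dna_chrom, dna_center, bins)]
  ga <- assign_rna_to_gene(m$rna_chrom, m$rna_center, m$rna_strand, annotation)
  m[, `:=`(gene_id = ga$gene_id, gene_biotype = ga$biotype,
           rna_region = ga$region, gene_status = ga$status)]
  n_amb <- sum(ga$status == "ambiguous")
  m <- m[gene_status != "ambiguous"]

  pre_bl <- nrow(m)
  m <- blacklist_filter(m, blacklist)
  n_bl <- pre_bl - nrow(m)

  m[, distance := ifelse(rna_chrom == dna_chrom,
                         abs(dna_center - rna_center), NA_integer_)]
  m[, class := classify_distance_vec(rna_chrom, dna_chrom, distance)]
  out <- m[, .(read_id, rna_chrom, rna_center, rna_strand, gene_id,
               gene_biotype, rna_region, dna_chrom, dna_start, dna_end,
               dna_center, bin_id, distance, class)]
  setattr(out, "drop_counts",
          c(input = n_in, mapq_or_unpaired = n_mapq, ambiguous_gene = n_amb,
            blacklisted = n_bl, kept = nrow(out)))
  out
}

#' @noRd
empty_records <- function() {
  data.table(read_id = character(), rna_chrom = character(),
             rna_center = integer(), rna_strand = character(),
             gene_id = character(), gene_biotype = character(),
             rna_region = character(), dna_chrom = character(),
             dna_start = integer(), dna_end = integer(),
             dna_center = integer(), bin_id = character(),
             distance = integer(), class = character())
}

#' Aggregate interaction records into a (gene, bin) count table
#'
#' Records with an unassigned gene are excluded from the count matrix but
#' remain in the record table.
#'
#' @param records an [annotate_interactions()] table.
#' @return list with `records` (unchanged) and `counts` (data.table
#'   `gene_id`, `bin_id`, `count`); `sum(counts$count)` equals the number of
#'   gene-assigned records.
#' @export
build_pairs <- function(records) {
  counts <- records[!is.na(gene_id), .(count = .N), by = .(gene_id, bin_id)]
  setorder(counts, gene_id, bin_id)
  list(records = records, counts = counts[])
}

#' Write interaction records as TSV
#' @param records an interaction-record table.
#' @param path output path.
#' @export
write_pairs <- function(records, path) {
  fwrite(records, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read an interaction-record TSV written by [write_pairs()]
#' @param path input path.
#' @return interaction-record data.table.
#' @export
read_pairs <- function(path) {
  fread(path, sep = "\t", na.strings = "NA",
        colClasses = list(character = "gene_id"))
}
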