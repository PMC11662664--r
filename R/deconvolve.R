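## Chimeric-read deconvolution: locate the internal bridge adaptor in each
## read and split it into an RNA tag and a DNA tag, with length QC mirroring
## the 25-27 nt fragments produced by EcoP15I digestion.

#' Default (placeholder) bridge adaptor sequence
#'
#' The exact adaptor chemistry is protocol-specific; this fixed arbitrary
#' sequence is long enough (20 nt) that chance matches in random sequence are
#' negligible. Override it in [bridge_adaptor()] for real libraries.
#' @export
DEFAULT_ADAPTOR <- "CTGCTGACGAGTCCAGCTAC"

#' Bridge adaptor specification
#'
#' Describes the internal adaptor joining the RNA and DNA tags, the allowed
#' Hamming mismatch budget when locating it, which side of the adaptor holds
#' the RNA tag, and the accepted tag-length window.
#'
#' @param sequence adaptor DNA sequence (A/C/G/T, non-empty).
#' @param max_mismatches maximum Hamming distance when matching (no indels).
#' @param rna_side `"five_prime"` (RNA tag upstream of the adaptor, the
#'   default chimera layout) or `"three_prime"`.
#' @param min_tag_len,max_tag_len accepted tag lengths in nt (default 25/27).
#' @return an object of class `bridge_adaptor`.
#' @export
bridge_adaptor <- function(sequence = DEFAULT_ADAPTOR, max_mismatches = 0L,
                           rna_side = c("five_prime", "three_prime"),
                           min_tag_len = 25L, max_tag_len = 27L) {
  rna_side <- match.arg(rna_side)
  assert_that(nchar(sequence) >= 1 && dna_alphabet_ok(sequence),
              "adaptor sequence must be non-empty A/C/G/T")
  assert_that(min_tag_len <= max_tag_len, "min_tag_len must be <= max_tag_len")
  structure(list(sequence = toupper(sequence),
                 max_mismatches = as.integer(max_mismatches),
                 rna_side = rna_side,
                 min_tag_len = as.integer(min_tag_len),
                 max_tag_len = as.integer(max_tag_len)),
            class = "bridge_adaptor")
}

#' @export
print.bridge_adaptor <- function(x, ...) {
  cat(sprintf("bridge_adaptor %s (%d nt, <=%d mismatches, RNA %s, tags %d-%d nt)\n",
              x$sequence, nchar(x$sequence), x$max_mismatches,
              sub("_", " ", x$rna_side), x$min_tag_len, x$max_tag_len))
  invisible(x)
}

#' Locate the bridge adaptor in one read
#'
#' Finds the leftmost offset at which the adaptor matches the read with
#' Hamming distance at most `spec$max_mismatches`. Indels are not considered:
#' the library design sequences the entire adaptor, so a fixed-length match
#' is expected.
#'
#' @param read_seq a single read sequence.
#' @param spec a [bridge_adaptor()].
#' @return list with `offset` (0-based leftmost match start, or `NA` if not
#'   found) and `n_hits` (number of acceptable offsets; > 1 flags ambiguity).
#' @export
locate_adaptor <- function(read_seq, spec) {
  assert_that(length(read_seq) == 1L, "locate_adaptor takes a single read")
  if (spec$max_mismatches == 0L) {
    hits <- gregexpr(spec$sequence, read_seq, fixed = TRUE)[[1]]
    if (hits[1] < 0) return(list(offset = NA_integer_, n_hits = 0L))
    return(list(offset = hits[1] - 1L, n_hits = length(hits)))
  }
  h <- adaptor_scan(read_seq, spec)
  list(offset = h$offset, n_hits = h$n_hits)
}

# Leftmost 0-based match offset and hit count per read (vectorised). With a
# zero mismatch budget a C-level fixed-string search is used and n_hits is
# capped at 2 (enough for the multi-hit flag).
#' @noRd
adaptor_scan <- function(seqs, spec) {
  if (spec$max_mismatches == 0L) {
    off1 <- regexpr(spec$sequence, seqs, fixed = TRUE)
    has <- off1 > 0L
    n_hits <- integer(length(seqs))
    if (any(has)) {
      rest <- substr(seqs[has], off1[has] + 1L, nchar(seqs[has]))
      again <- regexpr(spec$sequence, rest, fixed = TRUE) > 0L
      n_hits[has] <- ifelse(again, 2L, 1L)
    }
    return(list(offset = ifelse(has, as.integer(off1) - 1L, NA_integer_),
                n_hits = n_hits))
  }
  subj <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(spec$sequence, subj,
                                 max.mismatch = spec$max_mismatches,
                                 fixed = TRUE)
  starts <- unlist(IRanges::start(m), use.names = FALSE)
  n_hits <- S4Vectors::elementNROWS(m)
  first <- cumsum(c(1L, head(n_hits, -1L)))  # index of each read's 1st hit
  offset <- rep(NA_integer_, length(seqs))
  has <- n_hits > 0L
  offset[has] <- starts[first[has]] - 1L
  list(offset = offset, n_hits = as.integer(n_hits))
}

#' Split one read into a tag pair at a known adaptor offset
#'
#' @param read list or one-row data.frame with `read_id`, `seq`, `qual`
#'   (qual may be omitted).
#' @param offset 0-based adaptor offset within the read.
#' @param spec a [bridge_adaptor()].
#' @return a one-row tag-pair data.table (see [deconvolve()]).
#' @export
split_chimera <- function(read, offset, spec) {
  assert_that(!is.na(offset) && offset >= 0 &&
                offset + nchar(spec$sequence) <= nchar(read$seq),
              "invalid adaptor offset")
  tp <- split_at(read$read_id, read$seq,
                 read$qual %||% strrep("I", nchar(read$seq)),
                 offset, rep(1L, 1L), spec)
  tp
}

# Vectorised splitter: offsets is 0-based (NA = adaptor not found).
#' @noRd
split_at <- function(read_id, seq, qual, offset, n_hits, spec) {
  A <- nchar(spec$sequence)
  found <- !is.na(offset)
  len <- nchar(seq)
  lseq <- ifelse(found, substr(seq, 1L, ifelse(found, offset, 0L)), "")
  lqual <- ifelse(found, substr(qual, 1L, ifelse(found, offset, 0L)), "")
  rseq <- ifelse(found, substr(seq, offset + A + 1L, len), "")
  rqual <- ifelse(found, substr(qual, offset + A + 1L, len), "")
  # trim to max_tag_len from the adaptor-proximal end: the left tag's
  # proximal end is its right end, the right tag's is its left end
  keep_tail <- function(s) substr(s, pmax(nchar(s) - spec$max_tag_len + 1L, 1L),
                                  nchar(s))
  keep_head <- function(s) substr(s, 1L, pmin(nchar(s), spec$max_tag_len))
  lseq <- keep_tail(lseq); lqual <- keep_tail(lqual)
  rseq <- keep_head(rseq); rqual <- keep_head(rqual)
  if (spec$rna_side == "five_prime") {
    rna_seq <- lseq; rna_qual <- lqual; dna_seq <- rseq; dna_qual <- rqual
  } else {
    rna_seq <- rseq; rna_qual <- rqual; dna_seq <- lseq; dna_qual <- lqual
  }
  inlen <- function(s) nchar(s) >= spec$min_tag_len & nchar(s) <= spec$max_tag_len
  tp <- data.table(read_id = read_id,
                   rna_seq = rna_seq, rna_qual = rna_qual,
                   dna_seq = dna_seq, dna_qual = dna_qual,
                   adaptor_offset = offset,
                   adaptor_found = found,
                   multi_hit = n_hits > 1L,
                   length_pass = found & inlen(rna_seq) & inlen(dna_seq))
  setattr(tp, "rna_side", spec$rna_side)
  tp
}

#' Deconvolve chimeric reads into RNA/DNA tag pairs
#'
#' Locates the bridge adaptor in every read (leftmost Hamming match within
#' the mismatch budget; multiple acceptable offsets flag the read
#' `multi_hit`), splits each read at the adaptor and trims both tags to
#' `max_tag_len` from the adaptor-proximal end. Reads without an adaptor are
#' retained with `adaptor_found = FALSE`. Output order follows input order.
#'
#' @param reads a data.table/data.frame with `read_id`, `seq` and optionally
#'   `qual`; a `sim_reads` object; or a FASTQ path.
#' @param spec a [bridge_adaptor()].
#' @return a tag-pair data.table with columns `read_id`, `rna_seq`,
#'   `rna_qual`, `dna_seq`, `dna_qual`, `adaptor_offset` (0-based),
#'   `adaptor_found`, `multi_hit`, `length_pass`.
#' @export
deconvolve <- function(reads, spec = bridge_adaptor()) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  reads <- as.data.table(reads)
  if (!"qual" %in% names(reads)) reads[, qual := strrep("I", nchar(seq))]
  if (nrow(reads) == 0L)
    return(split_at(character(0), character(0), character(0),
                    integer(0), integer(0), spec))
  h <- adaptor_scan(reads$seq, spec)
  split_at(reads$read_id, reads$seq, reads$qual, h$offset, h$n_hits, spec)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ (optionally gzipped) path.
#' @return data.table with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.table(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write deconvolved tags to paired FASTQ files
#'
#' Only tag pairs with `adaptor_found` and `length_pass` are written; the two
#' files share read ids.
#'
#' @param tag_pairs a tag-pair table from [deconvolve()].
#' @param rna_path,dna_path output FASTQ paths.
#' @return invisibly, the number of pairs written.
#' @export
write_tag_fastq <- function(tag_pairs, rna_path, dna_path) {
  tp <- tag_pairs[adaptor_found & length_pass]
  wr <- function(seqs, quals, ids, path) {
    d <- Biostrings::DNAStringSet(seqs); names(d) <- ids
    Biostrings::writeXStringSet(d, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(tp$rna_seq, tp$rna_qual, tp$read_id, rna_path)
  wr(tp$dna_seq, tp$dna_qual, tp$read_id, dna_path)
  invisible(nrow(tp))
}

#' Tag-level quality report
#'
#' Summarises Phred qualities, tag lengths and per-position base composition
#' for the found tag pairs. Purely descriptive; nothing is filtered.
#'
#' @param tag_pairs a tag-pair table.
#' @param phred_min threshold for the reported high-quality base fraction
#'   (default 25).
#' @return list with `n_pairs`, `adaptor_found_rate`, `frac_phred_ge` (per
#'   tag side), `mean_phred_by_pos`, `length_table`, `base_composition`
#'   (per-position base fractions).
#' @export
qc_report <- function(tag_pairs, phred_min = 25L) {
  if (nrow(tag_pairs) == 0L) {
    warning("empty tag-pair table: empty QC report")
    return(list(n_pairs = 0L, adaptor_found_rate = NA_real_))
  }
  tp <- tag_pairs[adaptor_found == TRUE]
  side <- function(seqs, quals) {
    q <- lapply(quals, function(s) utf8ToInt(s) - 33L)
    maxlen <- max(lengths(q), 1L)
    qm <- vapply(q, function(v) c(v, rep(NA_integer_, maxlen - length(v))),
                 integer(maxlen))
    qm <- matrix(qm, nrow = maxlen)
    comp <- base_composition(seqs, maxlen)
    list(frac_phred_ge = mean(unlist(q) >= phred_min),
         mean_phred_by_pos = rowMeans(qm, na.rm = TRUE),
         length_table = table(nchar(seqs)),
         base_composition = comp)
  }
  list(n_pairs = nrow(tag_pairs),
       adaptor_found_rate = mean(tag_pairs$adaptor_found),
       length_pass_rate = mean(tp$length_pass),
       rna = side(tp$rna_seq, tp$rna_qual),
       dna = side(tp$dna_seq, tp$dna_qual))
}

#' @noRd
base_composition <- function(seqs, maxlen) {
  ch <- vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    c(v, rep(NA_character_, maxlen - length(v)))
  }, character(maxlen))
  ch <- matrix(ch, nrow = maxlen)
  t(apply(ch, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(c(A = NA_real_, C = NA_real_,
                               G = NA_real_, T = NA_real_))
    tab <- table(factor(row, levels = c("A", "C", "G", "T")))
    setNames(as.numeric(tab) / length(row), c("A", "C", "G", "T"))
  }))
}

#' Truncate tags to a fixed length
#'
#' Truncates both tags to `target_len` nt from the adaptor-proximal end,
#' reproducing in silico tag-shortening experiments (e.g. 27 -> 20 nt). Tags
#' already shorter than `target_len` are left unchanged and flagged.
#'
#' @param tag_pairs a tag-pair table.
#' @param target_len target tag length in nt (>= 1).
#' @return the tag-pair table with truncated tags and a logical `trim_short`
#'   column flagging tags that were too short to truncate.
#' @export
trim_tags <- function(tag_pairs, target_len) {
  assert_that(is_count(target_len) && target_len >= 1,
              "target_len must be >= 1")
  rna_side <- attr(tag_pairs, "rna_side") %||% "five_prime"
  tp <- copy(tag_pairs)
  tail_trim <- function(s) substr(s, nchar(s) - target_len + 1L, nchar(s))
  head_trim <- function(s) substr(s, 1L, target_len)
  # adaptor-proximal end: right end for the left-hand tag, left end for the
  # right-hand tag
  if (rna_side == "five_prime") {
    rna_fun <- tail_trim; dna_fun <- head_trim
  } else {
    rna_fun <- head_trim; dna_fun <- tail_trim
  }
  short <- nchar(tp$rna_seq) < target_len | nchar(tp$dna_seq) < target_len
  ok <- !short
  tp[ok, `:=`(rna_seq = rna_fun(rna_seq), rna_qual = rna_fun(rna_qual),
              dna_seq = dna_fun(dna_seq), dna_qual = dna_fun(dna_qual))]
  tp[, trim_short := short]
  setattr(tp, "rna_side", rna_side)
  tp[]
}

#' Optional rRNA-style sequence blocklist filter
#'
#' Drops tag pairs whose RNA tag occurs verbatim within any blocklist
#' sequence (a lightweight stand-in for alignment-based contaminant removal).
#'
#' @param tag_pairs a tag-pair table.
#' @param blocklist character vector of contaminant sequences.
#' @return the filtered tag-pair table.
#' @export
filter_blocklist <- function(tag_pairs, blocklist) {
  if (length(blocklist) == 0L || nrow(tag_pairs) == 0L) return(tag_pairs)
  subject <- paste(toupper(blocklist), collapse = "N")
  hit <- vapply(tag_pairs$rna_seq, function(s)
    nchar(s) > 0 && grepl(s, subject, fixed = TRUE), logical(1))
  tag_pairs[!hit]
}
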