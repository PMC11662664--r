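# Small shared fixtures, built in code at test time.

toy_world <- function(seed = 11L, n_chroms = 3L,
                      lengths = c(4e5, 4e5, 3e5), n_genes = 80L) {
  g <- sim_genome(n_chroms, lengths, seed = seed)
  ann <- sim_annotation(g, n_genes, seed = seed + 1L)
  bins <- genome_bins(g$chrom_sizes, 25000L)
  peaks <- sim_peaks(g, n_peaks = 20L, width = 2000L, seed = seed + 2L)
  list(genome = g, annotation = ann, bins = bins, peaks = peaks)
}

# one read built by construction: rna | adaptor | dna
chimera_read <- function(rna, dna, adaptor = DEFAULT_ADAPTOR,
                         id = "r1", qual_char = "I") {
  seq <- paste0(rna, adaptor, dna)
  data.table::data.table(read_id = id, seq = seq,
                         qual = strrep(qual_char, nchar(seq)))
}

random_dna <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal in-memory aligned-tag table
tag_table <- function(read_id, chrom, start, end, strand = "+", mapq = 37L) {
  data.table::data.table(read_id = read_id, chrom = chrom, start = start,
                         end = end, strand = strand, mapq = mapq)
}
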