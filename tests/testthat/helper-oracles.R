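# Independent brute-force oracles, deliberately naive implementations.

# Upper-tail hypergeometric by full enumeration of all C(M, n) draws:
# universe of M items of which K are "special"; draw n; P(shared >= k).
hyper_tail_enumerate <- function(M, K, n, k) {
  draws <- combn(M, n)
  special <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= k)
}

# Longest ORF (in codons, ATG included, stop excluded) by naive scanning of
# every ATG position in every forward frame.
longest_orf_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (start in seq_len(max(0, n - 2))) {
    if (substr(seq, start, start + 2) != "ATG") next
    pos <- start
    len <- 0L
    while (pos + 2 <= n) {
      codon <- substr(seq, pos, pos + 2)
      if (codon %in% stops) {
        best <- max(best, len)
        break
      }
      len <- len + 1L
      pos <- pos + 3L
    }
  }
  best
}

# Compact constructor for exon GRanges used across geometry tests.
exons_gr <- function(chrom, starts, ends, strand, transcript_id,
                     gene_id = transcript_id) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strand, transcript_id = transcript_id,
                         gene_id = gene_id)
}

# A three-exon gene spanning [start, start+18999], matching the simulated
# gene geometry.
gene_gr <- function(start, strand = "+", id = "geneA", chrom = "chr1") {
  exons_gr(chrom, start + c(0, 9000, 18000), start + c(999, 9999, 18999),
           strand, paste0(id, ".t1"), id)
}

# Random nucleotide sequence without ATG (so no ORF can start).
random_no_atg <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}
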