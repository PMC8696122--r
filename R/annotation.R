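#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

## Annotation is carried as exon-level GRanges (1-based inclusive, the
## Bioconductor convention) with mcols transcript_id and gene_id. Transcript
## spans are the range over a transcript's exons.

#' Read exon annotation from a GTF/GFF file
#'
#' Imports a GTF/GFF3 file and returns the exon records. The attribute keys
#' `gene_id` and `transcript_id` are required.
#'
#' @param path path to a GTF or GFF3 file.
#' @return a `GRanges` of exons with `transcript_id` and `gene_id` metadata
#'   columns.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (is.null(gr$transcript_id) || is.null(gr$gene_id))
    stop("GTF must carry gene_id and transcript_id attributes")
  gr
}

#' Write exon annotation to GTF
#'
#' @param exons exon `GRanges` with `transcript_id` and `gene_id` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(exons, path) {
  exons$type <- "exon"
  exons$source <- "lncnet"
  rtracklayer::export(exons, path, format = "gtf")
  invisible(path)
}

transcript_spans <- function(exons) {
  if (length(exons) == 0) {
    return(GRanges())
  }
  spl <- split(exons, exons$transcript_id)
  sp <- unlist(range(spl))
  sp$transcript_id <- names(spl)
  gid <- vapply(spl, function(g) g$gene_id[1], character(1))
  sp$gene_id <- gid
  names(sp) <- NULL
  sp
}

gene_spans <- function(gene_exons) {
  if (length(gene_exons) == 0) return(GRanges())
  spl <- split(gene_exons, gene_exons$gene_id)
  sp <- unlist(range(spl))
  sp$gene_id <- names(spl)
  names(sp) <- NULL
  sp
}

validate_transcripts <- function(exons) {
  spl <- split(exons, exons$transcript_id)
  for (tid in names(spl)) {
    g <- sort(spl[[tid]])
    if (any(BiocGenerics::end(g) < BiocGenerics::start(g)))
      stop("malformed exon (end < start) in transcript ", tid)
    if (length(g) > 1 &&
        any(BiocGenerics::start(g[-1]) <=
              BiocGenerics::end(g[-length(g)])))
      stop("overlapping exons in transcript ", tid)
  }
  invisible(TRUE)
}

#' Filter candidate novel transcripts
#'
#' Keeps transcripts with total exonic length of at least 200 bp and at least
#' two exons, the standard structural filter for novel lncRNA candidates.
#'
#' @param exons exon `GRanges` with a `transcript_id` column.
#' @param min_length minimum summed exon length in bp (default 200).
#' @param min_exons minimum exon count (default 2).
#' @return list with `kept` (exon `GRanges` of passing transcripts) and
#'   `rejected` (data.frame of transcript_id and the rule that failed).
#' @export
filter_novel_transcripts <- function(exons, min_length = 200, min_exons = 2) {
  validate_transcripts(exons)
  tid <- as.character(exons$transcript_id)
  len <- tapply(BiocGenerics::width(exons), tid, sum)
  nex <- tapply(tid, tid, length)
  ids <- names(len)
  fail_len <- len < min_length
  fail_ex <- nex < min_exons
  reason <- ifelse(fail_ex & fail_len, "exon_count;length",
                   ifelse(fail_ex, "exon_count",
                          ifelse(fail_len, "length", NA_character_)))
  rejected <- data.frame(transcript_id = ids[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE, row.names = NULL)
  keep_ids <- ids[is.na(reason)]
  list(kept = exons[tid %in% keep_ids], rejected = rejected)
}

#' Coding-potential consensus
#'
#' A transcript is a lncRNA candidate only when all three coding-potential
#' assessors (two ab initio predictors and a protein-database search) agree
#' that it lacks coding potential: the candidate set is the intersection of
#' the three noncoding sets.
#'
#' @param calls data.frame with columns `transcript_id` and three logical
#'   verdict columns (TRUE = coding evidence); default column names
#'   `cpc_coding`, `cnci_coding`, `protein_hit`.
#' @param verdict_cols names of the three verdict columns.
#' @return character vector of lncRNA-candidate transcript ids.
#' @export
consensus_noncoding <- function(calls,
                                verdict_cols = c("cpc_coding", "cnci_coding",
                                                 "protein_hit")) {
  if (length(verdict_cols) != 3)
    stop("exactly three verdicts are required per transcript")
  missing_cols <- setdiff(verdict_cols, colnames(calls))
  if (length(missing_cols))
    stop("missing verdict column(s): ", paste(missing_cols, collapse = ", "))
  v <- as.matrix(calls[, verdict_cols])
  if (anyNA(v)) {
    bad <- calls$transcript_id[apply(v, 1, anyNA)]
    stop("missing verdict for transcript(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  as.character(calls$transcript_id[rowSums(v) == 0])
}

#' Simple ORF-based coding heuristic
#'
#' A built-in stand-in coding-potential assessor: a sequence is called coding
#' when its longest open reading frame (ATG to stop, any of the three forward
#' frames) spans at least `min_codons` codons (ATG included, stop excluded).
#'
#' @param seq nucleotide string (A/C/G/T/N, case-insensitive).
#' @param min_codons ORF length threshold in codons (default 100).
#' @return logical, TRUE when the sequence is called coding.
#' @export
orf_heuristic <- function(seq, min_codons = 100) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  n <- nchar(seq)
  longest <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0 || starts[1] > n - 2L) next
    codons <- substring(seq, starts, starts + 2L)
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        longest <- max(longest, i - open_at)
        open_at <- NA_integer_
      }
    }
  }
  longest >= min_codons
}

#' Classify lncRNAs by genomic position
#'
#' Assigns each lncRNA transcript exactly one positional category relative to
#' a gene annotation, testing rules in a fixed priority order:
#' \describe{
#'   \item{antisense}{at least 1 bp of exonic overlap with a gene on the
#'     opposite strand;}
#'   \item{sense_overlapping}{exonic overlap with a gene on the same strand;}
#'   \item{intronic}{transcript span entirely inside a single intron of a
#'     gene (either strand), with no exonic overlap;}
#'   \item{bidirectional}{non-overlapping, transcription start site within
#'     `bidirectional_window` bp of a gene's TSS on the opposite (divergent)
#'     strand;}
#'   \item{intergenic}{gap to the nearest gene greater than
#'     `intergenic_min_distance` bp (or no gene on the chromosome);}
#'   \item{other}{everything remaining (near a gene but none of the above).}
#' }
#'
#' @param lnc_exons exon `GRanges` of lncRNA transcripts (`transcript_id`).
#' @param gene_exons exon `GRanges` of annotated genes (`gene_id`).
#' @param bidirectional_window TSS distance for divergent promoters (bp).
#' @param intergenic_min_distance gap beyond which a locus is intergenic (bp).
#' @return data.frame: transcript_id, category, nearest_gene, distance_bp.
#' @export
classify_lncrna <- function(lnc_exons, gene_exons,
                            bidirectional_window = 1000,
                            intergenic_min_distance = 5000) {
  lnc_sp <- transcript_spans(lnc_exons)
  g_sp <- gene_spans(gene_exons)
  n <- length(lnc_sp)
  category <- rep("other", n)
  nearest_gene <- rep(NA_character_, n)
  distance_bp <- rep(NA_integer_, n)
  if (n == 0) {
    return(data.frame(transcript_id = character(), category = character(),
                      nearest_gene = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  if (length(g_sp) == 0) {
    warning("no genes in annotation; all lncRNAs classified intergenic")
    return(data.frame(transcript_id = lnc_sp$transcript_id,
                      category = "intergenic",
                      nearest_gene = NA_character_,
                      distance_bp = NA_integer_, stringsAsFactors = FALSE))
  }

  # exonic overlap, strand-resolved
  anti_hits <- findOverlaps(invertStrand(lnc_exons), gene_exons,
                            ignore.strand = FALSE)
  sense_hits <- findOverlaps(lnc_exons, gene_exons, ignore.strand = FALSE)
  anti_t <- unique(as.character(lnc_exons$transcript_id[queryHits(anti_hits)]))
  sense_t <- unique(as.character(lnc_exons$transcript_id[queryHits(sense_hits)]))

  tid <- as.character(lnc_sp$transcript_id)
  is_anti <- tid %in% anti_t
  is_sense <- tid %in% sense_t & !is_anti

  # intronic: span within a gene span, no exonic overlap with any gene
  within_hits <- findOverlaps(lnc_sp, g_sp, type = "within",
                              ignore.strand = TRUE)
  any_exonic <- tid %in% union(anti_t, sense_t)
  is_intronic <- rep(FALSE, n)
  is_intronic[unique(queryHits(within_hits))] <- TRUE
  is_intronic <- is_intronic & !any_exonic

  # bidirectional: divergent TSS within window, non-overlapping spans
  tss_pos <- function(gr) {
    ifelse(as.character(BiocGenerics::strand(gr)) == "-",
           BiocGenerics::end(gr), BiocGenerics::start(gr))
  }
  lnc_tss <- tss_pos(lnc_sp)
  g_tss <- tss_pos(g_sp)
  overlap_any <- overlapsAny(lnc_sp, g_sp, ignore.strand = TRUE)
  is_bidir <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (overlap_any[i]) next
    same_chr <- as.character(seqnames(g_sp)) == as.character(seqnames(lnc_sp[i]))
    opp <- as.character(BiocGenerics::strand(g_sp)) !=
      as.character(BiocGenerics::strand(lnc_sp[i]))
    cand <- which(same_chr & opp &
                    abs(g_tss - lnc_tss[i]) <= bidirectional_window)
    if (length(cand)) is_bidir[i] <- TRUE
  }

  # nearest gene and gap distance (strand-blind)
  dtn <- distanceToNearest(lnc_sp, g_sp, ignore.strand = TRUE)
  nearest_gene[queryHits(dtn)] <- g_sp$gene_id[subjectHits(dtn)]
  distance_bp[queryHits(dtn)] <- mcols(dtn)$distance

  is_intergenic <- !is.na(distance_bp) & distance_bp > intergenic_min_distance
  no_gene_on_chr <- is.na(distance_bp)

  category[is_intergenic | no_gene_on_chr] <- "intergenic"
  category[is_bidir] <- "bidirectional"
  category[is_intronic] <- "intronic"
  category[is_sense] <- "sense_overlapping"
  category[is_anti] <- "antisense"

  data.frame(transcript_id = tid, category = category,
             nearest_gene = nearest_gene, distance_bp = distance_bp,
             stringsAsFactors = FALSE)
}

#' Summarize lncRNA category counts
#'
#' Tabulates positional categories and reports percentages of the total,
#' rounded half-up to one decimal (the convention of published category
#' tables). Accepts either a classification data.frame (from
#' [classify_lncrna()]) or a named count vector.
#'
#' @param x data.frame with a `category` column, or a named integer vector of
#'   per-category counts.
#' @return data.frame: category, count, percentage (NA when total is 0).
#' @export
summarize_categories <- function(x) {
  if (is.data.frame(x)) {
    counts <- table(x$category)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- x
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 1)
         else rep(NA_real_, length(counts))
  data.frame(category = names(counts), count = as.integer(counts),
             percentage = as.numeric(pct), stringsAsFactors = FALSE,
             row.names = NULL)
}
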