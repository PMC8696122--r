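#' Antisense lncRNA-gene pairs
#'
#' A lncRNA is paired with a gene as its antisense target when at least 1 bp
#' of exonic sequence overlaps the gene's exons on the opposite strand;
#' evidence is the total overlapping exonic length.
#'
#' @param lnc_exons exon `GRanges` of lncRNAs (`transcript_id`).
#' @param gene_exons exon `GRanges` of genes (`gene_id`).
#' @return data.frame: lncrna_id, gene_id, mechanism, evidence, sign.
#' @export
antisense_pairs <- function(lnc_exons, gene_exons) {
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      mechanism = character(), evidence = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (length(lnc_exons) == 0 || length(gene_exons) == 0) return(empty)
  hits <- findOverlaps(invertStrand(lnc_exons), gene_exons,
                       ignore.strand = FALSE)
  if (length(hits) == 0) return(empty)
  ov <- BiocGenerics::width(pintersect(lnc_exons[queryHits(hits)],
                                       gene_exons[subjectHits(hits)],
                                       ignore.strand = TRUE))
  df <- data.frame(
    lncrna_id = as.character(lnc_exons$transcript_id[queryHits(hits)]),
    gene_id = as.character(gene_exons$gene_id[subjectHits(hits)]),
    evidence = ov, stringsAsFactors = FALSE)
  agg <- stats::aggregate(evidence ~ lncrna_id + gene_id, df, sum)
  data.frame(lncrna_id = agg$lncrna_id, gene_id = agg$gene_id,
             mechanism = "antisense", evidence = agg$evidence,
             sign = NA_character_, stringsAsFactors = FALSE)
}

#' Cis lncRNA-gene pairs
#'
#' A lncRNA is a candidate cis regulator of a gene when their spans do not
#' overlap and the gap between them is strictly less than `window` bp
#' (default 10 kb) upstream or downstream; evidence is the gap length.
#'
#' @param lnc_exons exon `GRanges` of lncRNAs.
#' @param gene_exons exon `GRanges` of genes.
#' @param window maximum gap in bp, exclusive (default 10000).
#' @return data.frame: lncrna_id, gene_id, mechanism, evidence, sign.
#' @export
cis_pairs <- function(lnc_exons, gene_exons, window = 10000) {
  if (window <= 0) stop("window must be positive")
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      mechanism = character(), evidence = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  lnc_sp <- transcript_spans(lnc_exons)
  g_sp <- gene_spans(gene_exons)
  if (length(lnc_sp) == 0 || length(g_sp) == 0) return(empty)
  hits <- findOverlaps(lnc_sp, g_sp, maxgap = window - 1,
                       ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- queryHits(hits); si <- subjectHits(hits)
  gap <- distance(lnc_sp[qi], g_sp[si], ignore.strand = TRUE)
  # overlapping spans are the antisense/sense domain, never cis
  overl <- as.logical(poverlaps(lnc_sp[qi], g_sp[si], ignore.strand = TRUE))
  keep <- !overl & gap < window
  if (!any(keep)) return(empty)
  data.frame(lncrna_id = as.character(lnc_sp$transcript_id[qi[keep]]),
             gene_id = as.character(g_sp$gene_id[si[keep]]),
             mechanism = "cis", evidence = as.numeric(gap[keep]),
             sign = NA_character_, stringsAsFactors = FALSE)
}

#' Trans lncRNA-gene pairs by co-expression
#'
#' Pairs every lncRNA with every gene whose expression profiles correlate
#' with `|r| >= threshold` (Pearson, inclusive); the correlation sign is
#' recorded. Profiles with zero variance are skipped with a warning.
#'
#' @param lnc_expr lncRNA expression matrix (features x samples).
#' @param gene_expr gene expression matrix over the same samples.
#' @param threshold absolute-correlation threshold, inclusive (default 0.9).
#' @return data.frame: lncrna_id, gene_id, mechanism, evidence (r), sign.
#' @export
trans_pairs <- function(lnc_expr, gene_expr, threshold = 0.9) {
  if (!identical(colnames(lnc_expr), colnames(gene_expr)))
    stop("sample columns must match")
  if (ncol(lnc_expr) < 3) stop("need >= 3 samples for correlation")
  var0_l <- apply(lnc_expr, 1, stats::var) == 0
  var0_g <- apply(gene_expr, 1, stats::var) == 0
  if (any(var0_l) || any(var0_g))
    warning("zero-variance profiles skipped: ",
            paste(c(rownames(lnc_expr)[var0_l],
                    rownames(gene_expr)[var0_g]), collapse = ", "))
  le <- lnc_expr[!var0_l, , drop = FALSE]
  ge <- gene_expr[!var0_g, , drop = FALSE]
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      mechanism = character(), evidence = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (nrow(le) == 0 || nrow(ge) == 0) return(empty)
  r <- stats::cor(t(le), t(ge))
  idx <- which(abs(r) >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  data.frame(lncrna_id = rownames(le)[idx[, 1]],
             gene_id = rownames(ge)[idx[, 2]],
             mechanism = "trans",
             evidence = r[idx],
             sign = ifelse(r[idx] >= 0, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build and export the lncRNA-target network
#'
#' Assembles mechanism-labeled edges into a bipartite igraph object
#' (lncRNA and gene nodes); duplicate (lncRNA, gene) pairs with different
#' mechanisms are retained as parallel edges.
#'
#' @param edges data.frame of target edges (rbind of [antisense_pairs()],
#'   [cis_pairs()], [trans_pairs()] outputs).
#' @param graphml_path,tsv_path optional output paths.
#' @return list: `graph` (igraph), `counts` (named edge counts per mechanism
#'   plus node counts).
#' @export
build_target_network <- function(edges, graphml_path = NULL,
                                 tsv_path = NULL) {
  lnc_nodes <- unique(edges$lncrna_id)
  gene_nodes <- unique(edges$gene_id)
  verts <- data.frame(name = c(lnc_nodes, gene_nodes),
                      type = c(rep("lncRNA", length(lnc_nodes)),
                               rep("gene", length(gene_nodes))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("lncrna_id", "gene_id", "mechanism", "evidence", "sign")],
    directed = FALSE, vertices = verts)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(tsv_path))
    utils::write.table(edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  mech <- table(factor(edges$mechanism,
                       levels = c("antisense", "cis", "trans")))
  list(graph = g,
       counts = c(as.list(mech),
                  list(n_edges = nrow(edges),
                       n_lncrna = length(lnc_nodes),
                       n_genes = length(gene_nodes))))
}
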