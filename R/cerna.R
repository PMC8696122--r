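#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), as used for
#' the miRNA negative co-expression filter.
#'
#' @param x,y numeric profiles of equal length >= 3.
#' @return correlation in `[-1, 1]`; NA with a warning when either profile
#'   has zero rank variance.
#' @export
spearman_cc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warning("zero rank variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Negatively co-expressed (feature, miRNA) pairs
#'
#' Retains a (feature, miRNA) pair when the miRNA targets the feature
#' according to the target table AND their Spearman correlation is strictly
#' below `threshold` (default -0.7).
#'
#' @param feat_expr expression matrix of mRNAs or lncRNAs (features x
#'   samples).
#' @param mirna_expr miRNA expression matrix over the same samples.
#' @param targets data.frame with columns `mirna_id` and `target_id` (rows
#'   restricted by the caller to the relevant target class).
#' @param threshold SCC cutoff, exclusive (default -0.7).
#' @return data.frame: feature_id, mirna_id, scc.
#' @export
negative_coexpression_pairs <- function(feat_expr, mirna_expr, targets,
                                        threshold = -0.7) {
  if (!identical(colnames(feat_expr), colnames(mirna_expr)))
    stop("sample columns must match")
  known <- targets$target_id %in% rownames(feat_expr) &
    targets$mirna_id %in% rownames(mirna_expr)
  if (any(!known))
    warning(sum(!known), " target-table row(s) absent from expression; skipped")
  tb <- targets[known, , drop = FALSE]
  if (nrow(tb) == 0) {
    return(data.frame(feature_id = character(), mirna_id = character(),
                      scc = numeric(), stringsAsFactors = FALSE))
  }
  scc <- vapply(seq_len(nrow(tb)), function(i) {
    suppressWarnings(
      spearman_cc(feat_expr[tb$target_id[i], ], mirna_expr[tb$mirna_id[i], ]))
  }, numeric(1))
  keep <- !is.na(scc) & scc < threshold
  data.frame(feature_id = tb$target_id[keep], mirna_id = tb$mirna_id[keep],
             scc = scc[keep], stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric shared-sponge test
#'
#' Upper-tail hypergeometric probability that two RNAs share at least `k`
#' sponged miRNAs out of a universe of `M`, when one sponges `K` and the
#' other `n`: `p = sum_{i=k}^{min(K,n)} C(K,i) C(M-K,n-i) / C(M,n)`.
#'
#' @param M miRNA universe size.
#' @param K miRNA count of the first RNA (e.g., the lncRNA).
#' @param n miRNA count of the second RNA (e.g., the mRNA).
#' @param k shared miRNA count.
#' @return upper-tail p-value in `(0, 1]`.
#' @export
sponge_hypergeom_test <- function(M, K, n, k) {
  if (any(c(M, K, n, k) < 0)) stop("counts must be non-negative")
  if (K > M || n > M) stop("K and n cannot exceed the universe M")
  if (k > min(K, n)) stop("shared count k cannot exceed min(K, n)")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Assemble ceRNA mRNA-miRNA-lncRNA triplets
#'
#' For every (mRNA, lncRNA) pair sharing at least one retained miRNA,
#' computes the Pearson correlation of the mRNA and lncRNA profiles and the
#' shared-sponge hypergeometric p-value; a triplet is kept when
#' `PCC > pcc_threshold` (strict) and `p < alpha` (strict). `K` and `n` are
#' the per-feature retained-miRNA counts after the SCC filter; the universe
#' `M` is the set of miRNAs in the miRNA expression set.
#'
#' @param mrna_mirna_pairs,lncrna_mirna_pairs outputs of
#'   [negative_coexpression_pairs()] for mRNAs and lncRNAs.
#' @param mrna_expr,lncrna_expr expression matrices over identical samples.
#' @param universe character vector of miRNA ids defining `M`.
#' @param alpha sponge-test threshold, exclusive (default 0.05).
#' @param pcc_threshold Pearson threshold, exclusive (default 0.9).
#' @return data.frame: mrna_id, lncrna_id, mirna_ids (comma-separated),
#'   k_shared, K_lncrna, n_mrna, scc_mrna_mirna, scc_lncrna_mirna (means over
#'   the shared miRNAs), pcc_mrna_lncrna, p_sponge.
#' @export
build_cerna_triplets <- function(mrna_mirna_pairs, lncrna_mirna_pairs,
                                 mrna_expr, lncrna_expr, universe,
                                 alpha = 0.05, pcc_threshold = 0.9) {
  M <- length(unique(universe))
  if (M == 0) stop("empty miRNA universe")
  empty <- data.frame(mrna_id = character(), lncrna_id = character(),
                      mirna_ids = character(), k_shared = integer(),
                      K_lncrna = integer(), n_mrna = integer(),
                      scc_mrna_mirna = numeric(),
                      scc_lncrna_mirna = numeric(),
                      pcc_mrna_lncrna = numeric(), p_sponge = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(mrna_mirna_pairs) == 0 || nrow(lncrna_mirna_pairs) == 0)
    return(empty)
  m_sets <- split(seq_len(nrow(mrna_mirna_pairs)),
                  mrna_mirna_pairs$feature_id)
  l_sets <- split(seq_len(nrow(lncrna_mirna_pairs)),
                  lncrna_mirna_pairs$feature_id)
  rows <- list()
  for (m in names(m_sets)) {
    mi_m <- mrna_mirna_pairs$mirna_id[m_sets[[m]]]
    for (l in names(l_sets)) {
      mi_l <- lncrna_mirna_pairs$mirna_id[l_sets[[l]]]
      shared <- intersect(mi_m, mi_l)
      if (length(shared) == 0) next
      k <- length(shared); K <- length(unique(mi_l)); n <- length(unique(mi_m))
      p <- sponge_hypergeom_test(M, K, n, k)
      pcc <- stats::cor(mrna_expr[m, ], lncrna_expr[l, ])
      if (is.na(pcc) || pcc <= pcc_threshold || p >= alpha) next
      rows[[length(rows) + 1L]] <- data.frame(
        mrna_id = m, lncrna_id = l,
        mirna_ids = paste(sort(shared), collapse = ","),
        k_shared = k, K_lncrna = K, n_mrna = n,
        scc_mrna_mirna = mean(mrna_mirna_pairs$scc[
          m_sets[[m]]][mi_m %in% shared]),
        scc_lncrna_mirna = mean(lncrna_mirna_pairs$scc[
          l_sets[[l]]][mi_l %in% shared]),
        pcc_mrna_lncrna = pcc, p_sponge = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mrna_id, out$lncrna_id), , drop = FALSE]
}

#' Export the ceRNA network
#'
#' Builds a tripartite graph with mRNA, miRNA and lncRNA node types; each
#' triplet contributes mRNA-miRNA and lncRNA-miRNA edges per shared miRNA
#' plus one lncRNA-mRNA edge.
#'
#' @param triplets output of [build_cerna_triplets()].
#' @param graphml_path,tsv_path optional output paths.
#' @return list: `graph` (igraph) and `counts` (distinct mRNA/miRNA/lncRNA
#'   node counts and edge count).
#' @export
export_cerna_network <- function(triplets, graphml_path = NULL,
                                 tsv_path = NULL) {
  edges <- list()
  for (i in seq_len(nrow(triplets))) {
    mis <- strsplit(triplets$mirna_ids[i], ",")[[1]]
    edges[[length(edges) + 1L]] <- data.frame(
      from = c(rep(triplets$mrna_id[i], length(mis)),
               rep(triplets$lncrna_id[i], length(mis)),
               triplets$lncrna_id[i]),
      to = c(mis, mis, triplets$mrna_id[i]),
      edge_type = c(rep("mRNA-miRNA", length(mis)),
                    rep("lncRNA-miRNA", length(mis)), "lncRNA-mRNA"),
      stringsAsFactors = FALSE)
  }
  edf <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = character(), to = character(),
               edge_type = character(), stringsAsFactors = FALSE)
  mrnas <- unique(triplets$mrna_id)
  lncs <- unique(triplets$lncrna_id)
  mis <- unique(unlist(strsplit(triplets$mirna_ids, ",")))
  verts <- data.frame(name = c(mrnas, mis, lncs),
                      type = c(rep("mRNA", length(mrnas)),
                               rep("miRNA", length(mis)),
                               rep("lncRNA", length(lncs))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = verts)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(tsv_path))
    utils::write.table(triplets, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(graph = g,
       counts = list(n_mrna = length(mrnas), n_mirna = length(mis),
                     n_lncrna = length(lncs), n_edges = nrow(edf),
                     n_triplets = nrow(triplets)))
}
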