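#' Read gene sets from a GMT file
#'
#' @param path path to a GMT file (set name, description, then gene ids,
#'   tab-separated).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(ln) strsplit(ln, "\t")[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis for one gene set
#'
#' Upper-tail hypergeometric test of the overlap between a DE gene list and
#' a gene set within a universe; shares the engine of
#' [sponge_hypergeom_test()].
#'
#' @param de_genes character vector of differentially expressed gene ids.
#' @param gene_set character vector of set member ids.
#' @param universe character vector of all considered gene ids.
#' @return list: `p`, `overlap`, `set_size`, `de_size`, `universe_size`
#'   (sizes after restriction to the universe).
#' @export
ora_hypergeom <- function(de_genes, gene_set, universe) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe)) {
    warning("DE genes outside the universe were dropped")
    de_genes <- intersect(de_genes, universe)
  }
  gene_set <- intersect(unique(gene_set), universe)
  overlap <- length(intersect(de_genes, gene_set))
  p <- sponge_hypergeom_test(M = length(universe), K = length(gene_set),
                             n = length(de_genes), k = overlap)
  list(p = p, overlap = overlap, set_size = length(gene_set),
       de_size = length(de_genes), universe_size = length(universe))
}

#' Run ORA over a gene-set collection
#'
#' @param de_genes DE gene ids.
#' @param gene_sets named list of gene sets (e.g., from [read_gmt()]).
#' @param universe universe gene ids.
#' @return data.frame: set, set_size, overlap, p (raw, the published
#'   filtering scale), q (BH, reported alongside).
#' @export
run_ora <- function(de_genes, gene_sets, universe) {
  res <- lapply(gene_sets, ora_hypergeom, de_genes = de_genes,
                universe = universe)
  df <- data.frame(set = names(gene_sets),
                   set_size = vapply(res, `[[`, numeric(1), "set_size"),
                   overlap = vapply(res, `[[`, numeric(1), "overlap"),
                   p = vapply(res, `[[`, numeric(1), "p"),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$q <- bh_fdr(df$p)
  df
}

#' Signal-to-noise gene ranking
#'
#' Scores each gene as `(mean_A - mean_B) / (sd_A + sd_B)` with each
#' standard deviation floored at `max(0.2 * |mean|, 0.2)` (the Broad GSEA
#' convention), then sorts descending; ties keep stable input order.
#'
#' @param expr expression matrix (genes x samples).
#' @param group_a,group_b column names of the two phenotype groups, each of
#'   size >= 2.
#' @return data.frame: gene, score, sorted by decreasing score.
#' @export
signal_to_noise_rank <- function(expr, group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 0.2)
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- floor_sd(apply(a, 1, stats::sd), ma)
  sb <- floor_sd(apply(b, 1, stats::sd), mb)
  score <- (ma - mb) / (sa + sb)
  ord <- order(-score)   # stable: ties keep feature order
  data.frame(gene = rownames(expr)[ord], score = as.numeric(score[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running statistic over a ranked gene list:
#' set members ("hits") increment the running sum by
#' `|score|^weight / sum_set |score|^weight`, non-members decrement by
#' `1 / (N - set size)`; the enrichment score is the signed maximum
#' deviation from zero.
#'
#' @param ranked data.frame with columns `gene` and `score`, sorted by
#'   decreasing score (as from [signal_to_noise_rank()]).
#' @param gene_set character vector of set member ids.
#' @param weight score-weighting exponent (default 1).
#' @return list: `es` and `running` (the running-sum vector).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  if (length(gene_set) == 0) stop("empty gene set")
  hit <- ranked$gene %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no member in the ranked list")
  N <- nrow(ranked)
  w <- abs(ranked$score)^weight
  inc <- numeric(N)
  if (sum(w[hit]) == 0) {
    inc[hit] <- 1 / nh      # all-zero scores: unweighted hits
  } else {
    inc[hit] <- w[hit] / sum(w[hit])
  }
  if (N > nh) inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

enumerate_relabelings <- function(n_a, n_b, limit, n_perm) {
  n <- n_a + n_b
  total <- choose(n, n_a)
  if (total <= limit) {
    combs <- utils::combn(n, n_a, simplify = FALSE)
    # drop the identity labeling (the observed phenotype)
    combs <- Filter(function(cc) !identical(cc, seq_len(n_a)), combs)
    combs
  } else {
    lapply(seq_len(n_perm), function(i) sort(sample.int(n, n_a)))
  }
}

#' GSEA with phenotype-permutation normalization
#'
#' Computes the enrichment score of each gene set on the observed
#' signal-to-noise ranking, then re-ranks under phenotype relabelings to
#' obtain a null ES distribution per set. When the number of distinct
#' relabelings is at most `exhaustive_limit` all of them (minus the observed
#' labeling) are enumerated; otherwise `n_perm` random relabelings are drawn.
#' NES is ES divided by the mean |null ES| of matching sign; the nominal p is
#' the add-one fraction of same-sign null ES at least as extreme; the FDR q
#' follows the standard positive/negative tail-area normalization.
#'
#' @param expr expression matrix (genes x samples).
#' @param group_a,group_b phenotype group column names.
#' @param gene_sets named list of gene sets.
#' @param weight ES weighting exponent (default 1).
#' @param n_perm random permutations when enumeration is infeasible
#'   (default 1000; must be >= 10).
#' @param exhaustive_limit enumerate all relabelings when their count is at
#'   most this (default 1000).
#' @param seed RNG seed for the sampled-permutation branch.
#' @return data.frame: set, size, es, nes, nominal_p, fdr_q,
#'   leading_edge (comma-separated gene ids).
#' @export
gsea_nes <- function(expr, group_a, group_b, gene_sets, weight = 1,
                     n_perm = 1000, exhaustive_limit = 1000, seed = 1) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  samples <- c(group_a, group_b)
  n_a <- length(group_a)
  obs_rank <- signal_to_noise_rank(expr, group_a, group_b)
  gene_sets <- Filter(function(s) any(s %in% rownames(expr)), gene_sets)
  if (length(gene_sets) == 0) stop("no gene set overlaps the expression matrix")
  obs <- lapply(gene_sets, function(s) gsea_es(obs_rank, s, weight))
  obs_es <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(seed)
  perms <- enumerate_relabelings(n_a, length(group_b), exhaustive_limit,
                                 n_perm)
  null_es <- matrix(NA_real_, nrow = length(perms),
                    ncol = length(gene_sets),
                    dimnames = list(NULL, names(gene_sets)))
  for (i in seq_along(perms)) {
    ga <- samples[perms[[i]]]
    gb <- samples[-perms[[i]]]
    rk <- signal_to_noise_rank(expr, ga, gb)
    null_es[i, ] <- vapply(gene_sets, function(s) gsea_es(rk, s, weight)$es,
                           numeric(1))
  }

  norm_factor <- function(es_null, sign_pos) {
    v <- es_null[if (sign_pos) es_null > 0 else es_null < 0]
    if (length(v) == 0) return(NA_real_)
    mean(abs(v))
  }
  nes <- numeric(length(gene_sets))
  nominal_p <- numeric(length(gene_sets))
  null_nes <- vector("list", length(gene_sets))
  for (j in seq_along(gene_sets)) {
    es <- obs_es[j]
    nulls <- null_es[, j]
    pos <- es >= 0
    same <- nulls[if (pos) nulls >= 0 else nulls < 0]
    nf <- norm_factor(nulls, pos)
    nes[j] <- if (is.na(nf) || nf == 0) sign(es) else es / nf
    nominal_p[j] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    npos <- norm_factor(nulls, TRUE); nneg <- norm_factor(nulls, FALSE)
    nn <- nulls
    nn[nulls >= 0] <- if (is.na(npos) || npos == 0) 0 else
      nulls[nulls >= 0] / npos
    nn[nulls < 0] <- if (is.na(nneg) || nneg == 0) 0 else
      nulls[nulls < 0] / nneg
    null_nes[[j]] <- nn
  }
  all_null_nes <- unlist(null_nes)
  fdr_q <- vapply(seq_along(gene_sets), function(j) {
    ns <- nes[j]
    if (ns >= 0) {
      num_pool <- all_null_nes[all_null_nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= ns) else 0
      den_pool <- nes[nes >= 0]
      den <- mean(den_pool >= ns)
    } else {
      num_pool <- all_null_nes[all_null_nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= ns) else 0
      den_pool <- nes[nes < 0]
      den <- mean(den_pool <= ns)
    }
    min(1, if (den == 0) 1 else num / den)
  }, numeric(1))

  leading <- vapply(seq_along(gene_sets), function(j) {
    run <- obs[[j]]$running
    peak <- which.max(abs(run))
    hits <- obs_rank$gene %in% gene_sets[[j]]
    le <- if (obs_es[j] >= 0) obs_rank$gene[seq_len(peak)][hits[seq_len(peak)]]
          else obs_rank$gene[peak:length(run)][hits[peak:length(run)]]
    paste(le, collapse = ",")
  }, character(1))

  data.frame(set = names(gene_sets),
             size = vapply(gene_sets, function(s)
               sum(s %in% rownames(expr)), numeric(1)),
             es = obs_es, nes = nes, nominal_p = nominal_p, fdr_q = fdr_q,
             leading_edge = leading, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter GSEA results by the published significance criteria
#'
#' Keeps sets with `|NES| > nes_threshold`, `nominal p < p_threshold` and
#' `FDR q < q_threshold`, all inequalities strict.
#'
#' @param results data.frame from [gsea_nes()].
#' @param nes_threshold default 1.
#' @param p_threshold default 0.05.
#' @param q_threshold default 0.25.
#' @return filtered data.frame.
#' @export
significant_sets <- function(results, nes_threshold = 1, p_threshold = 0.05,
                             q_threshold = 0.25) {
  keep <- abs(results$nes) > nes_threshold &
    results$nominal_p < p_threshold & results$fdr_q < q_threshold
  results[keep, , drop = FALSE]
}
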