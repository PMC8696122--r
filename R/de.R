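#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[i,j] = counts[i,j] * 1e9 / (total_counts[j] * length[i])`.
#'
#' @param counts non-negative count matrix (features x samples).
#' @param lengths named numeric vector of feature lengths in bp; must cover
#'   every row of `counts`.
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths) {
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing length for feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("feature lengths must be positive")
  sweep(counts, 2, totals, "/") * 1e9 / len
}

#' Log2 fold change between two group means
#'
#' `log2((b + pseudocount) / (a + pseudocount))`; positive values mean higher
#' abundance in the second group.
#'
#' @param a_mean mean of the first (reference) group.
#' @param b_mean mean of the second group.
#' @param pseudocount non-negative stabilizer added to both means (default 1).
#' @return numeric log2 fold change; NA when both means and the pseudocount
#'   are zero.
#' @export
log2_fold_change <- function(a_mean, b_mean, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  out <- log2((b_mean + pseudocount) / (a_mean + pseudocount))
  undef <- (a_mean + pseudocount) == 0 & (b_mean + pseudocount) == 0
  out[undef] <- NA_real_
  out
}

#' Per-feature two-group differential test
#'
#' Both methods work on `log2(x + 1)` and return two-sided p-values; the
#' method argument is a registration point so further tests (e.g., an NB
#' exact test) can be substituted under the same contract.
#'
#' `"moderated"` (default): a t-test whose per-feature pooled variance is
#' shrunk toward the mean variance across all features with `prior_df`
#' pseudo-degrees of freedom; with only two or three replicates per group the
#' per-feature variance estimate alone is too unstable to rank genes well,
#' and sharing variance information across features (as the count-based
#' packages in this field do) restores power. `"welch"`: plain Welch's
#' t-test per feature.
#'
#' Features that are constant across both groups get p = 1 (no signal);
#' constant-but-different degenerate rows get p = 0.
#'
#' @param expr expression matrix (FPKM or similar), features x samples.
#' @param group_a,group_b column names (or indices) of the two groups, each
#'   of size >= 2.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param prior_df pseudo-degrees of freedom of the shared-variance prior
#'   (moderated method only; default 10).
#' @return numeric vector of two-sided p-values, named by feature.
#' @export
de_test <- function(expr, group_a, group_b,
                    method = c("moderated", "welch"), prior_df = 10) {
  method <- match.arg(method)
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("each group needs >= 2 replicates")
  la <- log2(a + 1); lb <- log2(b + 1)
  if (method == "welch") {
    p <- vapply(seq_len(nrow(expr)), function(i) {
      x <- la[i, ]; y <- lb[i, ]
      tryCatch(stats::t.test(x, y)$p.value,
               error = function(e) {
                 if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
               })
    }, numeric(1))
  } else {
    na <- ncol(a); nb <- ncol(b)
    df_res <- na + nb - 2
    va <- apply(la, 1, stats::var)
    vb <- apply(lb, 1, stats::var)
    v <- ((na - 1) * va + (nb - 1) * vb) / df_res
    v0 <- mean(v)
    vs <- (prior_df * v0 + df_res * v) / (prior_df + df_res)
    diff <- rowMeans(lb) - rowMeans(la)
    se <- sqrt(vs * (1 / na + 1 / nb))
    p <- ifelse(se == 0, ifelse(diff == 0, 1, 0),
                2 * stats::pt(-abs(diff / se), df = prior_df + df_res))
  }
  stats::setNames(p, rownames(expr))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q(i) = min_{j >= i} m * p(j) / j` on sorted
#' p-values, restored to input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression call
#'
#' mRNA and lncRNA: `|log2FC| > 1` and `q < 0.05`; miRNA: `|log2FC| > 1` and
#' raw `p < 0.05`. All inequalities strict.
#'
#' @param log2fc,p,q numeric vectors (recycled together).
#' @param feature_class one of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param lfc_threshold fold-change threshold (default 1).
#' @param alpha significance threshold (default 0.05).
#' @return character vector of calls: `"up"`, `"down"` or `"ns"`.
#' @export
call_de <- function(log2fc, p, q, feature_class,
                    lfc_threshold = 1, alpha = 0.05) {
  feature_class <- match.arg(feature_class, c("mRNA", "lncRNA", "miRNA"))
  sig <- if (feature_class == "miRNA") p < alpha else q < alpha
  call <- rep("ns", length(log2fc))
  call[!is.na(log2fc) & log2fc > lfc_threshold & sig] <- "up"
  call[!is.na(log2fc) & log2fc < -lfc_threshold & sig] <- "down"
  call
}

#' Run the DE stage for one comparison
#'
#' Computes FPKM, group-mean log2 fold changes (pseudocount 1 on FPKM), the
#' per-feature test, BH q-values and the threshold call.
#'
#' @param counts count matrix (features x samples).
#' @param lengths named feature length vector (bp).
#' @param design data.frame with sample_id, tissue, stage, replicate.
#' @param tissue tissue to analyse.
#' @param stages length-2 character vector, earlier stage first; fold change
#'   is the second stage relative to the first.
#' @param feature_class `"mRNA"`, `"lncRNA"` or `"miRNA"`.
#' @param pseudocount pseudocount for fold change on FPKM (default 1).
#' @param method per-feature test, passed to [de_test()].
#' @return data.frame: feature_id, class, comparison, log2fc, p, q, call.
#' @export
run_de <- function(counts, lengths, design, tissue, stages, feature_class,
                   pseudocount = 1, method = c("moderated", "welch")) {
  stopifnot(length(stages) == 2)
  fpkm <- compute_fpkm(counts, lengths)
  sa <- design$sample_id[design$tissue == tissue & design$stage == stages[1]]
  sb <- design$sample_id[design$tissue == tissue & design$stage == stages[2]]
  if (length(sa) < 2 || length(sb) < 2)
    stop("each stage needs >= 2 replicates in tissue ", tissue)
  lfc <- log2_fold_change(rowMeans(fpkm[, sa, drop = FALSE]),
                          rowMeans(fpkm[, sb, drop = FALSE]),
                          pseudocount)
  p <- de_test(fpkm, sa, sb, method = method)
  q <- bh_fdr(p)
  data.frame(feature_id = rownames(counts),
             class = feature_class,
             comparison = paste0(stages[1], "_vs_", stages[2]),
             log2fc = as.numeric(lfc), p = as.numeric(p), q = as.numeric(q),
             call = call_de(lfc, p, q, feature_class),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize DE results across comparisons
#'
#' Reports per-comparison up/down/total counts, all pairwise intersection
#' sizes, the cross-comparison total as the *sum* of per-comparison counts
#' (the convention used when headline totals add comparisons without
#' deduplication), and the deduplicated union separately.
#'
#' @param results named list, one element per comparison: either a DE result
#'   data.frame (from [run_de()]) or a character vector of DE feature ids.
#' @return list: `per_comparison` (data.frame comparison/n_up/n_down/n_de),
#'   `sum_total`, `union_size`, `intersections` (data.frame of pairs).
#' @export
summarize_de <- function(results) {
  de_sets <- lapply(results, function(r) {
    if (is.data.frame(r)) unique(r$feature_id[r$call != "ns"])
    else unique(as.character(r))
  })
  per <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (is.data.frame(r)) {
      data.frame(comparison = nm,
                 n_up = sum(r$call == "up"), n_down = sum(r$call == "down"),
                 n_de = length(de_sets[[nm]]), stringsAsFactors = FALSE)
    } else {
      data.frame(comparison = nm, n_up = NA_integer_, n_down = NA_integer_,
                 n_de = length(de_sets[[nm]]), stringsAsFactors = FALSE)
    }
  }))
  cmb <- if (length(de_sets) >= 2) utils::combn(names(de_sets), 2) else NULL
  inter <- if (!is.null(cmb)) {
    data.frame(comparison_a = cmb[1, ], comparison_b = cmb[2, ],
               intersection = apply(cmb, 2, function(pr)
                 length(intersect(de_sets[[pr[1]]], de_sets[[pr[2]]]))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(comparison_a = character(), comparison_b = character(),
               intersection = integer(), stringsAsFactors = FALSE)
  }
  list(per_comparison = per,
       sum_total = sum(per$n_de),
       union_size = length(unique(unlist(de_sets))),
       intersections = inter)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)]`,
#' the standard qPCR quantification of a target gene relative to a reference
#' gene and a control condition.
#'
#' @param ct_target_case,ct_ref_case Ct values in the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control condition.
#' @return fold change of the target in case relative to control.
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
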