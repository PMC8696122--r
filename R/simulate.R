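#' Simulation configuration
#'
#' Defines the study conditions for the synthetic fixture generator: a
#' tissue x stage x replicate design with negative-binomial counts, planted
#' fold changes, planted lncRNA positional categories, planted
#' antisense/cis/trans target pairs and planted ceRNA triplets.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of protein-coding genes.
#' @param n_lncrna number of lncRNA transcripts.
#' @param n_mirna number of miRNAs (the sponge-test universe).
#' @param n_tissues,n_stages,n_reps design dimensions (defaults 2 x 3 x 3).
#' @param nb_dispersion negative-binomial dispersion (default 0.05).
#' @param baseline_mean expected baseline count (default 100).
#' @param planted_log2fc planted effect size in log2 units (default 2).
#' @param frac_de fraction of features planted as differentially expressed
#'   (default 0.25).
#' @param category_mix named proportions over the five lncRNA categories
#'   (must sum to 1).
#' @param n_cerna_triplets number of planted (mRNA, lncRNA) ceRNA pairs.
#' @param mirnas_per_triplet shared miRNAs per planted ceRNA pair
#'   (default 2).
#' @param corr_strength planted co-expression strength in (0, 1]; 1 gives
#'   exact monotone profiles.
#' @param decoy_rate probability that a non-planted (miRNA, feature)
#'   combination is added to the miRNA-target table.
#' @param n_filter_fail number of deliberately filter-failing candidate
#'   transcripts to emit (default 0).
#' @param n_random_sets number of random gene sets in the GMT fixture.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 80,
                              n_lncrna = 40,
                              n_mirna = 15,
                              n_tissues = 2,
                              n_stages = 3,
                              n_reps = 3,
                              nb_dispersion = 0.05,
                              baseline_mean = 100,
                              planted_log2fc = 2,
                              frac_de = 0.25,
                              category_mix = c(intergenic = 0.4,
                                               bidirectional = 0.15,
                                               intronic = 0.1,
                                               antisense = 0.2,
                                               sense_overlapping = 0.15),
                              n_cerna_triplets = 5,
                              mirnas_per_triplet = 2,
                              corr_strength = 0.9,
                              decoy_rate = 0.05,
                              n_filter_fail = 0,
                              n_random_sets = 5) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_tissues = n_tissues, n_stages = n_stages, n_reps = n_reps,
              nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
              planted_log2fc = planted_log2fc, frac_de = frac_de,
              category_mix = category_mix,
              n_cerna_triplets = n_cerna_triplets,
              mirnas_per_triplet = mirnas_per_triplet,
              corr_strength = corr_strength, decoy_rate = decoy_rate,
              n_filter_fail = n_filter_fail, n_random_sets = n_random_sets)
  valid_cats <- c("intergenic", "bidirectional", "intronic", "antisense",
                  "sense_overlapping")
  if (!all(names(category_mix) %in% valid_cats))
    stop("category_mix names must be among: ",
         paste(valid_cats, collapse = ", "))
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1")
  if (any(category_mix < 0)) stop("category_mix proportions must be >= 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (baseline_mean <= 0) stop("baseline_mean must be > 0")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must lie in [0, 1]")
  if (corr_strength <= 0 || corr_strength > 1)
    stop("corr_strength must lie in (0, 1]")
  if (decoy_rate < 0 || decoy_rate > 1) stop("decoy_rate must lie in [0, 1]")
  with(cfg, {
    if (n_genes < 1 || n_tissues < 1 || n_stages < 2 || n_reps < 2)
      stop("design requires n_genes >= 1, n_tissues >= 1, n_stages >= 2, ",
           "n_reps >= 2")
  })
  class(cfg) <- "simulation_config"
  cfg
}

apportion_categories <- function(mix, n) {
  if (n == 0) return(stats::setNames(integer(length(mix)), names(mix)))
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  if (sum(base) != n)
    stop("category_mix incompatible with n_lncrna")
  stats::setNames(as.integer(base), names(mix))
}

stage_labels <- function(n) {
  if (n <= 3) c("IV", "V", "VI")[seq_len(n)] else paste0("S", seq_len(n))
}
tissue_labels <- function(n) {
  if (n <= 2) c("brain", "pituitary")[seq_len(n)] else
    paste0("tissue", seq_len(n))
}

## Deterministic single-chromosome layout. Genes sit on a 200 kb grid, each
## with three 1 kb exons separated by 8 kb introns (span 19 kb). Each lncRNA
## is placed relative to a host gene so that it satisfies exactly one
## positional category by construction:
##   antisense / sense_overlapping : exons over the host's first exon
##   intronic                      : both exons inside the first intron
##   bidirectional                 : divergent TSS 800 bp from the host TSS
##   intergenic (cis-planted)      : 7,000 bp gap from the host span
##   intergenic (far)              : mid-grid, >80 kb from every gene
gene_layout <- function(i) {
  s <- 100000 + (i - 1) * 200000
  list(start = s, end = s + 18999,
       exon_starts = s + c(0, 9000, 18000),
       exon_ends = s + c(999, 9999, 18999))
}

#' Generate the annotated genome fixture with planted truth
#'
#' Emits a single-chromosome layout of protein-coding genes and lncRNA
#' transcripts constructed to satisfy exactly one positional category each,
#' together with the planted truth used by every downstream stage: DE
#' feature assignments per comparison, lncRNA categories, target pairs
#' (antisense / cis / trans) and ceRNA triplet memberships.
#'
#' @param config a [simulation_config()].
#' @return list: `gene_exons`, `lnc_exons`, `candidate_exons` (lncRNAs plus
#'   deliberate filter failures), `lengths` (named bp vector over all
#'   features), `truth` (list: de_features, lncrna_category, target_pairs,
#'   cerna_triplets, mirna_ids), `chrom`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chrom <- "chr1"
  n_g <- config$n_genes
  gene_ids <- sprintf("gene%03d", seq_len(n_g))
  gene_strand <- rep(c("+", "-"), length.out = n_g)

  ge <- lapply(seq_len(n_g), function(i) {
    gl <- gene_layout(i)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(gl$exon_starts, gl$exon_ends),
      strand = gene_strand[i],
      transcript_id = paste0(gene_ids[i], ".t1"),
      gene_id = gene_ids[i])
  })
  gene_exons <- do.call(c, ge)

  counts <- apportion_categories(config$category_mix, config$n_lncrna)
  lnc_cat <- rep(names(counts), counts)
  n_l <- config$n_lncrna
  lnc_ids <- if (n_l > 0) sprintf("lnc%03d", seq_len(n_l)) else character(0)
  host <- if (n_l > 0) ((seq_len(n_l) - 1L) %% n_g) + 1L else integer(0)
  cycle <- if (n_l > 0) (seq_len(n_l) - 1L) %/% n_g else integer(0)

  # alternate cis-planted vs far placement within the intergenic class
  is_intergenic <- lnc_cat == "intergenic"
  cis_flag <- logical(n_l)
  cis_flag[is_intergenic] <- (seq_len(sum(is_intergenic)) %% 2) == 1

  lnc_list <- list()
  pair_rows <- list()
  for (i in seq_len(n_l)) {
    gl <- gene_layout(host[i])
    s <- gl$start; e <- gl$end
    hstrand <- gene_strand[host[i]]
    opp <- if (hstrand == "+") "-" else "+"
    alt <- if (i %% 2 == 0) "+" else "-"
    cat_i <- lnc_cat[i]
    if (cat_i == "antisense") {
      st <- c(s + 500, s + 1400); en <- c(s + 1200, s + 1800); strand <- opp
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(lncrna_id = lnc_ids[i], gene_id = gene_ids[host[i]],
                   mechanism = "antisense", stringsAsFactors = FALSE)
    } else if (cat_i == "sense_overlapping") {
      st <- c(s + 500, s + 1400); en <- c(s + 1200, s + 1800)
      strand <- hstrand
    } else if (cat_i == "intronic") {
      st <- c(s + 2000, s + 2600); en <- c(s + 2299, s + 2899); strand <- alt
    } else if (cat_i == "bidirectional") {
      if (hstrand == "+") {
        st <- c(s - 1700, s - 1200); en <- c(s - 1400, s - 800); strand <- "-"
      } else {
        st <- c(e + 800, e + 1300); en <- c(e + 1100, e + 1700); strand <- "+"
      }
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(lncrna_id = lnc_ids[i], gene_id = gene_ids[host[i]],
                   mechanism = "cis", stringsAsFactors = FALSE)
    } else if (cis_flag[i]) {           # cis-planted intergenic
      st <- c(e + 7001, e + 7600); en <- c(e + 7400, e + 8000); strand <- alt
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(lncrna_id = lnc_ids[i], gene_id = gene_ids[host[i]],
                   mechanism = "cis", stringsAsFactors = FALSE)
    } else {                            # far intergenic
      m <- s + 100000 + 1500 * cycle[i]
      st <- c(m, m + 600); en <- c(m + 399, m + 999); strand <- alt
    }
    lnc_list[[i]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(st, en), strand = strand,
      transcript_id = lnc_ids[i], gene_id = lnc_ids[i])
  }
  lnc_exons <- if (n_l > 0) {
    do.call(c, lnc_list)
  } else {
    gr <- GenomicRanges::GRanges()
    gr$transcript_id <- character(0)
    gr$gene_id <- character(0)
    gr
  }

  # deliberate structural-filter failures, placed beyond the gene grid
  fail_list <- list()
  tail_pos <- 100000 + n_g * 200000 + 50000
  for (j in seq_len(config$n_filter_fail)) {
    fid <- sprintf("cand_fail%02d", j)
    pos <- tail_pos + (j - 1) * 20000
    if (j %% 2 == 1) {   # single exon, long: fails the exon-count rule
      st <- pos; en <- pos + 4999
    } else {             # two exons, 150 bp total: fails the length rule
      st <- c(pos, pos + 200); en <- c(pos + 74, pos + 274)
    }
    fail_list[[j]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(st, en), strand = "+",
      transcript_id = fid, gene_id = fid)
  }
  candidate_exons <- if (length(fail_list))
    c(lnc_exons, do.call(c, fail_list)) else lnc_exons

  mirna_ids <- sprintf("mir%03d", seq_len(config$n_mirna))

  # ceRNA triplet membership: disjoint, drawn from non-overlapping pools
  n_t <- config$n_cerna_triplets
  mpt <- config$mirnas_per_triplet
  if (n_t > 0) {
    if (n_t > n_g || n_t > n_l || n_t * mpt > config$n_mirna)
      stop("not enough features for the requested ceRNA triplets")
    cer_mrna <- sample(gene_ids, n_t)
    cer_lnc <- sample(lnc_ids, n_t)
    cer_mir <- matrix(sample(mirna_ids, n_t * mpt), nrow = n_t)
    cerna <- do.call(rbind, lapply(seq_len(n_t), function(tt)
      data.frame(mrna_id = cer_mrna[tt], mirna_id = cer_mir[tt, ],
                 lncrna_id = cer_lnc[tt], triplet = tt,
                 stringsAsFactors = FALSE)))
    for (tt in seq_len(n_t)) {
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(lncrna_id = cer_lnc[tt], gene_id = cer_mrna[tt],
                   mechanism = "trans", stringsAsFactors = FALSE)
    }
  } else {
    cer_mrna <- cer_lnc <- character(0)
    cerna <- data.frame(mrna_id = character(), mirna_id = character(),
                        lncrna_id = character(), triplet = integer(),
                        stringsAsFactors = FALSE)
  }

  # DE assignments, round-robin over consecutive-stage comparisons
  stages <- stage_labels(config$n_stages)
  comparisons <- paste0(stages[-length(stages)], "_vs_", stages[-1])
  pick_de <- function(ids, reserved, frac) {
    pool <- setdiff(ids, reserved)
    n_de <- min(length(pool), round(frac * length(ids)))
    if (n_de == 0) return(NULL)
    picked <- sample(pool, n_de)
    data.frame(feature_id = picked,
               comparison = rep(comparisons, length.out = n_de),
               direction = sample(c(1, -1), n_de, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  cer_mir_used <- unique(cerna$mirna_id)
  de_g <- pick_de(gene_ids, cer_mrna, config$frac_de)
  de_l <- pick_de(lnc_ids, cer_lnc, config$frac_de)
  de_m <- pick_de(mirna_ids, cer_mir_used, config$frac_de)
  de_features <- rbind(
    if (!is.null(de_g)) cbind(de_g, class = "mRNA"),
    if (!is.null(de_l)) cbind(de_l, class = "lncRNA"),
    if (!is.null(de_m)) cbind(de_m, class = "miRNA"))
  if (is.null(de_features))
    de_features <- data.frame(feature_id = character(),
                              comparison = character(), direction = numeric(),
                              class = character(), stringsAsFactors = FALSE)

  target_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(lncrna_id = character(), gene_id = character(),
               mechanism = character(), stringsAsFactors = FALSE)

  lengths <- c(
    stats::setNames(rep(3000, n_g), gene_ids),
    if (n_l > 0) stats::setNames(
      as.numeric(tapply(BiocGenerics::width(lnc_exons),
                        as.character(lnc_exons$transcript_id), sum)[lnc_ids]),
      lnc_ids),
    stats::setNames(rep(22, config$n_mirna), mirna_ids))

  list(gene_exons = gene_exons, lnc_exons = lnc_exons,
       candidate_exons = candidate_exons, lengths = lengths, chrom = chrom,
       truth = list(de_features = de_features,
                    lncrna_category = stats::setNames(lnc_cat, lnc_ids),
                    target_pairs = target_pairs,
                    cerna_triplets = cerna,
                    mirna_ids = mirna_ids,
                    gene_ids = gene_ids, lnc_ids = lnc_ids,
                    comparisons = comparisons))
}

#' Generate expression matrices with planted structure
#'
#' Draws negative-binomial counts (mean/dispersion parameterization) over
#' the tissue x stage x replicate design, with per-sample library-size
#' factors uniform in +/-20%. DE-planted features have their mean shifted by
#' `planted_log2fc` from the later stage of their designated comparison
#' onward. Each planted ceRNA triplet's members follow a shared latent
#' log-normal profile: mRNA and lncRNA monotone increasing in it, the miRNA
#' anti-monotone, mixed with feature-level noise in proportion
#' `corr_strength`; these rows are emitted deterministically (no count-level
#' resampling) so the noiseless limit `corr_strength = 1` gives exact
#' Spearman -1 / Pearson +1 relations.
#'
#' @param config a [simulation_config()].
#' @param ann output of [generate_annotation()] from the same config.
#' @return list: `mrna_counts`, `lncrna_counts`, `mirna_counts` (matrices),
#'   `design` (data.frame sample_id/tissue/stage/replicate).
#' @export
generate_expression <- function(config, ann) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- ann$truth
  set.seed(config$seed + 1L)
  tissues <- tissue_labels(config$n_tissues)
  stages <- stage_labels(config$n_stages)
  design <- expand.grid(replicate = seq_len(config$n_reps), stage = stages,
                        tissue = tissues, stringsAsFactors = FALSE)
  design <- design[, c("tissue", "stage", "replicate")]
  design$sample_id <- paste(design$tissue, design$stage,
                            paste0("r", design$replicate), sep = "_")
  ns <- nrow(design)
  stage_idx <- match(design$stage, stages)

  lf_rna <- stats::runif(ns, 0.8, 1.2)
  lf_mir <- stats::runif(ns, 0.8, 1.2)

  shift_matrix <- function(ids, class) {
    sh <- matrix(1, nrow = length(ids), ncol = ns,
                 dimnames = list(ids, design$sample_id))
    de <- truth$de_features
    de <- de[de$class == class & de$feature_id %in% ids, , drop = FALSE]
    if (nrow(de) == 0) return(sh)
    comp_idx <- match(de$comparison, truth$comparisons)
    for (r in seq_len(nrow(de))) {
      later <- stage_idx > comp_idx[r]
      sh[de$feature_id[r], later] <-
        2^(de$direction[r] * config$planted_log2fc)
    }
    sh
  }

  draw_counts <- function(ids, class, lf) {
    mu <- config$baseline_mean * shift_matrix(ids, class) *
      matrix(lf, nrow = length(ids), ncol = ns, byrow = TRUE)
    cts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                 size = 1 / config$nb_dispersion),
                  nrow = length(ids),
                  dimnames = list(ids, design$sample_id))
    cts
  }

  mrna <- draw_counts(truth$gene_ids, "mRNA", lf_rna)
  lncrna <- if (length(truth$lnc_ids))
    draw_counts(truth$lnc_ids, "lncRNA", lf_rna) else
    matrix(0, 0, ns, dimnames = list(NULL, design$sample_id))
  mirna <- draw_counts(truth$mirna_ids, "miRNA", lf_mir)

  # planted ceRNA profiles: deterministic rounded log-normal rows
  cer <- truth$cerna_triplets
  if (nrow(cer) > 0) {
    rho <- config$corr_strength
    amp <- 1   # log2 units per latent SD; keeps planted rows a small
               # share of the library so they do not distort FPKM totals
    mix <- function(z, eps) amp * (rho * z + sqrt(1 - rho^2) * eps)
    for (tt in unique(cer$triplet)) {
      rows <- cer[cer$triplet == tt, , drop = FALSE]
      z <- stats::rnorm(ns)
      m_id <- rows$mrna_id[1]; l_id <- rows$lncrna_id[1]
      mrna[m_id, ] <- round(2 * config$baseline_mean *
                              2^mix(z, stats::rnorm(ns)), 3)
      lncrna[l_id, ] <- round(config$baseline_mean *
                                2^mix(z, stats::rnorm(ns)), 3)
      for (mi in rows$mirna_id) {
        mirna[mi, ] <- round(config$baseline_mean *
                               2^(-mix(z, stats::rnorm(ns))), 3)
      }
    }
  }

  list(mrna_counts = mrna, lncrna_counts = lncrna, mirna_counts = mirna,
       design = design[, c("sample_id", "tissue", "stage", "replicate")])
}

#' Generate the miRNA-target table
#'
#' Every planted ceRNA triplet's miRNA lists both its mRNA and its lncRNA as
#' targets; decoy (miRNA, feature) assignments are added independently at
#' rate `decoy_rate` over all non-planted combinations.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element of [generate_annotation()] output.
#' @return data.frame: mirna_id, target_id, target_class.
#' @export
generate_mirna_targets <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  cer <- truth$cerna_triplets
  planted <- if (nrow(cer) > 0) rbind(
    data.frame(mirna_id = cer$mirna_id, target_id = cer$mrna_id,
               target_class = "mRNA", stringsAsFactors = FALSE),
    data.frame(mirna_id = cer$mirna_id, target_id = cer$lncrna_id,
               target_class = "lncRNA", stringsAsFactors = FALSE)) else
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character(), stringsAsFactors = FALSE)
  all_feats <- data.frame(
    target_id = c(truth$gene_ids, truth$lnc_ids),
    target_class = c(rep("mRNA", length(truth$gene_ids)),
                     rep("lncRNA", length(truth$lnc_ids))),
    stringsAsFactors = FALSE)
  combos <- merge(data.frame(mirna_id = truth$mirna_ids,
                             stringsAsFactors = FALSE), all_feats)
  key <- paste(combos$mirna_id, combos$target_id)
  pkey <- paste(planted$mirna_id, planted$target_id)
  candidates <- combos[!key %in% pkey, , drop = FALSE]
  take <- stats::runif(nrow(candidates)) < config$decoy_rate
  out <- rbind(planted,
               candidates[take, c("mirna_id", "target_id", "target_class")])
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate gene-set fixtures
#'
#' Emits one set of planted up-regulated and one of planted down-regulated
#' genes per comparison, plus random decoy sets.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element of [generate_annotation()] output.
#' @return named list of gene-id vectors.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  de <- truth$de_features
  de <- de[de$class == "mRNA", , drop = FALSE]
  sets <- list()
  for (comp in truth$comparisons) {
    up <- de$feature_id[de$comparison == comp & de$direction > 0]
    dn <- de$feature_id[de$comparison == comp & de$direction < 0]
    if (length(up)) sets[[paste0("planted_up_", comp)]] <- up
    if (length(dn)) sets[[paste0("planted_down_", comp)]] <- dn
  }
  size <- min(10, length(truth$gene_ids))
  for (j in seq_len(config$n_random_sets)) {
    sets[[sprintf("random_set_%02d", j)]] <-
      sort(sample(truth$gene_ids, size))
  }
  sets
}

#' Simulate a complete dataset
#'
#' Runs annotation, expression, miRNA-target and gene-set generation from a
#' single configuration.
#'
#' @param config a [simulation_config()].
#' @return list: `annotation` (see [generate_annotation()]), `expression`
#'   (see [generate_expression()]), `mirna_targets`, `gene_sets`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ann <- generate_annotation(config)
  expr <- generate_expression(config, ann)
  targets <- generate_mirna_targets(config, ann$truth)
  sets <- generate_gene_sets(config, ann$truth)
  list(annotation = ann, expression = expr, mirna_targets = targets,
       gene_sets = sets, config = config)
}

#' Write fixture files
#'
#' Serializes a simulated dataset to plain-text files: GTF annotation, TSV
#' count matrices (features as rows, header row of sample ids), sample
#' design TSV, feature lengths TSV, miRNA-target TSV, GMT gene sets, a
#' coding-potential call table and the planted-truth manifest.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return named list of written file paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- sim$annotation
  paths <- list(
    gtf = file.path(dir, "annotation.gtf"),
    mrna = file.path(dir, "mrna_counts.tsv"),
    lncrna = file.path(dir, "lncrna_counts.tsv"),
    mirna = file.path(dir, "mirna_counts.tsv"),
    design = file.path(dir, "design.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    targets = file.path(dir, "mirna_targets.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    coding_calls = file.path(dir, "coding_calls.tsv"),
    truth_de = file.path(dir, "truth_de.tsv"),
    truth_categories = file.path(dir, "truth_categories.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_triplets = file.path(dir, "truth_triplets.tsv"))
  write_annotation_gtf(c(ann$gene_exons, ann$candidate_exons), paths$gtf)
  write_matrix_tsv(sim$expression$mrna_counts, paths$mrna)
  write_matrix_tsv(sim$expression$lncrna_counts, paths$lncrna)
  write_matrix_tsv(sim$expression$mirna_counts, paths$mirna)
  utils::write.table(sim$expression$design, paths$design, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(ann$lengths), length = ann$lengths),
    paths$lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$mirna_targets, paths$targets, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(sim$gene_sets, paths$gmt)
  cand_ids <- unique(as.character(ann$candidate_exons$transcript_id))
  calls <- data.frame(
    transcript_id = c(paste0(ann$truth$gene_ids, ".t1"), cand_ids),
    cpc_coding = c(rep(TRUE, length(ann$truth$gene_ids)),
                   rep(FALSE, length(cand_ids))),
    cnci_coding = c(rep(TRUE, length(ann$truth$gene_ids)),
                    rep(FALSE, length(cand_ids))),
    protein_hit = c(rep(TRUE, length(ann$truth$gene_ids)),
                    rep(FALSE, length(cand_ids))),
    stringsAsFactors = FALSE)
  utils::write.table(calls, paths$coding_calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- ann$truth
  utils::write.table(tr$de_features, paths$truth_de, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(transcript_id = names(tr$lncrna_category),
               category = tr$lncrna_category),
    paths$truth_categories, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$target_pairs, paths$truth_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$cerna_triplets, paths$truth_triplets, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
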