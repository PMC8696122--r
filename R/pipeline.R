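#' Default pipeline configuration
#'
#' Returns the full default configuration: input file paths (as written by
#' [write_fixtures()]), the published analysis thresholds, and run options.
#' Thresholds: |log2FC| > 1, FDR q < 0.05 (mRNA/lncRNA), miRNA raw p < 0.05,
#' cis window 10,000 bp, trans |r| >= 0.9, SCC < -0.7, PCC > 0.9, sponge
#' p < 0.05, |NES| > 1, GSEA p < 0.05, q < 0.25.
#'
#' @return named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    input_dir = NULL,
    output_dir = NULL,
    seed = 1,
    lfc_threshold = 1,
    fdr_threshold = 0.05,
    mirna_p_threshold = 0.05,
    cis_window = 10000,
    trans_r_threshold = 0.9,
    scc_threshold = -0.7,
    pcc_threshold = 0.9,
    sponge_p_threshold = 0.05,
    nes_threshold = 1,
    gsea_p_threshold = 0.05,
    gsea_q_threshold = 0.25,
    bidirectional_window = 1000,
    intergenic_min_distance = 5000,
    targets_de_only = TRUE,
    run_gsea = TRUE,
    gsea_n_perm = 1000,
    gsea_exhaustive_limit = 1000)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills defaults for absent keys,
#' reports every violation rather than failing fast, and warns (not errors)
#' on unknown keys.
#'
#' @param config path to a YAML config file, or a named list.
#' @return list with `config` (defaults-filled) and `errors` (character
#'   vector, empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) stop("cannot parse config: ",
                                                conditionMessage(e)))
    if (is.null(config)) config <- list()
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("unknown config key(s) ignored: ",
            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  errors <- character(0)
  req <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  req(!is.null(cfg$input_dir), "input_dir is required")
  req(is.null(cfg$input_dir) || dir.exists(cfg$input_dir),
      "input_dir does not exist")
  req(!is.null(cfg$output_dir), "output_dir is required")
  req(cfg$lfc_threshold >= 0, "lfc_threshold must be >= 0")
  req(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1,
      "fdr_threshold must lie in (0, 1)")
  req(cfg$mirna_p_threshold > 0 && cfg$mirna_p_threshold < 1,
      "mirna_p_threshold must lie in (0, 1)")
  req(cfg$cis_window > 0, "cis_window must be positive")
  req(cfg$trans_r_threshold > 0 && cfg$trans_r_threshold <= 1,
      "trans_r_threshold must lie in (0, 1]")
  req(cfg$scc_threshold < 0, "scc_threshold must be negative")
  req(cfg$pcc_threshold > 0 && cfg$pcc_threshold <= 1,
      "pcc_threshold must lie in (0, 1]")
  req(cfg$sponge_p_threshold > 0 && cfg$sponge_p_threshold < 1,
      "sponge_p_threshold must lie in (0, 1)")
  req(cfg$nes_threshold >= 0, "nes_threshold must be >= 0")
  list(config = cfg, errors = errors)
}

read_fixture_inputs <- function(dir) {
  list(
    exons = read_annotation_gtf(file.path(dir, "annotation.gtf")),
    mrna = read_matrix_tsv(file.path(dir, "mrna_counts.tsv")),
    lncrna = read_matrix_tsv(file.path(dir, "lncrna_counts.tsv")),
    mirna = read_matrix_tsv(file.path(dir, "mirna_counts.tsv")),
    design = utils::read.delim(file.path(dir, "design.tsv"),
                               stringsAsFactors = FALSE),
    lengths = {
      lt <- utils::read.delim(file.path(dir, "lengths.tsv"),
                              stringsAsFactors = FALSE)
      stats::setNames(lt$length, lt$feature_id)
    },
    targets = utils::read.delim(file.path(dir, "mirna_targets.tsv"),
                                stringsAsFactors = FALSE),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    coding_calls = utils::read.delim(file.path(dir, "coding_calls.tsv"),
                                     stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes lncRNA identification, differential expression, target
#' assignment, ceRNA inference and enrichment in order on a fixture
#' directory, writing per-stage TSV/GraphML artifacts and a summary report
#' (JSON and human-readable text). The report contains lncRNA category
#' counts and percentages, per-comparison DE up/down counts with
#' intersection, sum and union, target-network edge counts per mechanism,
#' ceRNA node counts, and significant-set counts.
#'
#' @param config a config list or YAML path accepted by [validate_config()].
#' @return the report, invisibly (a nested list mirroring report.json).
#' @export
run_pipeline <- function(config) {
  vc <- validate_config(config)
  if (length(vc$errors))
    stop("invalid configuration:\n  ", paste(vc$errors, collapse = "\n  "))
  cfg <- vc$config
  if (!dir.exists(cfg$output_dir))
    dir.create(cfg$output_dir, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  stage <- function(name, expr) {
    message(sprintf("[lncnet] stage %s", name))
    tryCatch(expr, error = function(e) {
      writeLines(name, out("FAILED_STAGE"))
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  inp <- stage("load", read_fixture_inputs(cfg$input_dir))
  coding_tx <- unique(inp$coding_calls$transcript_id[
    inp$coding_calls$cpc_coding | inp$coding_calls$cnci_coding |
      inp$coding_calls$protein_hit])
  gene_exons <- inp$exons[inp$exons$transcript_id %in% coding_tx]
  cand_exons <- inp$exons[!inp$exons$transcript_id %in% coding_tx]

  ## stage 1: identify and classify lncRNAs
  ident <- stage("identify", {
    filt <- filter_novel_transcripts(cand_exons)
    lnc_ids <- consensus_noncoding(inp$coding_calls[
      inp$coding_calls$transcript_id %in%
        unique(as.character(filt$kept$transcript_id)), ])
    lnc_exons <- filt$kept[as.character(filt$kept$transcript_id) %in% lnc_ids]
    cls <- classify_lncrna(lnc_exons, gene_exons,
                           bidirectional_window = cfg$bidirectional_window,
                           intergenic_min_distance =
                             cfg$intergenic_min_distance)
    utils::write.table(cls, out("lncrna_classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(lnc_exons = lnc_exons, classification = cls,
         rejected = filt$rejected)
  })

  ## stage 2: differential expression per tissue and comparison
  de <- stage("de", {
    stages_present <- unique(inp$design$stage)
    comparisons <- cbind(stages_present[-length(stages_present)],
                         stages_present[-1])
    res <- list()
    for (tissue in unique(inp$design$tissue)) {
      for (i in seq_len(nrow(comparisons))) {
        st <- comparisons[i, ]
        key <- paste0(tissue, ".", st[1], "_vs_", st[2])
        res[[paste0(key, ".mRNA")]] <-
          run_de(inp$mrna, inp$lengths, inp$design, tissue, st, "mRNA")
        res[[paste0(key, ".lncRNA")]] <-
          run_de(inp$lncrna, inp$lengths, inp$design, tissue, st, "lncRNA")
        res[[paste0(key, ".miRNA")]] <-
          run_de(inp$mirna, inp$lengths, inp$design, tissue, st, "miRNA")
      }
    }
    tab <- do.call(rbind, c(lapply(names(res), function(k) {
      cbind(tissue = sub("\\..*$", "", k), res[[k]])
    }), make.row.names = FALSE))
    utils::write.table(tab, out("de_results.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res
  })

  de_summary <- stage("de_summary", {
    per_tissue <- list()
    for (tissue in unique(inp$design$tissue)) {
      for (class in c("mRNA", "lncRNA", "miRNA")) {
        keys <- grep(paste0("^", tissue, "\\..*\\.", class, "$"), names(de),
                     value = TRUE)
        comp_res <- stats::setNames(de[keys],
                                    sub(paste0("^", tissue, "\\.(.*)\\.",
                                               class, "$"), "\\1", keys))
        per_tissue[[paste0(tissue, ".", class)]] <- summarize_de(comp_res)
      }
    }
    per_tissue
  })

  ## stage 3: lncRNA target assignment
  tnet <- stage("targets", {
    lnc_exons <- ident$lnc_exons
    fpkm_l <- compute_fpkm(inp$lncrna, inp$lengths)
    fpkm_g <- compute_fpkm(inp$mrna, inp$lengths)
    if (cfg$targets_de_only) {
      de_l <- unique(unlist(lapply(de[grepl("\\.lncRNA$", names(de))],
                                   function(r) r$feature_id[r$call != "ns"])))
      de_g <- unique(unlist(lapply(de[grepl("\\.mRNA$", names(de))],
                                   function(r) r$feature_id[r$call != "ns"])))
      lnc_exons <- lnc_exons[as.character(lnc_exons$transcript_id) %in% de_l]
      gexons <- gene_exons[as.character(gene_exons$gene_id) %in% de_g]
      fpkm_l <- fpkm_l[intersect(rownames(fpkm_l), de_l), , drop = FALSE]
      fpkm_g <- fpkm_g[intersect(rownames(fpkm_g), de_g), , drop = FALSE]
    } else {
      gexons <- gene_exons
    }
    edges <- rbind(antisense_pairs(lnc_exons, gexons),
                   cis_pairs(lnc_exons, gexons, window = cfg$cis_window))
    # trans edges per tissue over its stages x replicates
    for (tissue in unique(inp$design$tissue)) {
      cols <- inp$design$sample_id[inp$design$tissue == tissue]
      if (nrow(fpkm_l) && nrow(fpkm_g)) {
        tr <- suppressWarnings(
          trans_pairs(fpkm_l[, cols, drop = FALSE],
                      fpkm_g[, cols, drop = FALSE],
                      threshold = cfg$trans_r_threshold))
        if (nrow(tr)) edges <- rbind(edges, tr)
      }
    }
    edges <- unique(edges)
    build_target_network(edges, graphml_path = out("target_network.graphml"),
                         tsv_path = out("target_edges.tsv"))
  })

  ## stage 4: ceRNA triplets per tissue
  cerna <- stage("cerna", {
    fpkm_m <- compute_fpkm(inp$mrna, inp$lengths)
    fpkm_l <- compute_fpkm(inp$lncrna, inp$lengths)
    fpkm_mi <- compute_fpkm(inp$mirna, inp$lengths)
    all_triplets <- list()
    for (tissue in unique(inp$design$tissue)) {
      cols <- inp$design$sample_id[inp$design$tissue == tissue]
      mm <- suppressWarnings(negative_coexpression_pairs(
        fpkm_m[, cols, drop = FALSE], fpkm_mi[, cols, drop = FALSE],
        inp$targets[inp$targets$target_class == "mRNA", ],
        threshold = cfg$scc_threshold))
      lm <- suppressWarnings(negative_coexpression_pairs(
        fpkm_l[, cols, drop = FALSE], fpkm_mi[, cols, drop = FALSE],
        inp$targets[inp$targets$target_class == "lncRNA", ],
        threshold = cfg$scc_threshold))
      tri <- build_cerna_triplets(mm, lm, fpkm_m[, cols, drop = FALSE],
                                  fpkm_l[, cols, drop = FALSE],
                                  universe = rownames(inp$mirna),
                                  alpha = cfg$sponge_p_threshold,
                                  pcc_threshold = cfg$pcc_threshold)
      if (nrow(tri)) all_triplets[[tissue]] <- cbind(tissue = tissue, tri)
    }
    triplets <- if (length(all_triplets))
      unique(do.call(rbind, c(all_triplets, make.row.names = FALSE))[
        , -1, drop = FALSE]) else
      build_cerna_triplets(
        data.frame(feature_id = character(), mirna_id = character(),
                   scc = numeric()),
        data.frame(feature_id = character(), mirna_id = character(),
                   scc = numeric()),
        fpkm_m, fpkm_l, universe = rownames(inp$mirna))
    export_cerna_network(triplets, graphml_path = out("cerna_network.graphml"),
                         tsv_path = out("cerna_triplets.tsv"))
  })

  ## stage 5: enrichment (ORA on DE genes; GSEA per comparison, tissues
  ## pooled so the relabeling space supports a meaningful permutation p)
  enrich <- stage("enrichment", {
    universe <- rownames(inp$mrna)
    de_genes <- unique(unlist(lapply(de[grepl("\\.mRNA$", names(de))],
                                     function(r) r$feature_id[r$call != "ns"])))
    ora <- run_ora(de_genes, inp$gene_sets, universe)
    utils::write.table(ora, out("ora_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gsea_sig <- 0L
    if (isTRUE(cfg$run_gsea)) {
      # signal-to-noise uses natural-scale FPKM: its sd floor (0.2 * |mean|)
      # is calibrated for natural-scale expression and saturates on log data
      lexpr <- compute_fpkm(inp$mrna, inp$lengths)
      stages_present <- unique(inp$design$stage)
      gres <- list()
      for (i in seq_len(length(stages_present) - 1)) {
        sa <- inp$design$sample_id[inp$design$stage == stages_present[i]]
        sb <- inp$design$sample_id[inp$design$stage == stages_present[i + 1]]
        r <- gsea_nes(lexpr, sa, sb, inp$gene_sets,
                      n_perm = cfg$gsea_n_perm,
                      exhaustive_limit = cfg$gsea_exhaustive_limit,
                      seed = cfg$seed + i)
        r$comparison <- paste0(stages_present[i], "_vs_",
                               stages_present[i + 1])
        gres[[i]] <- r
      }
      gall <- do.call(rbind, gres)
      utils::write.table(gall, out("gsea_results.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      gsea_sig <- nrow(significant_sets(gall, cfg$nes_threshold,
                                        cfg$gsea_p_threshold,
                                        cfg$gsea_q_threshold))
    }
    list(ora = ora, n_ora_significant = sum(ora$p < 0.05),
         n_gsea_significant = gsea_sig)
  })

  report <- list(
    thresholds = cfg[c("lfc_threshold", "fdr_threshold", "mirna_p_threshold",
                       "cis_window", "trans_r_threshold", "scc_threshold",
                       "pcc_threshold", "sponge_p_threshold",
                       "nes_threshold", "gsea_p_threshold",
                       "gsea_q_threshold")],
    lncrna_categories = summarize_categories(ident$classification),
    n_rejected_transcripts = nrow(ident$rejected),
    de = lapply(de_summary, function(s)
      list(per_comparison = s$per_comparison, sum_total = s$sum_total,
           union_size = s$union_size, intersections = s$intersections)),
    target_network = tnet$counts[names(tnet$counts) != "graph"],
    cerna_network = cerna$counts,
    enrichment = enrich[c("n_ora_significant", "n_gsea_significant")])
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  txt <- c("lncnet pipeline report",
           "======================",
           "",
           "lncRNA categories:",
           utils::capture.output(print(report$lncrna_categories)),
           "",
           paste0("target network edges: ", tnet$counts$n_edges,
                  " (antisense ", tnet$counts$antisense,
                  ", cis ", tnet$counts$cis,
                  ", trans ", tnet$counts$trans, ")"),
           paste0("ceRNA triplets: ", cerna$counts$n_triplets,
                  " (", cerna$counts$n_lncrna, " lncRNAs, ",
                  cerna$counts$n_mirna, " miRNAs, ",
                  cerna$counts$n_mrna, " mRNAs)"),
           paste0("ORA significant sets (p < 0.05): ",
                  enrich$n_ora_significant),
           paste0("GSEA significant sets: ", enrich$n_gsea_significant))
  writeLines(txt, out("report.txt"))
  invisible(report)
}
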