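# A compact configuration keeps the simulation tests fast; study-scale
# conditions (2 x 3 x 3 design, lfc 2, dispersion 0.05) are exercised in the
# acceptance suite.
small_config <- function(...) {
  simulation_config(seed = 101, n_genes = 24, n_lncrna = 12, n_mirna = 12,
                    n_cerna_triplets = 3, ...)
}

test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(category_mix = c(intergenic = 0.5)),
               "sum to 1")
  expect_error(simulation_config(category_mix = c(nonsense = 1)), "among")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(frac_de = 1.5), "frac_de")
  expect_error(simulation_config(corr_strength = 0), "corr_strength")
  expect_error(simulation_config(n_stages = 1), "design requires")
})

test_that("identical config produces byte-identical fixtures", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_fixtures(simulate_dataset(small_config()), d1)
  write_fixtures(simulate_dataset(small_config()), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("single-category mix and empty lncRNA set are honored", {
  cfg <- simulation_config(seed = 3, n_genes = 10, n_lncrna = 6,
                           n_mirna = 10, n_cerna_triplets = 2,
                           category_mix = c(intergenic = 1))
  ann <- generate_annotation(cfg)
  cls <- classify_lncrna(ann$lnc_exons, ann$gene_exons)
  expect_true(all(cls$category == "intergenic"))
  cfg0 <- simulation_config(seed = 3, n_genes = 10, n_lncrna = 0,
                            n_mirna = 5, n_cerna_triplets = 0)
  ann0 <- generate_annotation(cfg0)
  expect_length(ann0$lnc_exons, 0)
  expect_equal(length(unique(ann0$gene_exons$gene_id)), 10)
})

test_that("planted categories round-trip through the classifier exactly", {
  ann <- generate_annotation(small_config())
  cls <- classify_lncrna(ann$lnc_exons, ann$gene_exons)
  expect_equal(stats::setNames(cls$category, cls$transcript_id)[
    names(ann$truth$lncrna_category)],
    ann$truth$lncrna_category)
  # a planted antisense lncRNA sits opposite its host gene
  anti <- names(ann$truth$lncrna_category)[
    ann$truth$lncrna_category == "antisense"][1]
  rec <- classify_lncrna(
    ann$lnc_exons[ann$lnc_exons$transcript_id == anti], ann$gene_exons)
  expect_equal(rec$category, "antisense")
})

test_that("deliberate filter failures are emitted and rejected", {
  ann <- generate_annotation(small_config(n_filter_fail = 4))
  res <- filter_novel_transcripts(ann$candidate_exons)
  expect_setequal(res$rejected$transcript_id, sprintf("cand_fail%02d", 1:4))
  expect_setequal(unique(res$kept$transcript_id), ann$truth$lnc_ids)
})

test_that("count marginals match the configured baseline", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  truth <- sim$annotation$truth
  planted <- unique(c(truth$de_features$feature_id,
                      truth$cerna_triplets$mrna_id))
  null_genes <- setdiff(truth$gene_ids, planted)
  x <- colMeans(sim$expression$mrna_counts[null_genes, ])
  # per-sample means absorb the library-size factors; their spread defines
  # the standard error of the grand mean
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - cfg$baseline_mean), 3 * se)
})

test_that("noiseless limit gives exact planted correlation structure", {
  cfg <- small_config(corr_strength = 1)
  sim <- simulate_dataset(cfg)
  ex <- sim$expression
  cer <- sim$annotation$truth$cerna_triplets
  for (i in seq_len(nrow(cer))) {
    m <- ex$mrna_counts[cer$mrna_id[i], ]
    l <- ex$lncrna_counts[cer$lncrna_id[i], ]
    mi <- ex$mirna_counts[cer$mirna_id[i], ]
    expect_equal(spearman_cc(mi, m), -1)
    expect_equal(spearman_cc(mi, l), -1)
    expect_gt(cor(m, l), 0.999999)
  }
})

test_that("miRNA-target table contains planted rows plus binomial decoys", {
  cfg <- small_config(decoy_rate = 0)
  sim <- simulate_dataset(cfg)
  tab <- sim$mirna_targets
  cer <- sim$annotation$truth$cerna_triplets
  expect_equal(nrow(tab), 2 * nrow(cer))   # exactly the planted pairs
  for (i in seq_len(nrow(cer))) {
    expect_true(any(tab$mirna_id == cer$mirna_id[i] &
                      tab$target_id == cer$mrna_id[i]))
    expect_true(any(tab$mirna_id == cer$mirna_id[i] &
                      tab$target_id == cer$lncrna_id[i]))
  }
  # decoy count within 3 SD of the binomial expectation
  cfg2 <- small_config(decoy_rate = 0.5)
  tab2 <- generate_mirna_targets(cfg2, sim$annotation$truth)
  n_candidates <- cfg2$n_mirna * (cfg2$n_genes + cfg2$n_lncrna) -
    2 * nrow(cer)
  n_decoys <- nrow(tab2) - 2 * nrow(cer)
  expected <- n_candidates * 0.5
  expect_lt(abs(n_decoys - expected), 3 * sqrt(n_candidates * 0.25))
})

test_that("fixtures round-trip exactly through their file formats", {
  sim <- simulate_dataset(small_config())
  dir <- file.path(tempdir(), "simRT")
  paths <- write_fixtures(sim, dir)
  expect_equal(read_matrix_tsv(paths$mrna), sim$expression$mrna_counts)
  expect_equal(read_matrix_tsv(paths$mirna), sim$expression$mirna_counts)
  expect_equal(read_gmt(paths$gmt), sim$gene_sets)
  # GTF re-parse reproduces exon structures
  reread <- read_annotation_gtf(paths$gtf)
  orig <- c(sim$annotation$gene_exons, sim$annotation$candidate_exons)
  key <- function(g) sort(paste(g$transcript_id,
                                GenomicRanges::seqnames(g),
                                GenomicRanges::start(g),
                                GenomicRanges::end(g),
                                GenomicRanges::strand(g)))
  expect_equal(key(reread), key(orig))
})

test_that("planted DE features are recovered by the DE stage", {
  sim <- simulate_dataset(small_config())
  ann <- sim$annotation; ex <- sim$expression
  truth <- ann$truth$de_features
  r <- run_de(ex$mrna_counts, ann$lengths, ex$design, "brain",
              c("IV", "V"), "mRNA")
  planted <- truth$feature_id[truth$comparison == "IV_vs_V" &
                                truth$class == "mRNA"]
  called <- r$feature_id[r$call != "ns"]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.8)
  # planted direction agrees with the call
  dirs <- truth$direction[match(intersect(called, planted),
                                truth$feature_id)]
  calls <- r$call[match(intersect(called, planted), r$feature_id)]
  expect_true(all(ifelse(dirs > 0, "up", "down") == calls))
})
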