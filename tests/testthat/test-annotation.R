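test_that("structural filter applies the >=200 bp and >=2 exon rules", {
  tx <- c(
    exons_gr("chr1", c(1000, 1200), c(1099, 1299), "+", "t_pass"),   # 200 bp
    exons_gr("chr1", c(2000, 2200), c(2098, 2299), "+", "t_short"),  # 199 bp
    exons_gr("chr1", 3000, 7999, "+", "t_monoexonic"))               # 1 exon
  res <- filter_novel_transcripts(tx)
  expect_setequal(unique(res$kept$transcript_id), "t_pass")
  expect_setequal(res$rejected$transcript_id, c("t_short", "t_monoexonic"))
  expect_equal(res$rejected$reason[res$rejected$transcript_id == "t_short"],
               "length")
  expect_equal(
    res$rejected$reason[res$rejected$transcript_id == "t_monoexonic"],
    "exon_count")
})

test_that("structural filter is idempotent and validates exon structure", {
  tx <- c(exons_gr("chr1", c(100, 400), c(250, 700), "+", "a"),
          exons_gr("chr1", c(900, 1100), c(1000, 1190), "-", "b"))
  once <- filter_novel_transcripts(tx)
  twice <- filter_novel_transcripts(once$kept)
  expect_identical(sort(unique(once$kept$transcript_id)),
                   sort(unique(twice$kept$transcript_id)))
  bad <- exons_gr("chr1", c(100, 150), c(200, 400), "+", "overlapper")
  expect_error(filter_novel_transcripts(bad), "overlapper")
})

test_that("coding-potential consensus is the three-way intersection", {
  calls <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    cpc_coding = c(FALSE, FALSE, TRUE, FALSE),
    cnci_coding = c(FALSE, FALSE, FALSE, FALSE),
    protein_hit = c(FALSE, TRUE, FALSE, FALSE))
  expect_setequal(consensus_noncoding(calls), c("t1", "t4"))
  expect_length(consensus_noncoding(calls[0, ]), 0)
  calls$protein_hit[1] <- NA
  expect_error(consensus_noncoding(calls), "t1")
  expect_error(consensus_noncoding(calls, verdict_cols = c("a", "b")),
               "three")
})

test_that("ORF heuristic thresholds at 100 codons and matches a naive scan", {
  expect_false(orf_heuristic(random_no_atg(90)))
  long_orf <- paste0("ATG", strrep("GCC", 299), "TAA")
  expect_true(orf_heuristic(long_orf))
  expect_error(orf_heuristic("ATGXX"), "non-ACGTN")
  # boundary pair verified against the enumeration oracle
  orf99 <- paste0("CC", "ATG", strrep("GGA", 98), "TAG")
  orf100 <- paste0("CC", "ATG", strrep("GGA", 99), "TAG")
  expect_identical(longest_orf_codons(orf99), 99L)
  expect_identical(longest_orf_codons(orf100), 100L)
  expect_false(orf_heuristic(orf99))
  expect_true(orf_heuristic(orf100))
  # random sequences: heuristic agrees with the oracle at several thresholds
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    expect_identical(orf_heuristic(s, min_codons = 10),
                     longest_orf_codons(s) >= 10)
    expect_identical(orf_heuristic(s, min_codons = 25),
                     longest_orf_codons(s) >= 25)
  }
})

test_that("positional classifier assigns the five categories by geometry", {
  gene <- gene_gr(100000, "+")
  cases <- list(
    antisense = exons_gr("chr1", c(100500, 101400), c(101200, 101800), "-",
                         "l_anti"),
    sense_overlapping = exons_gr("chr1", c(100500, 101400),
                                 c(101200, 101800), "+", "l_sense"),
    intronic = exons_gr("chr1", c(102000, 102600), c(102299, 102899), "-",
                        "l_intr"),
    bidirectional = exons_gr("chr1", c(98300, 98800), c(98600, 99200), "-",
                             "l_bidir"),
    intergenic = exons_gr("chr1", c(200000, 200600), c(200399, 200999), "+",
                          "l_inter"),
    other = exons_gr("chr1", c(121000, 121600), c(121399, 121999), "+",
                     "l_other"))  # 2 kb gap: near but not divergent
  for (cat in names(cases)) {
    rec <- classify_lncrna(cases[[cat]], gene)
    expect_equal(rec$category, cat, info = cat)
    expect_equal(rec$nearest_gene, "geneA")
  }
  # distances: intergenic case gap = 200000 - 118999 - 1
  rec <- classify_lncrna(cases$intergenic, gene)
  expect_equal(rec$distance_bp, 200000 - 119000)
})

test_that("antisense and sense_overlapping swap under strand flip", {
  gene <- gene_gr(100000, "+")
  lnc <- exons_gr("chr1", c(100500, 101400), c(101200, 101800), "-", "l1")
  expect_equal(classify_lncrna(lnc, gene)$category, "antisense")
  flipped <- GenomicRanges::invertStrand(lnc)
  expect_equal(classify_lncrna(flipped, gene)$category, "sense_overlapping")
})

test_that("classification is a partition and tolerates empty annotation", {
  gene <- gene_gr(100000, "+")
  lncs <- c(exons_gr("chr1", c(100500, 101400), c(101200, 101800), "-", "a"),
            exons_gr("chr1", c(300000, 300500), c(300400, 300900), "+", "b"))
  rec <- classify_lncrna(lncs, gene)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$category %in% c("intergenic", "bidirectional",
                                      "intronic", "antisense",
                                      "sense_overlapping", "other")))
  expect_warning(rec2 <- classify_lncrna(lncs, gene[0]), "intergenic")
  expect_true(all(rec2$category == "intergenic"))
})

test_that("category summary computes half-up percentages that partition", {
  one <- summarize_categories(data.frame(category = "antisense"))
  expect_equal(one$percentage, 100.0)
  two <- summarize_categories(c(x = 1L, y = 3L))
  expect_equal(two$percentage[two$category == "x"], 25.0)
  expect_equal(two$percentage[two$category == "y"], 75.0)
  empty <- summarize_categories(data.frame(category = character()))
  expect_equal(nrow(empty), 0)
  # half-up rounding: 1/8 of total = 12.5 stays 12.5; 49.85 rounds up
  expect_equal(summarize_categories(c(a = 1L, b = 7L))$percentage,
               c(12.5, 87.5))
})
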