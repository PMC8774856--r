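test_that("CDS extraction frames codons and completes incomplete terminators", {
  g <- toy_gene_genome("ATGAAATAA")
  cds <- extract_cds(g, "g1")
  expect_equal(cds$codons, c("ATG", "AAA", "TAA"))
  expect_equal(cds$stop_completion, "none")
  expect_identical(classify_start_stop(cds), c(start = "ATG", stop = "TAA_complete"))

  gg <- generate_genome(genome_spec(seed = 21))
  nad4 <- extract_cds(gg$genome, "nad4")       # size 1378, trailing T
  expect_equal(nad4$stop_completion, "T_plus_AA")
  expect_equal(length(nad4$codons), 460)
  expect_equal(nad4$stop_codon, "TAA")
  nad1 <- extract_cds(gg$genome, "nad1")       # size 956, trailing TA
  expect_equal(nad1$stop_completion, "TA_plus_A")
  expect_identical(classify_start_stop(extract_cds(gg$genome, "nad2")),
                   c(start = "ATT", stop = "incomplete_T"))
  expect_identical(classify_start_stop(extract_cds(gg$genome, "cytb")),
                   c(start = "ATG", stop = "AGA_complete"))
  # L-strand gene extracts on its coding strand
  nad6 <- extract_cds(gg$genome, "nad6")
  expect_equal(nad6$start_codon, "ATG")
  expect_true(nad6$start_is_atn)
})

test_that("internal in-frame stops are rejected with their position", {
  g <- toy_gene_genome("ATGTAACCCTAA")
  err <- tryCatch(extract_cds(g, "g1"), error = function(e) e)
  expect_s3_class(err, "mp_internal_stop")
  expect_match(conditionMessage(err), "codon 2")
})

test_that("codon usage pools genes, reports percents and bins N codons", {
  g <- toy_gene_genome("ATGTAA")
  u <- codon_usage(extract_cds(g, "g1"))
  expect_equal(unname(u$percent["ATG"]), 50)
  expect_equal(unname(u$percent["TAA"]), 50)
  expect_equal(u$total_codons, 2)
  expect_equal(sum(u$percent), 100)
  gN <- mitogenome("n", "ATGNNATAA",
                   feature_table(data.frame(name = "g1", kind = "PCG",
                                            start = 1, end = 9, strand = "H")))
  uN <- codon_usage(extract_cds(gN, "g1"))
  expect_equal(uN$n_discarded, 1)
  expect_equal(uN$total_codons, 2)
})

test_that("published codon percents aggregate to the printed amino-acid frequencies", {
  tab <- read.delim(system.file("extdata", "codon_usage_reference.tsv",
                                package = "mitoprofile"), comment.char = "#")
  pct <- setNames(tab$percent, tab$codon)
  aa <- aa_percent_from_codon_percent(pct)
  expect_equal(unname(aa["I"]), 8.64)
  expect_equal(unname(aa["S"]), 7.49)
  expect_equal(unname(aa["C"]), 0.68)
  expect_equal(unname(aa["D"]), 1.76)
  expect_equal(unname(aa["Q"]), 2.31)
  expect_equal(unname(aa["H"]), 2.52)
  expect_equal(unname(aa["L"]), 16.00)
  # the bundled table is internally consistent with the genetic code mapping
  expect_equal(unname(mito_code()[tab$codon]), tab$aa)
})

test_that("RSCU: family sums equal family size; published Leu percents give CTA = 2.70", {
  # uniform usage in every family -> all RSCU 1
  counts <- setNames(rep(5L, 64), names(mito_code()))
  u <- structure(list(counts = counts), class = "codon_usage")
  r <- rscu(u)
  expect_true(all(abs(r - 1) < 1e-12))
  # single codon used among the 6 Leu codons
  counts2 <- setNames(rep(0L, 64), names(mito_code()))
  counts2["CTA"] <- 10L
  u2 <- structure(list(counts = counts2), class = "codon_usage")
  r2 <- rscu(u2)
  expect_equal(unname(r2["CTA"]), 6)
  expect_equal(unname(r2["CTT"]), 0)
  expect_true(is.na(r2["GGA"]))     # empty family -> NA
  # family sums = family size for nonzero families (random usage)
  set.seed(1)
  counts3 <- setNames(sample(0:50, 64, replace = TRUE), names(mito_code()))
  u3 <- structure(list(counts = counts3), class = "codon_usage")
  r3 <- rscu(u3)
  fam <- split(names(mito_code()), unname(mito_code()))
  for (codons in fam) {
    if (sum(counts3[codons]) > 0) {
      expect_equal(sum(r3[codons]), length(codons))
    }
  }
  # printed Leu percents: RSCU(CTA) = 7.20 / (16.00 / 6)
  leu <- c(TTA = 3.31, TTG = 0.58, CTT = 1.89, CTC = 1.92, CTA = 7.20, CTG = 1.10)
  counts4 <- setNames(rep(0, 64), names(mito_code()))
  counts4[names(leu)] <- leu * 100   # scale-free
  u4 <- structure(list(counts = counts4), class = "codon_usage")
  expect_equal(round(unname(rscu(u4)["CTA"]), 2), 2.70)
})

test_that("ENc spans [20, 60] from maximal bias to no bias and ignores scaling", {
  # uniform usage of all 60 sense codons
  counts <- setNames(rep(10L, 64), names(mito_code()))
  counts[c("TAA", "TAG", "AGA", "AGG")] <- 0L
  u <- structure(list(counts = counts), class = "codon_usage")
  expect_equal(as.numeric(enc(u)), 60, tolerance = 1e-9)
  # exactly one codon per amino acid: 12 + 6 + 2 families -> 20
  fam <- split(names(mito_code()), unname(mito_code()))
  fam <- fam[names(fam) != "*"]
  counts2 <- setNames(rep(0L, 64), names(mito_code()))
  for (codons in fam) counts2[sort(codons)[1]] <- 30L
  u2 <- structure(list(counts = counts2), class = "codon_usage")
  expect_equal(as.numeric(enc(u2)), 20)
  # invariance to total scaling
  u3 <- structure(list(counts = counts * 7L), class = "codon_usage")
  expect_equal(as.numeric(enc(u3)), as.numeric(enc(u)))
  expect_error(enc(structure(list(counts = setNames(rep(0L, 64), names(mito_code()))),
                             class = "codon_usage")),
               class = "mp_parameter_error")
})

test_that("CBI is 1 for pure optimal usage and 0 for uniform usage", {
  fam <- split(names(mito_code()), unname(mito_code()))
  fam <- fam[names(fam) != "*"]
  counts <- setNames(rep(0L, 64), names(mito_code()))
  for (codons in fam) counts[sort(codons)[1]] <- 20L
  u <- structure(list(counts = counts), class = "codon_usage")
  expect_equal(cbi(u), 1)
  counts2 <- setNames(rep(6L, 64), names(mito_code()))
  u2 <- structure(list(counts = counts2), class = "codon_usage")
  expect_equal(cbi(u2), 0, tolerance = 1e-12)
})

test_that("GC3s and the expected-ENc curve follow their closed forms", {
  counts <- setNames(rep(0L, 64), names(mito_code()))
  counts[c("ATG", "CAG", "GGG")] <- 4L     # all third positions G
  u <- structure(list(counts = counts), class = "codon_usage")
  expect_equal(gc3s(u), 1)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 2 + 1 + 29)
  # stop codons are excluded from GC3s
  counts["TAA"] <- 100L
  u2 <- structure(list(counts = counts), class = "codon_usage")
  expect_equal(gc3s(u2), 1)
})

test_that("per-gene bias table is consistent and bounded on a synthetic genome", {
  gg <- generate_genome(genome_spec(seed = 13))
  tab <- codon_bias_table(gg$genome)
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$enc >= 20 & tab$enc <= 60))
  expect_true(all(tab$cbi <= 1))
  expect_true(all(tab$gc3s >= 0 & tab$gc3s <= 1))
  # pooled codon count ties back to gene sizes: ceil(size/3) per gene
  ft <- gg$genome$features
  expect_equal(tab$n_codons[tab$gene == "overall"],
               sum(ceiling(ft$size[ft$kind == "PCG"] / 3)))
})
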