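test_that("variant calling types substitutions and merges gap runs", {
  aln0 <- mito_alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_equal(nrow(call_variants(aln0)), 0)
  # one A/G column, one A/T column, one 2-bp gap run
  aln <- mito_alignment(c(ref = "AAGTACGTA",
                          s1  = "AGGTACGTA",
                          s2  = "AAGT--GTT"))
  calls <- call_variants(aln)
  expect_equal(sum(calls$kind == "transition"), 1)
  expect_equal(sum(calls$kind == "transversion"), 1)
  expect_equal(sum(calls$kind == "indel"), 1)
  ind <- calls[calls$kind == "indel", ]
  expect_equal(ind$ref_position, 4)      # preceding reference base
  expect_equal(ind$carriers, "s2")
  tv <- calls[calls$kind == "transversion", ]
  expect_equal(tv$ref_position, 9)
  expect_equal(tv$carriers, "s2")
  ts <- calls[calls$kind == "transition", ]
  expect_equal(ts$ref_position, 2)
  expect_equal(ts$carriers, "s1")
  expect_error(call_variants(mito_alignment(c(a = "ACGT"))),
               class = "mp_alignment_error")
})

test_that("insertions relative to the reference take the preceding base's position", {
  aln <- mito_alignment(c(ref = "ACG--TT", alt = "ACGGGTT"))
  calls <- call_variants(aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "indel")
  expect_equal(calls$ref_position, 3)
  expect_equal(calls$carriers, "alt")
})

test_that("coding effects follow the mitochondrial code, including L-strand genes", {
  g <- toy_gene_genome("ATGCTACCCTACTAA")       # ATG CTA CCC TAC TAA
  ft <- g$features
  # third-position Leu change CTA -> CTG: synonymous
  expect_equal(classify_coding_effect(6, "A", "G", g$sequence, ft), "synonymous")
  # TAC -> TAA mid-gene: nonsense
  expect_equal(classify_coding_effect(12, "C", "A", g$sequence, ft), "nonsense")
  # outside any PCG
  ft2 <- feature_table(data.frame(name = "g1", kind = "PCG", start = 1,
                                  end = 6, strand = "H"))
  expect_equal(classify_coding_effect(9, "C", "A", g$sequence, ft2), "noncoding")
  # GCA -> GTA (Ala -> Val): missense
  g2 <- toy_gene_genome("ATGGCATAA")
  expect_equal(classify_coding_effect(5, "C", "T", g2$sequence, g2$features),
               "missense")
  # systematic check: all 9 single-base mutants of codon 2 agree with the code
  code <- mito_code()
  for (within in 1:3) {
    pos <- 3 + within
    ref <- substr("GCA", within, within)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      altc <- "GCA"; substr(altc, within, within) <- alt
      expected <- if (code[[altc]] == code[["GCA"]]) "synonymous"
                  else if (code[[altc]] == "*") "nonsense" else "missense"
      expect_equal(classify_coding_effect(pos, ref, alt, g2$sequence, g2$features),
                   expected, info = altc)
    }
  }
  # L-strand gene: alleles are complemented onto the coding strand
  gl <- toy_gene_genome("ATGGCATAA", strand = "L")
  # genomic position of the GCA codon's middle base on the L strand
  # coding position 5 maps to genomic end - 5 + 1 = 5; allele on H is comp(C)=G
  expect_equal(classify_coding_effect(5, "G", "A", gl$sequence, gl$features),
               "missense")
})

test_that("incidence reproduces the published arithmetic", {
  i1 <- incidence(54, 16504)
  expect_equal(i1$one_per_bp, 305.6)
  expect_equal(i1$percent, 0.33)
  expect_equal(incidence(0, 100)$label, "none")
  i2 <- incidence(1, 100)
  expect_equal(i2$one_per_bp, 100.0)
  expect_equal(i2$percent, 1.00)
})

test_that("haplotype diversity of the published partition (2,1,1,1,1; n = 6) is 0.9333", {
  rows <- c(a = "AAAA", b = "AAAA", c = "AAAT", d = "AATA", e = "ATAA", f = "TAAA")
  ds <- diversity_stats(mito_alignment(rows))
  expect_equal(ds$n_haplotypes, 5)
  expect_equal(round(ds$hd, 4), 0.9333)
  # closed form: n/(n-1) * (1 - sum p^2)
  expect_equal(ds$hd, 6 / 5 * (1 - sum((c(2, 1, 1, 1, 1) / 6)^2)))
})

test_that("pi and k follow from direct pairwise counts", {
  ds <- diversity_stats(mito_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT")))
  expect_equal(ds$pi, 0.1)
  expect_equal(ds$k, 1)
  expect_equal(ds$c_index, 0.9)
  for (s in 1:10) {
    rows <- vapply(1:5, function(i) random_seq(50, seed = 1000 + 10 * s + i),
                   character(1))
    names(rows) <- paste0("r", 1:5)
    ds <- diversity_stats(mito_alignment(rows))
    orc <- oracle_diversity(rows)
    expect_equal(ds$pi, orc$pi)
    expect_equal(ds$k, orc$k)
    expect_equal(ds$n_variable_sites, orc$n_variable)
    expect_equal(ds$n_parsimony_informative_sites, orc$n_pinf)
    expect_equal(ds$n_singleton_sites, orc$n_singleton)
    expect_equal(ds$c_index + orc$n_variable / orc$S, 1)
  }
})

test_that("hd is order-invariant and zero for a single haplotype", {
  rows <- c(a = "ACGT", b = "ACGT", c = "ACTT", d = "AGGT")
  h1 <- diversity_stats(mito_alignment(rows))$hd
  h2 <- diversity_stats(mito_alignment(rows[c(3, 1, 4, 2)]))$hd
  expect_equal(h1, h2)
  same <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_equal(diversity_stats(mito_alignment(same))$hd, 0)
  expect_equal(haplotype_partition(mito_alignment(same))$n_haplotypes, 1)
})

test_that("indel columns split haplotypes only when requested", {
  rows <- c(a = "ACGTA", b = "ACGTA", c = "ACG-A")
  p1 <- haplotype_partition(mito_alignment(rows), include_indels = FALSE)
  expect_equal(p1$n_haplotypes, 1)
  p2 <- haplotype_partition(mito_alignment(rows), include_indels = TRUE)
  expect_equal(p2$n_haplotypes, 2)
})

test_that("haplotype network is the union of all minimum spanning trees", {
  rows <- c(a = "AAAA", b = "AAAT")
  aln <- mito_alignment(rows)
  p <- haplotype_partition(aln)
  net <- haplotype_network(p, aln)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  # 3 haplotypes at mutual distances 1,1,2: path through the two 1-edges
  rows3 <- c(a = "AAAA", b = "AAAT", c = "AATA")   # a-b 1, a-c 1, b-c 2
  aln3 <- mito_alignment(rows3)
  net3 <- haplotype_network(haplotype_partition(aln3), aln3)
  expect_equal(nrow(net3$edges), 2)
  expect_true(all(net3$edges$weight == 1))
  # randomized check against exhaustive spanning-tree enumeration
  for (s in 1:5) {
    rows <- vapply(1:5, function(i) random_seq(40, seed = 2000 + 10 * s + i),
                   character(1))
    names(rows) <- paste0("r", 1:5)
    aln <- mito_alignment(rows)
    p <- haplotype_partition(aln)
    if (p$n_haplotypes < 3) next
    net <- haplotype_network(p, aln)
    idx <- function(h) match(h, p <- rownames(net$distances))
    got <- sort(apply(net$edges, 1, function(e) {
      paste(sort(c(match(e[["from"]], rownames(net$distances)),
                   match(e[["to"]], rownames(net$distances)))), collapse = "-")
    }))
    expect_equal(got, oracle_msn_edges(net$distances))
  }
})

test_that("variant totals are conserved across kinds", {
  gg <- generate_genome(genome_spec(seed = 17))
  sim <- simulate_haplotypes(gg, mutation_spec(seed = 5))
  calls <- call_variants(sim$alignment)
  expect_equal(sum(calls$kind %in% c("transition", "transversion", "indel")),
               nrow(calls))
})

test_that("windowed variability flags planted hypervariable segments", {
  base <- strrep("A", 300)
  rows <- c(ref = base, s1 = base, s2 = base)
  # plant variants only in columns 100-120
  for (pos in seq(100, 120, by = 4)) substr(rows["s1"], pos, pos) <- "G"
  aln <- mito_alignment(rows)
  vt <- variability_track(aln, window = 50, step = 10,
                          hvs_min_incidence = 2 / 50)
  expect_equal(nrow(vt$hvs), 1)
  expect_lte(vt$hvs$start, 100)
  expect_gte(vt$hvs$end, 120)
  # no variants -> C = 1 everywhere, no HVS
  clean <- mito_alignment(c(a = base, b = base))
  vt0 <- variability_track(clean, window = 50, step = 10)
  expect_true(all(vt0$track$C == 1))
  expect_equal(nrow(vt0$hvs), 0)
})
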