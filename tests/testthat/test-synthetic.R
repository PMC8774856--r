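test_that("the generator is deterministic under seed and distinct across seeds", {
  g1 <- generate_genome(genome_spec(seed = 3))
  g2 <- generate_genome(genome_spec(seed = 3))
  g3 <- generate_genome(genome_spec(seed = 4))
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("realized composition tracks the published fractions", {
  gg <- generate_genome(genome_spec(seed = 19))
  p <- base_stats(gg$genome$sequence)
  expect_equal(p$at_percent, 60.06, tolerance = 0.017)  # within ~1 point
  cnt <- unlist(p$counts[c("nA", "nT", "nC", "nG")])
  expect_true(all(diff(rev(c(cnt["nA"], cnt["nT"], cnt["nC"], cnt["nG"]))) > 0) ||
              cnt["nA"] > cnt["nT"] && cnt["nT"] > cnt["nC"] && cnt["nC"] > cnt["nG"])
})

test_that("planted minisatellite arrays are recovered by the tandem scanner", {
  gg <- generate_genome(genome_spec(rs3_copies = 22, seed = 29))
  rs3 <- gg$truth[gg$truth$name == "RS3", ]
  cr <- gg$truth[gg$truth$name == "CR", ]
  hits <- find_tandem_repeats(substr(gg$genome$sequence, cr$start, cr$end))
  hits$start <- hits$start + cr$start - 1
  hits$end <- hits$end + cr$start - 1
  hit <- hits[hits$start <= rs3$start + 5 & hits$end >= rs3$end - 5, , drop = FALSE]
  expect_gte(nrow(hit), 1)
  top <- hit[which.max(hit$score), ]
  expect_equal(top$period, 10)
  expect_equal(top$copies, 22, tolerance = 0.3 / 22)
  expect_gte(top$percent_matches, 98)
})

test_that("every planted element is recovered by its scanner across seeds", {
  for (s in 1:20) {
    cr <- assemble_control_region(seed = 5000 + s)
    ann <- annotate_control_region(cr$sequence)
    expect_length(ann$missing, 0)
  }
  # the planted replication-origin hairpin is found genome-wide
  gg <- generate_genome(genome_spec(seed = 37))
  ol <- gg$truth[gg$truth$name == "OL", ]
  hp <- find_hairpins(substr(gg$genome$sequence, ol$start - 20, ol$end + 20),
                      stem_min = 5, loop_min = 3, loop_max = 20)
  top <- hp[which.max(hp$arm_length), ]
  expect_equal(top$arm_length, 11)
  expect_equal(top$loop_length, 13)
})

test_that("mutation simulator honours its contracts", {
  gg <- generate_genome(genome_spec(seed = 41))
  # mu = 0: identical rows, pi = 0
  sim0 <- simulate_haplotypes(gg, mutation_spec(mu = 0, indel_rate = 0,
                                                vntr_copy_sd = 0, seed = 1))
  expect_equal(length(unique(sim0$alignment$rows)), 1)
  expect_equal(diversity_stats(sim0$alignment)$pi, 0)
  # multiple-hit regime refused
  expect_error(mutation_spec(mu = 0.02), class = "mp_parameter_error")
  # determinism
  s1 <- simulate_haplotypes(gg, mutation_spec(seed = 2))
  s2 <- simulate_haplotypes(gg, mutation_spec(seed = 2))
  expect_identical(s1$alignment$rows, s2$alignment$rows)
  expect_identical(s1$truth, s2$truth)
})

test_that("called variants exactly match the planted truth (substitution-only run)", {
  gg <- generate_genome(genome_spec(seed = 43))
  sim <- simulate_haplotypes(gg, mutation_spec(mu = 0.002, kappa = 10,
                                               indel_rate = 0, vntr_copy_sd = 0,
                                               seed = 11))
  calls <- call_variants(sim$alignment, reference_id = "hap1")
  tr <- sim$truth[sim$truth$type == "substitution", ]
  anc <- strsplit(sim$ancestor, "")[[1]]
  # expected polymorphic columns: ancestor positions where the mutated rows
  # do not all carry the same allele as every other row
  states_at <- function(pos) {
    alts <- tr$alt[tr$pos == pos]
    n_mut <- length(alts)
    unique(c(alts, if (n_mut < 6) anc[pos]))
  }
  exp_pos <- sort(unique(tr$pos[vapply(tr$pos, function(p) length(states_at(p)) > 1,
                                       logical(1))]))
  # truth positions are ancestor coordinates == hap1 coordinates at indel-free
  # sites, except positions where hap1 itself mutated stay comparable
  expect_equal(sort(unique(calls$ref_position)), exp_pos)
  # per-column allele sets agree with the truth record
  m <- do.call(rbind, strsplit(sim$alignment$rows, ""))
  for (i in seq_len(nrow(calls))) {
    col <- m[, calls$aln_column[i]]
    expect_setequal(unique(col), states_at(calls$ref_position[i]))
  }
})

test_that("pi matches its star-genealogy expectation and ts:tv tracks kappa", {
  g <- mitogenome("anc", random_seq(2000, seed = 55))
  mu <- 0.002; kappa <- 10
  pis <- numeric(100); ts <- 0; tv <- 0
  for (r in 1:100) {
    sim <- simulate_haplotypes(g, mutation_spec(mu = mu, kappa = kappa,
                                                indel_rate = 0, vntr_copy_sd = 0,
                                                seed = 6000 + r))
    pis[r] <- diversity_stats(sim$alignment)$pi
    ts <- ts + sum(sim$truth$transition)
    tv <- tv + sum(!sim$truth$transition)
  }
  # E[pi] = 2 mu (1 + o(mu)); compare within 3 Monte-Carlo SE
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 2 * mu * (1 - mu)), 3 * se + 1e-6)
  # binomial check on the transition fraction kappa/(kappa+1)
  n <- ts + tv
  p_hat <- ts / n
  p_exp <- kappa / (kappa + 1)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("VNTR copy-number variation appears as indel events at the array", {
  gg <- generate_genome(genome_spec(seed = 47))
  sim <- simulate_haplotypes(gg, mutation_spec(mu = 0, indel_rate = 0,
                                               vntr_copy_sd = 2, seed = 13))
  rs3 <- gg$truth[gg$truth$name == "RS3", ]
  vn <- sim$truth
  expect_gte(nrow(vn), 1)
  expect_true(all(vn$type %in% c("insertion", "deletion")))
  expect_true(all(vn$length %% 10 == 0))
  expect_true(all(vn$pos >= rs3$start & vn$pos <= rs3$end))
  # indel-excluded haplotype partition is unaffected by pure VNTR variation
  expect_equal(haplotype_partition(sim$alignment)$n_haplotypes, 1)
  # rows differ in ungapped length
  lens <- nchar(gsub("-", "", sim$alignment$rows))
  expect_gt(length(unique(lens)), 1)
})
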