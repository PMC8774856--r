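test_that("SSR scan finds perfect runs with primitive units", {
  h <- find_ssrs("ACACACAC")
  expect_equal(nrow(h), 1)
  expect_equal(h$unit, "AC")
  expect_equal(h$copies, 4)
  expect_equal(h$period, 2)
  # homopolymer with unit_min = 1
  h2 <- find_ssrs("GGTTTTTTGG", min_length = 6)
  expect_true(any(h2$unit == "T" & h2$copies == 6))
  # fractional trailing copy
  h3 <- find_ssrs("ACGACGACGAC", unit_min = 3, unit_max = 3, min_length = 9)
  expect_equal(h3$copies, 11 / 3)
})

test_that("SSR scan equals exhaustive enumeration on random sequences", {
  for (s in 1:20) {
    sq <- random_seq(200, seed = 300 + s, prob = c(0.4, 0.1, 0.1, 0.4))
    got <- find_ssrs(sq)
    exp <- oracle_ssrs(sq)
    expect_equal(got[, c("start", "end", "unit", "period", "copies")],
                 exp, ignore_attr = TRUE)
  }
})

test_that("tandem scan recovers perfect and mutated planted arrays", {
  sq <- paste0(random_seq(60, seed = 1), strrep("ACGTAC", 5), random_seq(60, seed = 2))
  h <- find_tandem_repeats(sq, min_score = 40)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  expect_equal(top$period, 6)
  expect_equal(top$copies, 5)
  expect_equal(top$percent_matches, 100)
  expect_equal(top$start, 61)
  expect_equal(top$end, 90)

  # 8-mer repeated 10x with two point mutations: percent matches equals an
  # independent positional consensus-identity computation
  unit <- "GATCCGTA"
  arr <- strsplit(strrep(unit, 10), "")[[1]]
  arr[19] <- "T"; arr[53] <- "C"
  sq2 <- paste0(random_seq(50, seed = 3), paste(arr, collapse = ""),
                random_seq(50, seed = 4))
  h2 <- find_tandem_repeats(sq2, min_score = 40)
  top2 <- h2[which.max(h2$score), ]
  expect_equal(top2$period, 8)
  # oracle: align the 10 copies positionally to the column-majority consensus
  m <- matrix(arr, ncol = 8, byrow = TRUE)
  cons <- apply(m, 2, function(cc) names(sort(table(cc), decreasing = TRUE))[1])
  oracle_pct <- 100 * mean(t(m) == cons)
  expect_equal(top2$percent_matches, oracle_pct, tolerance = 0.5)
  expect_equal(top2$copies, 10, tolerance = 0.3)
})

test_that("inverted-repeat scan matches the constructed example and brute force", {
  sq <- paste0("GAGGCA", "TTTTT", "TGCCTC")
  h <- find_inverted_repeats(sq)
  expect_equal(nrow(h), 1)
  expect_equal(h$arm_length, 6)
  expect_equal(h$gap, 5)
  expect_equal(h$start, 1)
  expect_equal(h$end, 17)
  for (s in 1:20) {
    sq <- random_seq(300, seed = 400 + s)
    got <- find_inverted_repeats(sq, arm_min = 4, gap_max = 10)
    exp <- oracle_gapped_ir(sq, gaps = 0:10, arm_min = 4, arm_max = 50)
    expect_equal(got[, c("start", "end", "arm_length", "gap")],
                 exp, ignore_attr = TRUE)
  }
})

test_that("palindrome scan matches center-by-center brute force", {
  h <- find_palindromes("GAATTC")
  expect_equal(nrow(h), 1)
  expect_equal(h$length, 6)
  expect_equal(nrow(find_palindromes("AAAAAA")), 0)   # not self-revcomp
  for (s in 1:20) {
    sq <- random_seq(500, seed = 500 + s)
    got <- find_palindromes(sq, len_min = 4)
    exp <- oracle_palindromes(sq, len_min = 4)
    expect_equal(got[, c("start", "end", "length")], exp, ignore_attr = TRUE)
    # per-length census via count_all decomposition
    all_h <- find_palindromes(sq, len_min = 4, count_all = TRUE)
    for (len in unique(all_h$length)) {
      expect_equal(sum(all_h$length == len),
                   sum(floor(exp$length / 2) >= len / 2))
    }
  }
})

test_that("palindrome and inverted-repeat hit sets mirror under revcomp", {
  for (s in 1:5) {
    sq <- random_seq(400, seed = 600 + s)
    L <- nchar(sq)
    fwd <- find_palindromes(sq)
    rev <- find_palindromes(revcomp(sq))
    mirrored <- data.frame(start = L - rev$end + 1, end = L - rev$start + 1,
                           length = rev$length)
    expect_equal(fwd[, c("start", "end", "length")],
                 mirrored[order(mirrored$start, mirrored$length), ],
                 ignore_attr = TRUE)
    fwd_ir <- find_inverted_repeats(sq)
    rev_ir <- find_inverted_repeats(revcomp(sq))
    expect_equal(nrow(fwd_ir), nrow(rev_ir))
    if (nrow(fwd_ir)) {
      mir <- data.frame(start = L - rev_ir$end + 1, end = L - rev_ir$start + 1,
                        arm_length = rev_ir$arm_length, gap = rev_ir$gap)
      mir <- mir[order(mir$start, mir$gap), ]
      expect_equal(fwd_ir[, c("start", "end", "arm_length", "gap")],
                   mir, ignore_attr = TRUE)
    }
  }
})

test_that("hairpin scan equals the loop-bounded inverted-repeat oracle", {
  arm <- "GCTGGCTTACA"                       # 11 bp stem
  hp <- paste0(arm, "AAATTTATTTCAA", revcomp(arm))   # 13 nt loop
  sq <- paste0(random_seq(40, seed = 7), hp, random_seq(40, seed = 8))
  h <- find_hairpins(sq)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$arm_length), ]
  expect_equal(top$arm_length, 11)
  expect_equal(top$loop_length, 13)
  expect_equal(top$start, 41)
  for (s in 1:10) {
    sq <- random_seq(300, seed = 700 + s)
    got <- find_hairpins(sq, stem_min = 4)
    exp <- oracle_gapped_ir(sq, gaps = 3:20, arm_min = 4, arm_max = nchar(sq))
    expect_equal(got[, c("start", "end", "arm_length")],
                 exp[, c("start", "end", "arm_length")], ignore_attr = TRUE)
    expect_equal(got$loop_length, exp$gap)
  }
})

test_that("motif scan handles N wildcards, both strands and circularity", {
  sq <- "ACGTACGTAA"
  expect_equal(find_motif(sq, sq)$start, 1)          # whole-sequence pattern
  expect_equal(nrow(find_motif("ACG", "ACGTT")), 0)  # pattern longer than seq
  h <- find_motif(paste0("TT", "ATG", "ACATACGTC", "CAT", "TT"),
                  "ATGNNNNNNNNNCAT", both_strands = TRUE)
  expect_equal(h$start, 3)
  # reverse-strand hit reported in H coordinates
  h2 <- find_motif(paste0("TTTT", revcomp("GCCCCAT"), "TTTT"), "GCCCCAT")
  expect_equal(h2$strand, "L")
  expect_equal(h2$start, 5)
  # circular wrap: motif split across the origin
  sq3 <- "CATAAAAAAATG"                      # ATG..CAT wraps at position 10
  h3 <- find_motif(sq3, "ATGCAT", circular = TRUE)
  expect_equal(h3$start[1], 10)
  expect_equal(nrow(find_motif(sq3, "ATGCAT", circular = FALSE)), 0)
})

test_that("perfect planted repeats are always recovered exactly across seeds", {
  for (s in 1:20) {
    bg <- random_seq(400, seed = 800 + s)
    unit <- substr(random_seq(10, seed = 900 + s), 1, 10)
    if (.min_period_test(unit) < 10) next    # keep the plant unambiguous
    sq <- paste0(substr(bg, 1, 200), strrep(unit, 8), substr(bg, 201, 400))
    h <- find_tandem_repeats(sq, min_score = 40)
    hit <- h[h$start <= 201 & h$end >= 201 + 79, , drop = FALSE]
    expect_gte(nrow(hit), 1)
    expect_equal(hit$percent_matches[which.max(hit$score)], 100)
  }
})
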