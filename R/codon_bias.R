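#' The vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map (translation table 2): TGA = Trp, ATA = Met,
#' and the four terminators TAA, TAG, AGA, AGG (family `*`).  Under this
#' code every sense amino-acid family has at least two synonymous codons:
#' twelve two-fold families, six four-fold families and the two six-fold
#' families Leu and Ser (kept as single families, not split sub-families).
#'
#' @return named character vector of length 64 (names are DNA codons).
#' @export
mito_code <- function() {
  Biostrings::getGeneticCode("2")
}

# synonymous families under the mito code: list aa -> codon vector
.mito_families <- function(include_stops = FALSE) {
  code <- mito_code()
  fam <- split(names(code), unname(code))
  if (!include_stops) fam <- fam[names(fam) != "*"]
  fam
}

.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Extract and frame a protein-coding sequence
#'
#' L-strand genes are reverse-complemented before codon splitting.  A
#' trailing length of 1 mod 3 is an incomplete single-T stop (completed
#' with AA), a trailing length of 2 an incomplete TA stop (completed with
#' A); completion yields a terminal TAA, mirroring mRNA polyadenylation.
#'
#' @param genome a `mitogenome`.
#' @param feature a PCG feature row (or feature name).
#' @param complete_stops complete incomplete terminators (default TRUE).
#' @return a `coding_sequence` list: `gene`, `codons`, `start_codon`,
#'   `stop_codon`, `stop_completion` (none/TA_plus_A/T_plus_AA), `strand`,
#'   `start_is_atn` (flag; a non-ATN start is flagged, not an error).
#' @examples
#' g <- mitogenome("toy", "ATGAAATAA",
#'                 feature_table(data.frame(name = "g1", kind = "PCG",
#'                                          start = 1, end = 9, strand = "H")))
#' extract_cds(g, "g1")$codons
#' @export
extract_cds <- function(genome, feature, complete_stops = TRUE) {
  if (is.character(feature)) {
    i <- match(feature, genome$features$name)
    if (is.na(i)) .mp_stop("mp_feature_error", paste0("no feature named '", feature, "'"))
    feature <- genome$features[i, ]
  }
  if (!identical(feature$kind, "PCG")) {
    .mp_stop("mp_feature_error", paste0("feature '", feature$name, "' is not a PCG"))
  }
  s <- feature_sequence(genome, feature)
  rem <- nchar(s) %% 3L
  completion <- c("none", "T_plus_AA", "TA_plus_A")[rem + 1L]
  if (complete_stops && rem > 0L) s <- paste0(s, strrep("A", 3L - rem))
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  internal <- which(codons[-n] %in% .MITO_STOPS)
  if (length(internal)) {
    .mp_stop("mp_internal_stop",
             paste0("in-frame stop codon ", codons[internal[1]], " at codon ",
                    internal[1], " of gene '", feature$name, "'"))
  }
  structure(list(gene = feature$name, codons = codons,
                 start_codon = codons[1], stop_codon = codons[n],
                 stop_completion = if (complete_stops) completion else "none",
                 strand = feature$strand,
                 start_is_atn = grepl("^AT[ACGT]$", codons[1])),
            class = "coding_sequence")
}

#' Classify start and stop codon usage of a CDS
#'
#' @param cds a `coding_sequence`.
#' @return character vector `c(start = ..., stop = ...)`; start classes are
#'   ATG/ATA/ATT/ATC/other, stop classes TAA_complete, AGA_complete,
#'   incomplete_TA, incomplete_T, other.
#' @export
classify_start_stop <- function(cds) {
  start <- if (cds$start_codon %in% c("ATG", "ATA", "ATT", "ATC")) cds$start_codon else "other"
  stop <- switch(cds$stop_completion,
                 TA_plus_A = "incomplete_TA",
                 T_plus_AA = "incomplete_T",
                 none = if (cds$stop_codon == "TAA") "TAA_complete"
                        else if (cds$stop_codon == "AGA") "AGA_complete"
                        else "other")
  c(start = start, stop = stop)
}

#' Pooled codon usage of one or more coding sequences
#'
#' @param cds_list a `coding_sequence` or list of them.
#' @param include_stops include termination codons in counts/percentages
#'   (default TRUE; completed TAA stops count as TAA).
#' @return a `codon_usage` object: `counts` and `percent` over the 64
#'   codons, `total_codons`, `aa_percent` (synonymous-family sums, stops as
#'   family `*`), `n_discarded` (codons containing N, excluded from
#'   counting but reported).
#' @export
codon_usage <- function(cds_list, include_stops = TRUE) {
  if (inherits(cds_list, "coding_sequence")) cds_list <- list(cds_list)
  if (length(cds_list) == 0) .mp_stop("mp_parameter_error", "codon_usage(): no CDS supplied")
  codons <- unlist(lapply(cds_list, `[[`, "codons"), use.names = FALSE)
  withN <- grepl("N", codons, fixed = TRUE)
  n_discarded <- sum(withN)
  codons <- codons[!withN]
  if (!include_stops) codons <- codons[!codons %in% .MITO_STOPS]
  code <- mito_code()
  counts <- table(factor(codons, levels = names(code)))
  counts <- setNames(as.integer(counts), names(code))
  total <- sum(counts)
  percent <- 100 * counts / total
  aa_percent <- tapply(percent, unname(code[names(percent)]), sum)
  structure(list(counts = counts, percent = percent, total_codons = total,
                 aa_percent = aa_percent, n_discarded = n_discarded),
            class = "codon_usage")
}

#' Amino-acid frequencies from a published codon-percentage table
#'
#' Sums per-codon percentages into synonymous-family totals under the
#' vertebrate mitochondrial code; used to recompute amino-acid frequency
#' summaries from printed codon usage tables.
#'
#' @param percent named numeric vector of per-codon percentages (names are
#'   DNA codons).
#' @return named numeric vector of per-amino-acid percentages (stops as
#'   `*`).
#' @export
aa_percent_from_codon_percent <- function(percent) {
  code <- mito_code()
  bad <- setdiff(names(percent), names(code))
  if (length(bad)) .mp_stop("mp_parameter_error",
                            paste0("unknown codon(s): ", paste(bad, collapse = ", ")))
  out <- tapply(unname(percent), unname(code[names(percent)]), sum)
  setNames(as.numeric(out), names(out))
}

#' Relative synonymous codon usage
#'
#' For codon `c` in a synonymous family of size `k` with family total `N`,
#' RSCU = k * count(c) / N: 1 means unbiased usage, >1 over-use.  Families
#' with zero counts yield `NA` for all of their codons.  Leu and Ser are
#' single six-fold families; the terminators form family `*`.
#'
#' @param usage a `codon_usage` object.
#' @param include_stops include the terminator family (default TRUE).
#' @return named numeric vector of RSCU values.
#' @export
rscu <- function(usage, include_stops = TRUE) {
  fams <- .mito_families(include_stops = include_stops)
  out <- numeric(0)
  for (codons in fams) {
    N <- sum(usage$counts[codons])
    k <- length(codons)
    vals <- if (N > 0) k * usage$counts[codons] / N else rep(NA_real_, k)
    out <- c(out, setNames(as.numeric(vals), codons))
  }
  out
}

#' Effective number of codons (ENc)
#'
#' Wright's statistic generalised to the vertebrate mitochondrial code.
#' For each amino-acid family with usage count `n` and within-family codon
#' fractions `p`, the homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)`;
#' families with `n <= 1` are excluded.  ENc sums, over the degeneracy
#' classes of the code (12 two-fold, 6 four-fold, 2 six-fold families),
#' the class size divided by the mean F of its eligible families.  A class
#' with no eligible (or no informative) family has its mean F imputed from
#' the global mean across all eligible families; imputation is flagged via
#' `attr(, "imputed_classes")`.  The result is clipped to at most 60; 20
#' indicates maximal bias (one codon per amino acid), 60 no bias.
#'
#' @param usage a `codon_usage` object (stop codons are ignored).
#' @return ENc value in [20, 60], or `NA` if no family is informative.
#' @export
enc <- function(usage) {
  fams <- .mito_families(include_stops = FALSE)
  ksz <- vapply(fams, length, integer(1))
  F_of <- function(codons) {
    n <- sum(usage$counts[codons])
    if (n <= 1L) return(NA_real_)
    p <- usage$counts[codons] / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  Fv <- vapply(fams, F_of, numeric(1))
  if (all(is.na(Fv))) .mp_stop("mp_parameter_error", "enc(): all families empty")
  classes <- list(`2` = which(ksz == 2), `4` = which(ksz == 4), `6` = which(ksz == 6))
  global_mean <- mean(Fv[!is.na(Fv) & Fv > 0])
  imputed <- character(0)
  total <- 0
  for (k in names(classes)) {
    f <- Fv[classes[[k]]]
    f <- f[!is.na(f)]
    m <- if (length(f)) mean(f) else NA_real_
    if (is.na(m) || m <= 0) { m <- global_mean; imputed <- c(imputed, k) }
    total <- total + length(classes[[k]]) / m
  }
  out <- min(total, 60)
  attr(out, "imputed_classes") <- imputed
  out
}

#' Codon bias index (CBI)
#'
#' Bennetzen & Hall's index of the excess usage of a set of optimal codons:
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)`, where `N_opt` counts
#' occurrences of optimal codons, `N_tot` counts all codons of amino acids
#' with at least two synonyms (every sense family under the mitochondrial
#' code), and `N_ran = sum(n_aa / k_aa)` is the usage expected under
#' uniform synonym choice.  By default the optimal set is data-driven: the
#' most frequent codon of each family in the supplied usage (alphabetical
#' tie-break); a fixed named set may be supplied instead.
#'
#' @param usage a `codon_usage` object (stop codons are ignored).
#' @param optimal_codons optional character vector of optimal codons (one
#'   per family); NULL for data-driven selection.
#' @return CBI value (at most 1); `NA` when degenerate (N_tot == N_ran).
#' @export
cbi <- function(usage, optimal_codons = NULL) {
  fams <- .mito_families(include_stops = FALSE)
  if (is.null(optimal_codons)) {
    optimal_codons <- vapply(fams, function(codons) {
      cnt <- usage$counts[codons]
      sort(codons[cnt == max(cnt)])[1]   # alphabetical tie-break
    }, character(1))
  }
  n_tot <- 0; n_ran <- 0; n_opt <- 0
  for (codons in fams) {
    n <- sum(usage$counts[codons])
    n_tot <- n_tot + n
    n_ran <- n_ran + n / length(codons)
    n_opt <- n_opt + sum(usage$counts[intersect(optimal_codons, codons)])
  }
  if (n_tot == n_ran) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' GC3s: G+C fraction at synonymous third codon positions
#'
#' Under the vertebrate mitochondrial code every sense codon's third
#' position is synonymous, so GC3s is the fraction of sense codons ending
#' in G or C (stop codons excluded).
#'
#' @param usage a `codon_usage` object.
#' @return fraction in [0, 1].
#' @export
gc3s <- function(usage) {
  sense <- setdiff(names(usage$counts), .MITO_STOPS)
  third <- substr(sense, 3, 3)
  tot <- sum(usage$counts[sense])
  if (tot == 0) return(NA_real_)
  sum(usage$counts[sense][third %in% c("G", "C")]) / tot
}

#' Expected ENc under compositional constraint alone
#'
#' The null curve of the ENc-GC3s plot:
#' `ENc*(s) = 2 + s + 29 / (s^2 + (1 - s)^2)` for GC3s = s.  Genes below
#' the curve are candidates for selection on codon usage beyond mutation
#' bias.
#'
#' @param s GC3s value(s) in [0, 1].
#' @return expected ENc.
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(s) {
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Per-gene and pooled codon-bias indicators
#'
#' Extracts all protein-coding genes from an annotated genome and computes
#' ENc, CBI and GC3s per gene plus the pooled values over all PCGs, the
#' layout of a standard codon-bias indicator table.
#'
#' @param genome a `mitogenome` with PCG features.
#' @return data frame with columns `gene`, `enc`, `cbi`, `gc3s`,
#'   `enc_expected`, `n_codons`; the last row is the pooled `overall`.
#' @export
codon_bias_table <- function(genome) {
  pcgs <- genome$features[genome$features$kind == "PCG", ]
  if (nrow(pcgs) == 0) .mp_stop("mp_feature_error", "no PCG features in genome")
  cds <- lapply(seq_len(nrow(pcgs)), function(i) extract_cds(genome, pcgs[i, ]))
  row_of <- function(u, label) {
    g3 <- gc3s(u)
    data.frame(gene = label, enc = as.numeric(enc(u)), cbi = cbi(u), gc3s = g3,
               enc_expected = enc_expected(g3), n_codons = u$total_codons,
               stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, lapply(cds, function(x) row_of(codon_usage(x), x$gene)))
  rbind(per_gene, row_of(codon_usage(cds), "overall"))
}
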