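#' Base composition, AT/GC content and strand skews
#'
#' Computes base counts and the strand-asymmetry skews
#' `AT-skew = (A - T)/(A + T)` and `GC-skew = (G - C)/(G + C)`.
#' Percentages are taken over the non-N total; when a skew denominator is
#' zero the skew is reported as `NA` (undefined), never silently as 0.
#'
#' @param sequence DNA string over \{A,C,G,T,N\}.
#' @param label region label carried into the profile.
#' @return a `composition_profile` list: `region_label`, `counts` (nA, nC,
#'   nG, nT, nN, total), `at_percent`, `gc_percent`, `at_skew`, `gc_skew`.
#' @examples
#' p <- base_stats(strrep("ACGT", 10))
#' p$at_skew  # 0
#' @export
base_stats <- function(sequence, label = "sequence") {
  if (is.null(sequence) || !nzchar(sequence)) {
    .mp_stop("mp_sequence_error", "base_stats(): empty sequence")
  }
  af <- Biostrings::alphabetFrequency(Biostrings::DNAString(sequence))
  counts <- list(nA = unname(af["A"]), nC = unname(af["C"]),
                 nG = unname(af["G"]), nT = unname(af["T"]),
                 nN = unname(af["N"]), total = nchar(sequence))
  .profile_from_counts(counts, label)
}

#' Composition profile from explicit base counts
#'
#' Convenience for recomputing composition statistics from published count
#' tables rather than from a sequence.
#'
#' @param nA,nC,nG,nT,nN base counts.
#' @param label region label.
#' @return a `composition_profile` (see [base_stats()]).
#' @examples
#' p <- composition_from_counts(5417, 4309, 2282, 4496)
#' round(p$at_skew, 3)   # 0.093
#' round(p$gc_skew, 3)   # -0.308
#' @export
composition_from_counts <- function(nA, nC, nG, nT, nN = 0, label = "sequence") {
  counts <- list(nA = nA, nC = nC, nG = nG, nT = nT, nN = nN,
                 total = nA + nC + nG + nT + nN)
  .profile_from_counts(counts, label)
}

.profile_from_counts <- function(counts, label) {
  with(counts, {
    nonN <- nA + nC + nG + nT
    at <- nA + nT; gc <- nG + nC
    structure(list(
      region_label = label,
      counts = counts,
      at_percent = if (nonN > 0) 100 * at / nonN else NA_real_,
      gc_percent = if (nonN > 0) 100 * gc / nonN else NA_real_,
      at_skew = if (at > 0) (nA - nT) / at else NA_real_,
      gc_skew = if (gc > 0) (nG - nC) / gc else NA_real_
    ), class = "composition_profile")
  })
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition> %s: %d bp  A+T %.2f%%  AT-skew %s  GC-skew %s\n",
              x$region_label, x$counts$total,
              x$at_percent,
              ifelse(is.na(x$at_skew), "NA", sprintf("%.3f", round(x$at_skew, 3))),
              ifelse(is.na(x$gc_skew), "NA", sprintf("%.3f", round(x$gc_skew, 3)))))
  invisible(x)
}

#' Composition profiles per genomic partition
#'
#' Profiles the whole genome, the concatenation of all protein-coding
#' genes, all tRNA genes, all rRNA genes, the non-coding fraction
#' (positions covered by no PCG/tRNA/rRNA feature), and each individual
#' feature.  All counting is done on the H strand (the published
#' convention); nucleotides shared by overlapping features of a partition
#' are counted once per partition.
#'
#' @param genome a `mitogenome` with features.
#' @param features optional feature table overriding `genome$features`.
#' @return named list of `composition_profile` objects; partitions first
#'   (`genome`, `PCG`, `tRNA`, `rRNA`, `noncoding`), then one per feature.
#' @export
partition_profiles <- function(genome, features = genome$features) {
  if (is.null(features)) .mp_stop("mp_feature_error", "no feature table supplied")
  L <- genome$length
  ch <- .chars(genome$sequence)
  mask_of <- function(rows) {
    m <- logical(L)
    for (i in rows) m[features$start[i]:features$end[i]] <- TRUE
    m
  }
  prof_mask <- function(mask, label) {
    if (!any(mask)) {
      return(.profile_from_counts(list(nA = 0L, nC = 0L, nG = 0L, nT = 0L,
                                       nN = 0L, total = 0L), label))
    }
    base_stats(paste(ch[mask], collapse = ""), label)
  }
  genic <- which(features$kind %in% c("PCG", "tRNA", "rRNA"))
  out <- list(
    genome = base_stats(genome$sequence, "genome"),
    PCG = prof_mask(mask_of(which(features$kind == "PCG")), "PCG"),
    tRNA = prof_mask(mask_of(which(features$kind == "tRNA")), "tRNA"),
    rRNA = prof_mask(mask_of(which(features$kind == "rRNA")), "rRNA"),
    noncoding = prof_mask(!mask_of(genic), "noncoding")
  )
  for (i in seq_len(nrow(features))) {
    out[[features$name[i]]] <-
      base_stats(substr(genome$sequence, features$start[i], features$end[i]),
                 features$name[i])
  }
  out
}

#' Composition profiles as a data frame
#'
#' @param profiles list returned by [partition_profiles()] (or a single
#'   profile).
#' @param digits rounding for the skew/percent report columns (default 3,
#'   half away from zero as printed in the literature); raw values are kept
#'   in the `*_raw` columns.
#' @return data frame with one row per region.
#' @export
composition_table <- function(profiles, digits = 3) {
  if (inherits(profiles, "composition_profile")) profiles <- list(profiles)
  rnd <- function(x) ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(region = p$region_label,
               A = p$counts$nA, C = p$counts$nC, G = p$counts$nG,
               T = p$counts$nT, N = p$counts$nN, total = p$counts$total,
               at_percent = round(p$at_percent, 2), gc_percent = round(p$gc_percent, 2),
               at_skew = rnd(p$at_skew), gc_skew = rnd(p$gc_skew),
               at_skew_raw = p$at_skew, gc_skew_raw = p$gc_skew,
               stringsAsFactors = FALSE)
  }))
}

#' CpG island scan
#'
#' Slides a window along the sequence; windows with G+C percentage above
#' `min_gc` and observed/expected CpG ratio of at least `min_obs_exp`
#' (obs/exp = nCpG * window / (nC * nG), the Gardiner-Garden & Frommer
#' statistic) qualify.  Overlapping or abutting qualifying windows are
#' merged; merged islands shorter than `min_length` are discarded; the
#' reported GC% and obs/exp ratio are recomputed over the merged span.
#'
#' @param sequence DNA string.
#' @param window window size in bp (default 100).
#' @param min_length minimum merged island length in bp (default 200).
#' @param min_gc G+C percentage threshold, exclusive (default 50).
#' @param min_obs_exp observed/expected CpG threshold, inclusive
#'   (default 0.6).
#' @param step window step (default 1).
#' @return data frame with columns `start`, `end`, `length`, `gc_percent`,
#'   `obs_exp_cpg` (empty when no island qualifies).
#' @export
find_cpg_islands <- function(sequence, window = 100, min_length = 200,
                             min_gc = 50, min_obs_exp = 0.6, step = 1) {
  L <- nchar(sequence)
  if (window > L) .mp_stop("mp_parameter_error", "window larger than sequence")
  ch <- .chars(sequence)
  isC <- ch == "C"; isG <- ch == "G"
  cpg <- isC[-L] & isG[-1]                     # CpG starting at i
  cumC <- c(0, cumsum(isC)); cumG <- c(0, cumsum(isG))
  cumCpG <- c(0, cumsum(cpg))
  starts <- seq(1L, L - window + 1L, by = step)
  nC <- cumC[starts + window] - cumC[starts]
  nG <- cumG[starts + window] - cumG[starts]
  # CpG dinucleotides fully inside the window start at start..start+window-2
  nCpG <- cumCpG[starts + window - 1L] - cumCpG[starts]
  gc_pct <- 100 * (nC + nG) / window
  obs_exp <- ifelse(nC * nG > 0, nCpG * window / (nC * nG), 0)
  ok <- gc_pct > min_gc & obs_exp >= min_obs_exp
  if (!any(ok)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      gc_percent = numeric(), obs_exp_cpg = numeric()))
  }
  # merge overlapping/abutting qualifying windows
  ws <- starts[ok]; we <- ws + window - 1L
  keep <- list(); cs <- ws[1]; ce <- we[1]
  for (i in seq_along(ws)[-1]) {
    if (ws[i] <= ce + 1L) ce <- max(ce, we[i])
    else { keep[[length(keep) + 1L]] <- c(cs, ce); cs <- ws[i]; ce <- we[i] }
  }
  keep[[length(keep) + 1L]] <- c(cs, ce)
  res <- do.call(rbind, lapply(keep, function(iv) {
    len <- iv[2] - iv[1] + 1L
    span <- substr(sequence, iv[1], iv[2])
    sC <- sum(.chars(span) == "C"); sG <- sum(.chars(span) == "G")
    sCpG <- length(gregexpr("CG", span, fixed = TRUE)[[1]])
    if (sCpG == 1 && gregexpr("CG", span, fixed = TRUE)[[1]][1] == -1) sCpG <- 0
    data.frame(start = iv[1], end = iv[2], length = len,
               gc_percent = 100 * (sC + sG) / len,
               obs_exp_cpg = if (sC * sG > 0) sCpG * len / (sC * sG) else 0)
  }))
  res[res$length >= min_length, , drop = FALSE]
}

# Average anhydrous nucleotide-monophosphate residue masses (Da); the
# per-strand constant subtracts the condensation-water/terminal-phosphate
# adjustment used by common sequence-statistics calculators.
.NT_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
.STRAND_ADJ <- -61.96

#' Molecular weight of a DNA molecule
#'
#' Sums average nucleotide-monophosphate residue masses per strand (with a
#' -61.96 Da per-strand adjustment); in double-stranded mode the complement
#' strand is included, so the weight is symmetric under reverse
#' complementation.  Constants are documented in the source; different
#' calculators use slightly different mass dialects, so agreement with any
#' particular tool is at the percent level.
#'
#' @param sequence pure A/C/G/T string (N raises an error).
#' @param double_stranded include the complementary strand (default TRUE).
#' @return molecular weight in kDa.
#' @export
molecular_weight <- function(sequence, double_stranded = TRUE) {
  if (!grepl("^[ACGT]+$", sequence)) {
    .mp_stop("mp_alphabet_error", "molecular_weight(): sequence must be pure A/C/G/T")
  }
  ch <- .chars(sequence)
  w <- sum(.NT_MASS[ch]) + .STRAND_ADJ
  if (double_stranded) w <- w + sum(.NT_MASS[.comp_chars(ch)]) + .STRAND_ADJ
  unname(w / 1000)
}
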