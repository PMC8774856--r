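# Repeat, palindrome, hairpin and motif scanners.
#
# All scanners work on plain uppercase DNA strings and report 1-based
# inclusive coordinates.  N is treated as a literal character (N pairs only
# with N); detection on real data should mask long N runs first.

#' Simple sequence repeat (SSR / microsatellite) scan
#'
#' Reports maximal perfect tandem runs.  Each run is reported once with its
#' smallest (primitive) period, e.g. (AT)3 rather than (ATAT)1.5; runs of
#' different units may overlap and are all reported.  Copy number may be
#' fractional when the final copy is partial.
#'
#' @param seq DNA string.
#' @param unit_min,unit_max repeat-unit length bounds in bp (defaults 1 and
#'   10; unit_min = 1 includes homopolymer runs).
#' @param min_copies minimum copy number (default 3).
#' @param min_length minimum total repeat length in bp (default 6).
#' @return data frame: `kind`, `start`, `end`, `unit`, `period`, `copies`,
#'   `percent_matches` (always 100 for perfect SSRs).
#' @examples
#' find_ssrs("ACACACAC")  # unit AC, 4 copies
#' @export
find_ssrs <- function(seq, unit_min = 1, unit_max = 10, min_copies = 3,
                      min_length = 6) {
  L <- nchar(seq)
  ch <- .chars(seq)
  hits <- list()
  for (p in unit_min:unit_max) {
    if (L < p + 1L) break
    eq <- ch[seq_len(L - p)] == ch[(p + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]
      span <- r$lengths[k] + p
      copies <- span / p
      if (copies < min_copies || span < min_length) next
      unit <- substr(seq, i0, i0 + p - 1L)
      if (.min_period(unit) != p) next   # keep primitive units only
      hits[[length(hits) + 1L]] <- data.frame(
        kind = "SSR", start = i0, end = i0 + span - 1L, unit = unit,
        period = p, copies = copies, percent_matches = 100,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(), start = integer(), end = integer(),
               unit = character(), period = integer(), copies = numeric(),
               percent_matches = numeric())
  out[order(out$start, out$period), , drop = FALSE]
}

# smallest period of a string (length of its primitive root if the string
# is an integer number of root copies, else its own length)
.min_period <- function(unit) {
  p <- nchar(unit)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && unit == strrep(substr(unit, 1, d), p / d)) return(d)
  }
  p
}

#' Approximate tandem repeat scan
#'
#' A seed-and-extend detector in the spirit of Tandem Repeats Finder,
#' honouring its scoring weights: candidate periods are seeded by lag-p
#' character agreement, high-scoring segments are grown under a
#' match/mismatch score with an X-drop cutoff, copies are compared
#' positionally to the column-majority consensus, and the region score is
#' `match_weight * matches - mismatch_penalty * mismatches`.  The indel
#' wraparound alignment of the full TRF model is not implemented in this
#' version; `indel` is accepted for interface compatibility and unused.
#' Overlapping calls are resolved by score (ties to the smaller period), so
#' period harmonics of one array are reported once.
#'
#' @param seq DNA string.
#' @param match,mismatch,indel scoring weights (defaults 2, 7, 7).
#' @param min_score minimum reported score (default 50).
#' @param max_period maximum period size (default 500).
#' @param min_period minimum period size (default 2).
#' @return data frame: `kind`, `start`, `end`, `unit` (consensus),
#'   `period`, `copies`, `percent_matches`, `score`.
#' @export
find_tandem_repeats <- function(seq, match = 2, mismatch = 7, indel = 7,
                                min_score = 50, max_period = 500,
                                min_period = 2) {
  L <- nchar(seq)
  ch <- .chars(seq)
  cand <- list()
  for (p in min_period:min(max_period, L %/% 2)) {
    eq <- ch[seq_len(L - p)] == ch[(p + 1L):L]
    for (seg in .hss_segments(eq, match, mismatch, min_keep = 4 * match)) {
      a <- seg[1]; b <- seg[2]
      span <- b + p - a + 1L
      copies <- span / p
      if (copies < 2) next
      idx <- a:(b + p)
      col <- ((idx - a) %% p) + 1L
      cons <- vapply(split(ch[idx], col), function(cc) {
        names(sort(table(cc), decreasing = TRUE))[1]
      }, character(1))
      agree <- ch[idx] == cons[col]
      score <- match * sum(agree) - mismatch * sum(!agree)
      if (score < min_score) next
      cand[[length(cand) + 1L]] <- data.frame(
        kind = "tandem", start = a, end = b + p,
        unit = paste(cons, collapse = ""), period = p, copies = copies,
        percent_matches = 100 * mean(agree), score = score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      unit = character(), period = integer(), copies = numeric(),
                      percent_matches = numeric(), score = numeric()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$period, cand$start), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- FALSE
    for (j in which(keep)) {
      inter <- min(cand$end[i], cand$end[j]) - max(cand$start[i], cand$start[j]) + 1L
      if (inter > 0.5 * (cand$end[i] - cand$start[i] + 1L)) { ov <- TRUE; break }
    }
    keep[i] <- !ov
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# maximal high-scoring segments of a logical agreement vector under
# +match/-mismatch scoring with reset at zero; returns list of c(start, end)
# (indices into eq) for segments whose best score reaches min_keep.
.hss_segments <- function(eq, match, mismatch, min_keep) {
  segs <- list()
  cur <- 0; start <- 1L; best <- 0; best_i <- 0L
  flush <- function() {
    if (best >= min_keep) segs[[length(segs) + 1L]] <<- c(start, best_i)
  }
  for (i in seq_along(eq)) {
    cur <- cur + if (eq[i]) match else -mismatch
    if (cur > best) { best <- cur; best_i <- i }
    if (cur <= 0) {
      flush()
      cur <- 0; start <- i + 1L; best <- 0; best_i <- i
    }
  }
  flush()
  segs
}

# core gapped inverted-repeat extension: for every spacer length in `gaps`
# and every possible arm1 end, the maximal arm length (up to arm_max) such
# that the downstream arm (after the spacer) is the reverse complement of
# the upstream arm.
.gapped_ir <- function(seq, gaps, arm_min, arm_max) {
  L <- nchar(seq)
  ch <- .chars(seq)
  co <- .comp_chars(ch)
  res <- list()
  for (g in gaps) {
    emax <- L - g - 1L
    if (emax < 1L) next
    alive <- seq_len(emax)
    ext <- integer(emax)
    j <- 0L
    while (length(alive) && j < arm_max) {
      idx1 <- alive - j
      idx2 <- alive + g + 1L + j
      ok <- idx1 >= 1L & idx2 <= L
      cond <- ok
      cond[ok] <- ch[idx1[ok]] == co[idx2[ok]]
      ext[alive[cond]] <- j + 1L
      alive <- alive[cond]
      j <- j + 1L
    }
    es <- which(ext >= arm_min)
    if (length(es)) {
      m <- pmin(ext[es], arm_max)
      res[[length(res) + 1L]] <- data.frame(
        start = es - m + 1L, end = es + g + m, arm_length = m, gap = g)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(), end = integer(),
               arm_length = integer(), gap = integer())
}

# drop hits whose full span is contained in the span of a kept, longer-armed
# hit (absorption of shorter arms by longer reported hits)
.absorb <- function(df) {
  if (nrow(df) < 2) return(df)
  df <- df[order(-df$arm_length, df$start, df$gap), ]
  keep <- logical(nrow(df))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(df))) {
    contained <- any(df$start[i] >= ks & df$end[i] <= ke)
    if (!contained) {
      keep[i] <- TRUE
      ks <- c(ks, df$start[i]); ke <- c(ke, df$end[i])
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$gap), , drop = FALSE]
}

#' Short inverted repeat (SIR) scan
#'
#' Finds maximal arm pairs: an arm, a spacer of at most `gap_max` bp, and
#' the arm's reverse complement.  Arms are extended to maximal length per
#' (position, spacer); hits whose whole span lies inside the span of a
#' longer-armed hit are absorbed.  Only exact arms are supported
#' (`mismatches = 0`).
#'
#' @param seq DNA string.
#' @param arm_min,arm_max arm length bounds in bp (defaults 6, 50).
#' @param gap_max maximum spacer in bp (default 20).
#' @param mismatches must be 0 in this version.
#' @return data frame: `kind`, `start`, `end`, `unit` (upstream arm),
#'   `arm_length`, `gap`.
#' @export
find_inverted_repeats <- function(seq, arm_min = 6, arm_max = 50,
                                  gap_max = 20, mismatches = 0) {
  if (mismatches != 0) .mp_stop("mp_parameter_error",
                                "find_inverted_repeats(): only mismatches = 0 is supported")
  df <- .gapped_ir(seq, gaps = 0:gap_max, arm_min = arm_min, arm_max = arm_max)
  df <- .absorb(df)
  if (!nrow(df)) {
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      unit = character(), arm_length = integer(), gap = integer()))
  }
  data.frame(kind = "inverted", start = df$start, end = df$end,
             unit = substring(seq, df$start, df$start + df$arm_length - 1L),
             arm_length = df$arm_length, gap = df$gap,
             stringsAsFactors = FALSE)
}

#' DNA palindrome scan
#'
#' A DNA palindrome is an even-length sequence equal to its own reverse
#' complement.  By default the maximal palindrome per center is reported;
#' with `count_all = TRUE` every even-length palindrome in
#' `[len_min, len_max]` at every center is reported (the convention of
#' per-length palindrome censuses).
#'
#' @param seq DNA string.
#' @param len_min,len_max length bounds in bp (defaults 6, 30; even).
#' @param count_all report all nested lengths rather than the maximal
#'   extent per center (default FALSE).
#' @return data frame: `kind`, `start`, `end`, `unit`, `length`.
#' @examples
#' find_palindromes("GAATTC")  # the EcoRI site
#' @export
find_palindromes <- function(seq, len_min = 6, len_max = 30, count_all = FALSE) {
  df <- .gapped_ir(seq, gaps = 0L, arm_min = max(1L, ceiling(len_min / 2)),
                   arm_max = len_max %/% 2L)
  empty <- data.frame(kind = character(), start = integer(), end = integer(),
                      unit = character(), length = integer())
  if (!nrow(df)) return(empty)
  if (count_all) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      arms <- ceiling(len_min / 2):df$arm_length[i]
      center <- df$start[i] + df$arm_length[i] - 1L
      data.frame(start = center - arms + 1L, end = center + arms,
                 length = 2L * arms)
    })
    df <- do.call(rbind, rows)
  } else {
    df$length <- 2L * df$arm_length
  }
  out <- data.frame(kind = "palindrome", start = df$start, end = df$end,
                    unit = substring(seq, df$start, df$end),
                    length = df$length, stringsAsFactors = FALSE)
  out[order(out$start, out$length), , drop = FALSE]
}

#' Stem-loop (hairpin) scan
#'
#' Local inverted repeats whose spacer length lies in
#' `[loop_min, loop_max]`, reported as hairpins with stem (arm) and loop
#' lengths; stems are maximal per (position, loop).
#'
#' @param seq DNA string.
#' @param stem_min minimum stem length in bp (default 5).
#' @param loop_min,loop_max loop length bounds in nt (defaults 3, 20).
#' @param mismatches must be 0 in this version.
#' @return data frame: `kind`, `start`, `end`, `unit` (5' stem arm),
#'   `arm_length`, `loop_length`.
#' @export
find_hairpins <- function(seq, stem_min = 5, loop_min = 3, loop_max = 20,
                          mismatches = 0) {
  if (mismatches != 0) .mp_stop("mp_parameter_error",
                                "find_hairpins(): only mismatches = 0 is supported")
  df <- .gapped_ir(seq, gaps = loop_min:loop_max, arm_min = stem_min,
                   arm_max = nchar(seq))
  df <- .absorb(df)
  if (!nrow(df)) {
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      unit = character(), arm_length = integer(),
                      loop_length = integer()))
  }
  data.frame(kind = "hairpin", start = df$start, end = df$end,
             unit = substring(seq, df$start, df$start + df$arm_length - 1L),
             arm_length = df$arm_length, loop_length = df$gap,
             stringsAsFactors = FALSE)
}

#' Ambiguity-coded motif search
#'
#' Finds occurrences of a motif over \{A,C,G,T,N\}; N in the pattern
#' matches any base at zero mismatch cost.  Both strands are searched by
#' default (hits are reported in H-strand coordinates with a strand flag),
#' and circular sequences are scanned across the origin (a hit's `end` may
#' exceed the sequence length; positions wrap modulo the length).
#'
#' @param seq DNA string.
#' @param pattern motif over \{A,C,G,T,N\}.
#' @param max_mismatch allowed mismatches (N never counts; default 0).
#' @param circular scan across the origin (default TRUE).
#' @param both_strands also search the reverse complement (default TRUE).
#' @return data frame: `kind`, `start`, `end`, `motif`, `strand`, sorted by
#'   position; empty when the pattern is longer than the sequence.
#' @export
find_motif <- function(seq, pattern, max_mismatch = 0, circular = TRUE,
                       both_strands = TRUE) {
  pattern <- toupper(pattern)
  if (!grepl("^[ACGTN]+$", pattern)) {
    .mp_stop("mp_alphabet_error", "motif pattern restricted to A,C,G,T,N")
  }
  L <- nchar(seq)
  np <- nchar(pattern)
  empty <- data.frame(kind = character(), start = integer(), end = integer(),
                      motif = character(), strand = character())
  if (np > L) return(empty)
  subject <- if (circular && np > 1) paste0(seq, substr(seq, 1, np - 1)) else seq
  subj <- Biostrings::DNAString(subject)
  scan1 <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = max_mismatch, fixed = "subject")
    st <- Biostrings::start(m)
    st <- st[st <= L]
    if (!length(st)) return(NULL)
    data.frame(kind = "motif", start = st, end = st + np - 1L,
               motif = pattern, strand = strand, stringsAsFactors = FALSE)
  }
  out <- scan1(pattern, "H")
  if (both_strands) {
    rcp <- revcomp(pattern)
    if (rcp != pattern) out <- rbind(out, scan1(rcp, "L"))
  }
  if (is.null(out)) return(empty)
  out[order(out$start), , drop = FALSE]
}

#' Combined repeat/motif scan
#'
#' Runs the selected scanners with their default (published) parameters and
#' binds the hits into one table with a common column set, ready for TSV
#' export.
#'
#' @param seq DNA string.
#' @param kinds subset of `c("ssr", "tandem", "inverted", "palindrome",
#'   "hairpin")`.
#' @return data frame with columns `kind`, `start`, `end`, `unit`,
#'   `period`, `copies`, `percent_matches`, `arm_length`, `loop_or_gap`,
#'   `score` (NA where not applicable).
#' @export
scan_repeats <- function(seq, kinds = c("ssr", "tandem", "inverted", "palindrome")) {
  pad <- function(df, cols = c("kind", "start", "end", "unit", "period", "copies",
                               "percent_matches", "arm_length", "loop_or_gap", "score")) {
    if (!nrow(df)) return(NULL)
    if (!is.null(df$gap)) df$loop_or_gap <- df$gap
    if (!is.null(df$loop_length)) df$loop_or_gap <- df$loop_length
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[, cols]
  }
  out <- list()
  if ("ssr" %in% kinds) out$ssr <- pad(find_ssrs(seq))
  if ("tandem" %in% kinds) out$tandem <- pad(find_tandem_repeats(seq))
  if ("inverted" %in% kinds) out$inverted <- pad(find_inverted_repeats(seq))
  if ("palindrome" %in% kinds) out$palindrome <- pad(find_palindromes(seq))
  if ("hairpin" %in% kinds) out$hairpin <- pad(find_hairpins(seq))
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(kind = character(), start = integer(), end = integer(),
                      unit = character(), period = integer(), copies = numeric(),
                      percent_matches = numeric(), arm_length = integer(),
                      loop_or_gap = integer(), score = numeric())
  }
  rownames(out) <- NULL
  out[order(out$start, out$kind), , drop = FALSE]
}
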