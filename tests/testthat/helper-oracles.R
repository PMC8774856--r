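# Independent brute-force oracles and small fixture builders used across
# the test files.  These deliberately re-derive results by exhaustive
# enumeration, not by calling the package's scanners.

random_seq <- function(n, seed, prob = c(0.3, 0.25, 0.15, 0.3)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

.min_period_test <- function(u) {
  p <- nchar(u)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && u == strrep(substr(u, 1, d), p / d)) return(d)
  }
  p
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive perfect-SSR enumeration: maximal runs, primitive units
oracle_ssrs <- function(seq, unit_min = 1, unit_max = 10, min_copies = 3,
                        min_length = 6) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  primitive <- function(u) {
    p <- nchar(u)
    for (d in seq_len(p - 1)) {
      if (p %% d == 0 && u == strrep(substr(u, 1, d), p / d)) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (p in unit_min:unit_max) {
    i <- 1
    while (i + p <= L) {
      # maximal run starting at i for period p (left-maximal check)
      if ((i == 1 || i - 1 + p > L || ch[i - 1] != ch[i - 1 + p]) &&
          ch[i] == ch[i + p]) {
        j <- i
        while (j + p <= L && ch[j] == ch[j + p]) j <- j + 1
        span <- j - i + p
        copies <- span / p
        unit <- substr(seq, i, i + p - 1)
        if (copies >= min_copies && span >= min_length && primitive(unit)) {
          rows[[length(rows) + 1]] <- data.frame(
            start = i, end = i + span - 1, unit = unit, period = p,
            copies = copies, stringsAsFactors = FALSE)
        }
        i <- i + 1
      } else i <- i + 1
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), unit = character(),
               period = integer(), copies = numeric())
  out[order(out$start, out$period), , drop = FALSE]
}

# all maximal gapped inverted repeats by direct substring comparison,
# followed by span-containment absorption (same reported convention,
# independently coded)
oracle_gapped_ir <- function(seq, gaps, arm_min, arm_max) {
  L <- nchar(seq)
  rows <- list()
  for (g in gaps) {
    for (e in seq_len(max(0, L - g - 1))) {
      m <- 0
      while (m < arm_max) {
        i1 <- e - m; i2 <- e + g + 1 + m
        if (i1 < 1 || i2 > L) break
        if (substr(seq, i1, i1) != oracle_revcomp(substr(seq, i2, i2))) break
        m <- m + 1
      }
      if (m >= arm_min) {
        rows[[length(rows) + 1]] <- data.frame(start = e - m + 1, end = e + g + m,
                                               arm_length = m, gap = g)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      arm_length = integer(), gap = integer()))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$arm_length, df$start, df$gap), ]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    if (nrow(kept) == 0 ||
        !any(df$start[i] >= kept$start & df$end[i] <= kept$end)) {
      kept <- rbind(kept, df[i, ])
    }
  }
  kept[order(kept$start, kept$gap), , drop = FALSE]
}

# maximal even-length palindromes per center by direct comparison
oracle_palindromes <- function(seq, len_min = 6, len_max = 30) {
  L <- nchar(seq)
  rows <- list()
  for (c in seq_len(L - 1)) {
    k <- 0
    while (2 * (k + 1) <= len_max && c - k >= 1 && c + 1 + k <= L &&
           substr(seq, c - k, c - k) ==
           oracle_revcomp(substr(seq, c + 1 + k, c + 1 + k))) {
      k <- k + 1
    }
    if (2 * k >= len_min) {
      rows[[length(rows) + 1]] <- data.frame(start = c - k + 1, end = c + k,
                                             length = 2 * k)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), length = integer())
  out[order(out$start, out$length), , drop = FALSE]
}

# exhaustive sliding-window CpG island detection (windows, merge, filter)
oracle_cpg <- function(seq, window = 100, min_length = 200, min_gc = 50,
                       min_obs_exp = 0.6) {
  L <- nchar(seq)
  stats_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    nC <- sum(ch == "C"); nG <- sum(ch == "G")
    nCpG <- 0
    for (i in seq_len(nchar(s) - 1)) if (substr(s, i, i + 1) == "CG") nCpG <- nCpG + 1
    list(gc = 100 * (nC + nG) / nchar(s),
         oe = if (nC * nG > 0) nCpG * nchar(s) / (nC * nG) else 0)
  }
  ok <- logical(0); starts <- integer(0)
  for (s in 1:(L - window + 1)) {
    st <- stats_of(substr(seq, s, s + window - 1))
    starts <- c(starts, s)
    ok <- c(ok, st$gc > min_gc && st$oe >= min_obs_exp)
  }
  # interval union of every qualifying window (overlapping or abutting
  # windows merge, regardless of non-qualifying windows in between)
  merged <- list()
  qs <- starts[ok]
  if (length(qs)) {
    a <- qs[1]; b <- qs[1] + window - 1
    for (s in qs[-1]) {
      if (s <= b + 1) b <- max(b, s + window - 1)
      else { merged[[length(merged) + 1]] <- c(a, b); a <- s; b <- s + window - 1 }
    }
    merged[[length(merged) + 1]] <- c(a, b)
  }
  out <- Filter(function(iv) iv[2] - iv[1] + 1 >= min_length, merged)
  do.call(rbind, lapply(out, function(iv) data.frame(start = iv[1], end = iv[2])))
}

# direct all-pairs diversity computation (complete deletion)
oracle_diversity <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  clean <- colSums(m == "-" | m == "N") == 0
  mc <- m[, clean, drop = FALSE]
  n <- nrow(mc); S <- ncol(mc)
  d <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) d <- c(d, sum(mc[i, ] != mc[j, ]))
  nstates <- apply(mc, 2, function(col) length(unique(col)))
  pinf <- apply(mc, 2, function(col) sum(table(col) >= 2) >= 2)
  list(pi = mean(d / S), k = mean(d), S = S,
       n_variable = sum(nstates > 1),
       n_pinf = sum(pinf),
       n_singleton = sum(nstates > 1 & !pinf))
}

# enumerate all spanning trees of a small complete graph and return the
# union of the minimum-weight ones, as a sorted edge-key set
oracle_msn_edges <- function(dm) {
  H <- nrow(dm)
  pairs <- t(utils::combn(H, 2))
  n_edges <- nrow(pairs)
  best <- Inf; union_edges <- character(0)
  for (sel in utils::combn(n_edges, H - 1, simplify = FALSE)) {
    # connectivity check
    parent <- 1:H
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok) next
    w <- sum(dm[pairs[sel, , drop = FALSE]])
    keys <- apply(pairs[sel, , drop = FALSE], 1, paste, collapse = "-")
    if (w < best - 1e-9) { best <- w; union_edges <- keys }
    else if (abs(w - best) <= 1e-9) union_edges <- union(union_edges, keys)
  }
  sort(union_edges)
}

# small annotated toy genome with a single H-strand gene
toy_gene_genome <- function(gene_seq, strand = "H", flank = "") {
  seqs <- if (strand == "H") paste0(flank, gene_seq, flank) else
    paste0(flank, oracle_revcomp(gene_seq), flank)
  ft <- feature_table(data.frame(
    name = "g1", kind = "PCG", start = nchar(flank) + 1,
    end = nchar(flank) + nchar(gene_seq), strand = strand,
    stringsAsFactors = FALSE))
  mitogenome("toy", seqs, features = ft)
}
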