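# Variant calling and diversity statistics from a multiple alignment of
# conspecific mitogenomes.

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

.is_transition <- function(a, b) {
  (a %in% .PURINES & b %in% .PURINES) | (a %in% .PYRIMIDINES & b %in% .PYRIMIDINES)
}

#' Call variants from a multiple alignment
#'
#' One call is made per polymorphic alignment column (multi-allelic columns
#' count once and record every alternate allele); contiguous gap runs
#' shared by the same set of rows are merged into single indel events.  A
#' column carrying both a substitution and a gap yields two calls (one
#' substitution, one indel).  Positions are reported on the gap-stripped
#' reference; insertions relative to the reference take the position of the
#' preceding reference base.  Substitutions are typed as transition
#' (A<->G, C<->T) when every ref-to-alt change is a transition, otherwise
#' transversion.
#'
#' @param aln a `mito_alignment` (>= 2 rows).
#' @param reference_id reference row (default: the alignment's).
#' @param features optional `mito_features` in reference coordinates, used
#'   to assign each call a region and (for substitutions inside
#'   protein-coding genes) a coding effect.
#' @return data frame: `ref_position`, `aln_column`, `kind`
#'   (transition/transversion/indel), `ref_allele`, `alt_alleles`
#'   (comma-separated), `carriers` (comma-separated row ids), `region`,
#'   `coding_effect`.
#' @export
call_variants <- function(aln, reference_id = aln$reference_id, features = NULL) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 2) .mp_stop("mp_alignment_error", "need at least 2 aligned rows")
  ref <- m[reference_id, ]
  ref_pos <- cumsum(ref != "-")        # 0 before the first reference base
  refseq <- paste(ref[ref != "-"], collapse = "")
  calls <- list()
  add <- function(ref_position, aln_column, kind, ref_allele, alt, carriers) {
    calls[[length(calls) + 1L]] <<- data.frame(
      ref_position = ref_position, aln_column = aln_column, kind = kind,
      ref_allele = ref_allele, alt_alleles = paste(alt, collapse = ","),
      carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
  }
  # substitutions: columns with >= 2 distinct bases among A,C,G,T
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    bases <- col[col %in% c("A", "C", "G", "T")]
    states <- unique(bases)
    if (length(states) < 2) next
    ra <- ref[j]
    if (ra %in% states) {
      alts <- setdiff(states, ra)
      carriers <- rownames(m)[col %in% alts]
      kind <- if (all(.is_transition(ra, alts))) "transition" else "transversion"
    } else {
      # reference is gap/N here; type by the two most frequent states
      alts <- states
      carriers <- rownames(m)[col %in% states]
      top2 <- names(sort(table(bases), decreasing = TRUE))[1:2]
      kind <- if (.is_transition(top2[1], top2[2])) "transition" else "transversion"
    }
    add(max(ref_pos[j], 1L), j, kind, ra, alts, carriers)
  }
  # indels: contiguous gap columns with an identical set of gapped rows
  gapped <- m == "-"
  has_gap <- which(colSums(gapped) > 0)
  if (length(has_gap)) {
    key <- vapply(has_gap, function(j) paste(which(gapped[, j]), collapse = ","),
                  character(1))
    run_id <- cumsum(c(TRUE, diff(has_gap) != 1L | key[-1] != key[-length(key)]))
    for (r in split(seq_along(has_gap), run_id)) {
      cols <- has_gap[r]
      j0 <- cols[1]
      rows_gapped <- which(gapped[, j0])
      ref_has_gap <- reference_id %in% rownames(m)[rows_gapped]
      carriers <- if (ref_has_gap) rownames(m)[-rows_gapped] else rownames(m)[rows_gapped]
      ref_allele <- paste(ref[cols], collapse = "")
      alt <- paste(m[if (ref_has_gap) setdiff(seq_len(nrow(m)), rows_gapped)[1]
                     else rows_gapped[1], cols], collapse = "")
      add(max(ref_pos[j0 - if (j0 > 1) 1L else 0L], 1L), j0, "indel",
          ref_allele, alt, carriers)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(ref_position = integer(), aln_column = integer(),
               kind = character(), ref_allele = character(),
               alt_alleles = character(), carriers = character())
  out <- out[order(out$aln_column, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out$region <- rep(NA_character_, nrow(out))
  out$coding_effect <- rep(NA_character_, nrow(out))
  if (!is.null(features) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      hit <- which(features$start <= out$ref_position[i] &
                   features$end >= out$ref_position[i])
      out$region[i] <- if (length(hit)) features$name[hit[1]] else "intergenic"
      if (out$kind[i] != "indel") {
        alt1 <- strsplit(out$alt_alleles[i], ",")[[1]][1]
        ra <- out$ref_allele[i]
        if (ra %in% c("A", "C", "G", "T")) {
          out$coding_effect[i] <- classify_coding_effect(
            out$ref_position[i], ra, alt1, refseq, features)
        }
      }
    }
  }
  out
}

#' Coding effect of a substitution
#'
#' Translates the reference and alternate codons under the vertebrate
#' mitochondrial code.  Light-strand genes are handled by complementing the
#' alleles and reading the codon on the coding strand.  Positions outside
#' every protein-coding gene are `noncoding`; positions in the (incomplete)
#' terminator or otherwise untranslatable yield `NA`.
#'
#' @param ref_position 1-based position on the reference sequence.
#' @param ref_allele,alt_allele reference and alternate bases (H strand).
#' @param genome reference sequence string or a `mitogenome`.
#' @param features `mito_features` table.
#' @return one of `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"noncoding"`, or `NA`.
#' @export
classify_coding_effect <- function(ref_position, ref_allele, alt_allele,
                                   genome, features) {
  seqs <- if (inherits(genome, "mitogenome")) genome$sequence else genome
  pcg <- features[features$kind == "PCG" &
                  features$start <= ref_position & features$end >= ref_position, ]
  if (nrow(pcg) == 0) return("noncoding")
  ft <- pcg[1, ]
  gene_seq <- substr(seqs, ft$start, ft$end)
  if (ft$strand == "L") {
    gene_seq <- revcomp(gene_seq)
    off <- ft$end - ref_position + 1L
    ref_allele <- .comp_chars(ref_allele)
    alt_allele <- .comp_chars(alt_allele)
  } else {
    off <- ref_position - ft$start + 1L
  }
  codon_i <- (off - 1L) %/% 3L
  within <- (off - 1L) %% 3L + 1L
  codon <- substr(gene_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return(NA_character_)     # incomplete terminator
  if (substr(codon, within, within) != ref_allele) return(NA_character_)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_allele
  code <- mito_code()
  aa_ref <- unname(code[codon]); aa_alt <- unname(code[alt_codon])
  if (is.na(aa_ref) || is.na(aa_alt)) return(NA_character_)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Variant incidence summary
#'
#' Expresses a variant count over a sequence length as "one variant per X
#' bp" (1 decimal) and as a percentage of nucleotides (2 decimals).
#'
#' @param n_variants number of variants (>= 0).
#' @param length_bp sequence length (> 0).
#' @return list with `one_per_bp`, `percent`, `label`; zero variants yield
#'   `one_per_bp = NA` and label `"none"`.
#' @examples
#' incidence(54, 16504)  # 1/305.6 bp, 0.33%
#' @export
incidence <- function(n_variants, length_bp) {
  if (length_bp <= 0) .mp_stop("mp_parameter_error", "length_bp must be positive")
  if (n_variants == 0) {
    return(list(one_per_bp = NA_real_, percent = 0, label = "none"))
  }
  opb <- round(length_bp / n_variants, 1)
  pct <- round(100 * n_variants / length_bp, 2)
  list(one_per_bp = opb, percent = pct,
       label = sprintf("1/%.1f bp (%.2f%%)", opb, pct))
}

#' Nucleotide and haplotype diversity statistics
#'
#' Computes nucleotide diversity (pi: mean pairwise differences per
#' considered site), haplotype diversity (`hd = n/(n-1) * (1 - sum p_i^2)`
#' over haplotype frequencies), mean pairwise difference count (k), the
#' sequence conservation index (C: fraction of monomorphic considered
#' sites), and site classes.  Under `complete_deletion` every column
#' containing a gap or N is excluded for all pairs (the DnaSP-like
#' default); under `pairwise_deletion` each pair uses its own gap/N-free
#' columns (pi and C are then computed over the complete-deletion site set,
#' but pairwise distances use per-pair sites).
#'
#' @param aln a `mito_alignment` (>= 2 rows).
#' @param gap_mode `"complete_deletion"` (default) or
#'   `"pairwise_deletion"`.
#' @return a `diversity_stats` list: `pi`, `hd`, `k`, `c_index`,
#'   `n_sites_considered`, `n_variable_sites`, `n_singleton_sites`,
#'   `n_parsimony_informative_sites`, `n_haplotypes`, `incidence_bp`,
#'   `incidence_percent`.
#' @export
diversity_stats <- function(aln, gap_mode = c("complete_deletion", "pairwise_deletion")) {
  gap_mode <- match.arg(gap_mode)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) .mp_stop("mp_alignment_error", "need at least 2 aligned rows")
  clean <- colSums(m == "-" | m == "N") == 0
  if (!any(clean)) .mp_stop("mp_alignment_error", "no gap/N-free columns to consider")
  mc <- m[, clean, drop = FALSE]
  S <- ncol(mc)
  # site classes over the complete-deletion site set
  n_states <- apply(mc, 2, function(col) length(unique(col)))
  variable <- n_states > 1
  pinf <- apply(mc, 2, function(col) sum(table(col) >= 2) >= 2)
  singleton <- variable & !pinf
  # pairwise differences
  pairs <- utils::combn(n, 2)
  d <- numeric(ncol(pairs)); s_used <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (gap_mode == "complete_deletion") {
      d[p] <- sum(mc[i, ] != mc[j, ]); s_used[p] <- S
    } else {
      ok <- !(m[i, ] %in% c("-", "N")) & !(m[j, ] %in% c("-", "N"))
      d[p] <- sum(m[i, ok] != m[j, ok]); s_used[p] <- sum(ok)
    }
  }
  if (any(s_used == 0)) .mp_stop("mp_alignment_error",
                                 "a sequence pair has zero considered sites")
  part <- haplotype_partition(aln, include_indels = FALSE)
  freq <- vapply(part$haplotypes, length, integer(1))
  pfreq <- freq / n
  hd <- if (length(freq) > 1) n / (n - 1) * (1 - sum(pfreq^2)) else 0
  nvar <- sum(variable)
  inc <- incidence(nvar, S)
  structure(list(
    pi = mean(d / s_used), hd = hd, k = mean(d),
    c_index = 1 - nvar / S,
    n_sites_considered = S, n_variable_sites = nvar,
    n_singleton_sites = sum(singleton),
    n_parsimony_informative_sites = sum(pinf),
    n_haplotypes = length(freq),
    incidence_bp = inc$one_per_bp, incidence_percent = inc$percent
  ), class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("<diversity> n_sites %d  pi %.4f  Hd %.4f  k %.2f  C %.4f  haplotypes %d\n",
              x$n_sites_considered, x$pi, x$hd, x$k, x$c_index, x$n_haplotypes))
  invisible(x)
}

#' Haplotype partition of an alignment
#'
#' Rows identical over the considered sites share a haplotype; haplotypes
#' are numbered by first occurrence (row order).  By default indel (and N)
#' columns are excluded, so copy-number differences in repeat arrays do not
#' split haplotypes; `include_indels = TRUE` compares full rows.
#'
#' @param aln a `mito_alignment`.
#' @param include_indels compare gap columns too (default FALSE).
#' @return list: `assignment` (named integer vector, one entry per row),
#'   `haplotypes` (list of member-id vectors in haplotype order),
#'   `n_haplotypes`, plus the considered column indices as attribute
#'   `"columns"`.
#' @export
haplotype_partition <- function(aln, include_indels = FALSE) {
  m <- .aln_matrix(aln)
  cols <- if (include_indels) seq_len(ncol(m)) else
    which(colSums(m == "-" | m == "N") == 0)
  keys <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(keys)
  hap_id <- match(keys, keys[first])
  haplotypes <- split(rownames(m), hap_id)
  names(haplotypes) <- paste0("H", seq_along(haplotypes))
  out <- list(assignment = setNames(hap_id, rownames(m)),
              haplotypes = haplotypes, n_haplotypes = length(haplotypes))
  attr(out, "columns") <- cols
  out
}

#' Haplotype network (union of minimum spanning trees)
#'
#' Builds Hamming distances between haplotype representative rows (over the
#' partition's considered sites) and returns the minimum-spanning network:
#' the union of all minimum spanning trees, i.e. every edge (u, v, w) such
#' that u and v are disconnected among edges strictly shorter than w.  Edge
#' labels are difference counts.
#'
#' @param partition result of [haplotype_partition()].
#' @param aln the `mito_alignment` the partition came from.
#' @return a `haplotype_network` list: `nodes` (haplotype, members,
#'   frequency), `edges` (from, to, weight), `distances` (matrix).
#' @export
haplotype_network <- function(partition, aln) {
  if (partition$n_haplotypes < 2) {
    .mp_stop("mp_parameter_error", "need at least 2 haplotypes for a network")
  }
  m <- .aln_matrix(aln)
  cols <- attr(partition, "columns")
  reps <- vapply(partition$haplotypes, `[`, character(1), 1L)
  H <- length(reps)
  dm <- matrix(0L, H, H, dimnames = list(names(reps), names(reps)))
  for (i in seq_len(H - 1)) {
    for (j in (i + 1):H) {
      dm[i, j] <- dm[j, i] <- sum(m[reps[i], cols] != m[reps[j], cols])
    }
  }
  # union of all MSTs via the cut rule, processed by weight class
  edges <- data.frame(from = character(), to = character(), weight = integer(),
                      stringsAsFactors = FALSE)
  parent <- seq_len(H)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  all_pairs <- utils::combn(H, 2)
  w <- dm[cbind(all_pairs[1, ], all_pairs[2, ])]
  for (wc in sort(unique(w))) {
    idx <- which(w == wc)
    qualifying <- idx[vapply(idx, function(e) {
      find(all_pairs[1, e]) != find(all_pairs[2, e])
    }, logical(1))]
    for (e in qualifying) {
      edges <- rbind(edges, data.frame(
        from = names(reps)[all_pairs[1, e]], to = names(reps)[all_pairs[2, e]],
        weight = wc, stringsAsFactors = FALSE))
    }
    for (e in qualifying) {
      ra <- find(all_pairs[1, e]); rb <- find(all_pairs[2, e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  nodes <- data.frame(
    haplotype = names(partition$haplotypes),
    members = vapply(partition$haplotypes, paste, character(1), collapse = ","),
    frequency = vapply(partition$haplotypes, length, integer(1)),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, distances = dm),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Windowed variability and conservation track
#'
#' Slides windows along the gap-stripped reference, counting variant
#' positions per window, the variant incidence (variants per bp) and the
#' conservation index C (fraction of window positions without a variant).
#' Contiguous windows at or above `hvs_min_incidence` are merged into
#' candidate hypervariable segments (HVS).
#'
#' @param aln a `mito_alignment`.
#' @param window,step window size and step in bp (defaults 50 and 10).
#' @param hvs_min_incidence incidence threshold for HVS calling (default
#'   1/25 variants per bp).
#' @param reference_id reference row.
#' @return list: `track` (start, end, n_variants, incidence, C per window)
#'   and `hvs` (merged intervals with their variant counts and incidence).
#' @export
variability_track <- function(aln, window = 50, step = 10,
                              hvs_min_incidence = 1 / 25,
                              reference_id = aln$reference_id) {
  calls <- call_variants(aln, reference_id = reference_id)
  ref_len <- sum(.chars(aln$rows[[reference_id]]) != "-")
  if (window > ref_len) .mp_stop("mp_parameter_error", "window larger than reference")
  var_pos <- unique(calls$ref_position)
  starts <- seq(1L, ref_len - window + 1L, by = step)
  nvar <- vapply(starts, function(s) {
    sum(var_pos >= s & var_pos <= s + window - 1L)
  }, integer(1))
  track <- data.frame(start = starts, end = starts + window - 1L,
                      n_variants = nvar, incidence = nvar / window,
                      C = 1 - nvar / window)
  hot <- track$incidence >= hvs_min_incidence
  hvs <- data.frame(start = integer(), end = integer(),
                    n_variants = integer(), incidence = numeric())
  if (any(hot)) {
    r <- rle(hot)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
    for (k in which(r$values)) {
      s <- track$start[starts_i[k]]; e <- track$end[ends_i[k]]
      nv <- sum(var_pos >= s & var_pos <= e)
      hvs <- rbind(hvs, data.frame(start = s, end = e, n_variants = nv,
                                   incidence = nv / (e - s + 1L)))
    }
  }
  list(track = track, hvs = hvs)
}
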