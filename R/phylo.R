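# Distance-based phylogenetics: p / TN93 distance matrices, neighbour
# joining with the Kuhner-Felsenstein negative-branch adjustment, and
# nonparametric bootstrap supports.

#' Pairwise distance matrix from an alignment
#'
#' `model = "p"` is the proportion of differing sites; `model = "TN93"`
#' is the Tamura-Nei (1993) distance, which corrects for unequal base
#' frequencies and the two transition classes (A<->G and C<->T), computed
#' from the closed form with base frequencies estimated from the pooled
#' pair of sequences.  Under `pairwise_deletion` (default) every pair uses
#' its own gap/N-free sites; `complete_deletion` restricts all pairs to
#' globally clean columns.  A TN93 entry whose correction logarithm is
#' undefined (saturated pair) is returned as `NA` and flagged.
#'
#' @param aln a `mito_alignment` (>= 2 rows).
#' @param model `"p"` or `"TN93"`.
#' @param gap_mode `"pairwise_deletion"` or `"complete_deletion"`.
#' @return a `dist_matrix` list: `ids`, `matrix` (symmetric, zero
#'   diagonal), `model`, `gap_mode`, `n_sites` (matrix of sites used per
#'   pair).
#' @export
distance_matrix <- function(aln, model = c("p", "TN93"),
                            gap_mode = c("pairwise_deletion", "complete_deletion")) {
  model <- match.arg(model)
  gap_mode <- match.arg(gap_mode)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) .mp_stop("mp_alignment_error", "need at least 2 rows")
  if (gap_mode == "complete_deletion") {
    m <- m[, colSums(m == "-" | m == "N") == 0, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  NS <- matrix(0L, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- m[i, ]; xj <- m[j, ]
      ok <- !(xi %in% c("-", "N")) & !(xj %in% c("-", "N"))
      S <- sum(ok)
      if (S == 0) .mp_stop("mp_alignment_error",
                           paste0("pair ", rownames(m)[i], "/", rownames(m)[j],
                                  " has zero considered sites"))
      xi <- xi[ok]; xj <- xj[ok]
      NS[i, j] <- NS[j, i] <- S
      d <- if (model == "p") mean(xi != xj) else .tn93_pair(xi, xj)
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(ids = rownames(m), matrix = D, model = model,
                 gap_mode = gap_mode, n_sites = NS),
            class = "dist_matrix")
}

# Tamura-Nei (1993) closed-form distance for one pair of gap-free
# character vectors; base frequencies pooled over both sequences.
.tn93_pair <- function(xi, xj) {
  S <- length(xi)
  f <- table(factor(c(xi, xj), levels = c("A", "C", "G", "T"))) / (2 * S)
  pA <- f[["A"]]; pC <- f[["C"]]; pG <- f[["G"]]; pT <- f[["T"]]
  pR <- pA + pG; pY <- pC + pT
  diff <- xi != xj
  P1 <- mean(diff & ((xi == "A" & xj == "G") | (xi == "G" & xj == "A")))
  P2 <- mean(diff & ((xi == "C" & xj == "T") | (xi == "T" & xj == "C")))
  Q <- mean(diff) - P1 - P2
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pC * pT / pY
  if ((P1 > 0 && k1 == 0) || (P2 > 0 && k2 == 0) || pR == 0 || pY == 0) {
    return(NA_real_)
  }
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * pR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * pY) else 1
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) -
    2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY) * log(w3)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> ", length(x$ids), " taxa, model ", x$model,
      " (", x$gap_mode, ")\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Mean of all pairwise distances
#'
#' @param dm a `dist_matrix` or plain symmetric matrix.
#' @return mean of the n(n-1)/2 off-diagonal entries.
#' @export
overall_mean_distance <- function(dm) {
  M <- if (inherits(dm, "dist_matrix")) dm$matrix else dm
  mean(M[upper.tri(M)])
}

#' Neighbour-joining tree
#'
#' The Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Ties in Q are broken deterministically by the lexicographically
#' smallest (representative-id) pair.  Negative branch lengths are clamped
#' to zero with the deficit moved to the sister branch
#' (Kuhner-Felsenstein), preserving path lengths.
#'
#' @param dm a `dist_matrix` or symmetric matrix with dimnames (n >= 3).
#' @return an unrooted `phylo` tree (ape) with branch lengths.
#' @export
nj_tree <- function(dm) {
  M <- if (inherits(dm, "dist_matrix")) dm$matrix else dm
  if (is.null(rownames(M))) .mp_stop("mp_parameter_error", "matrix needs dimnames")
  if (!isTRUE(all.equal(M, t(M)))) .mp_stop("mp_parameter_error", "matrix not symmetric")
  if (anyNA(M)) .mp_stop("mp_parameter_error", "distance matrix contains NA entries")
  n <- nrow(M)
  if (n < 3) .mp_stop("mp_parameter_error", "need at least 3 taxa")
  labs <- rownames(M)                    # newick fragments per active cluster
  reps <- rownames(M)                    # lexicographic representatives
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3) {
    r <- rowSums(M)
    Q <- (n - 2) * M - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(reps[cand[, 1]], reps[cand[, 2]]),
                 pmax(reps[cand[, 1]], reps[cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- M[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- M[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    new_lab <- paste0("(", labs[i], ":", fmt(vi), ",", labs[j], ":", fmt(vj), ")")
    new_rep <- min(reps[i], reps[j])
    dk <- (M[i, -c(i, j)] + M[j, -c(i, j)] - M[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    M2 <- rbind(cbind(M[keep, keep, drop = FALSE], dk), c(dk, 0))
    labs <- c(labs[keep], new_lab)
    reps <- c(reps[keep], new_rep)
    rownames(M2) <- colnames(M2) <- reps
    M <- M2
    n <- n - 1
  }
  v1 <- (M[1, 2] + M[1, 3] - M[2, 3]) / 2
  v2 <- M[1, 2] - v1
  v3 <- M[1, 3] - v1
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- paste0("(", labs[1], ":", fmt(v[1]), ",", labs[2], ":", fmt(v[2]),
                ",", labs[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = nwk)
}

# canonical unrooted bipartitions of a phylo tree: for every internal edge,
# the sorted tip-label set of the side not containing the reference tip
# (the alphabetically first label); trivial splits dropped.
.bipartitions <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  parts <- ape::prop.part(phy)
  out <- character(0)
  for (p in parts) {
    side <- phy$tip.label[p]
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' distance matrix and NJ tree for each replicate, and reports for every
#' internal bipartition of the point-estimate tree the percentage of
#' replicates containing it.  Deterministic given `seed`.
#'
#' @param aln a `mito_alignment` (>= 4 rows).
#' @param model distance model passed to [distance_matrix()].
#' @param B number of replicates (default 1000).
#' @param seed RNG seed (default 1).
#' @param gap_mode passed to [distance_matrix()].
#' @return the point-estimate `phylo` tree with `node.label` set to
#'   bootstrap percentages (root label empty) and the support table in
#'   `attr(, "supports")`.
#' @export
bootstrap_support <- function(aln, model = "TN93", B = 1000, seed = 1,
                              gap_mode = "pairwise_deletion") {
  if (length(aln$ids) < 4) .mp_stop("mp_alignment_error", "need >= 4 rows")
  set.seed(seed)
  point <- nj_tree(distance_matrix(aln, model = model, gap_mode = gap_mode))
  target <- .bipartitions(point)
  counts <- setNames(numeric(length(target)), target)
  m <- .aln_matrix(aln)
  ok <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- mito_alignment(
      setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""), aln$ids),
      reference_id = aln$reference_id)
    rep_tree <- tryCatch(
      nj_tree(distance_matrix(rep_aln, model = model, gap_mode = gap_mode)),
      mitoprofile_error = function(e) NULL)
    if (is.null(rep_tree)) next
    ok <- ok + 1L
    bp <- .bipartitions(rep_tree)
    hit <- target %in% bp
    counts[hit] <- counts[hit] + 1
  }
  supports <- round(100 * counts / max(ok, 1L))
  # attach per-node labels: each non-root internal node's clade, as an
  # unrooted bipartition, looked up in the support table
  ntip <- length(point$tip.label)
  nnode <- point$Nnode
  labels <- character(nnode)
  parts <- ape::prop.part(point)
  ref <- sort(point$tip.label)[1]
  for (k in seq_len(nnode)) {
    side <- point$tip.label[parts[[k]]]
    if (ref %in% side) side <- setdiff(point$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    labels[k] <- if (key %in% names(supports)) as.character(supports[[key]]) else ""
  }
  point$node.label <- labels
  attr(point, "supports") <- supports
  attr(point, "n_replicates") <- ok
  point
}

#' Bootstrap support of a specific clade
#'
#' Convenience lookup: the support (in percent of replicates) of the
#' bipartition separating `clade_tips` from the rest, from a tree produced
#' by [bootstrap_support()].  `NA` when the point tree does not contain
#' that bipartition.
#'
#' @param tree result of [bootstrap_support()].
#' @param clade_tips character vector of tip labels.
#' @return support percentage or NA.
#' @export
clade_support <- function(tree, clade_tips) {
  supports <- attr(tree, "supports")
  ref <- sort(tree$tip.label)[1]
  side <- clade_tips
  if (ref %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "|")
  if (key %in% names(supports)) unname(supports[[key]]) else NA_real_
}
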