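# Deterministic synthetic mitogenome and haplotype-set generator with
# recorded ground truth.  Defaults emulate the study conditions of a
# mustelid mitogenome: ~16.5 kb, biased composition (A > T > C > G,
# A+T ~ 60%), the bundled 40-feature gene layout, a control region
# assembled from the bundled motif library (including an RS3-style
# minisatellite and SSRs), and a stem-loop replication origin.

#' Specification for a synthetic mitogenome
#'
#' @param length genome length in bp (default 16,504).
#' @param base_fractions named fractions for A, C, G, T (must sum to 1);
#'   defaults to the published composition of the reference mitogenome
#'   (A 0.3282, C 0.2611, G 0.1383, T 0.2724).
#' @param feature_template a `mito_features` table (default
#'   [lutreola_features()]); its coordinate span must fit `length`.
#' @param plant_cr assemble and plant a motif-library control region at the
#'   template's CR feature (default TRUE).
#' @param plant_ol plant a stem-loop (11 bp stem, 13 nt loop) at the
#'   template's origin feature, with the conserved GCCGG motif in the 3'
#'   flank (default TRUE).
#' @param rs3_copies copy number of the planted minisatellite array
#'   (default 22.1 copies of the 10-bp library unit).
#' @param seed RNG seed.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(length = 16504,
                        base_fractions = c(A = 0.3282, C = 0.2611,
                                           G = 0.1383, T = 0.2724),
                        feature_template = lutreola_features(),
                        plant_cr = TRUE, plant_ol = TRUE,
                        rs3_copies = 22.1, seed = 1) {
  if (abs(sum(base_fractions) - 1) > 1e-9) {
    .mp_stop("mp_parameter_error", "base fractions must sum to 1")
  }
  if (max(feature_template$end) > length) {
    .mp_stop("mp_parameter_error", "feature template does not fit genome length")
  }
  structure(list(length = as.integer(length), base_fractions = base_fractions,
                 feature_template = feature_template, plant_cr = plant_cr,
                 plant_ol = plant_ol, rs3_copies = rs3_copies,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# fixed CR-local layout of planted elements (1-based offsets within the CR)
.CR_LAYOUT <- list(
  ETAS1 = 75, `TAS-A` = 129, `F-box` = 185, `E-box` = 227, `D-box` = 285,
  `C-box` = 333, `B-box` = 399, CSB1 = 545, RS3 = 581, CSB2 = 840,
  CSB3 = 895, HSP = 999, LSP = 1011)
.CR_SSRS <- list(list(at = 430, unit = "CT", copies = 3),
                 list(at = 445, unit = "AT", copies = 3),
                 list(at = 460, unit = "T", copies = 6),
                 list(at = 470, unit = "C", copies = 6))

#' Assemble a synthetic control region from the motif library
#'
#' Draws a background with a CR-like composition and writes the library
#' elements at a fixed internal layout (ETAS1 with its embedded termination
#' motif and palindromic ATGN9CAT copy, TAS-A overlapping the ETAS1 3' end,
#' the five central-domain boxes, CSB1 with a second ATGN9CAT copy, an
#' RS3-style minisatellite array between CSB1 and CSB2, CSB2/CSB3 and the
#' promoter cores, plus a handful of planted microsatellites).
#'
#' @param length CR length in bp (>= 1,030; default 1,065).
#' @param library motif library (default bundled).
#' @param rs3_copies minisatellite copy number (default 22.1).
#' @param seed RNG seed.
#' @return list: `sequence`, `elements` (data frame of planted elements
#'   with CR-local coordinates).
#' @export
assemble_control_region <- function(length = 1065, library = cr_motif_library(),
                                    rs3_copies = 22.1, seed = 1) {
  if (length < 1030) .mp_stop("mp_parameter_error",
                              "control region must be at least 1030 bp for the default layout")
  set.seed(seed)
  bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c(0.295, 0.29, 0.15, 0.265))
  lib_motif <- function(el) library$motif[match(el, library$element)]
  elements <- list()
  write_at <- function(name, at, s, unit = s) {
    stopifnot(at + nchar(s) - 1L <= length)
    bg[at:(at + nchar(s) - 1L)] <<- .chars(s)
    elements[[length(elements) + 1L]] <<- data.frame(
      element = name, start = at, end = at + nchar(s) - 1L, unit = unit,
      stringsAsFactors = FALSE)
  }
  for (el in c("ETAS1", "TAS-A", "F-box", "E-box", "D-box", "C-box",
               "B-box", "CSB1", "CSB2", "CSB3", "HSP", "LSP")) {
    write_at(el, .CR_LAYOUT[[el]], lib_motif(el))
  }
  unit <- lib_motif("RS3_unit")
  n_full <- floor(rs3_copies)
  part <- round((rs3_copies - n_full) * nchar(unit))
  write_at("RS3", .CR_LAYOUT$RS3,
           paste0(strrep(unit, n_full), substr(unit, 1, part)), unit = unit)
  for (s in .CR_SSRS) {
    write_at(paste0("SSR_", s$unit, s$copies), s$at, strrep(s$unit, s$copies))
  }
  list(sequence = paste(bg, collapse = ""),
       elements = do.call(rbind, elements))
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' The background is drawn i.i.d. from the spec's base fractions; the
#' control region, replication-origin stem-loop and their internal
#' elements are written over the background at template coordinates; every
#' protein-coding gene is given its template start codon and (possibly
#' incomplete) terminator, and internal in-frame stop codons are removed
#' by deterministic single-base edits (avoiding positions inside another
#' gene's start/stop codons), so coding-sequence extraction runs cleanly.
#' Deterministic given the spec seed.
#'
#' @param spec a `genome_spec`.
#' @return list: `genome` (a `mitogenome`) and `truth` (data frame of
#'   planted elements with genomic coordinates).
#' @export
generate_genome <- function(spec = genome_spec()) {
  ft <- spec$feature_template
  cr_ft <- ft[ft$kind == "control_region", ]
  ol_ft <- ft[ft$kind == "origin", ]
  if (spec$plant_cr && nrow(cr_ft) == 0) {
    .mp_stop("mp_parameter_error", "plant_cr = TRUE but template has no control region")
  }
  set.seed(spec$seed)
  g <- sample(names(spec$base_fractions), spec$length, replace = TRUE,
              prob = spec$base_fractions)
  truth <- list()
  note <- function(kind, name, start, end, unit = NA_character_, copies = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = kind, name = name, start = start, end = end, unit = unit,
      copies = copies, stringsAsFactors = FALSE)
  }
  if (spec$plant_cr) {
    cr <- assemble_control_region(cr_ft$size[1], rs3_copies = spec$rs3_copies,
                                  seed = spec$seed + 1L)
    off <- cr_ft$start[1] - 1L
    g[cr_ft$start[1]:cr_ft$end[1]] <- .chars(cr$sequence)
    for (i in seq_len(nrow(cr$elements))) {
      e <- cr$elements[i, ]
      copies <- if (e$element == "RS3") spec$rs3_copies else NA_real_
      note("cr_element", e$element, off + e$start, off + e$end, e$unit, copies)
    }
    note("control_region", "CR", cr_ft$start[1], cr_ft$end[1])
  }
  if (spec$plant_ol && nrow(ol_ft) == 1 && ol_ft$size[1] >= 35) {
    arm <- "GCTGGCTTACA"; loop <- "AAATTTATTTCAA"
    hp <- paste0(arm, loop, revcomp(arm))
    g[ol_ft$start[1]:(ol_ft$start[1] + 34L)] <- .chars(hp)
    note("hairpin", "OL", ol_ft$start[1], ol_ft$start[1] + 34L, arm)
    if (ol_ft$end[1] + 5L <= spec$length) {
      g[(ol_ft$end[1] + 1L):(ol_ft$end[1] + 5L)] <- .chars("GCCGG")
      note("motif", "OL_GCCGG", ol_ft$end[1] + 1L, ol_ft$end[1] + 5L, "GCCGG")
    }
  }
  g <- .enforce_pcg_frames(g, ft, spec$base_fractions)
  genome <- mitogenome("synthetic_mitogenome", paste(g, collapse = ""),
                       features = ft, circular = TRUE)
  list(genome = genome,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

# Write template start/stop codons into the background and remove internal
# in-frame stops by single-base edits, avoiding positions inside any gene's
# start or terminator codon; replacement bases are drawn from the genome's
# base fractions (restricted to non-stop outcomes) so the edits do not bias
# the overall composition.
.enforce_pcg_frames <- function(g, ft, base_fractions) {
  pcgs <- ft[ft$kind == "PCG", ]
  # genomic positions of coding position p of gene i
  gpos <- function(row, p) {
    if (row$strand == "H") row$start + p - 1L else row$end - p + 1L
  }
  write_coding <- function(g, row, p0, s) {
    ch <- .chars(s)
    for (k in seq_along(ch)) {
      pos <- gpos(row, p0 + k - 1L)
      g[pos] <- if (row$strand == "H") ch[k] else .comp_chars(ch[k])
    }
    g
  }
  protected <- integer(0)
  for (i in seq_len(nrow(pcgs))) {
    row <- pcgs[i, ]
    g <- write_coding(g, row, 1L, row$start_codon)
    stop_s <- row$stop_codon
    g <- write_coding(g, row, row$size - nchar(stop_s) + 1L, stop_s)
    prot <- c(vapply(1:3, function(p) gpos(row, p), integer(1)),
              vapply((row$size - nchar(stop_s) + 1L):row$size,
                     function(p) gpos(row, p), integer(1)))
    protected <- c(protected, prot)
  }
  for (pass in 1:100) {
    dirty <- FALSE
    for (i in seq_len(nrow(pcgs))) {
      row <- pcgs[i, ]
      n_full <- row$size %/% 3L
      last_internal <- n_full - as.integer(row$size %% 3L == 0L)
      if (last_internal < 2L) next
      cds <- vapply(seq_len(row$size), function(p) {
        b <- g[gpos(row, p)]
        if (row$strand == "H") b else .comp_chars(b)
      }, character(1))
      for (ci in 2:last_internal) {
        codon <- paste(cds[(3 * ci - 2):(3 * ci)], collapse = "")
        if (!codon %in% .MITO_STOPS) next
        fixed <- FALSE
        for (within in c(2L, 1L, 3L)) {
          pos <- gpos(row, 3L * ci - 3L + within)
          if (pos %in% protected) next
          ok_bases <- Filter(function(b) {
            cand <- codon
            substr(cand, within, within) <- b
            !cand %in% .MITO_STOPS && b != substr(codon, within, within)
          }, c("A", "C", "G", "T"))
          if (length(ok_bases)) {
            b <- if (length(ok_bases) == 1) ok_bases[[1]] else
              sample(unlist(ok_bases), 1, prob = base_fractions[unlist(ok_bases)])
            g[pos] <- if (row$strand == "H") b else .comp_chars(b)
            fixed <- TRUE; dirty <- TRUE
            break
          }
        }
        if (!fixed) .mp_stop("mp_generator_error",
                             paste0("cannot remove in-frame stop in ", row$name))
      }
    }
    if (!dirty) return(g)
  }
  .mp_stop("mp_generator_error", "in-frame stop removal did not converge")
}

#' Specification for the haplotype mutation process
#'
#' A star genealogy: every haplotype mutates independently from the common
#' ancestor, so the expected pairwise difference per (ungapped) site is
#' `2 * mu * (1 + o(mu))`.  Given a substitution, the change is a
#' transition with probability `kappa / (kappa + 1)`, otherwise one of the
#' two transversions with equal probability.  Indel events insert or
#' delete short tracts (geometric length); the minisatellite array's copy
#' number can vary per haplotype (VNTR behaviour).  The single-hit regime
#' is enforced (`mu <= 0.01`).
#'
#' @param n_haplotypes number of haplotypes (default 6).
#' @param mu expected substitutions per site per lineage (default 0.002).
#' @param kappa transition/transversion odds (default 10).
#' @param indel_rate expected indel events per site per lineage (default
#'   1e-4).
#' @param indel_length_geometric_p geometric length parameter (default
#'   0.5; mean length 2).
#' @param vntr_copy_sd SD (in repeat units) of per-haplotype minisatellite
#'   copy-number change (default 1; 0 disables).
#' @param seed RNG seed.
#' @return a `mutation_spec` list.
#' @export
mutation_spec <- function(n_haplotypes = 6, mu = 0.002, kappa = 10,
                          indel_rate = 1e-4, indel_length_geometric_p = 0.5,
                          vntr_copy_sd = 1, seed = 1) {
  if (mu > 0.01) .mp_stop("mp_parameter_error",
                          "mu > 0.01: multiple-hit regime unsupported")
  if (mu < 0 || indel_rate < 0) .mp_stop("mp_parameter_error", "rates must be >= 0")
  if (kappa <= 0) .mp_stop("mp_parameter_error", "kappa must be positive")
  structure(list(n_haplotypes = as.integer(n_haplotypes), mu = mu,
                 kappa = kappa, indel_rate = indel_rate,
                 indel_length_geometric_p = indel_length_geometric_p,
                 vntr_copy_sd = vntr_copy_sd, seed = as.integer(seed)),
            class = "mutation_spec")
}

.TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))

#' Simulate an aligned haplotype set with known variants
#'
#' Applies the mutation process of a [mutation_spec()] independently to
#' each haplotype (star genealogy) and emits a ready-made multiple
#' alignment: deletions appear as gap characters, insertions as extra
#' columns gapped in every other row, so no aligner is involved and the
#' truth list enumerates every introduced variant in ancestor coordinates.
#'
#' @param genome a `mitogenome` (or the result of [generate_genome()], from
#'   which genome and minisatellite truth are taken).
#' @param mspec a `mutation_spec`.
#' @return list: `alignment` (a `mito_alignment`; rows `hap1..hapN`,
#'   reference `hap1`), `truth` (data frame: `row`, `type`
#'   (substitution/insertion/deletion), `pos` (ancestor coordinate),
#'   `ref`, `alt`, `transition`, `length`), `ancestor` (the unmutated
#'   sequence).
#' @export
simulate_haplotypes <- function(genome, mspec = mutation_spec()) {
  truth_in <- NULL
  if (!inherits(genome, "mitogenome") && is.list(genome) && !is.null(genome$genome)) {
    truth_in <- genome$truth
    genome <- genome$genome
  }
  set.seed(mspec$seed)
  anc <- .chars(genome$sequence)
  L <- length(anc)
  n <- mspec$n_haplotypes
  ids <- paste0("hap", seq_len(n))
  base <- matrix(rep(anc, n), nrow = n, byrow = TRUE, dimnames = list(ids, NULL))
  ins <- list()   # per row: list of (pos, seq)
  truth <- list()
  note <- function(row, type, pos, ref, alt, transition = NA, len = NA_integer_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      row = row, type = type, pos = pos, ref = ref, alt = alt,
      transition = transition, length = len, stringsAsFactors = FALSE)
  }
  vntr <- NULL
  if (!is.null(truth_in) && mspec$vntr_copy_sd > 0) {
    rs3 <- truth_in[truth_in$name == "RS3", ]
    if (nrow(rs3) == 1) vntr <- rs3
  }
  for (h in seq_len(n)) {
    id <- ids[h]
    row_ins <- list()
    # deletions (non-overlapping; first drawn wins)
    del_mask <- logical(L)
    del_sites <- which(runif(L) < mspec$indel_rate / 2)
    for (s in del_sites) {
      len <- min(rgeom(1, mspec$indel_length_geometric_p) + 1L, L - s + 1L)
      if (any(del_mask[s:(s + len - 1L)])) next
      del_mask[s:(s + len - 1L)] <- TRUE
      note(id, "deletion", s, paste(anc[s:(s + len - 1L)], collapse = ""), "-",
           len = len)
    }
    # insertions
    ins_sites <- which(runif(L) < mspec$indel_rate / 2)
    for (s in ins_sites) {
      len <- rgeom(1, mspec$indel_length_geometric_p) + 1L
      sq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      row_ins[[length(row_ins) + 1L]] <- list(pos = s, seq = sq)
      note(id, "insertion", s, "-", sq, len = len)
    }
    # VNTR copy-number change at the minisatellite 3' end
    if (!is.null(vntr)) {
      unit_len <- nchar(vntr$unit)
      delta <- round(rnorm(1, 0, mspec$vntr_copy_sd))
      if (delta < 0) {
        k <- min(-delta, floor((vntr$end - vntr$start + 1L) / unit_len) - 1L)
        if (k > 0) {
          s <- vntr$end - k * unit_len + 1L
          if (!any(del_mask[s:vntr$end])) {
            del_mask[s:vntr$end] <- TRUE
            note(id, "deletion", s, paste(anc[s:vntr$end], collapse = ""), "-",
                 len = k * unit_len)
          }
        }
      } else if (delta > 0) {
        sq <- strrep(vntr$unit, delta)
        row_ins[[length(row_ins) + 1L]] <- list(pos = vntr$end, seq = sq)
        note(id, "insertion", vntr$end, "-", sq, len = nchar(sq))
      }
    }
    # substitutions at non-deleted sites
    sub_sites <- which(runif(L) < mspec$mu & !del_mask)
    for (s in sub_sites) {
      ref <- anc[s]
      is_ts <- runif(1) < mspec$kappa / (mspec$kappa + 1)
      alt <- if (is_ts) .TRANSITION_OF[[ref]] else
        sample(.TRANSVERSIONS_OF[[ref]], 1)
      base[h, s] <- alt
      note(id, "substitution", s, ref, alt, transition = is_ts, len = 1L)
    }
    base[h, del_mask] <- "-"
    ins[[id]] <- row_ins
  }
  # weave insertion columns: after each ancestor position, one block per
  # inserting row (in row order); other rows are gapped across the block
  ins_by_pos <- vector("list", L + 1L)
  for (h in seq_len(n)) {
    for (ev in ins[[ids[h]]]) {
      p <- ev$pos + 1L
      ins_by_pos[[p]] <- c(ins_by_pos[[p]], list(list(row = h, seq = ev$seq)))
    }
  }
  rows <- lapply(seq_len(n), function(h) character(0))
  chunks <- vector("list", 2L * L + 2L)
  ci <- 0L
  add_chunk <- function(mat_chunk) { ci <<- ci + 1L; chunks[[ci]] <<- mat_chunk }
  for (p in seq_len(L)) {
    add_chunk(base[, p, drop = FALSE])
    blocks <- ins_by_pos[[p + 1L]]
    if (!is.null(blocks)) {
      for (b in blocks) {
        w <- nchar(b$seq)
        blk <- matrix("-", n, w)
        blk[b$row, ] <- .chars(b$seq)
        add_chunk(blk)
      }
    }
  }
  aln_m <- do.call(cbind, chunks[seq_len(ci)])
  rows <- setNames(apply(aln_m, 1, paste, collapse = ""), ids)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(row = character(), type = character(), pos = integer(),
               ref = character(), alt = character(), transition = logical(),
               length = integer())
  list(alignment = mito_alignment(rows, reference_id = ids[1]),
       truth = truth, ancestor = genome$sequence)
}
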