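# Control-region (D-loop) dissection: locate conserved elements from a
# motif library and derive the ETAS / central conserved (CD) / CSB domain
# boundaries from the located anchors.

#' The bundled control-region motif library
#'
#' Elements of the mammalian control region (ETAS1, termination motif,
#' TAS-A, the F/E/D/C/B boxes of the central conserved domain, CSB1-3, the
#' HSP/LSP promoter cores, the RS3 minisatellite unit and the ATGN9CAT
#' palindromic motif), each with a search window (as fractions of the CR
#' span) and a per-element edit-distance cap.  Rows marked `synthetic` in
#' the `source` column are stand-in consensus sequences written for this
#' package (the bundled simulator plants exactly these); replace them with
#' species-appropriate consensus sequences for real data.
#'
#' @param path optional path to a user library in the same TSV dialect.
#' @return data frame with columns `element`, `role`, `motif`, `max_edit`,
#'   `win_start`, `win_end`, `source`.
#' @export
cr_motif_library <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("cr_motif_library.tsv")
  lib <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "role", "motif", "max_edit", "win_start", "win_end")
  miss <- setdiff(need, names(lib))
  if (length(miss)) .mp_stop("mp_io_error",
                             paste0("motif library missing column(s): ",
                                    paste(miss, collapse = ", ")))
  lib$motif <- toupper(lib$motif)
  lib
}

# Semi-global (pattern-in-text) edit-distance search.  N in the pattern
# matches any base at zero cost.  Returns the best match's 1-based start and
# end in `text` plus the edit distance; ties resolved to the leftmost end.
.edit_locate <- function(pattern, text) {
  pc <- .chars(pattern)
  tc <- .chars(text)
  m <- length(pc); n <- length(tc)
  if (n == 0) return(list(start = NA, end = NA, dist = Inf))
  best_end_dp <- function(pc, tc) {
    n <- length(tc)
    prev <- rep(0, n + 1)
    for (i in seq_along(pc)) {
      cost <- as.integer(!(pc[i] == "N" | tc == pc[i]))
      cand <- pmin(prev[1:n] + cost, prev[2:(n + 1)] + 1)
      val <- c(i, cand)
      # horizontal pass: cur[j] = min over j' <= j of val[j'] + (j - j')
      cur <- cummin(val - 0:n) + 0:n
      prev <- cur
    }
    j <- which.min(prev[-1])
    list(end = j, dist = prev[j + 1])
  }
  fwd <- best_end_dp(pc, tc)
  # locate the start by re-running on the reversed prefix ending at the hit
  lo <- max(1L, fwd$end - m - fwd$dist)
  rev_seg <- rev(tc[lo:fwd$end])
  bwd <- best_end_dp(rev(pc), rev_seg)
  list(start = fwd$end - bwd$end + 1L, end = fwd$end, dist = fwd$dist)
}

#' Annotate a control-region sequence
#'
#' Locates each library element inside its search window by minimum edit
#' distance (N matching any base); elements whose best match exceeds the
#' per-element cap are reported as missing, never silently placed.  The
#' minisatellite row is located with the tandem-repeat scanner (period =
#' unit length), and N-containing palindromic motifs with the exact motif
#' scanner (all hits reported).  Domain boundaries are derived from the
#' located anchors: the ETAS domain runs from the CR 5' end to just before
#' the central conserved domain, which starts `cd_lead` bp before the F-box
#' and ends `cd_tail` bp after the B-box; the CSB domain covers the
#' remainder to the CR 3' end.
#'
#' @param cr_seq control-region sequence (>= 200 bp).
#' @param cr_offset genomic position of the base before the CR (so CR
#'   position `i` is genomic `cr_offset + i`); 0 for CR-local coordinates.
#' @param library motif library (default [cr_motif_library()]).
#' @param cd_lead,cd_tail distances (bp) from the F-box start and B-box end
#'   to the central-domain boundaries (defaults 7 and 89, the mustelid
#'   layout).
#' @return a `cr_annotation` list: `domains` (ETAS/CD/CSB intervals, NA if
#'   anchors are missing), `elements` (located elements with genomic
#'   coordinates and edit distances), `missing` (element names not located
#'   within their caps).
#' @export
annotate_control_region <- function(cr_seq, cr_offset = 0,
                                    library = cr_motif_library(),
                                    cd_lead = 7, cd_tail = 89) {
  L <- nchar(cr_seq)
  if (L < 200) .mp_stop("mp_sequence_error",
                        "control region shorter than 200 bp")
  elements <- list()
  missing <- character(0)
  add <- function(el, start, end, dist) {
    elements[[length(elements) + 1L]] <<- data.frame(
      element = el, start = cr_offset + start, end = cr_offset + end,
      edit_distance = dist, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(library))) {
    row <- library[i, ]
    w0 <- max(1L, floor(row$win_start * L) + 1L)
    w1 <- min(L, ceiling(row$win_end * L))
    win <- substr(cr_seq, w0, w1)
    if (row$role == "minisatellite") {
      tr <- find_tandem_repeats(win, max_period = nchar(row$motif) + 5)
      tr <- tr[tr$period == nchar(row$motif), , drop = FALSE]
      if (nrow(tr)) {
        tr <- tr[which.max(tr$score), ]
        add(row$element, w0 + tr$start - 1L, w0 + tr$end - 1L, NA)
      } else missing <- c(missing, row$element)
    } else if (grepl("N", row$motif, fixed = TRUE)) {
      mh <- find_motif(win, row$motif, circular = FALSE, both_strands = FALSE)
      if (nrow(mh)) {
        for (k in seq_len(nrow(mh))) {
          add(paste0(row$element, "_", k), w0 + mh$start[k] - 1L,
              w0 + mh$end[k] - 1L, 0)
        }
      } else missing <- c(missing, row$element)
    } else {
      loc <- .edit_locate(row$motif, win)
      if (is.finite(loc$dist) && loc$dist <= row$max_edit) {
        add(row$element, w0 + loc$start - 1L, w0 + loc$end - 1L, loc$dist)
      } else missing <- c(missing, row$element)
    }
  }
  elements <- if (length(elements)) do.call(rbind, elements) else
    data.frame(element = character(), start = integer(), end = integer(),
               edit_distance = numeric())
  anchor <- function(el) {
    i <- match(el, elements$element)
    if (is.na(i)) NULL else elements[i, ]
  }
  fb <- anchor("F-box"); bb <- anchor("B-box")
  domains <- data.frame(domain = c("ETAS", "CD", "CSB"),
                        start = NA_integer_, end = NA_integer_)
  if (!is.null(fb) && !is.null(bb)) {
    cd_start <- fb$start - cd_lead
    cd_end <- bb$end + cd_tail
    domains$start <- c(cr_offset + 1L, cd_start, cd_end + 1L)
    domains$end <- c(cd_start - 1L, cd_end, cr_offset + L)
  }
  structure(list(domains = domains, elements = elements, missing = missing,
                 cr_start = cr_offset + 1L, cr_end = cr_offset + L),
            class = "cr_annotation")
}

#' @export
print.cr_annotation <- function(x, ...) {
  cat("<cr_annotation> CR ", x$cr_start, "-", x$cr_end, "\n", sep = "")
  if (!any(is.na(x$domains$start))) {
    for (i in 1:3) cat(sprintf("  %-4s %d-%d\n", x$domains$domain[i],
                               x$domains$start[i], x$domains$end[i]))
  }
  cat("  elements located: ", nrow(x$elements),
      "; missing: ", if (length(x$missing)) paste(x$missing, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
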