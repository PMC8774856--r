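#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased and U is mapped to T.  Record order is
#' preserved.  Characters outside \{A,C,G,T,N\} (after U->T folding), empty
#' files and duplicated record ids raise typed errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are record ids, the
#'   first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .mp_stop("mp_io_error", paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .mp_stop("mp_io_error", conditionMessage(e)))
  if (length(set) == 0) .mp_stop("mp_empty_file", paste0("no FASTA records in ", path))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    .mp_stop("mp_duplicate_id", paste0("duplicate FASTA id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ok <- grepl("^[ACGTN-]*$", seqs)
  if (!all(ok)) {
    .mp_stop("mp_alphabet_error",
             paste0("record '", ids[which(!ok)[1]], "' contains non-IUPAC-DNA characters"))
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Build a feature table
#'
#' Validates a data frame of mitogenome features against the package's
#' coordinate conventions: 1-based inclusive H-strand coordinates, start <=
#' end (wrap-around features must be split before ingestion), kinds from a
#' fixed vocabulary, strand H or L (mandatory for protein-coding genes).
#'
#' @param df data frame with columns `name`, `kind`, `start`, `end`,
#'   `strand`, and optionally `anticodon`, `start_codon`, `stop_codon`,
#'   `aa_count`.
#' @param genome_length genome length used to range-check coordinates
#'   (optional).
#' @return the validated data frame with a recomputed `size` column, ordered
#'   as supplied, with class `mito_features`.
#' @export
feature_table <- function(df, genome_length = NULL) {
  need <- c("name", "kind", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) .mp_stop("mp_feature_error",
                             paste0("missing feature column(s): ", paste(miss, collapse = ", ")))
  kinds <- c("PCG", "tRNA", "rRNA", "origin", "control_region", "other")
  if (!all(df$kind %in% kinds)) {
    .mp_stop("mp_feature_error", paste0("unknown feature kind: ",
             paste(setdiff(unique(df$kind), kinds), collapse = ", ")))
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1L)) .mp_stop("mp_coordinate_error", "feature start < 1 (coordinates are 1-based)")
  if (!is.null(genome_length) && any(df$end > genome_length)) {
    .mp_stop("mp_coordinate_error",
             paste0("feature end beyond genome length ", genome_length))
  }
  if (any(df$start > df$end)) {
    .mp_stop("mp_coordinate_error",
             "feature with start > end (wrap-around features must be split)")
  }
  if (any(df$kind == "PCG" & !(df$strand %in% c("H", "L")))) {
    .mp_stop("mp_feature_error", "protein-coding feature without H/L strand")
  }
  size <- df$end - df$start + 1L
  if (!is.null(df$size) && any(!is.na(df$size) & df$size != size)) {
    .mp_stop("mp_feature_error", "declared size disagrees with coordinates")
  }
  df$size <- size
  if (is.null(df$anticodon)) df$anticodon <- NA_character_
  rownames(df) <- NULL
  class(df) <- c("mito_features", "data.frame")
  df
}

#' Read a feature table from TSV or GFF3
#'
#' The native format is a tab-separated dialect with columns `name`, `kind`,
#' `start`, `end`, `strand` (H/L) and optional `anticodon`, `start_codon`,
#' `stop_codon`, `aa_count`; lines starting with `#` are comments.  Files
#' whose first non-blank line starts with `##gff` are parsed as GFF3 (via
#' rtracklayer, if installed), with `gene`/`Name` attributes as names, the
#' `type` column mapped to kinds and +/- strands mapped to H/L.
#'
#' @param path input path.
#' @param genome_length genome length for coordinate range checks.
#' @return a `mito_features` data frame (see [feature_table()]).
#' @export
read_features <- function(path, genome_length = NULL) {
  if (!file.exists(path)) .mp_stop("mp_io_error", paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      .mp_stop("mp_io_error", "reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    md <- as.data.frame(gr)
    nm <- if (!is.null(md$Name)) md$Name else md$ID
    kind_map <- c(gene = "PCG", CDS = "PCG", mRNA = "PCG",
                  tRNA = "tRNA", rRNA = "rRNA",
                  rep_origin = "origin", origin = "origin",
                  D_loop = "control_region", control_region = "control_region")
    kind <- kind_map[as.character(md$type)]
    kind[is.na(kind)] <- "other"
    df <- data.frame(name = nm, kind = kind, start = md$start, end = md$end,
                     strand = ifelse(as.character(md$strand) == "-", "L", "H"),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  }
  feature_table(df, genome_length = genome_length)
}

#' The bundled reference feature template
#'
#' The 1-based gene layout of the European mink (*Mustela lutreola*)
#' reference mitogenome MW148603 (16,504 bp): 13 protein-coding genes, 22
#' tRNAs, 2 rRNAs, the light-strand replication origin and the control
#' region, with annotated start/stop codons and amino-acid counts.
#'
#' @return a `mito_features` data frame of 40 features.
#' @examples
#' ft <- lutreola_features()
#' sum(ft$size[ft$kind == "PCG"])  # 11410
#' @export
lutreola_features <- function() {
  read_features(.extdata("mustela_lutreola_features.tsv"), genome_length = 16504L)
}

#' Construct an annotated mitogenome
#'
#' @param id accession-like identifier.
#' @param sequence uppercase DNA string over \{A,C,G,T,N\}.
#' @param features optional `mito_features` table (see [feature_table()]).
#' @param circular logical; circular topology (default TRUE).
#' @return an object of class `mitogenome` with fields `id`, `sequence`,
#'   `circular`, `features`, `length`.
#' @export
mitogenome <- function(id, sequence, features = NULL, circular = TRUE) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) .mp_stop("mp_sequence_error", "empty genome sequence")
  if (!grepl("^[ACGTN]*$", sequence)) {
    .mp_stop("mp_alphabet_error", "genome sequence restricted to A,C,G,T,N")
  }
  len <- nchar(sequence)
  if (!is.null(features)) features <- feature_table(as.data.frame(features), genome_length = len)
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features, length = len),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$id, ": ", x$length, " bp",
      if (x$circular) " (circular)", "\n", sep = "")
  if (!is.null(x$features)) {
    cat("  features: ", nrow(x$features), " (",
        paste(names(table(x$features$kind)), table(x$features$kind),
              sep = "=", collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Extract a feature's sequence on its coding strand
#'
#' L-strand features are reverse-complemented on extraction; coordinates are
#' always stored on the H strand.
#'
#' @param genome a `mitogenome`.
#' @param feature one row of a `mito_features` table (or a name present in
#'   the genome's feature table).
#' @return the feature sequence, 5'->3' on its encoding strand.
#' @export
feature_sequence <- function(genome, feature) {
  if (is.character(feature)) {
    i <- match(feature, genome$features$name)
    if (is.na(i)) .mp_stop("mp_feature_error", paste0("no feature named '", feature, "'"))
    feature <- genome$features[i, ]
  }
  s <- substr(genome$sequence, feature$start, feature$end)
  if (identical(feature$strand, "L")) revcomp(s) else s
}

#' Intergenic spacings and overlaps between consecutive features
#'
#' For consecutive features (sorted by start), spacing is
#' `next.start - prev.end - 1`: positive values are intergenic nucleotides,
#' negative values are overlapping nucleotides, zero means abutting.  For a
#' circular genome the closure pair (last feature, first feature) is
#' included, with spacing `genome_length - last.end + first.start - 1`.
#'
#' @param features a `mito_features` table.
#' @param genome_length genome length (needed for the circular closure).
#' @param circular include the wrap-around pair (default TRUE).
#' @return data frame with columns `from`, `to`, `spacing`.
#' @examples
#' ft <- lutreola_features()
#' sp <- intergenic_and_overlaps(ft, 16504)
#' sp[sp$from == "atp8", ]  # -43 bp overlap with atp6
#' @export
intergenic_and_overlaps <- function(features, genome_length = NULL, circular = TRUE) {
  ft <- features[order(features$start, features$end), ]
  n <- nrow(ft)
  if (n < 2) return(data.frame(from = character(), to = character(), spacing = integer()))
  out <- data.frame(from = ft$name[-n], to = ft$name[-1],
                    spacing = ft$start[-1] - ft$end[-n] - 1L,
                    stringsAsFactors = FALSE)
  if (circular) {
    if (is.null(genome_length)) .mp_stop("mp_coordinate_error",
                                         "genome_length required for circular closure")
    out <- rbind(out, data.frame(from = ft$name[n], to = ft$name[1],
                                 spacing = genome_length - ft$end[n] + ft$start[1] - 1L))
  }
  out
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path aligned FASTA; all rows must have equal length and use only
#'   A,C,G,T,N,-.
#' @param reference_id id of the reference row; defaults to the first record.
#' @return a `mito_alignment` object with fields `ids`, `rows` (named
#'   character vector), `reference_id`, `ncol`.
#' @export
read_alignment <- function(path, reference_id = NULL) {
  rows <- read_fasta(path)
  mito_alignment(rows, reference_id = reference_id)
}

#' Construct a multiple alignment object
#'
#' @param rows named character vector of equal-length aligned sequences over
#'   \{A,C,G,T,N,-\}.
#' @param reference_id reference row id (defaults to the first row).
#' @return a `mito_alignment` object.
#' @export
mito_alignment <- function(rows, reference_id = NULL) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    .mp_stop("mp_alignment_error", "alignment rows must be named")
  }
  if (length(unique(nchar(rows))) != 1L) {
    .mp_stop("mp_alignment_error", "alignment rows differ in length")
  }
  if (!all(grepl("^[ACGTN-]*$", rows))) {
    .mp_stop("mp_alphabet_error", "alignment restricted to A,C,G,T,N,-")
  }
  if (is.null(reference_id)) reference_id <- names(rows)[1]
  if (!reference_id %in% names(rows)) {
    .mp_stop("mp_alignment_error", paste0("reference id '", reference_id, "' not in alignment"))
  }
  structure(list(ids = names(rows), rows = rows, reference_id = reference_id,
                 ncol = nchar(rows[[1]])),
            class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("<mito_alignment> ", length(x$ids), " rows x ", x$ncol,
      " columns (reference: ", x$reference_id, ")\n", sep = "")
  invisible(x)
}

# alignment as a character matrix (rows x columns)
.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Write a mitogenome (FASTA + feature TSV)
#'
#' Round-trips losslessly with [read_mitogenome()].
#'
#' @param genome a `mitogenome`.
#' @param fasta,features output paths; `features` may be NULL to skip.
#' @return invisibly, the fasta path.
#' @export
write_mitogenome <- function(genome, fasta, features = NULL) {
  write_fasta(setNames(genome$sequence, genome$id), fasta)
  if (!is.null(features) && !is.null(genome$features)) {
    ft <- as.data.frame(genome$features)
    write.table(ft, features, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read a mitogenome written by [write_mitogenome()]
#'
#' @param fasta,features input paths (`features` optional).
#' @param circular circular topology flag.
#' @return a `mitogenome`.
#' @export
read_mitogenome <- function(fasta, features = NULL, circular = TRUE) {
  seqs <- read_fasta(fasta)
  ft <- if (!is.null(features)) read_features(features, genome_length = nchar(seqs[[1]]))
  mitogenome(names(seqs)[1], seqs[[1]], features = ft, circular = circular)
}
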