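#!/usr/bin/env Rscript

# Optional helper: downloads the deposited mitogenome accessions from NCBI
# and prepares the aligned FASTA inputs used by the accession-based
# acceptance checks.  Requires network access and an aligner (mafft) on the
# PATH; nothing in the test suite depends on running this script -- the
# accession-based checks simply report the data as unavailable until the
# files below exist under inst/extdata/accessions/.
#
# Usage: Rscript scripts/fetch_accessions.R [out_dir]

conspecific <- c("MW197423", "MW197424", "MW197425", "MW197426",
                 "MW148603", "MT304869")
comparators <- c(M_putorius = "HM106318", M_eversmannii = "NC_028013",
                 M_nigripes = "NC_024942", M_sibirica = "MN206976",
                 M_itatsi = "NC_034330", M_altaica = "NC_021751",
                 M_nivalis = "MF459691", M_erminea = "MW257230",
                 M_kathiah = "HM106320", M_frenata = "HM106321",
                 N_vison = "NC_020641", L_lutra = "NC_011358",
                 G_gulo = "NC_009685", M_foina = "NC_020643",
                 M_meles = "NC_011125", T_aculeatus = "AJ303116")

args <- commandArgs(trailingOnly = TRUE)
out_dir <- if (length(args)) args[1] else "inst/extdata/accessions"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

efetch <- function(acc, dest) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", acc, "&rettype=fasta&retmode=text")
  utils::download.file(url, dest, quiet = TRUE)
  Sys.sleep(0.4)   # NCBI rate courtesy
}

fetch_set <- function(accs, raw_fasta, renames = NULL) {
  tmp <- tempfile()
  out <- character(0)
  for (i in seq_along(accs)) {
    efetch(accs[i], tmp)
    rec <- readLines(tmp)
    id <- if (!is.null(renames)) names(accs)[i] else accs[i]
    rec[1] <- paste0(">", id)
    out <- c(out, rec)
  }
  writeLines(out, raw_fasta)
}

message("fetching conspecific accessions ...")
fetch_set(conspecific, file.path(out_dir, "conspecific_raw.fasta"))
message("fetching comparator accessions ...")
inter <- c(M_lutreola = "MW148603", comparators)
fetch_set(inter, file.path(out_dir, "mustela_raw.fasta"), renames = TRUE)

align <- function(raw, aligned) {
  status <- system2("mafft", c("--auto", "--quiet", raw), stdout = aligned)
  if (status != 0) stop("mafft failed for ", raw)
}
message("aligning (mafft) ...")
align(file.path(out_dir, "conspecific_raw.fasta"),
      file.path(out_dir, "conspecific_aligned.fasta"))
align(file.path(out_dir, "mustela_raw.fasta"),
      file.path(out_dir, "mustela_aligned.fasta"))
message("done; re-install the package so system.file() can see the files.")
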