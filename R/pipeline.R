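# One-call orchestration of the characterisation stages into a report
# bundle of TSV/JSON/Newick files mirroring the tables a mitogenome
# description paper reports.

.default_config <- function() {
  list(
    cpg = list(window = 100, min_length = 200, min_gc = 50, min_obs_exp = 0.6),
    ssr = list(unit_min = 1, unit_max = 10, min_copies = 3, min_length = 6),
    tandem = list(match = 2, mismatch = 7, indel = 7, min_score = 50, max_period = 500),
    inverted = list(arm_min = 6, arm_max = 50, gap_max = 20, mismatches = 0),
    palindrome = list(len_min = 6, len_max = 30),
    hairpin = list(stem_min = 5, loop_min = 3, loop_max = 20),
    hvs = list(window = 50, step = 10, min_incidence = 1 / 25),
    distance = list(model = "TN93", gap_mode = "pairwise_deletion"),
    bootstrap = 0
  )
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys override the documented defaults (which are the
#' published scan parameters); unknown keys are rejected.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) .mp_stop("mp_config_error",
                            paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(cfg[[k]])) {
      bad2 <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad2)) .mp_stop("mp_config_error",
                                 paste0("unknown config key(s): ",
                                        paste(paste0(k, ".", bad2), collapse = ", ")))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Run the full characterisation pipeline
#'
#' Runs every applicable stage on an annotated genome (and optionally a
#' multiple alignment of conspecific sequences) and writes a report
#' bundle: feature table with intergenic spacings, per-partition
#' composition, codon usage / RSCU / bias indicators, repeat and motif
#' hits, control-region annotation, and - when an alignment is supplied -
#' variant table, diversity statistics, haplotype network edges, distance
#' matrix and NJ tree (with bootstrap supports when configured).  A
#' manifest logs package version, parameters and seed.  Any stage error
#' aborts with the stage name; outputs written so far are retained next to
#' a `FAILED` marker file.
#'
#' @param genome a `mitogenome` with features.
#' @param out_dir output directory (created if needed).
#' @param aln optional `mito_alignment` of conspecific sequences.
#' @param config configuration list (see [read_run_config()]).
#' @param seed seed used for the bootstrap stage.
#' @return invisibly, a named list of written file paths plus the summary
#'   list under `$summary`.
#' @export
run_characterization <- function(genome, out_dir, aln = NULL,
                                 config = read_run_config(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  summary <- list(genome_id = genome$id, genome_length = genome$length)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      .mp_stop("mp_pipeline_error",
               paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  wtsv <- function(df, file) {
    p <- file.path(out_dir, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[file]] <<- p
  }
  wjson <- function(x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[file]] <<- p
  }
  stage("features", function() {
    ft <- as.data.frame(genome$features)
    sp <- intergenic_and_overlaps(genome$features, genome$length,
                                  circular = genome$circular)
    ft$spacing_to_next <- sp$spacing[match(ft$name, sp$from)]
    wtsv(ft, "features.tsv")
  })
  stage("composition", function() {
    prof <- partition_profiles(genome)
    wtsv(composition_table(prof), "composition.tsv")
    summary$at_percent <<- prof$genome$at_percent
    summary$at_skew <<- prof$genome$at_skew
    summary$gc_skew <<- prof$genome$gc_skew
    cpg <- find_cpg_islands(genome$sequence, window = config$cpg$window,
                            min_length = config$cpg$min_length,
                            min_gc = config$cpg$min_gc,
                            min_obs_exp = config$cpg$min_obs_exp)
    wtsv(cpg, "cpg_islands.tsv")
    summary$n_cpg_islands <<- nrow(cpg)
  })
  stage("codon_bias", function() {
    pcgs <- genome$features[genome$features$kind == "PCG", ]
    cds <- lapply(seq_len(nrow(pcgs)), function(i) extract_cds(genome, pcgs[i, ]))
    usage <- codon_usage(cds)
    ut <- data.frame(codon = names(usage$counts),
                     aa = unname(mito_code()[names(usage$counts)]),
                     count = unname(usage$counts),
                     percent = round(unname(usage$percent), 2))
    wtsv(ut, "codon_usage.tsv")
    rs <- rscu(usage)
    wtsv(data.frame(codon = names(rs), aa = unname(mito_code()[names(rs)]),
                    rscu = round(unname(rs), 3)), "rscu.tsv")
    bias <- codon_bias_table(genome)
    wtsv(bias, "codon_bias.tsv")
    summary$total_codons <<- usage$total_codons
    summary$enc_overall <<- bias$enc[bias$gene == "overall"]
    summary$cbi_overall <<- bias$cbi[bias$gene == "overall"]
    summary$gc3s_overall <<- bias$gc3s[bias$gene == "overall"]
  })
  stage("repeats", function() {
    hits <- scan_repeats(genome$sequence)
    wtsv(hits, "repeat_hits.tsv")
    summary$n_repeat_hits <<- nrow(hits)
  })
  stage("control_region", function() {
    cr <- genome$features[genome$features$kind == "control_region", ]
    if (nrow(cr) == 1) {
      ann <- annotate_control_region(
        substr(genome$sequence, cr$start[1], cr$end[1]),
        cr_offset = cr$start[1] - 1L)
      wjson(list(domains = ann$domains, elements = ann$elements,
                 missing = ann$missing), "cr_annotation.json")
      summary$cr_missing_elements <<- length(ann$missing)
    }
  })
  if (!is.null(aln)) {
    stage("variation", function() {
      calls <- call_variants(aln, features = genome$features)
      wtsv(calls, "variants.tsv")
      ds <- diversity_stats(aln)
      wjson(unclass(ds), "diversity.json")
      part <- haplotype_partition(aln)
      if (part$n_haplotypes >= 2) {
        net <- haplotype_network(part, aln)
        wtsv(net$edges, "network_edges.tsv")
      }
      summary$n_variants <<- nrow(calls)
      summary$n_haplotypes <<- part$n_haplotypes
      summary$pi <<- ds$pi
      summary$hd <<- ds$hd
    })
    if (length(aln$ids) >= 3) {
      stage("phylogeny", function() {
        dm <- distance_matrix(aln, model = config$distance$model,
                              gap_mode = config$distance$gap_mode)
        wtsv(cbind(id = rownames(dm$matrix), as.data.frame(dm$matrix)),
             "distances.tsv")
        tree <- if (config$bootstrap > 0 && length(aln$ids) >= 4) {
          bootstrap_support(aln, model = config$distance$model,
                            B = config$bootstrap, seed = seed,
                            gap_mode = config$distance$gap_mode)
        } else nj_tree(dm)
        p <- file.path(out_dir, "tree.nwk")
        ape::write.tree(tree, p)
        paths[["tree.nwk"]] <<- p
        summary$overall_mean_distance <<- overall_mean_distance(dm)
      })
    }
  }
  stage("manifest", function() {
    wjson(list(package = "mitoprofile",
               version = as.character(utils::packageVersion("mitoprofile")),
               seed = seed, config = config, summary = summary,
               files = names(paths)), "manifest.json")
    wjson(summary, "summary.json")
  })
  invisible(c(paths, list(summary = summary)))
}
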