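#' Assemble a pipeline run configuration
#'
#' Single source of truth for one end-to-end run: input paths plus every
#' stage parameter, echoed verbatim to the run log.
#'
#' @param peaks,metabolites,fasta,peptides,coverage input file paths
#'   (`coverage` may be NULL/missing: the presence stage is then skipped
#'   with a warning).
#' @param out_dir output directory.
#' @param n_max,tol_ppm Kendrick stage parameters.
#' @param class_table_path optional JSON compound-class table (NULL for the
#'   default table).
#' @param formula_tol_ppm compound-class formula-assignment tolerance.
#' @param min_peptides,clust_distance,clust_linkage proteomics parameters.
#' @param alpha,lfc,prior_df enrichment parameters.
#' @param seed run seed (recorded; the analysis stages are deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(peaks, metabolites, fasta, peptides, coverage = NULL,
                       out_dir, n_max = 6, tol_ppm = 3,
                       class_table_path = NULL, formula_tol_ppm = 1,
                       min_peptides = 2, clust_distance = "bray",
                       clust_linkage = "average", alpha = 0.05, lfc = 1.5,
                       prior_df = 4, seed = 1) {
  cfg <- list(peaks = peaks, metabolites = metabolites, fasta = fasta,
              peptides = peptides, coverage = coverage, out_dir = out_dir,
              n_max = n_max, tol_ppm = tol_ppm,
              class_table_path = class_table_path,
              formula_tol_ppm = formula_tol_ppm, min_peptides = min_peptides,
              clust_distance = clust_distance, clust_linkage = clust_linkage,
              alpha = alpha, lfc = lfc, prior_df = prior_df,
              seed = as.integer(seed))
  required <- c("peaks", "metabolites", "fasta", "peptides")
  for (nm in required) {
    if (!file.exists(cfg[[nm]])) stop("input file not found: ", cfg[[nm]])
  }
  structure(cfg, class = "run_config")
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the Kendrick oligomer stage, the van Krevelen compound-class
#' stage, the metaproteome stage (uniqueness classes, NSAF, MAG
#' contributions, sample clustering, MAG presence when a coverage table is
#' supplied) and the metabolite enrichment stage, writing delimited-text
#' outputs, a JSON summary and a run log (effective parameters plus input
#' MD5 checksums) under `config$out_dir`. Rerunning over an existing output
#' directory requires `force = TRUE` and then reproduces identical files.
#'
#' @param config list from [run_config()].
#' @param force overwrite an existing, non-empty output directory.
#' @return named list of the per-stage result objects, invisibly.
#' @export
run_all <- function(config, force = FALSE) {
  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out)) && !force) {
    stop("output directory is not empty (use force = TRUE to overwrite): ",
         out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  # -- kendrick stage -------------------------------------------------------
  results$kendrick <- .run_stage("kendrick", {
    peaks <- read_peak_list(config$peaks)
    ladder <- ct_ion_ladder(n_max = config$n_max)
    assignments <- classify_peaks(peaks, ladder, config$tol_ppm)
    richness <- oligomer_richness(assignments)
    split <- isotopic_split_check(assignments)
    hexbin <- hexbin_kmd(assignments)
    write_ion_ladder(ladder, file.path(out, "ion_ladder.csv"))
    utils::write.csv(assignments, file.path(out, "oligomer_assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(richness, file.path(out, "oligomer_richness.csv"),
                     row.names = FALSE)
    utils::write.csv(split, file.path(out, "isotopic_split.csv"),
                     row.names = FALSE)
    utils::write.csv(hexbin, file.path(out, "kmd_hexbin.csv"),
                     row.names = FALSE)
    list(assignments = assignments, richness = richness, split = split)
  })

  # -- compound-class stage -------------------------------------------------
  results$dom_classes <- .run_stage("dom_classes", {
    peaks <- read_peak_list(config$peaks)
    assignments <- results$kendrick$assignments
    # CT-assigned peaks already have an identity; classify the remainder
    matrix_peaks <- peaks[!assignments$assigned, , drop = FALSE]
    class_table <- if (is.null(config$class_table_path)) default_class_table()
                   else read_class_table(config$class_table_path)
    classes <- class_relative_abundance(matrix_peaks,
                                        tol_ppm = config$formula_tol_ppm,
                                        class_table = class_table)
    utils::write.csv(classes, file.path(out, "compound_classes.csv"),
                     row.names = FALSE)
    classes
  })

  # -- metaproteome stage ---------------------------------------------------
  results$metaproteome <- .run_stage("metaproteome", {
    proteins <- read_protein_fasta(config$fasta)
    observations <- read_peptide_report(config$peptides)
    quant <- protein_quant(observations, proteins,
                           min_distinct_peptides = config$min_peptides)
    contrib <- mag_contribution(quant)
    tree <- cluster_samples(contrib, config$clust_distance,
                            config$clust_linkage)
    utils::write.csv(quant$quants, file.path(out, "protein_classes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(protein_id = rownames(quant$nsaf),
                                quant$nsaf, check.names = FALSE),
                     file.path(out, "nsaf.csv"), row.names = FALSE)
    utils::write.csv(data.frame(mag_id = rownames(contrib), contrib,
                                check.names = FALSE),
                     file.path(out, "mag_contribution.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(tree$merge, height = tree$height),
                     file.path(out, "sample_clustering.csv"),
                     row.names = FALSE)
    writeLines(tree$labels, file.path(out, "sample_clustering_labels.txt"))
    list(quant = quant, contrib = contrib, tree = tree)
  })

  # -- MAG presence (optional) ---------------------------------------------
  if (!is.null(config$coverage) && file.exists(config$coverage)) {
    results$presence <- .run_stage("presence", {
      coverage <- utils::read.csv(config$coverage, stringsAsFactors = FALSE)
      presence <- mag_presence(coverage)
      utils::write.csv(presence$per_sample,
                       file.path(out, "mag_presence_per_sample.csv"),
                       row.names = FALSE)
      utils::write.csv(presence$per_treatment,
                       file.path(out, "mag_presence_per_treatment.csv"),
                       row.names = FALSE)
      presence
    })
  } else {
    warning("no coverage table supplied; MAG presence stage skipped")
  }

  # -- enrichment stage -----------------------------------------------------
  results$enrichment <- .run_stage("enrichment", {
    areas <- read_metabolite_table(config$metabolites)
    calls <- moderated_test(areas, prior_df = config$prior_df,
                            alpha = config$alpha,
                            fc_threshold = config$lfc)
    utils::write.csv(calls, file.path(out, "enrichment_calls.csv"),
                     row.names = FALSE)
    calls
  })

  # -- summary + provenance -------------------------------------------------
  summary <- list(
    n_peaks = nrow(results$kendrick$assignments),
    n_assigned = sum(results$kendrick$assignments$assigned),
    richness = results$kendrick$richness,
    class_percent = results$dom_classes,
    n_proteins_quantified = nrow(results$metaproteome$quant$quants),
    uniqueness_counts = as.list(table(
      results$metaproteome$quant$quants$uniqueness_class)),
    n_significant_calls = sum(results$enrichment$significant)
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inputs <- Filter(Negate(is.null),
                   config[c("peaks", "metabolites", "fasta", "peptides",
                            "coverage")])
  log_lines <- c(
    "tanninflow run log",
    paste0("parameter ", names(unclass(config)), " = ",
           vapply(unclass(config), function(x)
             if (is.null(x)) "NULL" else paste(x, collapse = ","), "")),
    paste0("md5 ", unlist(inputs), " = ",
           unname(tools::md5sum(unlist(inputs))))
  )
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(results)
}
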