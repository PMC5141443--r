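# End-to-end orchestration: simulate (or load) a dataset, run motif
# enrichment across the catalog, the WRCG-vs-CpG-control contrast, the
# subsampling power procedure and the methylation association, writing
# one TSV per stage plus the resolved configuration.

#' Build a pipeline run configuration
#'
#' Either `truth` (simulate inputs) or the three file paths (load
#' existing inputs) must be given.
#'
#' @param outdir Output directory (created if needed).
#' @param truth Optional `synthetic_truth`: the pipeline simulates its
#'   inputs.
#' @param mutations_path,reference_path,methylation_path Input files used
#'   when `truth` is `NULL` (TSV/VCF, FASTA, TSV).
#' @param mutations_format `"tsv"` or `"vcf"`.
#' @param motifs Character subset of catalog motif names (default: all).
#' @param flank Neighborhood flank (default 60 = 120 bp window).
#' @param mask_cpg Also run the enrichment with CpG masking.
#' @param mc_reps Monte Carlo replicates for the enrichment stage.
#' @param sampling_reps Replicates for the methylation sampling test.
#' @param per_sample Additionally run enrichment per `sample_id` with
#'   Bonferroni correction across samples.
#' @param seed Master RNG seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(outdir, truth = NULL, mutations_path = NULL,
                       reference_path = NULL, methylation_path = NULL,
                       mutations_format = "tsv", motifs = NULL,
                       flank = 60L, mask_cpg = TRUE, mc_reps = 1000L,
                       sampling_reps = 10000L, per_sample = FALSE,
                       seed = 1L) {
  if (is.null(truth) && (is.null(mutations_path) ||
                         is.null(reference_path))) {
    stop("either truth or mutations_path + reference_path required")
  }
  structure(list(outdir = outdir, truth = truth,
                 mutations_path = mutations_path,
                 reference_path = reference_path,
                 methylation_path = methylation_path,
                 mutations_format = mutations_format, motifs = motifs,
                 flank = as.integer(flank), mask_cpg = mask_cpg,
                 mc_reps = as.integer(mc_reps),
                 sampling_reps = as.integer(sampling_reps),
                 per_sample = per_sample, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: input (simulate or load), neighborhood extraction, mutation
#' spectrum, catalog enrichment (plain and CpG-masked), WRCG contrast,
#' and methylation association. Each stage writes a TSV under the
#' configured output directory; the resolved configuration is written as
#' `config.json`. Deterministic given the seed: a rerun reproduces every
#' table byte for byte.
#'
#' @param config A `run_config`.
#' @return Invisible list of stage results (`enrichment`,
#'   `enrichment_masked`, `per_sample`, `contrast`, `methylation`,
#'   `spectrum`, `mutations`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- motif_catalog()
  if (!is.null(config$motifs)) catalog <- catalog[config$motifs]

  if (!is.null(config$truth)) {
    sim <- .stage("simulate", simulate_dataset(config$truth,
                                               outdir = config$outdir))
    reference <- sim$reference
    mutations <- sim$mutations
    methylation <- sim$methylation
  } else {
    mutations <- .stage("input", read_mutations(
      config$mutations_path, format = config$mutations_format))
    reference <- .stage("input", .as_reference(config$reference_path))
    methylation <- if (!is.null(config$methylation_path))
      .stage("input", read_methylation(config$methylation_path)) else NULL
  }
  message("pipeline: ", nrow(mutations), " mutations loaded")

  mutations <- .stage("neighborhoods", attach_neighborhoods(
    mutations, reference = reference, flank = config$flank))

  spectrum <- .stage("spectrum", spectrum_summary(mutations))

  enr <- .stage("enrich", enrich_catalog(
    mutations, catalog, mc_reps = config$mc_reps, seed = config$seed))
  write_results(enr, file.path(config$outdir, "enrichment.tsv"))

  enr_masked <- NULL
  if (config$mask_cpg) {
    masked_cat <- catalog[setdiff(names(catalog),
                                  c("CG", "WRCG", "YCG", "SNCG"))]
    if (length(masked_cat) > 0L) {
      enr_masked <- .stage("enrich-masked", enrich_catalog(
        mutations, masked_cat, mask_cpg = TRUE,
        mc_reps = config$mc_reps, seed = config$seed))
      write_results(enr_masked,
                    file.path(config$outdir, "enrichment_masked.tsv"))
    }
  }

  per_sample <- NULL
  if (config$per_sample) {
    per_sample <- .stage("per-sample", {
      samples <- unique(mutations$sample_id)
      rows <- lapply(samples, function(sm) {
        sub <- mutations[mutations$sample_id == sm, , drop = FALSE]
        r <- enrich_catalog(sub, catalog[intersect(c("WRC", "WRCG"),
                                                   names(catalog))],
                            mc_reps = config$mc_reps, seed = config$seed)
        cbind(sample_id = sm, r[setdiff(names(r), "bonferroni_flag")])
      })
      out <- do.call(rbind, rows)
      # family = motifs x samples
      out$bonferroni_flag <- bonferroni(out$fisher_p)
      out
    })
    write_results(per_sample,
                  file.path(config$outdir, "enrichment_per_sample.tsv"))
  }

  occ <- .stage("contrast", enumerate_cpg_occurrences(mutations))
  contrast <- .stage("contrast", contrast_test(occ, mutations))
  utils::write.table(
    data.frame(mutated_target = contrast$mutated_target,
               total_target = contrast$total_target,
               mutated_control = contrast$mutated_control,
               total_control = contrast$total_control,
               fraction_target = contrast$fraction_target,
               fraction_control = contrast$fraction_control,
               fisher_p = contrast$fisher_p),
    file.path(config$outdir, "contrast.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  meth <- NULL
  if (!is.null(methylation)) {
    meth <- .stage("methylation", methylation_association(
      methylation, reference, mutations, reps = config$sampling_reps,
      seed = config$seed))
    hm <- if (!is.null(meth$mutated)) meth$mutated else meth$all_sites
    if (!is.null(hm)) {
      comp <- data.frame(
        scope = c("mutated", "all_sites"),
        m1 = c(meth$mutated$m1 %||% NA, meth$all_sites$m1 %||% NA),
        m2 = c(meth$mutated$m2 %||% NA, meth$all_sites$m2 %||% NA),
        n1 = c(meth$mutated$n1 %||% NA, meth$all_sites$n1 %||% NA),
        n2 = c(meth$mutated$n2 %||% NA, meth$all_sites$n2 %||% NA),
        p_value = c(meth$mutated$p_value %||% NA,
                    meth$all_sites$p_value %||% NA))
      utils::write.table(comp, file.path(config$outdir,
                                         "methylation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(bin = colnames(hm$histogram),
                   wrcg = hm$histogram["group1", ],
                   control = hm$histogram["group2", ]),
        file.path(config$outdir, "methylation_histogram.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  cfg <- unclass(config)
  if (!is.null(config$truth)) {
    cfg$truth <- unclass(config$truth)
    cfg$truth$theta <- as.list(config$truth$theta)
  }
  jsonlite::write_json(cfg, file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(enrichment = enr, enrichment_masked = enr_masked,
                 per_sample = per_sample, contrast = contrast,
                 methylation = meth, spectrum = spectrum,
                 mutations = mutations))
}
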