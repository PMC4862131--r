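#' Pipeline run configuration
#'
#' Either real inputs (a pileup TSV plus reference FASTA) or a [sim_config()]
#' must be supplied, not neither.
#'
#' @param sim a [sim_config()] for a fully synthetic run, or NULL.
#' @param pileup_path,reference_path paths to real inputs (used when `sim` is
#'   NULL).
#' @param params a [caller_params()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used to override the
#'   sim seed when given.
#' @param annotation_path optional GFF3/BED for the genic-context stage.
#' @param fpkm_path optional expression table for the expression stage.
#' @param write_pileup also write the simulated pileup TSV (large; off by
#'   default).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, pileup_path = NULL, reference_path = NULL,
                       params = caller_params(), out_dir = "clonemut_out",
                       seed = NULL, annotation_path = NULL, fpkm_path = NULL,
                       write_pileup = FALSE) {
  if (is.null(sim) && (is.null(pileup_path) || is.null(reference_path))) {
    stop("either a sim_config or pileup_path + reference_path is required")
  }
  if (!is.null(sim) && !is.null(seed)) sim$seed <- seed
  structure(list(sim = sim, pileup_path = pileup_path,
                 reference_path = reference_path, params = params,
                 out_dir = out_dir,
                 seed = if (!is.null(seed)) seed else
                   if (!is.null(sim)) sim$seed else NA_integer_,
                 annotation_path = annotation_path, fpkm_path = fpkm_path,
                 write_pileup = write_pileup),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load), call, spectra, indel-context and rainfall
#' stages in order; writes a VCF of calls, TSV summaries and a JSON manifest
#' (inputs, parameters, seed, per-stage counts). Reruns with the same config
#' are byte-identical apart from file timestamps.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("expected a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, params = unclass(config$params),
                   stages = list())
  save_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  ## stage: inputs
  if (!is.null(config$sim)) {
    cohort <- run_stage("simulate", simulate_cohort(config$sim))
    reference <- cohort$reference
    pu <- cohort$pileup
    truth <- cohort$truth
    write_fasta(reference, file.path(config$out_dir, "reference.fa"))
    tr <- sort_mutations(truth$clone)
    write.table(tr, file.path(config$out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (config$write_pileup) {
      write_pileup_tsv(pu, file.path(config$out_dir, "pileup.tsv"))
    }
    manifest$stages$simulate <- list(
      status = "ok", n_truth = nrow(truth$clone),
      n_germline = nrow(truth$germline),
      genome_bp = sum(nchar(reference)))
  } else {
    reference <- run_stage("load", read_fasta(config$reference_path))
    pu <- run_stage("load", read_pileup_tsv(config$pileup_path))
    truth <- NULL
    manifest$stages$load <- list(status = "ok",
                                 n_positions = length(pu$pos))
  }

  ## stage: call
  calls <- run_stage("call",
                     call_unique_mutations(pu, config$params, reference))
  calls_sorted <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  write_vcf(calls_sorted[, c("sample_id", "chrom", "pos", "ref_allele",
                             "alt_allele", "mut_class")],
            reference, file.path(config$out_dir, "calls.vcf"))
  per_sample <- table(factor(calls$sample_id, levels = pu$samples))
  manifest$stages$call <- list(
    status = "ok", n_calls = nrow(calls),
    n_snv = sum(calls$mut_class == "SNV"),
    n_ins = sum(calls$mut_class == "INS"),
    n_del = sum(calls$mut_class == "DEL"),
    per_sample = as.list(per_sample))
  if (!is.null(truth)) {
    germ_key <- paste(truth$germline$chrom, truth$germline$pos)
    manifest$stages$call$n_calls_at_germline_sites <-
      sum(paste(calls$chrom, calls$pos) %in% germ_key)
  }

  ## stage: spectra
  snvs <- calls[calls$mut_class == "SNV", , drop = FALSE]
  spec <- run_stage("spectra", count_spectrum(snvs, reference))
  occ <- run_stage("spectra", triplet_occurrences(reference))
  rates <- normalize_rates(spec$spectrum96, occ)
  write.table(
    data.frame(channel = channel_labels(),
               count = as.numeric(spec$spectrum96),
               rate = as.numeric(rates)),
    file.path(config$out_dir, "spectrum.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest$stages$spectra <- list(
    status = "ok", n_classified = sum(spec$spectrum96),
    n_unassignable = spec$n_unassignable,
    six_class = as.list(spec$six_class))

  ## stage: indels + dinucleotides
  dn <- run_stage("indels", detect_dinucleotides(snvs))
  ins1 <- calls[calls$mut_class == "INS" & nchar(calls$alt_allele) == 1L, ,
                drop = FALSE]
  del1 <- calls[calls$mut_class == "DEL" & nchar(calls$ref_allele) == 1L, ,
                drop = FALSE]
  del2 <- calls[calls$mut_class == "DEL" & nchar(calls$ref_allele) == 2L, ,
                drop = FALSE]
  ins_ctx <- run_stage("indels", classify_insertion(reference, ins1))
  del_ctx <- run_stage("indels", classify_deletion(reference, del1))
  motif <- motif_overlap_two_base_deletions(reference, del2)
  rain <- intermutation_distances(
    snvs[order(snvs$sample_id, snvs$chrom, snvs$pos), , drop = FALSE])
  write.table(rain, file.path(config$out_dir, "rainfall.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cbind(ins1[, c("sample_id", "chrom", "pos")], ins_ctx),
              file.path(config$out_dir, "insertion_context.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(del1[, c("sample_id", "chrom", "pos")], del_ctx),
              file.path(config$out_dir, "deletion_context.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$indels <- list(
    status = "ok", n_dinucleotides = nrow(dn$dinucleotides),
    n_multi_runs = nrow(dn$multi_runs),
    n_ins1 = nrow(ins1), n_del1 = nrow(del1), n_del2 = nrow(del2),
    del2_motif_fraction = motif$fraction)

  ## optional stage: genic context
  if (!is.null(config$annotation_path)) {
    ann <- run_stage("context", read_annotation(
      config$annotation_path,
      seqlengths = setNames(nchar(reference), names(reference))))
    rt <- run_stage("context", assign_regions(snvs, ann))
    manifest$stages$context <- list(
      status = "ok",
      genome_fraction_genic = rt$genome_fraction_genic,
      observed_fraction_genic = rt$observed_fraction_genic,
      intergenic_enrichment = rt$intergenic_enrichment,
      chisq_p = rt$p_value)
  }

  save_manifest()
  invisible(manifest)
}
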