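#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run: design geometry, simulation
#' conditions, extraction tolerances and scoring thresholds. All randomness
#' flows from the single `seed`.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param n_enhancers Total library size (default 461).
#' @param barcodes_per_enhancer Barcodes per enhancer (default 20).
#' @param survival_prob Cloning survival probability (default 0.43).
#' @param animals Animal ids (default 3 animals).
#' @param tissues Tissue panel tibble (default [default_tissues()]); the
#'   simulated experiment samples every tissue in it for every animal.
#' @param dna_depth,rna_depth Expected reads per sample (default 2e5).
#' @param dispersion Negative-binomial size (default 10).
#' @param active_fold Activity fold of matched enhancer-tissue pairs.
#' @param error_rate Per-base read substitution rate (default 0.002).
#' @param read_length Amplicon read length (default 50).
#' @param pseudocount,dna_floor Activity-estimator settings.
#' @param detection_threshold Barcode detection cutoff (default 1).
#' @param fdr_level FDR level used when flagging significant tests.
#' @param mad_flag_level MAD-score level marking an enhancer as active
#'   (default 1.3).
#' @param design_params Extra arguments passed to [build_design()] (e.g.
#'   smaller category sizes for a quick run).
#' @return List of class `mpra_config`.
#' @export
mpra_config <- function(outdir, seed = 1, n_enhancers = 461,
                        barcodes_per_enhancer = 20, survival_prob = 0.43,
                        animals = c("m1", "m2", "m3"),
                        tissues = default_tissues(),
                        dna_depth = 2e5, rna_depth = 2e5, dispersion = 10,
                        active_fold = 10, error_rate = 0.002,
                        read_length = 50L, pseudocount = 1e-6, dna_floor = 1,
                        detection_threshold = 1, fdr_level = 0.05,
                        mad_flag_level = 1.3, design_params = list()) {
  structure(list(
    outdir = outdir, seed = as.integer(seed), n_enhancers = n_enhancers,
    barcodes_per_enhancer = barcodes_per_enhancer,
    survival_prob = survival_prob, animals = animals, tissues = tissues,
    dna_depth = dna_depth, rna_depth = rna_depth, dispersion = dispersion,
    active_fold = active_fold, error_rate = error_rate,
    read_length = as.integer(read_length), pseudocount = pseudocount,
    dna_floor = dna_floor, detection_threshold = detection_threshold,
    fdr_level = fdr_level, mad_flag_level = mad_flag_level,
    design_params = design_params
  ), class = "mpra_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the [mpra_config()] defaults;
#' unknown fields are an error.
#'
#' @param path YAML file path.
#' @param outdir,seed Optional overrides of the file's values.
#' @return An `mpra_config`.
#' @export
read_config_yaml <- function(path, outdir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  if (!is.null(seed)) raw$seed <- seed
  known <- names(formals(mpra_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(mpra_config, raw)
}

#' Run the full synthetic MPRA pipeline
#'
#' Executes every stage in order — library design, cloning-dropout and
#' count simulation, amplicon read emission, anchored barcode counting,
#' complexity metrics, activity estimation and scoring, aggregation, motif
#' disruption and allelic tests, cross-tissue correlations — and writes all
#' artifacts plus a run manifest (config hash, seed, per-stage record
#' counts) under `config$outdir`. Deterministic for a fixed config.
#'
#' @param config An [mpra_config()].
#' @return Invisible list with the main in-memory results (`design`,
#'   `complexity`, `activity`, `activity_tissue`, `disruption`, `allelic`,
#'   `correlation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mpra_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_msg <- function(...) message("[mprakit] ", ...)

  # --- design ---------------------------------------------------------
  log_msg("stage design")
  candidates <- do.call(build_design, c(
    list(seed = seed, total = config$n_enhancers), config$design_params))
  design <- assign_barcodes(candidates, k = config$barcodes_per_enhancer,
                            seed = derive_seed(seed, 2L))
  oligos <- assemble_oligo(design)
  write_design_tsv(design, file.path(out, "design.tsv"))
  write_oligo_fasta(oligos, file.path(out, "oligo_library.fasta"))

  # --- simulation -----------------------------------------------------
  log_msg("stage simulate")
  cloning <- simulate_cloning(design, config$survival_prob,
                              seed = derive_seed(seed, 3L))
  model <- expression_model(design, tissues = config$tissues,
                            active_fold = config$active_fold,
                            dispersion = config$dispersion,
                            dna_depth = config$dna_depth,
                            rna_depth = config$rna_depth)
  samples <- make_sample_sheet(config$animals, config$tissues$tissue)
  sim <- simulate_counts(cloning$surviving, model, samples,
                         seed = derive_seed(seed, 4L))
  template <- read_template(read_length = config$read_length)
  fq_dir <- file.path(out, "fastq")
  fq_dna <- emit_amplicon_reads(sim$dna, template, fq_dir,
                                error_rate = config$error_rate,
                                seed = derive_seed(seed, 5L))
  fq_rna <- emit_amplicon_reads(sim$rna, template, fq_dir,
                                error_rate = config$error_rate,
                                seed = derive_seed(seed, 6L))
  samples <- dplyr::left_join(samples, dplyr::bind_rows(fq_dna, fq_rna),
                              by = "sample_id")
  readr::write_tsv(samples, file.path(out, "sample_sheet.tsv"))
  readr::write_tsv(cloning$truth, file.path(out, "truth_cloning.tsv"))
  readr::write_tsv(sim$truth$alpha, file.path(out, "truth_alpha.tsv"))

  # --- counting -------------------------------------------------------
  log_msg("stage count")
  spec <- default_anchor_spec(template)
  counts <- count_barcodes(samples, spec, design$barcode)
  write_counts_tsv(counts$dna, file.path(out, "counts_dna.tsv"))
  write_counts_tsv(counts$rna, file.path(out, "counts_rna.tsv"))
  readr::write_tsv(counts$rejections, file.path(out, "read_rejections.tsv"))

  # --- complexity -----------------------------------------------------
  log_msg("stage complexity")
  complexity <- complexity_metrics(
    counts$dna, design, detection_threshold = config$detection_threshold)
  jsonlite::write_json(
    list(per_sample = complexity$per_sample,
         union_size = complexity$union_size,
         complexity = complexity$complexity,
         enhancer_coverage = complexity$enhancer_coverage,
         transduction_rate = complexity$transduction_rate,
         barcodes_per_enhancer = as.list(complexity$barcodes_per_enhancer)),
    file.path(out, "complexity.json"), auto_unbox = TRUE, digits = NA)

  # --- activity -------------------------------------------------------
  log_msg("stage activity")
  activity <- estimate_alpha(counts$rna, counts$dna, design, samples,
                             pseudocount = config$pseudocount,
                             dna_floor = config$dna_floor) |>
    score_activity(design)
  activity_tissue <- aggregate_activity(activity, design, "tissue",
                                        tissues = config$tissues)
  write_activity_tsv(activity, file.path(out, "activity_per_sample.tsv"))
  write_activity_tsv(activity_tissue, file.path(out, "activity_tissue.tsv"))

  # --- differential tests --------------------------------------------
  log_msg("stage test")
  brain_tissues <- config$tissues$tissue[config$tissues$tissue_type == "brain"]
  brain_samples <- unique(activity$sample[activity$tissue %in% brain_tissues])
  disruption <- motif_disruption_test(activity, design,
                                      sample_subset = brain_samples)
  non_liver <- unique(activity$sample[activity$tissue != "liver"])
  allelic <- allelic_test(activity, design, sample_subset = non_liver)
  readr::write_tsv(disruption, file.path(out, "test_motif_disruption.tsv"))
  readr::write_tsv(allelic, file.path(out, "test_allelic.tsv"))

  correlation <- cross_tissue_correlation(activity_tissue,
                                          group_col = "group")
  readr::write_tsv(
    tibble::as_tibble(correlation$rho, rownames = "group"),
    file.path(out, "correlation_tissue.tsv"))

  # --- manifest -------------------------------------------------------
  cfg_for_hash <- config
  cfg_for_hash$outdir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("mprakit")),
    seed = seed,
    config_hash = rlang::hash(cfg_for_hash),
    records = list(
      design_rows = nrow(design),
      surviving_barcodes = nrow(cloning$surviving),
      samples = nrow(samples),
      accepted_reads = sum(glance(counts$dna)$accepted) +
        sum(glance(counts$rna)$accepted),
      rejected_reads = sum(glance(counts$dna)$rejected) +
        sum(glance(counts$rna)$rejected),
      activity_rows = nrow(activity),
      disruption_units = nrow(disruption),
      allelic_units = nrow(allelic)
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("done: ", out)
  invisible(list(design = design, complexity = complexity,
                 activity = activity, activity_tissue = activity_tissue,
                 disruption = disruption, allelic = allelic,
                 correlation = correlation, manifest = manifest))
}
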