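#' Default tissue panel and per-tissue transduction
#'
#' The panel a systemic AAV screen samples: five brain regions, five
#' peripheral tissues and one cultured-cell pseudo-tissue. Transduction is
#' the fraction of library barcodes deliverable to a tissue; muscle and
#' heart are set markedly lower, reflecting the poor transduction of those
#' tissues by brain-penetrant AAV serotypes.
#'
#' @return Tibble with columns `tissue`, `tissue_type`, `transduction`.
#' @export
default_tissues <- function() {
  tibble::tibble(
    tissue = c("M1", "cortex", "striatum", "hippocampus", "hypothalamus",
               "liver", "kidney", "lung", "muscle", "heart", "HMC3"),
    tissue_type = c(rep("brain", 5), "liver", "other", "other", "other",
                    "other", "HMC3"),
    transduction = c(rep(0.95, 5), 0.95, 0.93, 0.93, 0.45, 0.45, 0.99)
  )
}

#' Simulate cloning dropout of a barcode library
#'
#' Each designed barcode survives the plasmid-cloning step independently with
#' probability `survival_prob` (default 0.43, i.e. 57% dropout). Enhancers
#' losing every barcode stay in the design with an empty barcode set, so
#' enhancer coverage can be measured downstream.
#'
#' @param design Design table (one row per enhancer-barcode pair).
#' @param survival_prob Per-barcode survival probability in (0, 1].
#' @param seed Integer seed.
#' @return List with `surviving` (design rows whose barcode survived),
#'   `truth` (the design plus a logical `survived` column) and
#'   `survival_prob`.
#' @export
#' @examples
#' design <- assign_barcodes(c("e1", "e2"), k = 5, seed = 1)
#' sim <- simulate_cloning(design, survival_prob = 0.43, seed = 1)
simulate_cloning <- function(design, survival_prob = 0.43, seed = 1) {
  stopifnot(survival_prob > 0, survival_prob <= 1)
  set.seed(derive_seed(seed, 11L))
  survived <- stats::rbinom(nrow(design), 1, survival_prob) == 1
  truth <- dplyr::mutate(design, survived = survived)
  list(
    surviving = dplyr::filter(truth, .data$survived) |>
      dplyr::select(-"survived"),
    truth = truth,
    survival_prob = survival_prob
  )
}

#' Build an expression model for the count simulator
#'
#' Assigns each (enhancer, tissue) pair a ground-truth transcription rate
#' `alpha_true`. Inactive pairs sit at the negative-control baseline
#' (`baseline_alpha`); pairs where the enhancer's class matches the tissue
#' are boosted by `active_fold`. Class rules: cross-tissue controls are
#' active everywhere; brain-class candidates (cortical, MEF2 baselines,
#' brain positives, SNP loci) in brain tissues; MEF2 baselines and SNP loci
#' additionally in the microglia-like cultured cells; liver/immune positives
#' in liver/HMC3; motif-shuffled, flank-shuffled and region-disrupt variants
#' fall back to baseline (disruption removes the effect); negatives and
#' placeholders are always at baseline. SNP alternative alleles get
#' `snp_alt_fold` times the reference activity in brain and cultured cells
#' (a gain-of-binding allele), matching activity in liver.
#'
#' @param design Design table or candidate tibble with `enhancer_id`,
#'   `category`, `target_tissue`, `variant_kind`.
#' @param tissues Tissue panel tibble (see [default_tissues()]).
#' @param baseline_alpha Null transcription rate (default 1).
#' @param active_fold Activity fold of a matched enhancer-tissue pair
#'   (default 10).
#' @param snp_alt_fold Fold change of alternative over reference alleles in
#'   responsive tissues (default 4).
#' @param dispersion Negative-binomial size parameter of the count model
#'   (default 10; smaller is noisier).
#' @param dna_depth,rna_depth Expected accepted reads per sample.
#' @return List of class `mpra_expression_model`.
#' @export
expression_model <- function(design, tissues = default_tissues(),
                             baseline_alpha = 1, active_fold = 10,
                             snp_alt_fold = 4, dispersion = 10,
                             dna_depth = 2e5, rna_depth = 2e5) {
  enh <- dplyr::distinct(design, .data$enhancer_id, .data$category,
                         .data$target_tissue, .data$variant_kind)
  grid <- tidyr::crossing(enh, tissue = tissues$tissue) |>
    dplyr::left_join(dplyr::select(tissues, "tissue", "tissue_type"),
                     by = "tissue")
  active <- with(grid,
    (category == "cross_tissue") |
    (target_tissue == "brain" & tissue_type == "brain" &
       variant_kind %in% c("baseline", "ref_allele", "alt_allele")) |
    (category %in% c("MEF2", "SNP") & tissue == "HMC3" &
       variant_kind %in% c("baseline", "ref_allele", "alt_allele")) |
    (target_tissue == "liver" & tissue_type == "liver") |
    (target_tissue == "immune" & tissue == "HMC3")
  )
  alpha <- ifelse(active, baseline_alpha * active_fold, baseline_alpha)
  is_alt <- grid$variant_kind == "alt_allele" & active
  alpha[is_alt] <- alpha[is_alt] * snp_alt_fold
  structure(list(
    alpha = dplyr::mutate(
      dplyr::select(grid, "enhancer_id", "tissue"), alpha_true = alpha),
    tissues = tissues,
    dispersion = dispersion,
    dna_depth = dna_depth,
    rna_depth = rna_depth,
    baseline_alpha = baseline_alpha
  ), class = "mpra_expression_model")
}

#' Build a sample sheet for a simulated experiment
#'
#' One DNA and one RNA sample per animal-tissue combination.
#'
#' @param animals Character vector of animal ids (the cultured-cell
#'   pseudo-tissue gets replicate ids instead).
#' @param tissues Character vector of tissue names.
#' @return Tibble with `sample_id`, `animal`, `tissue`, `molecule`.
#' @export
make_sample_sheet <- function(animals, tissues) {
  tidyr::crossing(animal = animals, tissue = tissues,
                  molecule = c("DNA", "RNA")) |>
    dplyr::mutate(sample_id = paste(.data$tissue, .data$animal,
                                    .data$molecule, sep = "_")) |>
    dplyr::select("sample_id", "animal", "tissue", "molecule")
}

#' Simulate DNA/RNA barcode count matrices
#'
#' For each animal-tissue pair a transduced barcode subset is drawn from the
#' surviving library with the tissue's transduction probability (shared by
#' the paired DNA and RNA samples of that animal). DNA counts are negative
#' binomial with mean `dna_depth / n_transduced` per transduced barcode; RNA
#' counts are negative binomial with mean proportional to the barcode's DNA
#' mean times the enhancer's `alpha_true` in that tissue, scaled by
#' `rna_depth / dna_depth`. Counts are independent across barcodes given
#' their means.
#'
#' @param surviving Design table of surviving barcodes (see
#'   [simulate_cloning()]).
#' @param model An [expression_model()].
#' @param samples Sample sheet (see [make_sample_sheet()]).
#' @param seed Integer seed.
#' @return List with `dna` and `rna` count tables (class `mpra_counts`: a
#'   tibble `barcode` x one column per sample, with a `tallies` attribute)
#'   and `truth` (list: per-sample transduced barcode sets, the alpha table,
#'   seed).
#' @export
simulate_counts <- function(surviving, model, samples, seed = 1) {
  unknown <- setdiff(samples$tissue, model$tissues$tissue)
  if (length(unknown)) {
    stop("sample sheet names tissues absent from the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(derive_seed(seed, 23L))
  barcodes <- surviving$barcode
  n_bc <- length(barcodes)
  alpha_lookup <- model$alpha
  units <- dplyr::distinct(samples, .data$animal, .data$tissue)
  transduced_sets <- list()

  dna_mat <- matrix(0L, nrow = n_bc, ncol = 0)
  rna_mat <- matrix(0L, nrow = n_bc, ncol = 0)
  dna_ids <- character(0); rna_ids <- character(0)

  for (u in seq_len(nrow(units))) {
    tis <- units$tissue[u]; ani <- units$animal[u]
    p_trans <- model$tissues$transduction[model$tissues$tissue == tis]
    trans <- stats::rbinom(n_bc, 1, p_trans) == 1
    transduced_sets[[paste(ani, tis, sep = "|")]] <- barcodes[trans]
    n_trans <- sum(trans)
    mu_dna <- ifelse(trans, if (n_trans > 0) model$dna_depth / n_trans else 0, 0)
    a <- dplyr::left_join(
      tibble::tibble(enhancer_id = surviving$enhancer_id, tissue = tis),
      alpha_lookup, by = c("enhancer_id", "tissue"))$alpha_true
    a[is.na(a)] <- model$baseline_alpha
    mu_rna <- mu_dna * a * (model$rna_depth / model$dna_depth)

    sub <- samples[samples$animal == ani & samples$tissue == tis, ]
    for (s in seq_len(nrow(sub))) {
      mu <- if (sub$molecule[s] == "DNA") mu_dna else mu_rna
      cnt <- integer(n_bc)
      nz <- mu > 0
      cnt[nz] <- stats::rnbinom(sum(nz), mu = mu[nz], size = model$dispersion)
      if (sub$molecule[s] == "DNA") {
        dna_mat <- cbind(dna_mat, cnt); dna_ids <- c(dna_ids, sub$sample_id[s])
      } else {
        rna_mat <- cbind(rna_mat, cnt); rna_ids <- c(rna_ids, sub$sample_id[s])
      }
    }
  }

  truth <- list(transduced = transduced_sets, alpha = alpha_lookup,
                surviving_barcodes = barcodes, seed = seed)
  list(
    dna = new_mpra_counts(barcodes, dna_mat, dna_ids, "DNA"),
    rna = new_mpra_counts(barcodes, rna_mat, rna_ids, "RNA"),
    truth = truth
  )
}

new_mpra_counts <- function(barcodes, mat, sample_ids, molecule,
                            tallies = NULL) {
  colnames(mat) <- sample_ids
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(barcode = barcodes), out)
  if (is.null(tallies)) {
    tallies <- tibble::tibble(
      sample_id = sample_ids,
      accepted = as.integer(colSums(mat)),
      rejected = 0L
    )
  }
  structure(out, molecule = molecule, tallies = tallies,
            class = c("mpra_counts", class(out)))
}

#' @export
print.mpra_counts <- function(x, ...) {
  cat("<mpra_counts> molecule:", attr(x, "molecule"),
      "|", nrow(x), "barcodes x", ncol(x) - 1L, "samples\n")
  NextMethod()
}

#' Tidy a count table into long form
#'
#' @param x An `mpra_counts` table.
#' @param ... Unused.
#' @return Long tibble with `barcode`, `sample_id`, `count`, `molecule`.
#' @export
tidy.mpra_counts <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"barcode",
                      names_to = "sample_id", values_to = "count") |>
    dplyr::mutate(molecule = attr(x, "molecule"))
}

#' Per-sample read tallies of a count table
#'
#' @param x An `mpra_counts` table.
#' @param ... Unused.
#' @return Tibble with per-sample accepted/rejected read totals.
#' @export
glance.mpra_counts <- function(x, ...) {
  attr(x, "tallies")
}

count_matrix <- function(x) {
  m <- as.matrix(tibble::as_tibble(x)[, -1, drop = FALSE])
  rownames(m) <- x$barcode
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV (barcodes x samples)
#'
#' @param counts `mpra_counts` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(tibble::as_tibble(counts), path)
  invisible(path)
}
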