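#' Estimate per-enhancer transcriptional activity (alpha)
#'
#' The raw transcriptional activity of an enhancer in a sample is the
#' library-size-normalised ratio of its RNA to its DNA barcode reads:
#' `alpha = (sum_b RNA_b / R + eps) / (sum_b DNA_b / D + eps)`, where the
#' sums run over the enhancer's barcodes with DNA count >= `dna_floor`, and
#' `R`, `D` are the accepted-read totals of the matched RNA/DNA samples.
#' RNA and DNA samples are paired by animal and tissue.
#'
#' @param rna,dna `mpra_counts` tables.
#' @param design Design table mapping barcodes to enhancers.
#' @param samples Sample sheet with `sample_id`, `animal`, `tissue`,
#'   `molecule` covering the count-table columns.
#' @param pseudocount Ratio stabiliser `eps` (default 1e-6, in normalised
#'   units).
#' @param dna_floor Barcodes with DNA count below this are excluded from
#'   both sums (default 1).
#' @return Activity tibble: one row per (enhancer, paired sample), columns
#'   `enhancer_id`, `sample` (the animal-tissue pair id), `animal`, `tissue`,
#'   `alpha`, `log_alpha`, `n_barcodes_used`.
#' @export
estimate_alpha <- function(rna, dna, design, samples, pseudocount = 1e-6,
                           dna_floor = 1) {
  stopifnot(pseudocount > 0)
  dna_mat <- count_matrix(dna)
  rna_mat <- count_matrix(rna)
  if (!identical(rownames(dna_mat), rownames(rna_mat))) {
    stop("DNA and RNA tables must share the same barcode whitelist",
         call. = FALSE)
  }
  dna_tot <- glance(dna); rna_tot <- glance(rna)

  meta <- dplyr::distinct(samples, .data$sample_id, .data$animal,
                          .data$tissue, .data$molecule)
  pairs <- dplyr::inner_join(
    meta |> dplyr::filter(.data$molecule == "DNA") |>
      dplyr::select(dna_sample = "sample_id", "animal", "tissue"),
    meta |> dplyr::filter(.data$molecule == "RNA") |>
      dplyr::select(rna_sample = "sample_id", "animal", "tissue"),
    by = c("animal", "tissue")
  )
  pairs <- pairs[pairs$dna_sample %in% colnames(dna_mat) &
                 pairs$rna_sample %in% colnames(rna_mat), ]
  if (nrow(pairs) == 0) {
    stop("no matched DNA/RNA sample pairs (same animal and tissue)",
         call. = FALSE)
  }

  enh_of <- design$enhancer_id[match(rownames(dna_mat), design$barcode)]
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ds <- pairs$dna_sample[i]; rs <- pairs$rna_sample[i]
    d <- dna_mat[, ds]; r <- rna_mat[, rs]
    D <- dna_tot$accepted[dna_tot$sample_id == ds]
    R <- rna_tot$accepted[rna_tot$sample_id == rs]
    if (D == 0 || R == 0) {
      D <- max(D, 1); R <- max(R, 1)
    }
    use <- d >= dna_floor & !is.na(enh_of)
    tibble::tibble(enhancer_id = enh_of[use],
                   d = d[use] / D, r = r[use] / R) |>
      dplyr::group_by(.data$enhancer_id) |>
      dplyr::summarise(
        alpha = (sum(.data$r) + pseudocount) / (sum(.data$d) + pseudocount),
        n_barcodes_used = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        sample = paste(pairs$tissue[i], pairs$animal[i], sep = "_"),
        animal = pairs$animal[i], tissue = pairs$tissue[i],
        log_alpha = log(.data$alpha))
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("enhancer_id", "sample", "animal", "tissue", "alpha",
                  "log_alpha", "n_barcodes_used")
}

#' Robust MAD score against a negative-control null
#'
#' Standardises log-activities against the negative-control population:
#' `(x - median(neg)) / (1.4826 * mad(neg))`. The 1.4826 factor makes the
#' median absolute deviation consistent with a standard deviation under
#' normality, so scores read as robust z-scores.
#'
#' @param log_alpha Numeric vector of log-activities to score.
#' @param neg_log_alpha Numeric vector of negative-control log-activities
#'   (>= 5 finite values required).
#' @return Numeric vector of MAD scores.
#' @export
mad_score <- function(log_alpha, neg_log_alpha) {
  neg <- neg_log_alpha[is.finite(neg_log_alpha)]
  if (length(neg) < 5) {
    stop("need at least 5 finite negative-control values", call. = FALSE)
  }
  s <- stats::mad(neg) # stats::mad already applies the 1.4826 constant
  if (s == 0) {
    stop("degenerate null: negative-control MAD is zero", call. = FALSE)
  }
  (log_alpha - stats::median(neg)) / s
}

#' One-sided empirical p-value against negative-control scores
#'
#' Add-one rank p-value: `p = (1 + #{neg >= score}) / (1 + N_neg)`. Warns
#' below 20 negative controls, where the p-value grid is coarse.
#'
#' @param score Numeric vector of scores to test.
#' @param neg_scores Negative-control scores forming the null.
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(score, neg_scores) {
  if (length(neg_scores) == 0) stop("empty null", call. = FALSE)
  if (length(neg_scores) < 20) {
    warning("fewer than 20 negative-control scores; empirical p-values are coarse")
  }
  vapply(score, function(s) {
    (1 + sum(neg_scores >= s)) / (1 + length(neg_scores))
  }, numeric(1))
}

#' Score an activity table against its negative controls
#'
#' Within each grouping unit (sample by default), computes MAD scores of all
#' enhancers against the negative-control log-activities of the same unit and
#' empirical p-values against the negative-control scores. Negative controls
#' are scored against the full negative set, themselves included.
#'
#' @param activity Activity tibble from [estimate_alpha()] (or an aggregated
#'   one); needs `enhancer_id`, `log_alpha` and the `group_col`.
#' @param design Design table (for category labels).
#' @param group_col Column defining the scoring unit (default `"sample"`).
#' @param neg_categories Categories forming the null population.
#' @return The activity tibble with `category`, `mad_score` and
#'   `p_empirical` columns added.
#' @export
score_activity <- function(activity, design, group_col = "sample",
                           neg_categories = c("negative_control",
                                              "random_negative")) {
  cats <- dplyr::distinct(design, .data$enhancer_id, .data$category)
  activity |>
    dplyr::left_join(cats, by = "enhancer_id") |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::group_modify(function(df, key) {
      neg <- df$log_alpha[df$category %in% neg_categories]
      df$mad_score <- mad_score(df$log_alpha, neg)
      neg_scores <- df$mad_score[df$category %in% neg_categories]
      df$p_empirical <- empirical_pvalue(df$mad_score, neg_scores)
      df
    }) |>
    dplyr::ungroup()
}

#' Aggregate per-sample activity across animals
#'
#' Collapses per-sample log-activities to tissue or tissue-type level by
#' averaging across animals, then rescoring (MAD score, empirical p) on the
#' aggregated values. Each enhancer also receives a `consistent` flag: TRUE
#' when its per-sample MAD scores agree in sign across all samples of the
#' group. Nothing is filtered — inconsistent enhancers are only flagged.
#'
#' @param activity Scored per-sample activity tibble (see
#'   [score_activity()]).
#' @param design Design table.
#' @param grouping `"tissue"` or `"tissue_type"`.
#' @param tissues Tissue panel mapping tissue to tissue_type (needed for
#'   `grouping = "tissue_type"`; default [default_tissues()]).
#' @param neg_categories Null categories, as in [score_activity()].
#' @return Aggregated, scored activity tibble with columns `enhancer_id`,
#'   `group`, `alpha`, `log_alpha`, `n_samples`, `mad_score`, `p_empirical`,
#'   `consistent`.
#' @export
aggregate_activity <- function(activity, design,
                               grouping = c("tissue", "tissue_type"),
                               tissues = default_tissues(),
                               neg_categories = c("negative_control",
                                                  "random_negative")) {
  grouping <- match.arg(grouping)
  df <- activity
  if (grouping == "tissue_type") {
    df <- dplyr::left_join(df, dplyr::select(tissues, "tissue",
                                             "tissue_type"), by = "tissue")
    if (anyNA(df$tissue_type)) stop("unknown tissue in activity table",
                                    call. = FALSE)
    df$group <- df$tissue_type
  } else {
    df$group <- df$tissue
  }
  has_scores <- "mad_score" %in% names(df)
  agg <- df |>
    dplyr::group_by(.data$enhancer_id, .data$group) |>
    dplyr::summarise(
      log_alpha = mean(.data$log_alpha),
      n_samples = dplyr::n(),
      consistent = if (has_scores) {
        all(.data$mad_score >= 0) || all(.data$mad_score <= 0)
      } else NA,
      .groups = "drop") |>
    dplyr::mutate(alpha = exp(.data$log_alpha))
  score_activity(agg, design, group_col = "group",
                 neg_categories = neg_categories) |>
    dplyr::select("enhancer_id", "group", "alpha", "log_alpha", "n_samples",
                  "category", "mad_score", "p_empirical", "consistent")
}

#' Write an activity table as TSV
#' @param activity Activity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_tsv <- function(activity, path) {
  readr::write_tsv(activity, path)
  invisible(path)
}
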