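#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

paired_t_rows <- function(pairs_df, unit_col = "unit") {
  # pairs_df: unit, sample, baseline, disrupted
  pairs_df |>
    dplyr::group_by(.data[[unit_col]]) |>
    dplyr::group_modify(function(df, key) {
      df <- df[stats::complete.cases(df[, c("baseline", "disrupted")]), ]
      n <- nrow(df)
      if (n < 2) {
        return(tibble::tibble(statistic = NA_real_, p_raw = NA_real_,
                              effect = NA_real_, n_pairs = n,
                              skipped = TRUE))
      }
      diffs <- df$baseline - df$disrupted
      if (stats::sd(diffs) == 0) {
        stat <- if (all(diffs == 0)) 0 else sign(mean(diffs)) * Inf
        p <- if (all(diffs == 0)) 1 else 0
      } else {
        tt <- stats::t.test(df$baseline, df$disrupted, paired = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      tibble::tibble(statistic = stat, p_raw = p, effect = mean(diffs),
                     n_pairs = n, skipped = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Motif-disruption paired tests
#'
#' For each baseline enhancer with shuffled-motif versions, pairs its
#' per-sample MAD score with the mean MAD score of its shuffled versions in
#' the same sample, and runs a paired t-test across samples. P-values are
#' Benjamini-Hochberg adjusted across all baselines tested. The effect is the
#' mean paired score difference (baseline minus disrupted), i.e. the degree
#' of disruption.
#'
#' @param activity Scored per-sample activity tibble (needs `enhancer_id`,
#'   `sample`, `mad_score`).
#' @param design Design table carrying the variant lineage (`variant_of`,
#'   `variant_kind`).
#' @param sample_subset Optional character vector of sample ids to use (e.g.
#'   the brain samples: primary motor cortex, other cortex, striatum).
#' @param variant_kinds Which variant kinds count as disrupted versions.
#' @return Tibble: `unit` (baseline enhancer id), `statistic`, `p_raw`,
#'   `p_adjusted`, `effect`, `n_pairs`, `skipped`. Units with fewer than two
#'   complete pairs are kept with `skipped = TRUE` and NA statistics.
#' @export
motif_disruption_test <- function(activity, design, sample_subset = NULL,
                                  variant_kinds = c("motif_shuffled",
                                                    "motif_flank_shuffled")) {
  lineage <- design |>
    dplyr::distinct(.data$enhancer_id, .data$variant_of,
                    .data$variant_kind) |>
    dplyr::filter(.data$variant_kind %in% variant_kinds,
                  !is.na(.data$variant_of))
  if (!is.null(sample_subset)) {
    activity <- dplyr::filter(activity, .data$sample %in% sample_subset)
  }
  base_scores <- activity |>
    dplyr::semi_join(tibble::tibble(enhancer_id = unique(lineage$variant_of)),
                     by = "enhancer_id") |>
    dplyr::select(unit = "enhancer_id", "sample", baseline = "mad_score")
  shuf_scores <- activity |>
    dplyr::inner_join(lineage, by = "enhancer_id") |>
    dplyr::group_by(unit = .data$variant_of, .data$sample) |>
    dplyr::summarise(disrupted = mean(.data$mad_score), .groups = "drop")
  pairs_df <- dplyr::inner_join(base_scores, shuf_scores,
                                by = c("unit", "sample"))
  res <- paired_t_rows(pairs_df)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  dplyr::relocate(res, "p_adjusted", .after = "p_raw")
}

#' Allelic (SNP) paired tests
#'
#' Pairs per-sample MAD scores of the reference allele with the alternative
#' allele (and, where present, with the region-disrupt version) of each SNP
#' locus and runs paired t-tests across samples, BH-adjusted within each
#' comparison family. Effects are signed ref minus alt (negative effect means
#' the alternative allele is more active: a gain-of-binding allele).
#'
#' @param activity Scored per-sample activity tibble.
#' @param design Design table with SNP lineage.
#' @param sample_subset Optional sample ids (the original analysis excluded
#'   liver tissue).
#' @return Tibble with `unit` (reference-allele enhancer id), `comparison`
#'   (`"ref_vs_alt"` or `"ref_vs_region_disrupt"`), `statistic`, `p_raw`,
#'   `p_adjusted`, `effect`, `n_pairs`, `skipped`.
#' @export
allelic_test <- function(activity, design, sample_subset = NULL) {
  if (!is.null(sample_subset)) {
    activity <- dplyr::filter(activity, .data$sample %in% sample_subset)
  }
  run_family <- function(kind, label) {
    lineage <- design |>
      dplyr::distinct(.data$enhancer_id, .data$variant_of,
                      .data$variant_kind) |>
      dplyr::filter(.data$variant_kind == kind, !is.na(.data$variant_of))
    if (nrow(lineage) == 0) return(NULL)
    ref <- activity |>
      dplyr::semi_join(tibble::tibble(enhancer_id = lineage$variant_of),
                       by = "enhancer_id") |>
      dplyr::select(unit = "enhancer_id", "sample", baseline = "mad_score")
    var <- activity |>
      dplyr::inner_join(lineage, by = "enhancer_id") |>
      dplyr::select(unit = "variant_of", "sample", disrupted = "mad_score")
    pairs_df <- dplyr::inner_join(ref, var, by = c("unit", "sample"))
    res <- paired_t_rows(pairs_df)
    res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
    res$comparison <- label
    res
  }
  dplyr::bind_rows(
    run_family("alt_allele", "ref_vs_alt"),
    run_family("region_disrupt", "ref_vs_region_disrupt")
  ) |>
    dplyr::relocate("comparison", .after = "unit") |>
    dplyr::relocate("p_adjusted", .after = "p_raw")
}

#' One-sided group activity test against negative controls
#'
#' Welch two-sample t-test that the mean score of an enhancer group exceeds
#' the negative-control mean.
#'
#' @param group_scores Numeric scores of the enhancer group (>= 2 values).
#' @param neg_scores Negative-control scores (>= 2 values).
#' @param alternative Test direction (default `"greater"`).
#' @return Tibble with `statistic`, `p_value`, `mean_group`, `mean_neg`,
#'   `n_group`, `n_neg`.
#' @export
group_activity_test <- function(group_scores, neg_scores,
                                alternative = "greater") {
  if (length(group_scores) < 2 || length(neg_scores) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(group_scores) == 0 && stats::sd(neg_scores) == 0) {
    stop("degenerate variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(group_scores, neg_scores, alternative = alternative,
                      var.equal = FALSE)
  tibble::tibble(
    statistic = unname(tt$statistic), p_value = tt$p.value,
    mean_group = mean(group_scores), mean_neg = mean(neg_scores),
    n_group = length(group_scores), n_neg = length(neg_scores)
  )
}

#' Pairwise cross-group Spearman correlation of enhancer activity
#'
#' Spearman's rho over paired enhancer alphas for every pair of groups
#' (tissues or samples); enhancers missing in either group are dropped
#' pairwise, and cells with fewer than `min_shared` shared enhancers are NA.
#'
#' @param activity Activity tibble with `enhancer_id`, a grouping column and
#'   `alpha`.
#' @param group_col Grouping column name (default `"tissue"`).
#' @param min_shared Minimum shared enhancers per pair (default 10).
#' @return List of class `mpra_correlation`: `rho` and `p` matrices (groups x
#'   groups, diagonal 1 / NA).
#' @export
cross_tissue_correlation <- function(activity, group_col = "tissue",
                                     min_shared = 10) {
  wide <- activity |>
    dplyr::select("enhancer_id", group = dplyr::all_of(group_col), "alpha") |>
    dplyr::group_by(.data$enhancer_id, .data$group) |>
    dplyr::summarise(alpha = mean(.data$alpha), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "alpha")
  groups <- setdiff(names(wide), "enhancer_id")
  k <- length(groups)
  rho <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  pmat <- rho
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- wide[[groups[i]]]; y <- wide[[groups[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_shared) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pmat, n_groups = k),
            class = "mpra_correlation")
}

#' @export
print.mpra_correlation <- function(x, ...) {
  cat("<mpra_correlation>", x$n_groups, "groups; Spearman rho:\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Tidy a correlation matrix into pair rows
#' @param x An `mpra_correlation`.
#' @param ... Unused.
#' @return Tibble with `group1`, `group2`, `rho`, `p` (upper triangle).
#' @export
tidy.mpra_correlation <- function(x, ...) {
  groups <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    group1 = groups[idx[, 1]], group2 = groups[idx[, 2]],
    rho = x$rho[idx], p = x$p[idx]
  )
}

#' Correlate measured activity with external open-chromatin predictions
#'
#' Averages forward- and reverse-strand predictor scores per enhancer, then
#' computes Spearman's rho between the averaged prediction and measured
#' alpha. Enhancers without a prediction (or without activity) are reported
#' and dropped.
#'
#' @param activity Activity tibble with `enhancer_id` and `alpha` (one row
#'   per enhancer; aggregate first if needed).
#' @param scores Tibble with `enhancer_id`, `score_fwd`, `score_rev`.
#' @return Tibble with `rho`, `p_value`, `n_used`, `n_dropped`.
#' @export
prediction_correlation <- function(activity, scores) {
  scores <- dplyr::mutate(scores,
                          score = (.data$score_fwd + .data$score_rev) / 2)
  merged <- dplyr::inner_join(
    dplyr::select(activity, "enhancer_id", "alpha"),
    dplyr::select(scores, "enhancer_id", "score"), by = "enhancer_id")
  n_dropped <- dplyr::n_distinct(activity$enhancer_id) +
    dplyr::n_distinct(scores$enhancer_id) -
    2 * dplyr::n_distinct(merged$enhancer_id)
  if (n_dropped > 0) {
    message(n_dropped, " enhancer id(s) unmatched between activity and ",
            "prediction tables; dropped")
  }
  ct <- suppressWarnings(
    stats::cor.test(merged$alpha, merged$score, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_used = nrow(merged), n_dropped = n_dropped)
}
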