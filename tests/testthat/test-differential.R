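test_that("motif disruption paired t matches the closed form", {
  # 4-sample worked vector
  base <- c(2.1, 1.7, 2.5, 1.9)
  shuf <- c(0.3, 0.6, 0.2, 0.5)
  x <- make_score_table("u1", paste0("s", 1:4), matrix(base, 1),
                        matrix(shuf, 1))
  res <- motif_disruption_test(x$activity, x$design)
  expect_equal(res$statistic, paired_t_by_hand(base, shuf))
  expect_equal(res$effect, mean(base - shuf))
  expect_equal(res$n_pairs, 4L)
  expect_equal(res$p_raw,
               t.test(base, shuf, paired = TRUE)$p.value)

  # identical scores in every sample -> t = 0, p = 1
  same <- make_score_table("u1", paste0("s", 1:4), matrix(base, 1),
                           matrix(base, 1))
  res0 <- motif_disruption_test(same$activity, same$design)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_raw, 1)

  # a unit with <2 complete pairs is kept but skipped
  x1 <- make_score_table("u1", "s1", matrix(1, 1), matrix(0, 1))
  res1 <- motif_disruption_test(x1$activity, x1$design)
  expect_true(res1$skipped)
  expect_true(is.na(res1$statistic))
})

test_that("disruption tests separate active from inactive baselines on simulation", {
  fx <- FIX
  res <- motif_disruption_test(fx$activity, fx$design,
                               sample_subset = brain_samples_of(fx))
  # shuffling removes a 10x activity effect: every MEF2 baseline (active in
  # brain) should be significantly disrupted at FDR 0.05
  expect_gte(mean(res$p_adjusted < 0.05, na.rm = TRUE), 0.75)
  expect_true(all(res$effect > 0, na.rm = TRUE))

  # null calibration: no disruption effect -> <= 7% raw-p discoveries
  set.seed(77)
  n_units <- 8; n_samp <- 9
  hits <- replicate(200, {
    b <- matrix(rnorm(n_units * n_samp), n_units)
    d <- matrix(rnorm(n_units * n_samp), n_units)
    x <- make_score_table(paste0("u", 1:n_units),
                          paste0("s", 1:n_samp), b, d)
    r <- motif_disruption_test(x$activity, x$design)
    r$p_raw < 0.05
  })
  expect_lte(mean(hits), 0.07)
})

test_that("allelic tests are sign-symmetric and match the closed form", {
  ref <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  alt <- c(2.2, 2.1, 2.8, 2.5, 1.9)
  units <- "snp_01_ref"
  design <- tibble::tibble(
    enhancer_id = c("snp_01_ref", "snp_01_alt"),
    sequence = NA_character_, category = "SNP", target_tissue = "brain",
    variant_of = c(NA_character_, "snp_01_ref"),
    variant_kind = c("ref_allele", "alt_allele"),
    barcode = NA_character_
  )
  act <- tibble::tibble(
    enhancer_id = rep(c("snp_01_ref", "snp_01_alt"), each = 5),
    sample = rep(paste0("s", 1:5), 2),
    mad_score = c(ref, alt)
  )
  res <- allelic_test(act, design)
  expect_equal(res$comparison, "ref_vs_alt")
  expect_equal(res$statistic, paired_t_by_hand(ref, alt))
  expect_equal(res$effect, mean(ref - alt)) # negative: gain-of-binding
  expect_lt(res$effect, 0)

  # swapping ref/alt labels flips the effect sign, p unchanged
  design_sw <- design
  design_sw$enhancer_id <- c("snp_01_alt", "snp_01_ref")
  design_sw$variant_of <- c(NA_character_, "snp_01_alt")
  res_sw <- allelic_test(act, design_sw)
  expect_equal(res_sw$effect, -res$effect)
  expect_equal(res_sw$p_raw, res$p_raw)
})

test_that("a gain-of-function allele is detected in brain but not liver", {
  fx <- FIX
  non_liver <- unique(fx$activity$sample[fx$activity$tissue != "liver"])
  liver_only <- unique(fx$activity$sample[fx$activity$tissue == "liver"])
  res_brain <- allelic_test(fx$activity, fx$design,
                            sample_subset = non_liver) |>
    dplyr::filter(comparison == "ref_vs_alt")
  res_liver <- allelic_test(fx$activity, fx$design,
                            sample_subset = liver_only) |>
    dplyr::filter(comparison == "ref_vs_alt")
  # alt alleles are 4x ref in brain/HMC3, equal in liver
  expect_gte(mean(res_brain$p_adjusted < 0.05, na.rm = TRUE), 0.5)
  expect_true(all(res_brain$effect < 0, na.rm = TRUE))
  expect_lte(mean(res_liver$p_raw < 0.05, na.rm = TRUE), 0.35)

  # region-disrupt family is present and reduces activity (positive effect)
  res_rd <- allelic_test(fx$activity, fx$design,
                         sample_subset = non_liver) |>
    dplyr::filter(comparison == "ref_vs_region_disrupt")
  expect_gt(nrow(res_rd), 0)
  expect_gt(mean(res_rd$effect > 0, na.rm = TRUE), 0.5)
})

test_that("group activity test is a one-sided Welch t with calibrated null", {
  set.seed(15)
  neg <- rnorm(20)
  shifted <- rnorm(20) + 3
  res <- group_activity_test(shifted, neg)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value,
               t.test(shifted, neg, alternative = "greater")$p.value)

  # null: p approximately uniform over replicates
  ps <- replicate(200, group_activity_test(rnorm(20), rnorm(20))$p_value)
  expect_lte(mean(ps < 0.05), 0.1)
  expect_gt(mean(ps), 0.4)

  expect_error(group_activity_test(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(group_activity_test(1, rnorm(5)), "at least 2")
})

test_that("liver-class controls test significant in liver but not brain", {
  agg <- aggregate_activity(FIX$activity, FIX$design, "tissue",
                            tissues = FIX$tissues)
  neg_scores <- function(tis) {
    dplyr::filter(agg, group == tis,
                  category %in% c("negative_control",
                                  "random_negative"))$mad_score
  }
  liver_grp <- dplyr::filter(agg, group == "liver",
                             grepl("posLiver", enhancer_id))$mad_score
  brain_grp <- dplyr::filter(agg, group == "cortex",
                             grepl("posLiver", enhancer_id))$mad_score
  expect_lt(group_activity_test(liver_grp, neg_scores("liver"))$p_value,
            0.05)
  expect_gt(group_activity_test(brain_grp, neg_scores("cortex"))$p_value,
            0.05)
})

test_that("cross-tissue Spearman matrices match a rank-transform oracle", {
  # identical activity vectors -> rho 1
  act <- tidyr::crossing(enhancer_id = paste0("e", 1:12),
                         tissue = c("t1", "t2"))
  set.seed(16)
  vals <- c(rnorm(10), 1.5, 1.5) # ties included
  act$alpha <- rep(vals, each = 2)
  cm <- cross_tissue_correlation(act, min_shared = 10)
  expect_equal(unname(cm$rho["t1", "t2"]), 1)
  expect_equal(diag(cm$rho), c(t1 = 1, t2 = 1))

  # worked 12-enhancer vectors with ties: rank-then-Pearson oracle
  act2 <- act
  y <- c(rnorm(9), 2, 2, 2)
  act2$alpha[act2$tissue == "t2"] <- y
  cm2 <- cross_tissue_correlation(act2, min_shared = 10)
  oracle <- cor(rank(vals), rank(y))
  expect_equal(unname(cm2$rho["t1", "t2"]), oracle, tolerance = 1e-12)
  expect_true(isSymmetric(cm2$rho))

  # too few shared enhancers -> NA cell
  cm3 <- cross_tissue_correlation(act2, min_shared = 13)
  expect_true(is.na(cm3$rho["t1", "t2"]))

  # on the simulated experiment brain-brain pairs beat brain-liver pairs
  agg <- aggregate_activity(FIX$activity, FIX$design, "tissue",
                            tissues = FIX$tissues)
  cm4 <- cross_tissue_correlation(agg, group_col = "group")
  expect_gt(cm4$rho["cortex", "M1"], cm4$rho["cortex", "liver"])

  td <- tidy(cm4)
  expect_equal(nrow(td), choose(nrow(cm4$rho), 2))
})

test_that("prediction correlation averages strands before Spearman", {
  agg <- aggregate_activity(FIX$activity, FIX$design, "tissue",
                            tissues = FIX$tissues) |>
    dplyr::filter(group == "cortex")
  # scores equal to alpha -> rho 1 (asymmetric fwd/rev around alpha)
  scores <- tibble::tibble(enhancer_id = agg$enhancer_id,
                           score_fwd = agg$alpha + 0.1,
                           score_rev = agg$alpha - 0.1)
  res <- prediction_correlation(agg, scores)
  expect_equal(res$rho, 1)
  expect_equal(res$n_dropped, 0)

  # monotone transform of truth beats shuffled scores by a wide margin
  truth <- dplyr::inner_join(
    dplyr::distinct(agg, enhancer_id),
    dplyr::filter(FIX$model$alpha, tissue == "cortex"),
    by = "enhancer_id")
  mono <- tibble::tibble(enhancer_id = truth$enhancer_id,
                         score_fwd = log1p(truth$alpha_true),
                         score_rev = log1p(truth$alpha_true))
  set.seed(17)
  shuf <- dplyr::mutate(mono,
                        score_fwd = sample(score_fwd),
                        score_rev = score_fwd)
  rho_mono <- prediction_correlation(agg, mono)$rho
  rho_shuf <- prediction_correlation(agg, shuf)$rho
  expect_gt(rho_mono - rho_shuf, 0.3)

  # unmatched ids are reported and dropped
  extra <- dplyr::bind_rows(
    scores, tibble::tibble(enhancer_id = "ghost", score_fwd = 1,
                           score_rev = 1))
  expect_message(res2 <- prediction_correlation(agg, extra), "unmatched")
  expect_equal(res2$n_used, nrow(agg))
})

test_that("BH adjustment is monotone within each test family", {
  res <- motif_disruption_test(FIX$activity, FIX$design,
                               sample_subset = brain_samples_of(FIX))
  ok <- !is.na(res$p_raw)
  expect_true(all(res$p_adjusted[ok] >= res$p_raw[ok]))
  o <- order(res$p_raw[ok])
  expect_true(all(diff(res$p_adjusted[ok][o]) >= -1e-15))
  expect_equal(res$p_adjusted[ok], p.adjust(res$p_raw[ok], "BH"))
})
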