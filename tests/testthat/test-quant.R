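make_reads <- function(barcodes, template = read_template()) {
  paste0(template$prefix, barcodes, template$suffix)
}

test_that("anchored extraction enforces the quality rule and resolves barcodes", {
  template <- read_template()
  spec <- default_anchor_spec(template)
  wl <- FIX$design$barcode[1:50]
  reads <- make_reads(wl, template)

  # noiseless round trip
  res <- extract_barcode(reads, spec, wl)
  expect_identical(res$barcode, wl)

  # one substitution inside the anchor at zero tolerance -> anchor_fail
  r <- reads[1]
  pos <- spec$anchor_offset
  substr(r, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, pos, pos))[1]
  expect_equal(extract_barcode(r, spec, wl)$reason, "anchor_fail")

  # substitution in the adjacent bases -> flank_fail
  r <- reads[1]
  fpos <- spec$barcode_offset - 1L
  substr(r, fpos, fpos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r, fpos, fpos))[1]
  expect_equal(extract_barcode(r, spec, wl)$reason, "flank_fail")

  # substitution in the barcode at zero tolerance -> barcode_unmatched
  r <- reads[1]
  bpos <- spec$barcode_offset + 3L
  substr(r, bpos, bpos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r, bpos, bpos))[1]
  expect_equal(extract_barcode(r, spec, wl)$reason, "barcode_unmatched")

  # short read -> too_short, not an exception
  expect_equal(extract_barcode("ACGT", spec, wl)$reason, "too_short")
})

test_that("one-mismatch barcode rescue is unique on a min-Hamming-3 whitelist", {
  template <- read_template()
  tol <- default_anchor_spec(template, max_barcode_mismatches = 1L)
  wl <- FIX$design$barcode[1:60]
  set.seed(8)
  # mutate one barcode base in each read
  mutated <- vapply(wl, function(bc) {
    p <- sample.int(16, 1)
    substr(bc, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substr(bc, p, p)), 1)
    bc
  }, character(1), USE.NAMES = FALSE)
  res <- extract_barcode(make_reads(mutated, template), tol, wl)
  expect_true(all(res$reason == "accepted"))
  expect_identical(res$barcode, wl)

  # brute-force nearest-neighbour oracle agrees
  for (i in seq_along(mutated)) {
    d <- vapply(wl, brute_hamming, integer(1), a = mutated[i],
                USE.NAMES = FALSE)
    expect_equal(wl[which.min(d)], res$barcode[i])
    expect_equal(sum(d <= 1), 1)
  }
})

test_that("anchored extraction agrees with a sliding-window anchor scan", {
  template <- read_template()
  spec <- default_anchor_spec(template)
  wl <- FIX$design$barcode
  set.seed(9)
  n <- 1000
  # half true reads with substitution noise, half random junk
  true_reads <- make_reads(sample(wl, n / 2, replace = TRUE), template)
  true_reads <- mprakit:::add_substitution_errors(true_reads, 0.02)
  junk <- vapply(seq_len(n / 2), function(i) {
    paste0(sample(c("A", "C", "G", "T"), template$read_length,
                  replace = TRUE), collapse = "")
  }, character(1))
  reads <- c(true_reads, junk)
  res <- extract_barcode(reads, spec, wl)

  # oracle: scan for the anchor anywhere, require it at the designed offset,
  # exact flanks, exact whitelist membership
  flank_l <- spec$flank_left; flank_r <- spec$flank_right
  oracle <- vapply(reads, function(r) {
    hit <- regexpr(spec$anchor_sequence, r, fixed = TRUE)
    if (hit != spec$anchor_offset) return(NA_character_)
    if (substr(r, spec$barcode_offset - nchar(flank_l),
               spec$barcode_offset - 1) != flank_l) return(NA_character_)
    if (substr(r, spec$barcode_offset + 16,
               spec$barcode_offset + 15 + nchar(flank_r)) != flank_r) {
      return(NA_character_)
    }
    bc <- substr(r, spec$barcode_offset, spec$barcode_offset + 15)
    if (bc %in% wl) bc else NA_character_
  }, character(1), USE.NAMES = FALSE)
  # the scan finding the anchor elsewhere (or not at all) must match a
  # rejection; agreement on accepted assignments must be exact
  expect_identical(res$barcode, oracle)
})

test_that("counting conserves reads and matches simulated counts losslessly", {
  surv <- FIX$cloning$surviving
  flat <- expression_model(FIX$design, tissues = FIX$tissues,
                           active_fold = 2, dna_depth = 2e4, rna_depth = 2e4)
  sheet <- make_sample_sheet(c("m1", "m2"), "cortex")
  sim <- simulate_counts(surv, flat, sheet, seed = 51)
  template <- read_template()
  dir <- withr::local_tempdir()
  fq <- dplyr::bind_rows(
    emit_amplicon_reads(sim$dna, template, dir, error_rate = 0, seed = 1),
    emit_amplicon_reads(sim$rna, template, dir, error_rate = 0, seed = 2))
  sheet <- dplyr::left_join(sheet, fq, by = "sample_id")
  spec <- default_anchor_spec(template)

  out <- count_barcodes(sheet, spec, FIX$design$barcode)
  surv_idx <- FIX$design$barcode %in% surv$barcode
  expect_identical(mprakit:::count_matrix(out$dna)[surv_idx, ],
                   mprakit:::count_matrix(sim$dna))
  expect_identical(mprakit:::count_matrix(out$rna)[surv_idx, ],
                   mprakit:::count_matrix(sim$rna))
  expect_true(all(mprakit:::count_matrix(out$dna)[!surv_idx, ] == 0))

  # per-sample conservation: accepted + rejected = emitted reads
  tall <- dplyr::bind_rows(glance(out$dna), glance(out$rna))
  emitted <- vapply(sheet$fastq_path,
                    function(p) length(readLines(p)) / 4, numeric(1))
  expect_equal(tall$accepted + tall$rejected,
               unname(emitted[match(tall$sample_id, sheet$sample_id)]))

  # empty FASTQ -> all-zero column, zero accepted
  empty_path <- file.path(dir, "empty.fastq")
  file.create(empty_path)
  esheet <- tibble::tibble(sample_id = "empty", animal = "m9",
                           tissue = "cortex", molecule = "DNA",
                           fastq_path = empty_path)
  eout <- count_barcodes(esheet, spec, FIX$design$barcode)
  expect_true(all(mprakit:::count_matrix(eout$dna) == 0))
  expect_equal(glance(eout$dna)$accepted, 0L)

  esheet$fastq_path <- file.path(dir, "missing.fastq")
  expect_error(count_barcodes(esheet, spec, FIX$design$barcode),
               "missing.fastq")
})

test_that("noisy-channel acceptance matches the Bernoulli product rate", {
  surv <- FIX$cloning$surviving
  flat <- expression_model(FIX$design, tissues = FIX$tissues,
                           active_fold = 1, snp_alt_fold = 1,
                           dna_depth = 4e4, rna_depth = 4e4)
  sheet <- make_sample_sheet("m1", "M1")[1, ]
  sim <- simulate_counts(surv, flat, sheet, seed = 61)
  template <- read_template()
  dir <- withr::local_tempdir()
  e <- 0.01
  fq <- emit_amplicon_reads(sim$dna, template, dir, error_rate = e, seed = 3)
  sheet <- dplyr::left_join(sheet, fq, by = "sample_id")
  spec <- default_anchor_spec(template)
  out <- count_barcodes(sheet, spec, FIX$design$barcode)

  # a read passes iff anchor (8), both flanks (3+3) and barcode (16) are all
  # error-free: (1-e)^30; one-mismatch whitelist rescue is off by default
  span <- nchar(spec$anchor_sequence) + nchar(spec$flank_left) +
    nchar(spec$flank_right) + 16
  p_acc <- (1 - e)^span
  tall <- glance(out$dna)
  n <- tall$accepted + tall$rejected
  expect_lt(abs(tall$accepted / n - p_acc),
            3 * sqrt(p_acc * (1 - p_acc) / n))
})

test_that("complexity metrics match set oracles and are threshold-monotone", {
  design <- FIX$design
  surv_bc <- FIX$cloning$surviving$barcode
  counts <- plasmid_library_counts(surv_bc, design$barcode)
  rep <- complexity_metrics(counts, design)
  expect_equal(rep$union_size, length(surv_bc))
  expect_equal(rep$complexity, length(surv_bc) / nrow(design))
  expect_true(all(rep$per_enhancer$n_detected >= 0 &
                    rep$per_enhancer$n_detected <= 8))

  # brute-force union oracle on a multi-sample matrix
  dna <- FIX$sim$dna
  rep2 <- complexity_metrics(dna, design)
  mat <- mprakit:::count_matrix(dna)
  union_brute <- sum(apply(mat >= 1, 1, any))
  expect_equal(rep2$union_size, union_brute)

  # monotonicity: raising the detection threshold never raises proportions
  # or coverage
  rep5 <- complexity_metrics(dna, design, detection_threshold = 5)
  expect_true(all(rep5$per_sample$detected <= rep2$per_sample$detected))
  expect_lte(rep5$enhancer_coverage, rep2$enhancer_coverage)
  expect_lte(rep5$union_size, rep2$union_size)

  # degenerate inputs
  zero <- plasmid_library_counts(character(0), design$barcode)
  rep0 <- complexity_metrics(zero, design)
  expect_equal(rep0$enhancer_coverage, 0)
  expect_equal(rep0$transduction_rate, 0)
  expect_error(complexity_metrics(counts, design[0, ]), "empty")

  # tidiers give the per-sample and global views
  expect_equal(nrow(tidy(rep2)), ncol(mat))
  expect_equal(glance(rep2)$union_size, union_brute)
})
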