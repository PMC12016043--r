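# Shared desk-scale fixture: a compact library with every category, simulated
# through cloning + counts once and reused across test files. Strong effects
# (active_fold = 10) so directional checks have power at small depth.

fixture_tissues <- function() {
  dplyr::filter(default_tissues(),
                tissue %in% c("M1", "cortex", "striatum", "liver", "HMC3"))
}

make_fixture <- function(seed = 42, active_fold = 10) {
  candidates <- build_design(seed = seed, n_cortical = 20, n_mef2 = 8,
                             n_snp = 6, n_region_disrupt = 3, total = 140)
  design <- assign_barcodes(candidates, k = 8, seed = seed + 1)
  cloning <- simulate_cloning(design, survival_prob = 0.9, seed = seed + 2)
  tissues <- fixture_tissues()
  model <- expression_model(design, tissues = tissues,
                            active_fold = active_fold,
                            dna_depth = 5e4, rna_depth = 5e4)
  samples <- make_sample_sheet(c("m1", "m2", "m3"), tissues$tissue)
  sim <- simulate_counts(cloning$surviving, model, samples, seed = seed + 3)
  activity <- estimate_alpha(sim$rna, sim$dna, design, samples) |>
    score_activity(design)
  list(candidates = candidates, design = design, cloning = cloning,
       tissues = tissues, model = model, samples = samples, sim = sim,
       activity = activity)
}

# computed once when helpers are sourced; ~2 s
FIX <- make_fixture()

brain_samples_of <- function(fx) {
  brain <- fx$tissues$tissue[fx$tissues$tissue_type == "brain"]
  unique(fx$activity$sample[fx$activity$tissue %in% brain])
}

# independent brute-force oracles -------------------------------------------

brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

brute_min_pairwise_hamming <- function(barcodes) {
  n <- length(barcodes)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- min(best, brute_hamming(barcodes[i], barcodes[j]))
    }
  }
  best
}

brute_gc <- function(s) {
  sum(strsplit(s, "")[[1]] %in% c("G", "C"))
}

paired_t_by_hand <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}

# distinct-by-construction barcodes: index written in base 4
indexed_barcodes <- function(n, len = 16) {
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len)
    for (p in seq_len(len)) {
      digits[p] <- i %% 4L
      i <- i %/% 4L
    }
    paste0(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

# scored activity table plus design lineage for paired tests:
# baseline/disrupted are matrices units x samples
make_score_table <- function(units, samples, baseline, disrupted,
                             kind = "motif_shuffled") {
  design <- tibble::tibble(
    enhancer_id = c(units, paste0(units, "_shuf")),
    sequence = NA_character_, category = "MEF2", target_tissue = "brain",
    variant_of = c(rep(NA_character_, length(units)), units),
    variant_kind = c(rep("baseline", length(units)),
                     rep(kind, length(units))),
    barcode = NA_character_
  )
  act <- dplyr::bind_rows(
    tidyr::crossing(enhancer_id = units, sample = samples),
    tidyr::crossing(enhancer_id = paste0(units, "_shuf"), sample = samples)
  )
  act$mad_score <- c(as.vector(t(baseline)), as.vector(t(disrupted)))
  list(design = design, activity = act)
}

small_config <- function(outdir, seed = 3) {
  mpra_config(
    outdir = outdir, seed = seed, n_enhancers = 120,
    barcodes_per_enhancer = 4, survival_prob = 0.9,
    animals = c("m1", "m2"), tissues = fixture_tissues(),
    dna_depth = 1e4, rna_depth = 1e4, error_rate = 0.002,
    design_params = list(n_cortical = 10, n_mef2 = 4, n_snp = 4,
                         n_region_disrupt = 2)
  )
}
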