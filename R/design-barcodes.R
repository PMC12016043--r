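#' Default oligo scaffold parts
#'
#' Fixed sequences shared by every library member: 5'/3' cloning adapters and
#' the 27-nt linker separating the enhancer from its 16-nt barcode. The
#' linker carries the restriction-enzyme site (`GGCGCGCC`) that downstream
#' barcode extraction anchors on; barcodes are generated to exclude this
#' motif so anchor matching is unambiguous.
#'
#' @return Named list with `adapter5`, `linker`, `adapter3`, `anchor` and
#'   `anchor_in_linker` (1-based offset of the anchor within the linker).
#' @export
oligo_parts <- function() {
  list(
    adapter5 = "AGGACCGGATCAACTCGAGT",
    linker   = "TCTAGAGGCGCGCCTAGTCGACTGCAG",
    adapter3 = "GGTACCAAGCTTGATATCGA",
    anchor   = "GGCGCGCC",
    anchor_in_linker = 7L
  )
}

#' Assign unique barcodes to enhancers
#'
#' Draws `k` barcodes per enhancer subject to three constraints: global
#' uniqueness, pairwise Hamming distance >= `min_hamming` (so a
#' mismatch-tolerant extraction can never mis-assign a read), and exclusion
#' of the anchor restriction-site sequence from every barcode. Candidates are
#' rejection-sampled; the distance constraint is enforced with a pigeonhole
#' chunk index (a 16-mer pair at Hamming distance < 3 must agree on one of
#' three chunks), which keeps assignment near-linear in the number of
#' barcodes.
#'
#' @param enhancers Tibble of enhancer candidates (needs `enhancer_id`; other
#'   columns are carried through), or a character vector of enhancer ids.
#' @param k Barcodes per enhancer (default 20).
#' @param barcode_length Barcode length in nt (default 16).
#' @param min_hamming Minimum pairwise Hamming distance between any two
#'   barcodes (default 3).
#' @param seed Integer seed; the table is deterministic per seed.
#' @param exclude Character vector of motifs no barcode may contain
#'   (default: the anchor restriction site).
#' @return A design table: one row per enhancer-barcode pair, with all
#'   enhancer columns plus `barcode`.
#' @export
#' @examples
#' assign_barcodes(c("enhA", "enhB"), k = 3, seed = 1)
assign_barcodes <- function(enhancers, k = 20, barcode_length = 16,
                            min_hamming = 3, seed = 1,
                            exclude = oligo_parts()$anchor) {
  if (is.character(enhancers)) {
    enhancers <- tibble::tibble(
      enhancer_id = enhancers, sequence = NA_character_,
      category = NA_character_, target_tissue = NA_character_,
      variant_of = NA_character_, variant_kind = NA_character_
    )
  }
  stopifnot(k >= 1, min_hamming >= 1)
  n_needed <- k * nrow(enhancers)
  if (4^barcode_length < 20 * n_needed) {
    stop("barcode space too small for ", n_needed, " barcodes", call. = FALSE)
  }
  set.seed(seed)

  # chunk boundaries for pigeonhole screening (only exact for min_hamming<=3;
  # for larger min_hamming every accepted barcode is checked exhaustively)
  n_chunks <- 3L
  cuts <- round(seq(0, barcode_length, length.out = n_chunks + 1))
  chunk_keys <- function(bc) {
    vapply(seq_len(n_chunks), function(i) {
      paste0(i, ":", substr(bc, cuts[i] + 1L, cuts[i + 1L]))
    }, character(1))
  }

  accepted <- character(n_needed)
  n_acc <- 0L
  index <- new.env(hash = TRUE, parent = emptyenv())
  seen <- new.env(hash = TRUE, parent = emptyenv())
  brute <- min_hamming > 3
  max_rounds <- 60L
  round_i <- 0L
  while (n_acc < n_needed) {
    round_i <- round_i + 1L
    if (round_i > max_rounds) {
      stop("barcode capacity error: constraints unsatisfiable after ",
           max_rounds, " sampling rounds", call. = FALSE)
    }
    batch <- random_dna(max(2L * (n_needed - n_acc), 1000L), barcode_length)
    for (motif in exclude) batch <- batch[!grepl(motif, batch, fixed = TRUE)]
    for (bc in batch) {
      if (n_acc >= n_needed) break
      if (!is.null(seen[[bc]])) next
      seen[[bc]] <- TRUE
      if (brute) {
        cand_idx <- seq_len(n_acc)
      } else {
        cand_idx <- unique(unlist(lapply(chunk_keys(bc), function(key) {
          index[[key]]
        })))
      }
      ok <- TRUE
      if (length(cand_idx)) {
        d <- hamming(rep(bc, length(cand_idx)), accepted[cand_idx])
        ok <- all(d >= min_hamming)
      }
      if (ok) {
        n_acc <- n_acc + 1L
        accepted[n_acc] <- bc
        for (key in chunk_keys(bc)) index[[key]] <- c(index[[key]], n_acc)
      }
    }
  }

  out <- enhancers[rep(seq_len(nrow(enhancers)), each = k), , drop = FALSE]
  out$barcode <- accepted
  tibble::as_tibble(out)
}

#' Assemble reporter oligos from enhancers and barcodes
#'
#' Concatenates the fixed scaffold around each enhancer-barcode pair:
#' `adapter5 | enhancer | linker(27 nt) | barcode(16 nt) | adapter3`. The
#' fixed part lengths make the decomposition unique, which is what the
#' anchored barcode extraction relies on.
#'
#' @param design Design table (one row per enhancer-barcode pair, with
#'   `sequence` and `barcode` columns).
#' @param parts Scaffold parts, as from [oligo_parts()]; adapters may be
#'   empty strings, the linker must be 27 nt and barcodes 16 nt.
#' @return The design table with an added `oligo` column.
#' @export
assemble_oligo <- function(design, parts = oligo_parts()) {
  if (nchar(parts$linker) != 27L) {
    stop("linker must be exactly 27 nt", call. = FALSE)
  }
  if (any(nchar(design$barcode) != 16L)) {
    stop("all barcodes must be exactly 16 nt", call. = FALSE)
  }
  dplyr::mutate(
    design,
    oligo = paste0(parts$adapter5, .data$sequence, parts$linker,
                   .data$barcode, parts$adapter3)
  )
}

MEF2_MOTIF <- "CTAAAAATAG"

#' Build the full in-silico MPRA library design
#'
#' Constructs the complete candidate set of a systemic MPRA enhancer screen
#' (default 461 members): cross-tissue viral controls, tissue positive
#' controls (brain/liver/immune), published negative controls, GC-stratified
#' random negatives, cortical candidate enhancers, MEF2-motif enhancers with
#' motif-shuffled and motif-plus-flank-shuffled variants, SNP loci as
#' reference/alternative allele pairs (a subset with an additional
#' region-disrupt variant), and labelled placeholder candidates filling the
#' remaining slots.
#'
#' @param seed Integer seed.
#' @param length Enhancer length in nt (default 120).
#' @param n_cortical,n_mef2,n_snp,n_region_disrupt Category sizes; defaults
#'   reproduce the published composition (144 cortical candidates, 28 MEF2
#'   enhancers in three versions, 27 SNP loci of which 10 carry a
#'   region-disrupt version).
#' @param total Total library size (default 461); the balance after all
#'   categories is filled with placeholder cortical candidates.
#' @return Tibble of enhancer candidates (`enhancer_id`, `sequence`,
#'   `category`, `target_tissue`, `variant_of`, `variant_kind`).
#' @export
#' @examples
#' d <- build_design(seed = 1)
#' nrow(d)  # 461
build_design <- function(seed = 1, length = 120,
                         n_cortical = 144, n_mef2 = 28, n_snp = 27,
                         n_region_disrupt = 10, total = 461) {
  set.seed(derive_seed(seed, 1L))
  cand <- function(ids, seqs, category, tissue, variant_of = NA_character_,
                   variant_kind = "baseline") {
    tibble::tibble(
      enhancer_id = ids, sequence = seqs, category = category,
      target_tissue = tissue, variant_of = variant_of,
      variant_kind = variant_kind
    )
  }

  cross <- cand(sprintf("crossTissue_%d", 1:3), random_dna(3, length),
                "cross_tissue", "all")
  pos <- dplyr::bind_rows(
    cand(sprintf("posBrain_%02d", 1:10), random_dna(10, length),
         "positive_control", "brain"),
    cand(sprintf("posLiver_%02d", 1:10), random_dna(10, length),
         "positive_control", "liver"),
    cand(sprintf("posImmune_%02d", 1:10), random_dna(10, length),
         "positive_control", "immune")
  )
  neg <- cand(sprintf("negCtrl_%02d", 1:10), random_dna(10, length),
              "negative_control", "none")
  rand_neg <- generate_negative_controls(10, c(0.30, 0.50, 0.70), length,
                                         seed = derive_seed(seed, 2L))
  rand_neg$gc_level <- NULL
  cortical <- cand(sprintf("cortical_%03d", seq_len(n_cortical)),
                   random_dna(n_cortical, length), "cortical", "brain")

  # MEF2 enhancers: consensus motif embedded at the sequence centre, plus a
  # motif-shuffled and a motif+flank-shuffled version of each baseline
  motif_len <- nchar(MEF2_MOTIF)
  m_start <- (length - motif_len) %/% 2 + 1L
  m_end <- m_start + motif_len - 1L
  mef2_base_seq <- random_dna(n_mef2, length)
  substr(mef2_base_seq, m_start, m_end) <- strrep(MEF2_MOTIF, 1)
  mef2_ids <- sprintf("MEF2_%02d", seq_len(n_mef2))
  mef2 <- dplyr::bind_rows(
    cand(mef2_ids, mef2_base_seq, "MEF2", "brain"),
    cand(paste0(mef2_ids, "_motifShuf"),
         vapply(seq_len(n_mef2), function(i) {
           shuffle_interval(mef2_base_seq[i], m_start, m_end, flank = 0,
                            seed = derive_seed(seed, 100L + i))
         }, character(1)),
         "MEF2", "brain", variant_of = mef2_ids,
         variant_kind = "motif_shuffled"),
    cand(paste0(mef2_ids, "_flankShuf"),
         vapply(seq_len(n_mef2), function(i) {
           shuffle_interval(mef2_base_seq[i], m_start, m_end, flank = 5,
                            seed = derive_seed(seed, 200L + i))
         }, character(1)),
         "MEF2", "brain", variant_of = mef2_ids,
         variant_kind = "motif_flank_shuffled")
  )

  # SNP loci: ref/alt allele pair centred on the variant; a subset gets a
  # third version with the local binding-site region shuffled
  snp_pos <- length %/% 2
  snp_seq <- random_dna(n_snp, length)
  snp_ids <- sprintf("snp_%02d", seq_len(n_snp))
  snp_rows <- purrr::map(seq_len(n_snp), function(i) {
    ref_base <- substr(snp_seq[i], snp_pos, snp_pos)
    alt_base <- sample(setdiff(DNA_BASES, ref_base), 1)
    pair <- make_allele_pair(snp_seq[i], snp_pos, ref_base, alt_base)
    rows <- dplyr::bind_rows(
      cand(paste0(snp_ids[i], "_ref"), pair$ref, "SNP", "brain",
           variant_kind = "ref_allele"),
      cand(paste0(snp_ids[i], "_alt"), pair$alt, "SNP", "brain",
           variant_of = paste0(snp_ids[i], "_ref"),
           variant_kind = "alt_allele")
    )
    if (i <= n_region_disrupt) {
      rows <- dplyr::bind_rows(rows, cand(
        paste0(snp_ids[i], "_regionDisrupt"),
        shuffle_interval(pair$ref, snp_pos - 5L, snp_pos + 4L, flank = 5,
                         seed = derive_seed(seed, 300L + i)),
        "SNP", "brain", variant_of = paste0(snp_ids[i], "_ref"),
        variant_kind = "region_disrupt"
      ))
    }
    rows
  })
  snp <- dplyr::bind_rows(snp_rows)

  core <- dplyr::bind_rows(cross, pos, neg, rand_neg, cortical, mef2, snp)
  n_filler <- total - nrow(core)
  if (n_filler < 0) {
    stop("category sizes exceed total library size ", total, call. = FALSE)
  }
  filler <- cand(sprintf("filler_%03d", seq_len(n_filler)),
                 random_dna(n_filler, length), "cortical", "unassigned")
  dplyr::bind_rows(core, filler)
}

#' Write/read a design table as TSV
#'
#' One row per enhancer-barcode pair with the columns `enhancer_id`,
#' `category`, `variant_of`, `variant_kind`, `sequence`, `barcode`
#' (plus `target_tissue`).
#'
#' @param design Design table.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); the design tibble (reader).
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Write the assembled oligo library as FASTA
#'
#' Record ids are `enhancer_id|barcode`.
#'
#' @param design Design table with an `oligo` column (see [assemble_oligo()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(design, path) {
  if (is.null(design$oligo)) stop("design has no 'oligo' column", call. = FALSE)
  x <- Biostrings::DNAStringSet(design$oligo)
  names(x) <- paste0(design$enhancer_id, "|", design$barcode)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
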