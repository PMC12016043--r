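#' Anchor specification for barcode extraction
#'
#' A read is accepted only if it matches the designed restriction-enzyme site
#' (the anchor) and the bases immediately adjacent to the barcode, and its
#' extracted 16-mer resolves uniquely against the barcode whitelist. All
#' offsets are 1-based positions within the read.
#'
#' @param anchor_sequence Anchor (restriction-site context) sequence.
#' @param anchor_offset Position of the anchor within the read.
#' @param barcode_offset Position of the barcode within the read.
#' @param barcode_length Barcode length (16).
#' @param flank_left,flank_right Bases expected immediately before/after the
#'   barcode (the "adjacent bases"; default 3 nt each side).
#' @param max_anchor_mismatches Mismatches tolerated in the anchor and in
#'   each flank (default 0 — the strictest quality rule).
#' @param max_barcode_mismatches Mismatches tolerated when matching the
#'   extracted 16-mer against the whitelist (default 0).
#' @return List of class `mpra_anchor_spec`.
#' @export
anchor_spec <- function(anchor_sequence, anchor_offset, barcode_offset,
                        barcode_length = 16L, flank_left = "",
                        flank_right = "", max_anchor_mismatches = 0L,
                        max_barcode_mismatches = 0L) {
  stopifnot(max_anchor_mismatches >= 0, max_barcode_mismatches >= 0,
            anchor_offset >= 1, barcode_offset >= 1)
  structure(list(
    anchor_sequence = anchor_sequence,
    anchor_offset = as.integer(anchor_offset),
    barcode_offset = as.integer(barcode_offset),
    barcode_length = as.integer(barcode_length),
    flank_left = flank_left,
    flank_right = flank_right,
    max_anchor_mismatches = as.integer(max_anchor_mismatches),
    max_barcode_mismatches = as.integer(max_barcode_mismatches)
  ), class = "mpra_anchor_spec")
}

#' Default anchor spec matching the read template
#'
#' Derives the extraction spec from the oligo scaffold: the anchor is the
#' restriction site inside the linker, and the adjacent bases are the
#' `flank_width` scaffold bases on either side of the barcode.
#'
#' @param template Read template (see [read_template()]).
#' @param flank_width Adjacent-base width on each side (default 3).
#' @param ... Passed to [anchor_spec()] (mismatch tolerances).
#' @return An `mpra_anchor_spec`.
#' @export
default_anchor_spec <- function(template = read_template(), flank_width = 3L,
                                ...) {
  parts <- template$parts
  bc_off <- template$barcode_offset
  pre <- template$prefix
  anchor_spec(
    anchor_sequence = parts$anchor,
    anchor_offset = parts$anchor_in_linker,
    barcode_offset = bc_off,
    barcode_length = 16L,
    flank_left = substr(pre, nchar(pre) - flank_width + 1L, nchar(pre)),
    flank_right = substr(template$suffix, 1L, flank_width),
    ...
  )
}

required_span <- function(spec) {
  max(spec$anchor_offset + nchar(spec$anchor_sequence) - 1L,
      spec$barcode_offset + spec$barcode_length - 1L +
        nchar(spec$flank_right))
}

#' Extract barcodes from reads with anchor filtering
#'
#' Vectorised over reads. A read is assigned to a whitelist barcode iff the
#' anchor matches within `max_anchor_mismatches`, both adjacent-base flanks
#' match within the same tolerance, and the extracted 16-mer matches exactly
#' one whitelist barcode within `max_barcode_mismatches`. Otherwise a
#' rejection reason is returned: `too_short`, `anchor_fail`, `flank_fail`,
#' `barcode_unmatched` or `barcode_ambiguous`.
#'
#' @param reads Character vector of read sequences.
#' @param spec An [anchor_spec()].
#' @param whitelist Character vector of designed barcodes.
#' @return Tibble with `barcode` (`NA` for rejected reads) and `reason`
#'   (`"accepted"` or the rejection reason).
#' @export
extract_barcode <- function(reads, spec, whitelist) {
  n <- length(reads)
  barcode <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  span <- required_span(spec)
  short <- nchar(reads) < span
  reason[short] <- "too_short"
  live <- !short

  if (any(live)) {
    mm <- window_mismatches(reads[live], spec$anchor_sequence,
                            spec$anchor_offset)
    bad <- mm > spec$max_anchor_mismatches
    reason[live][bad] <- "anchor_fail"
    live[live] <- !bad
  }
  if (any(live) && nchar(spec$flank_left) + nchar(spec$flank_right) > 0) {
    mm_l <- if (nchar(spec$flank_left) > 0) {
      window_mismatches(reads[live], spec$flank_left,
                        spec$barcode_offset - nchar(spec$flank_left))
    } else 0L
    mm_r <- if (nchar(spec$flank_right) > 0) {
      window_mismatches(reads[live], spec$flank_right,
                        spec$barcode_offset + spec$barcode_length)
    } else 0L
    bad <- (mm_l > spec$max_anchor_mismatches) |
           (mm_r > spec$max_anchor_mismatches)
    reason[live][bad] <- "flank_fail"
    live[live] <- !bad
  }
  if (any(live)) {
    bc <- substr(reads[live], spec$barcode_offset,
                 spec$barcode_offset + spec$barcode_length - 1L)
    hit <- match(bc, whitelist)
    if (spec$max_barcode_mismatches > 0) {
      miss <- which(is.na(hit))
      for (i in miss) {
        d <- hamming(rep(bc[i], length(whitelist)), whitelist)
        near <- which(d <= spec$max_barcode_mismatches)
        if (length(near) == 1L) {
          hit[i] <- near
        } else if (length(near) > 1L) {
          hit[i] <- -1L # ambiguous sentinel
        }
      }
    }
    amb <- !is.na(hit) & hit == -1L
    got <- !is.na(hit) & hit > 0L
    reason[live][amb] <- "barcode_ambiguous"
    reason[live][!got & !amb] <- "barcode_unmatched"
    barcode[live][got] <- whitelist[hit[got]]
    reason[live][got] <- "accepted"
  }
  tibble::tibble(barcode = barcode, reason = reason)
}

#' Count whitelist barcodes across FASTQ samples
#'
#' Streams each sample's FASTQ through [extract_barcode()] and assembles a
#' barcode-by-sample count table per molecule type, recording per-sample
#' accepted/rejected tallies (by rejection reason) as attributes.
#'
#' @param samples Sample sheet tibble with `sample_id`, `molecule`
#'   (`"DNA"`/`"RNA"`) and `fastq_path` columns (plus `animal`, `tissue`).
#' @param spec An [anchor_spec()].
#' @param whitelist Character vector of designed barcodes (whitelist order is
#'   preserved as row order).
#' @return List with `dna` and `rna` `mpra_counts` tables (either may be
#'   absent if the sheet has no samples of that molecule) and `rejections`,
#'   a tibble of per-sample, per-reason read counts.
#' @export
count_barcodes <- function(samples, spec, whitelist) {
  missing <- samples$fastq_path[!file.exists(samples$fastq_path)]
  if (length(missing)) {
    stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  reasons <- c("accepted", "too_short", "anchor_fail", "flank_fail",
               "barcode_unmatched", "barcode_ambiguous")
  mats <- list(DNA = NULL, RNA = NULL)
  ids <- list(DNA = character(0), RNA = character(0))
  tallies <- list()
  rej_rows <- list()
  for (i in seq_len(nrow(samples))) {
    reads <- read_fastq_sequences(samples$fastq_path[i])
    res <- extract_barcode(reads, spec, whitelist)
    cnt <- integer(length(whitelist))
    acc <- res$barcode[res$reason == "accepted"]
    if (length(acc)) {
      t <- table(factor(acc, levels = whitelist))
      cnt <- as.integer(t)
    }
    mol <- samples$molecule[i]
    mats[[mol]] <- cbind(mats[[mol]], cnt)
    ids[[mol]] <- c(ids[[mol]], samples$sample_id[i])
    by_reason <- table(factor(res$reason, levels = reasons))
    rej_rows[[i]] <- tibble::tibble(
      sample_id = samples$sample_id[i], molecule = mol,
      reason = reasons, reads = as.integer(by_reason)
    )
    tallies[[i]] <- tibble::tibble(
      sample_id = samples$sample_id[i],
      accepted = as.integer(by_reason["accepted"]),
      rejected = length(reads) - as.integer(by_reason["accepted"])
    )
  }
  tallies <- dplyr::bind_rows(tallies)
  out <- list(rejections = dplyr::bind_rows(rej_rows))
  for (mol in c("DNA", "RNA")) {
    if (!is.null(mats[[mol]])) {
      out[[tolower(mol)]] <- new_mpra_counts(
        whitelist, mats[[mol]], ids[[mol]], mol,
        tallies = dplyr::semi_join(
          tallies, tibble::tibble(sample_id = ids[[mol]]), by = "sample_id")
      )
    }
  }
  out
}

read_fastq_sequences <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Represent a plasmid library as a one-sample DNA count table
#'
#' The plasmid-library sequencing run that measures cloning dropout is a
#' single DNA sample; this builds its count table over the full designed
#' whitelist (count 1 for each surviving barcode, 0 for dropped ones) so it
#' can flow through [complexity_metrics()].
#'
#' @param surviving_barcodes Character vector of barcodes present in the
#'   plasmid library.
#' @param whitelist Full designed barcode whitelist.
#' @param sample_id Column name for the pseudo-sample.
#' @return An `mpra_counts` table with one sample column.
#' @export
plasmid_library_counts <- function(surviving_barcodes, whitelist,
                                   sample_id = "plasmid_library") {
  mat <- matrix(as.integer(whitelist %in% surviving_barcodes), ncol = 1)
  new_mpra_counts(whitelist, mat, sample_id, "DNA")
}

#' Library complexity and transduction metrics
#'
#' Summarises a DNA count table against the designed library: per-sample
#' detected barcode counts and proportions (relative to the global
#' high-quality barcode union), the union size and its share of the designed
#' barcodes (library complexity), per-enhancer detected-barcode statistics,
#' enhancer coverage, and the overall transduction rate computed as
#' `union size / (n_enhancers x effective_barcodes_per_enhancer)`.
#'
#' @param dna `mpra_counts` table of DNA samples.
#' @param design Design table of the full designed library.
#' @param effective_barcodes_per_enhancer Divisor for the transduction rate;
#'   defaults to the observed mean detected barcodes per enhancer, rounded
#'   (the normalisation the original analysis used, with 9 as its rounded
#'   mean).
#' @param detection_threshold Minimum count for a barcode to be called
#'   detected in a sample (default 1).
#' @return List of class `mpra_complexity`: `per_sample` (tibble:
#'   `sample_id`, `detected`, `proportion`), `per_enhancer` (tibble:
#'   `enhancer_id`, `n_detected`), `union_size`, `complexity` (union /
#'   designed barcodes), `enhancer_coverage`, `transduction_rate`,
#'   `barcodes_per_enhancer` (min/mean/max over enhancers with >= 1 detected
#'   barcode), `n_designed_barcodes`, `n_enhancers`.
#' @export
complexity_metrics <- function(dna, design,
                               effective_barcodes_per_enhancer = NULL,
                               detection_threshold = 1) {
  if (nrow(design) == 0) stop("empty design table", call. = FALSE)
  mat <- count_matrix(dna)
  det <- mat >= detection_threshold
  union_bc <- dna$barcode[rowSums(det) > 0]
  union_size <- length(union_bc)

  det_per_sample <- as.integer(colSums(det))
  per_sample <- tibble::tibble(
    sample_id = colnames(mat),
    detected = det_per_sample,
    proportion = if (union_size > 0) det_per_sample / union_size else 0
  )

  n_enh <- dplyr::n_distinct(design$enhancer_id)
  per_enh <- design |>
    dplyr::mutate(hit = .data$barcode %in% union_bc) |>
    dplyr::group_by(.data$enhancer_id) |>
    dplyr::summarise(n_detected = sum(.data$hit), .groups = "drop")
  covered <- per_enh$n_detected >= 1
  bpe <- per_enh$n_detected[covered]
  mean_bpe <- if (length(bpe)) mean(bpe) else 0
  if (is.null(effective_barcodes_per_enhancer)) {
    effective_barcodes_per_enhancer <- max(1, round(mean_bpe))
  }
  structure(list(
    per_sample = per_sample,
    per_enhancer = per_enh,
    union_size = union_size,
    complexity = union_size / dplyr::n_distinct(design$barcode),
    enhancer_coverage = mean(covered),
    transduction_rate = union_size /
      (n_enh * effective_barcodes_per_enhancer),
    barcodes_per_enhancer = c(
      min = if (length(bpe)) min(bpe) else 0,
      mean = mean_bpe,
      max = if (length(bpe)) max(bpe) else 0),
    effective_barcodes_per_enhancer = effective_barcodes_per_enhancer,
    n_designed_barcodes = dplyr::n_distinct(design$barcode),
    n_enhancers = n_enh
  ), class = "mpra_complexity")
}

#' @export
print.mpra_complexity <- function(x, ...) {
  cat("<mpra_complexity>\n",
      sprintf("  designed barcodes : %d (%d enhancers)\n",
              x$n_designed_barcodes, x$n_enhancers),
      sprintf("  detected union    : %d (complexity %.1f%%)\n",
              x$union_size, 100 * x$complexity),
      sprintf("  enhancer coverage : %.1f%%\n", 100 * x$enhancer_coverage),
      sprintf("  barcodes/enhancer : min %d, mean %.1f, max %d\n",
              x$barcodes_per_enhancer["min"], x$barcodes_per_enhancer["mean"],
              x$barcodes_per_enhancer["max"]),
      sprintf("  transduction rate : %.1f%% (effective %d bc/enhancer)\n",
              100 * x$transduction_rate, x$effective_barcodes_per_enhancer),
      sep = "")
  invisible(x)
}

#' One-row summary of a complexity report
#' @param x An `mpra_complexity` object.
#' @param ... Unused.
#' @return One-row tibble of the global metrics.
#' @export
glance.mpra_complexity <- function(x, ...) {
  tibble::tibble(
    n_designed_barcodes = x$n_designed_barcodes,
    n_enhancers = x$n_enhancers,
    union_size = x$union_size,
    complexity = x$complexity,
    enhancer_coverage = x$enhancer_coverage,
    transduction_rate = x$transduction_rate,
    min_bc_per_enhancer = unname(x$barcodes_per_enhancer["min"]),
    mean_bc_per_enhancer = unname(x$barcodes_per_enhancer["mean"]),
    max_bc_per_enhancer = unname(x$barcodes_per_enhancer["max"])
  )
}

#' Per-sample rows of a complexity report
#' @param x An `mpra_complexity` object.
#' @param ... Unused.
#' @return Tibble of per-sample detected counts and proportions.
#' @export
tidy.mpra_complexity <- function(x, ...) {
  x$per_sample
}
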