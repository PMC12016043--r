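#' Read template for simulated amplicon sequencing
#'
#' Simulated reads start at the linker (so they carry the restriction-site
#' anchor), run through the 16-nt barcode and into the 3' adapter. The
#' template records the fixed prefix/suffix around the barcode and the
#' offsets the extraction anchor spec needs.
#'
#' @param parts Oligo scaffold parts (see [oligo_parts()]).
#' @param read_length Total read length (default 50).
#' @return Named list: `prefix` (linker), `suffix` (3' adapter fill),
#'   `read_length`, `barcode_offset` (1-based), `parts`.
#' @export
read_template <- function(parts = oligo_parts(), read_length = 50L) {
  prefix <- parts$linker
  bc_off <- nchar(prefix) + 1L
  suffix_len <- read_length - nchar(prefix) - 16L
  if (suffix_len < 0) stop("read_length too short for linker + barcode",
                           call. = FALSE)
  list(
    prefix = prefix,
    suffix = substr(parts$adapter3, 1L, suffix_len),
    read_length = read_length,
    barcode_offset = bc_off,
    parts = parts
  )
}

#' Emit amplicon FASTQ reads from a count table
#'
#' Writes one FASTQ file per sample containing exactly `count` copies of each
#' barcode's read, each base substituted independently with probability
#' `error_rate` (substitutions only; no indels). Read order is randomised per
#' sample, and output is deterministic for a fixed seed.
#'
#' @param counts `mpra_counts` table.
#' @param template Read template (see [read_template()]).
#' @param dir Output directory (created if needed).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @param gzip Compress output FASTQ files (default FALSE).
#' @return Tibble with `sample_id` and `fastq_path`.
#' @export
emit_amplicon_reads <- function(counts, template = read_template(), dir,
                                error_rate = 0, seed = 1, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, 37L))
  base_reads <- paste0(template$prefix, counts$barcode, template$suffix)
  sample_ids <- setdiff(names(counts), "barcode")
  paths <- character(length(sample_ids))
  for (j in seq_along(sample_ids)) {
    sid <- sample_ids[j]
    n_per_bc <- counts[[sid]]
    reads <- rep(base_reads, times = n_per_bc)
    if (length(reads)) reads <- reads[sample.int(length(reads))]
    if (error_rate > 0 && length(reads)) {
      reads <- add_substitution_errors(reads, error_rate)
    }
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    path <- file.path(dir, paste0(sid, ext))
    write_fastq(reads, path, id_prefix = sid, gzip = gzip)
    paths[j] <- path
  }
  tibble::tibble(sample_id = sample_ids, fastq_path = paths)
}

# Substitution channel: draw the number of errors per read, then mutate only
# the affected reads (each error picks one of the 3 other bases).
add_substitution_errors <- function(reads, error_rate) {
  L <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), L, error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(L, n_err[i])
    chars <- strsplit(reads[i], "")[[1]]
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
    reads[i] <- paste0(chars, collapse = "")
  }
  reads
}

# 4-line FASTQ records, Phred+33, constant quality
write_fastq <- function(reads, path, id_prefix = "read", quality_char = "I",
                        gzip = FALSE) {
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads) == 0) {
    return(invisible(path))
  }
  lines <- as.vector(rbind(
    paste0("@", id_prefix, ":", seq_along(reads)),
    reads,
    rep("+", length(reads)),
    strrep(quality_char, nchar(reads))
  ))
  writeLines(lines, con)
  invisible(path)
}
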