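#' Reporter specification
#'
#' A reporter is the fixed coordinate frame for every positional analysis in
#' the package: a CDS-scale nucleotide sequence carrying a translational stall
#' element (a stem loop or a run of inhibitory codons) at a known 1-based
#' position, and the annealing position of the 5' amplification primer used in
#' the 3'-RACE library. Stall-relative distances, simulated cleavage sites and
#' mapped fragment coordinates are all expressed against this frame.
#'
#' @param name Short identifier, e.g. `"PGK1-SL"`.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T` (the reporter CDS;
#'   positions are 1-based).
#' @param stall_start 1-based position of the first nucleotide of the stall
#'   element, or `NA` for a stall-less control (`stall_type = "none"`).
#' @param stall_type One of `"SL"`, `"CGA12"`, `"AAA12"`, `"UUU12"`, `"none"`.
#' @param primer_start 1-based position where the 5' amplification primer
#'   anneals. Fragments ending 5' of this position cannot be amplified.
#'
#' @return An object of class `reporter_spec`.
#' @export
#' @examples
#' rep <- reporter_spec("toy", strrep("ACGT", 300), stall_start = 1040,
#'                      stall_type = "SL", primer_start = 585)
#' rep$stall_start
reporter_spec <- function(name, sequence, stall_start = NA_integer_,
                          stall_type = c("SL", "CGA12", "AAA12", "UUU12", "none"),
                          primer_start = 1L) {
  stall_type <- match.arg(stall_type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("reporter sequence must be a non-empty string over A/C/G/T", call. = FALSE)
  }
  len <- nchar(sequence)
  primer_start <- as.integer(primer_start)
  if (is.na(primer_start) || primer_start < 1L || primer_start > len) {
    stop("primer_start must lie in [1, ", len, "]", call. = FALSE)
  }
  if (stall_type == "none") {
    if (!is.na(stall_start)) {
      stop("stall_type 'none' is incompatible with a stall_start", call. = FALSE)
    }
    stall_start <- NA_integer_
  } else {
    stall_start <- as.integer(stall_start)
    if (is.na(stall_start)) {
      stop("stall_type '", stall_type, "' requires stall_start", call. = FALSE)
    }
    if (stall_start > len) {
      stop("stall_start (", stall_start, ") beyond sequence end (", len, ")",
           call. = FALSE)
    }
    if (primer_start >= stall_start) {
      stop("primer_start must lie strictly 5' of stall_start", call. = FALSE)
    }
  }
  structure(
    list(name = name, sequence = sequence, stall_start = stall_start,
         stall_type = stall_type, primer_start = primer_start),
    class = "reporter_spec"
  )
}

#' @export
print.reporter_spec <- function(x, ...) {
  cat("<reporter_spec> ", x$name, "\n", sep = "")
  cat("  length      : ", nchar(x$sequence), " nt\n", sep = "")
  cat("  stall       : ", x$stall_type,
      if (!is.na(x$stall_start)) paste0(" at position ", x$stall_start) else "",
      "\n", sep = "")
  cat("  primer      : position ", x$primer_start, "\n", sep = "")
  invisible(x)
}

# Fail loudly when a positional operation needs a stall and there is none.
require_stall <- function(reporter) {
  if (is.na(reporter$stall_start)) {
    stop("reporter '", reporter$name,
         "' has no stall element; stall-relative operation is undefined",
         call. = FALSE)
  }
  invisible(reporter$stall_start)
}

#' Load a reporter specification from a flat key-value file
#'
#' The file format is flat `key = value` text (TOML-like, human-editable):
#' required keys `name`, `stall_type`, `primer_start`, plus either `sequence`
#' (inline nucleotides) or `fasta` (path to a FASTA file, resolved relative to
#' the spec file; the first record is used). `stall_start` is required unless
#' `stall_type = none`. Lines starting with `#` are comments.
#'
#' @param path Path to the reporter spec file.
#' @return A validated [reporter_spec].
#' @export
load_reporter <- function(path) {
  if (!file.exists(path)) stop("reporter spec not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) {
    stop("malformed line in reporter spec: '", lines[bad][1L], "'", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  vals <- gsub('^"|"$', "", vals)
  spec <- stats::setNames(as.list(vals), keys)

  need <- c("name", "stall_type", "primer_start")
  missing <- setdiff(need, keys)
  if (length(missing)) {
    stop("reporter spec missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(spec$sequence)) {
    sequence <- spec$sequence
  } else if (!is.null(spec$fasta)) {
    fasta_path <- spec$fasta
    if (!file.exists(fasta_path)) {
      fasta_path <- file.path(dirname(path), spec$fasta)
    }
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path, call. = FALSE)
    sequence <- as.character(seqs[[1L]])
  } else {
    stop("reporter spec must declare 'sequence' or 'fasta'", call. = FALSE)
  }
  stall_start <- if (is.null(spec$stall_start)) NA_integer_ else
    as.integer(spec$stall_start)
  reporter_spec(
    name = spec$name, sequence = sequence, stall_start = stall_start,
    stall_type = spec$stall_type, primer_start = as.integer(spec$primer_start)
  )
}

#' Write a reporter specification to a flat key-value file
#'
#' Inverse of [load_reporter()] with the sequence inline.
#'
#' @param reporter A [reporter_spec].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reporter <- function(reporter, path) {
  stopifnot(inherits(reporter, "reporter_spec"))
  lines <- c(
    paste0("name = ", reporter$name),
    paste0("sequence = ", reporter$sequence),
    paste0("stall_type = ", reporter$stall_type),
    if (!is.na(reporter$stall_start)) paste0("stall_start = ", reporter$stall_start),
    paste0("primer_start = ", reporter$primer_start)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic stalling reporter with the canonical coordinate layout
#'
#' Builds a reporter with a random (seeded) sequence and the coordinate layout
#' used throughout the package's examples and simulations: a 1500-nt CDS with
#' the stall element at position 1040 (stem-loop layout) or 950 (codon-run
#' layout) and the amplification primer at position 585. The sequence itself
#' is synthetic -- only the coordinate geometry, not the nucleotide identity,
#' matters for positional analyses.
#'
#' @param stall_type Stall element type; determines the stall coordinate
#'   (1040 for `"SL"`, 950 for the codon runs, none for `"none"`).
#' @param length Total sequence length in nt.
#' @param seed Integer seed for the random sequence.
#' @return A [reporter_spec].
#' @export
#' @examples
#' synthetic_reporter()
synthetic_reporter <- function(stall_type = c("SL", "CGA12", "AAA12", "UUU12", "none"),
                               length = 1500L, seed = 42L) {
  stall_type <- match.arg(stall_type)
  stall_start <- switch(stall_type,
    SL = 1040L, CGA12 = 950L, AAA12 = 950L, UUU12 = 950L, none = NA_integer_)
  seq <- with_seed_local(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  reporter_spec(
    name = paste0("synthetic-", stall_type),
    sequence = seq, stall_start = stall_start, stall_type = stall_type,
    primer_start = 585L
  )
}
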