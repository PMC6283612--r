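#' Read 3'-RACE reads from FASTQ
#'
#' Parses a (plain or gzipped) FASTQ file into a tibble with one row per read,
#' preserving file order. Sequence and quality lengths are checked per record.
#'
#' @param path FASTQ file.
#' @return A tibble with columns `id`, `sequence`, `qualities`.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_race_fastq(fq)
read_race_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  info <- file.size(path)
  if (!is.na(info) && info == 0) {
    return(tibble(id = character(), sequence = character(),
                  qualities = character()))
  }
  reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(reads)$qualities)
  out <- tibble(
    id = names(reads) %||% as.character(seq_along(reads)),
    sequence = unname(as.character(reads)),
    qualities = unname(qual)
  )
  bad <- !is.na(out$qualities) & nchar(out$qualities) != nchar(out$sequence)
  if (any(bad)) {
    stop("FASTQ record '", out$id[which(bad)[1L]],
         "': quality length differs from sequence length", call. = FALSE)
  }
  if (any(nchar(out$sequence) == 0L)) {
    stop("FASTQ contains a zero-length read", call. = FALSE)
  }
  out
}

#' Write reads to FASTQ
#'
#' Inverse of [read_race_fastq()]; records are written in row order. Missing
#' qualities are written as constant `I`.
#'
#' @param reads Tibble with columns `id`, `sequence` and optionally
#'   `qualities`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_race_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  qual <- if ("qualities" %in% names(reads)) reads$qualities else
    strrep("I", nchar(reads$sequence))
  qual[is.na(qual)] <- strrep("I", nchar(reads$sequence[is.na(qual)]))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  }
  invisible(path)
}
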