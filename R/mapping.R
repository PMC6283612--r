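#' Trim the 3' adapter from a read
#'
#' Locates the ligated adapter in a read and removes it together with
#' everything 3' of it, exposing the fragment 3' end. Two match geometries are
#' accepted: the full adapter occurring internally (read longer than
#' fragment + adapter), or a 3'-terminal partial match where a read suffix
#' matches an adapter prefix of length at least `min_overlap`. Matches
#' tolerate a mismatch fraction up to `max_mismatch_frac` of the aligned
#' length; among qualifying matches the longest (most 5') wins. Reads with no
#' qualifying match are rejected -- their 3' end is unknowable -- which is a
#' categorized outcome, not an error.
#'
#' @param sequence Read sequence (single string).
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum aligned length for a 3'-terminal partial match.
#' @param max_mismatch_frac Maximum mismatch fraction of the aligned length.
#' @return The trimmed sequence, or `NA_character_` if no qualifying adapter
#'   match was found.
#' @export
#' @examples
#' trim_adapter(paste0("ACGTACGT", "CTGTAGGCACCATCAAT"))
trim_adapter <- function(sequence, adapter = "CTGTAGGCACCATCAAT",
                         min_overlap = 6L, max_mismatch_frac = 0.1) {
  stopifnot(nzchar(adapter))
  la <- nchar(adapter)
  lr <- nchar(sequence)
  if (lr == 0L) return(NA_character_)
  rch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  ach <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  # scan adapter start positions 5' to 3'; the first qualifying one removes
  # the most sequence, i.e. is the longest match
  for (p in seq_len(lr)) {
    alen <- min(la, lr - p + 1L)
    terminal <- alen < la  # partial match must reach the read's 3' end
    if (terminal && alen < min_overlap) break
    mm <- sum(rch[p:(p + alen - 1L)] != ach[seq_len(alen)])
    if (mm <= floor(max_mismatch_frac * alen)) {
      return(substr(sequence, 1L, p - 1L))
    }
  }
  NA_character_
}

#' Place a trimmed fragment on the reporter by ungapped alignment
#'
#' Finds the forward-strand placement minimizing Hamming distance over all
#' offsets. The placement is accepted iff the minimum distance is at most
#' `max_mismatches` and is achieved at a unique offset. The library design (a
#' reporter-specific 5' primer plus 3' adapter ligation) fixes the
#' orientation, so only the forward strand is searched.
#'
#' @param trimmed Adapter-trimmed read sequence.
#' @param reporter A [reporter_spec].
#' @param max_mismatches Maximum Hamming distance accepted.
#' @param min_length Minimum trimmed length submitted to alignment.
#' @return One-row tibble `start`, `end3`, `mismatches` on success, or a
#'   zero-row tibble with attribute `why` in
#'   `c("too_short", "too_many_mismatches", "ambiguous")`.
#' @export
align_fragment <- function(trimmed, reporter, max_mismatches = 2L,
                           min_length = 15L) {
  stopifnot(inherits(reporter, "reporter_spec"))
  empty <- function(why) {
    structure(tibble(start = integer(), end3 = integer(),
                     mismatches = integer()), why = why)
  }
  if (is.na(trimmed) || nchar(trimmed) < min_length) return(empty("too_short"))
  hits <- Biostrings::matchPattern(
    trimmed, Biostrings::DNAString(reporter$sequence),
    max.mismatch = max_mismatches, with.indels = FALSE
  )
  # drop edge placements extending past the reporter ends
  ok <- BiocGenerics::start(hits) >= 1L &
    BiocGenerics::end(hits) <= nchar(reporter$sequence)
  hits <- hits[ok]
  if (length(hits) == 0L) return(empty("too_many_mismatches"))
  mm <- Biostrings::neditStartingAt(
    Biostrings::DNAString(trimmed),
    Biostrings::DNAString(reporter$sequence),
    starting.at = BiocGenerics::start(hits)
  )
  best <- min(mm)
  at_best <- which(mm == best)
  if (length(at_best) > 1L) return(empty("ambiguous"))
  s <- BiocGenerics::start(hits)[at_best]
  tibble(start = as.integer(s),
         end3 = as.integer(s + nchar(trimmed) - 1L),
         mismatches = as.integer(best))
}

#' Stall-relative upstream distance of a fragment 3' end
#'
#' The profile coordinate: `stall_start - end3`, positive for ends upstream
#' of the stall. Ends at or downstream of the stall give distances `<= 0`;
#' they are retained by [map_reads()] in a flagged bin but excluded from peak
#' calling.
#'
#' @param end3 Fragment 3'-end coordinate(s), 1-based.
#' @param reporter A [reporter_spec] with a stall element.
#' @return Integer distance(s) in nt.
#' @export
#' @examples
#' rep <- synthetic_reporter()  # stall at 1040
#' upstream_distance(890, rep)  # 150
upstream_distance <- function(end3, reporter) {
  stopifnot(inherits(reporter, "reporter_spec"))
  stall <- require_stall(reporter)
  as.integer(stall - end3)
}

#' Map RACE reads to stall-relative fragment coordinates
#'
#' The full read-level pipeline: adapter trimming ([trim_adapter()]), ungapped
#' placement ([align_fragment()]) and stall-relative coordinate conversion
#' ([upstream_distance()]). Every input read is assigned exactly one fate:
#' `mapped`, `no_adapter`, `too_short`, `too_many_mismatches` or `ambiguous`;
#' fate counts always partition the input. Duplicate reads contribute
#' duplicate fragments -- each read is one observation and nothing is
#' collapsed.
#'
#' @param reads Tibble with columns `id`, `sequence` (e.g. from
#'   [read_race_fastq()] or [synthesize_reads()]).
#' @param reporter A [reporter_spec].
#' @param config An [analysis_config].
#' @return Tibble with one row per read: `read_id`, `fate`, `start`, `end3`,
#'   `mismatches`, `distance_upstream` (NA unless mapped; `<= 0` flags
#'   at/downstream-of-stall ends when the reporter has a stall).
#' @export
map_reads <- function(reads, reporter, config = analysis_config()) {
  stopifnot(all(c("id", "sequence") %in% names(reads)),
            inherits(reporter, "reporter_spec"),
            inherits(config, "analysis_config"))
  has_stall <- !is.na(reporter$stall_start)
  rows <- purrr::map2_dfr(reads$id, reads$sequence, function(id, seq) {
    trimmed <- trim_adapter(seq, config$adapter, config$min_overlap,
                            config$max_mismatch_frac)
    if (is.na(trimmed)) {
      return(tibble(read_id = id, fate = "no_adapter", start = NA_integer_,
                    end3 = NA_integer_, mismatches = NA_integer_))
    }
    hit <- align_fragment(trimmed, reporter, config$max_align_mismatches,
                          config$min_fragment_length)
    if (nrow(hit) == 0L) {
      return(tibble(read_id = id, fate = attr(hit, "why"),
                    start = NA_integer_, end3 = NA_integer_,
                    mismatches = NA_integer_))
    }
    tibble(read_id = id, fate = "mapped", start = hit$start, end3 = hit$end3,
           mismatches = hit$mismatches)
  })
  rows$distance_upstream <- if (has_stall) {
    ifelse(rows$fate == "mapped", reporter$stall_start - rows$end3, NA_integer_)
  } else NA_integer_
  rows
}

#' Summarise read fates
#'
#' @param fragments Output of [map_reads()].
#' @return Tibble `fate`, `n` covering every input read.
#' @export
fate_summary <- function(fragments) {
  dplyr::count(fragments, .data$fate, name = "n")
}

#' Import pre-aligned fragments from a SAM/BAM file
#'
#' Bypass for externally aligned reads: each mapped record's rightmost aligned
#' reference base is taken as the fragment 3' end (`end3`). Requires the
#' Rsamtools and GenomicAlignments packages. Soft-clipped or unmapped records
#' are dropped with a message.
#'
#' @param path SAM or BAM file aligned against the reporter sequence.
#' @param reporter A [reporter_spec]; used for the stall-relative coordinate.
#' @return Tibble `read_id`, `fate`, `start`, `end3`, `mismatches` (NA),
#'   `distance_upstream`, comparable to [map_reads()] output.
#' @export
read_sam_fragments <- function(path, reporter) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("SAM input requires the Rsamtools and GenomicAlignments packages",
         call. = FALSE)
  }
  stopifnot(inherits(reporter, "reporter_spec"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(bam, use.names = TRUE)
  out <- tibble(
    read_id = names(aln) %||% as.character(seq_along(aln)),
    fate = "mapped",
    start = BiocGenerics::start(aln),
    end3 = BiocGenerics::end(aln),
    mismatches = NA_integer_
  )
  out$distance_upstream <- if (!is.na(reporter$stall_start)) {
    reporter$stall_start - out$end3
  } else NA_integer_
  out
}
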