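# Read refinement: raw selection-round reads -> clean, deduplicated
# fixed-length randomized cores.

#' Construct a refined core set
#'
#' @param cores character vector of equal-length DNA cores.
#' @param stats named list/vector of refinement counters.
#' @return object of class `refined_core_set`.
#' @export
refined_core_set <- function(cores, stats = list()) {
  if (length(cores) > 0 && length(unique(nchar(cores))) != 1L)
    stop("all cores must have the same length")
  structure(list(cores = cores, stats = stats), class = "refined_core_set")
}

#' @export
print.refined_core_set <- function(x, ...) {
  cat("refined_core_set:", length(x$cores), "cores\n")
  if (length(x$stats))
    cat(paste(names(x$stats), unlist(x$stats), sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}

# first-leftmost match start of `anchor` in `subjects`, NA when absent
first_anchor_start <- function(anchor, subjects, max_mismatch) {
  m <- Biostrings::vmatchPattern(anchor, subjects,
                                 max.mismatch = max_mismatch,
                                 with.indels = FALSE)
  st <- Biostrings::startIndex(m)
  vapply(st, function(s) if (length(s)) min(s) else NA_integer_, integer(1))
}

#' Refine raw selection-round reads to fixed-length cores
#'
#' A read passes when (in order): its mean Phred quality reaches
#' `min_mean_quality`; both flank anchors are located (first-leftmost match,
#' at most `max_anchor_mismatches` substitutions each) in either the given or
#' the reverse-complement orientation of the read; and the segment between
#' the anchors is exactly `core_length` bases. Cores are reported in template
#' orientation (reads found in reverse-complement orientation are flipped
#' back). Each read is counted in exactly one bucket of `stats`, so the
#' counters sum to the input read count.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] or a FASTQ path.
#' @param left_anchor,right_anchor flanking anchor sequences (template
#'   orientation), e.g. the defined template flanks.
#' @param core_length expected randomized-core length (default 24).
#' @param min_mean_quality read-level mean Phred threshold (default 20).
#' @param max_anchor_mismatches substitutions tolerated per anchor; default
#'   one per 10 anchor bases (rounded down), tolerating sequencing error
#'   without admitting chimeras.
#' @return a [refined_core_set()] whose `stats` holds `input`,
#'   `quality_failed`, `flank_failed`, `length_failed` and `passed`.
#' @examples
#' lib <- generate_library(50, seed = 1)
#' tpl <- selection_template()
#' reads <- reads_from_library(lib, seed = 1)
#' rc <- refine_reads(reads, tpl$left_flank, tpl$right_flank)
#' @export
refine_reads <- function(reads, left_anchor, right_anchor,
                         core_length = 24L, min_mean_quality = 20,
                         max_anchor_mismatches = NULL) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- tryCatch(read_fastq(reads),
                      error = function(e) stop("malformed FASTQ: ",
                                               conditionMessage(e)))
  }
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  left_anchor <- toupper(left_anchor)
  right_anchor <- toupper(right_anchor)
  if (nchar(left_anchor) < 1L || nchar(right_anchor) < 1L)
    stop("anchors must be non-empty")
  if (core_length < 1L) stop("'core_length' must be >= 1")
  n <- length(reads)
  mm <- function(anchor) {
    if (is.null(max_anchor_mismatches)) nchar(anchor) %/% 10L
    else as.integer(max_anchor_mismatches)
  }

  qual <- methods::as(Biostrings::quality(reads), "IntegerList")
  mean_q <- vapply(qual, mean, numeric(1))
  ok_q <- !is.na(mean_q) & mean_q >= min_mean_quality

  seqs <- Biostrings::DNAStringSet(as.character(reads))
  cores <- rep(NA_character_, n)
  flank_ok <- rep(FALSE, n)
  len_ok <- rep(FALSE, n)

  extract <- function(subjects, candidates) {
    if (!length(candidates)) return(invisible(NULL))
    sub <- subjects[candidates]
    ls <- first_anchor_start(left_anchor, sub, mm(left_anchor))
    rs <- first_anchor_start(right_anchor, sub, mm(right_anchor))
    found <- !is.na(ls) & !is.na(rs)
    flank_ok[candidates[found]] <<- TRUE
    core_start <- ls + nchar(left_anchor)
    good <- found & (rs - core_start == core_length)
    # guard against windows running off the read
    good[is.na(good)] <- FALSE
    good <- good & core_start >= 1L
    if (any(good)) {
      ci <- candidates[good]
      len_ok[ci] <<- TRUE
      cores[ci] <<- as.character(
        Biostrings::subseq(sub[good], start = core_start[good],
                           width = core_length)
      )
    }
    invisible(NULL)
  }

  cand <- which(ok_q)
  extract(seqs, cand)
  # orientation recovery: retry unresolved reads on the reverse complement
  unresolved <- which(ok_q & is.na(cores))
  if (length(unresolved)) {
    flank_fwd <- flank_ok[unresolved]
    extract(Biostrings::reverseComplement(seqs), unresolved)
    flank_ok[unresolved] <- flank_ok[unresolved] | flank_fwd
  }

  passed <- !is.na(cores)
  stats <- list(
    input = n,
    quality_failed = sum(!ok_q),
    flank_failed = sum(ok_q & !flank_ok & !passed),
    length_failed = sum(ok_q & flank_ok & !passed),
    passed = sum(passed)
  )
  refined_core_set(cores[passed], stats)
}

#' Remove exact duplicate cores
#'
#' Keeps the first occurrence of each exact (forward-strand) core string and
#' drops later repeats. Reverse-complement pairs are deliberately kept as
#' distinct cores: collapsing them would discard strand information that the
#' palindrome analysis downstream relies on. Idempotent.
#'
#' @param cores character vector of equal-length cores, or a
#'   [refined_core_set()].
#' @return a [refined_core_set()]; `stats` gains `duplicates_removed` and
#'   `duplicate_fraction` (duplicates / input).
#' @examples
#' deduplicate(c("AAA", "AAA", "AAC"))
#' @export
deduplicate <- function(cores) {
  prev_stats <- list()
  if (inherits(cores, "refined_core_set")) {
    prev_stats <- cores$stats
    cores <- cores$cores
  }
  stopifnot(is.character(cores))
  if (length(cores) > 0 && length(unique(nchar(cores))) != 1L)
    stop("cores of mixed lengths")
  dup <- duplicated(cores)
  stats <- prev_stats
  stats$duplicates_removed <- sum(dup)
  stats$duplicate_fraction <- if (length(cores)) sum(dup) / length(cores)
                              else 0
  refined_core_set(cores[!dup], stats)
}
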