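# Genome scanning: log-odds scores, exact p-values by dynamic programming,
# Benjamini-Hochberg q-values over all tested windows, and promoter-window
# annotation of hits.

#' Log-odds score matrix of a motif
#'
#' `entry(b, j) = log2((p_bj + pseudocount) / background_b)`.
#'
#' @param pwm a [pwmotif()].
#' @param background length-4 base probabilities (default: the motif's own
#'   background).
#' @param pseudocount added to every letter probability before the ratio
#'   (default 0; scanning applies its own small pseudocount so that zero
#'   probabilities stay finite).
#' @return 4 x width numeric matrix (rows A, C, G, T), in bits.
#' @export
log_odds <- function(pwm, background = NULL, pseudocount = 0) {
  stopifnot(inherits(pwm, "pwmotif"))
  background <- background %||% pwm$background
  stopifnot(length(background) == 4L, all(background > 0))
  lo <- log2(sweep(pwm$matrix + pseudocount, 1L, background, "/"))
  rownames(lo) <- DNA_BASES
  lo
}

#' Exact null distribution of a PWM score
#'
#' Discretizes the log-odds matrix to integer scores (a common step size
#' chosen so that the widest column range spans `granularity` bins) and
#' computes the exact distribution of the discretized score of a random
#' background word by position-wise convolution. The survival function
#' `P(score >= s)` is exact for the discretized matrix; discretization error
#' on the original scores is bounded by `width * step / 2`.
#'
#' @param score_matrix 4 x width log-odds matrix (finite entries), e.g. from
#'   [log_odds()].
#' @param background length-4 base probabilities of the null model.
#' @param granularity bins spanned by the widest column range (default 1000,
#'   giving p-value discretization error far below the thresholds in common
#'   use).
#' @return object of class `score_dist`: the integer score matrix
#'   (`int_matrix`), bin width (`step`), real-score offset (`offset`), the
#'   null pmf and survival function over total integer scores `0..max_int`.
#' @export
score_pvalue_distribution <- function(score_matrix, background,
                                      granularity = 1000L) {
  stopifnot(is.matrix(score_matrix), nrow(score_matrix) == 4L)
  if (ncol(score_matrix) == 0L) stop("degenerate zero-width score matrix")
  if (any(!is.finite(score_matrix)))
    stop("score matrix has non-finite entries; use a pseudocount")
  stopifnot(granularity >= 1L)
  background <- as.numeric(background)
  background <- background / sum(background)
  w <- ncol(score_matrix)
  col_min <- apply(score_matrix, 2L, min)
  col_max <- apply(score_matrix, 2L, max)
  step <- max(col_max - col_min) / granularity
  if (step == 0) step <- 1            # constant matrix: single bin per column
  int_matrix <- round(sweep(score_matrix, 2L, col_min, "-") / step)
  storage.mode(int_matrix) <- "integer"
  max_int <- sum(apply(int_matrix, 2L, max))

  pmf <- 1                             # pmf covers scores 0..length(pmf)-1
  for (j in seq_len(w)) {
    mj <- max(int_matrix[, j])
    new <- numeric(length(pmf) + mj)
    for (b in 1:4) {
      s <- int_matrix[b, j]
      new[(s + 1L):(s + length(pmf))] <-
        new[(s + 1L):(s + length(pmf))] + pmf * background[b]
    }
    pmf <- new
  }
  sf <- rev(cumsum(rev(pmf)))
  sf <- pmin(sf, 1)                    # guard against rounding above 1
  structure(list(int_matrix = int_matrix, step = step,
                 offset = sum(col_min), granularity = granularity,
                 pmf = pmf, sf = sf, max_int = max_int),
            class = "score_dist")
}

#' p-value of a PWM score under the null distribution
#'
#' @param dist a `score_dist` from [score_pvalue_distribution()].
#' @param score real log-odds score(s) (converted to the discretized scale)
#'   or, with `integer_score = TRUE`, already-discretized integer total(s).
#' @param integer_score interpret `score` as integer totals.
#' @return p-value(s) `P(null score >= score)`.
#' @export
score_pvalue <- function(dist, score, integer_score = FALSE) {
  stopifnot(inherits(dist, "score_dist"))
  s_int <- if (integer_score) as.integer(score)
           else as.integer(round((score - dist$offset) / dist$step))
  s_int <- pmax(0L, pmin(s_int, dist$max_int))
  dist$sf[s_int + 1L]
}

#' Scan sequences for motif occurrences with exact p-values
#'
#' Scores every window of every sequence on both strands with the motif's
#' log-odds matrix and reports windows whose exact p-value (from
#' [score_pvalue_distribution()]) is at most `p_threshold`. q-values are
#' Benjamini-Hochberg adjusted over the full number of tested windows
#' (`2 * sum(len - width + 1)`), not just the reported ones. Hits are sorted
#' by p-value, then coordinate. Windows containing non-ACGT characters are
#' skipped.
#'
#' @param genome a `DNAStringSet`, a FASTA path, or a named character vector.
#' @param pwm a [pwmotif()].
#' @param p_threshold report windows with `p <= p_threshold` (default 1e-4).
#' @param background length-4 null base probabilities; default is the 0-order
#'   composition of the scanned sequences.
#' @param pseudocount added to motif probabilities before log-odds (default
#'   0.001) so zero-probability cells stay finite.
#' @param granularity discretization bins (see
#'   [score_pvalue_distribution()]).
#' @return data frame of hits with columns `seqnames`, `start`, `end`
#'   (1-based inclusive), `strand`, `score` (real log2-odds), `p_value`,
#'   `q_value`, `matched_sequence` (motif orientation). The total number of
#'   tested windows is attached as attribute `"n_tests"`.
#' @examples
#' pwm <- pwm_from_consensus("ATTGTGACACACATCACAAT", mismatch_prob = 0.02)
#' g <- generate_genome(20000, seed = 4, planted_sites = data.frame(
#'   sequence = "ATTGTGACACACATCACAAT", position = 5000, strand = "+"))
#' hits <- scan_genome(g$genome, pwm, p_threshold = 1e-5)
#' @export
scan_genome <- function(genome, pwm, p_threshold = 1e-4, background = NULL,
                        pseudocount = 0.001, granularity = 1000L) {
  stopifnot(inherits(pwm, "pwmotif"), is_probability(p_threshold))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- sprintf("seq_%d", seq_along(genome))
  w <- pwm_width(pwm)
  if (any(Biostrings::width(genome) < w))
    stop("every scanned sequence must be at least as long as the motif")

  if (is.null(background)) {
    counts <- colSums(Biostrings::alphabetFrequency(genome)[, DNA_BASES,
                                                            drop = FALSE])
    background <- (counts + 1) / sum(counts + 1)
  }
  background <- background / sum(background)

  lo <- log_odds(pwm, background = background, pseudocount = pseudocount)
  dist <- score_pvalue_distribution(lo, background, granularity)
  I_fwd <- dist$int_matrix
  I_rev <- I_fwd[4:1, rev(seq_len(w)), drop = FALSE]  # scores revcomp windows
  # smallest integer score whose p-value passes the threshold
  ok <- which(dist$sf <= p_threshold)
  s_cut <- if (length(ok)) min(ok) - 1L else dist$max_int + 1L

  window_ints <- function(idx, I) {
    nwin <- length(idx) - w + 1L
    s <- integer(nwin)
    for (j in seq_len(w)) {
      v <- I[cbind(idx[j:(nwin + j - 1L)], j)]
      s <- s + v
    }
    s
  }

  hits <- list()
  n_tests <- 0
  for (k in seq_along(genome)) {
    seq_chr <- as.character(genome[[k]])
    idx <- match(strsplit(seq_chr, "", fixed = TRUE)[[1L]], DNA_BASES)
    nwin <- length(idx) - w + 1L
    n_tests <- n_tests + 2 * nwin
    for (str in c("+", "-")) {
      s_int <- window_ints(idx, if (str == "+") I_fwd else I_rev)
      sel <- which(!is.na(s_int) & s_int >= s_cut)
      if (!length(sel)) next
      matched <- substring(seq_chr, sel, sel + w - 1L)
      if (str == "-") matched <- revcomp_chr(matched)
      real_score <- s_int[sel] * dist$step + dist$offset
      hits[[length(hits) + 1L]] <- data.frame(
        seqnames = names(genome)[k],
        start = sel, end = sel + w - 1L, strand = str,
        score = real_score,
        p_value = score_pvalue(dist, s_int[sel], integer_score = TRUE),
        matched_sequence = matched,
        stringsAsFactors = FALSE
      )
    }
  }

  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seqnames = character(0), start = integer(0),
               end = integer(0), strand = character(0), score = numeric(0),
               p_value = numeric(0), matched_sequence = character(0))
  out$q_value <- if (nrow(out)) p.adjust(out$p_value, method = "BH",
                                         n = n_tests) else numeric(0)
  out <- out[order(out$p_value, out$seqnames, out$start, out$strand), ,
             drop = FALSE]
  out <- out[, c("seqnames", "start", "end", "strand", "score", "p_value",
                 "q_value", "matched_sequence")]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  out
}

#' Annotate motif hits relative to gene starts
#'
#' Retains hits with `p_value <= p_max` and assigns each to every gene whose
#' (strand-aware) start places the hit within the promoter window
#' `[-window_upstream, +window_downstream]` — by default the -200..+20
#' region most common for transcription activator binding, with the
#' annotated gene start (translation start) serving as the transcription
#' start proxy. Offsets are signed, negative = upstream of the gene start.
#' A hit inside two opposite-strand promoter windows (a divergent,
#' bidirectional promoter) produces two calls flagged `bidirectional`. Hits
#' in no window are classed `intragenic` when they lie inside a gene body
#' and `intergenic_far` otherwise.
#'
#' @param hits data frame from [scan_genome()].
#' @param features a `GRanges` (with a `gene_id` metadata column) or a data
#'   frame with columns `seqnames`, `start`, `end`, `strand`, `gene_id`.
#' @param window_upstream,window_downstream promoter window bounds in bp
#'   (defaults 200 and 20).
#' @param p_max p-value cutoff for hits considered (default 5e-6).
#' @return data frame of promoter calls: hit coordinates plus `gene_id`,
#'   `offset`, `location_class` (`window`, `intragenic`, `intergenic_far`)
#'   and `bidirectional`.
#' @export
annotate_hits <- function(hits, features, window_upstream = 200L,
                          window_downstream = 20L, p_max = 5e-6) {
  if (methods::is(features, "GRanges")) {
    gene_id <- features$gene_id %||% names(features) %||%
      sprintf("gene_%d", seq_along(features))
    features <- data.frame(
      seqnames = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features),
      end = GenomicRanges::end(features),
      strand = as.character(GenomicRanges::strand(features)),
      gene_id = gene_id, stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("seqnames", "start", "end", "strand", "gene_id") %in%
                  names(features)))
  if (any(features$end < features$start))
    stop("features with end < start")
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strands must be '+' or '-'")

  keep <- hits$p_value <= p_max
  hits <- hits[keep, , drop = FALSE]
  calls <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    f <- features[features$seqnames == h$seqnames, , drop = FALSE]
    if (nrow(f) == 0L) next
    d <- ifelse(f$strand == "+", h$start - f$start, f$end - h$end)
    in_win <- d >= -window_upstream & d <= window_downstream
    if (any(in_win)) {
      wgenes <- which(in_win)
      bidir <- length(unique(f$strand[wgenes])) == 2L
      for (g in wgenes) {
        calls[[length(calls) + 1L]] <- cbind(
          h, data.frame(gene_id = f$gene_id[g], offset = d[g],
                        location_class = "window", bidirectional = bidir,
                        stringsAsFactors = FALSE))
      }
    } else {
      inside <- which(h$start <= f$end & h$end >= f$start)
      if (length(inside)) {
        g <- inside[1L]
        calls[[length(calls) + 1L]] <- cbind(
          h, data.frame(gene_id = f$gene_id[g], offset = d[g],
                        location_class = "intragenic", bidirectional = FALSE,
                        stringsAsFactors = FALSE))
      } else {
        calls[[length(calls) + 1L]] <- cbind(
          h, data.frame(gene_id = NA_character_, offset = NA_integer_,
                        location_class = "intergenic_far",
                        bidirectional = FALSE, stringsAsFactors = FALSE))
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    cbind(hits[0, , drop = FALSE],
          data.frame(gene_id = character(0), offset = integer(0),
                     location_class = character(0),
                     bidirectional = logical(0)))
  rownames(out) <- NULL
  out
}
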