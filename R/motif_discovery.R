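# Motif discovery: ZOOPS expectation-maximization over refined cores, with
# an optional palindromic constraint, plus consensus derivation and
# information content.

#' Construct a consensus pattern
#'
#' A degenerate (IUPAC) consensus with its dyad decomposition: two half sites
#' of equal length separated by an unconstrained spacer of N's. Patterns with
#' no symmetric dyad structure carry `NA` half-site/spacer lengths.
#'
#' @param iupac string over IUPAC nucleotide codes.
#' @param half_site_length,spacer_length dyad decomposition; when both are
#'   given, `nchar(iupac)` must equal `2 * half_site_length + spacer_length`.
#' @return object of class `consensus_pattern`.
#' @examples
#' consensus_pattern("AWTGTRANNNNNNTYACAWT", 7, 6)
#' @export
consensus_pattern <- function(iupac, half_site_length = NA_integer_,
                              spacer_length = NA_integer_) {
  stopifnot(is.character(iupac), length(iupac) == 1L)
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  if (!is.na(half_site_length) && !is.na(spacer_length) &&
      nchar(iupac) != 2L * half_site_length + spacer_length)
    stop("iupac length must equal 2 * half_site_length + spacer_length")
  structure(list(iupac = iupac,
                 half_site_length = as.integer(half_site_length),
                 spacer_length = as.integer(spacer_length)),
            class = "consensus_pattern")
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat("consensus_pattern:", x$iupac)
  if (!is.na(x$half_site_length))
    cat("  [", x$half_site_length, "-nt half sites, ", x$spacer_length,
        "-nt spacer ]", sep = "")
  cat("\n")
  invisible(x)
}

# window table for ZOOPS EM: every width-W window of every sequence on both
# strands, as an integer matrix plus bookkeeping vectors
build_windows <- function(cores, width) {
  lens <- nchar(cores)
  X <- NULL; seq_id <- integer(0)
  for (L in sort(unique(lens))) {
    rows <- which(lens == L)
    idx <- dna_index_matrix(cores[rows])
    idxrc <- revcomp_index(idx)
    for (o in seq_len(L - width + 1L)) {
      X <- rbind(X, idx[, o:(o + width - 1L), drop = FALSE],
                 idxrc[, o:(o + width - 1L), drop = FALSE])
      seq_id <- c(seq_id, rows, rows)
    }
  }
  o <- order(seq_id)
  list(X = X[o, , drop = FALSE], seq_id = seq_id[o],
       m = as.integer(table(factor(seq_id, levels = seq_along(cores)))))
}

# one EM run from a given start matrix; returns theta, gamma, z stats, ll trace
zoops_em <- function(win, theta, bg, n_seq, palindromic, pseudocount,
                     max_iter, tol) {
  X <- win$X
  W <- ncol(X)
  M <- nrow(X)
  gamma <- 0.5
  log_bg <- log(bg)
  b_win <- rowSums(matrix(log_bg[X], nrow = M))
  m_i <- win$m
  m_of_win <- m_i[win$seq_id]
  grp <- win$seq_id   # every sequence has >= 1 window, so rowsum() over the
                      # integer ids yields one row per sequence in order
  ll_trace <- numeric(0)
  q_i <- NULL
  z <- NULL
  for (it in seq_len(max_iter)) {
    log_theta <- log(theta)
    s <- numeric(M)
    for (j in seq_len(W)) s <- s + log_theta[cbind(X[, j], j)]
    lr <- exp(s - b_win)                    # likelihood ratio per window
    sum_lr <- as.numeric(rowsum(lr, grp))   # per sequence
    denom_i <- (1 - gamma) + (gamma / m_i) * sum_lr
    # EM objective: data log likelihood (up to the constant background term)
    # plus the Dirichlet-smoothing term that the pseudocounted M-step
    # maximizes; this objective is non-decreasing across iterations
    ll <- sum(log(denom_i)) + pseudocount * sum(log_theta)
    ll_trace <- c(ll_trace, ll)
    z <- (gamma / m_of_win) * lr / denom_i[win$seq_id]
    q_i <- as.numeric(rowsum(z, grp))
    # M-step
    counts <- matrix(pseudocount, 4L, W)
    for (j in seq_len(W)) {
      for (b in 1:4) counts[b, j] <- counts[b, j] + sum(z[X[, j] == b])
    }
    if (palindromic) counts <- (counts + revcomp_matrix(counts)) / 2
    theta <- sweep(counts, 2L, colSums(counts), "/")
    gamma <- min(max(mean(q_i), 1 / (2 * n_seq)), 1 - 1e-9)
    if (it > 1L && ll_trace[it] - ll_trace[it - 1L] < tol) break
  }
  list(theta = theta, gamma = gamma, q_i = q_i,
       ll = ll_trace[length(ll_trace)],
       data_llr = sum(log(denom_i)),   # vs background-only model (llr = 0)
       ll_trace = ll_trace)
}

#' Discover an ungapped motif by ZOOPS expectation-maximization
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) motif model to a set of
#' equal- or mixed-length sequences, considering every window on both
#' strands. The run is repeated from `n_starts` seedings (each initialized
#' from a randomly chosen width-`width` window of the data) and the fit with
#' the best final log likelihood is returned. With `palindromic = TRUE` the
#' letter-probability matrix is averaged with its own reverse complement
#' after every M-step, which is the maximizer of the expected complete-data
#' log likelihood under the self-reverse-complementarity constraint, so the
#' log likelihood remains non-decreasing across iterations.
#'
#' When the input holds more than `max_sequences` sequences a random subset
#' of that size is drawn first (seeded), mirroring the practice of submitting
#' fixed-size sets of refined sequences to motif discovery.
#'
#' @param cores character vector of DNA sequences (all `>= width` long), or a
#'   [refined_core_set()].
#' @param width motif width.
#' @param palindromic enforce a self-reverse-complementary matrix.
#' @param n_starts number of EM seedings (>= 1).
#' @param max_iter maximum EM iterations per start.
#' @param tol stop when the log-likelihood improvement drops below this.
#' @param seed integer seed (start selection and subsampling).
#' @param pseudocount added to every base count in every column (default 0.1,
#'   a MEME-like default that stabilizes rare columns).
#' @param max_sequences subsample cap (default 1000); `NULL` disables.
#' @return a [pwmotif()]; `score_significance` holds the log-likelihood-ratio
#'   of the fitted model against the background-only model (a relative
#'   statistic, not a MEME E-value). Attributes: `"ll_trace"` (per-iteration
#'   values of the EM objective — the data log likelihood plus the
#'   Dirichlet-smoothing term of the pseudocounted M-step, which is
#'   non-decreasing across iterations — for the winning start), `"gamma"`
#'   (fitted site probability).
#' @examples
#' cores <- c(replicate(30, paste0(
#'   paste(sample(c("A","C","G","T"), 2, TRUE), collapse = ""),
#'   "ATTGTGACACACATCACAAT",
#'   paste(sample(c("A","C","G","T"), 2, TRUE), collapse = ""))))
#' pwm <- discover_motif(cores, width = 20, n_starts = 2, seed = 1)
#' @export
discover_motif <- function(cores, width, palindromic = FALSE, n_starts = 20L,
                           max_iter = 200L, tol = 1e-6, seed = 1L,
                           pseudocount = 0.1, max_sequences = 1000L) {
  if (inherits(cores, "refined_core_set")) cores <- cores$cores
  stopifnot(is.character(cores))
  if (length(cores) == 0L) stop("empty input")
  if (any(nchar(cores) < width))
    stop("'width' exceeds the shortest input sequence")
  if (n_starts < 1L) stop("'n_starts' must be >= 1")
  set.seed(seed)
  if (!is.null(max_sequences) && length(cores) > max_sequences)
    cores <- sample(cores, max_sequences)
  n_seq <- length(cores)

  # 0-order background from the input composition
  tab <- table(factor(unlist(strsplit(cores, "", fixed = TRUE)),
                      levels = DNA_BASES))
  bg <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  names(bg) <- DNA_BASES

  win <- build_windows(cores, width)
  starts <- sample(nrow(win$X), n_starts, replace = n_starts > nrow(win$X))
  best <- NULL
  for (r in starts) {
    theta0 <- matrix(0.15, 4L, width)
    theta0[cbind(win$X[r, ], seq_len(width))] <- 0.55
    if (palindromic) {
      theta0 <- (theta0 + revcomp_matrix(theta0)) / 2
    }
    fit <- zoops_em(win, theta0, bg, n_seq, palindromic, pseudocount,
                    max_iter, tol)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }

  rownames(best$theta) <- DNA_BASES
  out <- pwmotif(best$theta, nsites = round(sum(best$q_i)), background = bg,
                 score_significance = best$data_llr)
  attr(out, "ll_trace") <- best$ll_trace
  attr(out, "gamma") <- best$gamma
  out
}

#' Derive a degenerate consensus from a letter-probability matrix
#'
#' Per column: the top base when its probability reaches
#' `single_threshold`; otherwise the two-base IUPAC code when the top two
#' probabilities sum to at least `pair_threshold`; otherwise `N`. The dyad
#' decomposition (half sites, spacer) is then read off as the maximal non-N
#' runs flanking the longest internal all-N run; when the flanks are of
#' unequal length the pattern is reported without a dyad decomposition.
#'
#' @param pwm a [pwmotif()].
#' @param single_threshold probability in `(0, 1]` for calling a single base.
#' @param pair_threshold probability in `(0, 1]` for calling a two-base code;
#'   must satisfy `single_threshold >= pair_threshold / 2`.
#' @return a [consensus_pattern()].
#' @export
consensus_from_pwm <- function(pwm, single_threshold = 0.7,
                               pair_threshold = 0.8) {
  stopifnot(inherits(pwm, "pwmotif"))
  if (!(single_threshold > 0 && single_threshold <= 1) ||
      !(pair_threshold > 0 && pair_threshold <= 1))
    stop("thresholds must be in (0, 1]")
  if (single_threshold < pair_threshold / 2)
    stop("'single_threshold' must be >= pair_threshold / 2")
  pair_code <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  chars <- apply(pwm$matrix, 2L, function(p) {
    o <- order(p, decreasing = TRUE)
    if (p[o[1L]] >= single_threshold) return(DNA_BASES[o[1L]])
    if (p[o[1L]] + p[o[2L]] >= pair_threshold) {
      key <- paste(sort(DNA_BASES[o[1:2]]), collapse = "")
      return(unname(pair_code[key]))
    }
    "N"
  })
  iupac <- paste(chars, collapse = "")

  # dyad structure: longest internal all-N run as the spacer
  r <- rle(chars == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  internal <- which(r$values & starts > 1L & ends < length(chars))
  if (length(internal)) {
    k <- internal[which.max(r$lengths[internal])]
    left <- starts[k] - 1L
    right <- length(chars) - ends[k]
    if (left == right)
      return(consensus_pattern(iupac, half_site_length = left,
                               spacer_length = r$lengths[k]))
  }
  consensus_pattern(iupac)
}

#' Per-position information content of a motif
#'
#' Against a uniform background: `2 + sum_b p_b log2 p_b` bits per column
#' (zero probabilities contribute zero). The motif's total information
#' content is the sum over columns.
#'
#' @param pwm a [pwmotif()].
#' @return numeric vector of bits, one entry per motif position.
#' @examples
#' ic <- information_content(pwm_from_consensus("ACGT", mismatch_prob = 0))
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "pwmotif"))
  apply(pwm$matrix, 2L, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
}
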