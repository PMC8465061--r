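random_pwm <- function(width) {
  m <- matrix(runif(4 * width) + 0.05, 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwmotif(m)
}

test_that("log-odds scoring matches its definition", {
  uni <- pwmotif(matrix(0.25, 4, 3,
                        dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_true(all(log_odds(uni, rep(0.25, 4)) == 0))

  det <- pwm_from_consensus("G", mismatch_prob = 0)
  lo <- log_odds(det, rep(0.25, 4))
  expect_equal(unname(lo["G", 1]), 2)

  # max-scoring word = per-column argmax concatenation (enumeration, w <= 6)
  set.seed(61)
  pwm <- random_pwm(5)
  lo <- log_odds(pwm, rep(0.25, 4))
  words <- as.matrix(expand.grid(rep(list(1:4), 5)))
  scores <- rowSums(sapply(1:5, function(j) lo[cbind(words[, j], j)]))
  best_enum <- words[which.max(scores), ]
  expect_equal(unname(best_enum), unname(apply(lo, 2, which.max)))
})

test_that("DP p-values equal brute-force enumeration for widths <= 6", {
  set.seed(62)
  for (rep in 1:20) {
    w <- sample(2:6, 1)
    bg <- runif(4) + 0.1; bg <- bg / sum(bg)
    lo <- log_odds(random_pwm(w), bg, pseudocount = 0.001)
    d <- score_pvalue_distribution(lo, bg, granularity = 200)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    ints <- rowSums(sapply(seq_len(w),
                           function(j) d$int_matrix[cbind(words[, j], j)]))
    wp <- apply(words, 1, function(x) prod(bg[x]))
    sf_bf <- vapply(0:d$max_int, function(s) sum(wp[ints >= s]), numeric(1))
    expect_equal(d$sf, sf_bf, tolerance = 1e-12)
  }
})

test_that("the survival function is a valid, monotone tail distribution", {
  set.seed(63)
  lo <- log_odds(random_pwm(8), rep(0.25, 4), pseudocount = 0.001)
  d <- score_pvalue_distribution(lo, rep(0.25, 4))
  expect_true(all(diff(d$sf) <= 1e-15))
  expect_equal(d$sf[1], 1)          # any word scores at least the minimum
  expect_gt(d$sf[length(d$sf)], 0)

  # width-1 matrix with a unique best base: p-value of the max score = 0.25
  lo1 <- log_odds(pwm_from_consensus("G", mismatch_prob = 0.03),
                  rep(0.25, 4))
  d1 <- score_pvalue_distribution(lo1, rep(0.25, 4))
  expect_equal(score_pvalue(d1, max(lo1)), 0.25)

  expect_error(score_pvalue_distribution(lo[, 0, drop = FALSE],
                                         rep(0.25, 4)), "zero-width")
})

test_that("scanning recovers planted maximal-score sites at their coordinates", {
  pwm <- pwm_from_consensus("ATTGTGACACACATCACAAT", mismatch_prob = 0.02)
  site <- "ATTGTGACACACATCACAAT"
  plants <- data.frame(sequence = site,
                       position = c(3000, 11000, 17000, 24000, 31000),
                       strand = c("+", "-", "+", "+", "-"))
  g <- generate_genome(4e4, seed = 64, planted_sites = plants)
  hits <- scan_genome(g$genome, pwm, p_threshold = 1e-4)
  top <- hits[hits$score > 30, ]
  expect_equal(sort(top$start), sort(plants$position))
  expect_identical(top$strand[order(top$start)], plants$strand)
  expect_true(all(top$matched_sequence == site))
  expect_true(all(hits$p_value <= 1e-4))
})

test_that("p_threshold = 1 reports every window on both strands", {
  set.seed(65)
  g <- Biostrings::DNAStringSet(c(chr = random_cores(1, len = 300)))
  pwm <- random_pwm(8)
  hits <- scan_genome(g, pwm, p_threshold = 1)
  expect_equal(nrow(hits), 2 * (300 - 8 + 1))
  expect_equal(attr(hits, "n_tests"), nrow(hits))
})

test_that("reverse-complementing the genome mirrors hits", {
  set.seed(66)
  g <- Biostrings::DNAStringSet(c(chr = random_cores(1, len = 500)))
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- "chr"
  pwm <- random_pwm(7)
  bg <- rep(0.25, 4)
  h1 <- scan_genome(g, pwm, p_threshold = 0.01, background = bg)
  h2 <- scan_genome(grc, pwm, p_threshold = 0.01, background = bg)
  expect_equal(nrow(h1), nrow(h2))
  key1 <- paste(h1$start, h1$strand)
  key2 <- paste(500 - h2$end + 1, ifelse(h2$strand == "+", "-", "+"))
  expect_setequal(key1, key2)
})

test_that("scanning is invariant to chunking with sufficient overlap", {
  set.seed(67)
  g <- Biostrings::DNAStringSet(c(chr = random_cores(1, len = 2000)))
  pwm <- random_pwm(9)
  bg <- rep(0.25, 4)
  full <- scan_genome(g, pwm, p_threshold = 0.01, background = bg)
  s <- as.character(g[[1]])
  chunks <- Biostrings::DNAStringSet(c(a = substr(s, 1, 1020),
                                       b = substring(s, 1001)))
  part <- scan_genome(chunks, pwm, p_threshold = 0.01, background = bg)
  part$start <- ifelse(part$seqnames == "a", part$start, part$start + 1000L)
  key_full <- sort(paste(full$start, full$strand))
  key_part <- sort(unique(paste(part$start, part$strand)))
  expect_identical(key_full, key_part)
})

test_that("q-values are a BH transform over all tested windows", {
  set.seed(68)
  g <- Biostrings::DNAStringSet(c(chr = random_cores(1, len = 1000)))
  pwm <- random_pwm(8)
  hits <- scan_genome(g, pwm, p_threshold = 0.05)
  expect_true(all(diff(hits$q_value[order(hits$p_value)]) >= -1e-15))
  expect_gte(hits$q_value[1], hits$p_value[1])
  expect_equal(hits$q_value,
               p.adjust(hits$p_value, "BH", n = attr(hits, "n_tests")))
})

test_that("promoter annotation classifies window, intragenic, far and bidirectional", {
  feats <- data.frame(seqnames = "chr",
                      start = c(500, 1100, 3000), end = c(950, 1500, 3500),
                      strand = c("-", "+", "+"),
                      gene_id = c("gA", "gB", "gC"))
  mk_hit <- function(start) data.frame(
    seqnames = "chr", start = start, end = start + 21, strand = "+",
    score = 30, p_value = 1e-8, q_value = 1e-4, matched_sequence = "X")

  # between divergent genes, within both windows -> two bidirectional calls
  div <- annotate_hits(mk_hit(1000), feats)
  expect_equal(nrow(div), 2)
  expect_setequal(div$gene_id, c("gA", "gB"))
  expect_true(all(div$bidirectional))
  expect_true(all(div$location_class == "window"))
  # offsets: negative = upstream of the gene start on its strand
  expect_equal(div$offset[div$gene_id == "gB"], 1000 - 1100)
  expect_equal(div$offset[div$gene_id == "gA"], 950 - 1021)

  # -50 from a forward gene start
  up <- annotate_hits(mk_hit(3000 - 50), feats)
  expect_equal(up$location_class, "window")
  expect_equal(up$offset, -50)
  expect_false(up$bidirectional)

  # inside a gene body, outside any window
  intra <- annotate_hits(mk_hit(3300), feats)
  expect_equal(intra$location_class, "intragenic")
  expect_equal(intra$gene_id, "gC")

  # far from everything
  far <- annotate_hits(mk_hit(8000), feats)
  expect_equal(far$location_class, "intergenic_far")
  expect_true(is.na(far$gene_id))

  # p-value gate and malformed features
  weak <- mk_hit(1000); weak$p_value <- 1e-3
  expect_equal(nrow(annotate_hits(weak, feats)), 0)
  bad <- feats; bad$end[1] <- 100
  expect_error(annotate_hits(mk_hit(1000), bad), "end < start")
})
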