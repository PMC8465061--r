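# Synthetic-data generators: selection templates and libraries, REPSA rounds,
# sequencing reads, test genomes, sensorgrams and REPA band intensities.

#' Selection template design
#'
#' Describes the fixed architecture of a selection template: a randomized
#' core flanked by defined primer sequences that carry the type IIS
#' restriction endonuclease (IISRE) recognition sites. The default design is
#' a 73-bp template with a 24-bp randomized core, a 25-nt left flank
#' containing a FokI recognition site (GGATG) and a 24-nt right flank
#' containing a BpmI recognition site on the bottom strand (CTCCAG on the
#' forward strand), so that either enzyme cleaves within the randomized core
#' unless a bound protein blocks it.
#'
#' @param left_flank,right_flank defined flanking sequences (DNA strings).
#' @param core_length length of the randomized core (default 24).
#' @return An object of class `selection_template` with fields `left_flank`,
#'   `core_length`, `right_flank` and `total_length`.
#' @examples
#' selection_template()
#' @export
selection_template <- function(left_flank = "GTAATACGACTCACTATAGGGATGC",
                               right_flank = "CTCCAGCTTACGGTAGCACGCATC",
                               core_length = 24L) {
  stopifnot(nchar(left_flank) >= 1L, nchar(right_flank) >= 1L,
            core_length >= 1L)
  structure(
    list(left_flank = toupper(left_flank),
         core_length = as.integer(core_length),
         right_flank = toupper(right_flank),
         total_length = nchar(left_flank) + core_length + nchar(right_flank)),
    class = "selection_template"
  )
}

#' @export
print.selection_template <- function(x, ...) {
  cat("selection_template:", x$total_length, "bp =",
      nchar(x$left_flank), "nt flank +", x$core_length, "nt random core +",
      nchar(x$right_flank), "nt flank\n")
  invisible(x)
}

#' Construct a selection library
#'
#' A weighted multiset of equal-length randomized cores together with the
#' selection round that produced it. Duplicate core strings in `cores` are
#' aggregated into counts.
#'
#' @param cores character vector of equal-length DNA core sequences.
#' @param counts positive integer multiplicities, one per core (default 1).
#' @param round_index selection round that produced the library (0 = naive).
#' @return An object of class `selection_library` with fields `cores`
#'   (unique strings), `counts` and `round_index`.
#' @export
selection_library <- function(cores, counts = NULL, round_index = 0L) {
  stopifnot(is.character(cores))
  if (length(cores) > 0 && length(unique(nchar(cores))) != 1L)
    stop("all cores must have the same length")
  if (is.null(counts)) counts <- rep(1L, length(cores))
  stopifnot(length(counts) == length(cores), all(counts >= 1))
  if (anyDuplicated(cores)) {
    agg <- rowsum(as.numeric(counts), group = cores, reorder = FALSE)
    cores <- rownames(agg)
    counts <- as.integer(agg[, 1L])
  }
  structure(list(cores = cores, counts = as.integer(counts),
                 round_index = as.integer(round_index)),
            class = "selection_library")
}

#' @export
print.selection_library <- function(x, ...) {
  cat("selection_library: round", x$round_index, "|",
      library_size(x), "templates |", length(x$cores), "unique cores\n")
  invisible(x)
}

#' Total number of template molecules in a library
#' @param lib a [selection_library()].
#' @return integer sum of core counts.
#' @export
library_size <- function(lib) sum(lib$counts)

#' Expand a library to one core string per molecule
#' @param lib a [selection_library()].
#' @return character vector of length `library_size(lib)`.
#' @export
expand_cores <- function(lib) rep(lib$cores, lib$counts)

#' Generate a naive selection library
#'
#' Draws `n_templates` cores i.i.d. uniform over `{A,C,G,T}^core_length`,
#' emulating the randomized cassette of the starting selection pool.
#'
#' @param n_templates number of template molecules (>= 1).
#' @param core_length randomized core length (default 24).
#' @param seed integer seed; the draw is reproducible under it.
#' @return a [selection_library()] at `round_index = 0`.
#' @examples
#' lib <- generate_library(100, seed = 1)
#' @export
generate_library <- function(n_templates, core_length = 24L, seed = 1L) {
  if (!is.numeric(n_templates) || n_templates < 1)
    stop("'n_templates' must be >= 1")
  if (!is.numeric(core_length) || core_length < 1)
    stop("'core_length' must be >= 1")
  set.seed(seed)
  selection_library(random_dna(as.integer(n_templates),
                               as.integer(core_length)),
                    round_index = 0L)
}

#' Sequence-to-affinity model for selection simulation
#'
#' Maps a core sequence to a dissociation constant through a planted "true"
#' motif: the core is scored with the motif's log2-odds matrix (uniform
#' background), taking the best-scoring window on either strand, and
#' \deqn{K_D(seq) = kd_{min} \exp(\beta (s_{max} - s(seq)))}
#' where `s_max` is the maximal attainable score. `kd_min` is the affinity of
#' a maximal-score sequence and `beta` controls how steeply affinity decays
#' per log-odds unit of score deficit; K_D is monotone non-increasing in
#' score.
#'
#' @param pwm a [pwmotif()]: the planted motif.
#' @param kd_min dissociation constant (nM) at the maximal score (> 0).
#' @param beta energy slope per log2-odds unit (>= 0).
#' @return an object of class `affinity_model`.
#' @examples
#' aff <- affinity_model(pwm_from_consensus("AWTGTRANNNNNNTYACAWT"),
#'                       kd_min = 3, beta = 1)
#' @export
affinity_model <- function(pwm, kd_min, beta) {
  stopifnot(inherits(pwm, "pwmotif"))
  if (!is.numeric(kd_min) || kd_min <= 0) stop("'kd_min' must be > 0")
  if (!is.numeric(beta) || beta < 0) stop("'beta' must be >= 0")
  sc <- log2(pmax(pwm$matrix, .Machine$double.xmin) / 0.25)
  structure(list(pwm = pwm, kd_min = kd_min, beta = beta,
                 score_matrix = sc, s_max = sum(apply(sc, 2, max))),
            class = "affinity_model")
}

#' Per-core dissociation constants under an affinity model
#'
#' @param aff an [affinity_model()].
#' @param cores character vector of equal-length cores (length >= motif
#'   width).
#' @return list with `score` (best log2-odds window score per core, either
#'   strand) and `kd` (nM).
#' @export
affinity_kd <- function(aff, cores) {
  stopifnot(inherits(aff, "affinity_model"))
  idx <- dna_index_matrix(cores)
  if (ncol(idx) < ncol(aff$score_matrix))
    stop("cores shorter than the motif width")
  s <- best_window_score(idx, aff$score_matrix)
  list(score = s, kd = aff$kd_min * exp(aff$beta * (aff$s_max - s)))
}

#' REPSA round configuration
#'
#' Per-round selection conditions. `protein_conc` and `cleavage_efficiency`
#' are recycled to `rounds` values, so an enzyme switch (e.g. FokI for rounds
#' 1-2, BpmI for rounds 3-5) is expressed purely as per-round cleavage
#' efficiencies; enzyme identity carries no sequence specificity here.
#'
#' @param protein_conc protein concentration (nM, dimer) per round.
#' @param cleavage_efficiency probability in `[0, 1]` that a protein-free
#'   template is cut, per round.
#' @param rounds number of selection rounds.
#' @param enzyme_schedule character label per round (default FokI for the
#'   first two rounds, BpmI after, mirroring common practice of switching
#'   enzymes to avoid cleavage-resistant artifacts).
#' @param pcr_resampling_depth library size restored by PCR resampling after
#'   each round.
#' @param seed integer master seed for the run.
#' @return an object of class `repsa_config`.
#' @export
repsa_config <- function(protein_conc = 34, cleavage_efficiency = 0.9,
                         rounds = 5L,
                         enzyme_schedule = NULL,
                         pcr_resampling_depth = 1e5, seed = 1L) {
  rounds <- as.integer(rounds)
  stopifnot(rounds >= 1L)
  protein_conc <- rep_len(protein_conc, rounds)
  cleavage_efficiency <- rep_len(cleavage_efficiency, rounds)
  if (any(protein_conc < 0)) stop("'protein_conc' must be >= 0")
  if (any(cleavage_efficiency < 0 | cleavage_efficiency > 1))
    stop("'cleavage_efficiency' must be in [0, 1]")
  if (is.null(enzyme_schedule))
    enzyme_schedule <- ifelse(seq_len(rounds) <= 2L, "FokI", "BpmI")
  enzyme_schedule <- rep_len(enzyme_schedule, rounds)
  structure(list(protein_conc = protein_conc,
                 cleavage_efficiency = cleavage_efficiency,
                 rounds = rounds, enzyme_schedule = enzyme_schedule,
                 pcr_resampling_depth = as.integer(pcr_resampling_depth),
                 seed = as.integer(seed)),
            class = "repsa_config")
}

#' Simulate one REPSA selection round
#'
#' Each template is bound with occupancy `theta = C / (C + K_D(core))` at the
#' round's protein concentration `C`; its survival probability against IISRE
#' cleavage is `theta + (1 - theta) * (1 - cleavage_efficiency)`. Survivors
#' are drawn binomially per unique core, then PCR amplification is emulated
#' by multinomial resampling with replacement back to
#' `pcr_resampling_depth` molecules. The number of survivors before
#' resampling never exceeds the input library size.
#'
#' @param lib a non-empty [selection_library()].
#' @param aff an [affinity_model()].
#' @param cfg a [repsa_config()].
#' @param round which configured round to apply (default
#'   `lib$round_index + 1`).
#' @return a [selection_library()] with `round_index` incremented; the
#'   attribute `"repsa_stats"` records input size, survivor count and mean
#'   best-window motif scores before/after selection.
#' @examples
#' aff <- affinity_model(pwm_from_consensus("AWTGTRANNNNNNTYACAWT"),
#'                       kd_min = 3, beta = 1)
#' lib <- generate_library(500, seed = 2)
#' r1 <- simulate_repsa_round(lib, aff, repsa_config(pcr_resampling_depth = 500))
#' @export
simulate_repsa_round <- function(lib, aff, cfg,
                                 round = lib$round_index + 1L) {
  stopifnot(inherits(lib, "selection_library"),
            inherits(aff, "affinity_model"),
            inherits(cfg, "repsa_config"))
  if (length(lib$cores) == 0L) stop("input library is empty")
  round <- as.integer(round)
  if (round < 1L || round > cfg$rounds)
    stop("'round' must be between 1 and cfg$rounds")
  C <- cfg$protein_conc[round]
  ce <- cfg$cleavage_efficiency[round]
  if (C < 0) stop("negative protein concentration")

  set.seed(cfg$seed + 7919L * round)
  ak <- affinity_kd(aff, lib$cores)
  theta <- C / (C + ak$kd)
  surv_p <- theta + (1 - theta) * (1 - ce)
  survivors <- rbinom(length(lib$counts), lib$counts, surv_p)
  n_in <- library_size(lib)
  n_surv <- sum(survivors)
  mean_in <- sum(ak$score * lib$counts) / n_in

  if (n_surv == 0L) {
    out <- selection_library(character(0), integer(0),
                             round_index = round)
    attr(out, "repsa_stats") <- list(round = round, n_input = n_in,
                                     n_survivors = 0L,
                                     mean_score_in = mean_in,
                                     mean_score_out = NA_real_)
    return(out)
  }

  keep <- survivors > 0L
  new_counts <- as.integer(
    rmultinom(1L, cfg$pcr_resampling_depth, prob = survivors[keep])
  )
  nz <- new_counts > 0L
  out <- selection_library(lib$cores[keep][nz], new_counts[nz],
                           round_index = round)
  sc_out <- ak$score[keep][nz]
  attr(out, "repsa_stats") <- list(
    round = round, n_input = n_in, n_survivors = n_surv,
    mean_score_in = mean_in,
    mean_score_out = sum(sc_out * new_counts[nz]) / sum(new_counts[nz])
  )
  out
}

#' Run a full REPSA selection
#'
#' Applies [simulate_repsa_round()] for every configured round.
#'
#' @inheritParams simulate_repsa_round
#' @return list of class `repsa_run`: `libraries` (the input library followed
#'   by one library per round) and `stats` (per-round data frame with
#'   survivor counts and mean motif scores).
#' @export
run_repsa <- function(lib, aff, cfg) {
  libs <- vector("list", cfg$rounds + 1L)
  libs[[1L]] <- lib
  stats <- vector("list", cfg$rounds)
  for (r in seq_len(cfg$rounds)) {
    libs[[r + 1L]] <- simulate_repsa_round(libs[[r]], aff, cfg, round = r)
    stats[[r]] <- as.data.frame(attr(libs[[r + 1L]], "repsa_stats"))
    if (length(libs[[r + 1L]]$cores) == 0L && r < cfg$rounds)
      stop("library went extinct at round ", r)
  }
  structure(list(libraries = libs, stats = do.call(rbind, stats)),
            class = "repsa_run")
}

#' Fraction of library molecules whose core matches an IUPAC consensus
#'
#' Counts molecules (weighted by multiplicity) whose core contains at least
#' one zero-mismatch match to the degenerate consensus on either strand.
#'
#' @param lib a [selection_library()].
#' @param iupac consensus string over IUPAC codes.
#' @return fraction in `[0, 1]`.
#' @export
consensus_match_fraction <- function(lib, iupac) {
  stopifnot(inherits(lib, "selection_library"))
  if (length(lib$cores) == 0L) return(NA_real_)
  x <- Biostrings::DNAStringSet(lib$cores)
  hit <- Biostrings::vcountPattern(iupac, x, fixed = FALSE) +
    Biostrings::vcountPattern(iupac, Biostrings::reverseComplement(x),
                              fixed = FALSE)
  sum(lib$counts[hit > 0L]) / library_size(lib)
}

#' Sample concrete sequences consistent with an IUPAC consensus
#'
#' Each position draws uniformly from the bases allowed by its IUPAC code
#' (`N` = any base).
#'
#' @param iupac consensus string over IUPAC codes.
#' @param n number of realizations.
#' @return character vector of length `n`; every element has
#'   `iupac_mismatches(x, iupac) == 0`.
#' @examples
#' set.seed(1); sample_from_iupac("AWTGTRANNNNNNTYACAWT", 3)
#' @export
sample_from_iupac <- function(iupac, n) {
  sets <- iupac_sets()
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(sets))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  m <- vapply(chars, function(ch) sample(sets[[ch]], n, replace = TRUE),
              character(n))
  if (n == 1L) paste0(m, collapse = "") else collapse_rows(m)
}

#' Plant consensus-consistent sites into a fraction of cores
#'
#' Overwrites a random window (random offset, random strand) of a
#' `prevalence` fraction of the cores with a fresh realization of the
#' degenerate consensus, emulating a library in which that fraction of
#' molecules carries a binding site.
#'
#' @param cores character vector of equal-length cores.
#' @param iupac consensus string over IUPAC codes (not longer than the
#'   cores).
#' @param prevalence fraction of cores receiving a site.
#' @param seed integer seed.
#' @return character vector of modified cores.
#' @export
plant_consensus_sites <- function(cores, iupac, prevalence = 0.8,
                                  seed = 1L) {
  stopifnot(is.character(cores), is_probability(prevalence))
  L <- unique(nchar(cores))
  if (length(L) != 1L) stop("all cores must have the same length")
  w <- nchar(iupac)
  if (w > L) stop("consensus longer than the cores")
  set.seed(seed)
  pick <- which(runif(length(cores)) < prevalence)
  if (!length(pick)) return(cores)
  sites <- sample_from_iupac(iupac, length(pick))
  flip <- runif(length(pick)) < 0.5
  sites[flip] <- revcomp_chr(sites[flip])
  off <- sample.int(L - w + 1L, length(pick), replace = TRUE)
  cores[pick] <- paste0(substr(cores[pick], 1L, off - 1L), sites,
                        substring(cores[pick], off + w))
  cores
}

#' Simulate sequencing reads from a selection library
#'
#' Each molecule yields one read `left_flank + core + right_flank` with
#' i.i.d. substitution errors at `error_rate`; a `flank_corruption_rate`
#' fraction of reads additionally lose a random 5' prefix (truncated left
#' flank). Base qualities are constant at the stated Phred value, giving a
#' thresholdable quality signal without modelling platform-specific error
#' profiles.
#'
#' @param lib a [selection_library()].
#' @param error_rate per-base substitution probability in `[0, 1]`.
#' @param flank_corruption_rate fraction of reads with a truncated 5' flank.
#' @param seed integer seed.
#' @param template a [selection_template()].
#' @param phred constant per-base Phred quality (default 30).
#' @return a [Biostrings::QualityScaledDNAStringSet] (Sanger Phred+33).
#' @examples
#' reads <- reads_from_library(generate_library(10, seed = 1), seed = 1)
#' @export
reads_from_library <- function(lib, error_rate = 0,
                               flank_corruption_rate = 0, seed = 1L,
                               template = selection_template(),
                               phred = 30L) {
  stopifnot(inherits(lib, "selection_library"),
            inherits(template, "selection_template"))
  if (!is_probability(error_rate) || !is_probability(flank_corruption_rate))
    stop("rates must be probabilities in [0, 1]")
  if (length(lib$cores) > 0L &&
      nchar(lib$cores[1L]) != template$core_length)
    stop("library core length does not match the template design")
  set.seed(seed)
  cores <- expand_cores(lib)
  n <- length(cores)
  reads <- paste0(template$left_flank, cores, template$right_flank)
  L <- template$total_length

  if (error_rate > 0 && n > 0) {
    idx <- dna_index_matrix(reads)
    n_err <- rbinom(1L, n * L, error_rate)
    if (n_err > 0) {
      cells <- sample.int(n * L, n_err)
      idx[cells] <- ((idx[cells] - 1L + sample(1:3, n_err, replace = TRUE))
                     %% 4L) + 1L
      reads <- collapse_rows(matrix(DNA_BASES[idx], nrow = n))
    }
  }

  if (flank_corruption_rate > 0 && n > 0) {
    corrupt <- which(runif(n) < flank_corruption_rate)
    if (length(corrupt)) {
      # drop a prefix reaching into the left anchor region
      drop <- sample(seq.int(5L, nchar(template$left_flank)),
                     length(corrupt), replace = TRUE)
      reads[corrupt] <- substring(reads[corrupt], drop + 1L)
    }
  }

  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- sprintf("read_%06d", seq_len(n))
  qual <- Biostrings::PhredQuality(
    strrep(intToUtf8(as.integer(phred) + 33L), nchar(reads))
  )
  Biostrings::QualityScaledDNAStringSet(dna, qual)
}

#' Write / read FASTQ (Sanger Phred+33)
#'
#' Thin wrappers over Biostrings FASTQ I/O so pipeline stages and the CLI
#' share one code path.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path file path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` returns a
#'   `QualityScaledDNAStringSet`.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # benign container-conversion notice emitted while attaching qualities
      if (grepl("metadata columns on input DNAStringSet",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Write / read FASTA
#'
#' @param x a `DNAStringSet` or named character vector of sequences.
#' @param path file path.
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` returns a
#'   `DNAStringSet`.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(x)
    if (is.null(names(x))) names(x) <- sprintf("seq_%d", seq_along(x))
  }
  if (is.null(names(x))) names(x) <- sprintf("seq_%d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Generate a synthetic genome with planted motif sites
#'
#' Background bases are drawn i.i.d. at the stated GC content; planted
#' sequences are then written at their stated positions (for strand `-` the
#' reverse complement is written on the forward strand). A feature table of
#' non-overlapping ORFs on both strands, including at least one divergent
#' gene pair, is generated alongside for promoter-annotation tests.
#'
#' @param length genome length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param planted_sites `NULL` or a data frame with columns `sequence`,
#'   `position` (1-based start on the forward strand) and `strand`
#'   (`"+"`/`"-"`). Plants must fit inside the genome and must not overlap.
#' @param seed integer seed.
#' @param gene_length,intergenic ranges (length-2 integer vectors) from which
#'   ORF lengths and intergenic gaps are drawn.
#' @return list with `genome` (a named `DNAStringSet` of length 1) and
#'   `features` (a `GRanges` with a `gene_id` column, `type = "gene"`).
#' @examples
#' g <- generate_genome(5000, seed = 3,
#'        planted_sites = data.frame(sequence = "ATTGTGACACACATCACAAT",
#'                                   position = 1000, strand = "+"))
#' @export
generate_genome <- function(length, gc = 0.5, planted_sites = NULL,
                            seed = 1L, gene_length = c(300L, 900L),
                            intergenic = c(100L, 300L)) {
  stopifnot(length >= 1, is_probability(gc))
  set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(DNA_BASES, length, replace = TRUE, prob = prob)

  if (!is.null(planted_sites) && nrow(planted_sites) > 0) {
    ps <- planted_sites
    stopifnot(all(c("sequence", "position", "strand") %in% names(ps)))
    starts <- as.integer(ps$position)
    ends <- starts + nchar(ps$sequence) - 1L
    if (any(starts < 1L) || any(ends > length))
      stop("planted sites must fit inside the genome")
    o <- order(starts)
    if (any(starts[o][-1L] <= ends[o][-length(ends)]))
      stop("planted sites must not overlap")
    for (i in seq_len(nrow(ps))) {
      s <- toupper(ps$sequence[i])
      if (ps$strand[i] == "-") s <- revcomp_chr(s)
      bases[starts[i]:ends[i]] <- strsplit(s, "", fixed = TRUE)[[1L]]
    }
  }

  genome <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(genome) <- "synthetic_genome"

  # non-overlapping ORFs with one guaranteed divergent pair (- then +)
  pos <- sample(seq.int(intergenic[1L], intergenic[2L]), 1L)
  gs <- ge <- integer(0)
  strand <- character(0)
  i <- 0L
  while (TRUE) {
    glen <- sample(seq.int(gene_length[1L], gene_length[2L]), 1L)
    if (pos + glen - 1L > length) break
    i <- i + 1L
    gs <- c(gs, pos); ge <- c(ge, pos + glen - 1L)
    strand <- c(strand, if (i == 2L) "-" else if (i == 3L) "+"
                        else sample(c("+", "-"), 1L))
    pos <- pos + glen + sample(seq.int(intergenic[1L], intergenic[2L]), 1L)
  }
  features <- GenomicRanges::GRanges(
    seqnames = "synthetic_genome",
    ranges = IRanges::IRanges(start = gs, end = ge),
    strand = strand
  )
  features$type <- "gene"
  features$gene_id <- sprintf("gene_%04d", seq_along(features))
  list(genome = genome, features = features)
}

#' Write / read a GFF3 feature table (1-based, inclusive)
#'
#' @param features a `GRanges` with a `gene_id` metadata column.
#' @param path file path.
#' @return `write_features_gff3()` returns `path` invisibly;
#'   `read_features_gff3()` returns a `GRanges`.
#' @export
write_features_gff3 <- function(features, path) {
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
read_features_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Simulate 1:1 binding sensorgrams
#'
#' Noise-free traces follow the closed-form 1:1 Langmuir
#' association-then-dissociation model (see [model_response()]); Gaussian
#' noise of `noise_sd` response units is added on top.
#'
#' @param kon association rate constant (1/(M*s), > 0).
#' @param koff dissociation rate constant (1/s, > 0).
#' @param rmax maximal response (response units, > 0).
#' @param concs analyte concentrations in nM.
#' @param t_assoc,t_dissoc association and dissociation durations (s).
#' @param dt sampling interval (s).
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return tidy data frame with columns `concentration_nM`, `time_s`,
#'   `response`; attribute `"t_switch"` records the phase boundary.
#' @examples
#' sg <- simulate_sensorgram(4.6e5, 1.6e-3, 1, concs = c(5.7, 17, 51),
#'                           t_assoc = 300, t_dissoc = 300, dt = 5)
#' @export
simulate_sensorgram <- function(kon, koff, rmax, concs = c(5.7, 17, 51, 153,
                                                           461),
                                t_assoc = 300, t_dissoc = 300, dt = 1,
                                noise_sd = 0, seed = 1L) {
  if (any(c(kon, koff, rmax) <= 0))
    stop("'kon', 'koff' and 'rmax' must be > 0")
  stopifnot(t_assoc > 0, t_dissoc >= 0, dt > 0, noise_sd >= 0)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  out <- do.call(rbind, lapply(concs, function(C) {
    data.frame(concentration_nM = C, time_s = times,
               response = model_response(kon, koff, rmax, C, times,
                                         t_switch = t_assoc))
  }))
  if (noise_sd > 0) {
    set.seed(seed)
    out$response <- out$response + rnorm(nrow(out), sd = noise_sd)
  }
  attr(out, "t_switch") <- t_assoc
  out
}

#' Simulate REPA cleavage-protection band intensities
#'
#' For each protein concentration the probe's uncleaved fraction is
#' `theta + (1 - theta) * (1 - cleavage_efficiency)` with occupancy
#' `theta = C / (C + kd)`; the control probe carries no binding site
#' (`kd = Inf`), so its uncleaved fraction is `1 - cleavage_efficiency`
#' in every lane. Fractions are scaled to `total_intensity` and optionally
#' perturbed with truncated Gaussian noise.
#'
#' @param kd probe dissociation constant (nM); `Inf` means no binding.
#' @param concs protein concentrations (nM).
#' @param cleavage_efficiency probability a protein-free probe is cut.
#' @param total_intensity total band intensity per lane and probe.
#' @param noise_sd Gaussian intensity noise (same units as
#'   `total_intensity`).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return data frame with columns `concentration_nM`, `probe_uncleaved`,
#'   `probe_cleaved`, `control_uncleaved`, `control_cleaved`.
#' @examples
#' simulate_repa_bands(100, concs = c(62.5, 125, 250, 500, 1000))
#' @export
simulate_repa_bands <- function(kd, concs, cleavage_efficiency = 0.9,
                                total_intensity = 1000, noise_sd = 0,
                                seed = 1L) {
  stopifnot(kd > 0, all(concs >= 0),
            is_probability(cleavage_efficiency), total_intensity > 0)
  theta <- concs / (concs + kd)
  uf_probe <- theta + (1 - theta) * (1 - cleavage_efficiency)
  uf_ctrl <- rep(1 - cleavage_efficiency, length(concs))
  out <- data.frame(
    concentration_nM = concs,
    probe_uncleaved = uf_probe * total_intensity,
    probe_cleaved = (1 - uf_probe) * total_intensity,
    control_uncleaved = uf_ctrl * total_intensity,
    control_cleaved = (1 - uf_ctrl) * total_intensity
  )
  if (noise_sd > 0) {
    set.seed(seed)
    cols <- 2:5
    out[cols] <- lapply(out[cols],
                        function(x) pmax(0, x + rnorm(length(x),
                                                      sd = noise_sd)))
  }
  out
}
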