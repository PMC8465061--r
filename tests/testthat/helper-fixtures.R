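# Shared fixtures, built in code at test time.

CONSENSUS <- "AWTGTRANNNNNNTYACAWT"

random_cores <- function(n, len = 24L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
}

# cores of which `prevalence` carry a planted consensus-consistent site
planted_cores <- function(n, prevalence = 0.8, seed = 1L, len = 24L,
                          consensus = CONSENSUS) {
  plant_consensus_sites(random_cores(n, len, seed = seed + 5000L),
                        consensus, prevalence, seed = seed)
}

# printed kinetic rate constants of the determinate probe rows (Table-style
# wild-type/mutant series), used by kinetics tests
DETERMINATE_RATES <- data.frame(
  name = c("wt", "wt_p2", "wt_p3", "wt_p6", "wt_p7", "CRP_Ec"),
  kon = c(457555, 317173, 215769, 288341, 267033, 726387),
  koff = c(0.001577, 0.01166, 0.01867, 0.02153, 0.006236, 0.0007341),
  stringsAsFactors = FALSE
)

PROBE_SEQUENCES <- c(
  wt    = "ATTGTGACACACATCACAAT",
  wt_p1 = "CTTGTGACACACATCACAAT",
  wt_p2 = "AGTGTGACACACATCACAAT",
  wt_p3 = "ATGGTGACACACATCACAAT",
  wt_p4 = "ATTTTGACACACATCACAAT",
  wt_p5 = "ATTGGGACACACATCACAAT",
  wt_p6 = "ATTGTTACACACATCACAAT",
  wt_p7 = "ATTGTGGCACACATCACAAT",
  wt_s5 = "ATTGTGACACACTCACAAT",
  wt_s7 = "ATTGTGACACACACTCACAAT"
)
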