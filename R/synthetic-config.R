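# Simulation configuration for the synthetic-data module.

#' Default target-site position weight matrix
#'
#' A 9-column PWM over the 3-bp target-site duplication plus 3-bp flanks
#' whose IUPAC consensus (at frequency threshold 0.25) is the
#' PIF/Harbinger-type string given in `consensus`. Bases belonging to the
#' degenerate code of a column share probability 0.9; the remaining bases
#' share 0.1.
#'
#' @param consensus IUPAC string defining the per-column admissible bases.
#' @return a 4 x nchar(consensus) column-stochastic matrix with rownames
#'   A, C, G, T.
#' @export
default_site_pwm <- function(consensus = "MWYTWARWK") {
  code_bases <- c(A = "A", C = "C", G = "G", T = "T",
                  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
                  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT")
  cols <- str_bases(toupper(consensus))
  if (!all(cols %in% names(code_bases))) stop("invalid IUPAC code in consensus")
  pwm <- vapply(cols, function(cc) {
    inset <- DNA_BASES %in% str_bases(code_bases[[cc]])
    p <- numeric(4)
    p[inset] <- 0.9 / sum(inset)
    if (any(!inset)) p[!inset] <- 0.1 / sum(!inset)
    p
  }, numeric(4))
  rownames(pwm) <- DNA_BASES
  pwm
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults
#' mirroring the melon system: 12 chromosomes, 150-bp reads, a
#' PIF/Harbinger element with TIR `GGGCCCGTTTG` and a 3-bp TAA-type target
#' site duplication, ~34 evidence reads per insertion locus split over two
#' replicates, 282 reference plus 50 new insertions, an 81-wild /
#' 480-cultivated accession panel, and a recessive single-locus F2 bulk
#' design with 10 plants per bulk.
#'
#' @param ... overrides for any default field (unknown names are an error).
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # genome
    n_contigs = 12L, contig_length = 200000L, gc = 0.38, n_genes = 240L,
    gene_length_range = c(1500L, 4000L), exons_per_gene = c(1L, 4L),
    # element
    te_length = 430L, tir = "GGGCCCGTTTG", tsd = "TAA",
    site_pwm = default_site_pwm(), flank = 3L,
    # insertions & reads
    n_reference_insertions = 282L, n_new_insertions = 50L,
    n_replicates = 2L, junction_reads = 9L, discordant_pairs = 8L,
    background_pairs = 200L, read_length = 150L, base_error_rate = 0.001,
    min_clip = 25L, max_insert = 500L,
    # chromatin
    signal_baseline = 1, signal_noise_sd = 0.5, signal_effect = 2,
    track_bin = 100L, meth_baseline = c(CG = 0.85, CHG = 0.55, CHH = 0.10),
    meth_effect = c(CG = 0, CHG = -0.30, CHH = -0.08),
    meth_depth = 20L, cytosine_rate = 0.05, chromatin_flank = 3000L,
    # population
    n_wild = 81L, n_cultivated = 480L,
    n_reference_loci = 182L, n_informative_loci = 333L,
    shared_presence = 0.97, freq_high = 0.8, freq_low = 0.1,
    singleton_rate_wild = 2.0, singleton_rate_cultivated = 0.8,
    # BSA
    bsa_n_contigs = 12L, bsa_contig_length = 2e7, bsa_causal_contig = 8L,
    bsa_causal_pos = 1.8e7, bsa_snps_per_contig = 500L, bsa_depth = 100L,
    cm_per_mb = 4, n_plants_per_bulk = 10L, pool_model = "plants"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("sim_config(): unknown field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  counts <- c("n_contigs", "contig_length", "n_genes", "te_length",
              "n_reference_insertions", "n_new_insertions", "n_replicates",
              "junction_reads", "discordant_pairs", "background_pairs",
              "read_length", "meth_depth", "n_wild", "n_cultivated",
              "bsa_snps_per_contig", "bsa_depth", "n_plants_per_bulk")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0)) {
      stop("sim_config(): field '", f, "' must be a non-negative number")
    }
  }
  probs <- c(cfg$gc, cfg$base_error_rate, cfg$shared_presence,
             cfg$freq_high, cfg$freq_low, cfg$cytosine_rate,
             cfg$meth_baseline)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config(): probabilities must lie in [0, 1]")
  }
  pwm <- cfg$site_pwm
  if (!is.matrix(pwm) || nrow(pwm) != 4 ||
      any(abs(colSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    stop("sim_config(): site_pwm columns must be probabilities summing to 1")
  }
  if (grepl("[^ACGT]", cfg$tir)) stop("sim_config(): tir must be over ACGT")
  if (!cfg$pool_model %in% c("plants", "expected")) {
    stop("sim_config(): pool_model must be 'plants' or 'expected'")
  }
  cfg
}
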