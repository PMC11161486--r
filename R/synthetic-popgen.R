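# Simulation of presence/absence insertion matrices over wild and
# cultivated accession panels, of F2 bulk allele depths under a recessive
# single-locus model, and of F2 phenotype segregation.

#' Simulate a two-group presence/absence insertion matrix
#'
#' Three locus strata mirror the germplasm analysis: reference-class loci
#' present in nearly all accessions (`shared_presence`), non-reference
#' group-informative loci whose carrier frequency is `freq_high` in one
#' group and `freq_low` in the other (direction alternating), and singleton
#' loci each carried by exactly one accession, drawn per accession at
#' Poisson rates `singleton_rate_wild` / `singleton_rate_cultivated`.
#' Non-singleton loci are guaranteed at least two carriers so that the
#' singleton ("new") classification matches the generated truth exactly.
#'
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to `config$seed + 31`).
#' @return list with `matrix` (accessions x loci, 0/1), `loci` (locus_id,
#'   contig, position, truth_class, truth_new), `groups` (named character
#'   vector, "wild"/"cultivated"), and `reference_annotation` (BED-style
#'   data frame of the reference-class insertion positions).
#' @export
simulate_population_matrix <- function(config = sim_config(),
                                       seed = config$seed + 31L) {
  if (config$n_wild < 2 || config$n_cultivated < 2) {
    stop("simulate_population_matrix(): need >= 2 accessions per group")
  }
  n_fixed <- config$n_reference_loci + config$n_informative_loci
  if (n_fixed == 0) stop("simulate_population_matrix(): zero loci requested")
  acc <- c(sprintf("W%03d", seq_len(config$n_wild)),
           sprintf("C%03d", seq_len(config$n_cultivated)))
  groups <- stats::setNames(rep(c("wild", "cultivated"),
                                c(config$n_wild, config$n_cultivated)), acc)
  n_acc <- length(acc)
  with_seed(seed, {
    cols <- list()
    meta <- list()
    add_locus <- function(col, class, new) {
      cols[[length(cols) + 1L]] <<- col
      meta[[length(meta) + 1L]] <<- c(class, new)
    }
    for (i in seq_len(config$n_reference_loci)) {
      col <- stats::rbinom(n_acc, 1L, config$shared_presence)
      add_locus(col, "reference", FALSE)
    }
    for (i in seq_len(config$n_informative_loci)) {
      wild_high <- i %% 2L == 1L
      p <- ifelse(groups == "wild",
                  if (wild_high) config$freq_high else config$freq_low,
                  if (wild_high) config$freq_low else config$freq_high)
      col <- stats::rbinom(n_acc, 1L, p)
      # enforce >= 2 carriers so no informative locus masquerades as new
      while (sum(col) < 2L) col[sample.int(n_acc, 1L)] <- 1L
      add_locus(col, "non_reference", FALSE)
    }
    rate <- ifelse(groups == "wild", config$singleton_rate_wild,
                   config$singleton_rate_cultivated)
    n_single <- stats::rpois(n_acc, rate)
    for (a in seq_len(n_acc)) {
      for (s in seq_len(n_single[a])) {
        col <- integer(n_acc)
        col[a] <- 1L
        add_locus(col, "non_reference", TRUE)
      }
    }
    mat <- do.call(cbind, cols)
    meta <- do.call(rbind, meta)
    n_loci <- ncol(mat)
    # scatter loci across synthetic chromosome coordinates, well separated
    contigs <- sprintf("chr%d", sample.int(config$n_contigs, n_loci,
                                           replace = TRUE))
    pos <- integer(n_loci)
    for (cn in unique(contigs)) {
      idx <- which(contigs == cn)
      pos[idx] <- sort(sample.int(config$contig_length %/% 1000L,
                                  length(idx)) * 1000L)
    }
    locus_id <- sprintf("L%04d", seq_len(n_loci))
    rownames(mat) <- acc
    colnames(mat) <- locus_id
    loci <- data.frame(locus_id = locus_id, contig = contigs, position = pos,
                       truth_class = meta[, 1L],
                       truth_new = as.logical(meta[, 2L]),
                       stringsAsFactors = FALSE)
    ref <- loci[loci$truth_class == "reference", , drop = FALSE]
    list(matrix = mat, loci = loci, groups = groups,
         reference_annotation = data.frame(contig = ref$contig,
                                           start = ref$position,
                                           end = ref$position + 1L,
                                           stringsAsFactors = FALSE))
  })
}

# Haldane map: centimorgans -> recombination fraction.
haldane_r <- function(cm) 0.5 * (1 - exp(-2 * cm / 100))

#' Simulate bulk-segregant allele depths for a recessive F2 design
#'
#' One biallelic causal locus; the mutant bulk pools homozygous-recessive
#' F2 plants, the phenotypically wild-type bulk pools AA and Aa plants in
#' their Mendelian 1:2 ratio. Each SNP's expected mutant-allele frequency
#' follows the recombination fraction to the causal locus under a Haldane
#' map at `cm_per_mb`; SNPs on other contigs are unlinked (r = 1/2). With
#' `pool_model = "plants"` the pool allele frequency is realized from
#' `n_plants_per_bulk` simulated plants per bulk before binomial read
#' sampling at fixed depth; `"expected"` uses the expected frequency
#' directly (zero overdispersion).
#'
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to `config$seed + 41`).
#' @return data.frame with contig, pos, ref, alt, ad_mut_ref, ad_mut_alt,
#'   ad_wt_ref, ad_wt_alt; the alt allele is the mutant-linked allele.
#' @export
simulate_bsa_pools <- function(config = sim_config(),
                               seed = config$seed + 41L) {
  if (config$bsa_depth <= 0) stop("simulate_bsa_pools(): depth must be > 0")
  with_seed(seed, {
    snps <- do.call(rbind, lapply(seq_len(config$bsa_n_contigs), function(i) {
      pos <- sort(sample.int(config$bsa_contig_length,
                             config$bsa_snps_per_contig))
      data.frame(contig = sprintf("chr%d", i), pos = pos,
                 stringsAsFactors = FALSE)
    }))
    causal_contig <- sprintf("chr%d", config$bsa_causal_contig)
    # guarantee a SNP exactly at the causal position
    if (!any(snps$contig == causal_contig & snps$pos == config$bsa_causal_pos)) {
      snps <- rbind(snps, data.frame(contig = causal_contig,
                                     pos = as.integer(config$bsa_causal_pos)))
      snps <- snps[order(snps$contig, snps$pos), ]
    }
    n <- nrow(snps)
    linked <- snps$contig == causal_contig
    cm <- config$cm_per_mb * abs(snps$pos - config$bsa_causal_pos) / 1e6
    r <- ifelse(linked, haldane_r(cm), 0.5)
    depth <- config$bsa_depth
    if (config$pool_model == "expected") {
      f_mut <- 1 - r
      f_wt <- (1 + r) / 3
    } else {
      f_mut <- pool_freq_mutant(r, config$n_plants_per_bulk)
      f_wt <- pool_freq_wildtype(r, config$n_plants_per_bulk)
    }
    alleles <- t(vapply(seq_len(n), function(i) sample(DNA_BASES, 2L),
                        character(2)))
    ad_mut_alt <- stats::rbinom(n, depth, f_mut)
    ad_wt_alt <- stats::rbinom(n, depth, f_wt)
    data.frame(contig = snps$contig, pos = snps$pos,
               ref = alleles[, 1L], alt = alleles[, 2L],
               ad_mut_ref = depth - ad_mut_alt, ad_mut_alt = ad_mut_alt,
               ad_wt_ref = depth - ad_wt_alt, ad_wt_alt = ad_wt_alt,
               stringsAsFactors = FALSE)
  })
}

# Realized mutant-allele pool frequency in the mutant (aa) bulk: both
# gametes of every plant carry the recessive causal allele; each transmits
# the linked marker allele with probability 1 - r.
pool_freq_mutant <- function(r, n_plants) {
  vapply(r, function(ri) {
    dosage <- stats::rbinom(n_plants, 2L, 1 - ri)
    mean(dosage) / 2
  }, numeric(1))
}

# Realized frequency in the phenotypically wild-type bulk (AA:Aa = 1:2):
# a gamete carrying the recessive allele transmits the marker allele with
# probability 1 - r, a gamete carrying the dominant allele with
# probability r.
pool_freq_wildtype <- function(r, n_plants) {
  vapply(r, function(ri) {
    n_het <- stats::rbinom(1L, n_plants, 2 / 3)
    dosage <- c(stats::rbinom(n_het, 1L, 1 - ri) + stats::rbinom(n_het, 1L, ri),
                stats::rbinom(n_plants - n_het, 2L, ri))
    mean(dosage) / 2
  }, numeric(1))
}

#' Simulate F2 phenotype segregation under single-locus recessive inheritance
#'
#' Selfed-F1 Mendelian genotype draws (1 AA : 2 Aa : 1 aa); homozygous
#' recessive plants are scored androecious, all others andromonoecious.
#'
#' @param n_plants F2 population size.
#' @param seed integer seed.
#' @return list with counts `n_dominant` (non-androecious) and
#'   `n_recessive` (androecious).
#' @export
simulate_f2_phenotypes <- function(n_plants = 200L, seed = 1L) {
  with_seed(seed, {
    n_rec <- sum(stats::rbinom(n_plants, 2L, 0.5) == 0L)
    list(n_dominant = n_plants - n_rec, n_recessive = n_rec)
  })
}

#' Average F2 segregation ratio over seeded replicates
#'
#' @param n_plants F2 population size per replicate.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return mean over replicates of the non-androecious : androecious count
#'   ratio (replicates with zero recessive plants are excluded; at n = 200
#'   this is a ~1e-25 probability event).
#' @export
f2_segregation_ratio <- function(n_plants = 200L, n_reps = 1000L, seed = 1L) {
  with_seed(seed, {
    ratios <- vapply(seq_len(n_reps), function(i) {
      n_rec <- sum(stats::rbinom(n_plants, 2L, 0.5) == 0L)
      if (n_rec == 0) return(NA_real_)
      (n_plants - n_rec) / n_rec
    }, numeric(1))
    mean(ratios, na.rm = TRUE)
  })
}
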