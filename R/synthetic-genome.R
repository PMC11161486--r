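# Seeded simulation of a genome, gene models, and PWM-biased insertion
# sites. All generators are pure functions of (config, seed): calling them
# twice with the same arguments yields identical output.

#' Simulate a genome with non-overlapping gene models
#'
#' Generates `n_contigs` i.i.d. random contigs at the configured GC
#' fraction and places `n_genes` non-overlapping genes (both strands, 1 or
#' more exons each) uniformly across them.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (a `genome_sequence`) and `models`
#'   (a `gene_models`).
#' @export
simulate_genome <- function(config = sim_config()) {
  with_seed(config$seed, {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(seq_len(config$n_contigs), function(i) {
      paste(sample(DNA_BASES, config$contig_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("chr%d", seq_len(config$n_contigs))
    genome <- as_genome(seqs)
    models <- place_genes(genome, config)
    list(genome = genome, models = models)
  })
}

# Greedy non-overlapping gene placement; errors when the genome cannot hold
# the requested gene count.
place_genes <- function(genome, config) {
  n <- config$n_genes
  if (n == 0) return(gene_models(empty_gene_df(), empty_exon_df()))
  lens <- contig_lengths(genome)
  genes <- vector("list", n)
  occupied <- lapply(lens, function(...) empty_df(start = integer(),
                                                  end = integer()))
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > n * 200L) {
      stop("simulate_genome(): cannot place ", n,
           " non-overlapping genes on this genome")
    }
    ci <- sample(length(lens), 1L, prob = lens)
    glen <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
    if (lens[ci] <= glen) next
    start <- sample.int(lens[ci] - glen, 1L) - 1L
    occ <- occupied[[ci]]
    if (any(start < occ$end & start + glen > occ$start)) next
    occupied[[ci]] <- rbind(occ, data.frame(start = start, end = start + glen))
    placed <- placed + 1L
    genes[[placed]] <- data.frame(
      gene_id = sprintf("gene%04d", placed), contig = names(lens)[ci],
      start = start, end = start + glen,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    k <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
    glen <- genes$end[i] - genes$start[i]
    # split the gene into 2k-1 blocks, odd blocks are exons
    cuts <- sort(sample.int(glen - 1L, 2L * k - 2L))
    bounds <- c(0L, cuts, glen)
    idx <- seq(1L, 2L * k - 1L, by = 2L)
    data.frame(gene_id = genes$gene_id[i], contig = genes$contig[i],
               start = genes$start[i] + bounds[idx],
               end = genes$start[i] + bounds[idx + 1L],
               stringsAsFactors = FALSE)
  })
  gene_models(genes, do.call(rbind, exons))
}

#' Simulate a TE consensus sequence
#'
#' A random interior flanked by the configured terminal inverted repeat:
#' the element starts with `tir` and ends with its reverse complement.
#'
#' @param config a [sim_config()].
#' @return single uppercase DNA string of length `config$te_length`.
#' @export
simulate_te <- function(config = sim_config()) {
  tlen <- nchar(config$tir)
  if (config$te_length < 2 * tlen + 10) {
    stop("simulate_te(): te_length too short for the TIRs")
  }
  with_seed(config$seed + 7L, {
    interior <- paste(sample(DNA_BASES, config$te_length - 2L * tlen,
                             replace = TRUE), collapse = "")
    paste0(config$tir, interior, revcomp(config$tir))
  })
}

# Per-position PWM likelihood of the width-w window starting at each
# admissible position of one contig (0-based window starts). N bases get
# likelihood 0.
pwm_window_likelihood <- function(seq, pwm) {
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  code <- match(str_bases(seq), DNA_BASES)  # NA for N
  nstart <- n - w + 1L
  lik <- rep(1, nstart)
  for (j in seq_len(w)) {
    b <- code[j:(j + nstart - 1L)]
    pj <- pwm[, j][b]
    pj[is.na(pj)] <- 0
    lik <- lik * pj
  }
  lik
}

#' Draw insertion sites biased by a target-site PWM
#'
#' Sites are breakpoints (0-based): the insertion duplicates the
#' `tsd_len`-bp target site beginning at the breakpoint, and the PWM scores
#' the `tsd_len + 2*flank` window around it (window start = breakpoint -
#' flank). Positions are sampled with probability proportional to the PWM
#' likelihood of their window, with no two accepted sites closer than
#' `min_spacing` and none nearer than `edge` to a contig end.
#'
#' @param genome a `genome_sequence`.
#' @param n number of sites to draw.
#' @param pwm 4 x width column-stochastic matrix (rows A,C,G,T).
#' @param seed integer seed.
#' @param tsd_len,flank window geometry (defaults give 9-nt windows).
#' @param min_spacing minimum distance between accepted sites.
#' @param edge minimum distance from contig ends.
#' @return data.frame with columns contig, breakpoint, strand.
#' @export
draw_insertion_sites <- function(genome, n, pwm, seed, tsd_len = 3L,
                                 flank = 3L, min_spacing = 300L,
                                 edge = 300L) {
  check_genome(genome)
  if (n == 0) {
    return(empty_df(contig = character(), breakpoint = integer(),
                    strand = character()))
  }
  w <- ncol(pwm)
  stopifnot(w == tsd_len + 2L * flank)
  lens <- contig_lengths(genome)
  lik <- lapply(names(genome), function(cn) {
    l <- pwm_window_likelihood(unclass(genome)[[cn]], pwm)
    # window start s corresponds to breakpoint s + flank; mask edges
    bp <- seq_along(l) - 1L + flank
    l[bp < edge | bp > lens[[cn]] - edge] <- 0
    l
  })
  contig_of <- rep(seq_along(lik), lengths(lik))
  bp_of <- unlist(lapply(lik, function(l) seq_along(l) - 1L)) + flank
  wts <- unlist(lik)
  if (sum(wts > 0) < n) stop("draw_insertion_sites(): too few admissible sites")
  with_seed(seed, {
    cum <- cumsum(wts)
    accepted <- integer(0)
    guard <- 0L
    while (length(accepted) < n) {
      guard <- guard + 1L
      if (guard > 200L) {
        stop("draw_insertion_sites(): cannot place ", n,
             " sites at spacing ", min_spacing)
      }
      k <- max(2L * (n - length(accepted)), 32L)
      draws <- findInterval(stats::runif(k, 0, cum[length(cum)]), cum) + 1L
      for (d in draws) {
        if (wts[d] == 0) next
        near <- abs(bp_of[accepted] - bp_of[d]) < min_spacing &
          contig_of[accepted] == contig_of[d]
        if (!any(near)) {
          accepted <- c(accepted, d)
          if (length(accepted) == n) break
        }
      }
    }
    data.frame(contig = names(genome)[contig_of[accepted]],
               breakpoint = bp_of[accepted],
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
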