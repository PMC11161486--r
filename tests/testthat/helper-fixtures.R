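# Shared fixtures and independent oracles, all built in code.

# Tiny deterministic genome from explicit sequences.
tiny_genome <- function(...) {
  seqs <- c(...)
  piftools:::as_genome(seqs)
}

# Random ACGT string.
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One SAM alignment row in the package-internal representation.
sam_row <- function(qname = "r1", flag = 0L, rname = "c1", pos = 0L,
                    mapq = 60L, cigar = "100M", rnext = "*", pnext = -1L,
                    seq = strrep("A", 100L)) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             seq = seq, stringsAsFactors = FALSE)
}

# Brute-force Hamming scan oracle for TIR matching (independent of
# Biostrings): per-window mismatch counts accumulated position by position
# over every window of |tir| bases on both strands.
brute_tir_scan <- function(genome, tir, max_mismatch) {
  w <- nchar(tir)
  rc <- piftools::revcomp(tir)
  out <- list()
  for (cn in names(genome)) {
    s <- unclass(genome)[[cn]]
    n <- nchar(s)
    if (n < w) next
    ch <- strsplit(s, "")[[1]]
    nstart <- n - w + 1L
    for (strand in c("+", "-")) {
      pat <- strsplit(if (strand == "+") tir else rc, "")[[1]]
      mm <- integer(nstart)
      for (j in seq_len(w)) {
        mm <- mm + (ch[j:(j + nstart - 1L)] != pat[j])
      }
      hit <- which(mm <= max_mismatch)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = cn, start = hit - 1L, end = hit - 1L + w, strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (oracle for small n).
exact_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2L, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Permutation oracle for the two-proportion test: condition on the table
# margins and resample the group-1 success count hypergeometrically,
# comparing |z| of the resampled tables to the observed |z|. The mid-p
# convention (half weight on resampled tables tying the observed one) is
# the standard target when checking a continuous approximation against a
# discrete permutation distribution.
permutation_ztest_p <- function(k1, n1, k2, n2, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  zstat <- function(k1, k2) {
    p1 <- k1 / n1
    p2 <- k2 / n2
    pp <- (k1 + k2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    ifelse(se == 0, 0, (p1 - p2) / se)
  }
  obs <- abs(zstat(k1, k2))
  k <- k1 + k2
  k1s <- stats::rhyper(n_perm, n1, n2, k)
  zs <- abs(zstat(k1s, k - k1s))
  mean(zs > obs + 1e-12) + 0.5 * mean(abs(zs - obs) <= 1e-12)
}

# Random binary tree with positive branch lengths and its additive
# (cophenetic) distance matrix.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
}

# Default-geometry TED-seq simulation at reduced scale, shared by caller
# tests.
small_tedseq <- function(seed = 11, n_ref = 6, n_new = 6, error = 0,
                         n_contigs = 4, contig_length = 60000) {
  cfg <- piftools::sim_config(
    seed = seed, n_contigs = n_contigs, contig_length = contig_length,
    n_genes = 0, n_reference_insertions = n_ref, n_new_insertions = n_new,
    junction_reads = 4, discordant_pairs = 4, background_pairs = 40,
    base_error_rate = error)
  g <- piftools::simulate_genome(cfg)
  te <- piftools::simulate_te(cfg)
  sites <- piftools::draw_insertion_sites(g$genome, n_ref + n_new,
                                          cfg$site_pwm, seed = seed + 1)
  truth <- sites
  truth$category <- rep(c("reference", "new"), c(n_ref, n_new))
  reps <- piftools::simulate_junction_alignments(g$genome, te, truth, cfg)
  ref_bed <- data.frame(contig = truth$contig[truth$category == "reference"],
                        start = truth$breakpoint[truth$category == "reference"],
                        end = truth$breakpoint[truth$category == "reference"] + 1L)
  list(cfg = cfg, genome = g$genome, te = te, truth = truth, reps = reps,
       ref_bed = ref_bed)
}
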