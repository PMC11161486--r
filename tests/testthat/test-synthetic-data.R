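test_that("genome simulation is deterministic and respects the config", {
  cfg <- sim_config(seed = 1, n_contigs = 12, contig_length = 20000,
                    n_genes = 24)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$models, g2$models)
  expect_length(g1$genome, 12L)
  expect_true(all(contig_lengths(g1$genome) == 20000L))

  g0 <- simulate_genome(sim_config(seed = 2, n_contigs = 2,
                                   contig_length = 20000, n_genes = 0))
  expect_equal(nrow(g0$models$genes), 0L)

  # genes do not overlap and carry at least one exon each
  genes <- g1$models$genes
  for (cn in unique(genes$contig)) {
    gc <- genes[genes$contig == cn, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) expect_true(all(diff_ok <- gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  expect_true(all(table(g1$models$exons$gene_id) >= 1))
  expect_setequal(unique(genes$strand), c("+", "-"))
})

test_that("site drawing follows the PWM sampling law", {
  g <- simulate_genome(sim_config(seed = 5, n_contigs = 2,
                                  contig_length = 150000, n_genes = 0))$genome
  # uniform PWM: sites uniform over admissible positions
  uni <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  sites <- draw_insertion_sites(g, 10000, uni, seed = 3, min_spacing = 1,
                                edge = 100)
  # chi-square GoF over 30 equal-width position bins per contig
  pos <- sites$breakpoint
  bins <- cut(pos, breaks = seq(100, 150000 - 100, length.out = 31))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)

  # degenerate PWM concentrated on one 9-mer draws only that window;
  # plant the 9-mer sparsely in an A-homopolymer background so it exists
  fixed <- "ACGTCCGTA"
  planted <- paste(rep(c(strrep("A", 491), fixed), 40), collapse = "")
  gp <- tiny_genome(p1 = planted)
  pw <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:9) pw[substr(fixed, j, j), j] <- 1
  s2 <- draw_insertion_sites(gp, 5, pw, seed = 4, min_spacing = 1, edge = 100)
  # minus-strand sites report the reverse-complemented window
  w <- extract_site_windows(gp, s2)
  expect_true(all(ifelse(s2$strand == "+", w == fixed,
                         w == revcomp(fixed))))

  expect_equal(nrow(draw_insertion_sites(g, 0, uni, seed = 1)), 0L)
  expect_error(draw_insertion_sites(g, 1e7, uni, seed = 1),
               "admissible|cannot place")
})

test_that("junction alignments place clip boundaries at truth breakpoints", {
  fx <- small_tedseq(seed = 21, n_ref = 1, n_new = 0, error = 0)
  reads <- fx$reps$rep1
  sc <- reads[grepl("S", reads$cigar), ]
  expect_gt(nrow(sc), 0)
  for (i in seq_len(nrow(sc))) {
    cg <- piftools:::parse_cigar(sc$cigar[i])
    bp <- if (cg$op[1] == "S") sc$pos[i]
          else sc$pos[i] + piftools:::cigar_ref_length(sc$cigar[i])
    expect_equal(bp, fx$truth$breakpoint[1])
  }
  # leading-clip reads end their clipped bases with the element terminus
  lead <- sc[grepl("^[0-9]+S", sc$cigar), ][1, ]
  clen <- piftools:::parse_cigar(lead$cigar)$len[1]
  clipped <- substr(lead$seq, 1, clen)
  ins_seq <- if (fx$truth$strand[1] == "+") fx$te else revcomp(fx$te)
  expect_equal(clipped,
               substr(ins_seq, nchar(ins_seq) - clen + 1, nchar(ins_seq)))
})

test_that("background-only alignments carry no TE-matching clips", {
  cfg <- sim_config(seed = 9, n_contigs = 2, contig_length = 30000,
                    n_genes = 0, background_pairs = 60, base_error_rate = 0)
  g <- simulate_genome(cfg)
  te <- simulate_te(cfg)
  truth <- data.frame(contig = character(), breakpoint = integer(),
                      strand = character())
  reps <- simulate_junction_alignments(g$genome, te, truth, cfg)
  ev <- extract_softclip_evidence(reps$rep1, te)
  expect_equal(nrow(ev), 0L)
  dc <- extract_discordant_evidence(reps$rep1)
  expect_equal(nrow(dc), 0L)
})

test_that("chromatin simulation shifts only new sites and keeps counts sane", {
  cfg <- sim_config(seed = 13, n_contigs = 2, contig_length = 100000,
                    n_genes = 0, signal_effect = 0, cytosine_rate = 0.02)
  g <- simulate_genome(cfg)
  sites <- sample_random_sites(g$genome, 20, seed = 2)
  truth <- data.frame(contig = sites$contig, breakpoint = sites$breakpoint,
                      category = "new")
  chr <- simulate_chromatin_tracks(g$genome, truth, cfg)
  expect_true(all(chr$methylation$total >= chr$methylation$meth))
  # zero effect: new-site and random-site profiles agree within noise
  rand <- sample_random_sites(g$genome, 20, seed = 3)
  pn <- profile_signal(truth, chr$track, g$genome)
  pr <- profile_signal(rand, chr$track, g$genome)
  expect_lt(abs(mean(pn$bins) - mean(pr$bins)), 0.15)

  cfg2 <- sim_config(seed = 13, n_contigs = 2, contig_length = 100000,
                     n_genes = 0, signal_effect = 2, cytosine_rate = 0.02)
  chr2 <- simulate_chromatin_tracks(g$genome, truth, cfg2)
  pn2 <- profile_signal(truth, chr2$track, g$genome)
  expect_gt(mean(pn2$bins) - mean(pr$bins), 1.5)
})

test_that("population matrix simulation honors singleton structure", {
  cfg <- sim_config(seed = 17, n_wild = 8, n_cultivated = 12,
                    n_reference_loci = 20, n_informative_loci = 30,
                    singleton_rate_wild = 0, singleton_rate_cultivated = 0)
  pop <- simulate_population_matrix(cfg)
  expect_true(all(colSums(pop$matrix) >= 2))
  expect_false(any(pop$loci$truth_new))

  pop2 <- simulate_population_matrix(cfg)
  expect_identical(pop$matrix, pop2$matrix)

  cfg3 <- sim_config(seed = 18, n_wild = 8, n_cultivated = 12,
                     n_reference_loci = 10, n_informative_loci = 10,
                     singleton_rate_wild = 2, singleton_rate_cultivated = 0.5)
  pop3 <- simulate_population_matrix(cfg3)
  single <- pop3$loci$truth_new
  expect_true(all(colSums(pop3$matrix[, single, drop = FALSE]) == 1L))
  expect_error(simulate_population_matrix(
    sim_config(n_wild = 1, n_cultivated = 5)), ">= 2")
})

test_that("BSA pools follow the recessive F2 expectations", {
  # zero-overdispersion, huge depth: indices approach 1 and 1/3 at the
  # causal SNP, 1/2 each far away
  cfg <- sim_config(seed = 19, bsa_n_contigs = 2, bsa_causal_contig = 1,
                    bsa_causal_pos = 5e6, bsa_contig_length = 2e7,
                    bsa_snps_per_contig = 50, bsa_depth = 200000,
                    pool_model = "expected")
  snps <- simulate_bsa_pools(cfg)
  d <- delta_snp_index(snps)
  at_causal <- d[d$contig == "chr1" & d$pos == 5e6, ]
  expect_equal(at_causal$index_mut, 1, tolerance = 0.01)
  expect_equal(at_causal$index_wt, 1 / 3, tolerance = 0.01)
  expect_equal(at_causal$delta, 2 / 3, tolerance = 0.02)
  unlinked <- d[d$contig == "chr2", ]
  expect_equal(mean(unlinked$index_mut), 0.5, tolerance = 0.01)
  expect_equal(mean(unlinked$delta), 0, tolerance = 0.01)
  # AD counts sum to the configured depth
  expect_true(all(snps$ad_mut_ref + snps$ad_mut_alt == cfg$bsa_depth))
  expect_true(all(snps$ad_wt_ref + snps$ad_wt_alt == cfg$bsa_depth))
  expect_error(simulate_bsa_pools(sim_config(bsa_depth = 0)), "depth")
})

test_that("F2 phenotype simulation reproduces 3:1 segregation", {
  f2 <- simulate_f2_phenotypes(200, seed = 4)
  expect_equal(f2$n_dominant + f2$n_recessive, 200L)
  ratio <- f2_segregation_ratio(200, n_reps = 500, seed = 4)
  expect_equal(ratio, 3, tolerance = 0.1)
})
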