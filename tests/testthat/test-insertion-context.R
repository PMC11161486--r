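test_that("site windows cover TSD plus flanks with strand handling", {
  g <- tiny_genome(c1 = "AAAACGTTAGGCATTTTT")
  calls <- data.frame(contig = "c1", breakpoint = 5L, strand = "+")
  # window = [2, 11): 3-bp flank, 3-bp TSD starting at the breakpoint
  expect_equal(extract_site_windows(g, calls), "AACGTTAGG")
  expect_equal(nchar(extract_site_windows(g, calls)), 9L)

  minus <- data.frame(contig = "c1", breakpoint = 5L, strand = "-")
  expect_equal(extract_site_windows(g, minus), revcomp("AACGTTAGG"))

  # boundary windows are dropped; all-dropped is an error
  edge <- data.frame(contig = "c1", breakpoint = c(2L, 5L), strand = "+")
  expect_message(w <- extract_site_windows(g, edge), "dropped 1")
  expect_length(w, 1L)
  expect_error(suppressMessages(extract_site_windows(
    g, data.frame(contig = "c1", breakpoint = 1L, strand = "+"))), "all")
})

test_that("PFM counting and consensus follow the IUPAC definitions", {
  pfm <- build_pfm(c("AC", "AG"))
  expect_equal(unclass(pfm)[, 1], c(A = 2L, C = 0L, G = 0L, T = 0L))
  expect_equal(unclass(pfm)[, 2], c(A = 0L, C = 1L, G = 1L, T = 0L))
  expect_error(build_pfm(c("AC", "ACG")), "unequal")
  expect_error(build_pfm(character(0)), "no usable")

  expect_equal(pfm_consensus(build_pfm(c("A", "C"))), "M")
  # base sets {A,C},{A,T},{C,T},{T},{A,T},{A},{A,G},{A,T},{G,T}
  seqs <- c("AATTAAAAG", "CTCTTAGTT")
  expect_equal(pfm_consensus(build_pfm(seqs)), "MWYTWARWK")
  # uniform column at the threshold: all four bases pass, giving N
  expect_equal(pfm_consensus(build_pfm(c("A", "C", "G", "T"))), "N")
  # no base reaching the threshold also gives N
  pfm5 <- build_pfm(c("A", "A", "C", "C", "G", "G", "T", "T", "A", "C",
                      "G", "T", "A", "C", "G", "T", "A", "C", "G", "T"))
  expect_equal(pfm_consensus(pfm5, min_freq = 0.4), "N")

  # consensus invariant under sequence duplication
  s <- c("ACGTACGTA", "TTGTAAGTA", "ACTTAAGTG")
  expect_equal(pfm_consensus(build_pfm(rep(s, 3))),
               pfm_consensus(build_pfm(s)))

  # sampled sequences recover the generating PWM frequencies
  pw <- default_site_pwm("MWYTWARWK")
  set.seed(8)
  seqs <- vapply(1:1000, function(i) {
    paste(apply(pw, 2, function(p) sample(c("A", "C", "G", "T"), 1,
                                          prob = p)), collapse = "")
  }, character(1))
  freq <- unclass(build_pfm(seqs)) / 1000
  expect_lt(max(abs(freq - pw)), 4 * sqrt(0.45 * 0.55 / 1000))
})

test_that("genomic context classification uses the stated priority", {
  models <- gene_models(
    genes = data.frame(gene_id = c("g1", "g2"), contig = "c1",
                       start = c(5000L, 7500L), end = c(7000L, 9500L),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("g1", "g1", "g2"), contig = "c1",
                       start = c(5000L, 6500L, 9000L),
                       end = c(5600L, 7000L, 9500L), stringsAsFactors = FALSE))
  cls <- function(bp) classify_genomic_context(
    data.frame(contig = "c1", breakpoint = bp), models)$classes
  expect_equal(cls(4500L), "promoter")       # 500 bp upstream of + gene TSS
  expect_equal(cls(6000L), "intron")
  expect_equal(cls(5100L), "exon")
  # exon of g1 also in g2's promoter region (g2 is -, promoter at end 9500+):
  # inside g1 exon at 6900 while within 2 kb upstream of nothing; instead use
  # a breakpoint in g2's exon that is also downstream: priority exon wins
  expect_equal(cls(9100L), "exon")
  expect_equal(cls(10000L), "promoter")      # - strand gene: upstream = end side
  expect_equal(cls(200L), "intergenic")

  none <- gene_models(piftools:::empty_gene_df(), piftools:::empty_exon_df())
  out <- classify_genomic_context(data.frame(contig = "c1",
                                             breakpoint = c(1L, 2L)), none)
  expect_equal(out$classes, c("intergenic", "intergenic"))
  expect_equal(out$counts$n_total, 2L)
})

test_that("two-proportion z-test matches the pooled formula and skips zeros", {
  eq <- two_proportion_ztest(5, 10, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_true(is.na(two_proportion_ztest(0, 10, 3, 10)$p))
  expect_true(is.na(two_proportion_ztest(3, 10, 0, 10)$p))

  # hand-computed pooled-variance value
  z <- two_proportion_ztest(9, 10, 1, 10)
  pp <- 0.5
  expect_equal(z$z, (0.9 - 0.1) / sqrt(pp * (1 - pp) * (2 / 10)))

  # permutation oracle agreement on a couple of tables
  for (tab in list(c(9, 10, 1, 10), c(20, 50, 30, 50))) {
    zp <- two_proportion_ztest(tab[1], tab[2], tab[3], tab[4])$p
    pp <- permutation_ztest_p(tab[1], tab[2], tab[3], tab[4], seed = 5)
    expect_lt(abs(zp - pp), 0.05)
  }
})

test_that("signal profiles are binned, truncated and linear", {
  g <- tiny_genome(c1 = strrep("A", 20000))
  const <- data.frame(contig = "c1", start = 0L, end = 20000L, value = 2.5)
  sites <- data.frame(contig = "c1", breakpoint = c(5000L, 12000L))
  p <- profile_signal(sites, const, g)
  expect_equal(p$n_bins, 60L)
  expect_true(all(abs(p$bins - 2.5) < 1e-12))

  p6 <- profile_signal(sites, const, g, flank = 300, bin_width = 100)
  expect_equal(p6$n_bins, 6L)

  # contig-end truncation leaves the out-of-range bins undefined
  edge_site <- data.frame(contig = "c1", breakpoint = 1000L)
  pe <- profile_signal(edge_site, const, g)
  expect_true(all(is.na(pe$per_site[1, 1:20])))
  expect_true(all(!is.na(pe$per_site[1, 21:60])))

  # linearity: profile(a*f + b*g) = a*profile(f) + b*profile(g)
  set.seed(3)
  mk_track <- function() data.frame(contig = "c1",
                                    start = seq(0L, 19900L, by = 100L),
                                    end = seq(100L, 20000L, by = 100L),
                                    value = rnorm(200))
  f <- mk_track(); h <- mk_track()
  combo <- f; combo$value <- 2 * f$value + 3 * h$value
  lhs <- profile_signal(sites, combo, g)$bins
  rhs <- 2 * profile_signal(sites, f, g)$bins +
    3 * profile_signal(sites, h, g)$bins
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(profile_signal(sites[0, ], const, g), "no sites")
})

test_that("methylation profiles filter by context and coverage", {
  g <- tiny_genome(c1 = strrep("A", 10000))
  sites <- data.frame(contig = "c1", breakpoint = 5000L)
  meth <- data.frame(contig = "c1",
                     pos = c(4000L, 4050L, 4100L, 6000L),
                     context = c("CG", "CG", "CHH", "CG"),
                     meth = c(10L, 10L, 0L, 5L),
                     total = c(10L, 10L, 10L, 0L))
  p <- profile_methylation(sites, meth, "CG")
  # fully methylated CG cytosines: their bin is exactly 1
  expect_equal(p$per_site[1, (4000 - 2000) %/% 100 + 1], 1)
  # the CHH record and the zero-coverage record contribute nothing
  expect_true(is.na(p$per_site[1, (4100 - 2000) %/% 100 + 1]))
  expect_true(is.na(p$per_site[1, (6000 - 2000) %/% 100 + 1]))
  expect_error(profile_methylation(sites, meth, "CPG"), "context")
})

test_that("random control sites are seeded and respect edge margins", {
  g <- tiny_genome(c1 = strrep("A", 20000), c2 = strrep("C", 20000))
  s1 <- sample_random_sites(g, 50, seed = 6)
  s2 <- sample_random_sites(g, 50, seed = 6)
  expect_identical(s1, s2)
  lens <- contig_lengths(g)
  expect_true(all(s1$breakpoint >= 3000 &
                    s1$breakpoint < lens[s1$contig] - 3000))
  expect_false(any(duplicated(paste(s1$contig, s1$breakpoint))))
  expect_equal(nrow(sample_random_sites(g, 0, seed = 1)), 0L)
  expect_error(sample_random_sites(g, 1e6, seed = 1), "insufficient")
})

test_that("profile comparison matches the exact Wilcoxon for small n", {
  mk_prof <- function(v) structure(list(bins = v, n_bins = length(v),
                                        n_sites = 1L), class = "profile_matrix")
  set.seed(12)
  for (rep in 1:5) {
    a <- rnorm(7); b <- rnorm(7) + rep / 4
    res <- compare_profiles(mk_prof(a), mk_prof(b))
    expect_equal(res$p, exact_wilcoxon_p(a, b), tolerance = 1e-10)
  }
  # identical profiles are not distinguishable
  v <- rnorm(60)
  expect_equal(compare_profiles(mk_prof(v), mk_prof(v))$p, 1, tolerance = 0.01)
  # complete separation attains the minimal normal-approximation p
  res <- compare_profiles(mk_prof(v), mk_prof(v + 10))
  expect_lt(res$p, 1e-15)
  expect_equal(unname(res$W), 0)
  expect_error(compare_profiles(mk_prof(c(1, NA)), mk_prof(c(NA, 2))),
               "fewer than 2")
})
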