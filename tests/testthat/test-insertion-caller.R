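# The TE fixture used throughout: leading clips must match a terminus of
# this sequence for evidence to count.
TE <- paste0("GGGCCCGTTTG", strrep("A", 40), "CAAACGGGCCC")

test_that("soft-clip evidence follows the breakpoint conventions", {
  te5 <- substr(TE, 1, 20)                      # TE 5' terminal 20-mer
  te3 <- substr(TE, nchar(TE) - 19, nchar(TE))  # TE 3' terminal 20-mer

  # leading clip: breakpoint at alignment start, side left
  r <- sam_row(pos = 1000L, cigar = "20S80M", seq = paste0(te3, rand_dna(80)))
  ev <- extract_softclip_evidence(r, TE)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$breakpoint, 1000L)
  expect_equal(ev$side, "left")

  # trailing clip: breakpoint at alignment end = pos + 80
  r2 <- sam_row(pos = 1000L, cigar = "80M20S", seq = paste0(rand_dna(80), te5))
  ev2 <- extract_softclip_evidence(r2, TE)
  expect_equal(ev2$breakpoint, 1080L)
  expect_equal(ev2$side, "right")

  # no clip, no evidence
  expect_equal(nrow(extract_softclip_evidence(
    sam_row(cigar = "100M"), TE)), 0L)

  # clip that does not match the TE is rejected
  r3 <- sam_row(pos = 1000L, cigar = "20S80M",
                seq = paste0(strrep("T", 20), rand_dna(80)))
  expect_equal(nrow(extract_softclip_evidence(r3, TE)), 0L)

  # mismatch tolerance: 2 errors in a 20-mer pass at 10%, 3 fail
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(k)] <- ifelse(ch[seq_len(k)] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  r4 <- sam_row(pos = 0L, cigar = "20S80M", seq = paste0(mut(te3, 2), rand_dna(80)))
  expect_equal(nrow(extract_softclip_evidence(r4, TE)), 1L)
  r5 <- sam_row(pos = 0L, cigar = "20S80M", seq = paste0(mut(te3, 3), rand_dna(80)))
  expect_equal(nrow(extract_softclip_evidence(r5, TE)), 0L)
})

test_that("discordant evidence requires a TE-mapped mate", {
  # forward genome read, mate on TE: window downstream of the read end
  r <- sam_row(flag = 1L + 32L, pos = 500L, cigar = "100M",
               rnext = "AndroPIF", pnext = 10L)
  ev <- extract_discordant_evidence(r, "AndroPIF", max_insert = 500)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$interval_start, 600L)
  expect_equal(ev$interval_end, 1100L)

  # reverse genome read: window upstream
  rr <- sam_row(flag = 1L + 16L, pos = 2000L, cigar = "100M",
                rnext = "AndroPIF", pnext = 10L)
  evr <- extract_discordant_evidence(rr, "AndroPIF", max_insert = 500)
  expect_equal(c(evr$interval_start, evr$interval_end), c(1500L, 2000L))

  # proper genome pair: no evidence
  pp <- sam_row(flag = 1L + 2L + 32L, rnext = "c1", pnext = 300L)
  expect_equal(nrow(extract_discordant_evidence(pp, "AndroPIF")), 0L)

  # mate unmapped: not attributable to the TE
  mu <- sam_row(flag = 1L + 8L, rnext = "*", pnext = -1L)
  expect_equal(nrow(extract_discordant_evidence(mu, "AndroPIF")), 0L)

  # unpaired read: skipped
  up <- sam_row(flag = 0L, rnext = "AndroPIF", pnext = 10L)
  expect_equal(nrow(extract_discordant_evidence(up, "AndroPIF")), 0L)
})

test_that("clustering uses single linkage and the modal breakpoint", {
  mk_sc <- function(bps, reads = paste0("r", seq_along(bps))) {
    data.frame(read = reads, class = rep("softclip", length(bps)),
               contig = rep("c1", length(bps)), breakpoint = bps,
               side = rep("left", length(bps)),
               te_end = rep("5'", length(bps)),
               replicate = rep("rep1", length(bps)), stringsAsFactors = FALSE)
  }
  no_dc <- data.frame(read = character(), class = character(),
                      contig = character(), interval_start = integer(),
                      interval_end = integer(), replicate = character())
  cl <- cluster_evidence(mk_sc(c(1000L, 1000L, 1000L, 1002L)), no_dc, 50L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$breakpoint, 1000L)

  # modal tie resolves to the smaller coordinate
  cl_tie <- cluster_evidence(mk_sc(c(1002L, 1000L, 1002L, 1000L)), no_dc, 50L)
  expect_equal(cl_tie$breakpoint, 1000L)

  cl2 <- cluster_evidence(mk_sc(c(1000L, 2000L)), no_dc, 50L)
  expect_equal(nrow(cl2), 2L)

  expect_equal(nrow(cluster_evidence(mk_sc(integer(0), character(0)),
                                     no_dc, 50L)), 0L)

  # discordant intervals attach when they overlap the cluster span
  dc <- data.frame(read = "d1", class = "discordant", contig = "c1",
                   interval_start = 900L, interval_end = 1050L,
                   replicate = "rep1", stringsAsFactors = FALSE)
  cl3 <- cluster_evidence(mk_sc(c(1000L, 1000L)), dc, 50L)
  expect_equal(nrow(cl3$discordant_reads[[1]]), 1L)
})

test_that("support filtering applies the per-replicate >=3 AND >=3 rule", {
  mk_cand <- function(sc, dc) {
    data.frame(contig = "c1", breakpoint = 1000L,
               softclip_reads = I(list(sc)), discordant_reads = I(list(dc)),
               stringsAsFactors = FALSE)
  }
  ev <- function(reads, reps) data.frame(read = reads, replicate = reps,
                                         stringsAsFactors = FALSE)
  # 3 softclip + 3 discordant in rep1, nothing in rep2: retained
  cand <- mk_cand(ev(paste0("s", 1:3), rep("rep1", 3)),
                  ev(paste0("d", 1:3), rep("rep1", 3)))
  expect_equal(nrow(filter_calls(cand)), 1L)

  # 2 softclip + 5 discordant: below the soft-clip floor, rejected
  cand2 <- mk_cand(ev(paste0("s", 1:2), rep("rep1", 2)),
                   ev(paste0("d", 1:5), rep("rep1", 5)))
  expect_equal(nrow(filter_calls(cand2)), 0L)

  # duplicate read names count once
  cand3 <- mk_cand(ev(c("s1", "s1", "s1"), rep("rep1", 3)),
                   ev(paste0("d", 1:3), rep("rep1", 3)))
  expect_equal(nrow(filter_calls(cand3)), 0L)

  # evidence split across replicates without either reaching the floor
  cand4 <- mk_cand(ev(paste0("s", 1:4), c("rep1", "rep1", "rep2", "rep2")),
                   ev(paste0("d", 1:4), c("rep1", "rep1", "rep2", "rep2")))
  expect_equal(nrow(filter_calls(cand4)), 0L)
  expect_equal(nrow(filter_calls(cand4, min_softclip = 2, min_discordant = 2)),
               1L)

  expect_error(filter_calls(cand, replicate_policy = "sometimes"), "policy")
})

test_that("reference comparison and parental reclassification categorize calls", {
  calls <- data.frame(contig = c("c1", "c1"), breakpoint = c(1000L, 15000L),
                      stringsAsFactors = FALSE)
  ref <- data.frame(contig = "c1", start = 1004L, end = 1005L)
  out <- compare_to_reference(calls, ref, match_window = 50L)
  expect_equal(out$category, c("common", "sample_specific"))

  # parental soft-clip support reclassifies a sample-specific call
  te3 <- substr(TE, nchar(TE) - 19, nchar(TE))
  parental <- do.call(rbind, lapply(1:3, function(i) {
    sam_row(qname = paste0("p", i), pos = 15000L, cigar = "20S80M",
            seq = paste0(te3, rand_dna(80)))
  }))
  out2 <- check_parental_evidence(out, parental, TE, min_reads = 3L)
  expect_equal(out2$category, c("common", "ancestral_reclassified"))

  # no parental reads: categories untouched
  out3 <- check_parental_evidence(out, parental[0, ], TE)
  expect_equal(out3$category, out$category)
})

test_that("error-free simulated calls hit truth breakpoints exactly", {
  fx <- small_tedseq(seed = 31)
  calls <- call_insertions(fx$reps, fx$te,
                           reference_insertions = fx$ref_bed)
  expect_equal(nrow(calls), nrow(fx$truth))
  key <- function(df, bp) paste(df$contig, bp)
  expect_setequal(key(calls, calls$breakpoint),
                  key(fx$truth, fx$truth$breakpoint))
  truth_cat <- fx$truth$category[match(key(calls, calls$breakpoint),
                                       key(fx$truth, fx$truth$breakpoint))]
  expect_equal(calls$category,
               ifelse(truth_cat == "reference", "common", "sample_specific"))
})

test_that("calls are invariant to read order and monotone in the filter", {
  fx <- small_tedseq(seed = 37)
  calls <- call_insertions(fx$reps, fx$te)
  shuffled <- lapply(fx$reps, function(r) {
    set.seed(99)
    out <- r[sample.int(nrow(r)), ]
    attr(out, "contig_lengths") <- attr(r, "contig_lengths")
    out
  })
  calls2 <- call_insertions(shuffled, fx$te)
  expect_equal(calls[order(calls$contig, calls$breakpoint),
                     c("contig", "breakpoint", "n_softclip", "n_discordant")],
               calls2[order(calls2$contig, calls2$breakpoint),
                      c("contig", "breakpoint", "n_softclip", "n_discordant")],
               ignore_attr = TRUE)

  # raising min_softclip can only shrink the call set
  n_prev <- Inf
  for (ms in c(1L, 3L, 5L)) {
    n <- nrow(call_insertions(fx$reps, fx$te, min_softclip = ms))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
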