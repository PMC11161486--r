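# Simulation of TED-seq-like alignments around known insertions: junction
# reads carrying terminal soft clips of TE sequence, discordant pairs with
# one mate on the TE contig, and concordant background pairs. SAM records
# are emitted directly; read mapping itself is outside the package's scope,
# so the caller's contract starts at aligned records.

TE_CONTIG <- "AndroPIF"

#' Simulate TED-seq junction alignments for a set of insertions
#'
#' For every truth insertion the simulator emits, per replicate:
#' `junction_reads` soft-clipped reads whose clipped bases reproduce the TE
#' terminus abutting the junction (split between leading-clip and
#' trailing-clip reads, all with clip boundary exactly at the truth
#' breakpoint), and `discordant_pairs` read pairs with the genomic mate
#' within `max_insert` of the breakpoint and the other mate on the TE
#' contig. `background_pairs` concordant pairs per replicate are scattered
#' uniformly. Base errors are substituted at `base_error_rate` per base.
#'
#' @param genome a `genome_sequence`.
#' @param te TE consensus sequence (single DNA string).
#' @param truth data.frame with contig, breakpoint (0-based), strand.
#' @param config a [sim_config()].
#' @return list of per-replicate alignment data frames (as [read_sam()]
#'   returns), each carrying a `contig_lengths` attribute that includes the
#'   TE contig.
#' @export
simulate_junction_alignments <- function(genome, te, truth,
                                         config = sim_config()) {
  check_genome(genome)
  lens <- contig_lengths(genome)
  if (config$read_length > min(lens)) {
    stop("simulate_junction_alignments(): read length exceeds contig length")
  }
  rl <- config$read_length
  te_len <- nchar(te)
  sq <- c(lens, stats::setNames(te_len, TE_CONTIG))
  with_seed(config$seed + 11L, {
    reps <- lapply(seq_len(config$n_replicates), function(rep_id) {
      recs <- list()
      for (i in seq_len(nrow(truth))) {
        recs[[length(recs) + 1L]] <-
          junction_reads_for(genome, te, truth[i, ], rep_id, i, config)
        recs[[length(recs) + 1L]] <-
          discordant_reads_for(genome, te, truth[i, ], rep_id, i, config)
      }
      recs[[length(recs) + 1L]] <- background_reads(genome, rep_id, config)
      reads <- do.call(rbind, recs)
      reads$seq <- add_base_errors(reads$seq, config$base_error_rate)
      attr(reads, "contig_lengths") <- sq
      reads
    })
    names(reps) <- sprintf("rep%d", seq_len(config$n_replicates))
    reps
  })
}

junction_reads_for <- function(genome, te, site, rep_id, ins_id, config) {
  rl <- config$read_length
  b <- site$breakpoint
  cseq <- unclass(genome)[[site$contig]]
  ins_seq <- if (site$strand == "+") te else revcomp(te)
  n <- config$junction_reads
  n_lead <- ceiling(n / 2)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    clip <- sample(config$min_clip:(rl - config$min_clip), 1L)
    m <- rl - clip
    if (k <= n_lead) {
      # leading clip: clipped bases are the TE end adjacent to the
      # downstream genome (the inserted element's last `clip` bases);
      # alignment starts at the breakpoint.
      clipped <- substr(ins_seq, nchar(ins_seq) - clip + 1L, nchar(ins_seq))
      aligned <- substr(cseq, b + 1L, b + m)
      seq <- paste0(clipped, aligned)
      cigar <- sprintf("%dS%dM", clip, m)
      pos <- b
    } else {
      # trailing clip: genome up to the breakpoint, then the inserted
      # element's first `clip` bases; alignment ends at the breakpoint.
      aligned <- substr(cseq, b - m + 1L, b)
      clipped <- substr(ins_seq, 1L, clip)
      seq <- paste0(aligned, clipped)
      cigar <- sprintf("%dM%dS", m, clip)
      pos <- b - m
    }
    out[[k]] <- data.frame(
      qname = sprintf("rep%d_ins%d_jx%d", rep_id, ins_id, k),
      flag = 0L, rname = site$contig, pos = pos, mapq = 60L,
      cigar = cigar, rnext = "*", pnext = -1L, seq = seq,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

discordant_reads_for <- function(genome, te, site, rep_id, ins_id, config) {
  rl <- config$read_length
  b <- site$breakpoint
  cseq <- unclass(genome)[[site$contig]]
  te_len <- nchar(te)
  n <- config$discordant_pairs
  out <- vector("list", 2L * n)
  for (k in seq_len(n)) {
    gap <- sample(10:150, 1L)
    te_pos <- sample.int(max(te_len - rl, 1L), 1L) - 1L
    upstream <- k %% 2L == 0L
    if (upstream) {
      # forward genomic mate ending `gap` bp before the breakpoint
      gpos <- b - gap - rl
      gflag <- 1L + 32L           # paired, mate reverse
    } else {
      # reverse genomic mate starting `gap` bp after the breakpoint
      gpos <- b + gap
      gflag <- 1L + 16L           # paired, reverse
    }
    gpos <- max(0L, min(gpos, nchar(cseq) - rl))
    qn <- sprintf("rep%d_ins%d_dc%d", rep_id, ins_id, k)
    out[[2L * k - 1L]] <- data.frame(
      qname = qn, flag = gflag, rname = site$contig, pos = gpos,
      mapq = 60L, cigar = sprintf("%dM", rl), rnext = TE_CONTIG,
      pnext = te_pos, seq = substr(cseq, gpos + 1L, gpos + rl),
      stringsAsFactors = FALSE)
    out[[2L * k]] <- data.frame(
      qname = qn, flag = 1L + if (upstream) 16L else 32L, rname = TE_CONTIG,
      pos = te_pos, mapq = 60L, cigar = sprintf("%dM", rl),
      rnext = site$contig, pnext = gpos,
      seq = substr(te, te_pos + 1L, te_pos + rl), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

background_reads <- function(genome, rep_id, config) {
  n <- config$background_pairs
  if (n == 0) {
    return(empty_df(qname = character(), flag = integer(), rname = character(),
                    pos = integer(), mapq = integer(), cigar = character(),
                    rnext = character(), pnext = integer(), seq = character()))
  }
  rl <- config$read_length
  lens <- contig_lengths(genome)
  ci <- sample(length(lens), n, replace = TRUE, prob = lens)
  isize <- sample(250:450, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(lens[ci[i]] - isize[i], 1L) - 1L
  }, integer(1))
  mate_start <- start + isize - rl
  recs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    cn <- names(lens)[ci[i]]
    cseq <- unclass(genome)[[cn]]
    qn <- sprintf("rep%d_bg%d", rep_id, i)
    recs[[2L * i - 1L]] <- data.frame(
      qname = qn, flag = 1L + 2L + 32L, rname = cn, pos = start[i],
      mapq = 60L, cigar = sprintf("%dM", rl), rnext = cn,
      pnext = mate_start[i], seq = substr(cseq, start[i] + 1L, start[i] + rl),
      stringsAsFactors = FALSE)
    recs[[2L * i]] <- data.frame(
      qname = qn, flag = 1L + 2L + 16L, rname = cn, pos = mate_start[i],
      mapq = 60L, cigar = sprintf("%dM", rl), rnext = cn, pnext = start[i],
      seq = substr(cseq, mate_start[i] + 1L, mate_start[i] + rl),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

# Substitute random bases at the given per-base rate.
add_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- str_bases(s)
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
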