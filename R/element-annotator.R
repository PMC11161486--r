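# Annotation of full-length and degenerate TE copies: terminal inverted
# repeat (TIR) search with mismatches, TIR pairing into candidate
# elements, and cross-support from DAP-seq binding peaks ("double peaks"
# flank an intact element, single peaks mark degenerate copies or chance
# TIR-like sequence).

#' Find TIR matches genome-wide with mismatches
#'
#' All windows within Hamming distance `max_mismatch` of `tir` on the +
#' strand and of its reverse complement on the - strand; overlapping
#' matches are all reported. Matching uses Biostrings (no indels).
#'
#' @param genome a `genome_sequence`.
#' @param tir TIR sequence (ACGT).
#' @param max_mismatch maximum Hamming distance.
#' @return data.frame with contig, start, end (0-based half-open), strand,
#'   mismatches, sorted by (contig, start).
#' @export
find_tir_matches <- function(genome, tir = "GGGCCCGTTTG", max_mismatch = 2L) {
  check_genome(genome)
  if (grepl("[^ACGT]", tir)) stop("find_tir_matches(): TIR must be over ACGT")
  w <- nchar(tir)
  pats <- list(`+` = Biostrings::DNAString(tir),
               `-` = Biostrings::reverseComplement(Biostrings::DNAString(tir)))
  out <- list()
  for (cn in names(genome)) {
    subj <- Biostrings::DNAString(unclass(genome)[[cn]])
    if (length(subj) < w) next
    for (strand in names(pats)) {
      hits <- Biostrings::matchPattern(pats[[strand]], subj,
                                       max.mismatch = max_mismatch,
                                       with.indels = FALSE)
      if (length(hits) == 0) next
      mm <- vapply(as.character(hits), hamming,
                   integer(1), b = as.character(pats[[strand]]),
                   USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = Biostrings::start(hits) - 1L,
        end = Biostrings::end(hits), strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(empty_df(contig = character(), start = integer(), end = integer(),
                    strand = character(), mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

#' Pair TIR matches into candidate elements
#'
#' Walks the - strand matches left to right, pairing each with the nearest
#' upstream unused + strand match whose outer span length lies in
#' `[min_len, max_len]`; every match is used at most once. This greedy
#' innermost pairing means that in a +,+,- arrangement the later + match
#' pairs. The element span is the outer coordinates of the two TIRs.
#'
#' @param matches output of [find_tir_matches()].
#' @param min_len,max_len admissible element length bounds (bp).
#' @return data.frame of candidates: contig, start, end, plus the left
#'   (+ strand) and right (- strand) TIR coordinates and mismatch counts.
#' @export
pair_tirs <- function(matches, min_len = 200L, max_len = 20000L) {
  cols <- empty_df(contig = character(), start = integer(), end = integer(),
                   left_tir_start = integer(), left_tir_end = integer(),
                   right_tir_start = integer(), right_tir_end = integer(),
                   left_mismatches = integer(), right_mismatches = integer())
  if (nrow(matches) == 0) return(cols)
  out <- list()
  for (cn in unique(matches$contig)) {
    plus <- matches[matches$contig == cn & matches$strand == "+", ,
                    drop = FALSE]
    minus <- matches[matches$contig == cn & matches$strand == "-", ,
                     drop = FALSE]
    plus <- plus[order(plus$start), , drop = FALSE]
    minus <- minus[order(minus$start), , drop = FALSE]
    used <- logical(nrow(plus))
    for (j in seq_len(nrow(minus))) {
      span <- minus$end[j] - plus$start
      ok <- !used & plus$end <= minus$start[j] &
        span >= min_len & span <= max_len
      if (!any(ok)) next
      i <- max(which(ok))                       # nearest upstream partner
      used[i] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = plus$start[i], end = minus$end[j],
        left_tir_start = plus$start[i], left_tir_end = plus$end[i],
        right_tir_start = minus$start[j], right_tir_end = minus$end[j],
        left_mismatches = plus$mismatches[i],
        right_mismatches = minus$mismatches[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(cols)
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

# Is any peak summit within `window` of the [start, end) interval?
summit_near <- function(peaks, contig, start, end, window) {
  p <- peaks[peaks$contig == contig, , drop = FALSE]
  if (nrow(p) == 0) return(FALSE)
  any(p$summit >= start - window & p$summit < end + window)
}

#' Annotate candidate elements with DAP-seq peak support
#'
#' A TIR is supported iff at least one peak summit lies within
#' `summit_window` of it; candidates with both TIRs supported carry a
#' double peak.
#'
#' @param candidates output of [pair_tirs()].
#' @param peaks peak data frame with contig, start, end, summit (see
#'   [read_peaks()]).
#' @param summit_window summit-to-TIR distance tolerance (bp).
#' @return `candidates` with logical columns left_supported,
#'   right_supported, double_peak.
#' @export
detect_double_peaks <- function(candidates, peaks, summit_window = 500L) {
  n <- nrow(candidates)
  candidates$left_supported <- vapply(seq_len(n), function(i) {
    summit_near(peaks, candidates$contig[i], candidates$left_tir_start[i],
                candidates$left_tir_end[i], summit_window)
  }, logical(1))
  candidates$right_supported <- vapply(seq_len(n), function(i) {
    summit_near(peaks, candidates$contig[i], candidates$right_tir_start[i],
                candidates$right_tir_end[i], summit_window)
  }, logical(1))
  candidates$double_peak <- candidates$left_supported &
    candidates$right_supported
  candidates
}

#' Classify candidate elements, lone TIRs and peaks into an element catalog
#'
#' Status rules: a paired-TIR candidate with a double peak is
#' `full_length`; a paired candidate with exactly one supported TIR, or a
#' lone (unpaired) TIR with a nearby peak, is `degenerate`; a paired
#' candidate with no peak support is `unsupported`; a peak with no TIR
#' match within `summit_window` is `solo_peak`.
#'
#' @param candidates output of [pair_tirs()].
#' @param matches all TIR matches ([find_tir_matches()]); those not used
#'   in a pair are the lone TIRs.
#' @param peaks peak data frame with summits.
#' @param summit_window summit-to-TIR distance tolerance (bp).
#' @return data.frame catalog: contig, start, end, status.
#' @export
classify_elements <- function(candidates, matches, peaks,
                              summit_window = 500L) {
  candidates <- detect_double_peaks(candidates, peaks, summit_window)
  rows <- list()
  n <- nrow(candidates)
  status <- ifelse(candidates$double_peak, "full_length",
                   ifelse(candidates$left_supported |
                            candidates$right_supported,
                          "degenerate", "unsupported"))
  if (n) {
    rows[[1L]] <- data.frame(contig = candidates$contig,
                             start = candidates$start, end = candidates$end,
                             status = status, stringsAsFactors = FALSE)
  }
  # lone TIRs: matches not covered by any candidate TIR footprint
  lone <- rep(TRUE, nrow(matches))
  for (i in seq_len(n)) {
    lone <- lone & !(matches$contig == candidates$contig[i] &
                       (matches$start == candidates$left_tir_start[i] |
                          matches$start == candidates$right_tir_start[i]))
  }
  lm <- matches[lone, , drop = FALSE]
  if (nrow(lm)) {
    supp <- vapply(seq_len(nrow(lm)), function(i) {
      summit_near(peaks, lm$contig[i], lm$start[i], lm$end[i], summit_window)
    }, logical(1))
    if (any(supp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = lm$contig[supp], start = lm$start[supp], end = lm$end[supp],
        status = "degenerate", stringsAsFactors = FALSE)
    }
  }
  # peaks with no TIR anywhere near the summit
  if (nrow(peaks)) {
    solo <- vapply(seq_len(nrow(peaks)), function(i) {
      m <- matches[matches$contig == peaks$contig[i], , drop = FALSE]
      !any(m$start - summit_window <= peaks$summit[i] &
             peaks$summit[i] < m$end + summit_window)
    }, logical(1))
    if (any(solo)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = peaks$contig[solo], start = peaks$start[solo],
        end = peaks$end[solo], status = "solo_peak", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(empty_df(contig = character(), start = integer(), end = integer(),
                    status = character()))
  }
  res <- do.call(rbind, rows)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Read a peak BED file with summits
#'
#' Accepts either BED with a 7th column holding the summit offset from
#' the peak start, or narrowPeak (10 columns, summit offset in column 10).
#' An offset of -1 (narrowPeak convention for "not called") falls back to
#' the peak midpoint.
#'
#' @param path peak file path.
#' @return data.frame with contig, start, end, summit (absolute, 0-based),
#'   score.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || !nf %in% c(7L, 10L)) {
    stop("read_peaks(): expected 7-column BED+summit or 10-column narrowPeak")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- as.integer(get(2))
  end <- as.integer(get(3))
  offset <- as.integer(get(if (nf == 7L) 7L else 10L))
  score <- if (nf >= 5L) as.numeric(get(5)) else rep(0, length(start))
  summit <- ifelse(offset < 0L, start + (end - start) %/% 2L, start + offset)
  data.frame(contig = get(1), start = start, end = end,
             summit = summit, score = score, stringsAsFactors = FALSE)
}

#' Position frequency matrix and consensus at peak summits
#'
#' Extracts `2*half_width + 1`-nt windows centered on each summit and
#' feeds them to [build_pfm()] / [pfm_consensus()]. Windows overrunning a
#' contig end are dropped.
#'
#' @param peaks peak data frame with contig and summit.
#' @param genome a `genome_sequence`.
#' @param half_width half window width (31-nt windows at the default 15).
#' @param min_freq consensus inclusion threshold.
#' @return list with `pfm` and `consensus`.
#' @export
summit_motif <- function(peaks, genome, half_width = 15L, min_freq = 0.25) {
  check_genome(genome)
  lens <- contig_lengths(genome)
  lo <- peaks$summit - half_width
  hi <- peaks$summit + half_width + 1L
  ok <- lo >= 0L & hi <= lens[peaks$contig]
  if (!any(ok)) stop("summit_motif(): all summit windows out of bounds")
  w <- substr(unclass(genome)[peaks$contig[ok]], lo[ok] + 1L, hi[ok])
  pfm <- build_pfm(unname(w))
  list(pfm = pfm, consensus = pfm_consensus(pfm, min_freq))
}
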