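# Non-reference TE insertion calling from soft-clipped and discordant
# alignment evidence.
#
# Breakpoint convention: the 0-based genomic position of the junction; the
# element inserts between breakpoint - 1 and breakpoint. A leading soft
# clip places the breakpoint at the alignment start, a trailing clip at
# the alignment end.

#' Extract soft-clip insertion evidence
#'
#' A read contributes evidence iff it carries a terminal soft clip of at
#' least `min_clip_len` bases whose clipped sequence matches a terminus of
#' the TE consensus (either end, forward or reverse complement) with a
#' mismatch fraction no greater than `max_clip_mismatch_frac`.
#'
#' @param reads alignment data frame (see [read_sam()]).
#' @param te_sequence TE consensus DNA string.
#' @param min_clip_len minimum terminal clip length considered.
#' @param max_clip_mismatch_frac maximum allowed mismatch fraction between
#'   the clipped bases and the best-matching TE terminus.
#' @param replicate replicate id recorded on each evidence row.
#' @return data.frame with read, class ("softclip"), contig, breakpoint,
#'   side ("left" for leading clips, "right" for trailing), te_end
#'   ("5'"/"3'"), replicate.
#' @export
extract_softclip_evidence <- function(reads, te_sequence, min_clip_len = 20L,
                                      max_clip_mismatch_frac = 0.1,
                                      replicate = "rep1") {
  out <- list()
  n_no_cigar <- 0L
  for (i in seq_len(nrow(reads))) {
    cigar <- reads$cigar[i]
    if (cigar == "*") { n_no_cigar <- n_no_cigar + 1L; next }
    if (flag_unmapped(reads$flag[i]) || flag_secondary(reads$flag[i]) ||
        flag_supplementary(reads$flag[i])) next
    cg <- parse_cigar(cigar)
    k <- length(cg$op)
    sides <- list()
    if (cg$op[1L] == "S" && cg$len[1L] >= min_clip_len) {
      sides$left <- substr(reads$seq[i], 1L, cg$len[1L])
    }
    if (cg$op[k] == "S" && cg$len[k] >= min_clip_len) {
      sides$right <- substr(reads$seq[i], nchar(reads$seq[i]) - cg$len[k] + 1L,
                            nchar(reads$seq[i]))
    }
    for (side in names(sides)) {
      m <- match_te_terminus(sides[[side]], te_sequence, side,
                             max_clip_mismatch_frac)
      if (is.null(m)) next
      bp <- if (side == "left") reads$pos[i]
            else reads$pos[i] + cigar_ref_length(cigar)
      out[[length(out) + 1L]] <- data.frame(
        read = reads$qname[i], class = "softclip", contig = reads$rname[i],
        breakpoint = bp, side = side, te_end = m, replicate = replicate,
        stringsAsFactors = FALSE)
    }
  }
  if (n_no_cigar > 0) {
    message("extract_softclip_evidence(): skipped ", n_no_cigar,
            " read(s) without CIGAR")
  }
  if (length(out) == 0) return(empty_evidence())
  do.call(rbind, out)
}

empty_evidence <- function() {
  empty_df(read = character(), class = character(), contig = character(),
           breakpoint = integer(), side = character(), te_end = character(),
           replicate = character())
}

# Best-matching TE terminus for a clipped sequence, or NULL. A leading
# (side "left") clip abuts the downstream junction, so it should end with
# TE sequence; a trailing clip should begin with TE sequence. Both TE ends
# and both orientations are tried; ties resolve to the smaller mismatch
# count, then 5' before 3'.
match_te_terminus <- function(clip, te, side, max_frac) {
  n <- nchar(clip)
  if (n > nchar(te)) return(NULL)
  rc <- revcomp(te)
  cand <- list(
    c("5'", substr(te, 1L, n)),
    c("3'", substr(te, nchar(te) - n + 1L, nchar(te))),
    c("3'", substr(rc, 1L, n)),                      # revcomp of 3' end
    c("5'", substr(rc, nchar(rc) - n + 1L, nchar(rc)))
  )
  best <- NULL
  best_mm <- Inf
  for (cc in cand) {
    mm <- hamming(clip, cc[[2L]])
    if (mm < best_mm) { best_mm <- mm; best <- cc[[1L]] }
  }
  if (best_mm / n <= max_frac) best else NULL
}

#' Extract discordant-pair insertion evidence
#'
#' A genome-aligned read contributes evidence iff its mate maps to the TE
#' contig. Discordant evidence does not carry an exact breakpoint; the
#' insertion is localized to a `max_insert`-wide interval downstream of
#' the read in its orientation (upstream for reverse-strand reads).
#'
#' @param reads alignment data frame.
#' @param te_contig_name contig name the TE consensus was aligned under.
#' @param max_insert library insert-size upper bound defining the interval.
#' @param replicate replicate id.
#' @return data.frame with read, class ("discordant"), contig,
#'   interval_start, interval_end, replicate.
#' @export
extract_discordant_evidence <- function(reads, te_contig_name = TE_CONTIG,
                                        max_insert = 500L,
                                        replicate = "rep1") {
  keep <- flag_paired(reads$flag) & !flag_unmapped(reads$flag) &
    !flag_mate_unmapped(reads$flag) &
    reads$rname != te_contig_name & reads$rnext == te_contig_name &
    !flag_secondary(reads$flag) & !flag_supplementary(reads$flag)
  r <- reads[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    return(empty_df(read = character(), class = character(),
                    contig = character(), interval_start = integer(),
                    interval_end = integer(), replicate = character()))
  }
  rev <- flag_reverse(r$flag)
  end <- r$pos + vapply(r$cigar, cigar_ref_length, integer(1))
  data.frame(read = r$qname, class = "discordant", contig = r$rname,
             interval_start = ifelse(rev, pmax(r$pos - max_insert, 0L), end),
             interval_end = ifelse(rev, r$pos, end + max_insert),
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Cluster insertion evidence into candidate loci
#'
#' Soft-clip breakpoints are clustered per contig by single linkage at
#' `cluster_window`; each cluster's breakpoint is the modal soft-clip
#' breakpoint (ties to the smallest coordinate). Discordant evidence is
#' attached to every cluster whose breakpoint span its interval overlaps.
#'
#' @param softclip soft-clip evidence ([extract_softclip_evidence()]),
#'   possibly pooled over replicates.
#' @param discordant discordant evidence
#'   ([extract_discordant_evidence()]), same pooling.
#' @param cluster_window single-linkage gap (bp).
#' @return data.frame of candidate loci: contig, breakpoint, plus list
#'   columns `softclip_reads` and `discordant_reads` holding per-candidate
#'   evidence tables (read, replicate).
#' @export
cluster_evidence <- function(softclip, discordant, cluster_window = 50L) {
  if (nrow(softclip) == 0) {
    return(empty_df(contig = character(), breakpoint = integer()))
  }
  softclip <- softclip[order(softclip$contig, softclip$breakpoint), ,
                       drop = FALSE]
  out <- list()
  for (cn in unique(softclip$contig)) {
    sc <- softclip[softclip$contig == cn, , drop = FALSE]
    gap <- c(0L, diff(sc$breakpoint))
    cl <- cumsum(gap > cluster_window)
    for (g in unique(cl)) {
      m <- sc[cl == g, , drop = FALSE]
      tab <- table(m$breakpoint)
      modal <- as.integer(names(tab)[tab == max(tab)])
      bp <- min(modal)
      span <- range(m$breakpoint)
      dc <- discordant[discordant$contig == cn &
                         discordant$interval_start <= span[2L] &
                         discordant$interval_end >= span[1L], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, breakpoint = bp,
        softclip_reads = I(list(m[, c("read", "replicate")])),
        discordant_reads = I(list(dc[, c("read", "replicate")])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Unique-read support counts per replicate for one evidence table.
support_by_replicate <- function(ev, replicates) {
  vapply(replicates, function(r) {
    length(unique(ev$read[ev$replicate == r]))
  }, integer(1))
}

#' Filter candidate loci by replicate-level read support
#'
#' A candidate is retained iff, in at least one replicate (policy "any")
#' or in every replicate (policy "all"), its unique soft-clip read count
#' reaches `min_softclip` and its unique discordant read count reaches
#' `min_discordant`.
#'
#' @param candidates output of [cluster_evidence()].
#' @param min_softclip,min_discordant per-replicate support floors.
#' @param replicate_policy "any" (default) or "all".
#' @return insertion call data.frame: contig, breakpoint, n_softclip,
#'   n_discordant (totals of unique reads), per-replicate count columns,
#'   and the supporting-evidence list columns.
#' @export
filter_calls <- function(candidates, min_softclip = 3L, min_discordant = 3L,
                         replicate_policy = "any") {
  if (!replicate_policy %in% c("any", "all")) {
    stop("filter_calls(): unknown replicate_policy '", replicate_policy, "'")
  }
  if (nrow(candidates) == 0) return(candidates)
  replicates <- sort(unique(unlist(lapply(
    seq_len(nrow(candidates)),
    function(i) c(candidates$softclip_reads[[i]]$replicate,
                  candidates$discordant_reads[[i]]$replicate)))))
  if (length(replicates) == 0) replicates <- "rep1"
  keep <- logical(nrow(candidates))
  sc_counts <- matrix(0L, nrow(candidates), length(replicates),
                      dimnames = list(NULL, paste0("softclip_", replicates)))
  dc_counts <- matrix(0L, nrow(candidates), length(replicates),
                      dimnames = list(NULL, paste0("discordant_", replicates)))
  for (i in seq_len(nrow(candidates))) {
    sc <- support_by_replicate(candidates$softclip_reads[[i]], replicates)
    dc <- support_by_replicate(candidates$discordant_reads[[i]], replicates)
    sc_counts[i, ] <- sc
    dc_counts[i, ] <- dc
    ok <- sc >= min_softclip & dc >= min_discordant
    keep[i] <- if (replicate_policy == "any") any(ok) else all(ok)
  }
  calls <- candidates[keep, , drop = FALSE]
  calls$n_softclip <- vapply(calls$softclip_reads,
                             function(x) length(unique(x$read)), integer(1))
  calls$n_discordant <- vapply(calls$discordant_reads,
                               function(x) length(unique(x$read)), integer(1))
  cbind(calls, sc_counts[keep, , drop = FALSE],
        dc_counts[keep, , drop = FALSE])
}

#' Categorize calls against a reference insertion annotation
#'
#' A call within `match_window` of its nearest reference insertion is
#' "common"; otherwise "sample_specific". Equidistant reference
#' insertions resolve to the smaller coordinate.
#'
#' @param calls output of [filter_calls()].
#' @param reference_insertions BED-style data frame (contig, start, end) of
#'   reference insertion positions.
#' @param match_window maximum breakpoint-to-reference distance (bp).
#' @return `calls` with a `category` column added.
#' @export
compare_to_reference <- function(calls, reference_insertions,
                                 match_window = 50L) {
  if (nrow(calls) == 0) { calls$category <- character(0); return(calls) }
  category <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ref <- reference_insertions[
      reference_insertions$contig == calls$contig[i], , drop = FALSE]
    if (nrow(ref) == 0) { category[i] <- "sample_specific"; next }
    d <- abs(ref$start - calls$breakpoint[i])
    category[i] <- if (min(d) <= match_window) "common" else "sample_specific"
  }
  calls$category <- category
  calls
}

#' Reclassify sample-specific calls with parental evidence as ancestral
#'
#' A sample-specific call supported by at least `min_reads` evidence reads
#' of either class in the parental alignments is reclassified
#' "ancestral_reclassified": it predates the sample and is not a new
#' transposition.
#'
#' @param calls categorized calls ([compare_to_reference()]).
#' @param parental_reads parental alignment data frame.
#' @param te_sequence TE consensus (for the soft-clip scan).
#' @param te_contig_name TE contig name (for the discordant scan).
#' @param min_reads evidence-read floor for reclassification.
#' @param match_window breakpoint/interval match window (bp).
#' @param ... passed through to the evidence extractors.
#' @return `calls` with categories updated.
#' @export
check_parental_evidence <- function(calls, parental_reads, te_sequence,
                                    te_contig_name = TE_CONTIG, min_reads = 3L,
                                    match_window = 50L, ...) {
  if (nrow(calls) == 0 || nrow(parental_reads) == 0) return(calls)
  sc <- extract_softclip_evidence(parental_reads, te_sequence,
                                  replicate = "parental", ...)
  dc <- extract_discordant_evidence(parental_reads, te_contig_name,
                                    replicate = "parental")
  for (i in seq_len(nrow(calls))) {
    if (calls$category[i] != "sample_specific") next
    n_sc <- length(unique(sc$read[sc$contig == calls$contig[i] &
                      abs(sc$breakpoint - calls$breakpoint[i]) <= match_window]))
    n_dc <- length(unique(dc$read[dc$contig == calls$contig[i] &
                      dc$interval_start <= calls$breakpoint[i] &
                      dc$interval_end >= calls$breakpoint[i]]))
    if (n_sc + n_dc >= min_reads) {
      calls$category[i] <- "ancestral_reclassified"
    }
  }
  calls
}

#' Run the full insertion-calling pipeline on replicate alignments
#'
#' Extracts soft-clip and discordant evidence per replicate, pools it,
#' clusters, filters by the per-replicate support rule, and (optionally)
#' categorizes against a reference annotation and parental alignments.
#'
#' @param replicates named list of alignment data frames, one per
#'   replicate.
#' @param te_sequence TE consensus string.
#' @param reference_insertions optional reference insertion BED data frame.
#' @param parental_reads optional parental alignment data frame.
#' @param te_contig_name TE contig name.
#' @param min_clip_len,max_clip_mismatch_frac soft-clip matching controls.
#' @param max_insert discordant interval width.
#' @param cluster_window,match_window clustering / matching windows (bp).
#' @param min_softclip,min_discordant,replicate_policy support filter.
#' @param min_parental_reads parental reclassification floor.
#' @return insertion call data.frame (see [filter_calls()]), with
#'   `category` when a reference annotation was given.
#' @export
call_insertions <- function(replicates, te_sequence,
                            reference_insertions = NULL,
                            parental_reads = NULL,
                            te_contig_name = TE_CONTIG,
                            min_clip_len = 20L, max_clip_mismatch_frac = 0.1,
                            max_insert = 500L, cluster_window = 50L,
                            match_window = 50L, min_softclip = 3L,
                            min_discordant = 3L, replicate_policy = "any",
                            min_parental_reads = 3L) {
  if (is.null(names(replicates))) {
    names(replicates) <- sprintf("rep%d", seq_along(replicates))
  }
  sc <- do.call(rbind, lapply(names(replicates), function(r) {
    extract_softclip_evidence(replicates[[r]], te_sequence, min_clip_len,
                              max_clip_mismatch_frac, replicate = r)
  }))
  dc <- do.call(rbind, lapply(names(replicates), function(r) {
    extract_discordant_evidence(replicates[[r]], te_contig_name, max_insert,
                                replicate = r)
  }))
  cand <- cluster_evidence(sc, dc, cluster_window)
  calls <- filter_calls(cand, min_softclip, min_discordant, replicate_policy)
  if (!is.null(reference_insertions)) {
    calls <- compare_to_reference(calls, reference_insertions, match_window)
  }
  if (!is.null(parental_reads)) {
    calls <- check_parental_evidence(calls, parental_reads, te_sequence,
                                     te_contig_name, min_parental_reads,
                                     match_window,
                                     min_clip_len = min_clip_len,
                                     max_clip_mismatch_frac =
                                       max_clip_mismatch_frac)
  }
  calls
}

#' Write insertion calls as BED6 (name = category, score = total support)
#'
#' @param calls insertion call data.frame.
#' @param path output path.
#' @export
write_call_bed <- function(calls, path) {
  bed <- data.frame(contig = calls$contig, start = calls$breakpoint,
                    end = calls$breakpoint + 1L,
                    name = if ("category" %in% names(calls)) calls$category
                           else ".",
                    score = calls$n_softclip + calls$n_discordant,
                    strand = ".", stringsAsFactors = FALSE)
  write_bed(bed, path)
}
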