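# Bulk-segregant delta SNP-index mapping: per-SNP indices from allele
# depths, mutant-minus-wild-type difference, sliding-window smoothing and
# candidate-region extraction.

#' Per-SNP alternate-allele index
#'
#' The SNP-index is the fraction of reads carrying the alternate allele.
#'
#' @param ad_ref,ad_alt reference and alternate allele depths (vectors).
#' @return numeric vector in [0, 1]; NA where total depth is zero.
#' @export
snp_index <- function(ad_ref, ad_alt) {
  stopifnot(all(ad_ref >= 0), all(ad_alt >= 0))
  total <- ad_ref + ad_alt
  ifelse(total > 0, ad_alt / total, NA_real_)
}

#' Per-SNP delta SNP-index (mutant bulk minus wild-type bulk)
#'
#' SNPs where either bulk's total depth is below `min_depth` are skipped
#' (delta = NA) with a message.
#'
#' @param records data.frame with contig, pos, ad_mut_ref, ad_mut_alt,
#'   ad_wt_ref, ad_wt_alt.
#' @param min_depth per-bulk minimum total depth.
#' @return `records` with columns index_mut, index_wt, delta added.
#' @export
delta_snp_index <- function(records, min_depth = 10L) {
  records$index_mut <- snp_index(records$ad_mut_ref, records$ad_mut_alt)
  records$index_wt <- snp_index(records$ad_wt_ref, records$ad_wt_alt)
  deep <- (records$ad_mut_ref + records$ad_mut_alt) >= min_depth &
    (records$ad_wt_ref + records$ad_wt_alt) >= min_depth
  records$delta <- ifelse(deep, records$index_mut - records$index_wt,
                          NA_real_)
  n_skip <- sum(!deep | is.na(records$index_mut) | is.na(records$index_wt))
  if (n_skip > 0) {
    message("delta_snp_index(): ", n_skip, " SNP(s) below min_depth skipped")
  }
  records
}

#' Sliding-window mean delta SNP-index
#'
#' Half-open windows of `window` bp tile each contig at `step` bp;
#' each window reports the mean delta over its SNPs, or NA (undefined,
#' never zero) when fewer than `min_snps` SNPs with defined delta fall in
#' it.
#'
#' @param records output of [delta_snp_index()].
#' @param window,step window and step sizes (bp).
#' @param min_snps minimum SNPs per defined window.
#' @param contig_lengths optional named lengths; defaults to the last SNP
#'   position per contig.
#' @return data.frame with contig, start, end, mean_delta, n_snps.
#' @export
sliding_window <- function(records, window = 1e6, step = 1e5, min_snps = 5L,
                           contig_lengths = NULL) {
  records <- records[order(records$contig, records$pos), , drop = FALSE]
  out <- list()
  for (cn in unique(records$contig)) {
    rc <- records[records$contig == cn & !is.na(records$delta), ,
                  drop = FALSE]
    len <- if (!is.null(contig_lengths)) contig_lengths[[cn]]
           else max(records$pos[records$contig == cn]) + 1
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    for (s in starts) {
      e <- min(s + window, len)
      inw <- rc$pos >= s & rc$pos < e
      n <- sum(inw)
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = s, end = e,
        mean_delta = if (n >= min_snps) mean(rc$delta[inw]) else NA_real_,
        n_snps = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Candidate association regions from a windowed delta profile
#'
#' Maximal runs of consecutive defined windows with mean delta at or above
#' `threshold`, merged across the step overlap; each region reports its
#' span, peak window and peak delta.
#'
#' @param profile output of [sliding_window()].
#' @param threshold minimum windowed mean delta.
#' @return data.frame with contig, start, end, peak_start, peak_end,
#'   peak_delta.
#' @export
candidate_regions <- function(profile, threshold = 0.5) {
  cols <- empty_df(contig = character(), start = numeric(), end = numeric(),
                   peak_start = numeric(), peak_end = numeric(),
                   peak_delta = numeric())
  hot <- !is.na(profile$mean_delta) & profile$mean_delta >= threshold
  if (!any(hot)) return(cols)
  out <- list()
  for (cn in unique(profile$contig[hot])) {
    pc <- profile[profile$contig == cn, , drop = FALSE]
    h <- !is.na(pc$mean_delta) & pc$mean_delta >= threshold
    runs <- rle(h)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      block <- pc[starts[k]:ends[k], , drop = FALSE]
      peak <- block[which.max(block$mean_delta), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = min(block$start), end = max(block$end),
        peak_start = peak$start, peak_end = peak$end,
        peak_delta = peak$mean_delta, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
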