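# Characterization of insertion sites: target-site-duplication consensus
# motifs, genomic-feature distribution with two-proportion Z-tests, and
# binned chromatin / methylation profiles compared by Wilcoxon rank-sum.

#' Extract target-site windows around insertion breakpoints
#'
#' The insertion at breakpoint b duplicates the `tsd_len`-bp target site
#' beginning at b; the returned window covers `flank` bases on each side
#' of it (width `tsd_len + 2*flank`, 9 nt at the defaults). Windows for
#' minus-strand elements are reverse-complemented; windows overrunning a
#' contig end are dropped with a message.
#'
#' @param genome a `genome_sequence`.
#' @param calls data.frame with contig, breakpoint and optionally strand.
#' @param tsd_len target-site-duplication length.
#' @param flank flanking bases on each side.
#' @return character vector of windows.
#' @export
extract_site_windows <- function(genome, calls, tsd_len = 3L, flank = 3L) {
  check_genome(genome)
  lens <- contig_lengths(genome)
  strand <- if ("strand" %in% names(calls)) calls$strand
            else rep("+", nrow(calls))
  lo <- calls$breakpoint - flank
  hi <- calls$breakpoint + tsd_len + flank          # half-open end
  ok <- lo >= 0L & hi <= lens[calls$contig]
  if (!all(ok)) {
    message("extract_site_windows(): dropped ", sum(!ok),
            " window(s) overrunning contig ends")
  }
  if (!any(ok)) stop("extract_site_windows(): all windows dropped")
  w <- substr(unclass(genome)[calls$contig[ok]], lo[ok] + 1L, hi[ok])
  neg <- strand[ok] == "-"
  w[neg] <- revcomp(w[neg])
  unname(w)
}

#' Build a position frequency matrix from equal-length sequences
#'
#' Sequences containing N are dropped; every kept column sums to the
#' number of kept sequences.
#'
#' @param sequences character vector of equal-length ACGT strings.
#' @return a `pfm`: 4 x width integer count matrix (rows A,C,G,T) with
#'   attribute `n_sequences`.
#' @export
build_pfm <- function(sequences) {
  sequences <- sequences[!grepl("N", sequences, fixed = TRUE)]
  if (length(sequences) == 0) stop("build_pfm(): no usable sequences")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("build_pfm(): sequences of unequal length")
  mat <- matrix(0L, 4L, w, dimnames = list(DNA_BASES, NULL))
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  ncol = w, byrow = TRUE)
  for (j in seq_len(w)) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- as.integer(tab)
  }
  structure(mat, n_sequences = length(sequences), class = "pfm")
}

#' IUPAC consensus of a position frequency matrix
#'
#' Per column, bases whose frequency reaches `min_freq` form the
#' degenerate base set; the set maps to its IUPAC code. A column where no
#' base reaches the threshold is reported as N.
#'
#' @param pfm a [build_pfm()] matrix.
#' @param min_freq per-column inclusion frequency threshold.
#' @return IUPAC consensus string.
#' @export
pfm_consensus <- function(pfm, min_freq = 0.25) {
  n <- attr(pfm, "n_sequences")
  freq <- unclass(pfm) / n
  codes <- vapply(seq_len(ncol(freq)), function(j) {
    bases <- DNA_BASES[freq[, j] >= min_freq]
    if (length(bases) == 0) return("N")
    IUPAC_CODES[[paste(bases, collapse = "")]]
  }, character(1))
  paste(codes, collapse = "")
}

#' Classify insertion breakpoints by genomic feature
#'
#' Each breakpoint receives exactly one class with priority
#' exon > intron > promoter > intergenic. The promoter is the
#' `promoter_len` bp upstream of a gene's strand-aware start.
#'
#' @param calls data.frame with contig, breakpoint.
#' @param models a `gene_models` list.
#' @param promoter_len promoter length (bp upstream of the TSS).
#' @return list with `classes` (per-call character vector) and `counts`
#'   (named counts over promoter/exon/intron/intergenic plus n_total).
#' @export
classify_genomic_context <- function(calls, models, promoter_len = 2000L) {
  g <- models$genes
  e <- models$exons
  hit_any <- function(df, contig, pos) {
    if (nrow(df) == 0) return(FALSE)
    any(df$contig == contig & df$start <= pos & pos < df$end)
  }
  classes <- vapply(seq_len(nrow(calls)), function(i) {
    cn <- calls$contig[i]
    bp <- calls$breakpoint[i]
    if (hit_any(e, cn, bp)) return("exon")
    if (hit_any(g, cn, bp)) return("intron")
    gp <- g[g$contig == cn, , drop = FALSE]
    if (nrow(gp)) {
      prom <- ifelse(gp$strand == "+",
                     gp$start - promoter_len, gp$end)
      prom_end <- ifelse(gp$strand == "+", gp$start, gp$end + promoter_len)
      if (any(pmax(prom, 0) <= bp & bp < prom_end)) return("promoter")
    }
    "intergenic"
  }, character(1))
  lv <- c("promoter", "exon", "intron", "intergenic")
  counts <- table(factor(classes, levels = lv))
  list(classes = classes,
       counts = c(as.list(counts), n_total = nrow(calls)))
}

#' Two-proportion Z-test (pooled variance, two-sided)
#'
#' Following the figure-legend convention of applying the test only to
#' classes observed in both groups, a zero count in either group returns
#' NA ("not applicable") rather than a statistic.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z` and two-sided `p` (both NA when not applicable).
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 <= n1, k2 <= n2)
  if (k1 == 0 || k2 == 0) return(list(z = NA_real_, p = NA_real_))
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Cumulative integral of a piecewise-constant track on one contig:
# returns a function I(x) = integral of the track value from 0 to x,
# treating uncovered stretches as 0.
track_integral <- function(track_contig) {
  tc <- track_contig[order(track_contig$start), , drop = FALSE]
  xs <- c(rbind(tc$start, tc$end))
  area <- cumsum(c(rbind(0, tc$value * (tc$end - tc$start))))
  function(x) {
    i <- findInterval(x, xs)
    base <- ifelse(i >= 1L, area[pmax(i, 1L)], 0)
    # inside a segment (odd index): add partial area
    inside <- i >= 1L & i %% 2L == 1L
    seg <- (i + 1L) %/% 2L
    base[inside] <- base[inside] +
      tc$value[seg[inside]] * (x[inside] - tc$start[seg[inside]])
    base
  }
}

#' Mean binned signal profile around sites
#'
#' Tiles the `±flank` window around each site into `2*flank/bin_width`
#' bins (60 at the defaults), computes the length-weighted mean of the
#' piecewise-constant bedGraph signal in each bin, and averages over
#' sites. Bins truncated by a contig end are excluded for that site.
#'
#' @param sites data.frame with contig, breakpoint.
#' @param track bedGraph data frame (contig, start, end, value).
#' @param genome optional `genome_sequence` used to detect contig-end
#'   truncation; when NULL the track extent is used.
#' @param flank half-window (bp).
#' @param bin_width bin size (bp).
#' @return a `profile_matrix`: list with `bins` (per-bin mean over sites),
#'   `per_site` (site x bin matrix), `n_sites`, `n_bins`, `bin_mid`
#'   (bin midpoints relative to the site).
#' @export
profile_signal <- function(sites, track, genome = NULL, flank = 3000L,
                           bin_width = 100L) {
  if (nrow(sites) == 0) stop("profile_signal(): no sites")
  n_bins <- as.integer(2L * flank / bin_width)
  lens <- if (!is.null(genome)) contig_lengths(genome) else
    tapply(track$end, track$contig, max)
  per_site <- matrix(NA_real_, nrow(sites), n_bins)
  ints <- lapply(split(track, track$contig), track_integral)
  for (i in seq_len(nrow(sites))) {
    cn <- sites$contig[i]
    if (!cn %in% names(ints)) next
    edges <- sites$breakpoint[i] - flank + bin_width * (0:n_bins)
    vals <- ints[[cn]](pmin(pmax(edges, 0), lens[[cn]]))
    v <- diff(vals) / bin_width
    v[edges[-length(edges)] < 0 | edges[-1L] > lens[[cn]]] <- NA_real_
    per_site[i, ] <- v
  }
  structure(list(bins = colMeans(per_site, na.rm = TRUE),
                 per_site = per_site, n_sites = nrow(sites), n_bins = n_bins,
                 bin_mid = -flank + bin_width * (seq_len(n_bins) - 0.5)),
            class = "profile_matrix")
}

#' Mean binned methylation profile around sites
#'
#' Per site and bin, the methylation level is sum(meth)/sum(total) over
#' cytosines of the requested context with coverage at least
#' `min_coverage`; bins without an eligible cytosine are missing and are
#' excluded from downstream tests.
#'
#' @param sites data.frame with contig, breakpoint.
#' @param methylation per-cytosine calls (contig, pos, context, meth,
#'   total).
#' @param context one of "CG", "CHG", "CHH".
#' @param flank,bin_width binning geometry.
#' @param min_coverage minimum per-cytosine total count.
#' @return a `profile_matrix` (see [profile_signal()]); per-bin value is
#'   the mean over sites with data.
#' @export
profile_methylation <- function(sites, methylation, context, flank = 3000L,
                                bin_width = 100L, min_coverage = 1L) {
  if (!context %in% c("CG", "CHG", "CHH")) {
    stop("profile_methylation(): unknown context '", context, "'")
  }
  if (nrow(sites) == 0) stop("profile_methylation(): no sites")
  m <- methylation[methylation$context == context &
                     methylation$total >= min_coverage, , drop = FALSE]
  n_bins <- as.integer(2L * flank / bin_width)
  per_site <- matrix(NA_real_, nrow(sites), n_bins)
  msplit <- split(m, m$contig)
  for (i in seq_len(nrow(sites))) {
    mc <- msplit[[sites$contig[i]]]
    if (is.null(mc)) next
    rel <- mc$pos - (sites$breakpoint[i] - flank)
    inwin <- rel >= 0L & rel < 2L * flank
    if (!any(inwin)) next
    bin <- rel[inwin] %/% bin_width + 1L
    meth <- tapply(mc$meth[inwin], bin, sum)
    total <- tapply(mc$total[inwin], bin, sum)
    per_site[i, as.integer(names(meth))] <- meth / total
  }
  structure(list(bins = colMeans(per_site, na.rm = TRUE),
                 per_site = per_site, n_sites = nrow(sites), n_bins = n_bins,
                 bin_mid = -flank + bin_width * (seq_len(n_bins) - 0.5)),
            class = "profile_matrix")
}

#' Draw uniform random control sites
#'
#' Uniform over positions at least `min_edge_distance` from contig ends,
#' without replacement, seeded.
#'
#' @param genome a `genome_sequence`.
#' @param n number of sites.
#' @param seed integer seed.
#' @param min_edge_distance exclusion zone at contig ends.
#' @return data.frame with contig, breakpoint.
#' @export
sample_random_sites <- function(genome, n, seed, min_edge_distance = 3000L) {
  check_genome(genome)
  if (n == 0) return(empty_df(contig = character(), breakpoint = integer()))
  lens <- contig_lengths(genome)
  adm <- pmax(lens - 2L * min_edge_distance, 0L)
  if (sum(adm) < n) stop("sample_random_sites(): insufficient admissible positions")
  with_seed(seed, {
    idx <- sample.int(sum(adm), n)
    cum <- cumsum(adm)
    ci <- findInterval(idx - 1L, cum) + 1L
    offset <- idx - c(0L, cum)[ci] - 1L
    data.frame(contig = names(lens)[ci],
               breakpoint = as.integer(min_edge_distance + offset),
               stringsAsFactors = FALSE)
  })
}

#' Compare two binned profiles by Wilcoxon rank-sum
#'
#' Two-sided rank-sum test over the two sets of per-bin values (n = 60
#' per group at the default binning). Bins missing in either profile are
#' dropped pairwise. Exact enumeration is used for n <= 8 per group with
#' no ties; otherwise the normal approximation with tie correction (and
#' continuity correction) applies, so identical profiles yield p = 1 up
#' to that convention.
#'
#' @param profile_a,profile_b `profile_matrix` objects sharing binning.
#' @return list with `W` and two-sided `p`.
#' @export
compare_profiles <- function(profile_a, profile_b) {
  if (profile_a$n_bins != profile_b$n_bins) {
    stop("compare_profiles(): profiles do not share binning")
  }
  ok <- !is.na(profile_a$bins) & !is.na(profile_b$bins)
  a <- profile_a$bins[ok]
  b <- profile_b$bins[ok]
  if (length(a) < 2L) stop("compare_profiles(): fewer than 2 defined bins")
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}
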