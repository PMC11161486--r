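# Presence/absence insertion matrices across accessions: genotype
# encoding, locus classification, Euclidean distances and neighbor-joining
# trees, and per-accession new-insertion burden.
#
# Genotype coding follows the germplasm convention: at a reference-class
# locus the insertion is in the assembly, so presence is REF ("0/0") and
# its deletion is "1/1"; at a non-reference locus absence is "0/0" and the
# insertion "1/1". Distances are computed on raw carrier bits, not the
# class-polarized genotype codes; Euclidean distance is invariant to
# complementing a column, so the two agree.

#' Encode a presence/absence matrix as VCF v4.2 (GT only)
#'
#' @param mat accessions x loci 0/1 matrix (rownames = accession ids,
#'   colnames = locus ids).
#' @param loci data.frame with locus_id, contig, position and a class
#'   column (`class` or `truth_class`), values "reference" /
#'   "non_reference".
#' @param path output path.
#' @return the path, invisibly.
#' @export
encode_vcf <- function(mat, loci, path) {
  cls <- if ("class" %in% names(loci)) loci$class else loci$truth_class
  if (is.null(cls) || !all(cls %in% c("reference", "non_reference"))) {
    stop("encode_vcf(): loci must carry class 'reference'/'non_reference'")
  }
  stopifnot(ncol(mat) == nrow(loci), all(mat %in% c(0L, 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Insertion locus class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(mat)), collapse = "\t")), con)
  for (j in seq_len(nrow(loci))) {
    present <- mat[, j] == 1L
    gt <- if (cls[j] == "reference") {
      ifelse(present, "0/0", "1/1")     # insertion is in the reference
    } else {
      ifelse(present, "1/1", "0/0")
    }
    writeLines(paste(c(loci$contig[j], loci$position[j] + 1L,
                       loci$locus_id[j], "N", "<INS>", ".", "PASS",
                       paste0("CLASS=", cls[j]), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Decode a presence/absence matrix from VCF
#'
#' Inverse of [encode_vcf()]: requires the CLASS INFO tag and haploid-coded
#' biallelic genotypes ("0/0" or "1/1" only).
#'
#' @param path VCF path.
#' @return list with `matrix` (accessions x loci, 0/1) and `loci`
#'   (locus_id, contig, position, class).
#' @export
decode_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  fix <- matrix(fix, ncol = 8L, dimnames = list(NULL, colnames(fix)))
  cls <- sub("^.*CLASS=([A-Za-z_]+).*$", "\\1", fix[, "INFO"])
  if (any(!grepl("CLASS=", fix[, "INFO"]))) {
    stop("decode_vcf(): missing CLASS INFO tag")
  }
  if (!all(cls %in% c("reference", "non_reference"))) {
    stop("decode_vcf(): unknown locus class in INFO")
  }
  gt <- vcfR::extract.gt(v)
  if (!all(gt %in% c("0/0", "1/1"))) {
    stop("decode_vcf(): genotypes must be 0/0 or 1/1")
  }
  present <- t(gt == ifelse(cls == "reference", "0/0", "1/1"))
  mode(present) <- "integer"
  rownames(present) <- colnames(gt)
  colnames(present) <- fix[, "ID"]
  list(matrix = present,
       loci = data.frame(locus_id = fix[, "ID"], contig = fix[, "CHROM"],
                         position = as.integer(fix[, "POS"]) - 1L,
                         class = cls, stringsAsFactors = FALSE))
}

#' Classify loci as reference / non-reference and flag new insertions
#'
#' A locus within `match_window` of a reference insertion is
#' reference-class; any other locus is non-reference, and a non-reference
#' locus carried by exactly one accession is flagged "new"
#' (a recent transposition).
#'
#' @param mat accessions x loci 0/1 matrix.
#' @param loci data.frame with locus_id, contig, position.
#' @param reference_annotation BED-style data frame (contig, start) of
#'   reference insertion positions.
#' @param match_window position match tolerance (bp).
#' @return `loci` with columns `class` and `new` added.
#' @export
classify_loci <- function(mat, loci, reference_annotation,
                          match_window = 50L) {
  carriers <- colSums(mat)
  cls <- vapply(seq_len(nrow(loci)), function(j) {
    ref <- reference_annotation[
      reference_annotation$contig == loci$contig[j], , drop = FALSE]
    if (nrow(ref) && any(abs(ref$start - loci$position[j]) <= match_window)) {
      "reference"
    } else "non_reference"
  }, character(1))
  loci$class <- cls
  loci$new <- cls == "non_reference" & carriers == 1L
  loci
}

#' Euclidean distance between accessions on carrier bits
#'
#' For binary rows this is the square root of the Hamming count.
#'
#' @param mat accessions x loci 0/1 matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance <- function(mat) {
  as.matrix(stats::dist(mat, method = "euclidean"))
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Iteratively joins the pair minimizing the Q criterion, with ties broken
#' by the smallest (i, j) index pair in the current matrix ordering;
#' branch lengths use the standard closed form, and a negative branch
#' length is clamped to zero with the deficit moved to its sister edge.
#' Exact on additive distance matrices. The returned tree is unrooted.
#'
#' @param d symmetric distance matrix (or `dist`) with labeled taxa.
#' @return an ape `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("neighbor_joining(): need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n == 2L) {
    half <- d[1L, 2L] / 2
    return(ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                         labels[1L], half, labels[2L], half)))
  }
  # each active node is a newick fragment (without trailing ; )
  frag <- labels
  while (n > 3L) {
    tot <- rowSums(d)
    q <- (n - 2) * d - outer(tot, tot, "+")
    diag(q) <- Inf
    # smallest (i, j), i < j, among minimizers
    min_q <- min(q)
    idx <- which(q - min_q <= min_q * 0 + 1e-12 * max(1, abs(min_q)),
                 arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]
    j <- idx[1L, 2L]
    li <- d[i, j] / 2 + (tot[i] - tot[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    # clamp negatives, moving the deficit to the sister edge
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], li, frag[j], lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
    n <- n - 1L
  }
  # terminal three-star
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  txt <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], ls[1], frag[2], ls[2], frag[3], ls[3])
  ape::read.tree(text = txt)
}

#' Build the presence/absence NJ tree for a matrix
#'
#' Convenience wrapper: Euclidean distance on carrier bits followed by
#' [neighbor_joining()].
#'
#' @param mat accessions x loci 0/1 matrix.
#' @return an ape `phylo` object.
#' @export
presence_absence_tree <- function(mat) {
  neighbor_joining(euclidean_distance(mat))
}

#' Does a group of taxa form a connected subtree?
#'
#' True iff some edge of the unrooted tree bipartitions the leaves into
#' the group versus the rest (checked by rooting at an outside leaf and
#' testing monophyly).
#'
#' @param tree an ape `phylo` object.
#' @param taxa character vector of leaf labels.
#' @return logical.
#' @export
is_group_subtree <- function(tree, taxa) {
  outside <- setdiff(tree$tip.label, taxa)
  if (length(outside) == 0 || length(taxa) <= 1L) return(TRUE)
  rooted <- ape::root(tree, outgroup = outside[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Per-accession new-insertion counts and group burden comparison
#'
#' Counts the "new"-flagged loci carried by each accession and compares
#' the two groups with a two-sided Wilcoxon rank-sum test.
#'
#' @param mat accessions x loci 0/1 matrix.
#' @param loci classified loci ([classify_loci()]) with a `new` column.
#' @param groups named character vector mapping accession to group
#'   (two levels).
#' @return list with `counts` (named per-accession), `by_group` (list of
#'   count vectors), `W`, `p` (NA when degenerate: no new loci anywhere).
#' @export
per_accession_new_counts <- function(mat, loci, groups) {
  stopifnot(all(rownames(mat) %in% names(groups)))
  gl <- groups[rownames(mat)]
  if (any(table(gl) < 2L)) {
    stop("per_accession_new_counts(): each group needs >= 2 accessions")
  }
  newcols <- which(loci$new)
  counts <- if (length(newcols)) {
    rowSums(mat[, newcols, drop = FALSE])
  } else stats::setNames(rep(0, nrow(mat)), rownames(mat))
  by_group <- split(counts, gl)
  if (all(counts == 0)) {
    return(list(counts = counts, by_group = by_group,
                W = NA_real_, p = NA_real_))
  }
  wt <- suppressWarnings(stats::wilcox.test(by_group[[1L]], by_group[[2L]]))
  list(counts = counts, by_group = by_group,
       W = unname(wt$statistic), p = wt$p.value)
}
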