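# Readers and writers for the external formats the pipeline touches.
#
# Internal convention, used everywhere in this package: coordinates are
# 0-based half-open ([start, end)), converted only at format boundaries.
# BED and bedGraph are already 0-based half-open; SAM, GFF3 and VCF are
# 1-based and are shifted on read/write.

#' Read a FASTA file into a genome_sequence
#'
#' Records are case-folded to uppercase and restricted to the A/C/G/T/N
#' alphabet; other IUPAC ambiguity codes are mapped to N with a warning.
#'
#' @param path path to a FASTA file.
#' @return a `genome_sequence`: named character vector of uppercase DNA
#'   strings, one per contig, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("read_fasta(): duplicate contig name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (any(grepl("[^ACGTNRYSWKMBDHVU]", seqs))) {
      stop("read_fasta(): non-IUPAC character in sequence")
    }
    warning("read_fasta(): non-ACGTN IUPAC codes mapped to N in ",
            sum(bad), " record(s)")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- nm
  as_genome(seqs)
}

#' @rdname read_fasta
#' @param genome a `genome_sequence` to write.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  check_genome(genome)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- unclass(genome)[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Construct a genome_sequence from a named character vector.
as_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  structure(seqs, class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence with", length(x), "contig(s):\n")
  print(contig_lengths(x))
  invisible(x)
}

# ---- SAM ------------------------------------------------------------------

# CIGAR helpers: parse "20S80M" into lengths + ops.
parse_cigar <- function(cigar) {
  if (cigar == "*") return(list(len = integer(), op = character()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(len = lens, op = ops)
}

cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

#' Read a SAM text file
#'
#' Only SAM text (with mandatory `@SQ` headers) is supported; alignments are
#' returned as a data frame with the alignment start converted to the
#' package-internal 0-based convention. A record whose query-consuming CIGAR
#' length disagrees with its sequence length raises an error naming the line.
#'
#' @param path path to a SAM file.
#' @return data.frame with columns qname, flag, rname, pos (0-based), mapq,
#'   cigar, rnext, pnext (0-based), seq; attribute `contig_lengths` holds the
#'   `@SQ` lengths.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ\t", lines)]
  if (length(sq) == 0) stop("read_sam(): no @SQ header lines in ", path)
  sq_name <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  sq_len <- as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
  body_idx <- which(!hdr & nzchar(lines))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("read_sam(): line ", body_idx[which(nf < 11L)[1L]],
         ": fewer than 11 mandatory fields")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  reads <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)) - 1L, mapq = as.integer(get(5)),
    cigar = get(6), rnext = get(7), pnext = as.integer(get(8)) - 1L,
    seq = get(10), stringsAsFactors = FALSE
  )
  reads$rnext <- ifelse(reads$rnext == "=", reads$rname, reads$rnext)
  ok <- reads$seq == "*" | reads$cigar == "*" |
    vapply(reads$cigar, cigar_query_length, integer(1)) == nchar(reads$seq)
  if (!all(ok)) {
    stop("read_sam(): line ", body_idx[which(!ok)[1L]],
         ": CIGAR query length does not match SEQ length")
  }
  attr(reads, "contig_lengths") <- stats::setNames(sq_len, sq_name)
  reads
}

#' @rdname read_sam
#' @param reads alignment data frame as returned by [read_sam()].
#' @param lengths named contig-length vector for the `@SQ` header; defaults
#'   to the `contig_lengths` attribute of `reads`.
#' @export
write_sam <- function(reads, path, lengths = attr(reads, "contig_lengths")) {
  if (is.null(lengths)) stop("write_sam(): contig lengths required for @SQ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), lengths), con)
  if (nrow(reads)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                       reads$qname, reads$flag, reads$rname, reads$pos + 1L,
                       reads$mapq, reads$cigar, reads$rnext, reads$pnext + 1L,
                       reads$seq), con)
  }
  invisible(path)
}

# SAM flag bit tests
flag_paired <- function(flag) bitwAnd(flag, 1L) > 0L
flag_unmapped <- function(flag) bitwAnd(flag, 4L) > 0L
flag_mate_unmapped <- function(flag) bitwAnd(flag, 8L) > 0L
flag_reverse <- function(flag) bitwAnd(flag, 16L) > 0L
flag_secondary <- function(flag) bitwAnd(flag, 256L) > 0L
flag_supplementary <- function(flag) bitwAnd(flag, 2048L) > 0L

# ---- BED / bedGraph -------------------------------------------------------

#' Read and write BED intervals
#'
#' BED3 and BED6 are supported; coordinates are kept 0-based half-open,
#' identical to the internal convention.
#'
#' @param path file path.
#' @return data.frame with columns contig, start, end and, when present,
#'   name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(empty_df(contig = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || !nf %in% c(3L, 6L)) {
    bad <- which(lengths(fields) != lengths(fields)[1L])[1L]
    stop("read_bed(): malformed or mixed-width line ",
         if (is.na(bad)) 1L else bad)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(contig = get(1), start = as.integer(get(2)),
                    end = as.integer(get(3)), stringsAsFactors = FALSE)
  if (nf == 6L) {
    out$name <- get(4)
    out$score <- as.numeric(get(5))
    out$strand <- get(6)
  }
  if (any(out$start >= out$end)) stop("read_bed(): start >= end")
  out
}

#' @rdname read_bed
#' @param intervals interval data frame (contig/start/end, optionally
#'   name/score/strand).
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  if (all(c("name", "score", "strand") %in% names(intervals))) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", intervals$contig,
                     as.integer(intervals$start), as.integer(intervals$end),
                     intervals$name, intervals$score, intervals$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", intervals$contig,
                     as.integer(intervals$start), as.integer(intervals$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write bedGraph signal tracks
#'
#' @param path file path.
#' @return data.frame with columns contig, start, end (0-based half-open),
#'   value.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop("read_bedgraph(): malformed line ", which(lengths(fields) != 4L)[1L])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(contig = get(1), start = as.integer(get(2)),
             end = as.integer(get(3)), value = as.numeric(get(4)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track bedGraph data frame (contig/start/end/value).
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$contig,
                     as.integer(track$start), as.integer(track$end),
                     track$value), path)
  invisible(path)
}

# ---- GFF3 -----------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features (via rtracklayer) and converts the
#' 1-based closed GFF3 coordinates to the internal 0-based half-open
#' convention.
#'
#' @param path path to a GFF3 file.
#' @return a `gene_models` list with data frames `genes` (gene_id, contig,
#'   start, end, strand) and `exons` (gene_id, contig, start, end).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (nrow(df) == 0 || !"type" %in% names(df)) {
    return(gene_models(empty_gene_df(), empty_exon_df()))
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  gene_id <- if ("ID" %in% names(genes)) as.character(genes$ID) else genes$seqnames
  # exon Parent may be a CharacterList
  parent <- if ("Parent" %in% names(exons)) {
    vapply(exons$Parent, function(p) as.character(p)[1L], character(1))
  } else rep(NA_character_, nrow(exons))
  gene_models(
    genes = data.frame(gene_id = gene_id,
                       contig = as.character(genes$seqnames),
                       start = genes$start - 1L, end = genes$end,
                       strand = as.character(genes$strand),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = parent,
                       contig = as.character(exons$seqnames),
                       start = exons$start - 1L, end = exons$end,
                       stringsAsFactors = FALSE)
  )
}

empty_gene_df <- function() {
  empty_df(gene_id = character(), contig = character(), start = integer(),
           end = integer(), strand = character())
}
empty_exon_df <- function() {
  empty_df(gene_id = character(), contig = character(), start = integer(),
           end = integer())
}

#' Bundle gene and exon tables into a gene_models object
#'
#' @param genes data.frame with gene_id, contig, start, end, strand
#'   (0-based half-open, strand in +/-).
#' @param exons data.frame with gene_id, contig, start, end.
#' @return a `gene_models` list.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$start < genes$end))
  if (nrow(exons)) {
    m <- match(exons$gene_id, genes$gene_id)
    if (anyNA(m)) stop("gene_models(): exon with unknown gene_id")
    if (any(exons$start < genes$start[m]) || any(exons$end > genes$end[m])) {
      stop("gene_models(): exon outside its gene span")
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models to GFF3
#'
#' @param models a `gene_models` list.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- models$genes
  e <- models$exons
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tpiftools\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ei)) {
      writeLines(sprintf(
        "%s\tpiftools\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        ei$contig, ei$start + 1L, ei$end, g$strand[i], g$gene_id[i],
        seq_len(nrow(ei)), g$gene_id[i]), con)
    }
  }
  invisible(path)
}

# ---- Newick ---------------------------------------------------------------

#' Read/write Newick trees (thin wrappers over ape)
#'
#' @param tree an ape `phylo` object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
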