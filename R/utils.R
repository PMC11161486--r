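# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate code for a set of bases (sorted A<C<G<T).
IUPAC_CODES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B",
  "ACGT" = "N"
)

#' Reverse complement of a DNA string
#'
#' Strict A/C/G/T/N alphabet; N maps to N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Split a DNA string into a character vector of single bases.
str_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Deterministic RNG scope: run `expr` under `seed` without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Validate a genome_sequence object (named uppercase ACGTN strings).
check_genome <- function(genome) {
  if (!inherits(genome, "genome_sequence")) {
    stop("expected a 'genome_sequence' (see read_fasta()/simulate_genome())")
  }
  invisible(genome)
}

#' Contig lengths of a genome
#'
#' @param genome a `genome_sequence`.
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  check_genome(genome)
  vapply(unclass(genome), nchar, integer(1))
}

# zero-row data.frame with given column name/class pairs, e.g.
# empty_df(contig = character(), start = integer())
empty_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
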