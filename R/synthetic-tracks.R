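# Simulation of chromatin signal tracks and per-cytosine methylation
# tables, with configurable enrichment around new insertion sites.

#' Simulate chromatin signal and methylation around insertion sites
#'
#' Produces a binned bedGraph signal track (Gaussian noise around
#' `signal_baseline`, arbitrary units) and a per-cytosine methylation table
#' (contexts CG/CHG/CHH read off the + strand sequence). Within
#' `chromatin_flank` of a new-category site the signal is shifted by
#' `signal_effect` and the per-context methylation probability by
#' `meth_effect` (clamped to [0, 1]); other sites are untouched.
#'
#' @param genome a `genome_sequence`.
#' @param truth insertion truth table with contig, breakpoint, category;
#'   only rows with category "new" receive the effect.
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to `config$seed + 23`).
#' @return list with `track` (bedGraph data frame) and `methylation`
#'   (data frame contig, pos, context, meth, total).
#' @export
simulate_chromatin_tracks <- function(genome, truth, config = sim_config(),
                                      seed = config$seed + 23L) {
  check_genome(genome)
  lens <- contig_lengths(genome)
  new_sites <- truth[truth$category == "new", , drop = FALSE]
  near_new <- function(contig, pos) {
    ns <- new_sites[new_sites$contig == contig, , drop = FALSE]
    if (nrow(ns) == 0) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (b in ns$breakpoint) {
      out <- out | abs(pos - b) <= config$chromatin_flank
    }
    out
  }
  with_seed(seed, {
    bw <- config$track_bin
    track <- do.call(rbind, lapply(names(lens), function(cn) {
      starts <- seq(0L, lens[[cn]] - bw, by = bw)
      mid <- starts + bw %/% 2L
      val <- stats::rnorm(length(starts), config$signal_baseline,
                          config$signal_noise_sd)
      val[near_new(cn, mid)] <- val[near_new(cn, mid)] + config$signal_effect
      data.frame(contig = cn, start = starts, end = starts + bw,
                 value = val, stringsAsFactors = FALSE)
    }))
    meth <- do.call(rbind, lapply(names(lens), function(cn) {
      s <- unclass(genome)[[cn]]
      ch <- str_bases(s)
      cpos <- which(ch == "C")
      cpos <- cpos[cpos <= length(ch) - 2L]
      keep <- stats::runif(length(cpos)) < config$cytosine_rate
      cpos <- cpos[keep]
      if (length(cpos) == 0) return(NULL)
      ctx <- ifelse(ch[cpos + 1L] == "G", "CG",
                    ifelse(ch[cpos + 2L] == "G", "CHG", "CHH"))
      p <- config$meth_baseline[ctx]
      hit <- near_new(cn, cpos - 1L)
      p[hit] <- p[hit] + config$meth_effect[ctx[hit]]
      p <- pmin(pmax(p, 0), 1)
      total <- stats::rpois(length(cpos), config$meth_depth)
      data.frame(contig = cn, pos = cpos - 1L, context = ctx,
                 meth = stats::rbinom(length(cpos), total, p), total = total,
                 stringsAsFactors = FALSE)
    }))
    list(track = track, methylation = meth)
  })
}
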