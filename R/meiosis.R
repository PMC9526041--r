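# Count-location meiosis. For each chromosome independently:
#   1. crossover count ~ Poisson(tracked span in Morgans),
#   2. crossover positions i.i.d. Uniform over the tracked cM span,
#   3. a fair coin picks which homolog the gamete starts on,
#   4. the gamete reads along the starting homolog, switching to the other
#      homolog each time a crossover position is passed.
# No interference, no mutation, no sex-specific maps. Under this model the
# recombination fraction between two markers d Morgans apart is Haldane's
# (1 - exp(-2d)) / 2.

#' Draw crossover counts for a chromosome
#'
#' The per-meiosis crossover count of a chromosome is Poisson with mean
#' equal to the chromosome's tracked map length in Morgans, so a 1-Morgan
#' chromosome sees one crossover on average, and a zero-span chromosome
#' (single marker, or all markers co-located) never recombines.
#'
#' @param length Chromosome span in Morgans (nonnegative scalar).
#' @param n Number of independent draws.
#' @return Integer vector of `n` crossover counts.
#' @export
draw_crossover_count <- function(length, n = 1L) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 0)
    stop("`length` must be a single nonnegative number of Morgans",
         call. = FALSE)
  if (length == 0) return(rep.int(0L, n))
  stats::rpois(n, length)
}

#' Draw crossover positions along a chromosome
#'
#' Positions are i.i.d. uniform over the tracked span and returned sorted
#' ascending, matching the order the gamete-builder consumes them in.
#'
#' @param count Number of crossovers (nonnegative integer).
#' @param span_start,span_end Ends of the tracked span, in centimorgans,
#'   with `span_end >= span_start`.
#' @return Sorted numeric vector of `count` positions in cM.
#' @export
draw_crossover_positions <- function(count, span_start, span_end) {
  stopifnot(count >= 0, span_end >= span_start)
  if (count == 0L) return(numeric(0))
  sort(stats::runif(count, span_start, span_end))
}

# Core gamete builder on raw haplotype columns. h1/h2: raw vectors over all
# mapped markers. Consumes RNG in the order: count, positions, starting
# homolog — per chromosome. A crossover falling exactly on a marker position
# toggles the active homolog *before* that marker is read (findInterval
# counts boundary positions as passed).
.gamete_raw <- function(map, h1, h2) {
  out <- h1
  for (ch in map$chr) {
    k <- if (ch$span > 0) stats::rpois(1L, ch$span) else 0L
    if (k > 0L) {
      x <- sort.int(stats::runif(k, ch$pos[1L], ch$pos[ch$n]))
      odd <- bitwAnd(findInterval(ch$pos, x), 1L) == 1L
    } else {
      odd <- FALSE
    }
    start2 <- stats::runif(1L) < 0.5
    take2 <- xor(start2, odd)
    if (any(take2)) {
      sel <- ch$idx[take2]
      out[sel] <- h2[sel]
    }
  }
  out
}

#' Generate one gamete from a parent
#'
#' Runs count-location meiosis over every chromosome of the session map and
#' returns the resulting haplotype. Every returned allele is one of the
#' parent's two alleles at that marker (meiosis is simulated without
#' mutation).
#'
#' @param sim A simulation session.
#' @param parent Id of a live genotype.
#' @return Character vector of single-character alleles, one per mapped
#'   marker, in map order.
#' @export
generate_gamete <- function(sim, parent) {
  .check_sim(sim)
  col <- .cols_of(sim, parent)
  g <- .gamete_raw(sim$map, sim$hap1[, col], sim$hap2[, col])
  strsplit(rawToChar(g), "", fixed = TRUE)[[1L]]
}
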