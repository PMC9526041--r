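# Synthetic founders, maps, and effect tables, so every test, demo, and
# packaged scenario runs without any external data. Fixtures are always
# emitted through the io writers (write_map_file(), write_genotype_file(),
# write_effects_file()) so the file dialects themselves get exercised.
#
# Synthetic loci are biallelic with a fixed A/B allele coding (reference
# "A", alternative "B"), which keeps synth_effects() consistent with
# synth_founders() without the two having to see each other's draws.
# Founders are exchangeable draws without linkage structure; LD structure
# arises downstream from simulated crossing, not from the founder draw.

#' Generate a synthetic genetic map
#'
#' Chromosomes are named `chr1 ... chrN`; each carries markers at sorted
#' uniform positions on `[0, length_cM]`, named `c<chr>m<index>`.
#'
#' @param n_chr Number of chromosomes.
#' @param markers_per_chr Markers on each chromosome.
#' @param length_cM Chromosome length in centimorgans.
#' @return A [new_genetic_map()] object.
#' @export
synth_map <- function(n_chr, markers_per_chr, length_cM) {
  stopifnot(n_chr >= 1L, markers_per_chr >= 1L, length_cM >= 0)
  tabs <- lapply(seq_len(n_chr), function(c) {
    pos <- sort(stats::runif(markers_per_chr, 0, length_cM))
    data.frame(marker = paste0("c", c, "m", seq_len(markers_per_chr)),
               chr = paste0("chr", c), pos = pos,
               stringsAsFactors = FALSE)
  })
  new_genetic_map(do.call(rbind, tabs))
}

#' Generate synthetic founder genotypes
#'
#' Every locus is biallelic (`A`/`B`) with its minor ("B") allele frequency
#' drawn uniformly from `maf_range`. With `inbred = TRUE` each founder is
#' fully homozygous (each locus fixed for `B` with the locus frequency);
#' otherwise the two alleles are drawn independently, so founders are
#' heterozygous at Hardy-Weinberg rates.
#'
#' @param n Number of founders.
#' @param map A `meiosim_map` the founders are genotyped on.
#' @param maf_range Length-2 numeric: bounds for the per-locus "B"
#'   frequency.
#' @param inbred Generate fully homozygous founders?
#' @return A [genotype_table()] (unphased) with founders named `f1 ... fn`.
#' @export
synth_founders <- function(n, map, maf_range = c(0.1, 0.5), inbred = FALSE) {
  stopifnot(inherits(map, "meiosim_map"), n >= 1L,
            length(maf_range) == 2L, maf_range[1] <= maf_range[2],
            maf_range[1] >= 0, maf_range[2] <= 1)
  m <- map$n_markers
  f <- stats::runif(m, maf_range[1], maf_range[2])
  pick <- function() ifelse(stats::runif(m) < f, "B", "A")
  cells <- matrix("", nrow = m, ncol = n)
  for (j in seq_len(n)) {
    a1 <- pick()
    a2 <- if (inbred) a1 else pick()
    cells[, j] <- paste0(a1, a2)
  }
  genotype_table(map$table$marker, paste0("f", seq_len(n)), cells,
                 phased = FALSE)
}

#' Generate a synthetic additive effect table
#'
#' A random subset of markers (`proportion_causal` of them, at least one)
#' becomes causal: the `A` allele at a causal marker gets an effect drawn
#' from Normal(0, `effect_sd`^2), the `B` allele keeps the implicit effect
#' 0. Noncausal markers are absent from the table.
#'
#' @param map A `meiosim_map`.
#' @param proportion_causal Fraction of markers with a nonzero-effect
#'   allele, in (0, 1].
#' @param effect_sd Standard deviation of the per-allele effects.
#' @return Data.frame `(marker, allele, effect)` for
#'   [write_effects_file()].
#' @export
synth_effects <- function(map, proportion_causal = 0.5, effect_sd = 1) {
  stopifnot(inherits(map, "meiosim_map"),
            proportion_causal > 0, proportion_causal <= 1, effect_sd >= 0)
  m <- map$n_markers
  k <- max(1L, as.integer(floor(m * proportion_causal)))
  causal <- sort(sample.int(m, k))
  data.frame(marker = map$table$marker[causal],
             allele = rep("A", k),
             effect = stats::rnorm(k, 0, effect_sd),
             stringsAsFactors = FALSE)
}

# write a complete synthetic data set into a directory; returns the paths.
# Convenience used by the packaged scenarios and the command-line front end.
.synth_dataset <- function(dir, n_founders, n_chr, markers_per_chr,
                           length_cM, inbred = TRUE,
                           maf_range = c(0.1, 0.5),
                           proportion_causal = 0.5, effect_sd = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  map <- synth_map(n_chr, markers_per_chr, length_cM)
  paths <- list(genotypes = file.path(dir, "founder-genotypes.txt"),
                map = file.path(dir, "genetic-map.txt"),
                effects = file.path(dir, "allele-effects.txt"))
  write_map_file(map, paths$map)
  write_genotype_file(synth_founders(n_founders, map, maf_range, inbred),
                      paths$genotypes)
  write_effects_file(synth_effects(map, proportion_causal, effect_sd),
                     paths$effects)
  paths
}
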