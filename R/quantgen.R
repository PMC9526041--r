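# Quantitative genetics: additive breeding values, heritability-masked
# phenotypes, truncation selection.
#
# The breeding value of a genotype is the sum over all marker positions of
# the effect values of its two alleles there; (marker, allele) pairs absent
# from the loaded effect set contribute 0, so sparse effect tables are fine
# and the missing character "-" is automatically neutral.

# breeding values for live columns (vectorized over the effect table)
.bv_cols <- function(sim, cols) {
  if (is.null(sim$effects))
    stop("no allele effects loaded; pass effects_file to load_data() or ",
         "call load_different_effects()", call. = FALSE)
  eff <- sim$effects
  bv <- numeric(length(cols))
  for (al in unique(eff$allele)) {
    sel <- eff$allele == al
    midx <- eff$midx[sel]
    e <- eff$effect[sel]
    # e recycles down the rows of the (marker subset x member) masks
    bv <- bv + colSums(e * (sim$hap1[midx, cols, drop = FALSE] == al)) +
               colSums(e * (sim$hap2[midx, cols, drop = FALSE] == al))
  }
  bv
}

#' Additive breeding values of a group
#'
#' @param sim A simulation session with a loaded effect set.
#' @param group Group handle.
#' @return Numeric vector, one breeding value per member in stable member
#'   order (identical to `see_group_data(sim, group, "bv")`).
#' @export
breeding_values <- function(sim, group) {
  .check_sim(sim)
  .bv_cols(sim, .group_cols(sim, group))
}

#' Mean and variance of a group's breeding values
#'
#' The two per-cycle summaries tracked when comparing breeding strategies:
#' genetic gain (mean) and remaining genetic variance.
#'
#' @param sim A simulation session with a loaded effect set.
#' @param group Group handle (nonempty).
#' @return Named numeric vector `c(mean, variance)`; variance is the
#'   unbiased (n - 1) sample variance, reported as 0 with a warning for a
#'   single-member group.
#' @export
group_bv_summary <- function(sim, group) {
  .check_sim(sim)
  bv <- breeding_values(sim, group)
  v <- if (length(bv) < 2L) {
    warning("variance undefined for a single-member group; reporting 0",
            call. = FALSE)
    0
  } else stats::var(bv)
  c(mean = mean(bv), variance = v)
}

#' Simulate phenotypes by masking breeding values
#'
#' Phenotypes follow P = G + E: each member's breeding value plus an
#' independent draw from Normal(0, Ve). The environmental variance is sized
#' from the target broad-sense heritability by rearranging
#' H2 = Vg / (Vg + Ve) into Ve = Vg / H2 - Vg, with Vg the unbiased sample
#' variance of the group's breeding values. `heritability = 1` gives
#' Ve = 0, i.e. P = G exactly. If the group has no genetic variance
#' (Vg = 0, including single-member groups), Ve is defined as 0 and the
#' phenotype equals the breeding value.
#'
#' Phenotypes are ephemeral: they are drawn fresh on every call and never
#' stored, so repeated phenotyping of the same group models independent
#' trials.
#'
#' @param sim A simulation session with a loaded effect set.
#' @param group Group handle.
#' @param heritability Broad-sense heritability H2, in (0, 1].
#' @return Numeric vector of phenotypes in stable member order.
#' @export
simulate_phenotypes <- function(sim, group, heritability) {
  .check_sim(sim)
  if (!is.numeric(heritability) || length(heritability) != 1L ||
      is.na(heritability) || heritability <= 0 || heritability > 1)
    stop("`heritability` must be in (0, 1]", call. = FALSE)
  bv <- breeding_values(sim, group)
  vg <- if (length(bv) < 2L) 0 else stats::var(bv)
  ve <- if (vg == 0) 0 else vg / heritability - vg
  bv + stats::rnorm(length(bv), mean = 0, sd = sqrt(ve))
}

# shared truncation machinery: pick top/bottom n by score, ties broken by
# creation order (earlier-created member wins), move them to a new group
.truncate_by <- function(sim, cols, score, n, lowest) {
  ord <- order(if (lowest) score else -score, sim$ids[cols], method = "radix")
  make_group(sim, sim$ids[cols][ord[seq_len(n)]])
}

.selection_n <- function(size, count, fraction) {
  if (is.null(count) == is.null(fraction))
    stop("give exactly one of `count` or `fraction`", call. = FALSE)
  if (!is.null(count)) {
    if (count < 1L || count > size)
      stop("`count` must be between 1 and the group size (", size, ")",
           call. = FALSE)
    as.integer(count)
  } else {
    if (fraction <= 0 || fraction > 1)
      stop("`fraction` must be in (0, 1]", call. = FALSE)
    max(1L, as.integer(floor(size * fraction)))
  }
}

#' Truncation selection on breeding values
#'
#' Moves the members with the highest (default) or lowest breeding values
#' into a new group. With `fraction`, the selected count is
#' `floor(size * fraction)`, with a minimum of 1. Ties at the cut are
#' broken in favour of the earlier-created member, so results are
#' deterministic.
#'
#' @param sim A simulation session with a loaded effect set.
#' @param group Group handle.
#' @param count Number of members to select (give this or `fraction`).
#' @param fraction Fraction of the group to select, in (0, 1].
#' @param lowest Select the lowest instead of the highest values.
#' @return The fresh group handle of the selected members.
#' @export
select_by_gebv <- function(sim, group, count = NULL, fraction = NULL,
                           lowest = FALSE) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  n <- .selection_n(length(cols), count, fraction)
  .truncate_by(sim, cols, .bv_cols(sim, cols), n, lowest)
}

#' Truncation selection on simulated phenotypes
#'
#' Phenotypes the group at the given heritability (see
#' [simulate_phenotypes()]) and moves the top `floor(size * portion)`
#' members (minimum 1) by phenotype into a new group. At
#' `heritability = 1` this is identical to [select_by_gebv()] with the same
#' portion; at low heritability the phenotype mask makes selection noisy,
#' emulating selection on unreplicated early-generation trials.
#'
#' @param sim A simulation session with a loaded effect set.
#' @param group Group handle.
#' @param heritability Broad-sense heritability of the phenotyping stage.
#' @param portion Fraction of the group to keep, in (0, 1].
#' @return The fresh group handle of the selected members.
#' @export
select_by_phenotype <- function(sim, group, heritability, portion) {
  .check_sim(sim)
  if (!is.numeric(portion) || portion <= 0 || portion > 1)
    stop("`portion` must be in (0, 1]", call. = FALSE)
  cols <- .group_cols(sim, group)
  p <- simulate_phenotypes(sim, group, heritability)
  n <- max(1L, as.integer(floor(length(cols) * portion)))
  .truncate_by(sim, cols, p, n, lowest = FALSE)
}
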