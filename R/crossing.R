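# Offspring-producing operations. Each operation draws gametes through the
# meiosis engine and registers the offspring in a fresh group. No
# distinction is made between "male" and "female" parent; the stored parent
# order is the call order. Offspring names are auto-generated as
# <op-prefix><id> ("cr" crosses, "sf" selfing, "dh" doubled haploids).

# produce offspring for parallel parent vectors (one offspring per entry)
.make_offspring <- function(sim, p1_ids, p2_ids, prefix) {
  n <- length(p1_ids)
  cols1 <- .cols_of(sim, p1_ids)
  cols2 <- .cols_of(sim, p2_ids)
  m <- sim$map$n_markers
  h1 <- matrix(raw(0), nrow = m, ncol = n)
  h2 <- matrix(raw(0), nrow = m, ncol = n)
  for (i in seq_len(n)) {
    h1[, i] <- .gamete_raw(sim$map, sim$hap1[, cols1[i]], sim$hap2[, cols1[i]])
    h2[, i] <- .gamete_raw(sim$map, sim$hap1[, cols2[i]], sim$hap2[, cols2[i]])
  }
  .add_records(sim, h1, h2, p1_ids, p2_ids, prefix)
}

#' Cross two specific parents
#'
#' Generates one gamete independently from each parent per offspring;
#' offspring haplotype 1 comes from `parent1` and haplotype 2 from
#' `parent2`.
#'
#' @param sim A simulation session.
#' @param parent1,parent2 Ids of live genotypes.
#' @param offspring Number of offspring to produce.
#' @return The fresh group handle holding the offspring.
#' @export
cross <- function(sim, parent1, parent2, offspring = 1L) {
  .check_sim(sim)
  stopifnot(length(parent1) == 1L, length(parent2) == 1L, offspring >= 1L)
  .make_offspring(sim, rep(as.integer(parent1), offspring),
                  rep(as.integer(parent2), offspring), "cr")
}

#' Random crosses within a group
#'
#' Draws `n_crosses` parent pairs uniformly (with replacement between
#' crosses) from the group, redrawing whenever the same individual is drawn
#' twice for one pair — selfing is a separate operation
#' ([self_n_times()]). Each pair produces `offspring` offspring.
#'
#' @param sim A simulation session.
#' @param group Group handle with >= 2 members.
#' @param n_crosses Number of parent pairs.
#' @param offspring Offspring per pair.
#' @return The fresh group handle (size `n_crosses * offspring`).
#' @export
cross_randomly <- function(sim, group, n_crosses, offspring = 1L) {
  .check_sim(sim)
  stopifnot(n_crosses >= 1L, offspring >= 1L)
  members <- sim$ids[.group_cols(sim, group)]
  if (length(members) < 2L)
    stop("cross_randomly() needs a group of >= 2 members", call. = FALSE)
  p1 <- sample(members, n_crosses, replace = TRUE)
  p2 <- sample(members, n_crosses, replace = TRUE)
  repeat {
    clash <- p1 == p2
    if (!any(clash)) break
    p2[clash] <- sample(members, sum(clash), replace = TRUE)
  }
  .make_offspring(sim, rep(p1, each = offspring), rep(p2, each = offspring),
                  "cr")
}

#' Execute a listed crossing plan
#'
#' Performs exactly the crosses `(parent1[i], parent2[i])`, in order. All
#' parent ids are validated before any offspring are produced
#' (all-or-nothing). Duplicated pairs are performed once per listing, each
#' with independent meioses.
#'
#' @param sim A simulation session.
#' @param parent1,parent2 Equal-length vectors of live genotype ids.
#' @param offspring Offspring per listed pair.
#' @return The fresh group handle (size `length(parent1) * offspring`).
#' @export
cross_combinations <- function(sim, parent1, parent2, offspring = 1L) {
  .check_sim(sim)
  if (length(parent1) == 0L)
    stop("empty crossing plan", call. = FALSE)
  if (length(parent1) != length(parent2))
    stop("`parent1` and `parent2` must have equal length", call. = FALSE)
  stopifnot(offspring >= 1L)
  .cols_of(sim, parent1)  # validate before producing anything
  .cols_of(sim, parent2)
  .make_offspring(sim, rep(as.integer(parent1), each = offspring),
                  rep(as.integer(parent2), each = offspring), "cr")
}

#' Cross every unordered pair in a group
#'
#' One offspring per unordered pair of distinct members: a group of n
#' produces choose(n, 2) offspring. Pairs are unordered because parent
#' order has no modeled consequence.
#'
#' @param sim A simulation session.
#' @param group Group handle with >= 2 members.
#' @return The fresh group handle (size `n * (n - 1) / 2`).
#' @export
cross_all_pairs <- function(sim, group) {
  .check_sim(sim)
  members <- sim$ids[.group_cols(sim, group)]
  if (length(members) < 2L)
    stop("cross_all_pairs() needs a group of >= 2 members", call. = FALSE)
  pairs <- utils::combn(members, 2L)
  .make_offspring(sim, pairs[1L, ], pairs[2L, ], "cr")
}

#' Self a group for n generations (single-seed descent)
#'
#' Each group member is independently self-fertilized for `n` sequential
#' generations: at each step two independent gametes are drawn from the
#' same current individual. Intermediate generations are not retained; only
#' the final generation is registered, one line per input member (times
#' `offspring`, which multiplies at the final step only — single-seed
#' descent until the last generation). Because the intermediates are
#' discarded, the recorded parents of each output line are the input group
#' member it descends from (the line progenitor), so family bookkeeping
#' follows lines rather than unretained intermediates.
#'
#' @param sim A simulation session.
#' @param group Group handle (nonempty).
#' @param n Number of selfing generations, `>= 1`.
#' @param offspring Progeny per line at the final selfing step.
#' @return The fresh group handle (size `group size * offspring`).
#' @export
self_n_times <- function(sim, group, n, offspring = 1L) {
  .check_sim(sim)
  if (!is.numeric(n) || length(n) != 1L || n < 1L)
    stop("`n` must be an integer >= 1", call. = FALSE)
  n <- as.integer(n)
  stopifnot(offspring >= 1L)
  cols <- .group_cols(sim, group)
  members <- sim$ids[cols]
  m <- sim$map$n_markers
  nl <- length(cols)
  h1 <- matrix(raw(0), nrow = m, ncol = nl * offspring)
  h2 <- matrix(raw(0), nrow = m, ncol = nl * offspring)
  for (i in seq_len(nl)) {
    a <- sim$hap1[, cols[i]]
    b <- sim$hap2[, cols[i]]
    if (n > 1L) for (gen in seq_len(n - 1L)) {
      a2 <- .gamete_raw(sim$map, a, b)
      b2 <- .gamete_raw(sim$map, a, b)
      a <- a2
      b <- b2
    }
    for (k in seq_len(offspring)) {
      j <- (i - 1L) * offspring + k
      h1[, j] <- .gamete_raw(sim$map, a, b)
      h2[, j] <- .gamete_raw(sim$map, a, b)
    }
  }
  .add_records(sim, h1, h2, rep(members, each = offspring),
               rep(members, each = offspring), "sf")
}

#' Make doubled haploids from a group
#'
#' For each member, one gamete is generated and duplicated into both
#' haplotypes, so every output locus is homozygous (heterozygosity exactly
#' 0).
#'
#' @param sim A simulation session.
#' @param group Group handle (nonempty).
#' @return The fresh group handle (same size as the input group).
#' @export
make_doubled_haploids <- function(sim, group) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  members <- sim$ids[cols]
  m <- sim$map$n_markers
  h <- matrix(raw(0), nrow = m, ncol = length(cols))
  for (i in seq_along(cols))
    h[, i] <- .gamete_raw(sim$map, sim$hap1[, cols[i]], sim$hap2[, cols[i]])
  .add_records(sim, h, h, members, members, "dh")
}
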