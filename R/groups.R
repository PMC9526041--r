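# Group bookkeeping. Every live genotype belongs to exactly one group, and
# groups are the unit of every crossing and selection operation. Handles
# are positive integers; a handle is valid only while at least one live
# record carries it (a group dies with its last member — there is no empty
# group). Member order within a group is creation order, which makes
# see_group_data() output and selection tie-breaking reproducible.

#' Move specific genotypes into a new group
#'
#' The workhorse of custom selection: identify individuals (e.g. from
#' [see_group_data()] output), then move them into a fresh "selected"
#' group. Their previous groups shrink accordingly; a previous group left
#' empty ceases to exist.
#'
#' @param sim A simulation session.
#' @param indices Nonempty vector of live genotype ids.
#' @return The fresh group handle.
#' @export
make_group <- function(sim, indices) {
  .check_sim(sim)
  if (length(indices) == 0L)
    stop("`indices` must name at least one genotype", call. = FALSE)
  cols <- .cols_of(sim, indices)
  g <- sim$next_group
  sim$next_group <- sim$next_group + 1L
  sim$group[cols] <- g
  g
}

#' Merge groups into one
#'
#' @param sim A simulation session.
#' @param groups Vector of valid group handles.
#' @return A fresh handle for the union; its size is the sum of the input
#'   sizes.
#' @export
combine_groups <- function(sim, groups) {
  .check_sim(sim)
  cols <- unlist(lapply(groups, .group_cols, sim = sim))
  g <- sim$next_group
  sim$next_group <- sim$next_group + 1L
  sim$group[cols] <- g
  g
}

#' Split a group into full-sib families
#'
#' One new group per distinct unordered parent-id pair (parent order has no
#' modeled meaning). Founders, which have no recorded parents, form a
#' single class of their own.
#'
#' @param sim A simulation session.
#' @param group Group handle (nonempty).
#' @return Integer vector of fresh group handles, one per family, in order
#'   of first appearance within the group.
#' @export
break_into_families <- function(sim, group) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  ids <- sim$ids[cols]
  rows <- match(ids, sim$ped$id)
  p1 <- sim$ped$parent1[rows]
  p2 <- sim$ped$parent2[rows]
  key <- ifelse(is.na(p1) | is.na(p2), "founder",
                paste(pmin(p1, p2), pmax(p1, p2)))
  .split_by_key(sim, cols, key)
}

#' Split a group into half-sib families
#'
#' One new group per distinct parent in the designated parent slot. Because
#' the model makes no male/female distinction, which slot defines the
#' shared parent is the caller's choice.
#'
#' @param sim A simulation session.
#' @param group Group handle (nonempty).
#' @param which_parent 1 or 2: the parent slot to group by.
#' @return Integer vector of fresh group handles.
#' @export
break_into_halfsib_families <- function(sim, group, which_parent = 1L) {
  .check_sim(sim)
  if (!which_parent %in% c(1L, 2L))
    stop("`which_parent` must be 1 or 2", call. = FALSE)
  cols <- .group_cols(sim, group)
  rows <- match(sim$ids[cols], sim$ped$id)
  p <- if (which_parent == 1L) sim$ped$parent1[rows] else sim$ped$parent2[rows]
  key <- ifelse(is.na(p), "founder", as.character(p))
  .split_by_key(sim, cols, key)
}

.split_by_key <- function(sim, cols, key) {
  lev <- unique(key)
  out <- integer(length(lev))
  for (i in seq_along(lev)) {
    g <- sim$next_group
    sim$next_group <- sim$next_group + 1L
    sim$group[cols[key == lev[i]]] <- g
    out[i] <- g
  }
  names(out) <- lev
  out
}

#' Randomly partition a group
#'
#' Moves random disjoint subgroups out of a group, e.g. to demarcate
#' male/female offspring or to carve out subsets of specific sizes. Give
#' either `n` (that many near-equal subgroups covering the whole group) or
#' `sizes` (explicit subgroup sizes; any remainder stays in the source
#' group).
#'
#' @param sim A simulation session.
#' @param group Group handle.
#' @param n Number of near-equal subgroups.
#' @param sizes Integer vector of subgroup sizes, summing to at most the
#'   group size.
#' @return Integer vector of fresh group handles, one per subgroup.
#' @export
split_randomly <- function(sim, group, n = NULL, sizes = NULL) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  sz <- length(cols)
  if (is.null(sizes)) {
    if (is.null(n) || n < 1L)
      stop("give either `n` >= 1 or `sizes`", call. = FALSE)
    n <- as.integer(n)
    sizes <- rep.int(sz %/% n, n)
    extra <- sz %% n
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 0L) || sum(sizes) > sz)
    stop("requested sizes exceed the group size (", sz, ")", call. = FALSE)
  shuffled <- sample(cols, sum(sizes))
  out <- integer(length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    g <- sim$next_group
    sim$next_group <- sim$next_group + 1L
    take <- shuffled[seq.int(at + 1L, length.out = sizes[i])]
    sim$group[take] <- g
    out[i] <- g
    at <- at + sizes[i]
  }
  out
}

#' Pull per-member data out of a group
#'
#' Returns one value per live member, in stable member order (creation
#' order). This is the hook for scripting custom selection in R: fetch
#' indices plus breeding values, rank them however you like, and pass the
#' chosen indices to [make_group()].
#'
#' @param sim A simulation session.
#' @param group Group handle.
#' @param data One of `"index"` (record ids), `"name"`, `"bv"` (additive
#'   breeding values; requires a loaded effect set), `"genotype"`
#'   (phase-encoded allele string, two characters per locus in map order),
#'   `"parent1"`, `"parent2"` (parent ids, `NA` for founders), or
#'   `"pedigree"` (text `"name = parent1 x parent2"`).
#' @return A vector with one element per member.
#' @export
see_group_data <- function(sim, group,
                           data = c("index", "name", "bv", "genotype",
                                    "parent1", "parent2", "pedigree")) {
  .check_sim(sim)
  data <- match.arg(data)
  cols <- .group_cols(sim, group)
  ids <- sim$ids[cols]
  rows <- match(ids, sim$ped$id)
  switch(data,
    index = ids,
    name = sim$ped$name[rows],
    bv = .bv_cols(sim, cols),
    genotype = apply(.cells_of_cols(sim, cols), 2L, paste, collapse = ""),
    parent1 = sim$ped$parent1[rows],
    parent2 = sim$ped$parent2[rows],
    pedigree = {
      p1 <- sim$ped$parent1[rows]
      p2 <- sim$ped$parent2[rows]
      nm <- function(p) ifelse(is.na(p), "(founder)",
                               sim$ped$name[match(p, sim$ped$id)])
      paste0(sim$ped$name[rows], " = ", nm(p1), " x ", nm(p2))
    })
}

#' Delete groups and their genotypes
#'
#' The only destructor: groups and genotypes persist until explicitly
#' deleted, so mixed-generation operations are possible and memory use is
#' under the script's control. Deleted ids are never reused; pedigree rows
#' (id, name, parents) of deleted records are retained so surviving
#' offspring can still resolve their ancestry.
#'
#' @param sim A simulation session.
#' @param groups Vector of valid group handles.
#' @return Number of deleted records, invisibly.
#' @export
delete_groups <- function(sim, groups) {
  .check_sim(sim)
  cols <- unlist(lapply(groups, .group_cols, sim = sim))
  keep <- setdiff(seq_along(sim$ids), cols)
  sim$hap1 <- sim$hap1[, keep, drop = FALSE]
  sim$hap2 <- sim$hap2[, keep, drop = FALSE]
  sim$ids <- sim$ids[keep]
  sim$group <- sim$group[keep]
  invisible(length(cols))
}
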