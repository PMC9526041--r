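# Simulation session: an environment holding the genetic map, the phased
# haplotypes of all live genotypes, the pedigree of every record ever
# created, the current marker-effect set, and the group partition.
#
# Haplotypes are stored as raw (one byte per allele) matrices with one row
# per mapped marker and one column per live genotype, in creation order.
# Record ids are strictly increasing and never reused; deleting a group
# drops its columns but keeps its pedigree rows, so parent references from
# surviving records still resolve to names.

MISSING_ALLELE <- as.raw(45L)  # "-", transmitted like any allele, effect 0

.new_session <- function(map) {
  stopifnot(inherits(map, "meiosim_map"))
  sim <- new.env(parent = emptyenv())
  sim$map <- map
  m <- map$n_markers
  sim$hap1 <- matrix(raw(0), nrow = m, ncol = 0)
  sim$hap2 <- matrix(raw(0), nrow = m, ncol = 0)
  sim$ids <- integer(0)        # live record ids, column order = creation order
  sim$group <- integer(0)      # group handle per live column
  sim$ped <- data.frame(id = integer(0), name = character(0),
                        parent1 = integer(0), parent2 = integer(0),
                        stringsAsFactors = FALSE)
  sim$effects <- NULL          # list(midx, allele (raw), effect)
  sim$effect_set_id <- 0L
  sim$next_id <- 1L
  sim$next_group <- 1L
  sim$founder_group <- NA_integer_
  class(sim) <- "meiosim"
  sim
}

.check_sim <- function(sim) {
  if (!inherits(sim, "meiosim"))
    stop("`sim` must be a meiosim session (see load_data())", call. = FALSE)
  invisible(sim)
}

# columns of live records with the given ids; errors on dead/unknown ids
.cols_of <- function(sim, ids) {
  cols <- match(as.integer(ids), sim$ids)
  if (anyNA(cols)) {
    bad <- ids[is.na(cols)]
    stop("no live genotype with id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cols
}

# member columns of a group, in creation order; empty groups are invalid
.group_cols <- function(sim, group) {
  if (length(group) != 1L || is.na(group))
    stop("`group` must be a single group handle", call. = FALSE)
  cols <- which(sim$group == as.integer(group))
  if (length(cols) == 0L)
    stop("invalid group handle: ", group, " (no live members)", call. = FALSE)
  cols
}

# register new records; h1/h2 are raw matrices (markers x n).
# Returns the fresh group handle; ids are assigned in column order.
.add_records <- function(sim, h1, h2, parent1, parent2, prefix) {
  n <- ncol(h1)
  stopifnot(ncol(h2) == n, nrow(h1) == sim$map$n_markers)
  ids <- seq.int(sim$next_id, length.out = n)
  sim$next_id <- sim$next_id + n
  g <- sim$next_group
  sim$next_group <- sim$next_group + 1L
  nm <- paste0(prefix, ids)
  sim$hap1 <- cbind(sim$hap1, h1)
  sim$hap2 <- cbind(sim$hap2, h2)
  sim$ids <- c(sim$ids, ids)
  sim$group <- c(sim$group, rep.int(g, n))
  sim$ped <- rbind(sim$ped,
                   data.frame(id = ids, name = nm,
                              parent1 = as.integer(parent1),
                              parent2 = as.integer(parent2),
                              stringsAsFactors = FALSE))
  g
}

#' List the live groups of a session
#'
#' @param sim A simulation session.
#' @return Named integer vector: group handle -> number of live members.
#'   Empty groups do not exist (a handle dies with its last member).
#' @export
all_groups <- function(sim) {
  .check_sim(sim)
  if (length(sim$group) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(sim$group)
  setNames(as.integer(tab), names(tab))
}

#' Number of live members of a group
#' @param sim A simulation session.
#' @param group Group handle.
#' @return Integer count.
#' @export
group_size <- function(sim, group) {
  .check_sim(sim)
  length(.group_cols(sim, group))
}

#' Founder group handle
#'
#' The group that [load_data()] placed the founder genotypes in. The handle
#' becomes invalid if all founders are later moved or deleted.
#' @param sim A simulation session.
#' @return Integer group handle.
#' @export
founders <- function(sim) {
  .check_sim(sim)
  sim$founder_group
}

#' @export
print.meiosim <- function(x, ...) {
  cat("<meiosim session>\n")
  cat("  map:      ", format(x$map), "\n", sep = "")
  cat("  live:     ", length(x$ids), " genotype(s) in ",
      length(unique(x$group)), " group(s)\n", sep = "")
  cat("  created:  ", x$next_id - 1L, " record(s) total\n", sep = "")
  cat("  effects:  ",
      if (is.null(x$effects)) "none loaded"
      else paste0(length(x$effects$effect), " (marker, allele) entries [set ",
                  x$effect_set_id, "]"),
      "\n", sep = "")
  invisible(x)
}
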