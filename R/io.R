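# Readers and writers for the three tab-separated input tables, and the
# tab-separated output files. All dialects are fixed and documented here:
#
# * genotype matrix: optional first line "#phased"; then a header line
#   "marker<TAB>name1<TAB>name2..."; then one row per marker, first column
#   the marker name, each remaining cell exactly two nonspace characters
#   (the two alleles at that locus). In a phased file the first character is
#   the allele on haplotype 1 and the second the allele on haplotype 2; in
#   an unphased file the order carries no information and the phase of
#   heterozygous loci is randomized on load (each ordering with probability
#   1/2, independently per locus per genotype).
# * linkage map: header "marker<TAB>chr<TAB>pos", positions in centimorgans.
# * allele effects: header "marker<TAB>allele<TAB>effect", one row per
#   (marker, allele) pair; pairs absent from the file have effect 0.
#
# Genotypes that lack some mapped markers are filled with the missing
# character "-", which carries effect 0 and is transmitted like any allele.

#' Read / write a linkage map file
#'
#' @param path File path. The format is three tab-separated columns
#'   `marker`, `chr`, `pos` (centimorgans) with one header line.
#' @return `read_map_file()`: a [new_genetic_map()] object.
#' @export
read_map_file <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  names(tab) <- c("marker", "chr", "pos")
  new_genetic_map(tab)
}

#' @rdname read_map_file
#' @param map A `meiosim_map` object (or the data.frame accepted by
#'   [new_genetic_map()]).
#' @export
write_map_file <- function(map, path) {
  if (!inherits(map, "meiosim_map")) map <- new_genetic_map(map)
  tab <- map$table
  lines <- c("marker\tchr\tpos",
             paste(tab$marker, tab$chr, format_num(tab$pos), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# deterministic, locale-independent number formatting for all writers
format_num <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    sub("(\\.\\d*?)0+$", "\\1", sub("\\.$", "", s))
  }, character(1))
}

# ---- genotype tables ------------------------------------------------------

#' Construct an in-memory genotype table
#'
#' A genotype table is the in-memory form of the genotype matrix file:
#' marker names, genotype names, and a character matrix of two-character
#' diploid cells. Fixture generators build these and write them through
#' [write_genotype_file()] so that every simulated data set exercises the
#' same file dialect as real data.
#'
#' @param markers Character vector of marker names (rows).
#' @param names Character vector of genotype names (columns).
#' @param cells Character matrix, `length(markers)` x `length(names)`, each
#'   cell exactly two nonspace characters.
#' @param phased Logical: does the character order within each cell encode
#'   linkage phase?
#' @return An object of class `meiosim_geno_table`.
#' @export
genotype_table <- function(markers, names, cells, phased = FALSE) {
  cells <- as.matrix(cells)
  stopifnot(nrow(cells) == length(markers), ncol(cells) == length(names))
  bad <- nchar(cells) != 2L | grepl("[[:space:]]", cells)
  if (any(bad))
    stop("every genotype cell must be exactly 2 nonspace characters ",
         "(diploid format); offending cell e.g. \"", cells[which(bad)[1L]],
         "\"", call. = FALSE)
  structure(list(markers = as.character(markers),
                 names = as.character(names),
                 cells = cells, phased = isTRUE(phased)),
            class = "meiosim_geno_table")
}

#' Read / write a genotype matrix file
#'
#' See the package vignette for the file dialect. Files written by
#' [save_genotypes()] carry a `#phased` flag line so that reloading them
#' does not re-randomize phase; plain founder files without the flag get
#' their heterozygous loci phased randomly at load time.
#'
#' @param path File path.
#' @return `read_genotype_file()`: a [genotype_table()].
#' @export
read_genotype_file <- function(path) {
  lines <- readLines(path)
  phased <- FALSE
  while (length(lines) && startsWith(lines[1L], "#")) {
    if (grepl("^#\\s*phased\\b", lines[1L])) phased <- TRUE
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("genotype file has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("genotype file has no genotype columns: ", path, call. = FALSE)
  gnames <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("ragged genotype file: row ", which(nf != length(header))[1L] + 1L,
         " has ", nf[nf != length(header)][1L], " fields, expected ",
         length(header), call. = FALSE)
  mk <- vapply(body, `[[`, character(1), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(mk),
                  ncol = length(gnames), byrow = TRUE)
  genotype_table(mk, gnames, cells, phased = phased)
}

#' @rdname read_genotype_file
#' @param tbl A [genotype_table()].
#' @export
write_genotype_file <- function(tbl, path) {
  stopifnot(inherits(tbl, "meiosim_geno_table"))
  lines <- character(0)
  if (tbl$phased) lines <- "#phased"
  lines <- c(lines,
             paste(c("marker", tbl$names), collapse = "\t"),
             paste(tbl$markers,
                   apply(tbl$cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Align a genotype table to the session map and split cells into two raw
# haplotype matrices. Matrix markers absent from the map are dropped with a
# warning; mapped markers absent from the matrix are filled with "-".
# Unphased input gets heterozygous loci randomized here (consumes RNG).
.align_genotypes <- function(map, tbl) {
  shared <- intersect(map$table$marker, tbl$markers)
  if (length(shared) == 0L)
    stop("no markers shared between the genotype matrix and the map",
         call. = FALSE)
  extra <- setdiff(tbl$markers, map$table$marker)
  if (length(extra))
    warning(length(extra), " genotype-matrix marker(s) absent from the map ",
            "were dropped (e.g. ", extra[1L], ")", call. = FALSE)
  missing <- setdiff(map$table$marker, tbl$markers)
  if (length(missing))
    warning(length(missing), " mapped marker(s) absent from the genotype ",
            "matrix were filled with the missing character \"-\"",
            call. = FALSE)

  m <- map$n_markers
  n <- length(tbl$names)
  row_of <- match(map$table$marker, tbl$markers)  # NA where missing
  cells <- matrix("--", nrow = m, ncol = n)
  cells[!is.na(row_of), ] <- tbl$cells[row_of[!is.na(row_of)], , drop = FALSE]

  # one charToRaw per column: cells are validated 2-byte strings
  h1 <- matrix(raw(0), nrow = m, ncol = n)
  h2 <- matrix(raw(0), nrow = m, ncol = n)
  for (j in seq_len(n)) {
    b <- charToRaw(paste(cells[, j], collapse = ""))
    h1[, j] <- b[c(TRUE, FALSE)]
    h2[, j] <- b[c(FALSE, TRUE)]
  }
  if (!tbl$phased && n > 0L && m > 0L) {
    swap <- (h1 != h2) & (matrix(stats::runif(m * n), m, n) < 0.5)
    tmp <- h1[swap]
    h1[swap] <- h2[swap]
    h2[swap] <- tmp
  }
  list(h1 = h1, h2 = h2)
}

# ---- effects --------------------------------------------------------------

#' Read / write an allele-effects file
#'
#' @param path File path. Three tab-separated columns `marker`, `allele`
#'   (one nonspace character), `effect` (real), one header line; multiple
#'   rows per marker are allowed (one per allele). Pairs absent from the
#'   file contribute 0 to breeding values.
#' @return `read_effects_file()`: a data.frame `(marker, allele, effect)`.
#' @export
read_effects_file <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  names(tab) <- c("marker", "allele", "effect")
  if (any(nchar(tab$allele) != 1L | grepl("[[:space:]]", tab$allele)))
    stop("effect alleles must be single nonspace characters", call. = FALSE)
  if (anyDuplicated(paste(tab$marker, tab$allele)))
    stop("duplicated (marker, allele) pair in effects file", call. = FALSE)
  tab
}

#' @rdname read_effects_file
#' @param effects Data.frame with columns `marker`, `allele`, `effect`.
#' @export
write_effects_file <- function(effects, path) {
  lines <- c("marker\tallele\teffect",
             paste(effects$marker, effects$allele,
                   format_num(effects$effect), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# compile an effects data.frame against the session map
.compile_effects <- function(map, tab) {
  midx <- match(tab$marker, map$table$marker)
  if (anyNA(midx)) {
    drop <- is.na(midx)
    warning(sum(drop), " effect entr(ies) for unmapped marker(s) dropped ",
            "(e.g. ", tab$marker[which(drop)[1L]], ")", call. = FALSE)
    tab <- tab[!drop, , drop = FALSE]
    midx <- midx[!drop]
  }
  list(midx = midx,
       allele = as.raw(vapply(tab$allele, function(a) as.integer(charToRaw(a)),
                              integer(1))),
       effect = as.numeric(tab$effect))
}

# ---- session-level loaders -----------------------------------------------

#' Start a simulation session from founder data files
#'
#' Reads a linkage map, a founder genotype matrix, and (optionally) a table
#' of additive allele effects, and returns a new simulation session with
#' all founders placed in one fresh group (see [founders()]). If the
#' genotype file is not marked `#phased`, the linkage phase of every
#' heterozygous founder locus is randomized at load (each of the two
#' orderings with probability 1/2, independently per locus per genotype);
#' phase is tracked exactly from then on.
#'
#' @param genotype_file Path to the founder genotype matrix (>= 1 genotype).
#' @param map_file Path to the linkage map.
#' @param effects_file Optional path to an allele-effects table; required
#'   before any breeding-value, phenotype, or selection call.
#' @return A `meiosim` session object. Sessions are environments: the
#'   crossing, grouping and selection functions modify them in place.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' map <- synth_map(n_chr = 2, markers_per_chr = 5, length_cM = 100)
#' write_map_file(map, file.path(dir, "map.txt"))
#' write_genotype_file(synth_founders(4, map, inbred = TRUE),
#'                     file.path(dir, "geno.txt"))
#' write_effects_file(synth_effects(map), file.path(dir, "eff.txt"))
#' sim <- load_data(file.path(dir, "geno.txt"), file.path(dir, "map.txt"),
#'                  file.path(dir, "eff.txt"))
#' sim
#' @export
load_data <- function(genotype_file, map_file, effects_file = NULL) {
  map <- read_map_file(map_file)
  sim <- .new_session(map)
  tbl <- read_genotype_file(genotype_file)
  hh <- .align_genotypes(map, tbl)
  g <- .add_records(sim, hh$h1, hh$h2,
                    rep(NA_integer_, length(tbl$names)),
                    rep(NA_integer_, length(tbl$names)), prefix = "")
  # founders keep their file names
  sim$ped$name[match(sim$ids, sim$ped$id)] <- tbl$names
  sim$founder_group <- g
  if (!is.null(effects_file)) load_different_effects(sim, effects_file)
  sim
}

#' Append more genotypes to a running session
#'
#' Loads an additional genotype matrix into an initialized session, e.g. to
#' introduce new genetic material into an ongoing program. The new records
#' are appended in a fresh group; existing records are untouched. Mapped
#' markers absent from the new file are filled with the missing character
#' `"-"` (effect 0, transmitted like any allele).
#'
#' @param sim A simulation session.
#' @param genotype_file Path to a genotype matrix sharing >= 1 marker with
#'   the session map.
#' @return The new group handle.
#' @export
load_more_genotypes <- function(sim, genotype_file) {
  .check_sim(sim)
  tbl <- read_genotype_file(genotype_file)
  hh <- .align_genotypes(sim$map, tbl)
  n <- length(tbl$names)
  g <- .add_records(sim, hh$h1, hh$h2, rep(NA_integer_, n),
                    rep(NA_integer_, n), prefix = "")
  new_ids <- sim$ids[sim$group == g]
  sim$ped$name[match(new_ids, sim$ped$id)] <- tbl$names
  g
}

#' Replace the session's marker-effect set
#'
#' Substitutes the stored set of additive allele effects, e.g. to score a
#' different trait or to emulate year-to-year fluctuation of effects.
#' Breeding values are always computed on demand from the current set, so
#' values computed before the swap are unaffected.
#'
#' @param sim A simulation session.
#' @param effects_file Path to an allele-effects table.
#' @return The (integer) id of the newly active effect set, invisibly.
#' @export
load_different_effects <- function(sim, effects_file) {
  .check_sim(sim)
  tab <- read_effects_file(effects_file)
  sim$effects <- .compile_effects(sim$map, tab)
  sim$effect_set_id <- sim$effect_set_id + 1L
  invisible(sim$effect_set_id)
}

# ---- savers ---------------------------------------------------------------

# group columns -> two-character cell matrix (phase-encoding)
.cells_of_cols <- function(sim, cols) {
  m <- sim$map$n_markers
  n <- length(cols)
  out <- matrix("", nrow = m, ncol = n)
  for (j in seq_len(n)) {
    b <- raw(2L * m)
    b[c(TRUE, FALSE)] <- sim$hap1[, cols[j]]
    b[c(FALSE, TRUE)] <- sim$hap2[, cols[j]]
    s <- rawToChar(b)
    out[, j] <- substring(s, seq(1L, 2L * m, by = 2L), seq(2L, 2L * m, by = 2L))
  }
  out
}

#' Save a group's genotypes to a tab-separated file
#'
#' The written file is phase-encoded and flagged `#phased`, so saving and
#' reloading a group reproduces its haplotypes exactly (no phase
#' re-randomization). Output is byte-stable for a fixed session state.
#'
#' @param sim A simulation session.
#' @param group Group handle.
#' @param path Output path.
#' @export
save_genotypes <- function(sim, group, path) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  nm <- sim$ped$name[match(sim$ids[cols], sim$ped$id)]
  tbl <- genotype_table(sim$map$table$marker, nm, .cells_of_cols(sim, cols),
                        phased = TRUE)
  write_genotype_file(tbl, path)
}

#' Save a group's breeding values to a tab-separated file
#'
#' One row per group member (columns `index`, `name`, `bv`), in stable
#' member order.
#'
#' @inheritParams save_genotypes
#' @export
save_breeding_values <- function(sim, group, path) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  bv <- .bv_cols(sim, cols)
  nm <- sim$ped$name[match(sim$ids[cols], sim$ped$id)]
  lines <- c("index\tname\tbv",
             paste(sim$ids[cols], nm, format_num(bv), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
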