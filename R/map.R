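# Genetic map: named markers at centimorgan positions on chromosomes.
# Internally every haplotype is indexed against the genome-wide marker order
# defined here, and the meiosis engine reads per-chromosome spans from it.

#' Construct a genetic map
#'
#' A genetic map places named markers on chromosomes at centimorgan (cM)
#' positions. It is the model of the genome that meiosis simulation runs on:
#' the number of crossovers per chromosome is drawn from a Poisson
#' distribution whose mean is the tracked map length in Morgans, so map
#' distances must be genetic (cM), not physical base-pair coordinates.
#'
#' Markers are ordered by chromosome (chromosomes in order of first
#' appearance) and by nondecreasing position within each chromosome;
#' co-located markers (identical positions, as occur in real maps) are kept
#' in their input order. Marker names must be unique genome-wide.
#'
#' @param markers A data.frame with columns `marker` (character), `chr`
#'   (character or factor), and `pos` (numeric, centimorgans, `>= 0`).
#' @return An object of class `meiosim_map`.
#' @seealso [chromosome_span()], [read_map_file()], [synth_map()]
#' @examples
#' map <- new_genetic_map(data.frame(
#'   marker = c("m1", "m2", "m3"),
#'   chr    = c("1A", "1A", "2B"),
#'   pos    = c(0, 150, 37.2)))
#' map
#' chromosome_span(map, "1A")
#' @export
new_genetic_map <- function(markers) {
  if (!is.data.frame(markers))
    stop("`markers` must be a data.frame", call. = FALSE)
  need <- c("marker", "chr", "pos")
  if (!all(need %in% names(markers)))
    stop("map table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  markers <- data.frame(marker = as.character(markers$marker),
                        chr = as.character(markers$chr),
                        pos = as.numeric(markers$pos),
                        stringsAsFactors = FALSE)
  if (nrow(markers) < 1L)
    stop("map must contain at least one marker", call. = FALSE)
  if (anyNA(markers))
    stop("map table contains missing values", call. = FALSE)
  if (any(markers$pos < 0))
    stop("map positions must be nonnegative centimorgans", call. = FALSE)
  if (anyDuplicated(markers$marker))
    stop("marker names must be unique genome-wide; duplicated: ",
         paste(unique(markers$marker[duplicated(markers$marker)]),
               collapse = ", "), call. = FALSE)

  chr_levels <- unique(markers$chr)
  # stable sort: chromosome appearance order, then position (ties keep input order)
  ord <- order(match(markers$chr, chr_levels), markers$pos, method = "radix")
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL

  chrs <- lapply(chr_levels, function(cn) {
    idx <- which(markers$chr == cn)
    pos <- markers$pos[idx]
    list(name = cn,
         idx = idx,
         pos = pos,
         n = length(idx),
         # tracked span in Morgans: distance between first and last marker
         span = (pos[length(pos)] - pos[1L]) / 100)
  })
  names(chrs) <- chr_levels

  structure(list(table = markers, chr = chrs, n_markers = nrow(markers)),
            class = "meiosim_map")
}

#' Tracked length of a chromosome in Morgans
#'
#' Returns the distance between the first and the last mapped position on a
#' chromosome, converted from centimorgans to Morgans. This span is the
#' Poisson mean used by the meiosis engine for that chromosome: a chromosome
#' carrying a single marker (or only co-located markers) has span 0 and never
#' recombines.
#'
#' @param map A [new_genetic_map()] object.
#' @param chromosome Chromosome name.
#' @return Length in Morgans (nonnegative scalar).
#' @export
chromosome_span <- function(map, chromosome) {
  stopifnot(inherits(map, "meiosim_map"))
  ch <- map$chr[[as.character(chromosome)]]
  if (is.null(ch))
    stop("unknown chromosome: ", chromosome, call. = FALSE)
  ch$span
}

#' @export
print.meiosim_map <- function(x, ...) {
  cat("<meiosim_map> ", x$n_markers, " markers on ",
      length(x$chr), " chromosome(s)\n", sep = "")
  for (ch in x$chr)
    cat("  ", ch$name, ": ", ch$n, " markers, span ",
        format(ch$span, digits = 4), " M\n", sep = "")
  invisible(x)
}

#' @export
format.meiosim_map <- function(x, ...) {
  paste0("<meiosim_map> ", x$n_markers, " markers / ",
         length(x$chr), " chromosomes")
}
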