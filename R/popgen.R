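# Population-genetic validation summaries: Rogers' genetic distance between
# individuals, and linkage-disequilibrium (r2) decay by map distance.
#
# Rogers' distance here is the individual-level variant of Rogers (1972):
# at each locus the two individuals are summarized by their within-
# individual allele frequencies (0, 1/2, or 1 per allele), the per-locus
# distance is sqrt(0.5 * sum_a (p_a - q_a)^2), and the distance between two
# individuals is the mean of the per-locus distances. Implementations
# differ in the variant they use; comparisons against other software should
# check this definition first.
#
# LD r2 is computed from the tracked (true) haplotypes — the simulator
# knows phase exactly — which differs from genotype-correlation estimators
# used on real unphased data.

# per-locus Rogers distance from match counts:
#   s = number of matching ordered allele pairs between the two genotypes,
#   h1/h2 = 1 if the respective genotype is homozygous.
#   d = sqrt((4 + 2 h1 + 2 h2 - 2 s) / 8)
# (algebraic reduction of sqrt(0.5 * sum_a (p_a - q_a)^2) for diploids)
.rogers_locus <- function(x1, y1, x2, y2) {
  s <- (x1 == x2) + (x1 == y2) + (y1 == x2) + (y1 == y2)
  h1 <- x1 == y1
  h2 <- x2 == y2
  sqrt((4 + 2 * h1 + 2 * h2 - 2 * s) / 8)
}

#' Rogers' genetic distance between two genotypes
#'
#' @param sim A simulation session.
#' @param a,b Ids of live genotypes.
#' @return Distance in `[0, 1]`: 0 for identical allele content, 1 for
#'   opposite homozygotes at every locus.
#' @export
rogers_distance <- function(sim, a, b) {
  .check_sim(sim)
  ca <- .cols_of(sim, a)
  cb <- .cols_of(sim, b)
  mean(.rogers_locus(sim$hap1[, ca], sim$hap2[, ca],
                     sim$hap1[, cb], sim$hap2[, cb]))
}

#' Rogers' distance matrix for a group
#'
#' Pairwise Rogers' distances between all members of a group; symmetric
#' with a zero diagonal. Loci are processed by unordered-genotype code with
#' a small per-locus lookup table, so the cost is about one n-by-n indexing
#' pass per locus.
#'
#' @param sim A simulation session.
#' @param group Group handle (nonempty).
#' @return Symmetric numeric matrix with member names as dimnames.
#' @export
rogers_distance_matrix <- function(sim, group) {
  .check_sim(sim)
  cols <- .group_cols(sim, group)
  n <- length(cols)
  m <- sim$map$n_markers
  if (m == 0L) stop("no loci", call. = FALSE)
  h1 <- sim$hap1[, cols, drop = FALSE]
  h2 <- sim$hap2[, cols, drop = FALSE]
  # unordered genotype code per (locus, individual)
  lo <- pmin(as.integer(h1), as.integer(h2))
  hi <- pmax(as.integer(h1), as.integer(h2))
  code <- matrix(lo * 256L + hi, nrow = m)
  D <- matrix(0, n, n)
  for (l in seq_len(m)) {
    codes <- code[l, ]
    lev <- unique(codes)
    k <- match(codes, lev)
    x1 <- as.raw(lev %/% 256L)
    y1 <- as.raw(lev %% 256L)
    tab <- outer(seq_along(lev), seq_along(lev), function(i, j)
      .rogers_locus(x1[i], y1[i], x1[j], y1[j]))
    D <- D + tab[cbind(rep(k, times = n), rep(k, each = n))]
  }
  D <- D / m
  nm <- sim$ped$name[match(sim$ids[cols], sim$ped$id)]
  dimnames(D) <- list(nm, nm)
  D
}

#' LD r-squared from a 2x2 haplotype count table
#'
#' For two biallelic markers with haplotype counts
#' `rbind(c(AB, Ab), c(aB, ab))`, computes `D = p_AB - p_A * p_B` and
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`. Invariant under allele
#' relabeling at either marker.
#'
#' @param counts 2x2 nonnegative numeric matrix of haplotype counts.
#' @return r-squared in `[0, 1]`; `NaN` if either marker is monomorphic in
#'   the table (undefined denominator).
#' @export
ld_r2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty haplotype table", call. = FALSE)
  pAB <- counts[1L, 1L] / n
  pA <- sum(counts[1L, ]) / n
  pB <- sum(counts[, 1L]) / n
  d <- pAB - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' LD decay profile of a group
#'
#' Mean r2 between marker pairs, binned by within-chromosome map distance.
#' Haplotypes are the tracked phased gametes of the group (2 per member).
#' Only biallelic polymorphic markers enter; markers with more than two
#' observed alleles are skipped with a message reporting the count, and
#' monomorphic markers are skipped silently (r2 undefined).
#' Inter-chromosomal pairs are excluded. Bins are left-closed, right-open
#' centimorgan intervals.
#'
#' @param sim A simulation session.
#' @param group Group handle.
#' @param breaks Increasing numeric vector of cM bin edges.
#' @return Data.frame with columns `lower`, `upper`, `mean_r2`, `n_pairs`;
#'   bins containing no pair get `NA` mean.
#' @export
ld_decay_profile <- function(sim, group, breaks) {
  .check_sim(sim)
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  cols <- .group_cols(sim, group)
  H <- cbind(sim$hap1[, cols, drop = FALSE], sim$hap2[, cols, drop = FALSE])
  nh <- ncol(H)
  nb <- length(breaks) - 1L
  sum_r2 <- numeric(nb)
  n_pairs <- integer(nb)
  n_multi <- 0L
  for (ch in sim$map$chr) {
    rows <- H[ch$idx, , drop = FALSE]
    n_alleles <- apply(rows, 1L, function(r) length(unique(r)))
    n_multi <- n_multi + sum(n_alleles > 2L)
    use <- which(n_alleles == 2L)
    if (length(use) < 2L) next
    sub <- rows[use, , drop = FALSE]
    ref <- sub[, 1L]  # arbitrary reference allele per marker (r2 invariant)
    X <- matrix(0, nrow = length(use), ncol = nh)
    X[sub == ref] <- 1
    p <- rowMeans(X)
    P <- tcrossprod(X) / nh
    Dm <- P - outer(p, p)
    denom <- outer(p * (1 - p), p * (1 - p))
    r2 <- Dm^2 / denom
    pos <- ch$pos[use]
    dist <- abs(outer(pos, pos, "-"))
    up <- upper.tri(r2)
    bin <- findInterval(dist[up], breaks, rightmost.closed = FALSE)
    ok <- bin >= 1L & bin <= nb
    if (any(ok)) {
      sums <- tapply(r2[up][ok], bin[ok], sum)
      cnts <- tapply(r2[up][ok], bin[ok], length)
      idx <- as.integer(names(sums))
      sum_r2[idx] <- sum_r2[idx] + as.numeric(sums)
      n_pairs[idx] <- n_pairs[idx] + as.integer(cnts)
    }
  }
  if (n_multi > 0L)
    message(n_multi, " marker(s) with >2 observed alleles skipped in LD ",
            "profile")
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
             mean_r2 = ifelse(n_pairs > 0L, sum_r2 / pmax(n_pairs, 1L), NA),
             n_pairs = n_pairs)
}

#' Write a labeled matrix / an LD profile to tab-separated text
#'
#' Writers for downstream plotting: the matrix writer puts labels in the
#' first row and column; the profile writer emits the data.frame columns.
#' Both are byte-stable for fixed input.
#'
#' @param mat Numeric matrix with dimnames (e.g. from
#'   [rogers_distance_matrix()]).
#' @param path Output path.
#' @export
write_distance_matrix <- function(mat, path) {
  lines <- c(paste(c("", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], format_num(mat[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param profile Data.frame from [ld_decay_profile()].
#' @export
write_ld_profile <- function(profile, path) {
  lines <- c("lower\tupper\tmean_r2\tn_pairs",
             paste(format_num(profile$lower), format_num(profile$upper),
                   ifelse(is.na(profile$mean_r2), "NA",
                          format_num(profile$mean_r2)),
                   profile$n_pairs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
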