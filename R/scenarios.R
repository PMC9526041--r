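# Packaged scenarios: a cyclic phenotypic-selection breeding program and a
# nested association mapping (NAM) population build. Both run on
# user-supplied data files or on synthetic fixtures generated on the fly,
# and both are driven entirely by the exported scripting functions — they
# are worked examples as much as canned experiments.

#' Simulate a cyclic truncation-selection breeding program
#'
#' Each cycle (nonoverlapping generations): random crosses among the
#' current founders generate new recombinants; one selfed progeny per
#' recombinant is grown and phenotype-selected at the first-stage
#' heritability and portion (low heritability emulating unreplicated early
#' trials); one selfed progeny of each survivor is grown and selected again
#' at the second-stage heritability and portion (more accurate later
#' trials); the survivors are selfed once more and become the founders of
#' the next cycle. The mean and unbiased variance of the final generation's
#' breeding values are recorded per cycle.
#'
#' Under `selection = "within_family"`, the recombinants are split into
#' full-sib families after crossing and the selfing/selection stages run
#' independently inside every family with the same per-stage portions; the
#' surviving lines of all families are merged into the next cycle's founder
#' pool. Across-population selection concentrates the best families and
#' gains faster; within-family selection retains more genetic variance.
#'
#' @param genotypes,map,effects Paths to input files, or `NULL` to generate
#'   a synthetic data set (inbred founders) with the `n_founders`, `n_chr`,
#'   `markers_per_chr`, `length_cM` parameters below.
#' @param n_cycles Number of breeding cycles.
#' @param n_crosses,offspring_per_cross Random-crossing stage size; the
#'   recombinant generation has `n_crosses * offspring_per_cross` members.
#' @param stage_heritabilities Length-2: broad-sense heritability of the
#'   first and second phenotyping stage.
#' @param stage_portions Length-2: fraction kept at each selection stage.
#' @param selection `"across"` (truncate over the whole generation) or
#'   `"within_family"` (truncate inside each full-sib family).
#' @param n_replicates Independent replicates of the whole program.
#' @param n_founders,n_chr,markers_per_chr,length_cM Synthetic data shape
#'   used when no input files are given: by default 50 inbred founders on a
#'   5,000-marker map (20 chromosomes of 250 markers over 150 cM).
#' @param proportion_causal,effect_sd Synthetic effect-table shape.
#' @param seed Optional integer seed for full-run reproducibility.
#' @return Long-format data.frame `(replicate, cycle, statistic, value)`
#'   with statistics `mean_bv` and `var_bv` measured on each cycle's final
#'   generation.
#' @examples
#' res <- run_cyclic_program(n_cycles = 2, n_crosses = 5,
#'                           offspring_per_cross = 4, n_replicates = 1,
#'                           n_founders = 8, n_chr = 2,
#'                           markers_per_chr = 20, seed = 1)
#' subset(res, statistic == "mean_bv")
#' @export
run_cyclic_program <- function(genotypes = NULL, map = NULL, effects = NULL,
                               n_cycles = 5L,
                               n_crosses = 25L, offspring_per_cross = 20L,
                               stage_heritabilities = c(0.1, 0.4),
                               stage_portions = c(0.2, 0.5),
                               selection = c("across", "within_family"),
                               n_replicates = 10L,
                               n_founders = 50L, n_chr = 20L,
                               markers_per_chr = 250L, length_cM = 150,
                               proportion_causal = 0.5, effect_sd = 1,
                               seed = NULL) {
  selection <- match.arg(selection)
  stopifnot(n_cycles >= 1L, n_replicates >= 1L,
            length(stage_heritabilities) == 2L, length(stage_portions) == 2L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genotypes) || is.null(map)) {
    paths <- .synth_dataset(tempfile("meiosim-cyclic-"), n_founders, n_chr,
                            markers_per_chr, length_cM, inbred = TRUE,
                            proportion_causal = proportion_causal,
                            effect_sd = effect_sd)
    genotypes <- paths$genotypes
    map <- paths$map
    if (is.null(effects)) effects <- paths$effects
  }
  if (is.null(effects))
    stop("an effects table is required (selection needs breeding values)",
         call. = FALSE)

  # one generation-advance: self, select, self, select, self
  advance <- function(sim, g) {
    f2 <- self_n_times(sim, g, n = 1L)
    f2s <- select_by_phenotype(sim, f2, stage_heritabilities[1L],
                               stage_portions[1L])
    f3 <- self_n_times(sim, f2s, n = 1L)
    f3s <- select_by_phenotype(sim, f3, stage_heritabilities[2L],
                               stage_portions[2L])
    self_n_times(sim, f3s, n = 1L)
  }

  out <- vector("list", n_replicates * n_cycles)
  row <- 0L
  for (rep_i in seq_len(n_replicates)) {
    sim <- load_data(genotypes, map, effects)
    g0 <- founders(sim)
    for (cyc in seq_len(n_cycles)) {
      f1 <- cross_randomly(sim, g0, n_crosses, offspring_per_cross)
      f4 <- if (selection == "across") {
        advance(sim, f1)
      } else {
        fams <- break_into_families(sim, f1)
        combine_groups(sim, vapply(fams, function(fg) advance(sim, fg),
                                   integer(1)))
      }
      stats <- group_bv_summary(sim, f4)
      row <- row + 1L
      out[[row]] <- data.frame(replicate = rep_i, cycle = cyc,
                               statistic = c("mean_bv", "var_bv"),
                               value = unname(stats),
                               stringsAsFactors = FALSE)
      # end of cycle: only the new founders survive
      live <- as.integer(names(all_groups(sim)))
      delete_groups(sim, setdiff(live, f4))
      g0 <- f4
    }
  }
  do.call(rbind, out)
}

#' Simulate a nested association mapping (NAM) population
#'
#' A set of donor founders is each crossed to one common elite founder; the
#' F1s are advanced by single-seed descent and the final selfing step is
#' expanded to `lines_per_family` progeny per line, producing
#' `n_donors * lines_per_family` inbred lines whose full-sib family
#' structure is recoverable with [break_into_families()]. The scenario
#' reports the Rogers' distance matrix of the final generation (which shows
#' the family block structure: within-family distances below
#' between-family distances) and its LD decay profile.
#'
#' @param genotypes,map Paths to input files, or `NULL` for a synthetic
#'   data set of `n_donors + 1` inbred founders (the first founder is the
#'   elite parent).
#' @param n_donors Number of donor parents (families).
#' @param lines_per_family Final-generation lines per family.
#' @param n_selfing_generations Selfing steps after the F1 (5 gives an F6
#'   final generation).
#' @param n_chr,markers_per_chr,length_cM,maf_range Synthetic data shape
#'   (durum-scale default: 14 chromosomes of 25 markers over 150 cM).
#' @param ld_breaks cM bin edges for the LD decay profile.
#' @param out_dir If non-`NULL`, the final-generation genotypes, Rogers
#'   matrix and LD profile are written there as tab-separated files
#'   (`final-genotypes.txt`, `rogers-distance.txt`, `ld-profile.txt`).
#' @param seed Optional integer seed for full-run reproducibility.
#' @return List with elements `sim` (the session), `families` (named vector
#'   of group handles from [break_into_families()] — the final generation,
#'   partitioned), `rogers` (distance matrix of the final generation),
#'   `within_mean` / `between_mean` (mean Rogers' distance inside / across
#'   families), and `ld` (decay profile data.frame).
#' @export
run_nam_scenario <- function(genotypes = NULL, map = NULL,
                             n_donors = 10L, lines_per_family = 100L,
                             n_selfing_generations = 5L,
                             n_chr = 14L, markers_per_chr = 25L,
                             length_cM = 150, maf_range = c(0.2, 0.5),
                             ld_breaks = seq(0, 150, by = 10),
                             out_dir = NULL, seed = NULL) {
  stopifnot(n_donors >= 1L, lines_per_family >= 1L,
            n_selfing_generations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genotypes) || is.null(map)) {
    dir <- tempfile("meiosim-nam-")
    dir.create(dir, recursive = TRUE)
    smap <- synth_map(n_chr, markers_per_chr, length_cM)
    map <- file.path(dir, "genetic-map.txt")
    genotypes <- file.path(dir, "founder-genotypes.txt")
    write_map_file(smap, map)
    write_genotype_file(synth_founders(n_donors + 1L, smap, maf_range,
                                       inbred = TRUE), genotypes)
  }
  sim <- load_data(genotypes, map)
  fd <- see_group_data(sim, founders(sim), "index")
  if (length(fd) < n_donors + 1L)
    stop("need ", n_donors + 1L, " founders (1 elite + ", n_donors,
         " donors), got ", length(fd), call. = FALSE)
  elite <- fd[1L]
  donors <- fd[seq.int(2L, n_donors + 1L)]

  f1 <- cross_combinations(sim, rep(elite, n_donors), donors, offspring = 1L)
  lines <- if (n_selfing_generations > 1L)
    self_n_times(sim, f1, n = n_selfing_generations - 1L)
  else f1
  final <- self_n_times(sim, lines, n = 1L, offspring = lines_per_family)

  # metrics on the intact final generation; the family split afterwards
  # consumes the `final` handle (its members move into the family groups)
  rogers <- rogers_distance_matrix(sim, final)
  fam_of <- .family_key_of(sim, final)
  same <- outer(fam_of, fam_of, "==")
  up <- upper.tri(rogers)
  within_mean <- mean(rogers[up & same])
  between_mean <- if (any(up & !same)) mean(rogers[up & !same]) else NA_real_
  ld <- ld_decay_profile(sim, final, ld_breaks)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    save_genotypes(sim, final, file.path(out_dir, "final-genotypes.txt"))
    write_distance_matrix(rogers, file.path(out_dir, "rogers-distance.txt"))
    write_ld_profile(ld, file.path(out_dir, "ld-profile.txt"))
  }
  families <- break_into_families(sim, final)
  list(sim = sim, families = families,
       rogers = rogers, within_mean = within_mean,
       between_mean = between_mean, ld = ld)
}

# family key (unordered parent pair) per member of a group, without moving
# anyone between groups
.family_key_of <- function(sim, group) {
  cols <- .group_cols(sim, group)
  rows <- match(sim$ids[cols], sim$ped$id)
  p1 <- sim$ped$parent1[rows]
  p2 <- sim$ped$parent2[rows]
  ifelse(is.na(p1) | is.na(p2), "founder",
         paste(pmin(p1, p2), pmax(p1, p2)))
}
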