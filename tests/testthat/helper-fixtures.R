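# Fixture helpers. Everything is written through the package's own file
# writers and re-read by its loaders, so every test exercises the io
# dialects end to end.

# write a toy data set (map + genotype matrix + optional effects) and
# return the file paths
toy_files <- function(markers, chr, pos, cells, names = NULL, phased = TRUE,
                      effects = NULL) {
  d <- tempfile("toy")
  dir.create(d)
  if (is.null(names)) names <- paste0("g", seq_len(ncol(as.matrix(cells))))
  paths <- list(map = file.path(d, "map.txt"),
                geno = file.path(d, "geno.txt"),
                effects = if (!is.null(effects)) file.path(d, "effects.txt"))
  write_map_file(new_genetic_map(
    data.frame(marker = markers, chr = chr, pos = pos)), paths$map)
  write_genotype_file(genotype_table(markers, names, cells, phased = phased),
                      paths$geno)
  if (!is.null(effects)) write_effects_file(effects, paths$effects)
  paths
}

# load a toy session in one call; cells is markers x genotypes
toy_sim <- function(markers, chr, pos, cells, names = NULL, phased = TRUE,
                    effects = NULL) {
  p <- toy_files(markers, chr, pos, cells, names, phased, effects)
  load_data(p$geno, p$map, p$effects)
}

# a session whose single founder is phased h1/h2 (character vectors)
phased_parent_sim <- function(chr, pos, h1, h2, markers = NULL) {
  if (is.null(markers)) markers <- paste0("m", seq_along(pos))
  toy_sim(markers, chr, pos, matrix(paste0(h1, h2), ncol = 1), "P",
          phased = TRUE)
}

# per-locus allele pairs of each group member, from the public genotype
# string (two characters per locus, hap1 then hap2)
genotype_chars <- function(sim, group) {
  g <- see_group_data(sim, group, "genotype")
  lapply(g, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    rbind(hap1 = ch[c(TRUE, FALSE)], hap2 = ch[c(FALSE, TRUE)])
  })
}

# independent brute-force breeding-value oracle: iterate every marker and
# both alleles, looking effects up in the raw (marker, allele, effect) table
bv_oracle <- function(sim, group, effects_tab) {
  chars <- genotype_chars(sim, group)
  markers <- sim$map$table$marker
  vapply(chars, function(x) {
    total <- 0
    for (i in seq_along(markers)) {
      for (h in 1:2) {
        hit <- effects_tab$marker == markers[i] &
               effects_tab$allele == x[h, i]
        if (any(hit)) total <- total + effects_tab$effect[hit]
      }
    }
    total
  }, numeric(1))
}

# mean per-locus heterozygosity of a group
het_fraction <- function(sim, group) {
  mean(vapply(genotype_chars(sim, group),
              function(m) mean(m[1L, ] != m[2L, ]), numeric(1)))
}

# partition property: group sizes over all live groups sum to the live count
expect_partition_ok <- function(sim) {
  sizes <- all_groups(sim)
  total <- sum(vapply(as.integer(names(sizes)),
                      function(g) group_size(sim, g), integer(1)))
  n_live <- length(unlist(lapply(as.integer(names(sizes)),
                                 function(g) see_group_data(sim, g, "index"))))
  expect_identical(total, n_live)
}

# gametes from one parent via a testcross against a homozygous "t" tester:
# offspring haplotype 1 is the parent's gamete. Returns a markers x n
# character matrix of gamete alleles.
testcross_gametes <- function(chr, pos, h1, h2, n) {
  m <- length(pos)
  markers <- paste0("m", seq_len(m))
  sim <- toy_sim(markers, chr, pos,
                 cbind(paste0(h1, h2), rep("tt", m)), c("P", "T"),
                 phased = TRUE)
  ids <- see_group_data(sim, founders(sim), "index")
  off <- cross(sim, ids[1L], ids[2L], offspring = n)
  chars <- genotype_chars(sim, off)
  matrix(vapply(chars, function(x) x[1L, ], character(m)), nrow = m)
}
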