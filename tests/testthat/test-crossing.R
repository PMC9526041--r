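test_that("crossing identical homozygous parents reproduces them; AA x aa gives Aa", {
  sim <- toy_sim(c("m1", "m2"), "1", c(0, 30),
                 matrix(c("AA", "TT", "AA", "TT"), 2, 2))
  off <- cross(sim, 1L, 2L)
  expect_identical(see_group_data(sim, off, "genotype"), "AATT")

  sim2 <- toy_sim("m1", "1", 0, matrix(c("AA", "aa"), 1, 2))
  off2 <- cross(sim2, 1L, 2L, offspring = 20L)
  expect_true(all(see_group_data(sim2, off2, "genotype") == "Aa"))
  # parent order is the call order
  expect_true(all(see_group_data(sim2, off2, "parent1") == 1L))
  expect_true(all(see_group_data(sim2, off2, "parent2") == 2L))
})

test_that("Aa x Aa segregates 1:2:1", {
  set.seed(201)
  sim <- toy_sim("m1", "1", 0, matrix(c("Aa", "Aa"), 1, 2))
  n <- 1e4
  off <- cross(sim, 1L, 2L, offspring = n)
  g <- see_group_data(sim, off, "genotype")
  counts <- c(AA = sum(g == "AA"), het = sum(g %in% c("Aa", "aA")),
              aa = sum(g == "aa"))
  expect_identical(sum(counts), as.integer(n))
  p <- c(0.25, 0.5, 0.25)
  for (i in 1:3)
    expect_lt(abs(counts[i] / n - p[i]), 3 * sqrt(p[i] * (1 - p[i]) / n))
})

test_that("offspring group sizes follow their closed forms", {
  set.seed(202)
  map <- synth_map(2, 5, 60)
  p <- toy_files(map$table$marker, map$table$chr, map$table$pos,
                 synth_founders(6, map, inbred = TRUE)$cells)
  sim <- load_data(p$geno, p$map)
  expect_identical(group_size(sim, cross_randomly(sim, founders(sim), 25, 20)),
                   500L)
  expect_identical(group_size(sim, cross_all_pairs(sim, founders(sim))), 15L)
  ids <- see_group_data(sim, founders(sim), "index")
  expect_identical(
    group_size(sim, cross_combinations(sim, ids[c(1, 1, 2)], ids[c(2, 3, 3)],
                                       offspring = 4L)), 12L)
  expect_identical(group_size(sim, self_n_times(sim, founders(sim), 2,
                                                offspring = 3L)), 18L)
  expect_identical(group_size(sim, make_doubled_haploids(sim, founders(sim))),
                   6L)
})

test_that("random crossing never selfs and respects preconditions", {
  set.seed(203)
  sim <- toy_sim("m1", "1", 0, matrix(c("AA", "aa"), 1, 2))
  off <- cross_randomly(sim, founders(sim), 50)
  p1 <- see_group_data(sim, off, "parent1")
  p2 <- see_group_data(sim, off, "parent2")
  expect_true(all(p1 != p2))
  # parents are AA and aa, so every non-self pair gives a heterozygote
  expect_true(all(see_group_data(sim, off, "genotype") %in% c("Aa", "aA")))
  single <- make_group(sim, 1L)
  expect_error(cross_randomly(sim, single, 5), ">= 2 members")
})

test_that("a listed crossing plan runs in order, all-or-nothing", {
  set.seed(204)
  map <- synth_map(1, 4, 40)
  p <- toy_files(map$table$marker, map$table$chr, map$table$pos,
                 synth_founders(11, map, inbred = TRUE)$cells)
  sim <- load_data(p$geno, p$map)
  ids <- see_group_data(sim, founders(sim), "index")
  elite <- ids[1]; donors <- ids[-1]
  f1 <- cross_combinations(sim, rep(elite, 10), donors)
  expect_identical(group_size(sim, f1), 10L)
  expect_identical(see_group_data(sim, f1, "parent2"), donors)
  expect_error(cross_combinations(sim, integer(0), integer(0)), "empty")
  # a dead id aborts before any offspring are made
  n_before <- sum(all_groups(sim))
  expect_error(cross_combinations(sim, c(elite, 99999L), c(donors[1], elite)),
               "no live genotype")
  expect_identical(sum(all_groups(sim)), n_before)
  # a duplicated pair yields two independent offspring
  dup <- cross_combinations(sim, c(elite, elite), c(donors[1], donors[1]))
  expect_identical(group_size(sim, dup), 2L)
})

test_that("cross_all_pairs makes each offspring heterozygous where its parents differ", {
  sim <- toy_sim(c("m1", "m2"), "1", c(0, 10),
                 matrix(c("AA", "CC", "AA", "GG", "TT", "GG"), 2, 3))
  fids <- see_group_data(sim, founders(sim), "index")
  fchars <- genotype_chars(sim, founders(sim))
  off <- cross_all_pairs(sim, founders(sim))
  expect_identical(group_size(sim, off), 3L)
  g <- genotype_chars(sim, off)
  p1 <- see_group_data(sim, off, "parent1")
  p2 <- see_group_data(sim, off, "parent2")
  # each offspring locus is het exactly where the two (homozygous) parents differ
  for (i in seq_along(g)) {
    d <- fchars[[match(p1[i], fids)]][1, ] != fchars[[match(p2[i], fids)]][1, ]
    expect_identical(unname(g[[i]][1, ] != g[[i]][2, ]), unname(d))
  }
})

test_that("selfing halves heterozygosity per generation", {
  set.seed(205)
  # independent heterozygous lines: selfed descents must not share ancestry
  n <- 1e4
  sim <- toy_sim("m1", "1", 0, matrix("Aa", 1, n))
  s1 <- self_n_times(sim, founders(sim), 1)
  h1 <- het_fraction(sim, s1)
  expect_lt(abs(h1 - 0.5), 3 * sqrt(0.25 / n))
  sim2 <- toy_sim("m1", "1", 0, matrix("Aa", 1, n))
  s3 <- self_n_times(sim2, founders(sim2), 3)
  h3 <- het_fraction(sim2, s3)
  expect_lt(abs(h3 - 0.125), 3 * sqrt(0.125 * 0.875 / n))
  # a homozygous line is invariant under selfing
  sim3 <- toy_sim(c("m1", "m2"), "1", c(0, 5), matrix(c("AA", "tt"), 2, 1))
  s <- self_n_times(sim3, founders(sim3), 4)
  expect_identical(see_group_data(sim3, s, "genotype"), "AAtt")
  expect_error(self_n_times(sim3, s, 0), ">= 1")
})

test_that("doubled haploids are fully homozygous and draw gametes fairly", {
  set.seed(206)
  n <- 1e4
  sim <- toy_sim("m1", "1", 0, matrix("Aa", 1, n), phased = TRUE)
  dh <- make_doubled_haploids(sim, founders(sim))
  expect_identical(het_fraction(sim, dh), 0)
  g <- see_group_data(sim, dh, "genotype")
  expect_true(all(g %in% c("AA", "aa")))
  expect_lt(abs(mean(g == "AA") - 0.5), 3 * sqrt(0.25 / n))
  # homozygous parent -> DH identical to parent
  sim2 <- toy_sim("m1", "1", 0, matrix("CC", 1, 1))
  dh2 <- make_doubled_haploids(sim2, founders(sim2))
  expect_identical(see_group_data(sim2, dh2, "genotype"), "CC")
})

test_that("random mating leaves the mean breeding value unchanged", {
  set.seed(207)
  map <- synth_map(3, 30, 100)
  eff <- synth_effects(map, proportion_causal = 0.5)
  p <- toy_files(map$table$marker, map$table$chr, map$table$pos,
                 synth_founders(20, map, inbred = TRUE)$cells, effects = eff)
  sim <- load_data(p$geno, p$map, p$effects)
  parent_mean <- mean(breeding_values(sim, founders(sim)))
  off <- cross_randomly(sim, founders(sim), 100, 20)
  bv <- breeding_values(sim, off)
  # effective sample size is the number of crosses, not offspring
  se <- sd(bv) / sqrt(100)
  expect_lt(abs(mean(bv) - parent_mean), 4 * se)
})

test_that("offspring pedigrees resolve to the parents used", {
  set.seed(208)
  sim <- toy_sim(c("m1", "m2"), "1", c(0, 50),
                 matrix(c("AA", "CC", "aa", "cc"), 2, 2),
                 names = c("mum", "dad"))
  off <- cross(sim, 1L, 2L, offspring = 3L)
  expect_identical(see_group_data(sim, off, "pedigree"),
                   paste0("cr", 3:5, " = mum x dad"))
  expect_identical(see_group_data(sim, off, "name"),
                   c("cr3", "cr4", "cr5"))
})

test_that("crossing with an identical seed reproduces allele content", {
  map <- synth_map(2, 10, 80)
  p <- toy_files(map$table$marker, map$table$chr, map$table$pos,
                 synth_founders(5, map)$cells, phased = FALSE)
  set.seed(209)
  sim1 <- load_data(p$geno, p$map)
  o1 <- cross_randomly(sim1, founders(sim1), 10, 2)
  g1 <- see_group_data(sim1, o1, "genotype")
  set.seed(209)
  sim2 <- load_data(p$geno, p$map)
  o2 <- cross_randomly(sim2, founders(sim2), 10, 2)
  expect_identical(g1, see_group_data(sim2, o2, "genotype"))
})
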