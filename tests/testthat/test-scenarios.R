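# scaled-down scenario runs: small maps and populations keep each run in
# the seconds range while preserving the program structure

test_that("a neutral cycle (h2 = 1, keep everything) does not shift the mean", {
  res <- run_cyclic_program(n_cycles = 1, n_crosses = 25,
                            offspring_per_cross = 4,
                            stage_heritabilities = c(1, 1),
                            stage_portions = c(1, 1),
                            n_replicates = 3, n_founders = 20, n_chr = 3,
                            markers_per_chr = 40, seed = 701)
  # founder pool mean is 0-centred only by chance; compare across cycles via
  # a fresh 2-cycle run: with no selection the drift between cycles is pure
  # Monte-Carlo noise at the scale of the between-family SE
  res2 <- run_cyclic_program(n_cycles = 2, n_crosses = 25,
                             offspring_per_cross = 4,
                             stage_heritabilities = c(1, 1),
                             stage_portions = c(1, 1),
                             n_replicates = 3, n_founders = 20, n_chr = 3,
                             markers_per_chr = 40, seed = 702)
  m <- with(subset(res2, statistic == "mean_bv"), tapply(value, cycle, mean))
  v <- with(subset(res2, statistic == "var_bv"), tapply(value, cycle, mean))
  se <- sqrt(mean(v) / 25 / 3)  # 25 crosses per cycle, 3 replicates
  expect_lt(abs(m[2] - m[1]), 4 * se + 1e-9)
  expect_identical(nrow(res), 6L)  # 1 cycle x 3 replicates x 2 statistics
  expect_identical(unique(res$statistic), c("mean_bv", "var_bv"))
})

test_that("selection drives gain and erodes variance; within-family keeps diversity", {
  set.seed(703)
  # shared synthetic data set so both conditions start from the same founders
  map <- synth_map(4, 50, 120)
  d <- tempfile(); dir.create(d)
  write_map_file(map, file.path(d, "map.txt"))
  write_genotype_file(synth_founders(24, map, inbred = TRUE),
                      file.path(d, "geno.txt"))
  write_effects_file(synth_effects(map, 0.5, 1), file.path(d, "eff.txt"))
  args <- list(genotypes = file.path(d, "geno.txt"),
               map = file.path(d, "map.txt"),
               effects = file.path(d, "eff.txt"),
               n_cycles = 3, n_crosses = 12, offspring_per_cross = 10,
               n_replicates = 3)
  across <- do.call(run_cyclic_program, c(args, selection = "across",
                                          seed = 704))
  within <- do.call(run_cyclic_program, c(args, selection = "within_family",
                                          seed = 704))
  ma <- with(subset(across, statistic == "mean_bv"),
             tapply(value, cycle, mean))
  mw <- with(subset(within, statistic == "mean_bv"),
             tapply(value, cycle, mean))
  va <- with(subset(across, statistic == "var_bv"), tapply(value, cycle, mean))
  vw <- with(subset(within, statistic == "var_bv"), tapply(value, cycle, mean))
  expect_true(all(diff(ma) > 0))         # gain accumulates
  expect_gt(ma[3], mw[3])                # across-population gains faster
  expect_gt(vw[3], va[3])                # within-family retains variance
  expect_lt(va[3], va[1])                # variance erodes under selection
})

test_that("the NAM scenario produces the designed family structure", {
  res <- run_nam_scenario(n_donors = 4, lines_per_family = 8,
                          n_selfing_generations = 4, n_chr = 3,
                          markers_per_chr = 10, seed = 705)
  sizes <- vapply(res$families, function(g) group_size(res$sim, g),
                  integer(1))
  expect_identical(unname(sizes), rep(8L, 4L))
  expect_identical(dim(res$rogers), c(32L, 32L))
  expect_lt(res$within_mean, res$between_mean)
  # degenerate single-donor, single-line design
  tiny <- run_nam_scenario(n_donors = 1, lines_per_family = 1,
                           n_chr = 2, markers_per_chr = 5, seed = 706)
  expect_identical(unname(vapply(tiny$families, function(g)
    group_size(tiny$sim, g), integer(1))), 1L)
})

test_that("scenario outputs are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_nam_scenario(n_donors = 3, lines_per_family = 5, n_chr = 2,
                         markers_per_chr = 8, out_dir = d1, seed = 707)
  r2 <- run_nam_scenario(n_donors = 3, lines_per_family = 5, n_chr = 2,
                         markers_per_chr = 8, out_dir = d2, seed = 707)
  for (f in c("final-genotypes.txt", "rogers-distance.txt",
              "ld-profile.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_identical(r1$rogers, r2$rogers)
  a <- run_cyclic_program(n_cycles = 2, n_crosses = 5,
                          offspring_per_cross = 4, n_replicates = 2,
                          n_founders = 8, n_chr = 2, markers_per_chr = 10,
                          seed = 708)
  b <- run_cyclic_program(n_cycles = 2, n_crosses = 5,
                          offspring_per_cross = 4, n_replicates = 2,
                          n_founders = 8, n_chr = 2, markers_per_chr = 10,
                          seed = 708)
  expect_identical(a, b)
})

test_that("the command-line front end runs end to end and rejects bad input", {
  script <- system.file("exec", "meiosim.R", package = "meiosim")
  expect_true(nzchar(script) && file.exists(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- tempfile()
  res <- system2(rscript, c(script, "simulate-nam", "--seed", "5",
                            "--donors", "2", "--lines-per-family", "3",
                            "--out-dir", out),
                 stdout = TRUE, stderr = TRUE, env = libs)
  expect_identical(attr(res, "status"), NULL)  # exit 0
  expect_true(file.exists(file.path(out, "rogers-distance.txt")))
  expect_true(file.exists(file.path(out, "ld-profile.txt")))
  # same seed, fresh directory: byte-identical outputs
  out2 <- tempfile()
  system2(rscript, c(script, "simulate-nam", "--seed", "5",
                     "--donors", "2", "--lines-per-family", "3",
                     "--out-dir", out2),
          stdout = TRUE, stderr = TRUE, env = libs)
  expect_identical(readLines(file.path(out, "final-genotypes.txt")),
                   readLines(file.path(out2, "final-genotypes.txt")))
  # a missing map file is a clean nonzero exit
  bad <- suppressWarnings(
    system2(rscript, c(script, "cross", "--map", "/no/such/file",
                       "--genotypes", "/no/such/file"),
            stdout = TRUE, stderr = TRUE, env = libs))
  expect_identical(attr(bad, "status"), 1L)
})
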