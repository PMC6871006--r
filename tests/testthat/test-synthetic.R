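small_cfg <- function(...) {
  sim_config(length_range = c(3000, 6000), ...)
}

test_that("same seed reproduces genomes byte for byte", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  sim1 <- simulate_genomes(small_cfg(seed = 7, n_genomes = 4,
                                     dtr_fraction = 0.5), out_prefix = f1)
  sim2 <- simulate_genomes(small_cfg(seed = 7, n_genomes = 4,
                                     dtr_fraction = 0.5), out_prefix = f2)
  expect_identical(readLines(paste0(f1, ".fna")),
                   readLines(paste0(f2, ".fna")))
  expect_identical(sim1$truth, sim2$truth)

  sim3 <- simulate_genomes(small_cfg(seed = 8, n_genomes = 4))
  expect_false(identical(sim1$genomes$sequence[1],
                         sim3$genomes$sequence[1]))
})

test_that("planted termini are recovered by the detectors", {
  sim <- simulate_genomes(small_cfg(seed = 11, n_genomes = 6,
                                    dtr_fraction = 1.0))
  tt <- detect_termini(sim$genomes)
  expect_true(all(tt$dtr_found))
  expect_true(all(tt$dtr_length >= sim$config$repeat_len))

  sim2 <- simulate_genomes(small_cfg(seed = 12, n_genomes = 6,
                                     itr_fraction = 1.0))
  tt2 <- detect_termini(sim2$genomes)
  expect_true(all(tt2$itr_found))
  expect_true(all(sim2$truth$planted_terminus == "itr"))

  expect_error(sim_config(length_range = c(1000, 2000), repeat_len = 600),
               "repeat_len")
})

test_that("planted vOTUs are recovered by clustering", {
  sim <- simulate_genomes(sim_config(seed = 13, n_genomes = 0,
                                     length_range = c(8000, 12000),
                                     votu_plan = list(c(3, 0.02))))
  expect_equal(nrow(sim$genomes), 3)
  cl <- suppressWarnings(cluster_votus(sim$genomes))
  expect_equal(nrow(cl$clusters), 1)
  # realized divergence is recorded and near the nominal rate
  expect_true(all(abs(sim$truth$divergence[-1] - 0.02) < 0.01))
})

test_that("fragments are faithful substrings with recorded truth", {
  sim <- simulate_genomes(small_cfg(seed = 14, n_genomes = 2))
  g <- sim$genomes
  lens <- c(1000, min(g$length))
  fr <- fragment_genomes(g, lens, seed = 5)
  expect_true(all(fr$truth$length == fr$fragments$length))
  for (i in seq_len(nrow(fr$truth))) {
    src <- g$sequence[g$id == fr$truth$source_id[i]]
    expect_equal(fr$fragments$sequence[i],
                 substr(src, fr$truth$start[i],
                        fr$truth$start[i] + fr$truth$length[i] - 1))
  }
  # a fragment of full genome length is the genome itself
  shortest <- g$id[which.min(g$length)]
  full <- fr$truth$length == min(g$length) & fr$truth$source_id == shortest
  expect_true(any(full))
  expect_equal(fr$fragments$sequence[full][1],
               g$sequence[g$id == shortest])

  # reproducible positions
  fr2 <- fragment_genomes(g, lens, seed = 5)
  expect_identical(fr$truth, fr2$truth)

  expect_warning(sk <- fragment_genomes(g[1, , drop = FALSE], 10^6,
                                        seed = 1), "skipped")
  expect_equal(nrow(sk$truth), 0)
})

test_that("fragmentation bias shrinks with fragment length, zero at full", {
  set.seed(15)
  anc <- rand_seq(8000)
  pairs <- list(c(anc, mutate_seq(anc, 0.10)$seq))
  res <- fragmentation_bias_experiment(pairs, c(1000, 4000, 8000),
                                       n_reps = 8, seed = 2)
  expect_equal(res$fragment_length, c(1000, 4000, 8000))
  expect_equal(res$mean_abs_dev[3], 0) # full-length fragment = the genome
  expect_gt(res$mean_abs_dev[1], res$mean_abs_dev[2])

  # deterministic under the seed
  res2 <- fragmentation_bias_experiment(pairs, c(1000, 4000, 8000),
                                        n_reps = 8, seed = 2)
  expect_identical(res, res2)

  # unrelated pairs are refused
  bad <- list(c(rand_seq(5000), rand_seq(5000)))
  expect_error(suppressWarnings(
    fragmentation_bias_experiment(bad, 1000, n_reps = 2, seed = 1)),
    "no usable pairs")
})
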