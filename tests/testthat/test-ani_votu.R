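test_that("identity and containment give ANI 100 / AF 100", {
  set.seed(41)
  a <- rand_seq(10000)
  p <- compute_ani_af(a, a)
  expect_equal(p$ani, 100)
  expect_equal(p$af, 100)
  expect_equal(p$wg_ani, 100)

  # AF is relative to the shorter member: a 5-kb prefix aligns fully
  b <- substr(a, 1, 5000)
  p2 <- compute_ani_af(a, b, id_a = "long", id_b = "short")
  expect_equal(p2$query_id, "short")
  expect_equal(p2$ani, 100)
  expect_equal(p2$af, 100)

  # symmetric call gives the identical comparison
  p3 <- compute_ani_af(b, a, id_a = "short", id_b = "long")
  expect_equal(p2, p3)

  expect_error(compute_ani_af("", a), "empty")
})

test_that("estimated ANI matches the planted-mutation oracle", {
  a <- rand_seq(10000, seed = 42)
  mut <- mutate_seq(a, 0.05, seed = 43)
  oracle <- 100 * (1 - length(mut$changed) / nchar(a))
  est <- compute_ani_af(a, mut$seq)
  expect_equal(est$af, 100)
  expect_lt(abs(est$ani - oracle), 0.5)

  # strand of assembly is arbitrary: reverse complement changes nothing
  est_rc <- compute_ani_af(a, rc_oracle(mut$seq))
  expect_equal(est_rc$ani, est$ani)
  expect_equal(est_rc$af, est$af)
})

test_that("wg_ani is the ANI x AF product with range checks", {
  expect_equal(wg_ani(95, 85), 80.75)
  expect_equal(wg_ani(100, 100), 100)
  expect_equal(wg_ani(90, 100), 90)
  expect_error(wg_ani(101, 50))
  expect_error(wg_ani(50, -1))
})

test_that("species cutoff: AF gate first, then wgANI (or plain ANI)", {
  expect_true(passes_votu_cutoff(data.frame(ani = 90, af = 100)))
  expect_false(passes_votu_cutoff(data.frame(ani = 100, af = 84.9)))
  # 94 x 85 / 100 = 79.9 < 80.75
  expect_false(passes_votu_cutoff(data.frame(ani = 94, af = 85)))
  expect_true(passes_votu_cutoff(data.frame(ani = 95, af = 85)))

  plain <- clustering_params(mode = "plain")
  expect_false(passes_votu_cutoff(data.frame(ani = 90, af = 100), plain))
  expect_true(passes_votu_cutoff(data.frame(ani = 95, af = 85), plain))

  # every plain pass is a wgani pass (wgani admits a superset)
  set.seed(44)
  for (i in 1:200) {
    pr <- data.frame(ani = runif(1, 50, 100), af = runif(1, 50, 100))
    if (passes_votu_cutoff(pr, plain)) {
      expect_true(passes_votu_cutoff(pr, clustering_params()))
    }
  }
})

test_that("pairwise matrix covers all pairs and honors the report window", {
  set.seed(45)
  a <- rand_seq(6000)
  genomes <- c(g1 = a, g2 = mutate_seq(a, 0.03)$seq, g3 = rand_seq(6000))
  m <- pairwise_matrix(genomes)
  expect_equal(nrow(m), 3) # n(n-1)/2
  # symmetric: ids always ordered with the shorter/lexicographic query
  expect_true(all(m$wg_ani <= m$ani + 1e-9))
  expect_true(all(m$af >= 0 & m$af <= 100))

  filt <- pairwise_matrix(genomes, filter_report = TRUE)
  expect_true(all(filt$ani > 60 & filt$af > 20))
  expect_lt(nrow(filt), nrow(m)) # the unrelated genome drops out
})

test_that("greedy clustering recovers planted structure deterministically", {
  a <- rand_seq(10000, seed = 46)
  genomes <- c(A = a, B = mutate_seq(a, 0.02, seed = 47)$seq,
               C = rand_seq(10000, seed = 48))
  cl <- suppressWarnings(cluster_votus(genomes))
  expect_equal(nrow(cl$clusters), 2)
  ab <- cl$assignment$cluster_id[match(c("A", "B"),
                                       cl$assignment$genome_id)]
  expect_equal(ab[1], ab[2])

  # identical trio: one cluster, representative is lexicographically first
  trio <- c(zz = a, mm = a, aa = a)
  cl3 <- suppressWarnings(cluster_votus(trio))
  expect_equal(nrow(cl3$clusters), 1)
  expect_equal(cl3$clusters$representative_id, "aa")

  # invariance to input order
  cl_rev <- suppressWarnings(cluster_votus(rev(genomes)))
  expect_equal(cl_rev$assignment[order(cl_rev$assignment$genome_id), ],
               cl$assignment[order(cl$assignment$genome_id), ],
               ignore_attr = TRUE)

  # representative is the longest member
  withlen <- c(short = substr(a, 1, 8000), long = a)
  cl4 <- suppressWarnings(cluster_votus(withlen))
  expect_equal(cl4$clusters$representative_id[1], "long")
  expect_warning(cluster_votus(withlen), "10000")
})
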