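test_that("zero-rate and all-invariant limits produce invariant sequences", {
  z <- simulate_parent_pools(sim_config(d = 0, within_group_theta = 0, seed = 3))
  expect_equal(length(unique(aln_strings(z$alignment))), 1L)

  inv <- simulate_parent_pools(sim_config(p_inv = 1, seed = 3))
  expect_equal(segregating_sites(inv$alignment), 0L)
  ## but an unreachable divergence under partial invariance is a config error
  expect_error(simulate_parent_pools(sim_config(d = 0.3, p_inv = 0.633)),
               class = "config_error")
})

test_that("a fixed seed reproduces byte-identical output", {
  a <- simulate_parent_pools(sim_config(seed = 9))
  b <- simulate_parent_pools(sim_config(seed = 9))
  expect_identical(aln_strings(a$alignment), aln_strings(b$alignment))
  expect_identical(a$truth, b$truth)
  expect_false(identical(aln_strings(a$alignment),
                         aln_strings(simulate_parent_pools(sim_config(seed = 10))$alignment)))
})

test_that("realized inter-parent divergence tracks the target and pooled pi lands in range", {
  pis <- numeric(5)
  devs <- numeric(5)
  for (s in 1:5) {
    pools <- simulate_parent_pools(sim_config(seed = 100 + s,
                                              within_group_theta = 0,
                                              alleles_per_parent = 1L))
    a <- pools$alignment
    d <- pairwise_distances(a, "p")$d
    devs[s] <- mean(d[upper.tri(d)])
    pis[s] <- nucleotide_diversity(a)
  }
  expect_lt(abs(mean(devs) - 0.06), 0.2 * 0.06)   # within 20% of target
  expect_true(all(pis >= 0.03 & pis <= 0.07))
})

test_that("recombinants are exact splices with tiling truth segments", {
  pools <- simulate_parent_pools(sim_config(seed = 5))
  L <- pools$cfg$L
  rec <- simulate_recombinants(pools,
    list(list(a = "P1_a1", b = "P2_a1", breakpoints = L %/% 2L)), seed = 2)
  child <- rec$alignment$seqs["R1", ]
  a1 <- pools$alignment$seqs["P1_a1", ]
  b1 <- pools$alignment$seqs["P2_a1", ]
  half <- L %/% 2L
  expect_identical(child[1:half], a1[1:half])
  expect_identical(child[(half + 1L):L], b1[(half + 1L):L])
  tr <- rec$truth
  expect_equal(tr$start, c(1L, half + 1L))
  expect_equal(tr$end, c(half, L))
  expect_equal(tr$donor, c("P1", "P2"))

  expect_error(simulate_recombinants(pools,
    list(list(a = "P1", b = "P2", breakpoints = L + 5L))), class = "input_error")

  ## empty event list leaves the pool unchanged
  none <- simulate_recombinants(pools, list(), seed = 2)
  expect_identical(aln_strings(none$combined$alignment),
                   aln_strings(pools$alignment))
})

test_that("nested recombinants compose donor segments (recombinant of a recombinant)", {
  pools <- simulate_parent_pools(sim_config(seed = 6))
  rec <- simulate_recombinants(pools, list(
    list(a = "P1_a1", b = "P2_a1", breakpoints = 500L),   # R1 = P1|P2
    list(a = "R1", b = "P3_a1", breakpoints = 900L)),     # R2 = R1|P3
    seed = 2)
  tr2 <- rec$truth[rec$truth$seq_id == "R2", ]
  expect_equal(nrow(tr2), 3L)
  expect_equal(tr2$donor, c("P1", "P2", "P3"))
  expect_equal(tr2$start, c(1L, 501L, 901L))
  expect_equal(tr2$end, c(500L, 900L, 1450L))
  ## truth always tiles [1, L]
  for (id in unique(rec$combined$truth$seq_id)) {
    seg <- rec$combined$truth[rec$combined$truth$seq_id == id, ]
    expect_equal(seg$start[1L], 1L)
    expect_equal(seg$end[nrow(seg)], pools$cfg$L)
    if (nrow(seg) > 1L)
      expect_equal(seg$start[-1L], utils::head(seg$end, -1L) + 1L)
  }
})

test_that("PCR chimera injection respects the rate and flags truth", {
  pools <- simulate_parent_pools(sim_config(seed = 7))
  a <- pools$alignment
  none <- inject_pcr_chimeras(a, rate = 0, seed = 1)
  expect_identical(aln_strings(none$alignment), aln_strings(a))
  expect_false(any(none$truth$chimera))

  all_ch <- inject_pcr_chimeras(a, rate = 1, seed = 1)
  flagged <- unique(all_ch$truth$seq_id[all_ch$truth$chimera])
  expect_setequal(flagged, aln_ids(a))
  expect_error(inject_pcr_chimeras(a, rate = 1.5), class = "input_error")
})

test_that("isolate sampling draws clones from the held alleles only", {
  pools <- simulate_parent_pools(sim_config(seed = 8))
  one <- sample_isolates(pools$alignment, n_isolates = 3,
                         alleles_per_isolate = 1L, clones_per_isolate = 12L,
                         seed = 4)
  for (iso in unique(one$clones$isolate))
    expect_equal(length(unique(one$clones$allele[one$clones$isolate == iso])), 1L)
  expect_equal(n_seq(one$alignment), 36L)

  expect_error(sample_isolates(pools$alignment, 2,
                               alleles_per_isolate = 10000L),
               class = "config_error")

  ## coupon-collector under-sampling: 5 alleles, 12 clones recovers < 5
  ## sometimes; exact P(all 5 seen) = sum_{k} (-1)^k C(5,k) ((5-k)/5)^12
  p_all <- sum(vapply(0:5, function(k)
    (-1)^k * choose(5, k) * ((5 - k) / 5)^12, numeric(1)))
  hits <- vapply(1:200, function(s) {
    sm <- sample_isolates(pools$alignment, 1, alleles_per_isolate = 5L,
                          clones_per_isolate = 12L, seed = s)
    length(unique(sm$clones$allele)) == 5L
  }, logical(1))
  expect_lt(abs(mean(hits) - p_all), 0.12)   # MC tolerance
})
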