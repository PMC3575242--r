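test_that("phi statistic is zero on tree-compatible data and NA when untestable", {
  ## nested bipartitions: every informative-site pair is compatible
  a <- aln_from(s1 = "AAAA", s2 = "AAAA", s3 = "ACAA",
                s4 = "GCAA", s5 = "GCCA", s6 = "GCCA")
  r <- phi_test(a, n_perm = 200, seed = 1)
  expect_true(r$testable)
  expect_equal(r$phi_stat, 0)

  same <- aln_from("ACGT", "ACGT", "ACGT")
  r2 <- phi_test(same)
  expect_false(r2$testable)
  expect_true(is.na(r2$p_value))
})

test_that("phi detects planted mosaics and holds its size on clonal data", {
  det <- vapply(1:8, function(s) {
    scen <- simulate_mosaic_scenario(sim_config(seed = 400 + s),
                                     n_recombinants = 10, seed = 400 + s)
    phi_test(scen$alignment, n_perm = 500, seed = s)$p_value
  }, numeric(1))
  expect_gte(sum(det < 0.01), 7L)

  nulls <- vapply(1:30, function(s) {
    pools <- simulate_parent_pools(sim_config(seed = 800 + s))
    phi_test(pools$alignment, n_perm = 200, seed = s)$p_value
  }, numeric(1))
  expect_lte(sum(nulls <= 0.05), 5L)   # ~5% nominal, allow MC slack
})

test_that("a perfectly split window yields the maximal 2x2 chi-square (N = 2h)", {
  L <- 200L
  p1 <- paste0(rep("A", L), collapse = "")
  p2 <- paste0(rep("G", L), collapse = "")
  child <- paste0(c(rep("A", 100), rep("G", 100)), collapse = "")
  a <- aln_from(P1 = p1, P2 = p2, child = child)
  mis <- as.integer(a$seqs["child", ] != a$seqs["P2", ])
  o <- temosaic:::maxchi_stat_cpp(mis, 100L)
  expect_equal(o$stat, 200)
  expect_equal(o$k, 100L)

  calls <- maxchi_scan(a, half_widths = 100L, n_perm = 2000, seed = 1)
  got <- calls[calls$seq1 == "P2" | calls$seq2 == "P2", ]
  got <- got[got$seq1 == "child" | got$seq2 == "child", ]
  expect_equal(nrow(got), 1L)
  expect_equal(got$chi2, 200)
  expect_true(got$left <= 100 && got$right >= 101)
})

test_that("maxchi statistic is invariant to nucleotide relabeling", {
  a <- random_alignment(5, 300, mut = 0.1, seed = 77)
  relab <- a$seqs
  relab[] <- c(A = "T", C = "G", G = "C", T = "A")[relab]
  b <- as_aln(relab)
  for (h in c(20L, 40L)) {
    for (q in list(c(1, 2), c(2, 4), c(3, 5))) {
      sa <- temosaic:::considered_sites(a)
      sb <- temosaic:::considered_sites(b)
      ma <- as.integer(sa$seqs[q[1], ] != sa$seqs[q[2], ])
      mb <- as.integer(sb$seqs[q[1], ] != sb$seqs[q[2], ])
      expect_identical(temosaic:::maxchi_stat_cpp(ma, h),
                       temosaic:::maxchi_stat_cpp(mb, h))
    }
  }
})

test_that("merging calls groups identical intervals only, idempotently", {
  mk <- function(left, right, s1 = "x", s2 = "y")
    data.frame(seq1 = s1, seq2 = s2, left = left, right = right,
               chi2 = 10, p_value = 1e-4, half_width = 100L, step = 1L,
               boundary_index = 1L, stringsAsFactors = FALSE)
  five <- do.call(rbind, lapply(1:5, function(i) mk(592, 607, paste0("a", i))))
  ev <- merge_calls(five)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$label, "I")
  expect_equal(c(ev$left, ev$right), c(592, 607))

  two <- rbind(mk(815, 856), mk(825, 856))
  ev2 <- merge_calls(two)
  expect_equal(nrow(ev2), 2L)      # overlapping but distinct stay separate
  expect_equal(ev2$label, c("I", "II"))

  empty <- merge_calls(five[0, ])
  expect_equal(nrow(empty), 0L)

  ## order independence and count monotonicity
  mixed <- rbind(five, two)
  shuf <- mixed[c(4, 7, 1, 6, 3, 2, 5), ]
  expect_equal(merge_calls(mixed), merge_calls(shuf))
  expect_lte(nrow(merge_calls(mixed)), nrow(mixed))
})

test_that("Rm matches the closed cases and the exhaustive oracle", {
  fg <- aln_from(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "CC")
  expect_equal(hudson_kaplan_rm(fg)$rm, 1L)

  tree_like <- aln_from(s1 = "AAAA", s2 = "AAAA", s3 = "CCAA", s4 = "CCGG")
  expect_equal(hudson_kaplan_rm(tree_like)$rm, 0L)

  for (s in 1:120) {
    a <- random_alignment(n = sample(4:8, 1), L = 15,
                          mut = runif(1, 0.1, 0.35), seed = 5000 + s)
    expect_equal(hudson_kaplan_rm(a)$rm, oracle_rm(a),
                 info = paste("seed", 5000 + s))
  }
})

test_that("Rh respects the haplotype formula, dominates Rm, and is row-order invariant", {
  fourhap <- aln_from(s1 = "AA", s2 = "AC", s3 = "CA", s4 = "CC")
  expect_equal(haplotype_bound_rh(fourhap)$rh, 1L)

  same <- aln_from("ACGT", "ACGT", "ACGT")
  expect_equal(haplotype_bound_rh(same)$rh, 0L)

  for (s in 1:120) {
    a <- random_alignment(n = sample(4:8, 1), L = 15,
                          mut = runif(1, 0.1, 0.35), seed = 6000 + s)
    rm_v <- hudson_kaplan_rm(a)$rm
    rh_v <- haplotype_bound_rh(a)$rh
    expect_gte(rh_v, rm_v)
    perm <- as_aln(a$seqs[sample(n_seq(a)), , drop = FALSE])
    expect_equal(haplotype_bound_rh(perm)$rh, rh_v)
    expect_equal(hudson_kaplan_rm(perm)$rm, rm_v)
  }
})

test_that("the local haplotype bound alone can miss events the combined bound keeps", {
  ## one incompatible site pair whose enclosing intervals all have
  ## H <= S + 1: the combined bound must still report rh >= rm = 1
  a <- aln_from(s1 = "AAAA", s2 = "AACC", s3 = "CACA", s4 = "CCCC")
  expect_equal(hudson_kaplan_rm(a)$rm, 1L)
  r <- haplotype_bound_rh(a)
  expect_gte(r$rh, 1L)
  expect_true(all(r$local_bounds == 0L))
})

test_that("fragment scan stays empty on tree-like data and recovers planted junctions", {
  nulls <- vapply(1:6, function(s) {
    pools <- simulate_parent_pools(sim_config(seed = 8600 + s))
    length(fragment_scan(pools$alignment, max_candidates = 40L)) == 0L
  }, logical(1))
  expect_gte(sum(nulls), 5L)

  hits <- 0L
  for (s in 1:6) {
    pools <- simulate_parent_pools(sim_config(d = 0.08, seed = 8700 + s))
    rec <- simulate_recombinants(pools, list(
      list(a = "P1", b = "P2", breakpoints = c(500L, 900L))), seed = s)
    bp <- fragment_scan(rec$combined$alignment, max_candidates = 40L)
    if (length(bp) == 2L && all(abs(bp - c(500L, 900L)) <= 30L)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
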