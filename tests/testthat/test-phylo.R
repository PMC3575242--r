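test_that("distance models match closed forms and ape's implementations", {
  same <- aln_from(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGA")
  for (mod in c("p", "JC69", "K2P"))
    expect_equal(pairwise_distances(same, mod)$d["a", "b"], 0)

  ## p = 15/400 = 0.0375 -> JC69 = -0.75 log(1 - 0.05)
  s1 <- paste0(rep("A", 400), collapse = "")
  s2 <- paste0(c(rep("G", 15), rep("A", 385)), collapse = "")
  a <- aln_from(x = s1, y = s2)
  expect_equal(pairwise_distances(a, "p")$d["x", "y"], 0.0375)
  expect_equal(pairwise_distances(a, "JC69")$d["x", "y"],
               -0.75 * log(1 - 0.05), tolerance = 1e-12)
  ## all mismatches above are transitions (A<->G): K2P with Q = 0
  P <- 0.0375
  expect_equal(pairwise_distances(a, "K2P")$d["x", "y"],
               -0.5 * log((1 - 2 * P) * sqrt(1)), tolerance = 1e-12)

  r <- random_alignment(6, 300, mut = 0.08, seed = 11)
  dnab <- ape::as.DNAbin(r$seqs)
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K2P", "K80"))) {
    mine <- pairwise_distances(r, pair[1])$d
    theirs <- as.matrix(ape::dist.dna(dnab, model = pair[2]))
    expect_equal(mine, theirs[rownames(mine), colnames(mine)],
                 tolerance = 1e-10, info = pair[1])
  }
})

test_that("NJ recovers additive trees exactly and ignores leaf order", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    perm <- sample(n)
    rec2 <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(rec, rec2), 0, ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), class = "input_error")
})

test_that("star distances resolve with zero-length internal branches", {
  D <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  tr <- nj_tree(D)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(tr$edge.length[internal] < 1e-12))
})

test_that("fragment trees split at breakpoints and expose mosaic ancestry", {
  scen_cfg <- sim_config(d = 0.08, seed = 31)
  pools <- simulate_parent_pools(scen_cfg)
  rec <- simulate_recombinants(pools, list(
    list(a = "P1_a1", b = "P2_a1", breakpoints = c(540L, 820L))), seed = 3)
  a <- rec$combined$alignment

  trees <- fragment_trees(a, c(540L, 820L))
  expect_equal(length(trees), 3L)
  expect_named(trees, c("1-540", "541-820", "821-1450"))
  one <- fragment_trees(a)
  expect_equal(length(one), 1L)

  ## the recombinant joins P2's group only in the middle fragment
  nearest_group <- function(span) {
    d <- pairwise_distances(temosaic:::extract_span(a, span[1], span[2]), "p")$d
    others <- setdiff(rownames(d), "R1")
    sub("_a\\d+$", "", others[which.min(d["R1", others])])
  }
  expect_equal(nearest_group(c(1, 540)), "P1")
  expect_equal(nearest_group(c(541, 820)), "P2")
  expect_equal(nearest_group(c(821, 1450)), "P1")

  ## newick write -> read -> write is stable
  f <- withr::local_tempfile(fileext = ".nwk")
  write_trees(trees, f)
  back <- read_trees(f)
  expect_equal(length(back), 3L)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_trees(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("parental assignment names the planted donors and reports ties", {
  pools <- simulate_parent_pools(sim_config(d = 0.08, seed = 41))
  rec <- simulate_recombinants(pools, list(
    list(a = "P3_a1", b = "P5_a1", breakpoints = 700L)), seed = 4)
  a <- rec$combined$alignment
  groups <- c(stats::setNames(sub("_a\\d+$", "", aln_ids(pools$alignment)),
                              aln_ids(pools$alignment)),
              R1 = "R1")
  dists <- list(pairwise_distances(temosaic:::extract_span(a, 1, 700), "p"),
                pairwise_distances(temosaic:::extract_span(a, 701, 1450), "p"))
  asn <- assign_parents("R1", dists, groups)
  expect_equal(asn$per_fragment$donor, c("P3", "P5"))
  expect_true(all(asn$per_fragment$margin > 0))
  expect_equal(asn$assignment, "P3 : P5")

  ## exact tie: two groups holding identical sequences
  D <- matrix(0.5, 4, 4, dimnames = list(c("R", "g1", "g2", "far"),
                                         c("R", "g1", "g2", "far")))
  diag(D) <- 0
  D["R", "g1"] <- D["g1", "R"] <- 0.1
  D["R", "g2"] <- D["g2", "R"] <- 0.1
  gm <- c(R = "R", g1 = "G1", g2 = "G2", far = "FAR")
  tie <- assign_parents("R", list(structure(list(d = D, model = "p"),
                                            class = "dist_matrix")), gm)
  expect_equal(tie$per_fragment$margin, 0)
  expect_match(tie$assignment, " or ")
})
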