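# Independent oracles and small fixture generators used across tests.
# Oracles deliberately avoid the package's code paths: diversity via
# string-split loops, Rm via exhaustive optimal interval selection.

# random alignment descended from a root, so statistics are non-trivial
random_alignment <- function(n, L, mut = 0.08, seed) {
  set.seed(seed)
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    flip <- runif(L) < mut
    out <- root
    out[flip] <- vapply(which(flip), function(k)
      sample(setdiff(c("A", "C", "G", "T"), root[k]), 1L), character(1))
    out
  }, character(L)))
  rownames(m) <- paste0("s", seq_len(n))
  as_aln(m)
}

# pi oracle: explicit loop over all pairs of residue strings
oracle_pi <- function(aln) {
  ss <- strsplit(unname(aln_strings(aln)), "")
  n <- length(ss)
  L <- length(ss[[1L]])
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      tot <- tot + sum(mapply(function(a, b) a != b, ss[[i]], ss[[j]]))
  tot / choose(n, 2) / L
}

# Watterson oracle: segregating-site count by explicit column scan
oracle_theta_w <- function(aln) {
  ss <- strsplit(unname(aln_strings(aln)), "")
  n <- length(ss)
  L <- length(ss[[1L]])
  S <- 0L
  for (k in seq_len(L)) {
    col <- vapply(ss, `[[`, "", k)
    if (length(unique(col)) > 1L) S <- S + 1L
  }
  S / sum(1 / seq_len(n - 1L)) / L
}

# Rm oracle: enumerate incompatible site pairs (four-gamete test via
# explicit gamete tabulation), then find the true maximum number of
# pairwise-disjoint open intervals by DP over intervals sorted by right
# endpoint (optimal, no reduction heuristics).
oracle_rm <- function(aln) {
  m <- aln$seqs
  keep <- apply(m, 2L, function(col) {
    u <- unique(col)
    length(u) == 2L && all(u %in% c("A", "C", "G", "T"))
  })
  m <- m[, keep, drop = FALSE]
  k <- ncol(m)
  if (k < 2L) return(0L)
  iv <- NULL
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k) {
      gam <- unique(paste(m[, i], m[, j]))
      if (length(gam) == 4L) iv <- rbind(iv, c(i, j))
    }
  if (is.null(iv)) return(0L)
  iv <- iv[order(iv[, 2L], iv[, 1L]), , drop = FALSE]
  P <- nrow(iv)
  best <- integer(P)            # best[p]: max disjoint set using intervals 1..p
  for (p in seq_len(P)) {
    with_p <- 1L
    compat <- which(iv[, 2L] <= iv[p, 1L])   # open intervals: touching ok
    if (length(compat)) with_p <- 1L + max(best[compat])
    without_p <- if (p > 1L) best[p - 1L] else 0L
    best[p] <- max(with_p, without_p)
  }
  best[P]
}

# quick helper: alignment from explicit strings
aln_from <- function(...) {
  s <- c(...)
  if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  as_aln(s)
}
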