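## Lower bounds on the minimum number of recombination events.
##
## Rm (Hudson-Kaplan): four-gamete test on all pairs of biallelic sites,
## then the maximum number of pairwise-disjoint incompatible (open)
## intervals via the standard interval reduction + greedy selection.
##
## Rh: local bounds b(i, j) combined across non-overlapping intervals by
## dynamic programming. The local bound is the haplotype bound
## max(0, H - S - 1) (H distinct haplotypes, S segregating sites in the
## interval), strengthened with the local Hudson-Kaplan count so the
## combined bound always dominates Rm (the pure haplotype bound alone does
## not in rare configurations where an incompatible site pair leaves no
## haplotype excess).

## internal: biallelic segregating clean columns, coded 0/1 (major = 0)
biallelic_sites <- function(aln) {
  cc <- clean_cols_with_map(aln)
  cols <- list(); pos <- integer()
  for (k in seq_len(ncol(cc$seqs))) {
    tab <- sort(table(cc$seqs[, k]), decreasing = TRUE)
    if (length(tab) == 2L) {
      cols[[length(cols) + 1L]] <- as.integer(cc$seqs[, k] == names(tab)[2L])
      pos <- c(pos, cc$map[k])
    }
  }
  if (length(cols)) {
    m <- do.call(cbind, cols)
    rownames(m) <- rownames(cc$seqs)
  } else m <- matrix(integer(), nrow(cc$seqs), 0L)
  list(m = m, pos = pos)
}

## internal: four-gamete incompatibility between two 0/1 columns
four_gametes <- function(x, y) length(unique(x * 2L + y)) == 4L

## internal: pairwise incompatibility matrix over biallelic sites
incompatibility_matrix <- function(m) {
  k <- ncol(m)
  inc <- matrix(FALSE, k, k)
  if (k >= 2L)
    for (i in seq_len(k - 1L))
      for (j in (i + 1L):k)
        inc[i, j] <- inc[j, i] <- four_gametes(m[, i], m[, j])
  inc
}

## internal: per-site partners. maxpart[q] = largest p < q with inc(p, q)
## (0 if none); minpart_fwd[p] = smallest q > p with inc(p, q) (NA if none).
partner_bounds <- function(inc) {
  k <- nrow(inc)
  maxpart <- integer(k); minfwd <- rep(NA_integer_, k)
  for (q in seq_len(k)) {
    before <- if (q > 1L) which(inc[seq_len(q - 1L), q]) else integer()
    maxpart[q] <- if (length(before)) max(before) else 0L
    after <- if (q < k) which(inc[q, (q + 1L):k]) + q else integer()
    minfwd[q] <- if (length(after)) min(after) else NA_integer_
  }
  list(maxpart = maxpart, minfwd = minfwd)
}

## internal: local Rm over every interval [i, j] of site indices, by the
## earliest-endpoint greedy run incrementally for each start i. O(k^2).
rm_local_matrix <- function(inc) {
  k <- nrow(inc)
  pb <- partner_bounds(inc)
  out <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    cnt <- 0L; last_right <- i
    for (q in i:k) {
      if (pb$maxpart[q] >= max(i, last_right)) {
        cnt <- cnt + 1L
        last_right <- q
      }
      out[i, q] <- cnt
    }
  }
  out
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' @param aln an `aln` object; sites with more than two states are excluded.
#' @return list of class `rm_result`: `rm`, `incompatible_intervals` (data
#'   frame of minimal incompatible site intervals, with source
#'   coordinates), `chosen_disjoint_set` (the intervals counted),
#'   `n_sites`.
#' @export
hudson_kaplan_rm <- function(aln) {
  bi <- biallelic_sites(aln)
  k <- ncol(bi$m)
  empty <- data.frame(i = integer(), j = integer(),
                      left = integer(), right = integer())
  res0 <- structure(list(rm = 0L, incompatible_intervals = empty,
                         chosen_disjoint_set = empty, n_sites = k),
                    class = "rm_result")
  if (k < 2L) return(res0)
  inc <- incompatibility_matrix(bi$m)
  if (!any(inc)) return(res0)
  pb <- partner_bounds(inc)
  ## minimal incompatible intervals: (i, j) with inc(i, j), no pair
  ## starting at i ending earlier (minfwd[i] == j), and no pair strictly
  ## inside (suffix-min of minfwd over i+1..j-1 exceeds j).
  sufmin <- rep(Inf, k + 1L)
  for (i in k:1)
    sufmin[i] <- min(if (is.na(pb$minfwd[i])) Inf else pb$minfwd[i],
                     sufmin[i + 1L])
  iv <- NULL
  for (i in seq_len(k - 1L)) {
    j <- pb$minfwd[i]
    if (is.na(j)) next
    if (sufmin[i + 1L] > j)
      iv <- rbind(iv, data.frame(i = i, j = j))
  }
  iv <- iv[order(iv$j, iv$i), , drop = FALSE]
  chosen <- logical(nrow(iv))
  last_right <- 0L
  for (r in seq_len(nrow(iv)))
    if (iv$i[r] >= last_right) {        # open intervals: touching is disjoint
      chosen[r] <- TRUE
      last_right <- iv$j[r]
    }
  iv$left <- bi$pos[iv$i]; iv$right <- bi$pos[iv$j]
  structure(list(rm = sum(chosen), incompatible_intervals = iv,
                 chosen_disjoint_set = iv[chosen, , drop = FALSE],
                 n_sites = k),
            class = "rm_result")
}

#' @export
print.rm_result <- function(x, ...) {
  cat(sprintf("Rm = %d (from %d biallelic sites, %d minimal incompatible intervals)\n",
              x$rm, x$n_sites, nrow(x$incompatible_intervals)))
  invisible(x)
}

#' Combined haplotype lower bound (Rh)
#'
#' Local bounds `b(i, j) = max(0, H - S - 1, rm_local(i, j))` over
#' segregating-site intervals are combined by dynamic programming over
#' breakpoints: `B(j) = max_i B(i) + b(i + 1, j)`; `rh = B(m)`. By
#' construction `rh >= rm` on the same data, and the haplotype term
#' frequently tightens the bound well beyond it.
#'
#' @param aln an `aln` object.
#' @return list of class `rh_result`: `rh`, `local_bounds` (matrix of the
#'   haplotype local bounds over segregating-site intervals), `dp_trace`
#'   (data frame of the chosen intervals and their bounds), `rm` (for
#'   reference).
#' @export
haplotype_bound_rh <- function(aln) {
  cc <- clean_cols_with_map(aln)
  seg <- apply(cc$seqs, 2L, function(col) length(unique(col)) > 1L)
  m <- cc$seqs[, seg, drop = FALSE]
  pos <- cc$map[seg]
  k <- ncol(m)
  rm_res <- hudson_kaplan_rm(aln)
  if (k < 2L)
    return(structure(list(rh = 0L, local_bounds = matrix(0, 0, 0),
                          dp_trace = NULL, rm = rm_res$rm), class = "rh_result"))
  ## haplotype local bounds over all intervals (segregating sites only;
  ## monomorphic columns change neither H nor S)
  hap_b <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    seen <- character(nrow(m))
    for (j in i:k) {
      seen <- paste(seen, m[, j], sep = ",")
      H <- length(unique(seen))
      hap_b[i, j] <- max(0L, H - (j - i + 1L) - 1L)
    }
  }
  ## local four-gamete counts on the biallelic subset of these sites
  bi <- biallelic_sites(aln)
  bi_in_seg <- match(bi$pos, pos)
  inc_bi <- incompatibility_matrix(bi$m)
  rmloc <- rm_local_matrix(inc_bi)
  ## first/last biallelic site within a segregating-site interval
  n_bi_le <- cumsum(tabulate(bi_in_seg, nbins = k))   # biallelic count <= seg site
  b_fun <- function(i, j) {
    val <- hap_b[i, j]
    lo <- if (i > 1L) n_bi_le[i - 1L] + 1L else 1L
    hi <- n_bi_le[j]
    if (hi > lo) val <- max(val, rmloc[lo, hi])
    val
  }
  B <- numeric(k + 1L)                  # B[j+1] = best bound over sites 1..j
  back <- integer(k + 1L)
  for (j in seq_len(k)) {
    best <- B[j]; arg <- 0L             # 0 = site j in no chosen interval
    for (i in seq_len(j)) {
      v <- B[i] + b_fun(i, j)
      if (v > best) { best <- v; arg <- i }
    }
    B[j + 1L] <- best
    back[j + 1L] <- arg
  }
  trace <- NULL
  j <- k
  while (j >= 1L) {
    i <- back[j + 1L]
    if (i > 0L) {
      trace <- rbind(data.frame(from_site = i, to_site = j,
                                left = pos[i], right = pos[j],
                                bound = B[j + 1L] - B[i]), trace)
      j <- i - 1L
    } else j <- j - 1L
  }
  structure(list(rh = as.integer(B[k + 1L]), local_bounds = hap_b,
                 dp_trace = trace, rm = rm_res$rm),
            class = "rh_result")
}

#' @export
print.rh_result <- function(x, ...) {
  cat(sprintf("Rh = %d (combined haplotype lower bound; Rm = %d)\n", x$rh, x$rm))
  invisible(x)
}
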