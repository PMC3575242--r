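## Exhaustive 0/1/2-breakpoint incongruence scan.
##
## A deliberately simple whole-alignment segmentation: every candidate
## breakpoint set (up to two breakpoints, candidates at midpoints between
## informative sites) is scored by the parsimony length of each segment on
## its own NJ topology, plus a complexity penalty per breakpoint. When
## segments support different topologies, splitting at the true junctions
## removes the homoplasy that the conflicting sites force on any single
## tree, so the total parsimony score drops sharply; on tree-like data a
## split only buys the few steps that come from topology overfitting,
## which the penalty absorbs. This is a stand-in for full phylogenetic
## breakpoint searches (no genetic algorithm, no topology-test
## significance).

#' Exhaustive two-breakpoint incongruence scan
#'
#' @param aln an `aln` object with >= 4 sequences.
#' @param max_breaks 0, 1 or 2 breakpoints considered (<= 2).
#' @param penalty additive cost per breakpoint, in parsimony steps. The
#'   default (`NULL`) uses 2% of the unsegmented parsimony score: on
#'   tree-like data a split recovers only a percent or two of the steps
#'   through topology overfitting, while a genuine donor switch recovers
#'   far more.
#' @param max_candidates cap on candidate positions (midpoints between
#'   consecutive informative sites, thinned evenly when more; chosen
#'   breakpoints are then refined over the unthinned candidates in their
#'   neighbourhood).
#' @param min_informative minimum informative sites a segment must retain;
#'   segmentations violating it are not considered. If the alignment
#'   itself cannot support segmentation, an empty set is returned with a
#'   warning.
#' @return integer vector of breakpoint positions (source coordinates;
#'   empty when no split improves the penalized score), with attribute
#'   `scores` (data frame of the best penalized score by number of
#'   breakpoints). Deterministic.
#' @export
fragment_scan <- function(aln, max_breaks = 2L, penalty = NULL,
                          max_candidates = 200L, min_informative = 3L) {
  if (max_breaks > 2L) te_stop("max_breaks must be <= 2", "input_error")
  if (n_seq(aln) < 4L) te_stop("need at least 4 sequences", "input_error")
  cc <- clean_cols_with_map(aln)
  m <- cc$seqs
  n <- nrow(m); L <- ncol(m)
  inf_flag <- apply(m, 2L, function(col) {
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  })
  inf_pos <- cc$map[inf_flag]
  if (length(inf_pos) < 2L * min_informative) {
    warning("too few informative sites; returning empty breakpoint set")
    return(structure(integer(), scores = NULL))
  }
  cum_inf <- c(0L, cumsum(inf_flag))

  pairs <- utils::combn(n, 2L)
  n_pairs <- ncol(pairs)
  ## prefix sums of per-pair mismatches along clean columns, for cheap
  ## per-segment distance matrices
  mis_cum <- matrix(0L, n_pairs, L + 1L)
  for (q in seq_len(n_pairs))
    mis_cum[q, -1L] <- cumsum(m[pairs[1L, q], ] != m[pairs[2L, q], ])
  labels <- rownames(m)
  ph <- phangorn::phyDat(m, type = "DNA")

  seg_parsimony <- function(c1, c2) {      # clean-column index range
    if (cum_inf[c2 + 1L] - cum_inf[c1] < min_informative) return(NA_real_)
    p <- (mis_cum[, c2 + 1L] - mis_cum[, c1]) / (c2 - c1 + 1L)
    D <- matrix(0, n, n, dimnames = list(labels, labels))
    D[t(pairs)] <- p
    D <- D + t(D)
    tr <- ape::nj(D)
    tr$edge.length[tr$edge.length < 0] <- 0
    phangorn::parsimony(tr, subset(ph, select = c1:c2, site.pattern = FALSE))
  }

  cand_all <- unique((utils::head(inf_pos, -1L) + inf_pos[-1L]) %/% 2L)
  cand <- cand_all
  if (length(cand) > max_candidates)
    cand <- cand[unique(round(seq(1L, length(cand), length.out = max_candidates)))]
  ## clean-column index of the last column at or before each candidate
  to_col <- function(b) findInterval(b, cc$map)
  cand_col <- to_col(cand)
  keep <- cand_col >= 1L & cand_col < L
  cand <- cand[keep]; cand_col <- cand_col[keep]

  memo <- new.env(parent = emptyenv())
  seg_score <- function(c1, c2) {
    key <- paste0(c1, ":", c2)
    val <- memo[[key]]
    if (is.null(val)) {
      val <- seg_parsimony(c1, c2)
      memo[[key]] <- val
    }
    val
  }
  score_bp <- function(bp) {               # penalized score of a breakpoint set
    cols <- to_col(sort(bp))
    if (any(cols < 1L) || any(cols >= L) || any(duplicated(cols)))
      return(NA_real_)
    bounds <- c(0L, cols, L)
    s <- 0
    for (seg in seq_len(length(bounds) - 1L)) {
      v <- seg_score(bounds[seg] + 1L, bounds[seg + 1L])
      if (is.na(v)) return(NA_real_)
      s <- s + v
    }
    s + penalty * length(bp)
  }

  score0 <- seg_score(1L, L)
  if (is.na(score0)) {
    warning("unsegmented alignment not scorable; returning empty breakpoint set")
    return(structure(integer(), scores = NULL))
  }
  if (is.null(penalty)) penalty <- max(2, 0.02 * score0)

  best <- list(score = score0, bp = integer())
  rows <- data.frame(n_breaks = 0L, score = score0)

  if (max_breaks >= 1L) {
    best1 <- Inf; bp1 <- NA_integer_
    for (ci in seq_along(cand)) {
      lft <- seg_score(1L, cand_col[ci])
      if (is.na(lft)) next
      s <- lft + seg_score(cand_col[ci] + 1L, L)
      if (!is.na(s) && s < best1) { best1 <- s; bp1 <- cand[ci] }
    }
    if (is.finite(best1)) {
      total <- best1 + penalty
      rows <- rbind(rows, data.frame(n_breaks = 1L, score = total))
      if (total < best$score) best <- list(score = total, bp = bp1)
    }
  }
  if (max_breaks >= 2L && length(cand) >= 2L) {
    best2 <- Inf; bp2 <- c(NA_integer_, NA_integer_)
    for (ai in seq_len(length(cand) - 1L)) {
      lft <- seg_score(1L, cand_col[ai])
      if (is.na(lft)) next
      for (bi in (ai + 1L):length(cand)) {
        if (cand_col[bi] == cand_col[ai]) next
        mid <- seg_score(cand_col[ai] + 1L, cand_col[bi])
        if (is.na(mid)) next
        s <- lft + mid + seg_score(cand_col[bi] + 1L, L)
        if (!is.na(s) && s < best2) { best2 <- s; bp2 <- c(cand[ai], cand[bi]) }
      }
    }
    if (is.finite(best2)) {
      total <- best2 + 2 * penalty
      rows <- rbind(rows, data.frame(n_breaks = 2L, score = total))
      if (total < best$score) best <- list(score = total, bp = bp2)
    }
  }
  ## refinement: the coarse grid fixes which segments exist; localize each
  ## boundary exactly by holding the two flanking segment topologies fixed
  ## and assigning every column to the tree that explains it in fewer
  ## steps (per-site parsimony + prefix sums give the exact argmin over
  ## all candidate positions in the span). Topologies are re-estimated
  ## between passes.
  if (length(best$bp)) {
    seg_tree <- function(c1, c2) {
      p <- (mis_cum[, c2 + 1L] - mis_cum[, c1]) / (c2 - c1 + 1L)
      D <- matrix(0, n, n, dimnames = list(labels, labels))
      D[t(pairs)] <- p
      D <- D + t(D)
      tr <- ape::nj(D)
      tr$edge.length[tr$edge.length < 0] <- 0
      tr
    }
    site_steps <- function(tree, c1, c2) {
      pd <- subset(ph, select = c1:c2, site.pattern = FALSE)
      per_pattern <- phangorn::parsimony(tree, pd, site = "site")
      per_pattern[attr(pd, "index")]     # expand patterns to sites
    }
    bp <- sort(best$bp)
    for (pass in 1:3) {
      changed <- FALSE
      bounds <- c(0L, to_col(bp), L)
      for (bi in seq_along(bp)) {
        lo <- bounds[bi] + 1L; cur <- bounds[bi + 1L]; hi <- bounds[bi + 2L]
        if (cur <= lo || hi <= cur + 1L) next
        tl <- seg_tree(lo, cur)
        tr_ <- seg_tree(cur + 1L, hi)
        sl <- site_steps(tl, lo, hi)
        sr <- site_steps(tr_, lo, hi)
        csl <- cumsum(sl); csr <- cumsum(sr)
        in_span <- cand_all[cand_all > cc$map[lo] & cand_all < cc$map[hi]]
        cols <- to_col(in_span)
        ok <- cols > lo & cols < hi
        in_span <- in_span[ok]; cols <- cols[ok]
        if (!length(cols)) next
        rel <- cols - lo + 1L
        tot_r <- csr[length(csr)]
        obj <- csl[rel] + (tot_r - csr[rel])
        b_new <- in_span[which.min(obj)]
        if (b_new != bp[bi]) { bp[bi] <- b_new; changed <- TRUE }
        bounds <- c(0L, to_col(sort(bp)), L)
      }
      bp <- sort(bp)
      if (!changed) break
    }
    best$bp <- bp
  }
  structure(as.integer(best$bp), scores = rows)
}
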