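## Stepwise maximum chi-square breakpoint detection.
##
## For every unordered sequence pair, a sliding boundary over the
## segregating columns of the alignment splits a window of h sites each
## side into a 2x2 table of matches/mismatches; the maximal chi-square is
## assessed against a Monte-Carlo permutation null (columns shuffled,
## statistic re-maximized). Accepted breakpoints condition the next round:
## permutations are restricted to the segments they delimit, and scanning
## repeats until no further breakpoint is significant. Half-windows are
## counted in segregating sites, not raw bp, so the table margins stay
## comparable when divergence varies along the sequence.

## internal: segregating clean columns and their source coordinates
considered_sites <- function(aln) {
  cc <- clean_cols_with_map(aln)
  seg <- apply(cc$seqs, 2L, function(col) length(unique(col)) > 1L)
  list(seqs = cc$seqs[, seg, drop = FALSE], pos = cc$map[seg],
       src_first = aln$column_map[1L],
       src_last = aln$column_map[length(aln$column_map)])
}

## internal: reported interval between the flanking pair-mismatch sites
call_interval <- function(k, mis, pos, src_first, src_last) {
  left_idx <- which(mis[seq_len(k)] == 1L)
  right_idx <- which(mis[(k + 1L):length(mis)] == 1L)
  left <- if (length(left_idx)) pos[max(left_idx)] else src_first
  right <- if (length(right_idx)) pos[k + min(right_idx)] else src_last
  c(left, right)
}

#' Stepwise maximum chi-square breakpoint scan
#'
#' @param aln an `aln` object; gap/ambiguous columns are excluded and the
#'   scan runs over the remaining segregating columns.
#' @param half_widths half-window sizes, in segregating sites each side of
#'   the candidate breakpoint.
#' @param n_perm Monte-Carlo replicates per pair and half-width.
#' @param alpha significance level; per-pair permutation p-values are
#'   Bonferroni-corrected by the number of pairs scanned in the step.
#' @param seed RNG seed governing all permutation layers.
#' @param max_steps safety cap on stepwise rounds.
#' @return data frame of class `breakpoint_calls`: `seq1`, `seq2` (the pair;
#'   one derived, one parental — the scan cannot orient them), `left`,
#'   `right` (source coordinates of the polymorphic sites flanking the
#'   inferred breakpoint), `chi2`, `p_value` (raw permutation p),
#'   `half_width`, `step`, `boundary_index`. Pairs with fewer than `2 * h`
#'   segregating sites are skipped for that half-width (attribute
#'   `skipped`).
#' @export
maxchi_scan <- function(aln, half_widths = c(70L, 80L, 90L, 100L),
                        n_perm = 10000L, alpha = 0.05, seed = 1L,
                        max_steps = 5L) {
  if (n_seq(aln) < 3L) te_stop("need at least 3 sequences", "input_error")
  cs <- considered_sites(aln)
  S <- ncol(cs$seqs)
  ids <- rownames(cs$seqs)
  pairs <- utils::combn(length(ids), 2L)
  n_pairs <- ncol(pairs)
  set.seed(as.integer(seed))

  mis_list <- lapply(seq_len(n_pairs), function(q)
    as.integer(cs$seqs[pairs[1L, q], ] != cs$seqs[pairs[2L, q], ]))

  half_widths <- as.integer(half_widths)
  skipped <- character()
  for (h in half_widths)
    if (S < 2L * h)
      skipped <- c(skipped, sprintf("h=%d: only %d segregating sites (< 2h)", h, S))

  calls <- list()
  accepted_k <- integer()
  for (step in seq_len(max_steps)) {
    block_ends <- sort(unique(c(accepted_k, S)))
    block_sizes <- diff(c(0L, block_ends))
    ## the null distribution of the permuted maximum depends only on the
    ## per-block mismatch counts, so it is computed once per distinct
    ## count profile and shared across pairs (and across half-widths,
    ## which reuse the same permutations)
    null_cache <- new.env(parent = emptyenv())
    new_k <- integer()
    for (q in seq_len(n_pairs)) {
      mis <- mis_list[[q]]
      obs <- lapply(half_widths, function(h) maxchi_stat_cpp(mis, h))
      if (all(vapply(obs, function(o) is.na(o$stat) || o$stat <= 0, logical(1))))
        next
      cmis <- cumsum(mis)
      block_mis <- diff(c(0L, cmis[block_ends]))
      key <- paste(c(block_sizes, block_mis), collapse = ",")
      null <- null_cache[[key]]
      if (is.null(null)) {
        null <- maxchi_null_cpp(block_sizes, block_mis, half_widths,
                                as.integer(n_perm))
        null_cache[[key]] <- null
      }
      for (hi in seq_along(half_widths)) {
        h <- half_widths[hi]
        o <- obs[[hi]]
        if (is.na(o$stat) || o$stat <= 0) next
        p <- (sum(null[, hi] >= o$stat - 1e-9) + 1) / (n_perm + 1)
        if (p * n_pairs <= alpha) {
          iv <- call_interval(o$k, mis, cs$pos, cs$src_first, cs$src_last)
          already <- length(calls) &&
            any(vapply(calls, function(cl)
              cl$seq1 == ids[pairs[1L, q]] && cl$seq2 == ids[pairs[2L, q]] &&
              cl$half_width == h && cl$boundary_index == o$k, logical(1)))
          if (!already) {
            calls[[length(calls) + 1L]] <- data.frame(
              seq1 = ids[pairs[1L, q]], seq2 = ids[pairs[2L, q]],
              left = iv[1L], right = iv[2L], chi2 = o$stat, p_value = p,
              half_width = h, step = step, boundary_index = o$k,
              stringsAsFactors = FALSE)
            new_k <- c(new_k, o$k)
          }
        }
      }
    }
    new_k <- setdiff(unique(new_k), accepted_k)
    if (!length(new_k)) break
    accepted_k <- sort(c(accepted_k, new_k))
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(seq1 = character(), seq2 = character(),
                         left = integer(), right = integer(),
                         chi2 = numeric(), p_value = numeric(),
                         half_width = integer(), step = integer(),
                         boundary_index = integer(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "n_pairs") <- n_pairs
  class(out) <- c("breakpoint_calls", "data.frame")
  out
}

#' Merge pairwise breakpoint calls into unique recombination events
#'
#' Calls whose breakpoint intervals are equivalent under the merge rule are
#' treated as the same historical event. The default rule is interval
#' identity: calls with exactly the same `(left, right)` interval merge;
#' overlapping but distinct intervals stay separate events. Events are
#' labelled with roman numerals ordered by left coordinate.
#'
#' @param calls a `breakpoint_calls` data frame.
#' @param rule `"identity"` or `"jaccard"`.
#' @param jaccard_t overlap threshold for the jaccard rule.
#' @return data frame of class `recomb_events`: `label`, `left`, `right`
#'   (consensus interval: min left, max right of members), `n_calls`,
#'   `members` (semicolon-joined pair strings). Merging is idempotent and
#'   independent of call order.
#' @export
merge_calls <- function(calls, rule = c("identity", "jaccard"), jaccard_t = 0.75) {
  rule <- match.arg(rule)
  if (nrow(calls) == 0L)
    return(structure(data.frame(label = character(), left = integer(),
                                right = integer(), n_calls = integer(),
                                members = character(), stringsAsFactors = FALSE),
                     class = c("recomb_events", "data.frame")))
  if (rule == "identity") {
    key <- paste(calls$left, calls$right, sep = "-")
    grp <- match(key, unique(key[order(calls$left, calls$right)]))
  } else {
    n <- nrow(calls)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n) {
        ov <- min(calls$right[i], calls$right[j]) - max(calls$left[i], calls$left[j]) + 1
        un <- max(calls$right[i], calls$right[j]) - min(calls$left[i], calls$left[j]) + 1
        if (ov > 0 && ov / un >= jaccard_t) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    roots <- vapply(seq_len(n), find, integer(1))
    grp <- match(roots, unique(roots))
  }
  ev <- lapply(split(seq_len(nrow(calls)), grp), function(idx) {
    data.frame(left = min(calls$left[idx]), right = max(calls$right[idx]),
               n_calls = length(idx),
               members = paste(sort(unique(paste(calls$seq1[idx], calls$seq2[idx],
                                                 sep = ":"))), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$left, ev$right), , drop = FALSE]
  ev <- data.frame(label = as.character(utils::as.roman(seq_len(nrow(ev)))), ev,
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  class(ev) <- c("recomb_events", "data.frame")
  ev
}

#' Write breakpoint calls / events
#'
#' `write_calls()` emits the pairwise call table as TSV; `write_events_bed()`
#' emits merged events as a BED-like 3-column file (0-based half-open
#' intervals against the source coordinate frame).
#'
#' @param calls a `breakpoint_calls` data frame.
#' @param events a `recomb_events` data frame.
#' @param path output path.
#' @param chrom name used in the first BED column.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_events_bed <- function(events, path, chrom = "alignment") {
  bed <- data.frame(chrom = chrom, start = events$left - 1L, end = events$right,
                    name = events$label)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
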