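## Distance matrices, neighbor-joining dendrograms per recombination
## fragment, and parental-donor assignment for recombinant sequences.
## A mosaic sequence clusters with a different donor group in the trees on
## either side of its breakpoint; comparing its per-fragment nearest groups
## therefore reads off the probable parental pair.

#' Pairwise distance matrix
#'
#' `p` = mismatches / sites; `JC69` = `-3/4 log(1 - 4p/3)`;
#' `K2P` from transition (P) and transversion (Q) proportions,
#' `-1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`. Saturated pairs (logarithm of a
#' non-positive value) fall back to the p-distance and are flagged.
#'
#' @param aln an `aln` object; computed on gap/ambiguity-free columns.
#' @param model `"p"`, `"JC69"` or `"K2P"`.
#' @return object of class `dist_matrix`: list with `d` (symmetric matrix),
#'   `model`, `saturated` (logical matrix of fallback entries).
#' @export
pairwise_distances <- function(aln, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  m <- clean_cols(aln)
  if (ncol(m) == 0L) te_stop("no analyzable sites", "undefined_error")
  n <- nrow(m); L <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      diff <- m[i, ] != m[j, ]
      p <- sum(diff) / L
      val <- p
      if (model == "JC69") {
        arg <- 1 - 4 * p / 3
        if (arg > 0) val <- -0.75 * log(arg) else { sat[i, j] <- sat[j, i] <- TRUE }
      } else if (model == "K2P") {
        ts <- sum(diff & (purine[m[i, ]] == purine[m[j, ]])) / L
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv; a2 <- 1 - 2 * tv
        if (a1 > 0 && a2 > 0) val <- -0.5 * log(a1 * sqrt(a2))
        else { sat[i, j] <- sat[j, i] <- TRUE }
      }
      d[i, j] <- d[j, i] <- val
    }
  if (any(sat)) warning("saturated pairs fell back to p-distance")
  structure(list(d = d, model = model, saturated = sat), class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix; on additive distances the
#' generating topology and branch lengths are recovered exactly. Negative
#' branch lengths are clamped to zero (the number clamped is recorded in
#' attribute `n_clamped`).
#'
#' @param D a `dist_matrix` (or plain symmetric matrix) over >= 3 taxa.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "dist_matrix")) D$d else as.matrix(D)
  if (nrow(d) < 3L) te_stop("need at least 3 taxa", "input_error")
  tr <- ape::nj(d)
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "n_clamped") <- n_clamped
  tr
}

## internal: fragment spans from breakpoints, in source coordinates
fragment_spans <- function(aln, breakpoints) {
  src_first <- aln$column_map[1L]
  src_last <- aln$column_map[length(aln$column_map)]
  breakpoints <- sort(unique(as.integer(breakpoints)))
  if (length(breakpoints) &&
      (any(breakpoints < src_first) || any(breakpoints >= src_last)))
    te_stop("breakpoint outside sequence bounds", "input_error")
  bounds <- c(src_first - 1L, breakpoints, src_last)
  data.frame(start = utils::head(bounds, -1L) + 1L, end = bounds[-1L])
}

## internal: sub-alignment of a source-coordinate span
extract_span <- function(aln, start, end) {
  keep <- aln$column_map >= start & aln$column_map <= end
  if (!any(keep)) return(NULL)
  as_aln(aln$seqs[, keep, drop = FALSE], aln$column_map[keep])
}

#' Neighbor-joining trees per recombination fragment
#'
#' Fragments are the spans between consecutive breakpoints (and the
#' alignment ends); breakpoints are source coordinates, e.g. the merged
#' event positions from [merge_calls()] or a fragment scan. Fragments with
#' fewer than 3 variable sites are skipped with a warning.
#'
#' @param aln an `aln` object.
#' @param breakpoints sorted source-coordinate breakpoints (may be empty).
#' @param model distance model passed to [pairwise_distances()].
#' @return named list of `phylo` trees (names `"start-end"`), with the
#'   fragment table in attribute `fragments`.
#' @export
fragment_trees <- function(aln, breakpoints = integer(), model = "p") {
  spans <- fragment_spans(aln, breakpoints)
  trees <- list()
  for (r in seq_len(nrow(spans))) {
    sub <- extract_span(aln, spans$start[r], spans$end[r])
    name <- paste0(spans$start[r], "-", spans$end[r])
    if (is.null(sub) || segregating_sites(sub) < 3L) {
      warning("fragment ", name, " has < 3 variable sites; skipped")
      next
    }
    trees[[name]] <- nj_tree(pairwise_distances(sub, model))
  }
  attr(trees, "fragments") <- spans
  trees
}

#' Read/write trees in newick format
#' @param trees named list of `phylo` objects (or a single tree).
#' @param path file path.
#' @return for `write_trees`, `path` invisibly; for `read_trees`, a list of
#'   `phylo` objects.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ape::write.tree(structure(unname(trees), class = "multiPhylo"), path)
  invisible(path)
}

#' @rdname write_trees
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' Assign probable parental donors to a recombinant, fragment by fragment
#'
#' For each fragment, the donor is the sequence group (excluding the
#' recombinant's own group) with the smallest mean distance to the
#' recombinant; the margin is the distance gap to the second-best group.
#' Groups whose margin is within `tie_tol` of the best distance are listed
#' as alternatives (the `"h : c` or `i : c"` style of ambiguous
#' assignments). The assignment string concatenates per-fragment donors
#' with `" : "`.
#'
#' @param recomb_id id of the recombinant sequence.
#' @param fragment_dists list of `dist_matrix` (one per fragment), e.g.
#'   computed on the fragments of [fragment_trees()].
#' @param groups named character vector mapping sequence id -> group label;
#'   sequences labelled `"ungrouped"` have no group identity and are never
#'   candidate donors (give such a sequence its own label to allow it, as
#'   one would for a named singleton).
#' @param tie_tol relative margin below which alternative donors are
#'   reported (fraction of the best mean distance).
#' @return list of class `parental_assignment`: `recomb_id`, `per_fragment`
#'   (data frame: fragment, donor, mean_dist, margin, alternatives),
#'   `assignment` (string).
#' @export
assign_parents <- function(recomb_id, fragment_dists, groups, tie_tol = 0.10) {
  if (!recomb_id %in% names(groups))
    te_stop(paste0("recombinant not in group map: ", recomb_id), "input_error")
  own <- groups[[recomb_id]]
  rows <- list()
  for (f in seq_along(fragment_dists)) {
    D <- fragment_dists[[f]]
    d <- if (inherits(D, "dist_matrix")) D$d else as.matrix(D)
    if (!recomb_id %in% rownames(d))
      te_stop("recombinant missing from a fragment distance matrix", "input_error")
    cand <- setdiff(rownames(d), recomb_id)
    cand_groups <- setdiff(unique(groups[cand]), c(own, "ungrouped"))
    if (!length(cand_groups))
      te_stop("no non-self groups to assign from", "assignment_impossible")
    means <- vapply(cand_groups, function(g) {
      members <- intersect(cand[groups[cand] == g], rownames(d))
      mean(d[recomb_id, members])
    }, numeric(1))
    ord <- order(means)
    best <- cand_groups[ord[1L]]
    margin <- if (length(means) > 1L) means[ord[2L]] - means[ord[1L]] else Inf
    tol <- tie_tol * max(means[ord[1L]], .Machine$double.eps)
    alts <- if (length(means) > 1L)
      cand_groups[ord[-1L]][means[ord[-1L]] - means[ord[1L]] <= tol]
    else character()
    rows[[f]] <- data.frame(fragment = f, donor = best,
                            mean_dist = means[ord[1L]],
                            margin = if (is.finite(margin)) margin else NA_real_,
                            alternatives = paste(alts, collapse = "|"),
                            stringsAsFactors = FALSE)
  }
  per_fragment <- do.call(rbind, rows)
  label <- function(r) if (nzchar(r$alternatives))
    paste0(r$donor, " or ", gsub("\\|", " or ", r$alternatives)) else r$donor
  assignment <- paste(vapply(seq_len(nrow(per_fragment)),
                             function(i) label(per_fragment[i, ]), character(1)),
                      collapse = " : ")
  structure(list(recomb_id = recomb_id, per_fragment = per_fragment,
                 assignment = assignment),
            class = "parental_assignment")
}

#' @export
print.parental_assignment <- function(x, ...) {
  cat(sprintf("%s -> %s\n", x$recomb_id, x$assignment))
  invisible(x)
}
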