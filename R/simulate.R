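## Mosaic-sequence simulator with full ground truth.
##
## Parental lineages diverge from a random root under a K80-style
## substitution process with among-site rate heterogeneity (a proportion of
## invariant sites plus a 4-category discrete gamma), emulating the
## substitution regime estimated for Pokey elements (alpha ~ 0.84, ~63% of
## sites invariant, ~1450 bp). Recombinants are exact splices of donor
## alleles at known breakpoints; every simulated molecule carries a truth
## record (ordered donor segments, chimera flag, isolate) so that all
## downstream detectors can be validated against planted events.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' @param n_parents number of divergent parental lineages.
#' @param L sequence length (bp).
#' @param d target expected pairwise p-distance between parents
#'   (mismatches/site). Branch lengths are calibrated numerically under the
#'   rate-heterogeneity model so realized divergence matches `d`.
#' @param alpha gamma shape for among-site rate heterogeneity.
#' @param p_inv proportion of invariant sites.
#' @param within_group_theta expected pairwise p-distance between alleles of
#'   the same parental lineage.
#' @param alleles_per_parent pool size per lineage.
#' @param kappa transition/transversion rate ratio.
#' @param gc stationary GC content of the root sequence.
#' @param indel_rate expected deletions per sequence per site (emitted as
#'   gap characters; 0 keeps the simulation gap-free).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_parents = 5L, L = 1450L, d = 0.06, alpha = 0.8423,
                       p_inv = 0.633, within_group_theta = 0.01,
                       alleles_per_parent = 3L, kappa = 2, gc = 0.5,
                       indel_rate = 0, seed = 1L) {
  if (L <= 0) te_stop("L must be positive", "config_error")
  if (d < 0 || d >= 0.75) te_stop("d must be in [0, 0.75)", "config_error")
  if (alpha <= 0) te_stop("alpha must be positive", "config_error")
  if (p_inv < 0 || p_inv > 1) te_stop("p_inv must be in [0, 1]", "config_error")
  if (within_group_theta < 0) te_stop("within_group_theta must be >= 0", "config_error")
  structure(list(n_parents = as.integer(n_parents), L = as.integer(L), d = d,
                 alpha = alpha, p_inv = p_inv,
                 within_group_theta = within_group_theta,
                 alleles_per_parent = as.integer(alleles_per_parent),
                 kappa = kappa, gc = gc, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Means of k equal-probability discrete-gamma categories (overall mean 1).
discrete_gamma_rates <- function(alpha, k = 4L) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  k * diff(stats::pgamma(q, shape = alpha + 1, rate = alpha))
}

## K80 substitution: probabilities of (same, transition, each transversion)
## after branch length bl (expected substitutions per site).
k80_probs <- function(bl, kappa) {
  a <- kappa / (kappa + 2)   # transition rate
  b <- 1 / (kappa + 2)       # each transversion rate (x2)
  e1 <- exp(-4 * b * bl)
  e2 <- exp(-2 * (a + b) * bl)
  cbind(same = 0.25 + 0.25 * e1 + 0.5 * e2,
        ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
        tv   = 0.25 - 0.25 * e1)
}

## Calibrate branch scale so expected pairwise mismatch over the rate
## mixture equals the target p-distance. `cats` are the variable-site
## category rates, each with weight (1 - p_inv)/k.
calibrate_path <- function(target, cats, p_inv, kappa) {
  if (target == 0) return(0)
  if (p_inv >= 1) return(0)    # every site invariant: divergence cannot accrue
  mism <- function(path) {
    q <- 1 - k80_probs(cats * path, kappa)[, "same"]
    (1 - p_inv) * mean(q) - target
  }
  max_reach <- (1 - p_inv) * 0.75
  if (target >= max_reach * 0.999)
    te_stop(sprintf("d = %.3f unreachable: at most %.3f of sites can differ under p_inv = %.3f",
                    target, max_reach, p_inv), "config_error")
  stats::uniroot(mism, c(1e-9, 500), tol = 1e-10)$root
}

## Evolve a sequence (integer-coded 1..4) along one branch.
mutate_seq <- function(seq_int, site_rates, bl, kappa) {
  if (bl == 0) return(seq_int)
  d_site <- site_rates * bl
  active <- which(d_site > 0)
  if (!length(active)) return(seq_int)
  pr <- k80_probs(d_site[active], kappa)
  u <- stats::runif(length(active))
  out <- seq_int
  cur <- seq_int[active]
  ts_partner <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)                 # first transversion partner
  tv2 <- c(4L, 3L, 4L, 3L)                 # second transversion partner
  new <- cur
  is_ts <- u >= pr[, "same"] & u < pr[, "same"] + pr[, "ts"]
  is_v1 <- u >= pr[, "same"] + pr[, "ts"] & u < pr[, "same"] + pr[, "ts"] + pr[, "tv"]
  is_v2 <- u >= pr[, "same"] + pr[, "ts"] + pr[, "tv"]
  new[is_ts] <- ts_partner[cur[is_ts]]
  new[is_v1] <- tv1[cur[is_v1]]
  new[is_v2] <- tv2[cur[is_v2]]
  out[active] <- new
  out
}

seq_int_to_char <- function(x) BASES[x]

truth_row <- function(seq_id, idx, donor, start, end, chimera = FALSE,
                      isolate = NA_character_) {
  data.frame(seq_id = seq_id, segment_index = idx, donor = donor,
             start = start, end = end, chimera = chimera, isolate = isolate,
             stringsAsFactors = FALSE)
}

#' Simulate parental allele pools
#'
#' Draws a root sequence, evolves `n_parents` lineages independently down a
#' star topology (or along a user-supplied tree), and generates a small
#' allele pool within each lineage at `within_group_theta`. Per-site rates
#' are invariant with probability `p_inv`, otherwise drawn from a
#' 4-category discrete gamma with shape `alpha`.
#'
#' @param cfg a [sim_config()].
#' @param tree optional `phylo` with `n_parents` tips; branch lengths are
#'   rescaled so the mean tip-tip p-distance matches `cfg$d`. Default is a
#'   star topology.
#' @return list with `alignment` (an [as_aln()] object of all pool alleles),
#'   `truth` (donor-segment data frame), `parents` (parent id -> allele ids),
#'   `site_rates`, and `cfg`.
#' @export
simulate_parent_pools <- function(cfg, tree = NULL) {
  set.seed(cfg$seed)
  L <- cfg$L
  cats <- discrete_gamma_rates(cfg$alpha)
  root <- sample.int(4L, L, replace = TRUE,
                     prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2))
  site_rates <- ifelse(stats::runif(L) < cfg$p_inv, 0,
                       cats[sample.int(4L, L, replace = TRUE)])
  path_between <- calibrate_path(cfg$d, cats, cfg$p_inv, cfg$kappa)
  path_within <- calibrate_path(cfg$within_group_theta, cats, cfg$p_inv, cfg$kappa)
  parent_ids <- paste0("P", seq_len(cfg$n_parents))

  parent_base <- vector("list", cfg$n_parents)
  names(parent_base) <- parent_ids
  if (is.null(tree)) {
    for (p in parent_ids)
      parent_base[[p]] <- mutate_seq(root, site_rates, path_between / 2, cfg$kappa)
  } else {
    if (length(tree$tip.label) != cfg$n_parents)
      te_stop("tree must have n_parents tips", "config_error")
    mean_path <- mean(ape::cophenetic.phylo(tree)[lower.tri(diag(cfg$n_parents))])
    scale <- path_between / mean_path
    nodes <- vector("list", max(tree$edge))
    nodes[[length(tree$tip.label) + 1L]] <- root
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      from <- ord$edge[k, 1L]; to <- ord$edge[k, 2L]
      nodes[[to]] <- mutate_seq(nodes[[from]], site_rates,
                                ord$edge.length[k] * scale, cfg$kappa)
    }
    for (i in seq_along(tree$tip.label))
      parent_base[[i]] <- nodes[[i]]
    names(parent_base) <- parent_ids
  }

  seqs <- list(); truth <- list(); parents <- list()
  for (p in parent_ids) {
    ids <- paste0(p, "_a", seq_len(cfg$alleles_per_parent))
    parents[[p]] <- ids
    for (j in seq_along(ids)) {
      s <- mutate_seq(parent_base[[p]], site_rates, path_within / 2, cfg$kappa)
      seqs[[ids[j]]] <- seq_int_to_char(s)
      truth[[ids[j]]] <- truth_row(ids[j], 1L, p, 1L, L)
    }
  }
  m <- do.call(rbind, seqs)
  rownames(m) <- names(seqs)
  if (cfg$indel_rate > 0) m <- apply_indels(m, cfg$indel_rate)
  list(alignment = as_aln(m), truth = do.call(rbind, truth),
       parents = parents, site_rates = site_rates, cfg = cfg)
}

## Random short deletions, emitted as gap characters (columns preserved, so
## the output is still a true alignment).
apply_indels <- function(m, rate) {
  L <- ncol(m)
  for (i in seq_len(nrow(m))) {
    n_del <- stats::rpois(1L, rate * L)
    if (n_del == 0L) next
    for (k in seq_len(n_del)) {
      len <- sample.int(3L, 1L)
      at <- sample.int(L - len + 1L, 1L)
      m[i, at:(at + len - 1L)] <- "-"
    }
  }
  m
}

## Resolve a donor label to a concrete allele id and its truth segments.
## `registry` maps allele id -> list(residues, segments).
resolve_donor <- function(donor, registry, parents) {
  if (donor %in% names(registry)) return(donor)
  if (donor %in% names(parents)) {
    ids <- parents[[donor]]
    return(ids[sample.int(length(ids), 1L)])
  }
  te_stop(paste0("unknown donor: ", donor), "input_error")
}

## Compose truth segments for a splice: take `donor_segments` clipped to
## [start, end]. Nested recombinants therefore propagate their own mosaic
## structure into the child record.
clip_segments <- function(segments, start, end) {
  keep <- segments$end >= start & segments$start <= end
  seg <- segments[keep, , drop = FALSE]
  seg$start <- pmax(seg$start, start)
  seg$end <- pmin(seg$end, end)
  seg
}

merge_adjacent_segments <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  out <- seg[1L, , drop = FALSE]
  for (k in 2L:nrow(seg)) {
    last <- nrow(out)
    if (seg$donor[k] == out$donor[last] && seg$start[k] == out$end[last] + 1L) {
      out$end[last] <- seg$end[k]
    } else {
      out <- rbind(out, seg[k, , drop = FALSE])
    }
  }
  out
}

#' Splice mosaic recombinants from donor alleles
#'
#' Each event is an exact splice of two donor alleles at the given strictly
#' increasing breakpoints (donors alternate across segments: a, b, a, ...).
#' Donors may be parent ids (a pool allele is drawn at random), allele ids,
#' or ids of previously created recombinants, in which case the truth
#' record composes the donor's own segments (recombinants of recombinants).
#'
#' @param pools result of [simulate_parent_pools()] (or a compatible list
#'   with `alignment`, `truth`, `parents`, `site_rates`, `cfg`).
#' @param events list of events, each `list(a =, b =, breakpoints =)`;
#'   breakpoints are the last positions of the left segments, strictly
#'   inside `(1, L)`.
#' @param n_copies identical copies generated per event.
#' @param seed RNG seed (donor draws, post-event mutation).
#' @param post_rate optional branch length for re-mutating each recombinant
#'   after splicing (0 = clean splice, the default).
#' @return list with `alignment` (recombinants only), `truth`, and
#'   `combined` (pool + recombinant alignment and truth).
#' @export
simulate_recombinants <- function(pools, events, n_copies = 1L, seed = 1L,
                                  post_rate = 0) {
  set.seed(as.integer(seed))
  L <- pools$cfg$L
  base <- aln_strings(pools$alignment)
  registry <- lapply(names(base), function(id) {
    list(residues = strsplit(base[[id]], "")[[1L]],
         segments = pools$truth[pools$truth$seq_id == id,
                                c("donor", "start", "end"), drop = FALSE])
  })
  names(registry) <- names(base)

  out_seqs <- list(); out_truth <- list()
  for (e_idx in seq_along(events)) {
    ev <- events[[e_idx]]
    bps <- sort(as.integer(ev$breakpoints))
    if (length(bps) && (any(bps <= 1L) || any(bps >= L)))
      te_stop("breakpoint outside (1, L)", "input_error")
    if (length(bps) > 1L && any(diff(bps) == 0L))
      te_stop("breakpoints must be strictly increasing", "input_error")
    for (cp in seq_len(n_copies)) {
      a_id <- resolve_donor(ev$a, registry, pools$parents)
      b_id <- resolve_donor(ev$b, registry, pools$parents)
      bounds <- c(0L, bps, L)
      res <- character(L); segs <- NULL
      for (s in seq_len(length(bounds) - 1L)) {
        from <- bounds[s] + 1L; to <- bounds[s + 1L]
        donor_id <- if (s %% 2L == 1L) a_id else b_id
        res[from:to] <- registry[[donor_id]]$residues[from:to]
        segs <- rbind(segs, clip_segments(registry[[donor_id]]$segments, from, to))
      }
      segs <- merge_adjacent_segments(segs)
      rid <- if (n_copies == 1L) paste0("R", e_idx) else paste0("R", e_idx, "_c", cp)
      if (post_rate > 0) {
        ri <- match(res, BASES)
        res <- seq_int_to_char(mutate_seq(ri, pools$site_rates, post_rate,
                                          pools$cfg$kappa))
      }
      registry[[rid]] <- list(residues = res, segments = segs)
      out_seqs[[rid]] <- res
      out_truth[[rid]] <- truth_row(rid, seq_len(nrow(segs)), segs$donor,
                                    segs$start, segs$end)
    }
  }
  if (length(out_seqs) == 0L) {
    return(list(alignment = NULL, truth = pools$truth[0, ],
                combined = list(alignment = pools$alignment, truth = pools$truth)))
  }
  m <- do.call(rbind, out_seqs)
  rownames(m) <- names(out_seqs)
  rec_aln <- as_aln(m)
  comb <- as_aln(rbind(pools$alignment$seqs, m))
  truth <- do.call(rbind, out_truth)
  rownames(truth) <- NULL
  list(alignment = rec_aln, truth = truth,
       combined = list(alignment = comb,
                       truth = rbind(pools$truth, truth)))
}

#' Inject PCR-chimera artifacts
#'
#' Emulates template switching during amplification: each molecule is,
#' independently with probability `rate`, replaced by a single-crossover
#' splice of two distinct randomly chosen templates at a uniform random
#' position. Chimeric molecules are flagged in the truth record; unlike
#' planted recombination events, chimera crossovers are uniform over the
#' sequence.
#'
#' @param aln template alignment (an `aln`).
#' @param rate per-molecule chimera probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param truth optional truth data frame for the templates; chimera truth
#'   composes donor segments through it.
#' @return list with `alignment` and `truth` (every row flagged
#'   `chimera = TRUE` for chimeric molecules).
#' @export
inject_pcr_chimeras <- function(aln, rate, seed = 1L, truth = NULL) {
  if (rate < 0 || rate > 1) te_stop("rate must be in [0, 1]", "input_error")
  set.seed(as.integer(seed))
  m <- aln$seqs
  orig <- aln$seqs                       # templates are the input molecules
  n <- nrow(m); L <- ncol(m)
  if (rate > 0 && nrow(unique(m)) < 2L)
    te_stop("need >= 2 distinct template sequences", "input_error")
  if (is.null(truth)) {
    truth <- do.call(rbind, lapply(rownames(m), function(id)
      truth_row(id, 1L, id, 1L, L)))
  }
  out_truth <- list()
  for (i in seq_len(n)) {
    id <- rownames(m)[i]
    if (rate > 0 && stats::runif(1) < rate) {
      pair <- sample.int(n, 2L)
      x <- pair[1L]; y <- pair[2L]
      bp <- sample(seq_len(L - 1L), 1L)
      newseq <- c(orig[x, 1:bp], orig[y, (bp + 1L):L])
      segs <- rbind(
        clip_segments(truth[truth$seq_id == rownames(orig)[x],
                            c("donor", "start", "end")], 1L, bp),
        clip_segments(truth[truth$seq_id == rownames(orig)[y],
                            c("donor", "start", "end")], bp + 1L, L))
      segs <- merge_adjacent_segments(segs)
      m[i, ] <- newseq
      out_truth[[id]] <- truth_row(id, seq_len(nrow(segs)), segs$donor,
                                   segs$start, segs$end, chimera = TRUE)
    } else {
      tr <- truth[truth$seq_id == id, , drop = FALSE]
      tr$chimera <- FALSE
      out_truth[[id]] <- tr
    }
  }
  tt <- do.call(rbind, out_truth)
  rownames(tt) <- NULL
  list(alignment = as_aln(m), truth = tt)
}

#' Sample per-isolate clone sets
#'
#' Each isolate holds a few distinct underlying alleles; clones are drawn
#' from them with replacement, emulating the cloning depth of a plasmid
#' screen (10-12 clones picked per isolate). Under-sampling of rare alleles
#' is therefore expected, as in a real screen.
#'
#' @param aln alignment of available alleles.
#' @param n_isolates number of isolates.
#' @param alleles_per_isolate scalar or range (e.g. `1:5`): distinct alleles
#'   held by each isolate (sampled uniformly from the range).
#' @param clones_per_isolate clones sequenced per isolate (>= 1).
#' @param seed RNG seed.
#' @return list with `clones` (data frame: isolate, clone_id, allele) and
#'   `alignment` (clone alignment, ids `<isolate>_<n>`).
#' @export
sample_isolates <- function(aln, n_isolates, alleles_per_isolate = 1:5,
                            clones_per_isolate = 11L, seed = 1L) {
  if (clones_per_isolate < 1L) te_stop("clones_per_isolate must be >= 1", "config_error")
  ids <- aln_ids(aln)
  if (max(alleles_per_isolate) > length(ids))
    te_stop("alleles_per_isolate exceeds available distinct alleles", "config_error")
  set.seed(as.integer(seed))
  rows <- list(); seqs <- list()
  for (k in seq_len(n_isolates)) {
    iso <- sprintf("I%02d", k)
    n_all <- if (length(alleles_per_isolate) == 1L) alleles_per_isolate
             else sample(alleles_per_isolate, 1L)
    held <- sample(ids, n_all)
    drawn <- sample(held, clones_per_isolate, replace = TRUE)
    clone_ids <- paste0(iso, "_", seq_len(clones_per_isolate))
    rows[[k]] <- data.frame(isolate = iso, clone_id = clone_ids,
                            allele = drawn, stringsAsFactors = FALSE)
    for (j in seq_along(clone_ids)) seqs[[clone_ids[j]]] <- aln$seqs[drawn[j], ]
  }
  m <- do.call(rbind, seqs)
  rownames(m) <- names(seqs)
  list(clones = do.call(rbind, rows), alignment = as_aln(m))
}

#' Default mosaic study scenario
#'
#' Generates parental pools plus `n_recombinants` single- (or multi-)
#' breakpoint mosaics between randomly chosen distinct parents, with
#' breakpoints planted uniformly in `breakpoint_range`. The default range
#' (bp 600-850) reflects where inter-allelic exchange concentrates in the
#' element (mid-transposase), keeping planted junctions well inside the
#' scannable region.
#'
#' @param cfg a [sim_config()].
#' @param n_recombinants number of mosaics.
#' @param n_breakpoints breakpoints per mosaic.
#' @param breakpoint_range inclusive bp range for planted breakpoints.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list with `alignment` (pools + mosaics), `truth`, `groups`
#'   (sequence id -> parent label, recombinants mapped to their own id),
#'   `planted` (data frame: seq_id, breakpoint, parent_a, parent_b) and
#'   `pools`.
#' @export
simulate_mosaic_scenario <- function(cfg = sim_config(), n_recombinants = 10L,
                                     n_breakpoints = 1L,
                                     breakpoint_range = NULL,
                                     seed = cfg$seed) {
  if (is.null(breakpoint_range))
    breakpoint_range <- round(c(0.41, 0.59) * cfg$L)   # bp 595-855 at L = 1450
  pools <- simulate_parent_pools(cfg)
  set.seed(as.integer(seed) + 1L)
  events <- vector("list", n_recombinants)
  planted <- NULL
  for (k in seq_len(n_recombinants)) {
    pr <- sample(names(pools$parents), 2L)
    bps <- sort(sample(seq(breakpoint_range[1L], breakpoint_range[2L]),
                       n_breakpoints))
    events[[k]] <- list(a = pr[1L], b = pr[2L], breakpoints = bps)
    planted <- rbind(planted, data.frame(seq_id = paste0("R", k),
                                         breakpoint = bps,
                                         parent_a = pr[1L], parent_b = pr[2L],
                                         stringsAsFactors = FALSE))
  }
  rec <- simulate_recombinants(pools, events, seed = as.integer(seed) + 2L)
  ids <- aln_ids(rec$combined$alignment)
  ## recombinants carry no group identity of their own
  groups <- ifelse(grepl("^P", ids), sub("_a\\d+$", "", ids), "ungrouped")
  names(groups) <- ids
  list(alignment = rec$combined$alignment, truth = rec$combined$truth,
       groups = groups, planted = planted, pools = pools)
}

#' Write a simulation truth table as TSV
#' @param truth truth data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
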