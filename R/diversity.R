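## Nucleotide diversity and similarity statistics, globally and per
## partition, plus the arithmetic combination of coalescent estimates into
## a population recombination rate.

## internal: pairwise difference count matrix (complete-deletion on the
## columns given; pairwise deletion handled by the caller).
pairwise_diff_counts <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

## internal: columns usable for statistics under complete deletion
clean_cols <- function(aln) {
  ok <- apply(aln$seqs, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  aln$seqs[, ok, drop = FALSE]
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences per site,
#' `pi = 2 / (n (n - 1)) * sum_{i<j} d_ij / L`, computed on columns free of
#' gaps and ambiguity codes (complete deletion) or, optionally, per pair on
#' the columns where both members are unambiguous (pairwise deletion).
#'
#' @param aln an `aln` with `n >= 2` sequences.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- n_seq(aln)
  if (n < 2L) te_stop("need at least 2 sequences", "input_error")
  if (deletion == "complete") {
    m <- clean_cols(aln)
    if (ncol(m) == 0L) te_stop("no analyzable sites", "undefined_error")
    d <- pairwise_diff_counts(m)
    return(sum(d[upper.tri(d)]) / choose(n, 2) / ncol(m))
  }
  acc <- 0; np <- 0L
  good <- aln$seqs %in% c("A", "C", "G", "T")
  dim(good) <- dim(aln$seqs)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      both <- good[i, ] & good[j, ]
      if (!any(both)) te_stop("no analyzable sites for a pair", "undefined_error")
      acc <- acc + sum(aln$seqs[i, both] != aln$seqs[j, both]) / sum(both)
      np <- np + 1L
    }
  acc / np
}

#' Watterson's theta
#'
#' `theta_w = S / (a_{n-1} * L)` with `a_{n-1} = sum_{k=1}^{n-1} 1/k`,
#' where `S` is the number of segregating sites among gap/ambiguity-free
#' columns.
#'
#' @param aln an `aln` with `n >= 2` sequences.
#' @return Watterson's estimator per site.
#' @export
watterson_theta <- function(aln) {
  n <- n_seq(aln)
  if (n < 2L) te_stop("need at least 2 sequences", "input_error")
  m <- clean_cols(aln)
  if (ncol(m) == 0L) te_stop("no analyzable sites", "undefined_error")
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  a <- sum(1 / seq_len(n - 1L))
  S / (a * ncol(m))
}

#' Segregating sites
#' @param aln an `aln` object.
#' @return count of segregating gap/ambiguity-free columns.
#' @export
segregating_sites <- function(aln) {
  m <- clean_cols(aln)
  if (ncol(m) == 0L) return(0L)
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

#' Mean pairwise similarity (%)
#' @param aln an `aln` object.
#' @return `100 * (1 - mean pairwise p-distance)`.
#' @export
mean_similarity <- function(aln) {
  m <- clean_cols(aln)
  if (ncol(m) == 0L) te_stop("no analyzable sites", "undefined_error")
  d <- pairwise_diff_counts(m) / ncol(m)
  100 * (1 - mean(d[upper.tri(d)]))
}

#' Per-partition diversity summaries
#'
#' One summary per region, plus `coding` / `noncoding` aggregates (regions
#' with / without a reading frame), laid out like a per-partition diversity
#' table: n, analyzed sites, segregating sites, pi, Watterson's theta, and
#' mean pairwise similarity. Regions left empty after stripping are skipped
#' with a warning.
#'
#' @param aln an `aln` object.
#' @param part a `partition_map`.
#' @return data frame of class `diversity_summary`.
#' @export
partition_diversity <- function(aln, part) {
  summarise_region <- function(sub, name) {
    m <- clean_cols(sub)
    data.frame(region = name, n = n_seq(sub), L_used = ncol(m),
               S = segregating_sites(sub),
               pi = nucleotide_diversity(sub),
               theta_w = watterson_theta(sub),
               mean_similarity = mean_similarity(sub),
               stringsAsFactors = FALSE)
  }
  out <- list()
  coding_regions <- unique(part$region[!is.na(part$frame)])
  groups <- list(coding = coding_regions,
                 noncoding = setdiff(unique(part$region), coding_regions))
  for (agg in names(groups)) {
    regs <- groups[[agg]]
    if (!length(regs)) next
    src <- unlist(lapply(regs, region_source_cols, part = part))
    keep <- aln$column_map %in% src
    if (any(keep)) {
      sub <- as_aln(aln$seqs[, keep, drop = FALSE], aln$column_map[keep])
      out[[agg]] <- summarise_region(sub, agg)
    }
    for (rg in regs) {
      sub <- tryCatch(extract_partition(aln, part, rg), error = function(e) NULL)
      if (is.null(sub) || ncol(clean_cols(sub)) == 0L) {
        warning("region ", rg, " empty after stripping; skipped")
        next
      }
      out[[rg]] <- summarise_region(sub, rg)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("diversity_summary", "data.frame")
  res
}

#' @export
print.diversity_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$pi <- round(y$pi, 3)
  y$theta_w <- round(y$theta_w, 3)
  y$mean_similarity <- round(y$mean_similarity, 1)
  print(y)
  invisible(x)
}

#' Population recombination rate 4Nec
#'
#' Combines a coalescent diversity estimate `theta_lam = 4 Ne mu` with a
#' relative recombination rate `r_lam = c / mu` into the population
#' recombination rate `R = theta_lam * r_lam = 4 Ne c`, in recombination
#' events per site per generation.
#'
#' @param theta_lam coalescent estimate of 4 Ne mu (>= 0).
#' @param r_lam coalescent estimate of c / mu (>= 0).
#' @return list of class `rate_estimates` with `theta_lam`, `r_lam`, `R`
#'   and a display value rounded to 3 significant figures.
#' @export
recombination_rate <- function(theta_lam, r_lam) {
  if (theta_lam < 0 || r_lam < 0) te_stop("rates must be non-negative", "input_error")
  R <- theta_lam * r_lam
  structure(list(theta_lam = theta_lam, r_lam = r_lam, R = R,
                 R_display = signif(R, 3),
                 interpretation = "4Nec per site per generation"),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("R = theta_LAM x r_LAM = %.3g x %.3g = %.3g (%s)\n",
              x$theta_lam, x$r_lam, x$R_display, x$interpretation))
  invisible(x)
}

#' Write a diversity summary as TSV
#' @param summary a `diversity_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
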