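## In-silico PCR-RFLP haplotyping.
##
## The screen amplifies the element's 3' end into the flanking 28S rDNA
## (an ~1600 bp product) and digests it with three enzymes whose
## recognition sites sit at diagnostic positions (~380, ~790, ~1080 bp).
## Presence/absence of the three cuts gives a 3-bit code rendered 1-8; a
## recombinant allele shows the left-of-crossover bits of one parent and
## the right-of-crossover bits of the other, which is what makes a cheap
## gel screen sensitive to mosaic alleles.

#' Primer definition
#' @param name primer name.
#' @param sequence 5'->3' IUPAC sequence.
#' @param max_mismatch mismatches tolerated (the 3'-terminal 5 bases must
#'   always match exactly).
#' @return a `primer` list.
#' @export
primer <- function(name, sequence, max_mismatch = 0L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGTRYSWKMBDHVN]", sequence))
    te_stop("primer must be non-empty IUPAC DNA", "input_error")
  if (max_mismatch < 0L) te_stop("max_mismatch must be >= 0", "input_error")
  structure(list(name = name, sequence = sequence,
                 max_mismatch = as.integer(max_mismatch)), class = "primer")
}

#' Restriction enzyme definition
#' @param name enzyme name.
#' @param pattern IUPAC recognition pattern (length >= 4), e.g. `"GGTNACC"`.
#' @param cut_offset cut position within the pattern (cut after this many
#'   bases, 0 = before the first).
#' @return an `enzyme` list.
#' @export
enzyme <- function(name, pattern, cut_offset) {
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4L) te_stop("pattern length must be >= 4", "input_error")
  if (cut_offset < 0L || cut_offset > nchar(pattern))
    te_stop("cut offset outside pattern", "input_error")
  structure(list(name = name, pattern = pattern,
                 cut_offset = as.integer(cut_offset)), class = "enzyme")
}

#' Default primer pair and enzyme panel
#'
#' The forward primer sits in the element's transposase region and the
#' reverse primer in the 28S rDNA 46 bp downstream of the TTAA target
#' site. The panel is DraI (TTT^AAA), BspHI (T^CATGA) and BstEII
#' (G^GTNACC) — all palindromic, so a single-strand scan finds every site.
#'
#' @return named list of [primer()] / [enzyme()] objects.
#' @export
default_primers <- function() list(
  fwd = primer("Pok5026F", "TCGAACCTGCAGCCGGACGAATTTGCAG"),
  rev = primer("28SR", "TCCATTCGTGCGCGTCACTAATTAGATGAC"))

#' @rdname default_primers
#' @export
default_enzymes <- function() list(
  DraI = enzyme("DraI", "TTTAAA", 3L),
  BspHI = enzyme("BspHI", "TCATGA", 1L),
  BstEII = enzyme("BstEII", "GGTNACC", 1L))

## internal: IUPAC-aware pattern match starts (1-based) with mismatches
iupac_match_starts <- function(pattern, subject, max_mismatch = 0L) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   max.mismatch = max_mismatch, fixed = FALSE)
  Biostrings::start(hits)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## internal: 3'-anchored primer matching. Returns start positions on the
## plus strand of the primer as written.
primer_match_starts <- function(p, template) {
  starts <- iupac_match_starts(p$sequence, template, p$max_mismatch)
  if (p$max_mismatch > 0L && length(starts)) {
    plen <- nchar(p$sequence)
    tail_pat <- substring(p$sequence, plen - 4L, plen)
    ok <- vapply(starts, function(s) {
      tail_sub <- substring(template, s + plen - 5L, s + plen - 1L)
      length(iupac_match_starts(tail_pat, tail_sub, 0L)) > 0L
    }, logical(1))
    starts <- starts[ok]
  }
  starts
}

#' In-silico PCR
#'
#' Finds forward-primer matches and reverse-complemented reverse-primer
#' matches on the template and returns every compatible pairing within the
#' size window. The amplicon spans from the first base of the forward
#' match to the last base of the reverse match, inclusive.
#'
#' @param template nucleotide string (or single-sequence `aln`).
#' @param fwd,rev [primer()] objects (default [default_primers()]).
#' @param size_range allowed amplicon lengths.
#' @return data frame of class `amplicons`: `start`, `end`, `length`,
#'   `sequence`. Zero rows when no pairing is found (not an error).
#' @export
in_silico_pcr <- function(template, fwd = default_primers()$fwd,
                          rev = default_primers()$rev,
                          size_range = c(300L, 5000L)) {
  if (inherits(template, "aln")) template <- aln_strings(template)[[1L]]
  template <- toupper(gsub("-", "", template))
  if (nchar(template) < nchar(fwd$sequence) + nchar(rev$sequence))
    te_stop("template shorter than combined primer length", "input_error")
  f_starts <- primer_match_starts(fwd, template)
  rc <- revcomp(rev$sequence)
  ## match the reverse primer as its reverse complement on the plus strand;
  ## its 3' end is the *first* base of the match, so anchor there.
  r_starts <- iupac_match_starts(rc, template, rev$max_mismatch)
  if (rev$max_mismatch > 0L && length(r_starts)) {
    head_pat <- substring(rc, 1L, 5L)
    ok <- vapply(r_starts, function(s) {
      length(iupac_match_starts(head_pat, substring(template, s, s + 4L), 0L)) > 0L
    }, logical(1))
    r_starts <- r_starts[ok]
  }
  r_ends <- r_starts + nchar(rc) - 1L
  out <- NULL
  for (fs in f_starts)
    for (re in r_ends) {
      len <- re - fs + 1L
      if (len >= size_range[1L] && len <= size_range[2L])
        out <- rbind(out, data.frame(start = fs, end = re, length = len,
                                     sequence = substring(template, fs, re),
                                     stringsAsFactors = FALSE))
    }
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(), length = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  class(out) <- c("amplicons", "data.frame")
  out
}

#' Digest an amplicon with a restriction enzyme panel
#'
#' All degenerate-pattern matches produce cuts at pattern start +
#' `cut_offset`; fragments are the spans between consecutive cuts. Total
#' fragment length always equals the amplicon length, and the result does
#' not depend on enzyme order.
#'
#' @param amplicon nucleotide string.
#' @param enzymes list of [enzyme()] objects (default [default_enzymes()]).
#' @return list of class `digest_profile`: `length`, `cuts` (named list of
#'   cut positions per enzyme: the last base of the left fragment),
#'   `fragments` (sorted lengths).
#' @export
digest <- function(amplicon, enzymes = default_enzymes()) {
  amplicon <- toupper(gsub("-", "", amplicon))
  L <- nchar(amplicon)
  cuts <- lapply(enzymes, function(e) {
    starts <- iupac_match_starts(e$pattern, amplicon, 0L)
    pos <- starts + e$cut_offset - 1L
    pos[pos >= 1L & pos < L]            # cuts strictly inside
  })
  names(cuts) <- vapply(enzymes, `[[`, "", "name")
  all_cuts <- sort(unique(unlist(cuts)))
  bounds <- c(0L, all_cuts, L)
  fragments <- sort(diff(bounds))
  structure(list(length = L, cuts = cuts, fragments = fragments),
            class = "digest_profile")
}

#' Default diagnostic windows
#'
#' +/- `slack` bp around the three diagnostic cut positions (380, 790,
#' 1080 bp from the amplicon start), one window per panel enzyme.
#'
#' @param slack half-width in bp.
#' @return list of 3 integer intervals.
#' @export
diagnostic_windows <- function(slack = 25L) list(
  DraI = c(380L - slack, 380L + slack),
  BspHI = c(790L - slack, 790L + slack),
  BstEII = c(1080L - slack, 1080L + slack))

#' RFLP haplotype code from a digest profile
#'
#' Bit k is set iff enzyme k cuts inside diagnostic window k; the code is
#' `1 + sum(bit_k * 2^(k-1))`, giving the 8 possible conformations 1-8
#' (1 = no diagnostic cut, 8 = all three). Cuts outside every window are
#' ignored for coding (they still shape the gel pattern).
#'
#' @param profile a `digest_profile`.
#' @param windows list of 3 intervals (default [diagnostic_windows()]),
#'   in the same enzyme order as the profile's cut list.
#' @return list of class `rflp_haplotype`: `code` (1-8), `bits` (named
#'   logical), `fragments`.
#' @export
haplotype_code <- function(profile, windows = diagnostic_windows()) {
  if (length(windows) != 3L) te_stop("need exactly 3 diagnostic windows", "input_error")
  iv <- do.call(rbind, windows)
  if (any(iv[, 1L] > iv[, 2L]) || any(iv[, 2L] > profile$length))
    te_stop("diagnostic windows must lie within the amplicon", "input_error")
  ord <- order(iv[, 1L])
  if (any(iv[ord[-3L], 2L] >= iv[ord[-1L], 1L]))
    te_stop("diagnostic windows must not overlap", "input_error")
  enzymes <- names(windows)
  bits <- vapply(seq_len(3L), function(k) {
    cuts <- profile$cuts[[enzymes[k]]]
    any(cuts >= windows[[k]][1L] & cuts <= windows[[k]][2L])
  }, logical(1))
  names(bits) <- enzymes
  structure(list(code = as.integer(1L + sum(bits * 2L^(seq_len(3L) - 1L))),
                 bits = bits, fragments = profile$fragments),
            class = "rflp_haplotype")
}

#' Gel band pattern with co-migration
#'
#' Fragments within `co_migration_bp` of each other collapse into one band
#' (single linkage), modelling the resolution of a 3% agarose gel. Bands
#' are reported largest first.
#'
#' @param fragments fragment lengths (bp).
#' @param co_migration_bp co-migration threshold.
#' @return numeric vector of band positions (mean length of each band's
#'   fragments), sorted descending.
#' @export
gel_pattern <- function(fragments, co_migration_bp = 40) {
  if (!length(fragments)) te_stop("no fragments", "input_error")
  f <- sort(fragments)
  grp <- cumsum(c(1, diff(f) > co_migration_bp))
  sort(vapply(split(f, grp), mean, numeric(1)), decreasing = TRUE)
}

#' Are two band patterns distinguishable on the gel?
#' @param p1,p2 band patterns from [gel_pattern()].
#' @param co_migration_bp threshold under which bands co-migrate.
#' @return `TRUE` when the patterns differ (different band count, or any
#'   band shifted by more than the threshold).
#' @export
gel_distinguishable <- function(p1, p2, co_migration_bp = 40) {
  if (length(p1) != length(p2)) return(TRUE)
  any(abs(p1 - p2) > co_migration_bp)
}

#' Per-isolate haplotype summary
#'
#' @param haplotypes_by_isolate named list: isolate -> vector of haplotype
#'   codes observed among its clones.
#' @return list of class `isolate_summary`: `per_isolate` (data frame:
#'   isolate, n_haplotypes), `mean`, `sd` (sample SD), `max`, and
#'   `frequency` (per haplotype, percentage of isolates carrying it).
#' @export
isolate_summary <- function(haplotypes_by_isolate) {
  if (!length(haplotypes_by_isolate)) te_stop("no isolates", "input_error")
  counts <- vapply(haplotypes_by_isolate, function(h) {
    if (!length(h)) { warning("empty isolate counted as 0"); 0L }
    else length(unique(h))
  }, integer(1))
  all_haps <- sort(unique(unlist(haplotypes_by_isolate)))
  freq <- vapply(all_haps, function(hp)
    100 * mean(vapply(haplotypes_by_isolate, function(h) hp %in% h, logical(1))),
    numeric(1))
  structure(list(
    per_isolate = data.frame(isolate = names(counts), n_haplotypes = counts,
                             row.names = NULL, stringsAsFactors = FALSE),
    mean = mean(counts),
    sd = stats::sd(counts),
    max = max(counts),
    frequency = data.frame(haplotype = all_haps, pct_isolates = unname(freq))),
    class = "isolate_summary")
}

#' @export
print.isolate_summary <- function(x, ...) {
  cat(sprintf("%d isolates: %.2f +/- %.2f distinct haplotypes (max %d)\n",
              nrow(x$per_isolate), x$mean, x$sd, x$max))
  invisible(x)
}

#' Synthetic RFLP template set
#'
#' Builds a deterministic ~1600 bp amplicon free of panel recognition
#' sites, frames it with the default primer pair, and returns the 8
#' variants obtained by planting (or not) each diagnostic site at 380, 790
#' and 1080 bp. Synthetic construction — a stand-in for real amplicons,
#' used to exercise the digest/coding/gel logic.
#'
#' @param amplicon_length amplicon length (bp).
#' @param seed RNG seed for the background sequence.
#' @return list with `templates` (named character vector, names `"code<k>"`),
#'   `amplicons` (amplicon sequence per code), `site_positions`.
#' @export
synth_rflp_templates <- function(amplicon_length = 1600L, seed = 42L) {
  set.seed(as.integer(seed))
  prim <- default_primers()
  enz <- default_enzymes()
  site_pos <- c(DraI = 380L, BspHI = 790L, BstEII = 1080L)
  fwd <- prim$fwd$sequence
  rev_rc <- revcomp(prim$rev$sequence)
  core_len <- amplicon_length - nchar(fwd) - nchar(rev_rc)
  repeat {
    core <- paste0(sample(BASES, core_len, replace = TRUE), collapse = "")
    amp0 <- paste0(fwd, core, rev_rc)
    clean <- !vapply(enz, function(e)
      length(iupac_match_starts(e$pattern, amp0, 0L)) > 0L, logical(1))
    if (all(clean)) break
  }
  plant <- function(amp, enzyme, at) {
    pat <- gsub("N", "A", enzyme$pattern)  # concrete site
    s <- at - enzyme$cut_offset + 1L       # so the cut lands exactly at `at`
    paste0(substring(amp, 1L, s - 1L), pat,
           substring(amp, s + nchar(pat), nchar(amp)))
  }
  amps <- character(8L)
  for (code in 1:8) {
    bits <- as.logical(bitwAnd(code - 1L, 2L^(0:2)))
    amp <- amp0
    for (k in which(bits)) amp <- plant(amp, enz[[k]], site_pos[k])
    amps[code] <- amp
  }
  names(amps) <- paste0("code", 1:8)
  ## 50 bp of flank around the amplicon makes these usable as PCR templates
  set.seed(as.integer(seed) + 1L)
  flank5 <- paste0(sample(BASES, 50L, replace = TRUE), collapse = "")
  flank3 <- paste0(sample(BASES, 50L, replace = TRUE), collapse = "")
  templates <- vapply(amps, function(a) paste0(flank5, a, flank3), character(1))
  list(templates = templates, amplicons = amps, site_positions = site_pos)
}

#' Full RFLP typing of one template
#'
#' PCR with the default primers, digestion with the default panel, and
#' haplotype coding; convenience wrapper used by the pipeline and screens.
#'
#' @param template nucleotide string.
#' @param fwd,rev primers. @param enzymes enzyme panel.
#' @param windows diagnostic windows.
#' @return `rflp_haplotype`, or `NULL` when no amplicon is found.
#' @export
rflp_type <- function(template, fwd = default_primers()$fwd,
                      rev = default_primers()$rev,
                      enzymes = default_enzymes(),
                      windows = diagnostic_windows()) {
  amps <- in_silico_pcr(template, fwd, rev)
  if (nrow(amps) == 0L) return(NULL)
  haplotype_code(digest(amps$sequence[1L], enzymes), windows)
}
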