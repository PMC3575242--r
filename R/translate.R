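## Translation and amino-acid polymorphism tabulation for the transposase
## exons. Elements inserted in rDNA are frequently pseudogenised, so stop
## codons inside coding regions are reported, never treated as errors.

#' Translate a nucleotide string
#'
#' Gaps are removed, `frame` leading bases are skipped, and complete codons
#' are translated with the standard genetic code. Codons containing
#' ambiguity codes translate to `X`; stops are `*`. A trailing incomplete
#' codon is dropped (partial exons are expected).
#'
#' @param x nucleotide string (or character vector of single residues).
#' @param frame 0, 1 or 2 bases to skip before the first complete codon.
#' @return amino-acid string.
#' @export
translate_dna <- function(x, frame = 0L) {
  if (length(x) > 1L) x <- paste0(x, collapse = "")
  x <- toupper(gsub("-", "", x))
  if (frame > 0L) x <- substring(x, frame + 1L)
  n_codon <- nchar(x) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(x, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Amino-acid polymorphism table and frameshift flags
#'
#' For every coding region of the partition map, translates each sequence's
#' ungapped residues and tabulates amino-acid counts per position. A
#' sequence is flagged frameshifted in a region when its ungapped length
#' differs from the modal ungapped length of that region by a non-multiple
#' of 3 (a single indel out of register); frameshifted sequences are
#' excluded from the per-position counts. Because of indels, counts at a
#' position may sum to fewer than the number of sequences.
#'
#' @param aln an `aln` object (typically unstripped, so indels are visible).
#' @param part a `partition_map` with at least one coding region
#'   (non-`NA` frame).
#' @return list with elements `counts` (data frame: region, aa_pos, residue,
#'   count), `frameshift` (data frame: id, region, ungapped_length,
#'   frameshifted), `translations` (per sequence, concatenated coding
#'   translation) and `n_unique_aa` (distinct concatenated translations).
#' @export
aa_polymorphism_table <- function(aln, part) {
  coding <- part[!is.na(part$frame), , drop = FALSE]
  if (nrow(coding) == 0L) te_stop("no coding regions in partition map", "input_error")
  regions <- unique(coding$region)
  counts <- list(); fs <- list()
  trans_concat <- stats::setNames(rep("", n_seq(aln)), aln_ids(aln))
  for (rg in regions) {
    frame <- coding$frame[coding$region == rg][1L]
    sub <- extract_partition(aln, part, rg)
    ung <- vapply(seq_len(n_seq(sub)), function(i)
      sum(sub$seqs[i, ] != "-"), integer(1))
    if (all(ung == 0L))
      te_stop(paste0("region ", rg, " has zero ungapped length everywhere"),
              "input_error")
    lens <- table(ung)
    modal <- as.integer(names(lens)[which.max(lens)])
    shifted <- (ung - modal) %% 3L != 0L
    fs[[rg]] <- data.frame(id = aln_ids(sub), region = rg,
                           ungapped_length = ung, frameshifted = shifted,
                           stringsAsFactors = FALSE)
    aa <- vapply(seq_len(n_seq(sub)), function(i)
      translate_dna(sub$seqs[i, ], frame = frame), character(1))
    trans_concat <- paste0(trans_concat, aa)
    keep <- which(!shifted & nzchar(aa))
    if (length(keep)) {
      aam <- strsplit(aa[keep], "")
      maxlen <- max(lengths(aam))
      for (p in seq_len(maxlen)) {
        res <- vapply(aam, function(v) if (p <= length(v)) v[p] else NA_character_,
                      character(1))
        tab <- table(res[!is.na(res)])
        if (length(tab))
          counts[[length(counts) + 1L]] <- data.frame(
            region = rg, aa_pos = p, residue = names(tab),
            count = as.integer(tab), stringsAsFactors = FALSE)
      }
    }
  }
  list(counts = do.call(rbind, counts),
       frameshift = do.call(rbind, fs),
       translations = trans_concat,
       n_unique_aa = length(unique(trans_concat[nzchar(trans_concat)])))
}

#' Write an amino-acid polymorphism table as TSV
#' @param tab result of [aa_polymorphism_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aa_table <- function(tab, path) {
  utils::write.table(tab$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
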