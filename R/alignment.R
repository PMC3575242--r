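## Core alignment container and column bookkeeping.
##
## An `aln` is a rectangular character matrix (rows = sequences, uppercase
## IUPAC nucleotides plus "-"), with a `column_map` attribute giving, for
## each current column, its 1-based coordinate in the source alignment.
## All breakpoints and partitions are reported in source coordinates so
## that results survive column stripping.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

te_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "temosaic_error", "error", "condition")))
}

#' Construct an alignment object
#'
#' @param seqs character matrix (rows = sequences) or named character vector
#'   of equal-length strings; lowercase is normalised to uppercase.
#' @param column_map integer vector of source coordinates, one per column;
#'   defaults to the identity map.
#' @param taxon_tag optional character vector of free-text species/hybrid
#'   labels, one per sequence.
#' @return an object of class `aln`.
#' @export
as_aln <- function(seqs, column_map = NULL, taxon_tag = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      te_stop("sequences have unequal lengths (not an alignment)", "alignment_error")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  }
  if (!is.matrix(seqs)) te_stop("seqs must be a matrix or character vector", "input_error")
  seqs[] <- toupper(seqs)
  if (is.null(rownames(seqs)))
    rownames(seqs) <- paste0("seq", seq_len(nrow(seqs)))
  ids <- rownames(seqs)
  if (anyDuplicated(ids)) te_stop("duplicate sequence ids", "input_error")
  if (any(!nzchar(ids))) te_stop("empty sequence id", "input_error")
  if (ncol(seqs) == 0L) te_stop("alignment has zero columns", "empty_alignment_error")
  bad <- setdiff(unique(as.vector(seqs)), IUPAC_DNA)
  if (length(bad))
    te_stop(paste0("non-IUPAC characters in alignment: ",
                   paste(bad, collapse = " ")), "input_error")
  if (is.null(column_map)) column_map <- seq_len(ncol(seqs))
  column_map <- as.integer(column_map)
  if (length(column_map) != ncol(seqs) || is.unsorted(column_map, strictly = TRUE))
    te_stop("column_map must be strictly increasing, one entry per column", "input_error")
  structure(list(seqs = seqs, column_map = column_map, taxon_tag = taxon_tag),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns (source span %d..%d)\n",
              nrow(x$seqs), ncol(x$seqs),
              x$column_map[1L], x$column_map[length(x$column_map)]))
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln an `aln` object.
#' @return integer count.
#' @export
n_seq <- function(aln) nrow(aln$seqs)

#' @rdname n_seq
#' @export
n_col <- function(aln) ncol(aln$seqs)

#' Sequence ids of an alignment
#' @param aln an `aln` object.
#' @return character vector.
#' @export
aln_ids <- function(aln) rownames(aln$seqs)

#' Extract sequences as strings
#' @param aln an `aln` object.
#' @return named character vector of residue strings.
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(aln$seqs, 1L, paste0, collapse = ""), rownames(aln$seqs))
}

## internal: DNAbin <-> aln
aln_to_DNAbin <- function(aln) ape::as.DNAbin(aln$seqs)

#' Read a multiple alignment
#'
#' Reads aligned FASTA (default) or sequential PHYLIP. Order is preserved,
#' lowercase is normalised to uppercase, and the returned alignment carries
#' an identity `column_map`.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return an `aln` object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) te_stop(paste0("no such file: ", path), "input_error")
  if (file.size(path) == 0L) te_stop("empty alignment file", "input_error")
  dna <- if (format == "fasta") ape::read.FASTA(path)
         else ape::read.dna(path, format = "sequential")
  if (length(dna) == 0L) te_stop("no sequences in file", "input_error")
  ch <- as.character(dna)            # list for ragged FASTA, matrix for phylip
  if (is.list(ch)) {
    lens <- lengths(ch)
    if (length(unique(lens)) > 1L)
      te_stop("sequences have unequal lengths (not an alignment)", "alignment_error")
    m <- do.call(rbind, ch)
    rownames(m) <- names(ch)
    ch <- m
  }
  as_aln(ch)
}

#' Write an alignment as FASTA
#'
#' @param aln an `aln` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(aln_to_DNAbin(aln), path)
  invisible(path)
}

#' Strip gap and ambiguous columns
#'
#' Removes every column containing a gap and/or an ambiguity code in any
#' sequence, recording surviving source coordinates in `column_map`.
#' With both flags set (the default) every remaining column is pure
#' A/C/G/T, the state assumed by all downstream recombination statistics:
#' indel and ambiguity columns are removed wholesale to avoid spurious
#' recombination signal. The operation is idempotent.
#'
#' @param aln an `aln` object.
#' @param drop_gap_cols drop columns containing `-`.
#' @param drop_ambiguous_cols drop columns containing any non-ACGT code.
#' @return a stripped `aln`.
#' @export
strip_columns <- function(aln, drop_gap_cols = TRUE, drop_ambiguous_cols = TRUE) {
  m <- aln$seqs
  keep <- rep(TRUE, ncol(m))
  if (drop_gap_cols)
    keep <- keep & colSums(m == "-") == 0L
  if (drop_ambiguous_cols) {
    ambig <- matrix(!(m %in% c("A", "C", "G", "T", "-")), nrow(m))
    keep <- keep & colSums(ambig) == 0L
  }
  if (!any(keep)) te_stop("all columns removed by stripping", "empty_alignment_error")
  as_aln(m[, keep, drop = FALSE], column_map = aln$column_map[keep],
         taxon_tag = aln$taxon_tag)
}

## ---- partitions ------------------------------------------------------------

#' Define a partition map
#'
#' A partition map assigns named regions (e.g. `exon1`, `intron`, `exon2`,
#' `ncr3`) to 1-based inclusive intervals in *source* coordinates. Coding
#' regions carry a reading-frame offset (0, 1 or 2 bases to skip before the
#' first complete codon); non-coding regions have `frame = NA`. A region may
#' span several intervals (several rows).
#'
#' @param regions data frame with columns `region`, `start`, `end` and
#'   optionally `frame`.
#' @return a `partition_map` (validated data frame).
#' @export
partition_map <- function(regions) {
  regions <- as.data.frame(regions)
  need <- c("region", "start", "end")
  if (!all(need %in% names(regions)))
    te_stop("partition map needs columns region, start, end", "input_error")
  if (is.null(regions$frame)) regions$frame <- NA_integer_
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$frame <- as.integer(regions$frame)
  if (any(regions$start < 1L) || any(regions$end < regions$start))
    te_stop("invalid partition interval", "input_error")
  class(regions) <- c("partition_map", "data.frame")
  regions
}

#' Read a partition map from TSV
#'
#' Expected columns: `region  start  end  frame` (frame empty or NA for
#' non-coding regions).
#'
#' @param path TSV file path.
#' @return a `partition_map`.
#' @export
read_partition_map <- function(path) {
  partition_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Names of regions in a partition map
#' @param part a `partition_map`.
#' @return character vector of unique region names.
#' @export
partition_regions <- function(part) unique(part$region)

## internal: source coordinates covered by a region
region_source_cols <- function(part, region) {
  rows <- part[part$region == region, , drop = FALSE]
  if (nrow(rows) == 0L)
    te_stop(paste0("unknown region: ", region), "input_error")
  sort(unique(unlist(Map(seq.int, rows$start, rows$end))))
}

#' Extract the surviving columns of a partition region
#'
#' Region coordinates are interpreted in source coordinates and mapped
#' through the alignment's `column_map`, so extraction works identically on
#' raw and stripped alignments.
#'
#' @param aln an `aln` object.
#' @param part a `partition_map`.
#' @param region region name.
#' @return sub-alignment (`aln`) of the region's surviving columns.
#' @export
extract_partition <- function(aln, part, region) {
  src <- region_source_cols(part, region)
  keep <- aln$column_map %in% src
  if (!any(keep))
    te_stop(paste0("region ", region, " has no surviving columns"),
            "empty_alignment_error")
  as_aln(aln$seqs[, keep, drop = FALSE], column_map = aln$column_map[keep],
         taxon_tag = aln$taxon_tag)
}
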