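test_that("FASTA read/write round-trips ids and residues and rejects bad input", {
  a <- aln_from(A1 = "ACGTACGTAC", B1 = "ACGTTCGTAC", C1 = "ACGAACGTAC")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(a, f)
  b <- read_alignment(f)
  expect_identical(aln_ids(b), aln_ids(a))
  expect_identical(aln_strings(b), aln_strings(a))
  expect_identical(b$column_map, 1:10)

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGTACGTAC", ">y", "ACGTACGTA"), ragged)
  expect_error(read_alignment(ragged), class = "alignment_error")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty), class = "input_error")

  expect_error(as_aln(c(x = "ACGT", x = "ACGT")), class = "input_error")
})

test_that("strip_columns removes gap/ambiguous columns, maps coordinates, and is idempotent", {
  m <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  m[2, 3] <- "-"
  m[3, 7] <- "N"
  a <- as_aln(m)
  s <- strip_columns(a)
  expect_equal(n_col(s), 8L)
  expect_equal(s$column_map, c(1L, 2L, 4L, 5L, 6L, 8L, 9L, 10L))
  expect_identical(aln_ids(s), aln_ids(a))
  expect_identical(strip_columns(s), s)

  clean <- aln_from("ACGT", "ACGA")
  expect_identical(strip_columns(clean), clean)

  allgap <- as_aln(matrix("-", 2, 3, dimnames = list(c("a", "b"), NULL)))
  expect_error(strip_columns(allgap), class = "empty_alignment_error")
})

test_that("partition extraction respects source coordinates and loses no kept column", {
  a <- aln_from("ACGTACGTAC", "ACGTTCGTAC")
  part <- partition_map(data.frame(region = c("left", "right"),
                                   start = c(1, 6), end = c(5, 10),
                                   frame = c(0, NA)))
  left <- extract_partition(a, part, "left")
  expect_equal(n_col(left), 5L)
  expect_equal(left$column_map, 1:5)
  expect_error(extract_partition(a, part, "nope"), class = "input_error")

  ## after stripping, region columns map through column_map
  m <- a$seqs; m[1, 2] <- "-"
  s <- strip_columns(as_aln(m))
  left_s <- extract_partition(s, part, "left")
  expect_equal(left_s$column_map, c(1L, 3L, 4L, 5L))

  ## concatenation of regions recovers the full column multiset
  right <- extract_partition(a, part, "right")
  expect_equal(sort(c(left$column_map, right$column_map)), 1:10)

  ## region entirely inside stripped columns errors
  m2 <- a$seqs; m2[1, 6:10] <- "-"
  s2 <- strip_columns(as_aln(m2))
  expect_error(extract_partition(s2, part, "right"),
               class = "empty_alignment_error")
})

test_that("translation matches an independent codon-table oracle on gap-free sequences", {
  skip_if_not_installed("seqinr")
  set.seed(42)
  for (rep in 1:20) {
    len <- 3L * sample(5:40, 1L)
    s <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    mine <- translate_dna(s)
    orac <- paste0(seqinr::translate(strsplit(s, "")[[1L]]), collapse = "")
    expect_identical(mine, orac)
  }
  expect_identical(translate_dna("ATGAAATAA"), "MK*")
})

test_that("aa polymorphism table counts residues and flags frameshifts", {
  part <- partition_map(data.frame(region = "cds", start = 1, end = 9, frame = 0))
  a <- aln_from(s1 = "ATGAAATAA", s2 = "ATGAAATAA")
  tab <- aa_polymorphism_table(a, part)
  expect_false(any(tab$frameshift$frameshifted))
  m <- tab$counts[tab$counts$aa_pos == 1, ]
  expect_equal(m$residue, "M")
  expect_equal(m$count, 2L)
  expect_equal(tab$counts$residue[tab$counts$aa_pos == 3], "*")

  ## one sequence with a 1-bp insertion relative to the others (others
  ## carry the gap): its ungapped length differs by 1 -> frameshifted
  b <- aln_from(s1 = "ATG-AAATAA", s2 = "ATG-AAATAA", s3 = "ATGCAAATAA")
  tb <- aa_polymorphism_table(b, part2 <- partition_map(
    data.frame(region = "cds", start = 1, end = 10, frame = 0)))
  expect_identical(tb$frameshift$frameshifted, c(FALSE, FALSE, TRUE))

  ## deduplication of identical amino-acid strings
  cc <- aln_from(s1 = "ATGAAATAA", s2 = "ATGAAGTAA", s3 = "ATGAAATAA")
  tc <- aa_polymorphism_table(cc, part)
  expect_equal(tc$n_unique_aa, 1L)   # AAA and AAG both encode K
})
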