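test_that("in-silico PCR returns the spanned amplicon or nothing", {
  prim <- default_primers()
  set.seed(1)
  bg <- paste0(sample(c("A", "C", "G", "T"), 1800, replace = TRUE), collapse = "")
  fwd <- prim$fwd$sequence
  rc <- temosaic:::revcomp(prim$rev$sequence)
  ## forward match starting at 101, reverse-complement match ending at 1700
  tmpl <- paste0(substring(bg, 1, 100), fwd,
                 substring(bg, 101 + nchar(fwd), 1700 - nchar(rc)), rc,
                 substring(bg, 1701, 1800))
  amps <- in_silico_pcr(tmpl, prim$fwd, prim$rev)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$start, 101L)
  expect_equal(amps$end, 1700L)
  expect_equal(amps$length, 1600L)

  no_rev <- paste0(substring(bg, 1, 100), fwd, substring(bg, 200, 1600))
  expect_equal(nrow(in_silico_pcr(no_rev, prim$fwd, prim$rev)), 0L)
})

test_that("digestion conserves length, ignores enzyme order, and hits the diagnostic cuts", {
  enz <- default_enzymes()
  set.seed(2)
  plain <- paste0(sample(c("A", "C", "G"), 500, replace = TRUE), collapse = "")
  plain <- gsub("TCATGA|GGT.ACC", "ACATGA", plain)
  d0 <- digest(plain, enz)
  expect_equal(sum(d0$fragments), nchar(plain))

  tpl <- synth_rflp_templates()
  d8 <- digest(tpl$amplicons[["code8"]])
  expect_equal(sort(d8$fragments), sort(c(380, 410, 290, 520)))
  expect_equal(d8$cuts$DraI, 380L)
  expect_equal(d8$cuts$BspHI, 790L)
  expect_equal(d8$cuts$BstEII, 1080L)

  ## enzyme order invariance + conservation on random sequences
  for (s in 1:25) {
    set.seed(100 + s)
    x <- paste0(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
    a <- digest(x, enz)
    b <- digest(x, rev(enz))
    expect_equal(a$fragments, b$fragments)
    expect_equal(sum(a$fragments), 800)
  }
})

test_that("haplotype coding is a bijection over the 8 cut-presence patterns", {
  tpl <- synth_rflp_templates()
  codes <- vapply(tpl$amplicons, function(amp)
    haplotype_code(digest(amp))$code, integer(1))
  expect_setequal(codes, 1:8)
  expect_equal(unname(codes["code1"]), 1L)   # no cuts
  expect_equal(unname(codes["code8"]), 8L)   # all three cut
  ## bits reconstruct the code
  for (amp in tpl$amplicons) {
    h <- haplotype_code(digest(amp))
    expect_equal(h$code, 1L + sum(h$bits * 2L^(0:2)))
  }
})

test_that("gel co-migration collapses close fragments and separates the 8 conformations", {
  expect_equal(length(gel_pattern(c(380, 410), 40)), 1L)
  expect_equal(length(gel_pattern(c(380, 520), 40)), 2L)

  tpl <- synth_rflp_templates()
  pats <- lapply(tpl$amplicons, function(amp) gel_pattern(digest(amp)$fragments))
  for (i in 1:7)
    for (j in (i + 1):8)
      expect_true(gel_distinguishable(pats[[i]], pats[[j]]),
                  info = paste(i, "vs", j))
})

test_that("a chimeric splice carries left bits from one parent and right bits from the other", {
  tpl <- synth_rflp_templates()
  x <- tpl$amplicons[["code2"]]   # DraI site only (bit 1, at 380)
  y <- tpl$amplicons[["code5"]]   # BstEII site only (bit 3, at 1080)
  cross <- 700L
  chim <- paste0(substring(x, 1, cross), substring(y, cross + 1, nchar(y)))
  h <- haplotype_code(digest(chim))
  expect_true(h$bits[["DraI"]])      # left of crossover: from x
  expect_false(h$bits[["BspHI"]])
  expect_true(h$bits[["BstEII"]])    # right of crossover: from y
  expect_equal(h$code, 6L)
})

test_that("isolate summaries compute mean/sd/max and haplotype frequencies", {
  s <- isolate_summary(list(i1 = c(1), i2 = c(1, 2), i3 = c(2, 2, 5)))
  expect_equal(s$mean, 5 / 3)
  expect_equal(s$max, 2L)
  expect_equal(s$frequency$pct_isolates[s$frequency$haplotype == 2], 200 / 3)

  mono <- isolate_summary(list(a = 3, b = 3, c = 3))
  expect_equal(mono$mean, 1)
  expect_equal(mono$sd, 0)

  expect_warning(isolate_summary(list(a = c(1, 2), b = integer())),
                 "empty isolate")
})

test_that("end-to-end typing of clone screens recovers plausible per-isolate counts", {
  tpl <- synth_rflp_templates()
  aln <- as_aln(stats::setNames(tpl$templates, names(tpl$templates)))
  iso <- sample_isolates(aln, n_isolates = 20, alleles_per_isolate = 1:5,
                         clones_per_isolate = 11L, seed = 9)
  codes <- split(
    vapply(iso$clones$allele, function(al)
      rflp_type(tpl$templates[[al]])$code, integer(1)),
    iso$clones$isolate)
  s <- isolate_summary(codes)
  expect_true(s$mean >= 1 && s$mean <= 5)
  expect_lte(s$max, 5L)
})
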