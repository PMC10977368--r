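test_that("amplicon coordinates and lengths follow the primer footprints", {
  set.seed(15)
  fwd <- "GACGTACGATCGATCGGACT"
  rev_site <- "CCATGGATCCAAGGTTCCAA" # genomic site; primer is its revcomp
  template <- paste0(fwd, rseq(80, c("A", "C")), rev_site,
                     rseq(80, c("A", "C")))
  pair <- primer_pair(fwd, reverse_complement(rev_site), "toy")
  prods <- pcr_products(template, pair)
  expect_identical(nrow(prods), 1L)
  expect_identical(prods$fwd_start, 0L)
  expect_identical(prods$rev_end, 120L)
  expect_identical(prods$length, 120L)
})

test_that("nested products are contained in and shorter than outer ones", {
  set.seed(16)
  of <- "GCTAGCTAGGATCCATGCAT"
  if_ <- "TTGACCATGACGTTCAGGTC"
  ir_site <- "CAAGGCCATTGCAGACCTAA"
  or_site <- "GGTCCAATTCGCGGCCATTA"
  template <- paste0(rseq(10, c("A", "C")), of, rseq(20, c("A", "C")), if_,
                     rseq(60, c("A", "C")), ir_site, rseq(15, c("A", "C")),
                     or_site, rseq(10, c("A", "C")))
  outer <- primer_pair(of, reverse_complement(or_site), "outer")
  inner <- primer_pair(if_, reverse_complement(ir_site), "inner")
  prods <- pcr_products(template, outer, inner)
  po <- prods[prods$round == "outer", ]
  pi_ <- prods[prods$round == "inner", ]
  expect_identical(nrow(po), 1L)
  expect_identical(nrow(pi_), 1L)
  expect_lt(pi_$length, po$length)
  expect_gte(pi_$fwd_start, po$fwd_start)
  expect_lte(pi_$rev_end, po$rev_end)
})

test_that("ambiguous primer sites warn and report all products", {
  fwd <- "GATTACAGATTACAGATTAC"
  rev_site <- "CCGGAATTCCGGAAGGCCTT"
  template <- paste0(fwd, strrep("CA", 20), fwd, strrep("AC", 20), rev_site)
  pair <- primer_pair(fwd, reverse_complement(rev_site), "multi")
  expect_warning(prods <- pcr_products(template, pair), "multiple sites")
  expect_identical(nrow(prods), 2L)

  # absent primer site: no products, no warning
  expect_silent(none <- pcr_products(strrep("ACAC", 30), pair))
  expect_identical(nrow(none), 0L)
})

test_that("wild-type minus skipped product size equals the exon length", {
  for (s in c(3L, 4L)) {
    fx <- make_toy_gene(fixture_spec(seed = s))
    wt <- spliced_sequence(fx$transcript, fx$genome)
    sk <- simulate_exon_skip(fx$transcript, 2L, fx$genome)$mrna
    for (round in c("outer", "inner")) {
      pw <- pcr_products(wt, fx$primers[[round]], template_id = "wt")
      ps <- pcr_products(sk, fx$primers[[round]], template_id = "skip")
      expect_identical(pw$length - ps$length,
                       exon_lengths(fx$transcript)[2L])
      expect_identical(pw$length, fx$truth$products[[round]]$wildtype_bp)
      expect_identical(ps$length, fx$truth$products[[round]]$skipped_bp)
    }
  }
})

test_that("primer pairs validate their inputs and read from disk", {
  expect_error(primer_pair("ACGTACGT", "ACGTACGTACGT"), "at least 10")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tforward\treverse",
               "p1\tGATTACAGATTACA\tCCGGAATTCCGGAA"), f)
  pairs <- read_primer_pairs(f)
  expect_identical(names(pairs), "p1")
  expect_identical(pairs$p1$forward, "GATTACAGATTACA")
})

test_that("qPCR ratios normalize against reference genes", {
  expect_equal(qpcr_relative(20, 20), 1)
  expect_equal(qpcr_relative(19, 20), 2)
  # two references: denominator is the geometric mean 2^-21
  expect_equal(qpcr_relative(21, rbind(c(20), c(22))), 1)
  expect_error(qpcr_relative(20, numeric(0)), "reference")
  expect_error(qpcr_relative(20, 20, target_eff = 2.5), "efficienc")

  # scale invariance: a constant Cq shift cancels
  set.seed(18)
  tc <- runif(6, 18, 30)
  rc <- rbind(runif(6, 18, 30), runif(6, 18, 30))
  r1 <- qpcr_relative(tc, rc, calibrator = 1L)
  r2 <- qpcr_relative(tc + 3.7, rc + 3.7, calibrator = 1L)
  expect_equal(r1, r2)
})

test_that("the virtual gel sorts bands by size", {
  prods <- data.frame(template = c("wt", "skip"), primer_pair = "p",
                      round = "inner", fwd_start = 0L,
                      rev_end = c(425L, 240L), length = c(425L, 240L))
  out <- capture.output(gel <- virtual_gel(prods))
  expect_identical(gel$length, c(425L, 240L))
  expect_match(out[2L], "425")
})
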