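test_that("toy genes match their spec exactly and deterministically", {
  spec <- fixture_spec(seed = 2L, exon_lengths = c(160L, 185L, 180L),
                       primers = list(inner = list(wt_size = 400L,
                                                   fwd_tail = 100L),
                                      outer = list(wt_size = 460L,
                                                   fwd_tail = 130L)))
  fx <- make_toy_gene(spec)
  expect_identical(exon_lengths(fx$transcript), c(160L, 185L, 180L))
  expect_identical(classify_exon_frame(exon_lengths(fx$transcript)[2L]),
                   "out_of_frame")
  expect_identical(fx$truth$target_exon_frame, "out_of_frame")

  # byte-identical regeneration under the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_toy_gene(spec, out_dir = d1)
  make_toy_gene(spec, out_dir = d2)
  for (f in c("genome.fa", "gene.gff3", "primers.tsv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
})

test_that("planted hexamers occur in the window and nowhere else", {
  fx <- make_toy_gene(fixture_spec(seed = 19L))
  tw <- fx$truth$ese_window
  reg <- extract_target_region(fx$transcript, 2L, fx$genome)
  hits <- scan_motifs(reg$sequence, hexamer_sets = list(
    hexamer_set("planted", "ESE", tw$hexamer)))
  plant0 <- reg$exon_span[1L] + tw$exon_offset
  inside <- hits$start >= plant0 & hits$start + 6L <= plant0 + tw$width
  expect_gte(sum(inside), tw$copies)
  expect_identical(sum(!inside), 0L)

  # independent exhaustive string search over the whole chromosome
  chrom <- fx$genome[[1L]]
  at <- gregexpr(tw$hexamer, chrom, fixed = TRUE)[[1L]] - 1L
  g0 <- fx$transcript$exon_starts[2L] + tw$exon_offset
  expect_true(all(at >= g0 & at + 6L <= g0 + tw$width))
})

test_that("contradictory primer placements are refused with an explanation", {
  expect_error(
    fixture_spec(seed = 1L,
                 primers = list(inner = list(wt_size = 150L,
                                             fwd_tail = 40L),
                                outer = list(wt_size = 360L,
                                             fwd_tail = 130L))),
    "inside the skipped exon")
  expect_error(fixture_spec(seed = 1L, target_exon = 1L), "internal")
})

test_that("emitted GFF3/FASTA round-trip through the annotation parser", {
  for (strand in c("+", "-")) {
    fx <- make_toy_gene(fixture_spec(seed = 29L, strand = strand))
    d <- withr::local_tempdir()
    make_toy_gene(fixture_spec(seed = 29L, strand = strand), out_dir = d)
    tx <- parse_annotation(file.path(d, "gene.gff3"),
                           file.path(d, "genome.fa"))
    t <- tx[[fx$transcript$id]]
    expect_identical(t$exon_starts, fx$transcript$exon_starts)
    expect_identical(t$exon_ends, fx$transcript$exon_ends)
    expect_identical(t$strand, strand)
    expect_identical(t$cds_start, fx$transcript$cds_start)
    expect_identical(t$cds_end, fx$transcript$cds_end)
    expect_identical(spliced_sequence(t, fx$genome),
                     spliced_sequence(fx$transcript, fx$genome))
  }
})

test_that("the wild-type ORF is clean and the skip creates a PTC", {
  for (s in c(41L, 42L)) {
    fx <- make_toy_gene(fixture_spec(seed = s))
    t <- fx$transcript
    wt <- spliced_sequence(t, fx$genome)
    cds <- substr(wt, t$cds_start + 1L, t$cds_end)
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_identical(codons[length(codons)], "TAA")
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))

    rep <- simulate_exon_skip(t, 2L, fx$genome)
    expect_true(rep$frameshift)
    expect_false(is.na(rep$ptc_mrna_offset))
  }
})

test_that("planted stems fold closed while the design window stays open", {
  fx <- make_toy_gene(fixture_spec(seed = 33L))
  reg <- extract_target_region(fx$transcript, 2L, fx$genome)
  prof <- ss_count_profile(reg$sequence)
  # region coordinates of the upstream stem (genomic truth -> region offset)
  g_region0 <- fx$transcript$exon_starts[2L] - reg$flank_up
  stem <- fx$truth$stems$upstream - g_region0
  arm_idx <- (stem[1L] + 1L):(stem[2L]) # both arms + loop
  tw <- fx$truth$ese_window
  plant_idx <- (reg$exon_span[1L] + tw$exon_offset + 1L):
    (reg$exon_span[1L] + tw$exon_offset + tw$width)
  expect_lt(mean(prof$openness[arm_idx]), 0.6)
  expect_gt(mean(prof$openness[plant_idx]), 0.8)
})

test_that("paper-like fixtures reproduce the published band sizes", {
  for (g in c("igfbp1", "igfbp3")) {
    fx <- make_paperlike_fixture(g, seed = 7L)
    wt <- spliced_sequence(fx$transcript, fx$genome)
    sk <- simulate_exon_skip(fx$transcript, 2L, fx$genome)
    pw <- pcr_products(wt, fx$primers$outer, fx$primers$inner, "wt")
    ps <- pcr_products(sk$mrna, fx$primers$outer, fx$primers$inner, "skip")
    want <- fx$truth$products$inner
    expect_identical(pw$length[pw$round == "inner"], want$wildtype_bp)
    expect_identical(ps$length[ps$round == "inner"], want$skipped_bp)
    expect_identical(want$wildtype_bp - want$skipped_bp,
                     exon_lengths(fx$transcript)[2L])
    expect_true(sk$frameshift)
  }
})
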