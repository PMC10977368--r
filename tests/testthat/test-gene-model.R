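test_that("GFF3 coordinates convert to 0-based half-open spans", {
  g <- segmented_genome(lead = strrep("A", 10), e1 = "ACGTACGTAC",
                        i1 = strrep("T", 10), e2 = "GGGGGCCCCC",
                        tail = strrep("A", 10))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff3(gff, list(c(10L, 20L), c(30L, 40L)))
  tx <- parse_annotation(gff, g$genome)
  expect_length(tx, 1L)
  t <- tx[["tx1"]]
  expect_identical(t$exon_starts, c(10L, 30L))
  expect_identical(t$exon_ends, c(20L, 40L))
  expect_identical(exon_lengths(t), c(10L, 10L))
  expect_identical(spliced_sequence(t, g$genome), "ACGTACGTACGGGGGCCCCC")
})

test_that("minus-strand exon 1 is the genomically later exon", {
  g <- segmented_genome(all = strrep("ACGT", 15))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff3(gff, list(c(10L, 20L), c(30L, 40L)), strand = "-")
  t <- parse_annotation(gff, g$genome)[["tx1"]]
  expect_identical(t$strand, "-")
  expect_identical(t$exon_starts[1L], 30L)
  expect_identical(t$exon_starts[2L], 10L)
})

test_that("orphan exons and unknown sequence ids raise structured errors", {
  g <- c(chr1 = strrep("A", 100))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\texon\t11\t20\t.\t+\t.\tID=lonely"), gff)
  expect_error(parse_annotation(gff, g), class = "aondesign_parse_error")
  expect_error(parse_annotation(gff, g), "without a transcript parent")

  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff3(gff2, list(c(10L, 20L)), seq_id = "chrMissing")
  expect_error(parse_annotation(gff2, g), "chrMissing")
})

test_that("minus-strand splicing reverse-complements and concatenates", {
  # 12-nt toy: genomic exon 1 "AAAC", exon 2 "GGGT"; on the minus strand
  # transcription order is exon "GGGT" first -> "ACCC" + "GTTT"
  g <- c(chr1 = "AAACTTGGGTTT")
  t <- transcript("m", "chr1", "-", exon_starts = c(6L, 0L),
                  exon_ends = c(10L, 4L), cds_start = 0L, cds_end = 8L)
  expect_identical(spliced_sequence(t, g), "ACCCGTTT")
  # involution on the exon sequence
  expect_identical(reverse_complement(reverse_complement("AAACGGGT")),
                   "AAACGGGT")
})

test_that("exon frame classification follows length mod 3", {
  expect_identical(classify_exon_frame(185), "out_of_frame")
  expect_identical(classify_exon_frame(227), "out_of_frame")
  expect_identical(classify_exon_frame(99), "in_frame")
  expect_error(classify_exon_frame(0), "positive")
  expect_error(classify_exon_frame(-3), "positive")
})

test_that("exon skip arithmetic: lengths and frameshift flags", {
  for (mid in c(185L, 99L)) {
    lens <- c(100L, mid, 120L)
    mrna <- rseq(sum(lens), c("A", "C"))
    fx <- transcript_from_mrna(mrna, lens, 0L, sum(lens) - sum(lens) %% 3L)
    rep <- simulate_exon_skip(fx$transcript, 2L, fx$genome)
    expect_identical(nchar(rep$mrna), 220L)
    expect_identical(rep$frameshift, mid %% 3L != 0L)
    expect_identical(rep$product_frame_mod, mid %% 3L)
    expect_identical(nchar(rep$mrna) + mid, nchar(rep$wt_mrna))
  }
  fx <- transcript_from_mrna(rseq(150, c("A", "C")), c(50L, 50L, 50L),
                             0L, 150L)
  expect_error(simulate_exon_skip(fx$transcript, 1L, fx$genome), "internal")
  expect_error(simulate_exon_skip(fx$transcript, 3L, fx$genome), "internal")
})

test_that("a constructed frameshift PTC is found and NMD-called", {
  # 4-exon transcript; skipping the 20-nt exon 2 shifts the frame so that
  # a TAA appears 12 nt after the skip junction, well upstream (>= 50 nt)
  # of the final junction -> NMD substrate.
  e1 <- paste0("ATG", strrep("GCA", 9))        # 30 nt, start at 0
  e2 <- strrep("GCAAC", 4)                      # 20 nt, mod 3 = 2
  e3 <- paste0("CACCACCACCAC", "TAAC", strrep("CAC", 20)) # 76 nt
  e4 <- strrep("CA", 30)                        # 60 nt
  # after skipping e2, frame at e3 shifts by +1 relative to annotation:
  # codons read ...| CAC CAC CAC CAC TAA ... -> stop 12 nt into e3
  mrna <- paste0(e1, e2, e3, e4)
  lens <- nchar(c(e1, e2, e3, e4))
  fx <- transcript_from_mrna(mrna, lens, 0L, sum(lens) - sum(lens) %% 3L)
  rep <- simulate_exon_skip(fx$transcript, 2L, fx$genome)
  expect_true(rep$frameshift)
  expect_identical(rep$ptc_mrna_offset, 30L + 12L)
  # final junction of the skipped transcript: 30 + 76 = 106; 106 - 42 >= 50
  expect_true(rep$nmd_predicted)
})

test_that("target region extraction honours the 50-nt flank rule", {
  lens <- c(100L, 185L, 120L)
  mrna <- rseq(sum(lens), c("A", "C", "G", "T"))
  fx <- transcript_from_mrna(mrna, lens, 0L, 405L, intron = 60L)
  reg <- extract_target_region(fx$transcript, 2L, fx$genome)
  expect_identical(nchar(reg$sequence), 285L)
  expect_identical(reg$exon_span, c(50L, 235L))
  expect_false(reg$truncated)

  short <- transcript_from_mrna(mrna, lens, 0L, 405L, intron = 20L)
  reg2 <- extract_target_region(short$transcript, 2L, short$genome)
  expect_identical(nchar(reg2$sequence), 185L + 20L + 20L)
  expect_true(reg2$truncated)

  reg3 <- extract_target_region(fx$transcript, 2L, fx$genome, flank = 0L)
  expect_identical(reg3$sequence,
                   substr(mrna, 101L, 285L))
  expect_identical(reg3$exon_span, c(0L, 185L))
})

test_that("skip length identity and frameshift biconditional hold on random transcripts", {
  set.seed(42)
  for (i in 1:1000) {
    fx <- random_transcript(n_exons = sample(3:5, 1L))
    ks <- seq(2L, length(fx$lengths) - 1L)
    k <- ks[sample.int(length(ks), 1L)]
    rep <- simulate_exon_skip(fx$transcript, k, fx$genome)
    stopifnot(nchar(rep$mrna) + fx$lengths[k] == nchar(rep$wt_mrna),
              rep$frameshift == (fx$lengths[k] %% 3L != 0L))
  }
  expect_true(TRUE)
})

test_that("PTC position agrees with exhaustive codon scanning", {
  set.seed(99)
  scan_stop <- function(mrna, start, from) {
    stops <- c("TAA", "TAG", "TGA")
    pos <- start
    while (pos + 3L <= nchar(mrna)) {
      cod <- substr(mrna, pos + 1L, pos + 3L)
      if (cod %in% stops && pos + 3L > from) return(pos)
      pos <- pos + 3L
    }
    NA_integer_
  }
  for (i in 1:60) {
    fx <- random_transcript(n_exons = 3L, min_len = 30L, max_len = 90L)
    rep <- simulate_exon_skip(fx$transcript, 2L, fx$genome)
    junction <- fx$lengths[1L]
    expect_identical(rep$ptc_mrna_offset,
                     scan_stop(rep$mrna, 0L, junction))
  }
})

test_that("minus-strand representation yields the same target region", {
  for (s in c(5L, 6L)) {
    plus <- make_toy_gene(fixture_spec(seed = s, strand = "+"))
    minus <- make_toy_gene(fixture_spec(seed = s, strand = "-"))
    rp <- extract_target_region(plus$transcript, 2L, plus$genome)
    rm <- extract_target_region(minus$transcript, 2L, minus$genome)
    expect_identical(rp$sequence, rm$sequence)
    expect_identical(rp$exon_span, rm$exon_span)
    expect_identical(spliced_sequence(plus$transcript, plus$genome),
                     spliced_sequence(minus$transcript, minus$genome))
  }
})

test_that("skip reports serialize to TSV and JSON", {
  fx <- transcript_from_mrna(rseq(300, c("A", "C", "G", "T")),
                             c(100L, 100L, 100L), 0L, 300L)
  rep <- simulate_exon_skip(fx$transcript, 2L, fx$genome)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_skip_report(rep, tsv, "tsv")
  write_skip_report(rep, jsn, "json")
  tab <- read.delim(tsv)
  expect_true("frameshift" %in% tab$field)
  parsed <- jsonlite::read_json(jsn)
  expect_identical(parsed$skipped_exon_index, 2L)
})
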