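test_that("candidate enumeration counts windows and enforces length bounds", {
  region <- rseq(30, c("A", "C", "G", "U"))
  cfg <- design_config(length_min = 20, length_max = 20)
  cands <- enumerate_candidates(region, cfg)
  expect_identical(nrow(cands), 11L) # 30 - 20 + 1

  expect_error(design_config(length_min = 17), "18-30")
  cfg17 <- design_config(length_min = 17, allow_length_override = TRUE)
  expect_identical(cfg17$length_min, 17L)

  # N - L + 1 candidates per allowed length
  cfg2 <- design_config(length_min = 18, length_max = 21)
  c2 <- enumerate_candidates(region, cfg2)
  for (L in 18:21) {
    expect_identical(sum(c2$length == L), 30L - L + 1L)
  }
})

test_that("every candidate is the reverse complement of its window", {
  set.seed(14)
  region <- rseq(60, c("A", "C", "G", "T"))
  cands <- enumerate_candidates(region, design_config())
  idx <- sample(nrow(cands), 50L)
  for (i in idx) {
    expect_identical(
      cands$aon[i],
      as.character(Biostrings::RNAString(Biostrings::reverseComplement(
        Biostrings::DNAString(cands$target_seq[i])))))
  }
})

test_that("ranking rewards the open ESE-rich window and is order-stable", {
  fx <- make_toy_gene(fixture_spec(seed = 23))
  rep <- design_aons(fx$transcript, 2L, fx$genome)
  top <- rep$candidates[1L, ]
  tw <- fx$truth$ese_window
  plant0 <- 50L + tw$exon_offset
  ov <- min(top$end, plant0 + tw$width) - max(top$start, plant0)
  expect_gte(ov, 0.5 * min(top$length, tw$width))

  # permuting candidate input order leaves the ranking unchanged
  reg <- extract_target_region(fx$transcript, 2L, fx$genome)
  prof <- ss_count_profile(reg$sequence)
  lib <- default_motif_library()
  hits <- scan_motifs(reg$sequence, lib$matrices, lib$hexamer_sets)
  cands <- enumerate_candidates(reg, design_config())
  set.seed(1)
  shuffled <- cands[sample(nrow(cands)), ]
  r1 <- score_and_rank(cands, prof, hits)
  r2 <- score_and_rank(shuffled, prof, hits)
  key <- function(r) r$candidates[!is.na(r$candidates$rank),
                                  c("start", "length", "rank")]
  expect_identical(key(r1), key(r2))
})

test_that("identical metrics break ties toward the 5'-most start", {
  win <- "GAAGAACCAGAAGAACCAGA"
  prof <- ss_count_profile(strrep("A", 60)) # openness 1 everywhere
  cands <- data.frame(start = c(30L, 0L), end = c(50L, 20L), length = 20L,
                      target_seq = win,
                      aon = reverse_complement(win, as = "RNA"))
  r <- score_and_rank(cands, prof, hits = data.frame(
    motif = character(0), kind = character(0), start = integer(0),
    width = integer(0), score = numeric(0)))
  ranked <- r$candidates
  expect_identical(ranked$start[ranked$rank == 1L], 0L)
  expect_identical(ranked$start[ranked$rank == 2L], 30L)
})

test_that("hard-filter failures stay in the report without a rank", {
  # all-AT windows fail the GC bounds
  region <- paste0(strrep("AT", 15), "GAAGAACCAGAAGAACCAGAAGAACCAGAA")
  prof <- ss_count_profile(region)
  cands <- enumerate_candidates(region,
                                design_config(length_min = 20,
                                              length_max = 20))
  r <- score_and_rank(cands, prof, hits = scan_motifs(
    region, hexamer_sets = list(hexamer_set("e", "ESE", "GAAGAA"))))
  failed <- r$candidates[!r$candidates$gc_ok, ]
  expect_gt(nrow(failed), 0L)
  expect_true(all(is.na(failed$rank)))
  expect_true(all(!failed$pass))
  expect_identical(r$n_input, nrow(cands))
  expect_identical(sum(!is.na(r$candidates$rank)), r$n_pass)
})

test_that("cross-dimer screening penalizes complementary co-oligos", {
  a <- "GGAGGAGGAGGAGGAGGA"
  cands <- data.frame(start = 0L, end = 18L, length = 18L,
                      target_seq = reverse_complement(a),
                      aon = a)
  prof <- ss_count_profile(strrep("A", 20))
  empty_hits <- data.frame(motif = character(0), kind = character(0),
                           start = integer(0), width = integer(0),
                           score = numeric(0))
  clean <- score_and_rank(cands, prof, empty_hits)
  clash <- score_and_rank(cands, prof, empty_hits,
                          cross_aons = "UCCUCCUCCUCCUCCUCC")
  expect_identical(clean$candidates$cross_dimer_dg, 0)
  expect_lt(clash$candidates$cross_dimer_dg, -8)
  expect_false(clash$candidates$cross_dimer_ok)
})

test_that("2'-O-methyl rendering is RNA, tagged and idempotent", {
  x <- to_2omeps("ACGT")
  expect_identical(unclass(x)[1L], "ACGU")
  expect_identical(attr(x, "chemistry"), "2OMePS")
  expect_identical(unclass(to_2omeps(x))[1L], "ACGU")
  expect_error(to_2omeps("ACGX"), "nucleotide")

  # the planted Igfbp1 exon-2 window renders as the published oligo
  fx <- make_paperlike_fixture("igfbp1", seed = 7)
  reg <- extract_target_region(fx$transcript, 2L, fx$genome)
  site <- fx$truth$aon_site
  w0 <- reg$exon_span[1L] + site$exon_offset
  window <- substr(reg$sequence, w0 + 1L, w0 + site$width)
  expect_identical(unclass(to_2omeps(reverse_complement(window)))[1L],
                   igfbp_aons()[["Igfbp1AON"]])
})

test_that("published oligos satisfy the default hard constraints", {
  cfg <- design_config()
  for (nm in c("Igfbp1AON", "Igfbp3AON")) {
    aon <- igfbp_aons()[[nm]]
    expect_gte(nchar(aon), cfg$length_min)
    expect_lte(nchar(aon), cfg$length_max)
    gc <- gc_content(aon)
    expect_gte(gc, cfg$gc_min)
    expect_lte(gc, cfg$gc_max)
    expect_gte(duplex_score(aon, aon)$delta_g, -cfg$max_self_dimer)
  }
})

test_that("design configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("length_min: 20", "length_max: 25", "gc_min: 0.35",
               "allow_length_override: false"), f)
  cfg <- read_design_config(f)
  expect_identical(cfg$length_min, 20L)
  expect_identical(cfg$length_max, 25L)
  expect_identical(cfg$gc_min, 0.35)
})
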