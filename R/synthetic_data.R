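# Synthetic fixtures: fully specified toy gene models with a
# frame-disrupting internal exon, planted open/ESE-rich design windows,
# planted hairpin stems, primer landing sites yielding chosen amplicon
# sizes, and negative-binomial count matrices. Every planted feature is
# listed in a truth record so each pipeline stage can be tested by
# plant-and-recover. Seeds are mandatory; with a fixed seed the output is
# byte-identical.

#' Specify a synthetic toy gene fixture
#'
#' Collects every knob of the generator. Primer placements are given as an
#' intended wild-type amplicon size plus the portion of the amplicon
#' falling in the upstream flanking exon (`fwd_tail`); the skipped-product
#' size is then `wt_size - target exon length` by construction, and the
#' generator refuses contradictory placements (e.g. a reverse primer that
#' would have to land inside the skipped exon).
#'
#' The default background is drawn from an A/C-only alphabet. Because the
#' fold scores only stacked (adjacent) base pairs and an A/C background
#' offers G:C pairs solely against the sparse G residues of planted
#' features, no helix can form outside the planted hairpin stems: planted
#' design windows are "partly open" by construction and structure
#' contrast comes only from the stems. Planted primer sites, oligo sites
#' and CDS anchors reintroduce G/T locally where the assays need them.
#'
#' @param seed Random seed (mandatory; there is no hidden global
#'   randomness).
#' @param exon_lengths Integer vector of exon lengths (transcription
#'   order).
#' @param target_exon 1-based index of the skippable exon (must be
#'   internal).
#' @param intron_lengths Intron lengths between consecutive exons.
#' @param flank Intronic flank used when interpreting planted-window
#'   region coordinates.
#' @param strand `"+"` or `"-"`.
#' @param seq_id,transcript_id Identifiers used in the emitted files.
#' @param pad Plain background sequence placed before and after the gene.
#' @param cds_start Spliced mRNA offset of the start codon.
#' @param background_weights Sampling weights for A, C, G, T background.
#' @param ese_window `NULL`, or a list with `hexamer` (the planted ESE
#'   6-mer), `copies` (number of tandem copies), `spacer` (short linker
#'   between copies keeping the window's GC content in the designable
#'   range without creating self-complementarity) and optional `offset`
#'   (0-based within the target exon; default centers the window).
#' @param aon_site `NULL`, or a list with `sequence` (planted verbatim in
#'   the target exon, e.g. a known oligo target window) and `offset`.
#' @param stems Plant one hairpin stem in each intronic flank of the
#'   target exon (default `TRUE`).
#' @param primers A list with elements `inner` and `outer`, each a list
#'   with `wt_size`, `fwd_tail` and optional explicit `forward`/`reverse`
#'   primer sequences (random 20-mers otherwise).
#' @param counts Parameters of [make_count_matrix()] stored alongside.
#' @return A `fixture_spec` object (a validated list).
#' @export
fixture_spec <- function(seed,
                         exon_lengths = c(160L, 100L, 180L),
                         target_exon = 2L,
                         intron_lengths = c(120L, 120L),
                         flank = 50L,
                         strand = "+",
                         seq_id = "chrT",
                         transcript_id = "toygene.t1",
                         pad = 60L,
                         cds_start = 9L,
                         background_weights = c(A = 0.75, C = 0.25,
                                                G = 0, T = 0),
                         ese_window = list(hexamer = "GAAGAA", copies = 5L,
                                           spacer = "CCA", offset = NULL),
                         aon_site = NULL,
                         stems = TRUE,
                         primers = list(
                           inner = list(wt_size = 300L, fwd_tail = 100L,
                                        forward = NULL, reverse = NULL),
                           outer = list(wt_size = 360L, fwd_tail = 130L,
                                        forward = NULL, reverse = NULL)),
                         counts = list(n_genes = 1000L, n_per_group = 3L,
                                       lfc = 1, frac_de = 0.1,
                                       dispersion = 0.1)) {
  if (missing(seed)) stop("fixture_spec requires an explicit seed",
                          call. = FALSE)
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  stopifnot(length(exon_lengths) >= 3L,
            length(intron_lengths) == length(exon_lengths) - 1L,
            all(exon_lengths > 0L), all(intron_lengths > 0L),
            strand %in% c("+", "-"))
  if (target_exon <= 1L || target_exon >= length(exon_lengths)) {
    stop("target_exon must be an internal exon", call. = FALSE)
  }
  ex_len <- exon_lengths[target_exon]
  for (round in names(primers)) {
    p <- primers[[round]]
    a <- p$fwd_tail
    b <- p$wt_size - a - ex_len
    flen <- if (is.null(p$forward)) 20L else nchar(p$forward)
    rlen <- if (is.null(p$reverse)) 20L else nchar(p$reverse)
    if (a < flen || b < rlen) {
      stop(sprintf(
        "contradictory primer placement for the %s pair: a wild-type product of %d bp with %d bp in the upstream exon leaves %d bp downstream of the %d-nt skipped exon, so a primer would have to land inside the skipped exon and the intended skipped product (%d bp) could not form",
        round, p$wt_size, a, b, ex_len, p$wt_size - ex_len), call. = FALSE)
    }
    if (a > exon_lengths[target_exon - 1L] ||
        b > exon_lengths[target_exon + 1L]) {
      stop(sprintf("primer placement for the %s pair exceeds a flanking exon",
                   round), call. = FALSE)
    }
  }
  if (!is.null(ese_window)) {
    stopifnot(nchar(ese_window$hexamer) == 6L, ese_window$copies >= 1L)
    if (is.null(ese_window$spacer)) ese_window$spacer <- ""
    unit <- 6L + nchar(ese_window$spacer)
    if (unit * ese_window$copies > ex_len) {
      stop("planted ESE window does not fit in the target exon",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), exon_lengths = exon_lengths,
                 target_exon = as.integer(target_exon),
                 intron_lengths = intron_lengths, flank = as.integer(flank),
                 strand = strand, seq_id = seq_id,
                 transcript_id = transcript_id, pad = as.integer(pad),
                 cds_start = as.integer(cds_start),
                 background_weights = background_weights,
                 ese_window = ese_window, aon_site = aon_site,
                 stems = isTRUE(stems), primers = primers, counts = counts),
            class = "fixture_spec")
}

.rand_seq <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

# plant `seqstr` into the chromosome character vector at 0-based `start`,
# marking it protected; planting over a protected base is a generator bug.
.plant <- function(state, start, seqstr, what) {
  idx <- start + seq_len(nchar(seqstr))
  if (any(state$protected[idx])) {
    stop("planted features overlap (", what, "); adjust the fixture spec",
         call. = FALSE)
  }
  state$chars[idx] <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  state$protected[idx] <- TRUE
  state
}

# mutate one unprotected base of the 0-based codon/word at `positions`
# (genomic), preferring the middle; returns updated state or NULL if every
# base is protected.
.break_word <- function(state, positions, prefer = 2L) {
  ord <- unique(c(prefer, seq_along(positions)))
  for (k in ord) {
    g <- positions[k] + 1L
    if (!state$protected[g]) {
      state$chars[g] <- if (state$chars[g] == "C") "G" else "C"
      return(state)
    }
  }
  NULL
}

#' Generate a synthetic toy gene fixture
#'
#' Builds a chromosome holding one multi-exon gene to the exact
#' specification: exon lengths and frames, planted ESE-rich window, planted
#' hairpin stems, primer landing sites with known product sizes, an
#' annotated CDS free of premature in-frame stops on the wild-type mRNA,
#' and a guaranteed in-frame stop downstream of the skip junction in the
#' shifted frame. The planted ESE hexamer is scrubbed from the background
#' so it occurs nowhere outside the planted window.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, `gene.gff3`,
#'   `genome.fa`, `primers.tsv` and `truth.json` are written there.
#' @return A `toy_gene` list with elements `genome` (named character),
#'   `gff` (GFF3 text), `transcript` (a [transcript] object), `primers`
#'   (list of [primer_pair]: `outer`, `inner`), `truth` (every planted
#'   feature), `files` (paths, when written) and `spec`.
#' @export
make_toy_gene <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)

  n_ex <- length(spec$exon_lengths)
  k <- spec$target_exon
  ex_len <- spec$exon_lengths[k]

  # genomic layout (+ strand; flipped at the end if requested)
  starts <- integer(n_ex)
  pos <- spec$pad
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    pos <- pos + spec$exon_lengths[i]
    if (i < n_ex) pos <- pos + spec$intron_lengths[i]
  }
  ends <- starts + spec$exon_lengths
  total <- pos + spec$pad

  state <- list(chars = .rand_seq(total, spec$background_weights),
                protected = rep(FALSE, total))
  truth <- list(seed = spec$seed, exon_lengths = spec$exon_lengths,
                target_exon = k,
                target_exon_frame = classify_exon_frame(ex_len))

  # --- planted stems: one hairpin inside each intronic flank of the target
  arm <- "GCCGGCGC"
  hairpin <- paste0(arm, "AAAA", reverse_complement(arm))
  if (spec$stems) {
    up_flank_start <- starts[k] - min(spec$flank, spec$intron_lengths[k - 1L])
    dn_flank_end <- ends[k] + min(spec$flank, spec$intron_lengths[k])
    s1 <- up_flank_start + 4L
    s2 <- dn_flank_end - nchar(hairpin) - 4L
    state <- .plant(state, s1, hairpin, "upstream stem")
    state <- .plant(state, s2, hairpin, "downstream stem")
    truth$stems <- list(upstream = c(s1, s1 + nchar(hairpin)),
                        downstream = c(s2, s2 + nchar(hairpin)))
  }

  # --- planted ESE window in the target exon
  if (!is.null(spec$ese_window)) {
    ew <- spec$ese_window
    plant <- strrep(paste0(toupper(rna_to_dna(ew$hexamer)),
                           toupper(rna_to_dna(ew$spacer))), ew$copies)
    off <- if (is.null(ew$offset)) (ex_len - nchar(plant)) %/% 2L else
      as.integer(ew$offset)
    state <- .plant(state, starts[k] + off, plant, "ESE window")
    truth$ese_window <- list(hexamer = toupper(rna_to_dna(ew$hexamer)),
                             copies = ew$copies,
                             exon_offset = off,
                             width = nchar(plant))
  }

  # --- primer landing sites
  # A planted site is protected from the stop-scrubbing repair below, so
  # no stop triplet inside it may sit in the wild-type reading frame.
  cum_len <- cumsum(c(0L, spec$exon_lengths))
  g2m <- function(g) { # genomic (+ strand) -> spliced offset, exonic only
    for (i in seq_len(n_ex)) {
      if (g >= starts[i] && g < ends[i]) return(cum_len[i] + g - starts[i])
    }
    stop("position is not exonic", call. = FALSE)
  }
  site_frame_ok <- function(site, g_start) {
    m0 <- g2m(g_start)
    for (stp in c("TAA", "TAG", "TGA")) {
      at <- gregexpr(stp, site, fixed = TRUE)[[1L]]
      if (at[1L] == -1L) next
      if (any((m0 + at - 1L - spec$cds_start) %% 3L == 0L)) return(FALSE)
    }
    ese_hex <- if (!is.null(spec$ese_window)) {
      toupper(rna_to_dna(spec$ese_window$hexamer))
    } else NULL
    if (!is.null(ese_hex) && grepl(ese_hex, site, fixed = TRUE)) {
      return(FALSE)
    }
    TRUE
  }
  rand_primer <- function(g_start, planted_is_rc = FALSE) {
    repeat {
      p <- paste(.rand_seq(20L, c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
                 collapse = "")
      if (gc_content(p) < 0.45 || gc_content(p) > 0.55) next
      site <- if (planted_is_rc) reverse_complement(p) else p
      if (site_frame_ok(site, g_start)) return(p)
    }
  }
  primers <- list()
  truth$products <- list()
  for (round in c("outer", "inner")) {
    p <- spec$primers[[round]]
    a <- p$fwd_tail
    b <- p$wt_size - a - ex_len
    flen <- if (is.null(p$forward)) 20L else nchar(p$forward)
    rlen <- if (is.null(p$reverse)) 20L else nchar(p$reverse)
    g_f <- ends[k - 1L] - a
    g_r <- starts[k + 1L] + b - rlen
    fwd <- if (is.null(p$forward)) rand_primer(g_f) else
      toupper(rna_to_dna(p$forward))
    rev <- if (is.null(p$reverse)) rand_primer(g_r, planted_is_rc = TRUE)
      else toupper(rna_to_dna(p$reverse))
    rc <- reverse_complement(rev)
    for (chk in list(list(fwd, g_f, "forward"), list(rc, g_r, "reverse"))) {
      if (!site_frame_ok(chk[[1L]], chk[[2L]])) {
        stop(sprintf(
          "the %s %s primer site holds a stop triplet in the wild-type reading frame (or the planted hexamer); shift cds_start or the placement",
          round, chk[[3L]]), call. = FALSE)
      }
    }
    state <- .plant(state, g_f, fwd, paste(round, "forward primer site"))
    state <- .plant(state, g_r, rc, paste(round, "reverse primer site"))
    primers[[round]] <- primer_pair(fwd, rev, paste0(round, "_pair"))
    truth$products[[round]] <- list(wildtype_bp = p$wt_size,
                                    skipped_bp = p$wt_size - ex_len)
  }

  # --- planted oligo target site in the target exon
  if (!is.null(spec$aon_site)) {
    site <- toupper(rna_to_dna(spec$aon_site$sequence))
    off <- as.integer(spec$aon_site$offset)
    if (!site_frame_ok(site, starts[k] + off)) {
      stop("the planted oligo target site holds a stop triplet in the ",
           "wild-type reading frame; shift its offset or cds_start",
           call. = FALSE)
    }
    state <- .plant(state, starts[k] + off, site, "AON target site")
    truth$aon_site <- list(sequence = site, exon_offset = off,
                           width = nchar(site))
  }

  # --- CDS anchors: start codon and terminal stop
  mrna_len <- sum(spec$exon_lengths)
  to_genomic <- function(off) { # spliced offset -> genomic (+ strand)
    cum <- cumsum(c(0L, spec$exon_lengths))
    i <- findInterval(off, cum, left.open = FALSE)
    starts[i] + (off - cum[i])
  }
  cds_start <- spec$cds_start
  cds_len <- 3L * ((mrna_len - cds_start - 15L) %/% 3L)
  stop_off <- cds_start + cds_len - 3L
  plant_codon <- function(state, off, codon, what) {
    g <- vapply(off + 0:2, to_genomic, integer(1))
    if (any(diff(g) != 1L)) stop("CDS anchor straddles an intron; ",
                                 "adjust cds_start", call. = FALSE)
    .plant(state, g[1L], codon, what)
  }
  state <- plant_codon(state, cds_start, "ATG", "start codon")
  while (any(state$protected[to_genomic(stop_off) + 1:3])) {
    stop_off <- stop_off - 3L
  }
  state <- plant_codon(state, stop_off, "TAA", "stop codon")
  cds_end <- stop_off + 3L

  get_mrna <- function(state) {
    paste(vapply(seq_len(n_ex), function(i) {
      paste(state$chars[(starts[i] + 1L):ends[i]], collapse = "")
    }, character(1)), collapse = "")
  }

  # --- repair loop: scrub wild-type in-frame stops, scrub stray planted
  # hexamers, guarantee a stop in the shifted frame after the skip
  ese_hex <- if (!is.null(spec$ese_window)) truth$ese_window$hexamer else NULL
  junction <- sum(spec$exon_lengths[seq_len(k - 1L)])
  for (iter in 1:80) {
    changed <- FALSE
    mrna <- get_mrna(state)

    # (a) premature in-frame stops on the wild-type mRNA
    stp <- .first_stop(mrna, cds_start)
    while (!is.na(stp) && stp < stop_off) {
      g <- vapply(stp + 0:2, to_genomic, integer(1))
      state2 <- .break_word(state, g)
      if (is.null(state2)) {
        stop("cannot scrub an in-frame stop inside a protected planted ",
             "feature; adjust the fixture spec", call. = FALSE)
      }
      state <- state2
      changed <- TRUE
      mrna <- get_mrna(state)
      stp <- .first_stop(mrna, cds_start)
    }

    # (b) planted hexamer must not occur outside the planted window
    if (!is.null(ese_hex)) {
      chrom <- paste(state$chars, collapse = "")
      win_g0 <- starts[k] + truth$ese_window$exon_offset
      win_g1 <- win_g0 + truth$ese_window$width
      hits <- gregexpr(ese_hex, chrom, fixed = TRUE)[[1L]]
      if (hits[1L] != -1L) {
        for (h in as.integer(hits) - 1L) {
          if (h >= win_g0 && h + 6L <= win_g1) next
          state2 <- .break_word(state, h + 0:5, prefer = 3L)
          if (is.null(state2)) {
            stop("stray planted hexamer overlaps a protected feature; ",
                 "adjust the fixture spec", call. = FALSE)
          }
          state <- state2
          changed <- TRUE
        }
      }
    }

    # (c) the shifted frame must hit a stop downstream of the junction
    if (ex_len %% 3L != 0L) {
      mrna <- get_mrna(state)
      skip <- paste0(.subseq0(mrna, 0L, junction),
                     .subseq0(mrna, junction + ex_len, mrna_len))
      if (is.na(.first_stop(skip, cds_start, junction))) {
        planted <- FALSE
        off <- cds_start + 3L * ((junction + 30L - cds_start) %/% 3L)
        while (off + 3L <= nchar(skip)) {
          g <- vapply(off + ex_len + 0:2, to_genomic, integer(1))
          if (!any(state$protected[g + 1L]) && all(diff(g) == 1L)) {
            state <- .plant(state, g[1L], "TAA", "skip-frame stop")
            planted <- TRUE
            changed <- TRUE
            break
          }
          off <- off + 3L
        }
        if (!planted) stop("cannot place a stop codon in the shifted frame",
                           call. = FALSE)
      }
    }
    if (!changed) break
    if (iter == 80L) stop("fixture repair did not converge", call. = FALSE)
  }

  # --- primer site uniqueness on the chromosome
  chrom <- paste(state$chars, collapse = "")
  for (round in names(primers)) {
    for (pat in c(primers[[round]]$forward,
                  reverse_complement(primers[[round]]$reverse))) {
      n_hits <- length(gregexpr(pat, chrom, fixed = TRUE)[[1L]])
      if (gregexpr(pat, chrom, fixed = TRUE)[[1L]][1L] == -1L || n_hits != 1L) {
        stop("primer site is not unique on the synthetic chromosome; ",
             "re-seed the fixture", call. = FALSE)
      }
    }
  }

  # --- assemble outputs (flip to minus strand representation if asked)
  exon_starts <- starts
  exon_ends <- ends
  if (spec$strand == "-") {
    chrom <- reverse_complement(chrom)
    ns <- total - exon_ends
    ne <- total - exon_starts
    exon_starts <- ns
    exon_ends <- ne
  }
  tx <- transcript(spec$transcript_id, spec$seq_id, spec$strand,
                   exon_starts, exon_ends, cds_start, cds_end)
  genome <- stats::setNames(chrom, spec$seq_id)
  truth$cds <- c(cds_start, cds_end)
  truth$wt_mrna_length <- mrna_len

  gff <- .toy_gene_gff3(spec, tx, total)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(gff = file.path(out_dir, "gene.gff3"),
                  fasta = file.path(out_dir, "genome.fa"),
                  primers = file.path(out_dir, "primers.tsv"),
                  truth = file.path(out_dir, "truth.json"))
    writeLines(gff, files$gff)
    write_fasta(genome, files$fasta)
    ptab <- data.frame(label = names(primers),
                       forward = vapply(primers, `[[`, "", "forward"),
                       reverse = vapply(primers, `[[`, "", "reverse"))
    utils::write.table(ptab, files$primers, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
  }

  structure(list(genome = genome, gff = gff, transcript = tx,
                 primers = primers, truth = truth, files = files,
                 spec = spec),
            class = "toy_gene")
}

# GFF3 rendering (1-based inclusive on output, as the format requires)
.toy_gene_gff3 <- function(spec, tx, total) {
  g1 <- function(s) s + 1L # 0-based start -> 1-based
  gene_id <- sub("\\..*$", "", spec$transcript_id)
  gs <- min(tx$exon_starts)
  ge <- max(tx$exon_ends)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", spec$seq_id, total),
             sprintf("%s\taondesign\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     spec$seq_id, g1(gs), ge, spec$strand, gene_id),
             sprintf("%s\taondesign\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     spec$seq_id, g1(gs), ge, spec$strand,
                     spec$transcript_id, gene_id))
  for (i in seq_along(tx$exon_starts)) {
    lines <- c(lines, sprintf(
      "%s\taondesign\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
      spec$seq_id, g1(tx$exon_starts[i]), tx$exon_ends[i], spec$strand,
      spec$transcript_id, i, spec$transcript_id))
  }
  # CDS: spliced [cds_start, cds_end) intersected with each exon
  lens <- tx$exon_ends - tx$exon_starts
  cum <- cumsum(c(0L, lens))
  for (i in seq_along(lens)) {
    s <- max(tx$cds_start, cum[i])
    e <- min(tx$cds_end, cum[i + 1L])
    if (s >= e) next
    if (tx$strand == "+") {
      gs_i <- tx$exon_starts[i] + (s - cum[i])
      ge_i <- tx$exon_starts[i] + (e - cum[i])
    } else {
      ge_i <- tx$exon_ends[i] - (s - cum[i])
      gs_i <- tx$exon_ends[i] - (e - cum[i])
    }
    lines <- c(lines, sprintf(
      "%s\taondesign\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
      spec$seq_id, g1(gs_i), ge_i, tx$strand, 0L,
      spec$transcript_id, spec$transcript_id))
  }
  lines
}

#' Reference oligo and primer sequences for the mouse Igfbp1/Igfbp3 assay
#'
#' The published 2'-O-methyl phosphorothioate antisense oligos targeting
#' exon 2 of mouse Igfbp1 and Igfbp3 (plus the non-targeting control), and
#' the nested RT-PCR primer pairs used to read out exon-2 skipping. These
#' are inputs to the paper-like fixtures and consistency checks.
#'
#' @return For `igfbp_aons()`, a named character vector of RNA sequences.
#'   For `igfbp_primers()`, a nested list of [primer_pair] objects
#'   (`$igfbp1$inner`, `$igfbp1$outer`, `$igfbp3$inner`, `$igfbp3$outer`).
#' @export
igfbp_aons <- function() {
  c(Igfbp1AON = "CUUCCAUUUCUUGAGGUCGG",
    Igfbp3AON = "AACUUGGAAUCGGUCACUCG",
    controlAON = "UUCAAGUUUAUCUUGCUCUUC")
}

#' @rdname igfbp_aons
#' @export
igfbp_primers <- function() {
  list(igfbp1 = list(
         inner = primer_pair("GTCCTTCCAGATTGGCGTGG",
                             "GTTGGGCTGCAGCTAATCTC", "igfbp1_inner"),
         outer = primer_pair("CCTCAAGAAATGGAAGGAGCCC",
                             "TCATCTCCTGCTTTCTGTTGGG", "igfbp1_outer")),
       igfbp3 = list(
         inner = primer_pair("GGAGCAGTACCCGCTGAG",
                             "CACAGTTTGGGATGTGGACG", "igfbp3_inner"),
         outer = primer_pair("GACAGAATACGGTCCCTGCC",
                             "CCCTTCTTGTCACAGTTTGGG", "igfbp3_outer")))
}

#' Generate a paper-like Igfbp1/Igfbp3 fixture
#'
#' Builds a synthetic gene emulating the design context of the mouse
#' Igfbp1 or Igfbp3 exon-2 skipping assay: a 185-nt (Igfbp1-like) or
#' 227-nt (Igfbp3-like) out-of-frame internal exon, the published nested
#' primer pairs planted in the flanking exons so that the inner wild-type
#' product is 425 bp (Igfbp1-like) or 422 bp (Igfbp3-like) and the
#' exon-2-skipped product 240 bp or 195 bp, and the exact target window of
#' the published antisense oligo planted inside exon 2. The genomic
#' background is synthetic; no attempt is made to reproduce the real
#' genomic sequences.
#'
#' @param gene `"igfbp1"` or `"igfbp3"`.
#' @param seed Random seed (default 7).
#' @param out_dir Optional output directory (see [make_toy_gene()]).
#' @return A `toy_gene` (see [make_toy_gene()]); its `truth$products`
#'   records the intended band sizes.
#' @export
make_paperlike_fixture <- function(gene = c("igfbp1", "igfbp3"), seed = 7L,
                                   out_dir = NULL) {
  gene <- match.arg(gene)
  aons <- igfbp_aons()
  prs <- igfbp_primers()[[gene]]
  # cds_start and the oligo-site offset are chosen per gene so that every
  # stop triplet occurring inside a planted (protected) primer or oligo
  # site lies out of frame on the wild-type mRNA; the stop-scrubbing of
  # make_toy_gene cannot touch protected bases.
  if (gene == "igfbp1") {
    ex2 <- 185L
    cds_start <- 9L
    inner <- list(wt_size = 425L, fwd_tail = 120L,
                  forward = prs$inner$forward, reverse = prs$inner$reverse)
    outer <- list(wt_size = 480L, fwd_tail = 145L,
                  forward = prs$outer$forward, reverse = prs$outer$reverse)
    site <- list(sequence = reverse_complement(aons[["Igfbp1AON"]]),
                 offset = 80L)
  } else {
    ex2 <- 227L
    cds_start <- 10L
    inner <- list(wt_size = 422L, fwd_tail = 100L,
                  forward = prs$inner$forward, reverse = prs$inner$reverse)
    outer <- list(wt_size = 482L, fwd_tail = 130L,
                  forward = prs$outer$forward, reverse = prs$outer$reverse)
    site <- list(sequence = reverse_complement(aons[["Igfbp3AON"]]),
                 offset = 81L)
  }
  spec <- fixture_spec(seed = seed,
                       exon_lengths = c(170L, ex2, 190L),
                       target_exon = 2L,
                       transcript_id = paste0(gene, "_like.t1"),
                       seq_id = paste0(gene, "_like"),
                       cds_start = cds_start,
                       ese_window = NULL,
                       aon_site = site,
                       stems = FALSE,
                       primers = list(inner = inner, outer = outer))
  make_toy_gene(spec, out_dir = out_dir)
}

#' Generate a two-group negative-binomial count matrix
#'
#' Simulates a genes x samples count matrix with two groups, a fraction of
#' genes differentially expressed at a specified log2 fold change, and
#' gene-wise negative-binomial noise. The defaults mirror a small
#' 3-vs-3 RNA-seq comparison.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_per_group Replicates per group (default 3).
#' @param lfc log2 fold change applied to the DE genes in group 2.
#' @param frac_de Fraction of DE genes (default 0.1).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline means.
#' @param seed Random seed (mandatory).
#' @return A list with `counts` (integer matrix), `groups`, `is_de`,
#'   `lfc`.
#' @export
make_count_matrix <- function(n_genes = 1000L, n_per_group = 3L, lfc = 1,
                              frac_de = 0.1, dispersion = 0.1,
                              base_meanlog = 4, base_sdlog = 1, seed) {
  if (missing(seed)) stop("make_count_matrix requires an explicit seed",
                          call. = FALSE)
  set.seed(seed)
  mu <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  n_de <- round(frac_de * n_genes)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
  mu2 <- mu * ifelse(is_de, 2^lfc, 1)
  size <- 1 / dispersion
  g1 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = mu, size = size),
               nrow = n_genes)
  g2 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = mu2, size = size),
               nrow = n_genes)
  counts <- cbind(g1, g2)
  rownames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(counts) <- c(paste0("ctrl_", seq_len(n_per_group)),
                        paste0("treat_", seq_len(n_per_group)))
  groups <- rep(c("control", "treated"), each = n_per_group)
  list(counts = count_matrix(counts, groups), groups = groups,
       is_de = is_de, lfc = lfc)
}
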