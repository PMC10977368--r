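# Gene models: annotation parsing, spliced sequences, exon reading-frame
# classification, exon-skip simulation and target-region extraction.
#
# Internal coordinates are 0-based half-open throughout; GFF3/GTF input is
# converted from 1-based inclusive at the parsing boundary.

#' Construct a transcript object
#'
#' Low-level constructor used by [parse_annotation()] and the synthetic-data
#' generator. Exons are given in transcription order with genomic 0-based
#' half-open coordinates; on the minus strand the genomic order of exons is
#' therefore the reverse of their list order.
#'
#' @param id Transcript identifier.
#' @param seq_id Identifier of the genomic sequence the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of genomic 0-based half-open
#'   exon coordinates, in transcription order.
#' @param cds_start,cds_end Optional coding-region offsets into the spliced
#'   mRNA (0-based half-open). `NA` when the transcript has no annotated CDS;
#'   translation then falls back to the longest open reading frame and the
#'   fallback is flagged in downstream reports.
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, seq_id, strand, exon_starts, exon_ends,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L, strand %in% c("+", "-"))
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_starts >= exon_ends)) {
    stop("every exon must satisfy start < end", call. = FALSE)
  }
  gen_order <- order(exon_starts)
  expected <- if (strand == "+") seq_along(exon_starts) else rev(seq_along(exon_starts))
  if (!identical(gen_order, expected)) {
    stop("exons must be supplied in transcription order ",
         "(genomically ascending on +, descending on -)", call. = FALSE)
  }
  if (length(exon_starts) > 1L) {
    g <- sort(exon_starts)
    ge <- sort(exon_ends)
    if (any(g[-1L] < ge[-length(ge)])) {
      stop("exons overlap", call. = FALSE)
    }
  }
  if (!is.na(cds_start) && !is.na(cds_end)) {
    if (cds_end <= cds_start) stop("CDS length must be > 0", call. = FALSE)
    if (cds_end > sum(exon_ends - exon_starts)) {
      stop("cds_end exceeds spliced length", call. = FALSE)
    }
  }
  structure(list(id = id, seq_id = seq_id, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 cds_annotated = !is.na(cds_start) && !is.na(cds_end)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  len <- x$exon_ends - x$exon_starts
  cat(sprintf("transcript %s (%s%s), %d exon(s), spliced length %d nt\n",
              x$id, x$seq_id, x$strand, length(len), sum(len)))
  cat(sprintf("  exon lengths: %s\n", paste(len, collapse = ", ")))
  if (x$cds_annotated) {
    cat(sprintf("  CDS (spliced offsets): [%d, %d)\n", x$cds_start, x$cds_end))
  } else {
    cat("  CDS: not annotated (longest-ORF fallback applies)\n")
  }
  invisible(x)
}

#' Exon lengths of a transcript
#'
#' @param t A [transcript] object.
#' @return Integer vector of exon lengths in transcription order.
#' @export
exon_lengths <- function(t) {
  stopifnot(inherits(t, "transcript"))
  t$exon_ends - t$exon_starts
}

.parse_error <- function(msg, lines = NULL) {
  stop(structure(class = c("aondesign_parse_error", "error", "condition"),
                 list(message = paste(c(msg, lines), collapse = "\n  "),
                      call = NULL, lines = lines)))
}

#' Parse a GFF3 or GTF annotation into transcript objects
#'
#' Reads an annotation file through [rtracklayer::import()], groups exon
#' features by their transcript parent (`Parent=` in GFF3,
#' `transcript_id` in GTF), converts 1-based inclusive coordinates to the
#' package-internal 0-based half-open convention, orders exons in
#' transcription order and projects any CDS features onto spliced mRNA
#' offsets.
#'
#' @param annotation Path to a GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @param genome Genome sequences: named character vector, `DNAStringSet`, or
#'   FASTA path. Every `seq_id` referenced by an exon must be present.
#' @return A named list of [transcript] objects.
#' @seealso [spliced_sequence()], [simulate_exon_skip()]
#' @export
parse_annotation <- function(annotation, genome) {
  genome <- .as_genome(genome)
  gr <- rtracklayer::import(annotation)
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0L) .parse_error("annotation contains no exon features")

  md <- S4Vectors::mcols(gr)
  if ("Parent" %in% colnames(md)) {
    parents <- as.list(md$Parent)
    parent <- vapply(parents, function(p) {
      if (length(p) == 0L) NA_character_ else sub("^transcript:", "", p[[1L]])
    }, character(1))
  } else if ("transcript_id" %in% colnames(md)) {
    parent <- as.character(md$transcript_id)
  } else {
    parent <- rep(NA_character_, length(gr)) # all features are orphans
  }

  orphan <- is.na(parent) | parent == ""
  if (any(orphan & type == "exon")) {
    bad <- which(orphan & type == "exon")
    lines <- sprintf("%s:%d-%d (exon without transcript parent)",
                     as.character(GenomicRanges::seqnames(gr))[bad],
                     GenomicRanges::start(gr)[bad], GenomicRanges::end(gr)[bad])
    .parse_error("exon feature(s) without a transcript parent:", lines)
  }

  seqid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(seqid), names(genome))
  if (length(unknown) > 0L) {
    stop("annotation references sequence id(s) absent from the genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  start0 <- GenomicRanges::start(gr) - 1L # 1-based inclusive -> 0-based
  end0 <- GenomicRanges::end(gr)          # inclusive end -> half-open end
  strand <- as.character(GenomicRanges::strand(gr))

  out <- list()
  for (tx in unique(parent[type == "exon"])) {
    sel <- parent == tx & type == "exon"
    st <- unique(strand[sel])
    if (length(st) != 1L || !st %in% c("+", "-")) {
      .parse_error(sprintf("transcript %s has missing or inconsistent strand", tx))
    }
    sq <- unique(seqid[sel])
    if (length(sq) != 1L) {
      .parse_error(sprintf("transcript %s spans multiple sequences", tx))
    }
    ord <- order(start0[sel])
    if (st == "-") ord <- rev(ord)
    es <- start0[sel][ord]
    ee <- end0[sel][ord]

    cds_sel <- parent == tx & type == "CDS"
    cs <- NA_integer_
    ce <- NA_integer_
    if (any(cds_sel)) {
      cg_start <- min(start0[cds_sel])
      cg_end <- max(end0[cds_sel])
      tmp <- transcript(tx, sq, st, es, ee)
      if (st == "+") {
        cs <- genomic_to_spliced(tmp, cg_start)
        ce <- genomic_to_spliced(tmp, cg_end - 1L) + 1L
      } else {
        cs <- genomic_to_spliced(tmp, cg_end - 1L)
        ce <- genomic_to_spliced(tmp, cg_start) + 1L
      }
    }
    out[[tx]] <- transcript(tx, sq, st, es, ee, cs, ce)
  }
  out
}

#' Map a genomic position onto spliced mRNA coordinates
#'
#' @param t A [transcript] object.
#' @param gpos Genomic 0-based position; must fall inside an exon.
#' @return 0-based offset of that base in the spliced mRNA.
#' @export
genomic_to_spliced <- function(t, gpos) {
  stopifnot(inherits(t, "transcript"))
  lens <- exon_lengths(t)
  offs <- cumsum(c(0L, lens))[seq_along(lens)]
  for (k in seq_along(lens)) {
    if (gpos >= t$exon_starts[k] && gpos < t$exon_ends[k]) {
      within <- if (t$strand == "+") gpos - t$exon_starts[k] else t$exon_ends[k] - 1L - gpos
      return(offs[k] + within)
    }
  }
  stop("genomic position ", gpos, " is not exonic in transcript ", t$id,
       call. = FALSE)
}

.exon_genomic_seq <- function(t, k, genome) {
  chrom <- genome[[t$seq_id]]
  if (is.null(chrom)) {
    stop("sequence id not in genome: ", t$seq_id, call. = FALSE)
  }
  if (t$exon_ends[k] > nchar(chrom) || t$exon_starts[k] < 0L) {
    stop(sprintf("exon %d of %s is out of bounds for sequence %s",
                 k, t$id, t$seq_id), call. = FALSE)
  }
  .subseq0(chrom, t$exon_starts[k], t$exon_ends[k])
}

#' Spliced mRNA sequence of a transcript
#'
#' Concatenates the exon sequences in transcription order; minus-strand
#' exons are reverse-complemented.
#'
#' @inheritParams genomic_to_spliced
#' @param genome Genome sequences (see [parse_annotation()]).
#' @return The spliced sequence as an uppercase DNA string.
#' @export
spliced_sequence <- function(t, genome) {
  stopifnot(inherits(t, "transcript"))
  genome <- .as_genome(genome)
  pieces <- vapply(seq_along(t$exon_starts), function(k) {
    s <- .exon_genomic_seq(t, k, genome)
    if (t$strand == "-") reverse_complement(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Classify an exon's reading-frame status
#'
#' An exon is out of frame when its length is not a multiple of 3, so that
#' removing it from the mature mRNA shifts the downstream reading frame --
#' the property exploited by exon-skipping knockdown.
#'
#' @param exon_length Exon length in nucleotides (positive integer).
#' @return `"out_of_frame"` or `"in_frame"`.
#' @examples
#' classify_exon_frame(185) # mouse Igfbp1 exon 2
#' classify_exon_frame(227) # mouse Igfbp3 exon 2
#' classify_exon_frame(99)
#' @export
classify_exon_frame <- function(exon_length) {
  if (length(exon_length) != 1L || is.na(exon_length) || exon_length <= 0 ||
      exon_length != as.integer(exon_length)) {
    stop("exon_length must be a positive integer", call. = FALSE)
  }
  if (exon_length %% 3L != 0L) "out_of_frame" else "in_frame"
}

.stop_codons <- c("TAA", "TAG", "TGA")

# First in-frame stop codon from the codon containing `from` onward
# (0-based offsets), translating in the frame anchored at `start`. Codons
# containing N never count as stops. Returns the codon start offset or NA.
.first_stop <- function(mrna, start, from = start) {
  n <- nchar(mrna)
  if (start + 3L > n) return(NA_integer_)
  pos <- start + 3L * (max(0L, from - start) %/% 3L)
  while (pos + 3L <= n) {
    codon <- .subseq0(mrna, pos, pos + 3L)
    if (!grepl("N", codon, fixed = TRUE) && codon %in% .stop_codons) {
      return(as.integer(pos))
    }
    pos <- pos + 3L
  }
  NA_integer_
}

# Longest ORF (ATG..stop) start offset; used when no CDS is annotated.
.longest_orf_start <- function(mrna) {
  n <- nchar(mrna)
  best_start <- NA_integer_
  best_len <- -1L
  starts <- gregexpr("ATG", mrna, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(NA_integer_)
  for (s in as.integer(starts) - 1L) {
    stp <- .first_stop(mrna, s)
    len <- if (is.na(stp)) n - s else stp - s
    if (len > best_len) {
      best_len <- len
      best_start <- s
    }
  }
  best_start
}

#' Simulate skipping of an internal exon
#'
#' Removes one internal exon from the spliced mRNA and reports the
#' reading-frame consequences: whether the skip shifts the frame, where the
#' first in-frame stop codon past the skip junction lies (the premature
#' termination codon, PTC), and whether the transcript is predicted to be a
#' nonsense-mediated-decay (NMD) substrate under the 50-nt rule (PTC at
#' least 50 nt upstream of the final exon-exon junction).
#'
#' Only internal exons can be skipped: terminal exons lack one of the two
#' flanking splice sites an antisense oligo needs to disrupt. Translation
#' starts from the annotated start codon of the wild-type CDS; without CDS
#' annotation the longest open reading frame is used and the report flags
#' the fallback.
#'
#' @inheritParams spliced_sequence
#' @param exon_index 1-based ordinal (transcription order) of the exon to
#'   skip; must be internal.
#' @return A `skip_report` object with fields `skipped_exon_index`, `mrna`,
#'   `frameshift`, `ptc_mrna_offset` (0-based offset of the PTC codon in the
#'   skipped mRNA, or `NA`), `nmd_predicted`, `product_frame_mod`,
#'   `start_lost`, `orf_fallback`.
#' @export
simulate_exon_skip <- function(t, exon_index, genome) {
  stopifnot(inherits(t, "transcript"))
  genome <- .as_genome(genome)
  n_ex <- length(t$exon_starts)
  if (exon_index <= 1L || exon_index >= n_ex) {
    stop("only internal exons can be skipped (exon ", exon_index,
         " of ", n_ex, " lacks two flanking splice sites)", call. = FALSE)
  }
  wt <- spliced_sequence(t, genome)
  lens <- exon_lengths(t)
  ex_len <- lens[exon_index]
  ex_start <- sum(lens[seq_len(exon_index - 1L)]) # spliced offset of exon
  mrna <- paste0(.subseq0(wt, 0L, ex_start),
                 .subseq0(wt, ex_start + ex_len, nchar(wt)))
  frameshift <- ex_len %% 3L != 0L

  orf_fallback <- !t$cds_annotated
  start0 <- if (t$cds_annotated) t$cds_start else .longest_orf_start(wt)
  start_lost <- FALSE
  ptc <- NA_integer_
  nmd <- FALSE
  junction <- ex_start # skip junction offset in the skipped mRNA
  if (is.na(start0)) {
    start_lost <- TRUE
  } else if (start0 >= ex_start + ex_len) {
    # skipped exon entirely 5' of the start codon: frame downstream intact
    start_new <- start0 - ex_len
    ptc <- .first_stop(mrna, start_new, junction)
  } else if (start0 >= ex_start) {
    start_lost <- TRUE # start codon removed with the exon
  } else {
    ptc <- .first_stop(mrna, start0, junction)
  }
  if (!is.na(ptc)) {
    last_junction <- sum(lens[-exon_index][seq_len(n_ex - 2L)])
    nmd <- (last_junction - ptc) >= 50L
  }
  structure(list(transcript_id = t$id,
                 skipped_exon_index = as.integer(exon_index),
                 mrna = mrna,
                 wt_mrna = wt,
                 frameshift = frameshift,
                 ptc_mrna_offset = ptc,
                 nmd_predicted = nmd,
                 product_frame_mod = as.integer(ex_len %% 3L),
                 start_lost = start_lost,
                 orf_fallback = orf_fallback),
            class = "skip_report")
}

#' @export
print.skip_report <- function(x, ...) {
  cat(sprintf("exon-skip report: %s, exon %d\n", x$transcript_id,
              x$skipped_exon_index))
  cat(sprintf("  skipped mRNA: %d nt (wild type %d nt)\n", nchar(x$mrna),
              nchar(x$wt_mrna)))
  cat(sprintf("  frameshift: %s (exon length mod 3 = %d)\n", x$frameshift,
              x$product_frame_mod))
  if (x$start_lost) {
    cat("  start codon lost with the skipped exon; no translation\n")
  } else if (!is.na(x$ptc_mrna_offset)) {
    cat(sprintf("  PTC at spliced offset %d; NMD predicted: %s\n",
                x$ptc_mrna_offset, x$nmd_predicted))
  } else {
    cat("  no in-frame stop past the skip junction\n")
  }
  if (x$orf_fallback) cat("  (translation start from longest-ORF fallback)\n")
  invisible(x)
}

#' Write a skip report as tab-delimited text or JSON
#'
#' @param report A `skip_report` from [simulate_exon_skip()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_skip_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "skip_report"))
  format <- match.arg(format)
  fields <- report[c("transcript_id", "skipped_exon_index", "frameshift",
                     "ptc_mrna_offset", "nmd_predicted", "product_frame_mod",
                     "start_lost", "orf_fallback")]
  fields$skipped_mrna_length <- nchar(report$mrna)
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, null = "null")
  } else {
    df <- data.frame(field = names(fields),
                     value = vapply(fields, function(v) as.character(v)[1L],
                                    character(1)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Extract a target exon with intronic flanks
#'
#' Returns the pre-mRNA sequence (sense strand of the transcript) of one
#' exon plus up to `flank` nucleotides of each flanking intron -- the
#' substrate for accessibility profiling and antisense design. Flanks are
#' truncated when the neighboring intron is shorter than `flank`, or at the
#' transcript ends for terminal exons; truncation is recorded.
#'
#' @inheritParams simulate_exon_skip
#' @param exon_index 1-based ordinal of the target exon.
#' @param flank Requested intronic flank length in nucleotides (default 50).
#' @return A `target_region` object with fields `sequence`, `flank`
#'   (requested), `flank_up`/`flank_down` (obtained), `exon_span` (0-based
#'   half-open offsets of the exon within `sequence`) and `truncated`.
#' @export
extract_target_region <- function(t, exon_index, genome, flank = 50L) {
  stopifnot(inherits(t, "transcript"))
  genome <- .as_genome(genome)
  n_ex <- length(t$exon_starts)
  if (exon_index < 1L || exon_index > n_ex) {
    stop("exon_index out of range", call. = FALSE)
  }
  flank <- as.integer(flank)
  stopifnot(flank >= 0L)
  chrom <- genome[[t$seq_id]]
  if (is.null(chrom)) stop("sequence id not in genome: ", t$seq_id,
                           call. = FALSE)

  k <- exon_index
  # Intron length toward the previous/next exon in transcription order;
  # 0 at transcript ends (terminal exons get no flank on that side).
  if (t$strand == "+") {
    gap_up <- if (k == 1L) 0L else t$exon_starts[k] - t$exon_ends[k - 1L]
    gap_dn <- if (k == n_ex) 0L else t$exon_starts[k + 1L] - t$exon_ends[k]
    f_up <- min(flank, gap_up)
    f_dn <- min(flank, gap_dn)
    g0 <- t$exon_starts[k] - f_up
    g1 <- t$exon_ends[k] + f_dn
    seq <- .subseq0(chrom, g0, g1)
  } else {
    gap_up <- if (k == 1L) 0L else t$exon_starts[k - 1L] - t$exon_ends[k]
    gap_dn <- if (k == n_ex) 0L else t$exon_starts[k] - t$exon_ends[k + 1L]
    f_up <- min(flank, gap_up)
    f_dn <- min(flank, gap_dn)
    g0 <- t$exon_starts[k] - f_dn
    g1 <- t$exon_ends[k] + f_up
    seq <- reverse_complement(.subseq0(chrom, g0, g1))
  }
  ex_len <- t$exon_ends[k] - t$exon_starts[k]
  structure(list(sequence = seq,
                 flank = flank,
                 flank_up = f_up,
                 flank_down = f_dn,
                 exon_span = c(f_up, f_up + ex_len),
                 truncated = (f_up < flank) || (f_dn < flank),
                 transcript_id = t$id,
                 exon_index = as.integer(exon_index)),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("target region: %s exon %d, %d nt (exon span [%d, %d))\n",
              x$transcript_id, x$exon_index, nchar(x$sequence),
              x$exon_span[1L], x$exon_span[2L]))
  cat(sprintf("  flanks: %d nt up / %d nt down (requested %d)%s\n",
              x$flank_up, x$flank_down, x$flank,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}
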