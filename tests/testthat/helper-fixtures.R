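# In-code fixture builders for the gene-model tests.

# genome with one chromosome assembled from labelled segments; returns the
# genome plus the 0-based half-open span of each segment
segmented_genome <- function(..., seq_id = "chr1") {
  segs <- list(...)
  seq <- paste(unlist(segs), collapse = "")
  ends <- cumsum(vapply(segs, nchar, integer(1)))
  starts <- c(0L, ends[-length(ends)])
  spans <- Map(c, starts, ends)
  names(spans) <- names(segs)
  list(genome = stats::setNames(seq, seq_id), spans = spans)
}

# write a minimal GFF3 for one transcript given 0-based half-open exon spans
write_test_gff3 <- function(path, exons, strand = "+", seq_id = "chr1",
                            tx_id = "tx1", cds = NULL) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=g1",
                     seq_id, min(vapply(exons, `[[`, 0L, 1L)) + 1L,
                     max(vapply(exons, `[[`, 0L, 2L)), strand, tx_id))
  for (e in exons) {
    lines <- c(lines,
               sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       seq_id, e[1L] + 1L, e[2L], strand, tx_id))
  }
  if (!is.null(cds)) {
    for (e in cds) {
      lines <- c(lines,
                 sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         seq_id, e[1L] + 1L, e[2L], strand, tx_id))
    }
  }
  writeLines(lines, path)
  path
}

# a transcript whose spliced mRNA is exactly `mrna`, laid out with introns
# of `intron` nt between exons of the given lengths
transcript_from_mrna <- function(mrna, exon_lengths, cds_start, cds_end,
                                 intron = 30L, pad = 10L, id = "tfix") {
  stopifnot(sum(exon_lengths) == nchar(mrna))
  filler <- function(n) paste(rep("C", n), collapse = "")
  pieces <- list(filler(pad))
  starts <- integer(length(exon_lengths))
  pos <- pad
  off <- 0L
  for (i in seq_along(exon_lengths)) {
    starts[i] <- pos
    pieces[[length(pieces) + 1L]] <- substr(mrna, off + 1L,
                                            off + exon_lengths[i])
    off <- off + exon_lengths[i]
    pos <- pos + exon_lengths[i]
    if (i < length(exon_lengths)) {
      pieces[[length(pieces) + 1L]] <- filler(intron)
      pos <- pos + intron
    }
  }
  pieces[[length(pieces) + 1L]] <- filler(pad)
  genome <- stats::setNames(paste(unlist(pieces), collapse = ""), "chrF")
  t <- transcript(id, "chrF", "+", starts, starts + exon_lengths,
                  cds_start, cds_end)
  list(transcript = t, genome = genome)
}

# random multi-exon plus-strand transcript over a random genome
random_transcript <- function(n_exons = 3L, min_len = 30L, max_len = 120L,
                              intron = 25L) {
  lens <- sample(min_len:max_len, n_exons, replace = TRUE)
  total <- sum(lens) + intron * (n_exons - 1L) + 20L
  genome <- stats::setNames(rseq(total, c("A", "C", "G", "T")), "chrR")
  starts <- integer(n_exons)
  pos <- 10L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    pos <- pos + lens[i] + intron
  }
  t <- transcript("rnd", "chrR", "+", starts, starts + lens, 0L, sum(lens))
  list(transcript = t, genome = genome, lengths = lens)
}
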