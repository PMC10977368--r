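# Shared sequence helpers. All coordinates in this package are 0-based
# half-open; converters to/from 1-based inclusive live at the I/O boundary.

.valid_nuc <- function(x, allow_n = TRUE) {
  alpha <- if (allow_n) "ACGTUN" else "ACGTU"
  grepl(sprintf("^[%s]+$", alpha), x)
}

.check_seq <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  x <- toupper(x)
  if (!.valid_nuc(x, allow_n = allow_n)) {
    stop(what, " contains characters outside the nucleotide alphabet",
         call. = FALSE)
  }
  x
}

#' Convert between DNA and RNA alphabets
#'
#' `dna_to_rna()` replaces T with U; `rna_to_dna()` replaces U with T. Both
#' uppercase their input and leave all other nucleotide codes untouched.
#'
#' @param x A nucleotide string.
#' @return A single string in the requested alphabet.
#' @examples
#' dna_to_rna("ACGT")
#' rna_to_dna("ACGU")
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of a nucleotide string
#'
#' Thin character wrapper around [Biostrings::reverseComplement()]. The
#' output alphabet follows `as`: antisense oligo sequences are conventionally
#' written as RNA.
#'
#' @param x A nucleotide string (DNA or RNA; T and U are interchangeable).
#' @param as Output alphabet, `"DNA"` or `"RNA"`.
#' @return The reverse complement as a single string.
#' @examples
#' reverse_complement("AAAC")
#' reverse_complement("AAAC", as = "RNA")
#' @export
reverse_complement <- function(x, as = c("DNA", "RNA")) {
  as <- match.arg(as)
  x <- .check_seq(x)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rna_to_dna(x))))
  if (as == "RNA") dna_to_rna(rc) else rc
}

# Encode A/C/G/(U|T) as 0/1/2/3 for the compiled routines.
.encode_seq <- function(x) {
  v <- strsplit(dna_to_rna(x), "", fixed = TRUE)[[1L]]
  code <- match(v, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    stop("sequence contains characters outside {A,C,G,T,U}", call. = FALSE)
  }
  code
}

# 0-based half-open substring of a character scalar.
.subseq0 <- function(x, start, end) substr(x, start + 1L, end)

.geometric_mean <- function(x) exp(mean(log(x)))

# Resolve a genome argument to a named character vector of sequences.
# Accepts a named character vector, a Biostrings::DNAStringSet, or a path to
# a FASTA file.
.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !.valid_nuc(toupper(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
    # FASTA headers may carry descriptions after the first word
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome))) {
    stop("genome must be a named character vector, DNAStringSet or FASTA ",
         "path with unique sequence ids", call. = FALSE)
  }
  toupper(genome)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(rna_to_dna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# Fast character-level reverse complement for hot loops (no S4 overhead).
# Input must be clean uppercase A/C/G/T/U; output alphabet per `rna`.
.rc_chr <- function(x, rna = FALSE) {
  y <- chartr("ACGTU", "TGCAA", x)
  y <- paste(rev(strsplit(y, "", fixed = TRUE)[[1L]]), collapse = "")
  if (rna) chartr("T", "U", y) else y
}
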