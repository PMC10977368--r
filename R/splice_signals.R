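# Exonic splicing enhancer/silencer (ESE/ESS) motif scanning.
#
# Two motif representations are supported: position weight matrices scored
# as summed per-position log-odds against a reportable threshold, and exact
# hexamer sets. The package ships a consensus-derived starter library (see
# inst/extdata/); it is a documented, user-replaceable substitute for the
# proprietary matrix collections of web servers, not a reconstruction of
# any particular one. Scanning is on the sense (exonic) strand only, since
# enhancers act on the pre-mRNA.

#' Construct a motif position-weight matrix
#'
#' @param name Motif name.
#' @param matrix Numeric 4 x W matrix of per-position scores with rows
#'   A, C, G, U (log-odds; width W >= 2).
#' @param threshold Minimum reportable score.
#' @param kind `"ESE"` or `"ESS"`.
#' @return A `motif_matrix` object.
#' @export
motif_matrix <- function(name, matrix, threshold, kind = c("ESE", "ESS")) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L || ncol(matrix) < 2L) {
    stop("motif matrix must be 4 rows (A,C,G,U) by width >= 2", call. = FALSE)
  }
  rownames(matrix) <- c("A", "C", "G", "U")
  structure(list(name = name, matrix = matrix,
                 threshold = as.numeric(threshold), kind = kind),
            class = "motif_matrix")
}

#' Construct a hexamer motif set
#'
#' @param name Set name.
#' @param kind `"ESE"` or `"ESS"`.
#' @param hexamers Character vector of 6-mers (DNA or RNA alphabet).
#' @return A `hexamer_set` object.
#' @export
hexamer_set <- function(name, kind = c("ESE", "ESS"), hexamers) {
  kind <- match.arg(kind)
  hexamers <- toupper(dna_to_rna(hexamers))
  if (any(nchar(hexamers) != 6L)) {
    stop("all hexamers must be exactly 6 nt", call. = FALSE)
  }
  structure(list(name = name, kind = kind, hexamers = unique(hexamers)),
            class = "hexamer_set")
}

#' Read a plain-text motif library
#'
#' Parses the package's tab-delimited PWM block format: each motif is a
#' header line `>name kind threshold` followed by four rows `A/C/G/U` of
#' per-position scores. Lines starting with `#` are comments.
#'
#' @param path Path to a motif library file.
#' @return A list of [motif_matrix] objects.
#' @export
read_motif_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no motif blocks in ", path, call. = FALSE)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    fields <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1L]]
    if (length(fields) < 3L) stop("malformed motif header: ", lines[i],
                                  call. = FALSE)
    rows <- lines[(i + 1L):(i + 4L)]
    mat <- t(vapply(rows, function(r) {
      v <- strsplit(trimws(r), "\\s+")[[1L]]
      as.numeric(v[-1L])
    }, numeric(length(strsplit(trimws(rows[1L]), "\\s+")[[1L]]) - 1L)))
    bases <- vapply(rows, function(r) strsplit(trimws(r), "\\s+")[[1L]][1L],
                    character(1))
    mat <- mat[match(c("A", "C", "G", "U"), bases), , drop = FALSE]
    out[[fields[1L]]] <- motif_matrix(fields[1L], mat,
                                      as.numeric(fields[3L]),
                                      kind = fields[2L])
  }
  out
}

#' Read a hexamer set file (one 6-mer per line)
#'
#' @param path File path; `#` lines are comments.
#' @param name Set name (defaults to the file name).
#' @param kind `"ESE"` or `"ESS"`.
#' @return A [hexamer_set].
#' @export
read_hexamer_set <- function(path, name = basename(path),
                             kind = c("ESE", "ESS")) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  hexamer_set(name, match.arg(kind), lines[nzchar(lines)])
}

#' The packaged default ESE/ESS motif library
#'
#' Loads the consensus-derived PWMs and hexamer sets shipped under
#' `inst/extdata/`. The library favours the purine-rich GA(A/G)-type
#' enhancer motifs bound by SR proteins and UAG-core hnRNP A1-type
#' silencers; the file headers document its provenance and format so users
#' can swap in their own collections.
#'
#' @return A list with elements `matrices` (list of [motif_matrix]) and
#'   `hexamer_sets` (list of [hexamer_set]).
#' @export
default_motif_library <- function() {
  ext <- system.file("extdata", package = "aondesign")
  list(matrices = read_motif_library(file.path(ext, "ese_pwms.txt")),
       hexamer_sets = list(
         read_hexamer_set(file.path(ext, "ese_hexamers.txt"),
                          name = "GA-rich-ESE", kind = "ESE"),
         read_hexamer_set(file.path(ext, "ess_hexamers.txt"),
                          name = "UAG-ESS", kind = "ESS")))
}

#' Scan a sequence for splicing-regulatory motifs
#'
#' Slides every PWM across the sequence reporting windows scoring at or
#' above the motif threshold, and reports every exact (overlapping) match
#' of each hexamer set. Hits are sorted by start, then motif name.
#'
#' @param sequence Sequence to scan (DNA or RNA; scanned as RNA).
#' @param matrices List of [motif_matrix] objects.
#' @param hexamer_sets List of [hexamer_set] objects.
#' @return A data frame of hits with columns `motif`, `kind`, `start`
#'   (0-based on the scanned sequence), `width`, `score` (`NA` for hexamer
#'   hits).
#' @examples
#' hits <- scan_motifs("UUGAAGAAUU",
#'                     hexamer_sets = list(hexamer_set("t", "ESE", "GAAGAA")))
#' @export
scan_motifs <- function(sequence, matrices = list(), hexamer_sets = list()) {
  if (length(matrices) == 0L && length(hexamer_sets) == 0L) {
    stop("empty motif library: supply at least one PWM or hexamer set",
         call. = FALSE)
  }
  sequence <- dna_to_rna(.check_seq(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  hits <- list()

  for (m in matrices) {
    stopifnot(inherits(m, "motif_matrix"))
    w <- ncol(m$matrix)
    if (w > n) next
    idx <- match(chars, c("A", "C", "G", "U"))
    # score of window starting at s (1-based): sum_j matrix[base[s+j-1], j]
    scores <- vapply(seq_len(n - w + 1L), function(s) {
      rows <- idx[s:(s + w - 1L)]
      if (anyNA(rows)) return(-Inf) # windows containing N never report
      sum(m$matrix[cbind(rows, seq_len(w))])
    }, numeric(1))
    hit <- which(scores >= m$threshold)
    if (length(hit) > 0L) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif = m$name, kind = m$kind, start = hit - 1L, width = w,
        score = scores[hit])
    }
  }

  subject <- Biostrings::RNAString(sequence)
  for (hs in hexamer_sets) {
    stopifnot(inherits(hs, "hexamer_set"))
    for (hx in hs$hexamers) {
      mt <- Biostrings::matchPattern(Biostrings::RNAString(hx), subject)
      if (length(mt) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif = hs$name, kind = hs$kind,
          start = Biostrings::start(mt) - 1L, width = 6L,
          score = NA_real_)
      }
    }
  }

  out <- if (length(hits) == 0L) {
    data.frame(motif = character(0), kind = character(0),
               start = integer(0), width = integer(0), score = numeric(0))
  } else {
    do.call(rbind, hits)
  }
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif-hit density in a window
#'
#' Counts hits of the requested kind whose start position lies inside the
#' window and divides by the window length. Counting by start keeps the
#' measure shift-equivariant and free of overlap conventions.
#'
#' @param hits Hit data frame from [scan_motifs()].
#' @param window_start 0-based window start.
#' @param window_len Window length (> 0).
#' @param kind `"ESE"` or `"ESS"`.
#' @return Hits per nucleotide (nonnegative).
#' @export
motif_density <- function(hits, window_start, window_len,
                          kind = c("ESE", "ESS")) {
  kind <- match.arg(kind)
  if (window_len <= 0L) stop("window length must be > 0", call. = FALSE)
  sel <- hits$kind == kind &
    hits$start >= window_start &
    hits$start < window_start + window_len
  sum(sel) / window_len
}

#' @rdname motif_density
#' @export
ese_density <- function(hits, window_start, window_len) {
  motif_density(hits, window_start, window_len, kind = "ESE")
}
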