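# Nearest-neighbor hybridization thermodynamics: GC%, duplex melting
# temperature, binding free energy and self/cross-dimer screening.
#
# The default parameter set is the RNA/RNA Watson-Crick table of Xia et
# al. (1998), appropriate as a first approximation for 2'-O-methyl RNA
# oligos hybridizing to pre-mRNA; the table is read from a plain-text file
# carrying a provenance tag and can be swapped wholesale.

#' Read a nearest-neighbor parameter table
#'
#' Parses the tab-delimited stack table format: comment lines (`#`, the
#' first of which is kept as the provenance tag), a `stack dH dS` header,
#' one row per top-strand dinucleotide plus `INIT`, `TERM_AU` and `SYM`
#' rows. dH in kcal/mol, dS in cal/(mol.K).
#'
#' @param path File path; default is the packaged Xia et al. (1998)
#'   RNA/RNA table.
#' @return An `nn_table` object.
#' @export
read_nn_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_rna_xia1998.txt", package = "aondesign")
  }
  lines <- readLines(path)
  comments <- lines[grepl("^\\s*#", lines)]
  provenance <- if (length(comments) > 0L) {
    trimws(sub("^\\s*#\\s*provenance:\\s*", "", comments[1L]))
  } else ""
  if (!nzchar(provenance)) {
    stop("nearest-neighbor table must carry a provenance comment",
         call. = FALSE)
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  rownames(tab) <- toupper(tab$stack)
  dinucs <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                            paste0))
  missing <- setdiff(dinucs, rownames(tab))
  if (length(missing) > 0L) {
    stop("nearest-neighbor table is missing stack(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list(dh = stats::setNames(tab[dinucs, "dH"], dinucs),
              ds = stats::setNames(tab[dinucs, "dS"], dinucs),
              init_dh = tab["INIT", "dH"], init_ds = tab["INIT", "dS"],
              term_au_dh = tab["TERM_AU", "dH"],
              term_au_ds = tab["TERM_AU", "dS"],
              sym_ds = tab["SYM", "dS"],
              provenance = provenance)
  out$dg37 <- {
    ord <- as.vector(t(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                             paste0)))
    unname(out$dh[ord] - 310.15 * out$ds[ord] / 1000)
  }
  structure(out, class = "nn_table")
}

#' @export
print.nn_table <- function(x, ...) {
  cat("nearest-neighbor table:", x$provenance, "\n")
  invisible(x)
}

# cached default table
.nn_cache <- new.env(parent = emptyenv())

#' @rdname read_nn_table
#' @export
default_nn_table <- function() {
  if (is.null(.nn_cache$default)) .nn_cache$default <- read_nn_table()
  .nn_cache$default
}

# Stack free energies at 37 C keyed by top-strand dinucleotide, in the
# A/C/G/U order the compiled duplex scan expects (index = 4*first + second).
.stack_dg37 <- function(params) {
  if (!is.null(params$dg37)) return(params$dg37)
  dinucs <- as.vector(t(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              paste0)))
  unname(params$dh[dinucs] - 310.15 * params$ds[dinucs] / 1000)
}

#' GC content of a nucleotide sequence
#'
#' @param sequence Nonempty nucleotide string (DNA or RNA).
#' @return Fraction of G + C bases, in `[0, 1]`.
#' @examples
#' gc_content("CUUCCAUUUCUUGAGGUCGG") # 0.5
#' @export
gc_content <- function(sequence) {
  sequence <- .check_seq(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(chars %in% c("G", "C")) / length(chars)
}

# Sum NN terms for a perfect duplex of `sequence` against its full
# complement. Returns list(dh, ds) before salt/concentration terms.
.nn_sum <- function(sequence, params) {
  rna <- dna_to_rna(sequence)
  n <- nchar(rna)
  stacks <- substring(rna, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  dh <- params$init_dh + sum(params$dh[stacks])
  ds <- params$init_ds + sum(params$ds[stacks])
  ends <- c(substr(rna, 1L, 1L), substr(rna, n, n))
  n_term_au <- sum(ends %in% c("A", "U"))
  dh <- dh + n_term_au * params$term_au_dh
  ds <- ds + n_term_au * params$term_au_ds
  self_comp <- identical(rna, .rc_chr(rna, rna = TRUE))
  if (self_comp) ds <- ds + params$sym_ds
  list(dh = dh, ds = ds, self_complementary = self_comp)
}

#' Nearest-neighbor melting temperature
#'
#' Tm of the duplex formed by `sequence` and its perfect complement:
#' `Tm = dH / (dS + R ln(C/x)) - 273.15`, with the SantaLucia-style
#' entropic salt correction `dS + 0.368 (n-1) ln[Na+]`. Self-complementary
#' duplexes receive the symmetry correction and `x = 1` (otherwise 4).
#'
#' @param sequence Nucleotide string, length >= 2.
#' @param params An `nn_table` (default: packaged RNA/RNA table).
#' @param conc Total strand concentration in mol/L (default 1e-6).
#' @param na Monovalent cation concentration in mol/L (default 0.1).
#' @return Melting temperature in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(sequence, params = default_nn_table(),
                                conc = 1e-6, na = 0.1) {
  sequence <- .check_seq(sequence, allow_n = FALSE)
  if (nchar(sequence) < 2L) stop("sequence must be at least 2 nt",
                                 call. = FALSE)
  s <- .nn_sum(sequence, params)
  n <- nchar(sequence)
  ds_salt <- s$ds + 0.368 * (n - 1L) * log(na)
  x <- if (s$self_complementary) 1 else 4
  1000 * s$dh / (ds_salt + 1.987 * log(conc / x)) - 273.15
}

#' Duplex free energy of a sequence against its perfect complement at 37 C
#'
#' @inheritParams tm_nearest_neighbor
#' @param initiation Include helix initiation and terminal A:U terms.
#' @return Free energy in kcal/mol.
#' @export
delta_g37 <- function(sequence, params = default_nn_table(),
                      initiation = TRUE) {
  sequence <- .check_seq(sequence, allow_n = FALSE)
  if (nchar(sequence) < 2L) stop("sequence must be at least 2 nt",
                                 call. = FALSE)
  if (initiation) {
    s <- .nn_sum(sequence, params)
    dg <- s$dh - 310.15 * s$ds / 1000
  } else {
    rna <- dna_to_rna(sequence)
    n <- nchar(rna)
    stacks <- substring(rna, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    dg <- sum(params$dh[stacks] - 310.15 * params$ds[stacks] / 1000)
  }
  unname(dg)
}

#' Best ungapped duplex between two oligos
#'
#' Screens every antiparallel alignment of `a` against `b` for the
#' best-scoring contiguous Watson-Crick complementary stretch, scored by
#' summing nearest-neighbor stack free energies at 37 C. This is the
#' standard oligo-dimer screen: `duplex_score(a, a)` is the
#' self-dimerization score, `duplex_score(aon, target)` the binding energy
#' against a target window. A duplex requires at least two stacks (three
#' consecutive pairs); otherwise `delta_g = 0` ("no duplex"). Helix
#' initiation is deliberately excluded so the score is a pure stability
#' sum, exactly reproducible by hand.
#'
#' @param a,b Nucleotide strings (DNA or RNA), both 5' to 3'.
#' @param params An `nn_table`.
#' @return A `duplex_result` with fields `delta_g` (kcal/mol, <= 0),
#'   `tm` (Tm of the paired stretch, `NA` if no duplex), `paired_span`
#'   (list of 0-based half-open spans on `a` and `b`), `n_pairs`,
#'   `mismatches`.
#' @examples
#' duplex_score("ACGUACGU", reverse_complement("ACGUACGU", as = "RNA"))
#' @export
duplex_score <- function(a, b, params = default_nn_table()) {
  a <- .check_seq(a, allow_n = FALSE)
  b <- .check_seq(b, allow_n = FALSE)
  res <- duplex_scan_cpp(.encode_seq(a), .encode_seq(b), .stack_dg37(params))
  if (res$n_pairs == 0L) {
    out <- list(delta_g = 0, tm = NA_real_, n_pairs = 0L,
                paired_span = list(a = c(NA_integer_, NA_integer_),
                                   b = c(NA_integer_, NA_integer_)),
                mismatches = 0L)
  } else {
    span_seq <- .subseq0(dna_to_rna(a), res$a_start, res$a_end + 1L)
    out <- list(delta_g = res$delta_g,
                tm = tm_nearest_neighbor(span_seq, params),
                n_pairs = res$n_pairs,
                paired_span = list(a = c(res$a_start, res$a_end + 1L),
                                   b = c(res$b_start, res$b_end + 1L)),
                mismatches = 0L)
  }
  structure(out, class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  if (x$n_pairs == 0L) {
    cat("duplex: none (delta G = 0)\n")
  } else {
    cat(sprintf("duplex: %d bp, delta G(37C) = %.2f kcal/mol, Tm = %.1f C\n",
                x$n_pairs, x$delta_g, x$tm))
  }
  invisible(x)
}
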