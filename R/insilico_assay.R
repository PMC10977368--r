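# In-silico RT-PCR: exact-match amplicon prediction on wild-type and
# exon-skipped templates, nested (outer -> inner) semantics, a textual
# "virtual gel", and reference-gene-normalized qPCR ratios.

#' Construct a primer pair
#'
#' @param forward,reverse Primer sequences, both written 5' to 3'; the
#'   reverse primer is matched against the reverse complement of the
#'   template. Both must be at least 10 nt.
#' @param label Pair label.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward, reverse, label = "pair") {
  forward <- .check_seq(forward, allow_n = FALSE)
  reverse <- .check_seq(reverse, allow_n = FALSE)
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    stop("primers must be at least 10 nt", call. = FALSE)
  }
  structure(list(forward = rna_to_dna(forward),
                 reverse = rna_to_dna(reverse), label = label),
            class = "primer_pair")
}

#' Read primer pairs from a tab-delimited file
#'
#' Expects columns `label`, `forward`, `reverse` (header required).
#'
#' @param path File path.
#' @return A named list of [primer_pair] objects.
#' @export
read_primer_pairs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("label", "forward", "reverse") %in% colnames(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(tab$forward[i], tab$reverse[i], tab$label[i])
  })
  stats::setNames(out, tab$label)
}

# 0-based starts of exact matches of `pattern` in `template`.
.match_starts <- function(pattern, template) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(template))
  Biostrings::start(m) - 1L
}

.pcr_one_round <- function(template, pair, template_id, round, offset = 0L) {
  f_starts <- .match_starts(pair$forward, template)
  r_rc <- reverse_complement(pair$reverse)
  r_starts <- .match_starts(r_rc, template)
  r_ends <- r_starts + nchar(r_rc) # half-open ends of the reverse footprint
  if (length(f_starts) > 1L || length(r_starts) > 1L) {
    warning(sprintf("primer pair '%s' has multiple sites on %s (%d forward, %d reverse); reporting all products",
                    pair$label, template_id, length(f_starts),
                    length(r_starts)), call. = FALSE)
  }
  rows <- list()
  for (fs in f_starts) {
    for (re in r_ends) {
      # amplicon includes both primer footprints
      if (re - fs > 0L && re - nchar(r_rc) >= fs) {
        rows[[length(rows) + 1L]] <- data.frame(
          template = template_id, primer_pair = pair$label, round = round,
          fwd_start = fs + offset, rev_end = re + offset,
          length = re - fs)
      }
    }
  }
  if (length(rows) == 0L) {
    data.frame(template = character(0), primer_pair = character(0),
               round = character(0), fwd_start = integer(0),
               rev_end = integer(0), length = integer(0))
  } else {
    do.call(rbind, rows)
  }
}

#' Predict PCR products, optionally with nested semantics
#'
#' Locates exact, correctly oriented primer sites on the template and
#' reports every forward/reverse combination yielding a positive-length
#' amplicon. Product length includes both primer footprints, so reported
#' sizes compare directly to gel band sizes. When an inner pair is given,
#' inner products are searched within each outer product (nested PCR);
#' their coordinates are reported on the original template. Primers with
#' multiple sites trigger a multiplicity warning and all products are
#' reported; primers with no site yield no products.
#'
#' @param template Template sequence (e.g. a cDNA; DNA alphabet).
#' @param outer A [primer_pair] for the first round.
#' @param inner Optional [primer_pair] for the nested second round.
#' @param template_id Label used in the output.
#' @return A data frame with columns `template`, `primer_pair`, `round`
#'   (`"outer"`/`"inner"`), `fwd_start`, `rev_end` (0-based half-open on
#'   the template) and `length` in bp.
#' @export
pcr_products <- function(template, outer, inner = NULL,
                         template_id = "template") {
  template <- rna_to_dna(.check_seq(template))
  stopifnot(inherits(outer, "primer_pair"))
  out <- .pcr_one_round(template, outer, template_id, "outer")
  if (!is.null(inner)) {
    stopifnot(inherits(inner, "primer_pair"))
    for (i in seq_len(nrow(out))) {
      sub <- .subseq0(template, out$fwd_start[i], out$rev_end[i])
      out <- rbind(out, .pcr_one_round(sub, inner, template_id, "inner",
                                       offset = out$fwd_start[i]))
    }
    out <- unique(out)
  }
  rownames(out) <- NULL
  out
}

#' Textual "virtual gel" of predicted products
#'
#' Prints products sorted by decreasing length, mimicking band order on an
#' agarose gel.
#'
#' @param products Data frame from [pcr_products()] (possibly several
#'   templates combined with `rbind`).
#' @return The sorted data frame, invisibly.
#' @export
virtual_gel <- function(products) {
  p <- products[order(-products$length), , drop = FALSE]
  cat("virtual gel (largest first)\n")
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %5d bp  %-12s %-10s %s\n", p$length[i],
                p$template[i], p$round[i], p$primer_pair[i]))
  }
  invisible(p)
}

#' Reference-gene-normalized qPCR relative expression
#'
#' Computes the efficiency-corrected expression ratio
#' `E_t^(-Cq_t) / geomean_r( E_r^(-Cq_r) )` per sample, with the
#' denominator the geometric mean over the reference (housekeeping) genes.
#' When a calibrator sample is given, all ratios are normalized so the
#' calibrator equals 1.
#'
#' @param target_cq Numeric vector of target-gene Cq values (one per
#'   sample).
#' @param reference_cq Reference-gene Cq values: a numeric vector (one
#'   reference) or a matrix/data frame with one row per reference gene and
#'   one column per sample.
#' @param target_eff Amplification efficiency of the target assay, in
#'   (1, 2].
#' @param reference_eff Efficiencies of the reference assays (recycled).
#' @param calibrator Optional index of the calibrator sample.
#' @return Numeric vector of relative expression ratios.
#' @examples
#' qpcr_relative(20, 20)            # 1
#' qpcr_relative(19, 20)            # 2
#' @export
qpcr_relative <- function(target_cq, reference_cq, target_eff = 2,
                          reference_eff = 2, calibrator = NULL) {
  if (missing(reference_cq) || length(reference_cq) == 0L) {
    stop("at least one reference gene is required", call. = FALSE)
  }
  if (is.vector(reference_cq)) {
    reference_cq <- matrix(reference_cq, nrow = 1L)
  }
  reference_cq <- as.matrix(reference_cq)
  if (anyNA(reference_cq) || anyNA(target_cq)) {
    stop("missing Cq values", call. = FALSE)
  }
  if (ncol(reference_cq) != length(target_cq)) {
    stop("reference Cq values must cover every sample", call. = FALSE)
  }
  effs <- c(target_eff, rep_len(reference_eff, nrow(reference_cq)))
  if (any(effs <= 1 | effs > 2)) {
    stop("efficiencies must lie in (1, 2]", call. = FALSE)
  }
  ref_eff <- rep_len(reference_eff, nrow(reference_cq))
  num <- target_eff^(-target_cq)
  den <- apply(ref_eff^(-reference_cq), 2L, .geometric_mean)
  ratio <- num / den
  if (!is.null(calibrator)) ratio <- ratio / ratio[calibrator]
  ratio
}
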