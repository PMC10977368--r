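# Secondary-structure prediction and per-base openness (ss-count) profiles.
#
# The fold is a stacking-weighted maximum-score nested-structure dynamic
# program over Watson-Crick plus G:U pairs: only stacked pairs score, so
# isolated pairs are never kept, and the minimum hairpin loop is 3 nt. It is
# a deliberately simple, exactly testable stand-in for a thermodynamic
# folding engine; any engine honouring the same contract (a set of nested
# pairs per structure) can be substituted upstream of the ss-count profile.

.dotbracket <- function(n, pairs) {
  db <- rep(".", n)
  if (nrow(pairs) > 0L) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

#' Predict the maximum-score nested secondary structure
#'
#' Folds an RNA sequence with a stacking-weighted Nussinov-style dynamic
#' program: a helix stack formed by the adjacent pairs (i, j) and
#' (i+1, j-1) scores the sum of the two pair strengths (G:C 1.5, A:U 1.0,
#' G:U 0.5), unstacked pairs score nothing, and hairpin loops must hold at
#' least `min_loop` unpaired bases. The result is deterministic: ties are
#' broken toward fewer pairs and 5'-most helices.
#'
#' @param sequence RNA (or DNA; T is read as U) string over A/C/G/U.
#' @param min_loop Minimum number of unpaired bases closed by a pair.
#' @param banned_pairs Optional integer matrix (m x 2) of 1-based (i, j)
#'   pairs that may not form; used internally for suboptimal re-folds.
#' @return A `secondary_structure` object with fields `pairs` (m x 2
#'   integer matrix of 1-based indices, i < j), `dotbracket`, `score`,
#'   `sequence`.
#' @examples
#' fold_mfe("GGGAAACCC")$dotbracket
#' @export
fold_mfe <- function(sequence, min_loop = 3L, banned_pairs = NULL) {
  sequence <- .check_seq(sequence, allow_n = FALSE)
  sequence <- dna_to_rna(sequence)
  code <- .encode_seq(sequence)
  banned <- if (is.null(banned_pairs)) {
    matrix(integer(0), ncol = 2L)
  } else {
    matrix(as.integer(banned_pairs), ncol = 2L) - 1L
  }
  res <- fold_nussinov_cpp(code, as.integer(min_loop), banned)
  pairs <- res$pairs + 1L
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  structure(list(sequence = sequence,
                 pairs = pairs,
                 dotbracket = .dotbracket(nchar(sequence), pairs),
                 score = res$score,
                 min_loop = as.integer(min_loop)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary structure: %d nt, %d pair(s), score %.1f\n",
              nchar(x$sequence), nrow(x$pairs), x$score))
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  invisible(x)
}

# Suboptimal structures by pair exclusion: re-fold once with each pair of
# the optimal structure banned, keep distinct structures scoring at least
# `tolerance` * optimal. Deterministic: sorted by score, then dot-bracket.
.suboptimal_ensemble <- function(mfe, k, tolerance) {
  structures <- list(mfe)
  if (k > 1L && nrow(mfe$pairs) > 0L && mfe$score > 0) {
    seen <- mfe$dotbracket
    cand <- list()
    for (r in seq_len(nrow(mfe$pairs))) {
      alt <- fold_mfe(mfe$sequence, min_loop = mfe$min_loop,
                      banned_pairs = mfe$pairs[r, , drop = FALSE])
      if (!(alt$dotbracket %in% seen) && alt$score >= tolerance * mfe$score) {
        seen <- c(seen, alt$dotbracket)
        cand[[length(cand) + 1L]] <- alt
      }
    }
    if (length(cand) > 0L) {
      ord <- order(-vapply(cand, `[[`, numeric(1), "score"),
                   vapply(cand, `[[`, character(1), "dotbracket"))
      structures <- c(structures, cand[ord][seq_len(min(k - 1L, length(cand)))])
    }
  }
  structures
}

#' Per-base openness profile over a structure ensemble
#'
#' Computes the ss-count style accessibility profile: for each base, the
#' fraction of ensemble structures in which it is unpaired. The ensemble is
#' the optimal structure plus up to `ensemble_size - 1` suboptimal
#' structures obtained by pair-exclusion re-folds, restricted to structures
#' scoring at least `suboptimal_tolerance` times the optimum. With
#' `ensemble_size = 1` the profile degenerates to the unpaired indicator of
#' the optimal structure. The procedure is fully deterministic.
#'
#' @inheritParams fold_mfe
#' @param ensemble_size Maximum number of structures in the ensemble
#'   (default 10).
#' @param suboptimal_tolerance Minimum score of a retained suboptimal
#'   structure, as a fraction of the optimal score (default 0.95).
#' @return An `sscount_profile` object with fields `openness` (numeric in
#'   `[0, 1]`, one value per base), `n_structures`, `sequence`,
#'   `structures`.
#' @examples
#' ss_count_profile("GGGAAACCC", ensemble_size = 1)$openness
#' @export
ss_count_profile <- function(sequence, ensemble_size = 10L,
                             suboptimal_tolerance = 0.95, min_loop = 3L) {
  ensemble_size <- as.integer(ensemble_size)
  if (is.na(ensemble_size) || ensemble_size < 1L) {
    stop("ensemble_size must be >= 1", call. = FALSE)
  }
  mfe <- fold_mfe(sequence, min_loop = min_loop)
  structures <- .suboptimal_ensemble(mfe, ensemble_size, suboptimal_tolerance)
  n <- nchar(mfe$sequence)
  unpaired <- vapply(structures, function(s) {
    u <- rep(1L, n)
    if (nrow(s$pairs) > 0L) u[as.vector(s$pairs)] <- 0L
    u
  }, integer(n))
  openness <- rowMeans(matrix(unpaired, nrow = n))
  structure(list(openness = openness,
                 n_structures = length(structures),
                 sequence = mfe$sequence,
                 structures = structures),
            class = "sscount_profile")
}

#' @export
print.sscount_profile <- function(x, ...) {
  cat(sprintf("ss-count profile: %d nt over %d structure(s); mean openness %.2f\n",
              nchar(x$sequence), x$n_structures, mean(x$openness)))
  invisible(x)
}

#' @export
as.data.frame.sscount_profile <- function(x, ...) {
  data.frame(position = seq_along(x$openness) - 1L,
             base = strsplit(x$sequence, "", fixed = TRUE)[[1L]],
             openness = x$openness)
}

#' Write an openness profile as tab-delimited text
#'
#' Emits the classic ss-count table layout: position (0-based), base,
#' openness fraction.
#'
#' @param profile An `sscount_profile` from [ss_count_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sscount <- function(profile, path) {
  stopifnot(inherits(profile, "sscount_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
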