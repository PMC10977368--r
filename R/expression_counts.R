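# Counts-per-million (CPM) pre-filtering of a gene count matrix -- the
# standard gate applied before differential-expression model fitting.
# Model fitting itself is deliberately out of scope here.

#' Validate a count matrix
#'
#' @param counts Genes x samples matrix of nonnegative counts with row and
#'   column names.
#' @param groups Optional factor/character vector of sample group labels
#'   (one per column).
#' @return The validated integer-mode matrix, with `groups` attached as an
#'   attribute when given.
#' @export
count_matrix <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be nonnegative and complete", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(counts))
    attr(counts, "groups") <- as.character(groups)
  }
  counts
}

#' Filter genes by average counts-per-million
#'
#' Computes `CPM = count / library size * 1e6` (library size = column
#' sum), keeps genes whose mean CPM exceeds `min_avg_cpm` (strictly; a
#' gene at exactly the threshold is dropped), and returns the log2-CPM
#' matrix with a pseudo-count. With `per_group = TRUE` a gene is kept when
#' its mean CPM exceeds the threshold in at least one group.
#'
#' @param counts Genes x samples count matrix (see [count_matrix()]).
#' @param min_avg_cpm Retention threshold on mean CPM (default 5).
#' @param per_group Average within sample groups instead of across all
#'   samples.
#' @param groups Group labels; defaults to the `groups` attribute of
#'   `counts`.
#' @param prior Pseudo-count added before taking log2 (default 0.5).
#' @return A list with `counts` (filtered), `cpm` (all genes), `log2cpm`
#'   (filtered genes), `keep` (logical per gene), `library_sizes`.
#' @examples
#' m <- matrix(c(10L, 10L, 0L, 1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' m <- rbind(m, matrix(100L, 98, 2, dimnames = list(paste0("x", 1:98), NULL)))
#' cpm_filter(m)$keep[1:2]
#' @export
cpm_filter <- function(counts, min_avg_cpm = 5, per_group = FALSE,
                       groups = attr(counts, "groups"), prior = 0.5) {
  counts <- count_matrix(counts, groups)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("library size is zero for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(counts, 2L, lib, `/`) * 1e6
  if (per_group) {
    if (is.null(groups)) stop("per_group filtering needs group labels",
                              call. = FALSE)
    grp_means <- vapply(unique(groups), function(g) {
      rowMeans(cpm[, groups == g, drop = FALSE])
    }, numeric(nrow(cpm)))
    keep <- apply(grp_means, 1L, max) > min_avg_cpm
  } else {
    keep <- rowMeans(cpm) > min_avg_cpm
  }
  list(counts = counts[keep, , drop = FALSE],
       cpm = cpm,
       log2cpm = log2(cpm[keep, , drop = FALSE] + prior),
       keep = keep,
       library_sizes = lib)
}

#' Read a tab-delimited count matrix and sample metadata
#'
#' @param counts_path Tab-delimited counts with gene ids in the first
#'   column and a header row of sample ids.
#' @param metadata_path Optional two-column tab-delimited file mapping
#'   sample id to group.
#' @return A count matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(counts_path, metadata_path = NULL) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE)
  groups <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    groups <- md[[2L]][match(colnames(tab), md[[1L]])]
  }
  count_matrix(as.matrix(tab), groups)
}
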