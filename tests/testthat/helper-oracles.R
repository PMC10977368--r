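# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: structures are enumerated explicitly,
# thermodynamic sums are recomputed term by term from the parameter file,
# and PWM windows are rescored with plain loops.

# -- exhaustive folding oracle ------------------------------------------------

.orc_strength <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) return(1.5)
  if (p %in% c("AU", "UA")) return(1.0)
  if (p %in% c("GU", "UG")) return(0.5)
  0
}

# every nested structure over chars[i..j] (1-based, inclusive) as a list of
# 2-column pair matrices; memoized per call
oracle_all_structures <- function(chars, min_loop = 3L) {
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), ncol = 2L)
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(empty))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j) # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (.orc_strength(chars[i], chars[k]) > 0) {
        left <- rec(i + 1L, k - 1L)
        right <- if (k + 1L <= j) rec(k + 1L, j) else list(empty)
        for (L in left) for (R in right) {
          out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# score of one structure: sum over stacked adjacent pairs
oracle_structure_score <- function(chars, pairs) {
  if (nrow(pairs) < 2L) return(0)
  key <- paste(pairs[, 1L], pairs[, 2L])
  s <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (paste(i + 1L, j - 1L) %in% key) {
      s <- s + .orc_strength(chars[i], chars[j]) +
        .orc_strength(chars[i + 1L], chars[j - 1L])
    }
  }
  s
}

oracle_fold_score <- function(sequence, min_loop = 3L) {
  chars <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1L]]
  structs <- oracle_all_structures(chars, min_loop)
  max(vapply(structs, function(p) oracle_structure_score(chars, p),
             numeric(1)))
}

# -- nearest-neighbor summation oracle ---------------------------------------

# read the shipped parameter file directly, bypassing read_nn_table
oracle_nn_params <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "nn_rna_xia1998.txt",
                        package = "aondesign")
    tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    rownames(tab) <- tab$stack
    cache <<- tab
    cache
  }
})

oracle_nn_sum <- function(sequence) {
  tab <- oracle_nn_params()
  s <- chartr("T", "U", toupper(sequence))
  ch <- strsplit(s, "")[[1L]]
  dh <- tab["INIT", "dH"]; ds <- tab["INIT", "dS"]
  for (i in seq_len(length(ch) - 1L)) {
    st <- paste0(ch[i], ch[i + 1L])
    dh <- dh + tab[st, "dH"]; ds <- ds + tab[st, "dS"]
  }
  for (e in c(ch[1L], ch[length(ch)])) {
    if (e %in% c("A", "U")) {
      dh <- dh + tab["TERM_AU", "dH"]; ds <- ds + tab["TERM_AU", "dS"]
    }
  }
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  selfc <- identical(ch, rev(unname(comp[ch])))
  if (selfc) ds <- ds + tab["SYM", "dS"]
  list(dh = dh, ds = ds, self_complementary = selfc)
}

oracle_tm <- function(sequence, conc = 1e-6, na = 0.1) {
  s <- oracle_nn_sum(sequence)
  n <- nchar(sequence)
  x <- if (s$self_complementary) 1 else 4
  1000 * s$dh / (s$ds + 0.368 * (n - 1) * log(na) +
                   1.987 * log(conc / x)) - 273.15
}

# stack-sum free energy of a perfect duplex (no initiation), as the dimer
# screen defines it
oracle_stack_dg <- function(sequence) {
  tab <- oracle_nn_params()
  ch <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1L]]
  dg <- 0
  for (i in seq_len(length(ch) - 1L)) {
    st <- paste0(ch[i], ch[i + 1L])
    dg <- dg + tab[st, "dH"] - 310.15 * tab[st, "dS"] / 1000
  }
  dg
}

# -- naive PWM rescoring ------------------------------------------------------

oracle_pwm_hits <- function(sequence, motif) {
  s <- chartr("T", "U", toupper(sequence))
  ch <- strsplit(s, "")[[1L]]
  w <- ncol(motif$matrix)
  hits <- integer(0)
  if (length(ch) >= w) {
    for (p in 1:(length(ch) - w + 1L)) {
      sc <- 0
      for (q in 1:w) sc <- sc + motif$matrix[ch[p + q - 1L], q]
      if (!is.na(sc) && sc >= motif$threshold) hits <- c(hits, p - 1L)
    }
  }
  hits
}

# random sequence helper
rseq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
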