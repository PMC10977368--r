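# Antisense candidate enumeration, filtering and composite ranking.
#
# The selection logic mirrors how splice-switching oligos are chosen in
# practice: slide every allowed window over the target exon (plus intronic
# flanks), keep windows that are partly open in the predicted structure
# ensemble and rich in exonic splicing enhancers, and screen the antisense
# sequences on GC%, Tm, target binding energy and self/cross-dimerization.
# Because published selections are qualitative, the composite score is an
# explicit, documented weighted sum of min-max-normalized metrics.

#' Design configuration
#'
#' Collects every tunable of the candidate pipeline with documented
#' defaults. Antisense oligos of this class are conventionally 18-30 nt
#' long; requesting lengths outside that range is an error unless
#' `allow_length_override = TRUE`.
#'
#' @param length_min,length_max Candidate length range in nt (default
#'   18-30).
#' @param gc_min,gc_max Hard GC-fraction bounds (default 0.40-0.60).
#' @param tm_min,tm_max Hard Tm bounds in degrees C (default 45-90).
#' @param max_self_dimer Maximum tolerated self-dimer stability magnitude
#'   in kcal/mol: a candidate fails when its self-dimer delta G is below
#'   `-max_self_dimer` (default 8).
#' @param max_cross_dimer Same bound for dimers against co-administered
#'   oligos (default 8).
#' @param min_mean_openness Hard lower bound on mean ensemble openness of
#'   the target window; 0.5 operationalizes "partly open" (default 0.5).
#' @param min_ese_density Hard lower bound on ESE hits per nt in the
#'   window (default 0: ESE content is rewarded in the score, not gated).
#' @param w_openness,w_ese,w_thermo Composite score weights (defaults 0.3,
#'   0.3, 0.4; the thermodynamic weight is split evenly over its
#'   sub-metrics). Nonnegative.
#' @param seed Random seed recorded in the config; the default pipeline is
#'   deterministic and does not consume it.
#' @param allow_length_override Permit lengths outside 18-30 nt.
#' @return A `design_config` object (a list).
#' @export
design_config <- function(length_min = 18L, length_max = 30L,
                          gc_min = 0.40, gc_max = 0.60,
                          tm_min = 45, tm_max = 90,
                          max_self_dimer = 8, max_cross_dimer = 8,
                          min_mean_openness = 0.5, min_ese_density = 0,
                          w_openness = 0.3, w_ese = 0.3, w_thermo = 0.4,
                          seed = 1L, allow_length_override = FALSE) {
  length_min <- as.integer(length_min)
  length_max <- as.integer(length_max)
  if (length_min > length_max) stop("length_min > length_max", call. = FALSE)
  if (!allow_length_override && (length_min < 18L || length_max > 30L)) {
    stop("candidate lengths must lie within the conventional 18-30 nt ",
         "range for splice-switching oligos ",
         "(set allow_length_override = TRUE to relax)", call. = FALSE)
  }
  if (any(c(w_openness, w_ese, w_thermo) < 0)) {
    stop("score weights must be nonnegative", call. = FALSE)
  }
  structure(list(length_min = length_min, length_max = length_max,
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 max_self_dimer = max_self_dimer,
                 max_cross_dimer = max_cross_dimer,
                 min_mean_openness = min_mean_openness,
                 min_ese_density = min_ese_density,
                 w_openness = w_openness, w_ese = w_ese,
                 w_thermo = w_thermo, seed = as.integer(seed),
                 allow_length_override = allow_length_override),
            class = "design_config")
}

#' Read a design configuration from YAML
#'
#' @param path YAML file whose keys are [design_config()] arguments.
#' @return A `design_config`.
#' @export
read_design_config <- function(path) {
  do.call(design_config, yaml::yaml.load_file(path))
}

#' Enumerate antisense candidate windows
#'
#' Slides windows of every allowed length over the target region; each
#' window is paired with its antisense sequence (reverse complement,
#' written as RNA). Candidates are ordered by window start, then length.
#'
#' @param region A `target_region` from [extract_target_region()], or a
#'   plain sequence string.
#' @param cfg A [design_config()].
#' @return A data frame with columns `start`, `end` (0-based half-open on
#'   the region), `length`, `target_seq` (sense, DNA), `aon` (antisense,
#'   RNA), and exon/flank overlap columns when `region` carries an exon
#'   span.
#' @export
enumerate_candidates <- function(region, cfg = design_config()) {
  seqstr <- if (inherits(region, "target_region")) region$sequence else
    .check_seq(region)
  n <- nchar(seqstr)
  if (n <= cfg$length_min) {
    stop("region (", n, " nt) is not longer than the minimum candidate ",
         "length (", cfg$length_min, " nt)", call. = FALSE)
  }
  lens <- seq(cfg$length_min, min(cfg$length_max, n))
  rows <- list()
  for (s in 0:(n - cfg$length_min)) {
    for (L in lens) {
      if (s + L > n) next
      rows[[length(rows) + 1L]] <- c(s, L)
    }
  }
  m <- do.call(rbind, rows)
  # order: start, then length
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  target <- substring(seqstr, m[, 1L] + 1L, m[, 1L] + m[, 2L])
  out <- data.frame(start = m[, 1L], end = m[, 1L] + m[, 2L],
                    length = m[, 2L],
                    target_seq = target,
                    aon = vapply(target, .rc_chr, character(1),
                                 rna = TRUE, USE.NAMES = FALSE))
  if (inherits(region, "target_region")) {
    ex <- region$exon_span
    ov <- pmax(0L, pmin(out$end, ex[2L]) - pmax(out$start, ex[1L]))
    out$exon_overlap <- ov
    out$intron_overlap <- out$length - ov
  }
  out
}

# Min-max normalization with a spread floor: when a metric barely varies
# across the passing set it carries no information, and rescaling it to
# [0, 1] would amplify numerical noise into the composite score, so it is
# mapped to a neutral constant instead. Floors are stated per metric in
# score_and_rank.
.minmax <- function(x, floor = 0) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1L]) || r[2L] - r[1L] <= floor) {
    return(rep(0.5, length(x)))
  }
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Score, filter and rank antisense candidates
#'
#' Annotates every candidate with its metrics (GC fraction, Tm, target
#' binding delta G, self- and cross-dimer delta G, mean window openness,
#' ESE and ESS densities), applies the hard filters of the configuration,
#' and ranks the passing candidates by a composite score: openness and net
#' ESE density are rewarded, dimer stability and deviation of GC/Tm from
#' the centre of their allowed bands are penalized, binding stability is
#' rewarded. Metrics are min-max normalized over the passing set before
#' weighting; ties are broken toward the 5'-most window start. Failing
#' candidates remain in the report with their failure flags and `NA` rank.
#'
#' @param candidates Candidate data frame from [enumerate_candidates()].
#' @param profile An `sscount_profile` computed on the same region.
#' @param hits Motif-hit data frame from [scan_motifs()] on the same
#'   region.
#' @param cfg A [design_config()].
#' @param cross_aons Character vector of co-administered oligo sequences
#'   to screen cross-dimerization against (empty for none).
#' @param params Nearest-neighbor table.
#' @return A `design_report`: list with `candidates` (annotated, ranked
#'   data frame), `n_input`, `filter_counts` (failures per criterion),
#'   `n_pass`, `config`.
#' @export
score_and_rank <- function(candidates, profile, hits, cfg = design_config(),
                           cross_aons = character(0),
                           params = default_nn_table()) {
  stopifnot(inherits(profile, "sscount_profile"))
  if (nrow(candidates) > 0 &&
      max(candidates$end) > length(profile$openness)) {
    stop("profile was computed on a shorter sequence than the candidates",
         call. = FALSE)
  }
  cum_open <- cumsum(c(0, profile$openness))
  k <- nrow(candidates)
  gc <- vapply(candidates$aon, gc_content, numeric(1), USE.NAMES = FALSE)
  tm <- vapply(candidates$aon, tm_nearest_neighbor, numeric(1),
               params = params, USE.NAMES = FALSE)
  binding <- vapply(seq_len(k), function(i) {
    duplex_score(candidates$aon[i], candidates$target_seq[i],
                 params = params)$delta_g
  }, numeric(1))
  self_dg <- vapply(candidates$aon, function(a) {
    duplex_score(a, a, params = params)$delta_g
  }, numeric(1), USE.NAMES = FALSE)
  cross_dg <- if (length(cross_aons) == 0L) rep(0, k) else
    vapply(candidates$aon, function(a) {
      min(vapply(cross_aons, function(b) {
        duplex_score(a, b, params = params)$delta_g
      }, numeric(1)))
    }, numeric(1), USE.NAMES = FALSE)
  mean_open <- (cum_open[candidates$end + 1L] -
                  cum_open[candidates$start + 1L]) / candidates$length
  ese <- vapply(seq_len(k), function(i) {
    ese_density(hits, candidates$start[i], candidates$length[i])
  }, numeric(1))
  ess <- vapply(seq_len(k), function(i) {
    motif_density(hits, candidates$start[i], candidates$length[i], "ESS")
  }, numeric(1))

  flags <- data.frame(
    gc_ok = gc >= cfg$gc_min & gc <= cfg$gc_max,
    tm_ok = tm >= cfg$tm_min & tm <= cfg$tm_max,
    self_dimer_ok = self_dg >= -cfg$max_self_dimer,
    cross_dimer_ok = cross_dg >= -cfg$max_cross_dimer,
    openness_ok = mean_open >= cfg$min_mean_openness,
    ese_ok = ese >= cfg$min_ese_density)
  pass <- Reduce(`&`, flags)

  out <- cbind(candidates,
               data.frame(gc = gc, tm = tm, binding_dg = binding,
                          self_dimer_dg = self_dg, cross_dimer_dg = cross_dg,
                          mean_openness = mean_open, ese_density = ese,
                          ess_density = ess),
               flags, pass = pass)
  out$score <- NA_real_
  out$rank <- NA_integer_

  if (any(pass)) {
    p <- which(pass)
    gc_mid <- (cfg$gc_min + cfg$gc_max) / 2
    tm_mid <- (cfg$tm_min + cfg$tm_max) / 2
    # spread floors: 0.1 on fractions, 2 kcal/mol on free energies,
    # 2 C on Tm
    thermo <- cbind(.minmax(-binding[p], 2),     # stronger binding better
                    .minmax(self_dg[p], 2),      # weaker self-dimer better
                    .minmax(cross_dg[p], 2),
                    .minmax(-abs(gc[p] - gc_mid), 0.05),
                    .minmax(-abs(tm[p] - tm_mid), 2))
    score <- cfg$w_openness * .minmax(mean_open[p], 0.1) +
      cfg$w_ese * .minmax(ese[p] - ess[p], 0.05) +
      cfg$w_thermo * rowMeans(thermo)
    out$score[p] <- score
    ord <- p[order(-score, candidates$start[p], candidates$length[p])]
    out$rank[ord] <- seq_along(ord)
  }

  filter_counts <- vapply(flags, function(f) sum(!f), integer(1))
  structure(list(candidates = out[order(out$rank, out$start, out$length), ,
                                  drop = FALSE],
                 n_input = k,
                 filter_counts = filter_counts,
                 n_pass = sum(pass),
                 config = cfg),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("design report: %d candidate(s), %d passing hard filters\n",
              x$n_input, x$n_pass))
  cat("  failures per criterion:\n")
  for (nm in names(x$filter_counts)) {
    cat(sprintf("    %-16s %d\n", nm, x$filter_counts[[nm]]))
  }
  if (x$n_pass > 0L) {
    top <- x$candidates[1L, ]
    cat(sprintf("  top candidate: [%d, %d) %d nt  %s  (score %.3f)\n",
                top$start, top$end, top$length, top$aon, top$score))
  }
  invisible(x)
}

#' Run the full design pipeline on one target exon
#'
#' Convenience wrapper: extracts the target region, computes the openness
#' profile and motif hits, enumerates candidates and returns the ranked
#' report.
#'
#' @inheritParams extract_target_region
#' @param cfg A [design_config()].
#' @param motif_library Motif library as returned by
#'   [default_motif_library()].
#' @param cross_aons Co-administered oligo sequences for the cross-dimer
#'   screen.
#' @param ensemble_size,suboptimal_tolerance Passed to
#'   [ss_count_profile()].
#' @param verbose Log per-stage counts to the console.
#' @return A `design_report` whose `region`, `profile` and `hits` fields
#'   carry the intermediates.
#' @export
design_aons <- function(t, exon_index, genome, flank = 50L,
                        cfg = design_config(),
                        motif_library = default_motif_library(),
                        cross_aons = character(0),
                        ensemble_size = 10L, suboptimal_tolerance = 0.95,
                        verbose = FALSE) {
  region <- extract_target_region(t, exon_index, genome, flank = flank)
  profile <- ss_count_profile(region$sequence, ensemble_size = ensemble_size,
                              suboptimal_tolerance = suboptimal_tolerance)
  hits <- scan_motifs(region$sequence, matrices = motif_library$matrices,
                      hexamer_sets = motif_library$hexamer_sets)
  cands <- enumerate_candidates(region, cfg)
  if (verbose) {
    message(sprintf("region %d nt; %d motif hits; %d candidates enumerated",
                    nchar(region$sequence), nrow(hits), nrow(cands)))
  }
  report <- score_and_rank(cands, profile, hits, cfg,
                           cross_aons = cross_aons)
  if (verbose) {
    message(sprintf("%d candidates pass hard filters", report$n_pass))
  }
  report$region <- region
  report$profile <- profile
  report$hits <- hits
  report
}

#' Write a design report as tab-delimited text or JSON
#'
#' @param report A `design_report`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "design_report"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report$candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(n_input = report$n_input,
                              n_pass = report$n_pass,
                              filter_counts = as.list(report$filter_counts),
                              candidates = report$candidates),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Render an antisense sequence in 2'-O-methyl phosphorothioate notation
#'
#' Normalizes an oligo to the RNA alphabet (uppercase, T written as U) and
#' tags it with the 2OMePS chemistry label used for splice-switching
#' oligos. Idempotent.
#'
#' @param antisense Nucleotide string.
#' @return The RNA-alphabet sequence with a `chemistry` attribute, class
#'   `omeps_oligo`.
#' @examples
#' to_2omeps("ACGT")
#' @export
to_2omeps <- function(antisense) {
  s <- .check_seq(antisense, allow_n = FALSE)
  out <- dna_to_rna(s)
  attr(out, "chemistry") <- "2OMePS"
  class(out) <- "omeps_oligo"
  out
}

#' @export
print.omeps_oligo <- function(x, ...) {
  cat(sprintf("5'-%s-3' (%s)\n", unclass(x)[1L], attr(x, "chemistry")))
  invisible(x)
}
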