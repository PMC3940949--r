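#' Windowing configuration
#'
#' @param window_size Window width in bp (default 10000).
#' @param drop_partial Drop the trailing partial window (default TRUE);
#'   features overlapping it contribute only their in-range half.
#' @return A `window_config` list.
#' @export
window_config <- function(window_size = 10000L, drop_partial = TRUE) {
  stopifnot(window_size > 0)
  structure(list(window_size = as.integer(window_size),
                 drop_partial = isTRUE(drop_partial)),
            class = "window_config")
}

#' Assign features to windows with the half-count boundary rule
#'
#' A feature entirely inside one window adds 1 to it; a feature spanning a
#' window boundary adds 1/2 to the window holding its first base and 1/2 to
#' the window holding its last base (features longer than a window, which
#' should not occur, likewise split between first and last). With
#' `drop_partial`, counts falling in the trailing partial window are lost.
#' Intervals are 0-based half-open.
#'
#' @param features Data frame with `start`, `end` columns within
#'   `[0, chrom_length)`.
#' @param chrom_length Chromosome length in bp.
#' @param cfg A [window_config()].
#' @return Numeric vector of per-window counts (possibly half-integral),
#'   length `floor(chrom_length / window_size)` when dropping the partial
#'   window.
#' @export
assign_counts <- function(features, chrom_length, cfg = window_config()) {
  W <- cfg$window_size
  n_win <- if (cfg$drop_partial) chrom_length %/% W
           else as.integer(ceiling(chrom_length / W))
  counts <- numeric(n_win)
  if (nrow(features) == 0) return(counts)
  if (any(features$start < 0 | features$end > chrom_length |
          features$end <= features$start))
    stop("features must be non-empty intervals within [0, chromosome length)")
  w1 <- features$start %/% W            # window of first base
  w2 <- (features$end - 1L) %/% W       # window of last base
  whole <- w1 == w2
  add <- function(w, val) {
    ok <- w < n_win
    if (any(ok)) {
      t <- tapply(val[ok], w[ok], sum)
      counts[as.integer(names(t)) + 1L] <<- counts[as.integer(names(t)) + 1L] + as.numeric(t)
    }
  }
  add(w1[whole], rep(1, sum(whole)))
  add(w1[!whole], rep(0.5, sum(!whole)))
  add(w2[!whole], rep(0.5, sum(!whole)))
  counts
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; two-sided p from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom. Constant input is an
#' error (r undefined).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = max(p, .Machine$double.xmin), n = n)
}

#' Windowed bend/site profiles and their correlations
#'
#' Partitions the chromosome into non-overlapping windows, counts predicted
#' bends and per-NAP binding sites with the half-count boundary rule, and
#' returns the window table together with one Pearson correlation (sites vs
#' bends) per NAP. Counts are raw: no correction for composition, codon
#' bias, gene content or any other factor.
#'
#' @param g A `genome_sequence`.
#' @param bends Data frame with `start`, `end` (from [detect_bends()]).
#' @param hits_list Named list of hit data frames; each needs `start` and
#'   either an `end` column or a `width` attribute (hit data frames from
#'   [scan_genome()] are given their width via `hit_intervals()`).
#' @param cfg A [window_config()].
#' @return List `table` (window_index, start, end, n_bends, n_<NAP>...) and
#'   `correlations` (named list of [pearson_cor()] results).
#' @export
correlate_profiles <- function(g, bends, hits_list, cfg = window_config()) {
  n_win <- g$length %/% cfg$window_size
  if (n_win < 3) stop("fewer than 3 windows; sequence too short")
  bc <- assign_counts(bends, g$length, cfg)
  tab <- data.frame(window_index = seq_len(n_win) - 1L,
                    start = (seq_len(n_win) - 1L) * cfg$window_size,
                    end = seq_len(n_win) * cfg$window_size,
                    n_bends = bc)
  cors <- list()
  for (nm in names(hits_list)) {
    h <- hits_list[[nm]]
    if (is.null(h$end)) stop("hit list '", nm, "' lacks an end column")
    sc <- assign_counts(h, g$length, cfg)
    tab[[paste0("n_", nm)]] <- sc
    cors[[nm]] <- pearson_cor(sc, bc)
  }
  list(table = tab, correlations = cors)
}

#' Turn scan hits into intervals
#'
#' Adds the `end` column (`start + width`) expected by
#' [correlate_profiles()].
#'
#' @param hits Data frame from [scan_genome()].
#' @param width Motif width in bp.
#' @return Data frame with `start`, `end`, `strand`, `score`.
#' @export
hit_intervals <- function(hits, width) {
  data.frame(start = hits$start, end = hits$start + width,
             strand = hits$strand, score = hits$score)
}
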