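#' Parameters of the A-tract wedge bend model
#'
#' Each maximal run of A (or of T) at least `min_run_length` long contributes
#' a planar wedge vector whose magnitude depends on run length and whose
#' direction is the run center's helical phase, 2*pi*(center mod P)/P with
#' P = `helical_period` (fixed 10.5 bp by default). The wedge magnitude
#' table maps run length to degrees; lengths beyond the last entry saturate
#' at the last value (very long runs are rigid but not progressively more
#' bent).
#'
#' @param helical_period Helix period in bp.
#' @param min_run_length Shortest run counted.
#' @param wedge_table Named numeric vector, names = run lengths, values =
#'   degrees; defaults length 3 -> 9, length >= 4 -> 18.
#' @return A `bend_params` list.
#' @export
bend_params <- function(helical_period = 10.5, min_run_length = 3L,
                        wedge_table = c("3" = 9, "4" = 18)) {
  stopifnot(helical_period > 0, min_run_length >= 1,
            all(wedge_table >= 0), !is.unsorted(wedge_table))
  structure(list(helical_period = helical_period,
                 min_run_length = as.integer(min_run_length),
                 wedge_table = wedge_table),
            class = "bend_params")
}

wedge_angle <- function(len, params) {
  lens <- as.integer(names(params$wedge_table))
  idx <- findInterval(len, lens)
  ifelse(idx < 1, 0, params$wedge_table[pmax(idx, 1L)])
}

#' Bend detector presets
#'
#' `60w100`: net deflection of at least 60 degrees within at most 100 bp.
#' `45w60`: at least 45 degrees within at most 60 bp.
#'
#' @param name `"60w100"` or `"45w60"`.
#' @return A `bend_preset` with `name`, `min_deflection`, `max_span`.
#' @export
bend_preset <- function(name = c("60w100", "45w60")) {
  name <- match.arg(name)
  p <- switch(name,
              "60w100" = list(name = "60w100", min_deflection = 60, max_span = 100),
              "45w60"  = list(name = "45w60",  min_deflection = 45, max_span = 60))
  structure(p, class = "bend_preset")
}

#' Maximal A and T runs in a genome
#'
#' Finds all maximal runs of A and maximal runs of T of length at least
#' `params$min_run_length`, sorted by start. Runs containing N cannot occur
#' (N breaks runs).
#'
#' @param g A `genome_sequence`.
#' @param params A [bend_params()].
#' @return Data frame with columns `start` (0-based), `length`, `base`,
#'   `center` (fractional bp), `wedge` (degrees).
#' @export
find_runs <- function(g, params = bend_params()) {
  v <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values %in% c("A", "T") & r$lengths >= params$min_run_length
  df <- data.frame(start = starts[keep], length = r$lengths[keep],
                   base = r$values[keep])
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$center <- df$start + (df$length - 1) / 2
  df$wedge <- as.numeric(wedge_angle(df$length, params))
  df
}

#' Net helical-axis deflection of a set of A-tract runs
#'
#' Planar wedge-vector sum: run j contributes magnitude `wedge(length_j)` at
#' phase angle 2*pi*(center_j mod P)/P. Runs in phase (centers separated by
#' whole helical turns) add collinearly; antiphase runs cancel.
#'
#' @param runs Data frame from [find_runs()] (rows within one segment).
#' @param params A [bend_params()].
#' @return Magnitude of the vector sum, degrees.
#' @export
deflection <- function(runs, params = bend_params()) {
  if (nrow(runs) == 0) return(0)
  phi <- 2 * pi * (runs$center %% params$helical_period) / params$helical_period
  sqrt(sum(runs$wedge * cos(phi))^2 + sum(runs$wedge * sin(phi))^2)
}

# All candidate segments: consecutive run windows i..j whose interval
# [start_i, end_j) spans <= max_span, with their vector-sum deflection.
# Vectorized via cumulative wedge-vector sums.
bend_candidates <- function(runs, params, preset) {
  n <- nrow(runs)
  if (n == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      deflection = numeric(0), n_tracts = integer(0)))
  phi <- 2 * pi * (runs$center %% params$helical_period) / params$helical_period
  cx <- cumsum(runs$wedge * cos(phi))
  cy <- cumsum(runs$wedge * sin(phi))
  run_end <- runs$start + runs$length
  # last j for each i with run_end[j] - start[i] <= max_span
  jmax <- findInterval(runs$start + preset$max_span, run_end)
  jmax <- pmax(jmax, seq_len(n))         # always include the single run
  jmax <- pmin(jmax, n)
  counts <- jmax - seq_len(n) + 1L
  i <- rep.int(seq_len(n), counts)
  j <- sequence(counts, from = seq_len(n))
  dx <- cx[j] - c(0, cx)[i]
  dy <- cy[j] - c(0, cy)[i]
  defl <- sqrt(dx^2 + dy^2)
  keep <- defl >= preset$min_deflection & run_end[j] - runs$start[i] <= preset$max_span
  data.frame(start = runs$start[i][keep], end = run_end[j][keep],
             deflection = defl[keep], n_tracts = (j - i + 1L)[keep])
}

# Greedy non-overlap selection: descending deflection, ties by leftmost
# start; an interval is kept if it shares no base with an already-kept one.
select_nonoverlapping <- function(cand, genome_length) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cand$deflection, cand$start)
  cand <- cand[ord, , drop = FALSE]
  covered <- logical(genome_length)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    span <- (cand$start[k] + 1L):cand$end[k]
    if (!any(covered[span])) {
      covered[span] <- TRUE
      keep[k] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict intrinsic DNA bends
#'
#' Enumerates all segments delimited by consecutive A/T runs whose interval
#' (first run start to last run end) is at most `max_span` bp, keeps those
#' whose wedge-vector deflection reaches `min_deflection`, and reports a
#' non-overlapping subset chosen greedily by descending deflection (ties by
#' leftmost start). Intervals are 0-based half-open.
#'
#' @param g A `genome_sequence`.
#' @param params A [bend_params()].
#' @param preset A [bend_preset()] or its name.
#' @return Data frame of bends: `start`, `end`, `deflection`, `n_tracts`,
#'   sorted by start, mutually non-overlapping.
#' @export
detect_bends <- function(g, params = bend_params(),
                         preset = bend_preset("60w100")) {
  if (is.character(preset)) preset <- bend_preset(preset)
  runs <- find_runs(g, params)
  cand <- bend_candidates(runs, params, preset)
  select_nonoverlapping(cand, g$length)
}

#' Write predicted bends as BED6
#'
#' Columns: chrom, start, end, name ("bend"), score = deflection rounded to
#' 0.1 degree, strand ".". Coordinates 0-based half-open.
#'
#' @param g A `genome_sequence`.
#' @param bends Data frame from [detect_bends()].
#' @param path Output file.
#' @export
bends_to_bed <- function(g, bends, path) {
  df <- data.frame(chrom = g$id, start = bends$start, end = bends$end,
                   name = "bend", score = round(bends$deflection, 1),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
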