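#' Random i.i.d. background genome
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2. All generators in this module consume R's
#' default Mersenne-Twister stream: passing `seed` calls `set.seed(seed)`,
#' so identical spec + seed gives identical output on any platform.
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed Optional integer seed.
#' @param id Record id.
#' @return A `genome_sequence`.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL, id = "synthetic") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome_sequence(id, paste(bases, collapse = ""))
}

#' Plant phased A-tract arrays into a genome
#'
#' Writes `n_arrays` arrays at uniformly drawn non-overlapping loci. Each
#' array is `tracts_per_array` runs of A (arrays alternate between A and T)
#' of `tract_length` bp, with successive tract starts alternating between
#' `spacing_low` and `spacing_high` bp (defaults 10 and 11, averaging the
#' 10.5 bp helical period on the integer lattice). Spacer bases between
#' tracts are drawn from C/G so planted runs never merge.
#'
#' @param g A `genome_sequence`.
#' @param n_arrays Number of arrays.
#' @param tracts_per_array Runs per array.
#' @param tract_length Run length in bp (default 5).
#' @param spacing_low,spacing_high Alternating start-to-start spacings (bp).
#' @param seed Optional integer seed.
#' @param max_tries Placement retries before giving up.
#' @return List `genome` (modified sequence) and `truth` (data frame of
#'   planted intervals `start`, `end`, 0-based half-open).
#' @export
plant_periodic_arrays <- function(g, n_arrays, tracts_per_array = 8L,
                                  tract_length = 5L, spacing_low = 10L,
                                  spacing_high = 11L, seed = NULL,
                                  max_tries = 50L * max(n_arrays, 1L)) {
  if (!is.null(seed)) set.seed(seed)
  if (n_arrays == 0) {
    return(list(genome = g,
                truth = data.frame(start = integer(0), end = integer(0))))
  }
  spacings <- rep(c(spacing_low, spacing_high),
                  length.out = tracts_per_array - 1L)
  starts_in_array <- cumsum(c(0L, spacings))
  array_len <- starts_in_array[tracts_per_array] + tract_length
  if (array_len > g$length) stop("array does not fit in the genome")
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  placed <- integer(0)
  occupied <- logical(g$length)
  tries <- 0L
  while (length(placed) < n_arrays) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place arrays without overlap")
    s <- sample.int(g$length - array_len + 1L, 1L) - 1L
    span <- (s + 1L):(s + array_len)
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    base <- if (length(placed) %% 2L == 0L) "A" else "T"
    seg <- sample(c("C", "G"), array_len, replace = TRUE)
    for (t in starts_in_array) {
      seg[(t + 1L):(t + tract_length)] <- base
    }
    chars[span] <- seg
    placed <- c(placed, s)
  }
  placed <- sort(placed)
  list(genome = genome_sequence(g$id, paste(chars, collapse = "")),
       truth = data.frame(start = placed, end = placed + array_len))
}

#' Plant motif occurrences into a genome
#'
#' Plants `n_sites` site sequences sampled column-wise from a motif model's
#' frequencies. A `fraction_near` of the sites is placed within
#' `proximity_bp` of a ground-truth interval (e.g. planted bends); the rest
#' are placed uniformly. Sites never overlap each other.
#'
#' @param g A `genome_sequence`.
#' @param m A `motif_model`.
#' @param n_sites Number of sites to plant.
#' @param near_intervals Optional data frame of `start`, `end` anchors.
#' @param proximity_bp Maximal distance from an anchor midpoint (bp).
#' @param fraction_near Fraction of sites placed near anchors.
#' @param seed Optional integer seed.
#' @param max_tries Placement retries before giving up.
#' @return List `genome` and `truth` (data frame `start`, `end`, `near`).
#' @export
plant_motif_sites <- function(g, m, n_sites, near_intervals = NULL,
                              proximity_bp = 200L, fraction_near = 0,
                              seed = NULL, max_tries = 100L * max(n_sites, 1L)) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sites == 0) {
    return(list(genome = g, truth = data.frame(start = integer(0),
                                               end = integer(0),
                                               near = logical(0))))
  }
  if (fraction_near > 0 &&
      (is.null(near_intervals) || nrow(near_intervals) == 0))
    stop("fraction_near > 0 requires non-empty near_intervals")
  w <- m$width
  n_near <- round(fraction_near * n_sites)
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  occupied <- logical(g$length)
  bases <- c("A", "C", "G", "T")
  draw_site <- function() {
    vapply(seq_len(w), function(c) sample(bases, 1, prob = m$probs[, c]),
           character(1))
  }
  starts <- integer(0); near <- logical(0)
  tries <- 0L
  while (length(starts) < n_sites) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place sites without overlap")
    is_near <- length(starts) < n_near
    if (is_near) {
      k <- sample.int(nrow(near_intervals), 1L)
      mid <- (near_intervals$start[k] + near_intervals$end[k]) %/% 2L
      s <- mid + sample.int(2L * proximity_bp + 1L, 1L) - proximity_bp - 1L
    } else {
      s <- sample.int(g$length - w + 1L, 1L) - 1L
    }
    if (s < 0 || s + w > g$length) next
    span <- (s + 1L):(s + w)
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    chars[span] <- draw_site()
    starts <- c(starts, s); near <- c(near, is_near)
  }
  ord <- order(starts)
  list(genome = genome_sequence(g$id, paste(chars, collapse = "")),
       truth = data.frame(start = starts[ord], end = starts[ord] + w,
                          near = near[ord]))
}

#' Random fixture site collection
#'
#' Draws a uniform random consensus of the given width and `n_sites`
#' variants of it with independent per-position mutation probability
#' `1 - sharpness` (mutations are drawn from the three other bases). Stands
#' in for curated binding-site collections in tests; deliberately carries no
#' real motif's identity.
#'
#' @param name Collection name.
#' @param width Site width (>= 4).
#' @param n_sites Number of sites.
#' @param sharpness Per-position probability of matching the consensus.
#' @param seed Optional integer seed.
#' @return A [site_collection()] with attribute `consensus`.
#' @export
make_fixture_sites <- function(name, width, n_sites, sharpness = 0.9,
                               seed = NULL) {
  stopifnot(width >= 4, sharpness > 0, sharpness <= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  consensus <- sample(bases, width, replace = TRUE)
  sites <- vapply(seq_len(n_sites), function(i) {
    s <- consensus
    mut <- stats::runif(width) > sharpness
    if (any(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  out <- site_collection(name, sites)
  attr(out, "consensus") <- paste(consensus, collapse = "")
  out
}

#' Simulate a genome-attribute table from group specifications
#'
#' Each spec describes one group of genomes: its size, the Normal
#' distribution of its MaxQ* values (clipped below at 0; the index is a
#' non-negative peak height), its flag assignments, and optionally a taxon
#' label. Useful specs mirror published group summaries, e.g. genomes with
#' a NAP at mean 3.08, sd 0.76 (n = 130) versus without at 2.78, sd 0.71
#' (n = 443).
#'
#' @param specs List of specs; each is a list with `n`, `mean`, `sd`,
#'   `flags` (named 0/1 vector) and optional `group`.
#' @param seed Optional integer seed.
#' @return An `attribute_table` data frame.
#' @export
simulate_attribute_table <- function(specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_flags <- unique(unlist(lapply(specs, function(s) names(s$flags))))
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    stopifnot(s$n > 0, s$sd > 0)
    vals <- pmax(0, stats::rnorm(s$n, s$mean, s$sd))
    df <- data.frame(genome_id = sprintf("g%d_%04d", i, seq_len(s$n)),
                     maxq_star = vals)
    for (f in all_flags) df[[f]] <- unname(s$flags[f] %||% 0)
    for (f in all_flags) if (is.na(df[[f]][1])) df[[f]] <- 0
    if (!is.null(s$group)) df$group <- s$group
    df
  })
  has_group <- any(vapply(rows, function(r) "group" %in% names(r), logical(1)))
  if (has_group) {
    rows <- lapply(rows, function(r) {
      if (!"group" %in% names(r)) r$group <- NA_character_
      r
    })
  }
  validate_attribute_table(do.call(rbind, rows))
}

#' Two-group attribute table from summary statistics
#'
#' Convenience wrapper over [simulate_attribute_table()] for the common
#' flagged-versus-unflagged design.
#'
#' @param flag Flag column name.
#' @param n1,mean1,sd1 Size and MaxQ* distribution of the flagged group.
#' @param n0,mean0,sd0 Same for the unflagged group.
#' @param seed Optional integer seed.
#' @return An `attribute_table`.
#' @export
simulate_two_group_table <- function(flag, n1, mean1, sd1, n0, mean0, sd0,
                                     seed = NULL) {
  simulate_attribute_table(list(
    list(n = n1, mean = mean1, sd = sd1, flags = stats::setNames(1, flag)),
    list(n = n0, mean = mean0, sd = sd0, flags = stats::setNames(0, flag))),
    seed = seed)
}
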