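#' Binding-site collection
#'
#' A named set of equal-length aligned binding sites over A, C, G, T, the
#' raw material for a PSSM.
#'
#' @param name Collection name (typically a NAP, e.g. "H-NS").
#' @param sites Character vector of at least two equal-length sites.
#' @return A `site_collection` with `name`, `sites`, `width`.
#' @export
site_collection <- function(name, sites) {
  sites <- toupper(sites)
  if (length(sites) < 2) stop("need at least 2 sites")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must all have the same length")
  if (any(grepl("[^ACGT]", sites))) stop("sites must be over A,C,G,T")
  structure(list(name = name, sites = sites, width = as.integer(w)),
            class = "site_collection")
}

#' Read a site collection from FASTA or one-site-per-line text
#'
#' @param path Input file; a leading `>` marks FASTA.
#' @param name Collection name; defaults to the file base name.
#' @return A [site_collection()].
#' @export
read_sites <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read site file: ", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    set <- Biostrings::readDNAStringSet(path)
    sites <- as.character(set)
  } else {
    sites <- trimws(readLines(path))
    sites <- sites[nzchar(sites)]
  }
  site_collection(name, unname(sites))
}

#' Build a log-odds position-specific score matrix
#'
#' Column frequencies are (count + pseudocount) / (n_sites + 4*pseudocount);
#' scores are log2(frequency / background), in bits.
#'
#' @param sites A [site_collection()].
#' @param background Named base frequencies (A,C,G,T), strictly positive,
#'   summing to 1. Default uniform.
#' @param pseudocount Added per base per column (> 0; default 0.5).
#' @return A `motif_model` with `name`, `width`, `log_odds` (4 x width,
#'   rows A,C,G,T), `probs` (column frequencies), `background`,
#'   `pseudocount`, `max_score`.
#' @export
build_pssm <- function(sites, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pseudocount = 0.5) {
  stopifnot(inherits(sites, "site_collection"), pseudocount > 0,
            all(background > 0))
  background <- background[c("A", "C", "G", "T")] / sum(background)
  w <- sites$width
  n <- length(sites$sites)
  mat <- do.call(rbind, strsplit(sites$sites, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(c)
    tabulate(match(mat[, c], c("A", "C", "G", "T")), 4L), integer(4))
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  lo <- log2(probs / as.numeric(background))
  rownames(lo) <- rownames(probs) <- c("A", "C", "G", "T")
  structure(list(name = sites$name, width = w, log_odds = lo, probs = probs,
                 background = background, pseudocount = pseudocount,
                 max_score = sum(apply(lo, 2, max))),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: width %d, max score %.2f bits\n",
              x$name, x$width, x$max_score))
  invisible(x)
}

#' Mononucleotide composition of a genome
#'
#' Background frequencies for within-genome scanning; N is excluded from the
#' denominator.
#'
#' @param g A `genome_sequence`.
#' @return Named frequencies (A,C,G,T) summing to 1.
#' @export
genome_background <- function(g) {
  code <- seq_to_code(g$seq)
  n <- tabulate(code, 4L)
  stats::setNames(n / sum(n), c("A", "C", "G", "T"))
}

#' Score one window against a motif model
#'
#' Sum of per-column log-odds for the forward window, or for the reverse
#' complement of the window when `strand == "-"`. Windows containing N get
#' `NA` (skipped by callers).
#'
#' @param m A `motif_model`.
#' @param g A `genome_sequence`.
#' @param pos 0-based window start; `pos + width <= length`.
#' @param strand `"+"` or `"-"`.
#' @return Score in bits, or `NA` for a window containing N.
#' @export
score_window <- function(m, g, pos, strand = "+") {
  stopifnot(pos >= 0, pos + m$width <= g$length)
  win <- substr(g$seq, pos + 1, pos + m$width)
  if (strand == "-") win <- revcomp_string(win)
  code <- seq_to_code(win)
  if (anyNA(code)) return(NA_real_)
  sum(m$log_odds[cbind(code, seq_len(m$width))])
}

#' Exact score distribution under an i.i.d. background
#'
#' Scores are discretized to a lattice (default 0.01 bits) and the window
#' score distribution is built by column-wise convolution: exact up to the
#' discretization, total mass within 1e-9 of 1.
#'
#' @param m A `motif_model`.
#' @param background Named base frequencies; default the model's own.
#' @param resolution Lattice step in bits.
#' @return List `scores` (lattice values, bits) and `prob`.
#' @export
score_distribution <- function(m, background = m$background,
                               resolution = 0.01) {
  background <- background[c("A", "C", "G", "T")] / sum(background)
  lat <- round(m$log_odds / resolution)      # integer lattice per column
  lo_min <- cumsum(apply(lat, 2, min))
  lo_max <- cumsum(apply(lat, 2, max))
  offset <- lo_min[m$width]
  size <- lo_max[m$width] - offset + 1L
  prob <- numeric(size)
  # first column
  prob_prev <- numeric(lo_max[1] - lo_min[1] + 1L)
  for (b in 1:4) {
    k <- lat[b, 1] - lo_min[1] + 1L
    prob_prev[k] <- prob_prev[k] + background[b]
  }
  base_prev <- lo_min[1]
  if (m$width > 1) {
    for (col in 2:m$width) {
      base_new <- lo_min[col]
      prob_new <- numeric(lo_max[col] - base_new + 1L)
      idx_prev <- seq_along(prob_prev)
      for (b in 1:4) {
        sh <- base_prev + lat[b, col] - base_new
        tgt <- idx_prev + sh
        prob_new[tgt] <- prob_new[tgt] + background[b] * prob_prev
      }
      prob_prev <- prob_new
      base_prev <- base_new
    }
  }
  list(scores = (seq_along(prob_prev) - 1L + base_prev) * resolution,
       prob = prob_prev)
}

#' Calibrate a score cutoff to an expected false-positive rate
#'
#' Returns the smallest lattice score t with P(score >= t) <= `fp_rate`
#' under the background score distribution. The default rate 1e-4 per bp per
#' strand corresponds to about one expected background hit per 10 kb window
#' per strand; a stricter second setting is conventionally this cutoff plus
#' 3 bits.
#'
#' @param m A `motif_model`.
#' @param fp_rate Expected hits per bp per strand, in (0, 1).
#' @param background Background frequencies for the null distribution.
#' @param resolution Lattice step in bits.
#' @return Cutoff in bits. If even the maximal score has tail mass above
#'   `fp_rate`, the maximal score is returned with a warning.
#' @export
calibrate_cutoff <- function(m, fp_rate = 1e-4, background = m$background,
                             resolution = 0.01) {
  stopifnot(fp_rate > 0, fp_rate <= 1)
  dist <- score_distribution(m, background, resolution)
  support <- dist$prob > 0
  scores <- dist$scores[support]
  tail <- rev(cumsum(rev(dist$prob[support])))
  ok <- which(tail <= fp_rate)
  if (length(ok) == 0) {
    warning("fp_rate below the minimal attainable tail mass; returning max score")
    return(scores[length(scores)])
  }
  scores[ok[1]]
}

# Vectorized both-strand window scores; NA where the window contains N.
.window_scores <- function(m, g) {
  code <- seq_to_code(g$seq)
  n <- g$length - m$width + 1L
  if (n < 1) return(list(fwd = numeric(0), rev = numeric(0)))
  fwd <- numeric(n)
  rev_ <- numeric(n)
  # minus-strand score at window p = sum of log_odds[complement(base at
  # p+width-c), c] — evaluate with the complement-reversed matrix.
  lo_rc <- m$log_odds[4:1, m$width:1, drop = FALSE]
  for (c in seq_len(m$width)) {
    b <- code[seq_len(n) + c - 1L]
    fwd <- fwd + m$log_odds[cbind(b, c)]
    rev_ <- rev_ + lo_rc[cbind(b, c)]
  }
  list(fwd = fwd, rev = rev_)
}

#' Scan a genome for motif hits on both strands
#'
#' Reports every window, on either strand, scoring at least `cutoff` bits.
#' Windows containing N are skipped. Overlapping hits (including palindromic
#' hits on both strands at one locus) are all reported.
#'
#' @param g A `genome_sequence`.
#' @param m A `motif_model`.
#' @param cutoff Score threshold in bits (see [calibrate_cutoff()]).
#' @return Data frame `start` (0-based window start), `strand`, `score`,
#'   sorted by start then strand.
#' @export
scan_genome <- function(g, m, cutoff) {
  sc <- .window_scores(m, g)
  hf <- which(!is.na(sc$fwd) & sc$fwd >= cutoff)
  hr <- which(!is.na(sc$rev) & sc$rev >= cutoff)
  hits <- data.frame(start = c(hf, hr) - 1L,
                     strand = rep(c("+", "-"), c(length(hf), length(hr))),
                     score = c(sc$fwd[hf], sc$rev[hr]))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write scan hits as BED6
#'
#' Score column is bits x 100, rounded; strand column is used. Coordinates
#' 0-based half-open.
#'
#' @param g A `genome_sequence`.
#' @param m The `motif_model` scanned.
#' @param hits Data frame from [scan_genome()].
#' @param path Output file.
#' @export
hits_to_bed <- function(g, m, hits, path) {
  df <- data.frame(chrom = g$id, start = hits$start,
                   end = hits$start + m$width, name = m$name,
                   score = round(hits$score * 100), strand = hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export / import a motif model as minimal text
#'
#' A MEME-like plain-text matrix: header lines with name, width, pseudocount
#' and background, then one line of four log-odds values per position.
#'
#' @param m A `motif_model`.
#' @param path Output file.
#' @export
write_motif <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("name\t", m$name),
               paste0("width\t", m$width),
               paste0("pseudocount\t", m$pseudocount),
               paste0("background\t", paste(sprintf("%.6g", m$background),
                                            collapse = "\t")),
               "A\tC\tG\tT"), con)
  utils::write.table(t(signif(m$log_odds, 8)), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motif
#' @param path Input file written by [write_motif()].
#' @export
read_motif <- function(path) {
  lines <- readLines(path)
  name <- sub("^name\t", "", lines[1])
  width <- as.integer(sub("^width\t", "", lines[2]))
  pc <- as.numeric(sub("^pseudocount\t", "", lines[3]))
  bg <- as.numeric(strsplit(sub("^background\t", "", lines[4]), "\t")[[1]])
  names(bg) <- c("A", "C", "G", "T")
  mat <- utils::read.table(text = lines[-(1:5)], sep = "\t")
  lo <- t(as.matrix(mat))
  rownames(lo) <- c("A", "C", "G", "T")
  probs <- bg * 2^lo
  structure(list(name = name, width = width, log_odds = lo, probs = probs,
                 background = bg, pseudocount = pc,
                 max_score = sum(apply(lo, 2, max))),
            class = "motif_model")
}
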