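# Independent brute-force oracles. These deliberately share no code with the
# package: every scan is a per-window loop, every statistic is enumerated
# from its definition.

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# window-by-window membership scan (0-based starts)
oracle_tracts <- function(seq, patterns, w) {
  n <- nchar(seq)
  if (n < w) return(integer(0))
  hits <- integer(0)
  for (p in 0:(n - w)) {
    if (substr(seq, p + 1, p + w) %in% patterns) hits <- c(hits, p)
  }
  hits
}

# all-pairs spacing counter
oracle_spacing <- function(positions, s_max) {
  counts <- numeric(s_max)
  n <- length(positions)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- positions[j] - positions[i]
      if (s <= s_max) counts[s] <- counts[s] + 1
    }
  }
  counts
}

# per-window PSSM scorer over both strands; list(start, strand, score)
oracle_scan <- function(g, m, cutoff) {
  n <- g$length - m$width + 1L
  out <- list()
  for (p in 0:(n - 1)) {
    win <- substr(g$seq, p + 1, p + m$width)
    for (strand in c("+", "-")) {
      w <- if (strand == "-") rc(win) else win
      ch <- strsplit(w, "")[[1]]
      idx <- match(ch, c("A", "C", "G", "T"))
      if (anyNA(idx)) next
      sc <- sum(m$log_odds[cbind(idx, seq_len(m$width))])
      if (sc >= cutoff) out[[length(out) + 1]] <-
          data.frame(start = p, strand = strand, score = sc)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# exact score distribution by enumerating all 4^w windows
oracle_score_dist <- function(m, background) {
  w <- m$width
  grid <- expand.grid(rep(list(1:4), w))
  scores <- apply(grid, 1, function(idx)
    sum(m$log_odds[cbind(idx, seq_len(w))]))
  probs <- apply(grid, 1, function(idx) prod(background[idx]))
  list(scores = scores, prob = probs)
}

# exhaustive run-delimited segment search for bend candidates
oracle_bend_candidates <- function(runs, params, preset) {
  n <- nrow(runs)
  out <- list()
  if (n > 0) {
    for (i in 1:n) for (j in i:n) {
      if (runs$start[j] + runs$length[j] - runs$start[i] > preset$max_span) break
      d <- deflection(runs[i:j, ], params)
      if (d >= preset$min_deflection) out[[length(out) + 1]] <-
          data.frame(start = runs$start[i],
                     end = runs$start[j] + runs$length[j],
                     deflection = d, n_tracts = j - i + 1L)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      deflection = numeric(0), n_tracts = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# independent greedy non-overlap selection (re-implementation with interval
# comparisons instead of a coverage vector)
oracle_greedy_select <- function(cand) {
  cand <- cand[order(-cand$deflection, cand$start), , drop = FALSE]
  sel <- cand[0, ]
  for (k in seq_len(nrow(cand))) {
    ok <- TRUE
    if (nrow(sel) > 0) {
      ok <- all(cand$end[k] <= sel$start | cand$start[k] >= sel$end)
    }
    if (ok) sel <- rbind(sel, cand[k, ])
  }
  sel <- sel[order(sel$start), ]
  rownames(sel) <- NULL
  sel
}

# Mann-Whitney: U by pair counting, exact p by enumerating group labels
oracle_mwu_exact_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  u_obs <- u_of(a, b)
  splits <- utils::combn(n, na)
  us <- apply(splits, 2, function(idx) u_of(pool[idx], pool[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Pearson r from the definition, p via cor.test
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  list(r = r, p = stats::cor.test(x, y)$p.value)
}

# recall of truth intervals by predicted intervals (any overlap)
interval_recall <- function(truth, pred) {
  if (nrow(truth) == 0) return(NA_real_)
  if (nrow(pred) == 0) return(0)
  mean(vapply(seq_len(nrow(truth)), function(i)
    any(pred$start < truth$end[i] & pred$end > truth$start[i]), logical(1)))
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$seq)))
  writeLines(lines, path)
  path
}
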