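# Internal helpers shared across modules.

# ASCII codes for the stored alphabet; sequences are kept as uppercase
# character scalars and converted to integer vectors only where hot loops
# need random access.
.base_int <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)

# Integer vector of 1..4 for A,C,G,T and NA for N.
seq_to_code <- function(seq) {
  v <- utf8ToInt(seq)
  code <- match(v, .base_int[c("A", "C", "G", "T")])
  code
}

revcomp_string <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Centered moving average with edges handled by symmetric window shrinkage:
# at distance k < halfwidth from either end, the window is 2k+1 wide.
moving_average <- function(x, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  if (width == 1) return(x)
  n <- length(x)
  h <- (width - 1L) / 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  idx <- seq_len(n)
  k <- pmin(h, idx - 1L, n - idx)
  lo <- idx - k
  hi <- idx + k
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Flat key = value config reader (TOML-like; strings may be quoted, numbers
# and booleans are coerced). Comment lines start with '#'.
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (val %in% c("true", "false")) identical(val, "true")
      else val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
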