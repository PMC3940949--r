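#' Mann-Whitney U test
#'
#' U is computed from midranks (ties share their average rank). For total
#' sample size at most `exact_threshold` (default 16), the two-sided p-value
#' comes from exhaustive enumeration of all equally likely rank splits
#' (p = 2 min tail probability, capped at 1). For larger samples it uses the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction toward the mean.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_threshold Largest total n for the exact branch.
#' @return A `test_result` list: `statistic` (U of the first sample), `p`,
#'   `n_a`, `n_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 16L) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))              # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_threshold) {
    splits <- utils::combn(n, na)
    us <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_lo <- mean(us <= u + eps)
    p_hi <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(v)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal"
  }
  structure(list(statistic = u, p = p, n_a = na, n_b = nb,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  size <- if (!is.null(x$n_a)) sprintf("n=%d vs %d", x$n_a, x$n_b)
          else sprintf("cells=%d,%d,%d,%d", x$n1, x$n2, x$n3, x$n4)
  cat(sprintf("<test_result> statistic=%.4g p=%.4g (%s)\n",
              x$statistic, x$p, size))
  invisible(x)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p-value under the standard convention: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (within a 1e-7
#' relative tolerance). The table layout follows the NAP-by-CRISPR
#' convention: `n1` both present, `n2` only the column factor, `n3` only the
#' row factor, `n4` neither, i.e. `rbind(c(n1, n2), c(n3, n4))`.
#'
#' @param n1,n2,n3,n4 Non-negative cell counts; alternatively `n1` may be a
#'   2x2 matrix.
#' @return A `test_result` with `statistic` = odds ratio (n1 n4)/(n2 n3),
#'   `p`, and the cells. A zero margin returns p = 1 with a warning.
#' @export
fisher_exact <- function(n1, n2 = NULL, n3 = NULL, n4 = NULL) {
  if (is.matrix(n1)) {
    m <- n1; n1 <- m[1, 1]; n2 <- m[1, 2]; n3 <- m[2, 1]; n4 <- m[2, 2]
  }
  cells <- c(n1, n2, n3, n4)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  or <- if (n2 * n3 == 0) {
    if (n1 * n4 == 0) NaN else Inf
  } else (n1 * n4) / (n2 * n3)
  row1 <- n1 + n2; row2 <- n3 + n4; col1 <- n1 + n3; col2 <- n2 + n4
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    warning("degenerate table (zero margin); p = 1")
    p <- 1
  } else {
    # log P(k in cell 1 | margins), hypergeometric, via lchoose
    k <- max(0, col1 - row2):min(col1, row1)
    logp <- lchoose(row1, k) + lchoose(row2, col1 - k) - lchoose(row1 + row2, col1)
    logp_obs <- logp[k == n1]
    p <- sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)]))
    p <- min(1, p)
  }
  structure(list(statistic = or, p = p,
                 n1 = n1, n2 = n2, n3 = n3, n4 = n4),
            class = "test_result")
}

#' Read / write a genome-attribute table
#'
#' TSV with header: `genome_id`, `maxq_star`, one 0/1 column per
#' presence flag (NAPs and CRISPR), optional `group` (taxon label).
#'
#' @param path File path.
#' @return Data frame of class `attribute_table`.
#' @export
read_attribute_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  validate_attribute_table(tab)
}

#' @rdname read_attribute_table
#' @param tab An attribute table data frame.
#' @export
write_attribute_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_attribute_table
#' @export
validate_attribute_table <- function(tab) {
  if (!all(c("genome_id", "maxq_star") %in% names(tab)))
    stop("attribute table needs 'genome_id' and 'maxq_star' columns")
  if (anyDuplicated(tab$genome_id))
    stop("duplicate genome_id values")
  if (any(!is.finite(tab$maxq_star)))
    stop("maxq_star must be finite")
  for (f in attribute_flags(tab)) {
    if (!all(tab[[f]] %in% c(0, 1)))
      stop("flag column '", f, "' must be strictly 0/1")
  }
  class(tab) <- c("attribute_table", "data.frame")
  tab
}

# Flag columns: everything except the fixed columns.
attribute_flags <- function(tab) {
  setdiff(names(tab), c("genome_id", "maxq_star", "group"))
}

#' Compare MaxQ* between genomes with and without a flag
#'
#' Splits the table by a presence flag (optionally restricted to one taxon
#' group first), summarizes both groups and runs the Mann-Whitney U test;
#' one output row of the NAP-comparison kind.
#'
#' @param tab An attribute table.
#' @param flag_name Name of the 0/1 column to split by.
#' @param subset Optional `group` label to restrict to before splitting.
#' @return The [mann_whitney_u()] `test_result`, with `flag` and `subset`
#'   fields added (group "a" = flag present, "b" = absent).
#' @export
group_compare <- function(tab, flag_name, subset = NULL) {
  if (!flag_name %in% names(tab)) stop("no such flag: ", flag_name)
  if (!is.null(subset)) {
    if (!"group" %in% names(tab)) stop("table has no 'group' column")
    tab <- tab[tab$group == subset, , drop = FALSE]
  }
  a <- tab$maxq_star[tab[[flag_name]] == 1]
  b <- tab$maxq_star[tab[[flag_name]] == 0]
  if (length(a) == 0 || length(b) == 0)
    stop("flag '", flag_name, "' splits into an empty group")
  res <- mann_whitney_u(a, b)
  res$flag <- flag_name
  res$subset <- subset
  res
}

# Box-and-whisker summary: median, quartiles, whiskers at the most extreme
# points within 1.5 IQR of the box.
box_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  inside <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  c(lo = min(inside), q1 = q[1], median = q[2], q3 = q[3], hi = max(inside))
}

#' Correlate NAP repertoire size with MaxQ*
#'
#' Counts, per genome, how many bridging and how many non-bridging NAPs it
#' possesses and returns the Pearson correlation of each count with MaxQ*,
#' plus per-count box-plot summaries (median, quartiles, whiskers excluding
#' points beyond 1.5 IQR).
#'
#' @param tab An attribute table.
#' @param bridging_flags,nonbridging_flags Flag column names.
#' @return List with `bridging` and `nonbridging`, each holding `cor`
#'   ([pearson_cor()] result or an error message if the count is constant)
#'   and `distribution` (one box summary row per count value).
#' @export
nap_count_correlation <- function(tab, bridging_flags, nonbridging_flags) {
  missing <- setdiff(c(bridging_flags, nonbridging_flags), names(tab))
  if (length(missing)) stop("no such flags: ", paste(missing, collapse = ", "))
  one <- function(flags) {
    cnt <- if (length(flags) == 1) tab[[flags]]
           else rowSums(tab[, flags, drop = FALSE])
    cor <- tryCatch(pearson_cor(cnt, tab$maxq_star),
                    error = function(e) conditionMessage(e))
    dist <- do.call(rbind, lapply(sort(unique(cnt)), function(k) {
      data.frame(count = k, n = sum(cnt == k),
                 t(box_stats(tab$maxq_star[cnt == k])))
    }))
    list(cor = cor, distribution = dist)
  }
  list(bridging = one(bridging_flags), nonbridging = one(nonbridging_flags))
}

#' NAP-by-CRISPR contingency tables and Fisher exact tests
#'
#' Builds one 2x2 table per NAP flag against the CRISPR flag (n1 both, n2
#' only CRISPR, n3 only the NAP, n4 neither), runs [fisher_exact()] and
#' marks a positive trend when the odds ratio exceeds 1 with p < 0.01.
#'
#' @param tab An attribute table with a CRISPR flag.
#' @param nap_flags NAP flag column names.
#' @param crispr_flag Name of the CRISPR column (default "CRISPR").
#' @return Data frame: `nap`, `n1`..`n4`, `odds_ratio`, `p`,
#'   `positive_trend`.
#' @export
crispr_nap_association <- function(tab, nap_flags, crispr_flag = "CRISPR") {
  if (!crispr_flag %in% names(tab)) stop("no CRISPR flag column: ", crispr_flag)
  cr <- tab[[crispr_flag]]
  rows <- lapply(nap_flags, function(f) {
    nap <- tab[[f]]
    n1 <- sum(nap == 1 & cr == 1); n2 <- sum(nap == 0 & cr == 1)
    n3 <- sum(nap == 1 & cr == 0); n4 <- sum(nap == 0 & cr == 0)
    res <- fisher_exact(n1, n2, n3, n4)
    data.frame(nap = f, n1 = n1, n2 = n2, n3 = n3, n4 = n4,
               odds_ratio = res$statistic, p = res$p,
               positive_trend = is.finite(res$p) & res$p < 0.01 &
                 (is.infinite(res$statistic) | res$statistic > 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CRISPR comparison of MaxQ* controlled for NAP presence
#'
#' Restricts the table to genomes possessing the given NAP, then compares
#' MaxQ* between CRISPR-positive and CRISPR-negative genomes within that
#' stratum.
#'
#' @param tab An attribute table.
#' @param nap_name NAP flag to condition on.
#' @param crispr_flag Name of the CRISPR column.
#' @return A `test_result` as from [group_compare()].
#' @export
controlled_compare <- function(tab, nap_name, crispr_flag = "CRISPR") {
  if (!nap_name %in% names(tab)) stop("no such flag: ", nap_name)
  sub <- tab[tab[[nap_name]] == 1, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty stratum: no genomes with ", nap_name)
  if (length(unique(sub[[crispr_flag]])) < 2)
    stop("empty stratum: only one CRISPR state among ", nap_name,
         "-possessing genomes")
  res <- group_compare(sub, crispr_flag)
  res$controlled_for <- nap_name
  res
}
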