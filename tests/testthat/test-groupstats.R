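test_that("mann_whitney_u reproduces exact small-sample results", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)
  expect_equal(r$p, 1)
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 0.1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact branch matches independent enumeration with ties", {
  set.seed(16)
  for (i in 1:12) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    # lattice values force ties
    a <- sample(1:4, na, replace = TRUE)
    b <- sample(1:4, nb, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p, oracle_mwu_exact_p(a, b),
                 info = sprintf("case %d", i))
  }
})

test_that("exact and normal branches agree for 8+8 samples", {
  # exhaustive enumeration over all attainable tieless 8+8 U values shows
  # the worst possible |exact - normal| gap is 0.01091 (at U = 24), so the
  # bound below is the true deterministic worst case, not a tolerance
  set.seed(17)
  diffs <- replicate(100, {
    a <- rnorm(8); b <- rnorm(8)
    p_ex <- mann_whitney_u(a, b)$p
    p_no <- mann_whitney_u(a, b, exact_threshold = 0L)$p
    abs(p_ex - p_no)
  })
  expect_lt(max(diffs), 0.011)
  expect_lt(median(diffs), 0.01)
})

test_that("U test is invariant under monotone transforms and matches wilcox", {
  set.seed(18)
  a <- rnorm(30, 0.5); b <- rnorm(25)
  p1 <- mann_whitney_u(a, b)$p
  expect_equal(mann_whitney_u(exp(a), exp(b))$p, p1)
  expect_equal(mann_whitney_u(a^3, b^3)$p, p1)
  # large-sample agreement with the standard implementation
  expect_equal(p1, wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("fisher_exact reproduces published contingency golden values", {
  # NAP x CRISPR tables where the printed p reproduces under the standard
  # two-sided convention (see also test-acceptance.R)
  expect_equal(round(fisher_exact(98, 177, 88, 79)$p, 4), 5e-04)
  expect_equal(round(fisher_exact(7, 268, 0, 167)$p, 3), 0.048)
  expect_equal(fisher_exact(1, 1, 1, 1)$p, 1)
  expect_true(is.infinite(fisher_exact(5, 0, 0, 5)$statistic))
  expect_warning(r <- fisher_exact(0, 0, 3, 4), "degenerate")
  expect_equal(r$p, 1)
})

test_that("fisher_exact matches stats::fisher.test over random tables", {
  set.seed(19)
  for (i in 1:30) {
    cells <- rpois(4, sample(c(2, 10, 40), 1)) + (i %% 2)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])
    want <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))
    expect_equal(got$p, want$p.value, tolerance = 1e-9,
                 info = paste(cells, collapse = ","))
  }
})

test_that("fisher_exact is symmetric under simultaneous row/column swaps", {
  set.seed(20)
  for (i in 1:10) {
    c4 <- rpois(4, 15) + 1
    p1 <- fisher_exact(c4[1], c4[2], c4[3], c4[4])$p
    p2 <- fisher_exact(c4[4], c4[3], c4[2], c4[1])$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("group_compare splits, summarizes and tests; errors are named", {
  tab <- simulate_two_group_table("NAPX", 30, 3.0, 0.0001, 40, 2.0, 0.0001,
                                  seed = 21)
  r <- group_compare(tab, "NAPX")
  expect_equal(r$n_a, 30)
  expect_equal(r$n_b, 40)
  expect_equal(r$mean_a, 3, tolerance = 0.01)
  expect_equal(r$mean_b, 2, tolerance = 0.01)
  expect_lt(r$p, 1e-10)     # complete separation
  expect_error(group_compare(tab, "nonesuch"), "no such flag")
  tab2 <- tab; tab2$NAPX <- 1
  expect_error(group_compare(validate_attribute_table(tab2), "NAPX"),
               "empty group")
})

test_that("group_compare respects taxon subsetting", {
  tab <- simulate_attribute_table(list(
    list(n = 20, mean = 3.5, sd = 0.1, flags = c(X = 1), group = "protGroup"),
    list(n = 20, mean = 2.0, sd = 0.1, flags = c(X = 0), group = "protGroup"),
    list(n = 20, mean = 2.0, sd = 0.1, flags = c(X = 1), group = "other"),
    list(n = 20, mean = 3.5, sd = 0.1, flags = c(X = 0), group = "other")),
    seed = 22)
  r_all <- group_compare(tab, "X")
  r_sub <- group_compare(tab, "X", subset = "protGroup")
  expect_equal(r_sub$n_a, 20)
  expect_gt(r_sub$mean_a, r_sub$mean_b)
  expect_gt(r_all$p, r_sub$p)   # opposing groups cancel in the full table
})

test_that("power at published H-NS group parameters exceeds 90%", {
  # flagged ~ N(3.08, 0.76) n=130 vs unflagged ~ N(2.78, 0.71) n=443
  set.seed(23)
  hits <- replicate(120, {
    tab <- simulate_two_group_table("HNS", 130, 3.08, 0.76, 443, 2.78, 0.71)
    group_compare(tab, "HNS")$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("permuted flags give near-nominal rejection", {
  set.seed(24)
  tab <- simulate_two_group_table("F", 130, 3.08, 0.76, 443, 2.78, 0.71)
  rej <- replicate(120, {
    tab$F <- sample(tab$F)
    group_compare(tab, "F")$p < 0.05
  })
  expect_lte(mean(rej), 0.1)
})

test_that("nap_count_correlation recovers designed correlations", {
  set.seed(25)
  n <- 573
  mk <- function() {
    b1 <- rbinom(n, 1, 0.5); b2 <- rbinom(n, 1, 0.5); b3 <- rbinom(n, 1, 0.4)
    validate_attribute_table(data.frame(
      genome_id = paste0("g", 1:n),
      maxq_star = 2.5 + 0.1 * (b1 + b2 + b3) + rnorm(n, 0, 0.7),
      B1 = b1, B2 = b2, B3 = b3, N1 = rbinom(n, 1, 0.5)))
  }
  # mean recovered r over seeds vs the linear-model closed form
  # r = 0.1 sd(count)/sd(response); single-table r has sd ~ 1/sqrt(573)
  pairs <- replicate(10, {
    tab <- mk()
    cnt <- tab$B1 + tab$B2 + tab$B3
    c(nap_count_correlation(tab, c("B1", "B2", "B3"), "N1")$bridging$cor$r,
      0.1 * sd(cnt) / sd(tab$maxq_star))
  })
  expect_lt(abs(mean(pairs[1, ]) - mean(pairs[2, ])), 0.1)
  tab <- mk()
  res <- nap_count_correlation(tab, c("B1", "B2", "B3"), "N1")
  expect_true(all(c("median", "q1", "q3") %in%
                    names(res$bridging$distribution)))
  cnt <- tab$B1 + tab$B2 + tab$B3
  # maxq_star equal to the count -> r = 1
  tab2 <- tab; tab2$maxq_star <- cnt
  expect_equal(nap_count_correlation(tab2, c("B1", "B2", "B3"),
                                     "N1")$bridging$cor$r, 1)
  # shuffled response decorrelates
  tab3 <- tab; tab3$maxq_star <- sample(tab$maxq_star)
  expect_lt(abs(nap_count_correlation(tab3, c("B1", "B2", "B3"),
                                      "N1")$bridging$cor$r), 0.15)
  # constant count yields an error marker, not a number
  tab4 <- tab; tab4$B1 <- tab4$B2 <- tab4$B3 <- 1
  res4 <- nap_count_correlation(tab4, c("B1", "B2", "B3"), "N1")
  expect_type(res4$bridging$cor, "character")
})

test_that("crispr_nap_association reproduces a constructed table", {
  # construct flags with exactly n1=98 n2=177 n3=88 n4=79
  n <- c(98, 177, 88, 79)
  nap <- c(rep(1, 98), rep(0, 177), rep(1, 88), rep(0, 79))
  cr <- c(rep(1, 98), rep(1, 177), rep(0, 88), rep(0, 79))
  tab <- validate_attribute_table(
    data.frame(genome_id = paste0("g", 1:442), maxq_star = rnorm(442, 3),
               NAP = nap, CRISPR = cr))
  res <- crispr_nap_association(tab, "NAP")
  expect_equal(unlist(res[1, c("n1", "n2", "n3", "n4")], use.names = FALSE), n)
  expect_equal(round(res$p, 4), 5e-04)
  # for these cells the odds ratio is (98*79)/(177*88) < 1, so the
  # positive-trend marker (OR > 1 and p < 0.01) is off despite significance
  expect_equal(res$odds_ratio, 98 * 79 / (177 * 88))
  expect_false(res$positive_trend)
})

test_that("independent flags rarely associate; identical flags always do", {
  set.seed(26)
  rej <- replicate(20, {
    tab <- validate_attribute_table(
      data.frame(genome_id = paste0("g", 1:500), maxq_star = rnorm(500),
                 NAP = rbinom(500, 1, 0.5), CRISPR = rbinom(500, 1, 0.4)))
    crispr_nap_association(tab, "NAP")$p < 0.01
  })
  expect_lte(sum(rej), 2)
  tab <- validate_attribute_table(
    data.frame(genome_id = paste0("g", 1:100), maxq_star = rnorm(100),
               NAP = rep(c(1, 0), each = 50), CRISPR = rep(c(1, 0), each = 50)))
  res <- crispr_nap_association(tab, "NAP")
  expect_true(is.infinite(res$odds_ratio))
  expect_lt(res$p, 1e-20)
})

test_that("controlled_compare restricts to the NAP stratum", {
  set.seed(27)
  # among NAP+ genomes: CRISPR+ ~ N(3.01,0.77) n=98, CRISPR- ~ N(2.67,0.67) n=88
  make_tab <- function() {
    napplus <- simulate_attribute_table(list(
      list(n = 98, mean = 3.01, sd = 0.77, flags = c(NAP = 1, CRISPR = 1)),
      list(n = 88, mean = 2.67, sd = 0.67, flags = c(NAP = 1, CRISPR = 0)),
      list(n = 50, mean = 2.8, sd = 0.7, flags = c(NAP = 0, CRISPR = 1)),
      list(n = 50, mean = 2.8, sd = 0.7, flags = c(NAP = 0, CRISPR = 0))))
    napplus
  }
  # true power at these parameters is ~0.875; 1000 replicates keep the
  # Monte Carlo error well below the 0.025 margin over the 0.85 threshold
  hits <- replicate(1000, controlled_compare(make_tab(), "NAP")$p < 0.05)
  expect_gte(mean(hits), 0.85)
  # invariance to NAP-absent rows
  tab <- make_tab()
  r1 <- controlled_compare(tab, "NAP")
  tab2 <- tab
  tab2$maxq_star[tab2$NAP == 0] <- 99
  r2 <- controlled_compare(validate_attribute_table(tab2), "NAP")
  expect_equal(r1$p, r2$p)
  expect_equal(r1$statistic, r2$statistic)
  # shuffled CRISPR within stratum: near-nominal rejection
  set.seed(28)
  tab3 <- make_tab()
  rej <- replicate(100, {
    idx <- tab3$NAP == 1
    tab3$CRISPR[idx] <- sample(tab3$CRISPR[idx])
    controlled_compare(tab3, "NAP")$p < 0.05
  })
  expect_lte(mean(rej), 0.1)
  # empty stratum errors
  tab4 <- tab
  tab4$CRISPR[tab4$NAP == 1] <- 1
  expect_error(controlled_compare(validate_attribute_table(tab4), "NAP"),
               "stratum")
})

test_that("attribute table IO validates flags and round-trips", {
  tab <- simulate_two_group_table("X", 5, 3, 0.5, 5, 2, 0.5, seed = 29)
  path <- tempfile(fileext = ".tsv")
  write_attribute_table(tab, path)
  tab2 <- read_attribute_table(path)
  expect_equal(tab2$maxq_star, tab$maxq_star, tolerance = 1e-9)
  bad <- tab; bad$X[1] <- 2
  expect_error(validate_attribute_table(bad), "0/1")
  bad2 <- tab; bad2$genome_id[2] <- bad2$genome_id[1]
  expect_error(validate_attribute_table(bad2), "duplicate")
})
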