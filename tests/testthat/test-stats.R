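test_that("TMD histograms bin TMP groups and track zero-TMD groups", {
  groups <- tibble::tibble(
    group_id = c("G1", "G2", "G3", "G4"),
    accession = c("G1", "G2", "G3", "G4")
  )
  tmds <- tibble::tibble(
    accession = c("G1", "G2", "G3", "G3"),
    start = c(1L, 1L, 1L, 30L), end = c(20L, 20L, 20L, 50L),
    ordinal = c(1L, 1L, 1L, 2L)
  )
  h <- tmd_histogram(groups, tmds)
  expect_equal(h$count[h$bin == "1"], 2L)
  expect_equal(h$count[h$bin == "2"], 1L)
  expect_equal(h$fraction[h$bin == "1"], 2 / 3)
  expect_equal(sum(h$fraction), 1)
  expect_equal(attr(h, "n_zero"), 1L)
  expect_equal(attr(h, "n_tmp"), 3L)

  # counts above the last single bin land in the ">10" bin
  many <- tibble::tibble(
    accession = rep(c("G1", "G2"), c(12L, 30L)),
    start = seq(1L, by = 40L, length.out = 42L),
    end = seq(20L, by = 40L, length.out = 42L),
    ordinal = c(1:12, 1:30)
  )
  h2 <- tmd_histogram(groups[1:2, ], many)
  expect_equal(h2$count[h2$bin == ">10"], 2L)

  expect_warning(
    h3 <- tmd_histogram(groups, tmds[0, ]),
    "no TMP groups"
  )
  expect_true(all(is.na(h3$fraction)))
})

test_that("group TMD count is the maximum over member proteins", {
  groups <- tibble::tibble(
    group_id = c("A", "A"),
    accession = c("A", "B")
  )
  tmds <- tibble::tibble(
    accession = c("A", "B", "B"),
    start = c(1L, 1L, 30L), end = c(20L, 20L, 50L),
    ordinal = c(1L, 1L, 2L)
  )
  h <- tmd_histogram(groups, tmds)
  expect_equal(h$count[h$bin == "2"], 1L)
  expect_equal(sum(h$count), 1L)
})

test_that("chi-square GoF matches hand computation and chisq.test", {
  obs <- tibble::tibble(bin = c("a", "b"), count = c(10L, 10L))
  expd <- tibble::tibble(bin = c("a", "b"), count = c(50L, 50L),
                         fraction = c(0.5, 0.5))
  g0 <- chi_square_gof(obs, expd)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)

  # all mass on one of two equiprobable bins: X2 = 10^2/10 + 10^2/10 = 20
  obs2 <- tibble::tibble(bin = c("a", "b"), count = c(20L, 0L))
  g2 <- chi_square_gof(obs2, expd)
  expect_equal(g2$statistic, 20)
  expect_equal(g2$df, 1L)

  # agreement with stats::chisq.test on a 4-bin table
  obs4 <- tibble::tibble(bin = letters[1:4], count = c(12L, 30L, 25L, 33L))
  exp4 <- tibble::tibble(bin = letters[1:4],
                         fraction = c(0.1, 0.3, 0.25, 0.35))
  g4 <- chi_square_gof(obs4, exp4)
  ref <- stats::chisq.test(obs4$count, p = exp4$fraction)
  expect_equal(g4$statistic, unname(ref$statistic))
  expect_equal(g4$p.value, unname(ref$p.value))
  expect_equal(g4$df, unname(ref$parameter))

  expect_error(
    chi_square_gof(
      tibble::tibble(bin = c("a", "b"), count = c(0L, 0L)), expd
    ),
    "all-zero"
  )
})

test_that("low-expectation bins merge right-to-left before testing", {
  obs <- tibble::tibble(bin = c("1", "2", "3"), count = c(50L, 45L, 5L))
  expd <- tibble::tibble(bin = c("1", "2", "3"),
                         fraction = c(0.5, 0.48, 0.02))
  g <- chi_square_gof(obs, expd)
  # expected count for bin 3 is 2 < 5, so it merges into bin 2
  expect_equal(nrow(g$table), 2L)
  expect_equal(g$table$bin, c("1", "2+3"))
  expect_equal(g$table$observed, c(50, 50))
  expect_match(g$merged, "'3' into '2'")
  expect_equal(g$df, 1L)
})

test_that("reproducibility is intersection over union of all sets", {
  r <- replicate_reproducibility(list(c("A", "B"), c("B", "C"), "B"))
  expect_equal(r$reproducibility_pct, 100 / 3)
  expect_equal(r$n_intersection, 1L)
  expect_equal(r$n_union, 3L)

  same <- replicate_reproducibility(list(c("A", "B"), c("A", "B"),
                                         c("B", "A")))
  expect_equal(same$reproducibility_pct, 100)

  disjoint <- replicate_reproducibility(list("A", "B"))
  expect_equal(disjoint$reproducibility_pct, 0)

  # permutation invariance of the set order
  a <- replicate_reproducibility(list(c("A", "B"), c("B", "C"), "B"))
  b <- replicate_reproducibility(list("B", c("B", "C"), c("A", "B")))
  expect_equal(a$reproducibility_pct, b$reproducibility_pct)

  expect_error(replicate_reproducibility(list(character(), character())),
               "empty")
})

test_that("reproducibility reports pairwise Jaccard and Venn regions", {
  r <- replicate_reproducibility(
    list(r1 = c("A", "B"), r2 = c("B", "C"), r3 = "B")
  )
  expect_equal(nrow(r$pairwise), 3L)
  j12 <- r$pairwise$jaccard[r$pairwise$set_a == "r1" &
                              r$pairwise$set_b == "r2"]
  expect_equal(j12, 1 / 3)
  expect_equal(sum(r$venn$count), r$n_union)
  expect_equal(r$venn$count[r$venn$region == "r1&r2&r3"], 1L)
})

test_that("per-bin t-tests match the textbook statistic", {
  a <- rbind(c(0.2, 0.5), c(0.21, 0.51), c(0.19, 0.49))
  b <- rbind(c(0.5, 0.5), c(0.51, 0.51), c(0.49, 0.49))
  colnames(a) <- colnames(b) <- c("bin1", "bin2")
  res <- per_bin_ttest(a, b)
  # hand-computed pooled-variance t for bin 1
  x <- a[, 1L]
  y <- b[, 1L]
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = 4)
  expect_equal(res$p.value[1L], p_hand)
  expect_lt(res$p.value[1L], 0.01)
  expect_equal(res$stars[1L], "**")
  # identical replicate vectors in bin 2: degenerate equal case, p = 1
  expect_equal(res$p.value[2L], 1)
  expect_equal(res$stars[2L], "")

  ident <- per_bin_ttest(a, a)
  expect_true(all(ident$p.value == 1))

  degen <- per_bin_ttest(
    rbind(c(0.1), c(0.1)), rbind(c(0.4), c(0.4))
  )
  expect_equal(degen$p.value, 0)
  expect_true(degen$degenerate)

  expect_error(per_bin_ttest(a[1L, , drop = FALSE], b), ">= 2 replicates")
  expect_error(per_bin_ttest(a, b[, 1L, drop = FALSE]), "same bins")
})

test_that("binomial enrichment tests against the pooled null proportion", {
  # exactly proportional counts: p = 1
  counts <- tibble::tibble(category = "t", count_a = 10L, count_b = 20L)
  res <- binomial_enrichment(counts, n_a = 100L, n_b = 200L)
  expect_equal(res$p.value, 1)
  expect_equal(res$q.value, res$p.value)
  expect_equal(res$direction, 0)

  # extreme split: exact binomial tail, hand-summed
  counts2 <- tibble::tibble(category = "t", count_a = 0L, count_b = 50L)
  res2 <- binomial_enrichment(counts2, n_a = 100L, n_b = 100L)
  p0 <- 50 / 200
  d <- stats::dbinom(0:100, 100, p0)
  p_hand <- sum(d[d <= stats::dbinom(0, 100, p0) * (1 + 1e-7)])
  expect_equal(res2$p.value, p_hand)
  expect_lt(res2$p.value, 0.001)
  expect_equal(res2$direction, -1)

  # direction sign matches the raw proportion difference; BH across rows
  counts3 <- tibble::tibble(
    category = c("up", "down", "flat"),
    count_a = c(40L, 5L, 20L),
    count_b = c(10L, 40L, 20L)
  )
  res3 <- binomial_enrichment(counts3, n_a = 100L, n_b = 100L)
  expect_equal(
    res3$direction[match(c("up", "down", "flat"), res3$category)],
    c(1, -1, 0)
  )
  expect_true(all(res3$q.value >= res3$p.value))
  expect_true(all(res3$p.value > 0 & res3$p.value <= 1))

  expect_error(binomial_enrichment(counts, n_a = 0L, n_b = 10L), "positive")
})
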