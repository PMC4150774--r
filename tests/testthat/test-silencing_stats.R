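test_that("fold-change area is the background-minus-target mean difference", {
  expect_equal(fold_change_area(c(-1, -1), c(0, 0)), 1.0)
  expect_equal(fold_change_area(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(fold_change_area(0.5, c(-0.25, 0.75)), -0.25)
  expect_error(fold_change_area(numeric(0), 1), "empty")
})

test_that("fold-change area equals the signed area between the two ECDFs", {
  # independent oracle: integrate F_target - F_background as step functions
  area_between_ecdfs <- function(t, b) {
    Ft <- stats::ecdf(t); Fb <- stats::ecdf(b)
    knots <- sort(unique(c(t, b)))
    lo <- min(knots); hi <- max(knots)
    xs <- sort(unique(c(knots, lo, hi)))
    total <- 0
    for (i in seq_len(length(xs) - 1)) {
      total <- total + (Ft(xs[i]) - Fb(xs[i])) * (xs[i + 1] - xs[i])
    }
    total
  }
  set.seed(55)
  for (i in 1:10) {
    t <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1), 0.3)
    expect_equal(fold_change_area(t, b), area_between_ecdfs(t, b),
                 tolerance = 1e-9)
  }
})

test_that("fold-change area is centered at zero under label permutation", {
  set.seed(66)
  pool <- rnorm(60)
  stats <- replicate(1500, {
    idx <- sample(60, 20)
    fold_change_area(pool[idx], pool[-idx])
  })
  se <- sd(stats) / sqrt(length(stats))
  expect_lt(abs(mean(stats)), 3 * se)
})

test_that("small-sample rank-sum p-values come from exact enumeration", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(res$p_value, 0.05) # 1 / choose(6, 3)
  expect_identical(res$method, "exact")

  # agreement with the bitmask enumeration oracle, with and without ties
  set.seed(77)
  for (i in 1:12) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(1:5, n, replace = TRUE)  # ties very likely
    y <- sample(1:5, m, replace = TRUE)
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(rank_sum_test(x, y, alt)$p_value,
                   oracle_rank_sum(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("tie-free exact p-values match the classical Wilcoxon distribution", {
  set.seed(88)
  for (i in 1:10) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(m)
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(rank_sum_test(x, y, alt)$p_value,
                   wilcox.test(x, y, alternative = alt, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("identical and degenerate samples give null p-values", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_gte(rank_sum_test(x, x, "less")$p_value, 0.4)
  expect_warning(res <- rank_sum_test(rep(1, 3), rep(1, 4)), "constant")
  expect_equal(res$p_value, 1)
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(99)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  res <- rank_sum_test(x, y, "less")
  expect_identical(res$method, "normal")
  expect_equal(res$p_value,
               wilcox.test(x, y, alternative = "less", exact = FALSE,
                           correct = TRUE)$p.value)
})

test_that("cumulative curves are valid right-continuous ECDFs", {
  expect_equal(cumulative_curve(0), tibble::tibble(M = 0, fraction = 1))
  cc <- cumulative_curve(c(-1, 0, 1))
  expect_equal(cc$fraction, c(1, 2, 3) / 3)
  # duplicated values collapse to one double-height step
  cc2 <- cumulative_curve(c(-1, 0, 0, 1))
  expect_identical(nrow(cc2), 3L)
  expect_equal(cc2$fraction, c(0.25, 0.75, 1))
  expect_true(all(diff(cc2$fraction) > 0))
  expect_equal(cc2$fraction[nrow(cc2)], 1)
})

test_that("pearson correlation validates input and hits the textbook cases", {
  x <- c(1, 3, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "constant")
  # invariance under positive-slope affine transforms
  y <- c(2, 0, 5, 4)
  expect_equal(pearson_r(10 + 3 * x, y), pearson_r(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, -2 + 0.5 * y), pearson_r(x, y), tolerance = 1e-12)
})

test_that("the packaged Tm / fold-change pairs correlate at 0.82", {
  res <- correlate_tm_silencing()
  expect_identical(res$n, 5L)
  expect_equal(round(res$r, 2), 0.82)
})

test_that("delta-delta-Ct relative expression behaves as 2^-ddCt", {
  expect_equal(qpcr_relative_expression(20, 20, 20, 20), 1.0)
  expect_equal(qpcr_relative_expression(21, 20, 20, 20), 0.5)
  expect_equal(qpcr_relative_expression(18, 20, 20, 20), 4.0)
  expect_error(qpcr_relative_expression(NA, 20, 20, 20), "finite")
})

test_that("per-group comparison joins M values with group structure", {
  m <- fix_motifs()
  mot <- setNames(m$motif, m$group)
  utrs <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:14),
    sequence = c(vapply(rep(mot[["U"]], 4), flanked, character(1)),
                 rep("GGGGGGGGGG", 10))
  )
  tg <- assign_target_groups(utrs, m, fix_dead())
  ma <- tibble::tibble(gene_id = utrs$gene_id,
                       M = c(rep(-1, 4), rep(0, 10)))
  cmp <- compare_groups(ma, tg)
  td <- tidy(cmp)
  u <- td[td$group == "U", ]
  expect_identical(u$n_target, 4L)
  expect_identical(u$n_background, 10L)
  expect_equal(u$fold_change, 1.0)
  expect_true(u$p_value < 0.01 && u$significant)
  # empty groups report their size and no p-value
  a <- td[td$group == "A", ]
  expect_identical(a$n_target, 0L)
  expect_true(is.na(a$p_value))
  g <- glance(cmp)
  expect_identical(g$top_group, "U")
  expect_identical(g$n_significant, 1L)
})

test_that("comparison plots build without error", {
  m <- fix_motifs()
  utrs <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    sequence = c(flanked(m$motif[m$group == "U"]), "GGGGGGGG", "CCCCCCCC")
  )
  tg <- assign_target_groups(utrs, m, fix_dead())
  ma <- tibble::tibble(gene_id = utrs$gene_id, M = c(-1, 0, 0.5))
  p <- autoplot(compare_groups(ma, tg))
  expect_s3_class(p, "ggplot")
})
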