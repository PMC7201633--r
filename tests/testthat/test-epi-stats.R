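# Crude odds ratios, Pearson chi-square, CMH trend, and the
# table-layout report, checked against independent textbook oracles.

test_that("crude OR and Woolf CI reproduce the published gender row", {
  fx <- table1_fixture()
  o <- crude_or(fx$gender, "female")
  expect_equal(round(o$odds_ratio, 2), 1.44)
  expect_equal(round(o$ci_low, 2), 1.16)
  expect_equal(round(o$ci_high, 2), 1.80)
})

test_that("crude OR basics: identity, reciprocity, zero cells", {
  tab <- contingency_table(c("a", "b"), aki = c(30, 30), non_aki = c(70, 70))
  expect_equal(crude_or(tab, "b")$odds_ratio, 1)
  expect_error(crude_or(tab, "a"), "reference")

  tab2 <- contingency_table(c("ref", "exp"), aki = c(20, 45), non_aki = c(80, 55))
  swapped <- contingency_table(c("ref", "exp"), aki = c(20, 45), non_aki = c(80, 55),
                               reference = "exp")
  o <- crude_or(tab2, "exp"); os <- crude_or(swapped, "ref")
  expect_equal(os$odds_ratio, 1 / o$odds_ratio)
  expect_equal(os$ci_low, 1 / o$ci_high)
  expect_equal(os$ci_high, 1 / o$ci_low)

  tabz <- contingency_table(c("ref", "exp"), aki = c(10, 0), non_aki = c(90, 50))
  expect_error(crude_or(tabz, "exp"), "Haldane")
  expect_gt(crude_or(tabz, "exp", haldane = TRUE)$odds_ratio, 0)
})

test_that("Pearson chi-square matches the O/E oracle and the 2x2 closed form", {
  fx <- table1_fixture()
  expect_equal(round(pearson_chi2(fx$gender)$statistic, 3), 10.561)

  # proportional rows: statistic exactly 0
  prop <- contingency_table(c("a", "b"), aki = c(10, 20), non_aki = c(30, 60))
  expect_lt(pearson_chi2(prop)$statistic, 1e-12)

  withr::with_seed(8, {
    for (rep in 1:20) {
      m <- matrix(rpois(6, 40) + 1, 3, 2)
      tab <- contingency_table(letters[1:3], aki = m[, 1], non_aki = m[, 2])
      # independent textbook O/E summation
      E <- outer(rowSums(m), colSums(m)) / sum(m)
      oracle <- sum((m - E)^2 / E)
      got <- pearson_chi2(tab)
      expect_equal(got$statistic, oracle, tolerance = 1e-10)
      expect_equal(got$df, 2L)
    }
    for (rep in 1:20) {
      m <- matrix(rpois(4, 30) + 1, 2, 2)
      tab <- contingency_table(c("a", "b"), aki = m[, 1], non_aki = m[, 2])
      a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]; n <- sum(m)
      closed <- n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
      expect_equal(pearson_chi2(tab)$statistic, closed, tolerance = 1e-10)
    }
  })
  # row permutation invariance
  fx_perm <- contingency_table(rev(fx$sua_band$level), rev(fx$sua_band$aki),
                               rev(fx$sua_band$non_aki))
  expect_equal(pearson_chi2(fx_perm)$statistic, pearson_chi2(fx$sua_band)$statistic)
})

test_that("CMH trend equals the (N-1) r^2 oracle on expanded data", {
  prop <- contingency_table(c("a", "b", "c"), aki = c(10, 20, 30),
                            non_aki = c(40, 80, 120), ordinal = TRUE)
  expect_lt(cmh_trend(prop)$statistic, 1e-12)

  fx <- table1_fixture()
  got <- cmh_trend(fx$sua_band)$statistic
  # individual-level expansion oracle
  tab <- fx$sua_band
  u <- rep(seq_len(nrow(tab)), times = tab$aki + tab$non_aki)
  y <- unlist(lapply(seq_len(nrow(tab)), function(i)
    c(rep(1, tab$aki[i]), rep(0, tab$non_aki[i]))))
  oracle <- (length(u) - 1) * stats::cor(u, y)^2
  expect_equal(got, oracle, tolerance = 1e-10)
  # reproduces the published SUA trend statistic with integer scores
  expect_equal(round(got, 3), 88.388)

  notord <- contingency_table(c("a", "b", "c"), c(1, 2, 3), c(4, 5, 6))
  expect_error(cmh_trend(notord), "ordinal")
})

test_that("the fixture report reproduces the published incidences and rows", {
  rep <- table1_report(table1_fixture())
  expect_equal(round(rep$overall$pct, 1), 15.4)
  expect_equal(rep$overall$n, 2395); expect_equal(rep$overall$aki, 370)

  rows <- rep$rows
  hm <- rows[rows$variable == "hm_category", ]
  expect_equal(round(hm$aki_pct[hm$level == "multiple_myeloma"], 1), 24.1)
  expect_equal(round(hm$aki_pct[hm$level == "leukemia"], 1), 23.9)
  expect_equal(round(hm$aki_pct[hm$level == "lymphoma"], 1), 13.4)

  db <- rows[rows$variable == "diabetes" & rows$level == "yes", ]
  expect_equal(round(db$odds_ratio, 2), 1.58)
  expect_equal(round(db$statistic, 3), 15.748)
  expect_lt(db$p_value, 0.001)
})

test_that("degenerate inputs are flagged and statistics skipped", {
  one_level <- list(x = contingency_table("only", aki = 5, non_aki = 20))
  rep1 <- table1_report(one_level)
  expect_match(paste(rep1$notes, collapse = " "), "single observed level")
  expect_true(all(is.na(rep1$rows$statistic)))

  no_aki <- list(g = contingency_table(c("a", "b"), aki = c(0, 0), non_aki = c(30, 40)))
  rep2 <- table1_report(no_aki)
  expect_match(paste(rep2$notes, collapse = " "), "degenerate")
  expect_true(all(is.na(rep2$rows$odds_ratio)))
})
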