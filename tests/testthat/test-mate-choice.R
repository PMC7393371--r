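test_that("copulation types are tallied per drop", {
  ev <- dplyr::bind_rows(
    fixture_drop_log("drop_01", c("LL", "LJ", "LJ", "JJ")),
    fixture_drop_log("drop_02", c("JJ", "JJ"))
  )
  ct <- count_copulation_types(ev)
  expect_equal(ct$m_LL, c(1L, 0L))
  expect_equal(ct$m_LJ, c(2L, 0L))
  expect_equal(ct$m_JJ, c(1L, 2L))
  expect_equal(ct$m_T, c(4L, 2L))
})

test_that("the first copulation is the earliest event", {
  ev <- fixture_drop_log("drop_01", c("LL", "LJ", "JJ"))
  ev$start_s <- c(500L, 20L, 900L)
  ev$end_s <- ev$start_s + 60L
  ft <- first_copulation_types(ev)
  expect_equal(ft$first_type, "LJ")
  # a record with no copulations gives NA
  ev2 <- fixture_drop_log("drop_02", "LL")
  ev2$event_kind <- "suck"
  ev2$copulation_type <- NA_character_
  expect_true(is.na(first_copulation_types(ev2)$first_type))
})

test_that("first-copulation chi-square reproduces the published statistic", {
  res <- first_copulation_test(c(LL = 34, LJ = 18, JJ = 7))
  expect_equal(round(res$statistic, 2), 33.68)
  expect_equal(res$df, 2L)
  expect_lt(res$p_value, 1e-6)
  # all three input forms agree
  vec <- rep(c("LL", "LJ", "JJ"), c(34, 18, 7))
  expect_equal(first_copulation_test(vec)$statistic, res$statistic)
  tb <- tibble::tibble(drop_id = seq_along(vec), first_type = vec)
  expect_equal(first_copulation_test(tb)$statistic, res$statistic)
})

test_that("chi-square goodness of fit has known closed-form values", {
  # observed equal to expected -> exactly zero
  expect_equal(first_copulation_test(c(LL = 5, LJ = 10, JJ = 5))$statistic, 0)
  # (8, 4, 8) against (5, 10, 5): 9/5 + 36/10 + 9/5 = 7.2
  expect_equal(first_copulation_test(c(LL = 8, LJ = 4, JJ = 8))$statistic, 7.2)
  expect_error(first_copulation_test(character(0)), "no drops")
})

test_that("G goodness of fit has known closed-form values", {
  g <- g_goodness_of_fit(c(10, 0), c(0.5, 0.5))
  expect_equal(g$statistic, 2 * 10 * log(2)) # 13.8629...
  expect_equal(g$df, 1L)
  expect_false(g$infinite_g)
  # observed at expectation -> G = 0
  expect_equal(g_goodness_of_fit(c(5, 10, 5), c(0.25, 0.5, 0.25))$statistic, 0)
  # positive count in a zero-probability category -> flagged infinite
  gi <- g_goodness_of_fit(c(3, 1), c(1, 0))
  expect_true(gi$infinite_g)
  expect_equal(gi$statistic, Inf)
  expect_error(g_goodness_of_fit(c(1, 1), c(0.5, 0.4)), "sum to 1")
})

test_that("chi-square and G agree on large multinomials", {
  set.seed(3)
  probs <- c(0.25, 0.5, 0.25)
  obs <- as.numeric(rmultinom(1, 1e4, c(0.27, 0.49, 0.24)))
  g <- g_goodness_of_fit(obs, probs)$statistic
  x2 <- sum((obs - probs * 1e4)^2 / (probs * 1e4))
  expect_lt(abs(g - x2) / x2, 0.02)
})

test_that("repeated G-tests report the heterogeneity df of the drops-by-types table", {
  counts <- fixture_drop_counts(59L)
  rg <- repeated_g_tests(counts)
  expect_s3_class(rg, "repeated_g")
  expect_equal(rg$heterogeneity$df, 116L) # (59 - 1) * (3 - 1)
  expect_equal(nrow(rg$per_drop), 59L)
  expect_equal(rg$per_drop$df, rep(2L, 59L))
  expect_equal(rg$total$df, 118L)
})

test_that("total G = pooled G + heterogeneity G, exactly", {
  set.seed(17)
  for (rep in 1:5) {
    counts <- tibble::tibble(
      drop_id = sprintf("d%02d", 1:20),
      m_LL = rpois(20, 4) + 1L, m_LJ = rpois(20, 6) + 1L,
      m_JJ = rpois(20, 3) + 1L
    )
    rg <- repeated_g_tests(counts)
    expect_equal(rg$total$statistic,
                 rg$pooled$statistic + rg$heterogeneity$statistic,
                 tolerance = 1e-8)
  }
})

test_that("repeated G-tests exclude empty drops and apply Bonferroni", {
  counts <- fixture_drop_counts(10L)
  counts[11, ] <- list("drop_11", 0L, 0L, 0L, 0L)
  expect_message(rg <- repeated_g_tests(counts), "zero copulations")
  expect_equal(rg$n_drops, 10L)
  expect_equal(rg$per_drop$p_bonferroni,
               pmin(1, rg$per_drop$p_value * 10))
  expect_error(suppressMessages(repeated_g_tests(counts[11, ])),
               "at least 2 drops")
})

test_that("pooling is flagged invalid under strong heterogeneity", {
  het <- tibble::tibble(drop_id = c("a", "b"),
                        m_LL = c(40L, 0L), m_LJ = c(10L, 10L),
                        m_JJ = c(0L, 40L))
  expect_false(repeated_g_tests(het)$pooling_valid)
  hom <- tibble::tibble(drop_id = c("a", "b"),
                        m_LL = c(5L, 5L), m_LJ = c(10L, 10L),
                        m_JJ = c(5L, 5L))
  expect_true(repeated_g_tests(hom)$pooling_valid)
})

test_that("mating rates follow the participation formula", {
  ct <- tibble::tibble(drop_id = "d1", m_LL = 3L, m_LJ = 2L, m_JJ = 1L)
  mr <- mating_rates(ct)
  expect_equal(mr$p, (2 * 3 + 2) / (2 * 6)) # 2/3
  expect_equal(mr$q, 1 - mr$p)
  empty <- mating_rates(tibble::tibble(drop_id = "d0", m_LL = 0L,
                                       m_LJ = 0L, m_JJ = 0L))
  expect_true(is.na(empty$p) && is.na(empty$q))
})

test_that("rate-adjusted expectations are Hardy-Weinberg and sum to m_T", {
  e <- rate_adjusted_expected(p = 2 / 3, q = 1 / 3, m_T = 9)
  expect_equal(as.numeric(e), c(4, 4, 1))
  expect_equal(sum(e), 9)
  expect_error(rate_adjusted_expected(0.7, 0.7, 10), "p \\+ q")
})

test_that("rate-adjusted test has known fixed points and values", {
  # counts exactly at the Hardy-Weinberg proportions of their own p
  hw <- tibble::tibble(drop_id = c("a", "b"),
                       m_LL = c(4L, 4L), m_LJ = c(8L, 4L), m_JJ = c(4L, 1L))
  res <- rate_adjusted_test(hw)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p_df1, c(1, 1))
  # (6, 0, 6): p = 1/2, expected (3, 6, 3), chi-square = 3 + 6 + 3 = 12
  dis <- rate_adjusted_test(tibble::tibble(drop_id = "c", m_LL = 6L,
                                           m_LJ = 0L, m_JJ = 6L))
  expect_equal(dis$statistic, 12)
  expect_equal(dis$p_df1, pchisq(12, 1, lower.tail = FALSE))
  expect_equal(dis$p_df2, pchisq(12, 2, lower.tail = FALSE))
  expect_equal(dis$p_value, dis$p_df2) # default df = 2
  expect_equal(rate_adjusted_test(dis[, 1:4], df = 1L)$p_value, dis$p_df1)
  # monomorphic drop: p = 1, expectations concentrate on LL, statistic 0
  mono <- rate_adjusted_test(tibble::tibble(drop_id = "m", m_LL = 7L,
                                            m_LJ = 0L, m_JJ = 0L))
  expect_equal(mono$statistic, 0)
})

test_that("rate-adjusted test keeps type-I error at or below nominal", {
  # study conditions, no preference: the null the test is used under
  ev <- sim_drops(sim_params(seed = 31), n_drops = 250)
  ct <- count_copulation_types(ev)
  ct <- ct[ct$m_T > 0, ]
  res <- rate_adjusted_test(ct)
  n <- nrow(res)
  expect_gt(n, 200)
  # rejection rate within 3 binomial SE above nominal at the default df
  expect_lt(mean(res$p_value < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
  # and no Bonferroni-corrected rejections
  expect_equal(sum(res$p_bonferroni < 0.05), 0L)
})

test_that("rate-adjusted test has power under strong conspecific preference", {
  params <- sim_params(seed = 13, propensity_J = 1, preference = 10,
                       base_rate_per_hour = 18)
  ev <- sim_drops(params, n_drops = 60)
  ct <- count_copulation_types(ev)
  big <- ct[ct$m_T >= 50, ]
  expect_gt(nrow(big), 30)
  res <- rate_adjusted_test(big)
  expect_gt(mean(res$p_value < 0.05), 0.8)
  expect_gt(mean(res$p_df1 < 0.05), 0.8)
})

test_that("gof_test and repeated_g expose broom-style methods", {
  res <- first_copulation_test(c(LL = 34, LJ = 18, JJ = 7))
  td <- tidy(res)
  expect_equal(td$category, c("LL", "LJ", "JJ"))
  expect_equal(sum(td$expected), sum(td$observed))
  gl <- glance(res)
  expect_equal(gl$statistic, res$statistic)
  expect_output(print(res), "chisq_gof")

  rg <- repeated_g_tests(fixture_drop_counts(12L))
  expect_equal(nrow(tidy(rg)), 12L)
  expect_named(glance(rg), c("n_drops", "heterogeneity_g", "heterogeneity_df",
                             "heterogeneity_p", "pooled_g", "total_g",
                             "pooling_valid"))
  expect_output(print(rg), "heterogeneity G")
})
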