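test_that("relative_distance_index reproduces the worked examples", {
  expect_equal(relative_distance_index(c(2, 2), c(2, 2))$value, 0)
  expect_equal(relative_distance_index(1, 3)$value, 0.5)
  expect_equal(relative_distance_index(c(1, 2), c(3, 4))$value,
               (0.5 + 0.6 + 0.2 + 1 / 3) / 4, tolerance = 1e-12)
  # all-negative values (carbon isotope-like) are negated first
  expect_equal(relative_distance_index(-28, -26)$value, 2 / 54,
               tolerance = 1e-12)
})

test_that("index errors on undefined inputs", {
  expect_error(relative_distance_index(c(-1, 2), c(3, 4)), "mixed-sign")
  expect_error(relative_distance_index(numeric(0), 1), "at least one")
  expect_error(relative_distance_index(c(1, NA), 2), "non-finite")
  expect_error(relative_distance_index(0, 0), "zero denominator")
})

test_that("index equals the brute-force pair enumeration", {
  withr::with_seed(101, {
    for (i in 1:60) {
      n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
      neg <- runif(1) < 0.3
      ww <- round(runif(n1, 0, 5), 3)
      ws <- round(runif(n2, 0, 5), 3)
      if (neg) { ww <- -ww - 0.1; ws <- -ws - 0.1 }
      res <- relative_distance_index(ww, ws)
      expect_equal(res$value, rdpi_oracle(ww, ws), tolerance = 1e-12)
      expect_equal(res$n_pairs + res$n_dropped, n1 * n2)
    }
  })
})

test_that("index is bounded, scale-free, symmetric and monotone", {
  withr::with_seed(202, {
    for (i in 1:40) {
      ww <- runif(sample(2:5, 1), 0.1, 10)
      ws <- runif(sample(2:5, 1), 0.1, 10)
      v <- relative_distance_index(ww, ws)$value
      expect_gte(v, 0); expect_lte(v, 1)
      # invariant to common positive scaling and to treatment swap
      s <- runif(1, 0.1, 100)
      expect_equal(relative_distance_index(s * ww, s * ws)$value, v,
                   tolerance = 1e-12)
      expect_equal(relative_distance_index(ws, ww)$value, v,
                   tolerance = 1e-12)
      # with WS already above the whole WW range, shifting WS further away
      # cannot decrease the index
      ws_hi <- ws + max(ww)
      v_hi <- relative_distance_index(ww, ws_hi)$value
      expect_gte(relative_distance_index(ww, ws_hi + runif(1, 0, 10))$value +
                   1e-12, v_hi)
    }
  })
})

test_that("indices_per_family separates phases and reports shape", {
  des <- experiment_design(n_families = 16, replicates = 2)
  tab <- simulate_experiment(des, seed = 13)
  pp <- indices_per_family(tab, "PP")
  re <- indices_per_family(tab, "RE")
  expect_setequal(unique(pp$family), des$families)
  expect_setequal(unique(pp$trait), trait_vocabulary()$trait)
  expect_true(all(unique(re$trait) %in% gas_exchange_traits()))
  expect_true(all(pp$value >= 0 & pp$value <= 1, na.rm = TRUE))
  expect_true(all(pp$kind == "PP") && all(re$kind == "RE"))

  im <- index_matrix(pp, re)
  expect_equal(nrow(im), 16L)
  expect_true(all(startsWith(colnames(im), "PP-") |
                    startsWith(colnames(im), "RE-")))

  # stress values differ, recovery values identical -> PP > 0, RE = 0
  # (the index is zero only when every cross-treatment pair is identical)
  ww <- list(`1` = c(10, 11), `2` = c(9, 10))
  rec <- list(`1` = c(10, 10), `2` = c(9, 9))
  tab2 <- rbind(
    as.data.frame(make_index_table(ww, list(`1` = c(4, 5), `2` = c(3, 4)))),
    as.data.frame(make_index_table(rec, rec, phase = "recovery")))
  tab2$seedling_id <- paste0(tab2$seedling_id, "_", tab2$phase)
  tab2 <- trait_table(tab2)
  expect_true(all(indices_per_family(tab2, "PP")$value > 0))
  expect_true(all(indices_per_family(tab2, "RE")$value == 0))
})

test_that("a family missing one treatment yields a flagged NA cell", {
  tab <- make_index_table(list(`1` = c(1, 2), `2` = c(1, 2)),
                          list(`1` = c(3, 4), `2` = c(3, 4)))
  tab <- trait_table(as.data.frame(tab)[!(tab$family == "2" &
                                            tab$treatment == "WS"), ])
  expect_warning(res <- indices_per_family(tab, "PP"), "missing a treatment")
  expect_true(is.na(res$value[res$family == "2"]))
  expect_false(is.na(res$value[res$family == "1"]))
})

test_that("family_difference_test validates its preconditions", {
  tab <- make_index_table(list(`1` = c(1, 2), `2` = c(1, 2)),
                          list(`1` = c(3, 4), `2` = c(3, 4)))
  expect_error(family_difference_test(tab, "A_area", "PP", n_perm = 0),
               "at least 99")
  one <- trait_table(as.data.frame(tab)[tab$family == "1", ])
  expect_error(family_difference_test(one, "A_area", "PP", n_perm = 99),
               "at least 2 families")
})

test_that("family_difference_test is deterministic and detects real differences", {
  # family A: no plasticity; family B: strong plasticity (index ~ 0.6)
  withr::with_seed(77, {
    rejected <- 0L
    for (rep in 1:30) {
      ww_a <- rnorm(5, 10, 0.3); ws_a <- rnorm(5, 10, 0.3)
      ww_b <- rnorm(5, 10, 0.3); ws_b <- rnorm(5, 40, 1.2)
      tab <- make_index_table(list(A = ww_a, B = ww_b),
                              list(A = ws_a, B = ws_b))
      ht <- family_difference_test(tab, "A_area", "PP", n_perm = 199,
                                   seed = rep)
      if (ht$p.value <= 0.05) rejected <- rejected + 1L
    }
    expect_gte(rejected, 27L)  # >= 90% power expected
  })

  tab <- make_index_table(list(A = c(1, 2, 3), B = c(2, 3, 4)),
                          list(A = c(4, 5, 6), B = c(3, 4, 5)))
  h1 <- family_difference_test(tab, "A_area", "PP", n_perm = 199, seed = 4)
  h2 <- family_difference_test(tab, "A_area", "PP", n_perm = 199, seed = 4)
  expect_identical(h1$p.value, h2$p.value)
  expect_identical(unname(h1$statistic), unname(h2$statistic))
})
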