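# hand-rolled balanced two-way ANOVA oracle (treatment x family, no block)
anova_oracle <- function(values, treatment, family) {
  g <- mean(values)
  mt <- tapply(values, treatment, mean)
  mf <- tapply(values, family, mean)
  mtf <- tapply(values, interaction(treatment, family), mean)
  nt <- table(treatment); nf <- table(family)
  ntf <- table(interaction(treatment, family))
  ss_t <- sum(nt * (mt - g)^2)
  ss_f <- sum(nf * (mf - g)^2)
  ss_cells <- sum(ntf * (mtf - g)^2)
  ss_tf <- ss_cells - ss_t - ss_f
  ss_res <- sum((values - mtf[interaction(treatment, family)])^2)
  c(Treatment = ss_t, Family = ss_f, `Treatment x Family` = ss_tf,
    Residuals = ss_res)
}

toy_table <- function(values) {
  grid <- expand.grid(rep = 1:3, treatment = c("WW", "WS"),
                      family = c("1", "2"), stringsAsFactors = FALSE)
  trait_table(data.frame(
    seedling_id = sprintf("s%02d", seq_len(nrow(grid))),
    family = grid$family, block = 1L, treatment = grid$treatment,
    phase = "recovery", trait = "A_area", value = values))
}

test_that("two-way ANOVA matches the hand-computed SS partition", {
  values <- c(1, 3, 2, 2, 6, 4, 2, 3, 4, 5, 7, 9)
  tab <- toy_table(values)
  res <- two_way_anova(tab, "A_area", "recovery")
  grid <- as.data.frame(tab)
  oracle <- anova_oracle(grid$value, grid$treatment, grid$family)
  got <- setNames(res$table$sum_sq, res$table$term)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
  expect_identical(res$table$df[res$table$term == "Treatment"], 1L)
  expect_identical(res$table$df[res$table$term == "Family"], 1L)
  expect_true(all(res$table$sum_sq >= 0))
})

test_that("ANOVA is invariant to location shifts, row order and block relabels", {
  tab <- simulate_experiment(experiment_design(n_families = 4,
                                               replicates = 3), seed = 8)
  r1 <- two_way_anova(tab, "A_area", "recovery")

  shifted <- as.data.frame(tab)
  sel <- shifted$trait == "A_area" & shifted$phase == "recovery"
  shifted$value[sel] <- shifted$value[sel] + 100
  r2 <- two_way_anova(trait_table(shifted), "A_area", "recovery")
  expect_equal(r1$table$sum_sq, r2$table$sum_sq, tolerance = 1e-8)

  reordered <- withr::with_seed(3, trait_table(
    as.data.frame(tab)[sample.int(nrow(tab)), ]))
  r3 <- two_way_anova(reordered, "A_area", "recovery")
  expect_equal(r1$table$sum_sq, r3$table$sum_sq, tolerance = 1e-10)

  relabeled <- as.data.frame(tab)
  relabeled$block <- 3L - relabeled$block  # swap block labels 1 <-> 2
  r4 <- two_way_anova(trait_table(relabeled), "A_area", "recovery")
  expect_equal(r1$table$sum_sq[r1$table$term != "Block"],
               r4$table$sum_sq[r4$table$term != "Block"], tolerance = 1e-8)
  expect_equal(r1$table$sum_sq[r1$table$term == "Block"],
               r4$table$sum_sq[r4$table$term == "Block"], tolerance = 1e-8)
})

test_that("empty or thin cells are reported by name", {
  tab <- simulate_experiment(experiment_design(n_families = 3,
                                               replicates = 2), seed = 2)
  df <- as.data.frame(tab)
  drop <- df$family == "2" & df$treatment == "WS" &
    df$trait == "A_area" & df$phase == "recovery"
  thin <- trait_table(df[!drop, ])
  expect_error(two_way_anova(thin, "A_area", "recovery"),
               "family 2.*fewer than 2")
  expect_error(two_way_anova(tab, "SLA", "recovery"), "no observations")
})

test_that("type-I error of all three terms is nominal under the null", {
  n_rep <- 400
  reject <- matrix(FALSE, n_rep, 3)
  withr::with_seed(55, {
    grid <- expand.grid(rep = 1:4, treatment = c("WW", "WS"),
                        family = as.character(1:4), block = 1:2,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n_rep)) {
      tab <- trait_table(data.frame(
        seedling_id = sprintf("s%03d", seq_len(nrow(grid))),
        family = grid$family, block = grid$block,
        treatment = grid$treatment, phase = "recovery", trait = "A_area",
        value = rnorm(nrow(grid), 10, 1)))
      p <- two_way_anova(tab, "A_area", "recovery")$table$p
      reject[i, ] <- p[1:3] < 0.05
    }
  })
  rate <- colMeans(reject)
  expect_true(all(rate > 0.02 & rate < 0.09))
})

test_that("check_assumptions returns calibrated Shapiro-Wilk results", {
  n_rep <- 500
  rej <- withr::with_seed(7, vapply(seq_len(n_rep), function(i) {
    r <- rnorm(40)
    check_assumptions(r, rep(1:2, each = 20))$shapiro_p < 0.05
  }, logical(1)))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("the Brown-Forsythe test detects unequal spread", {
  n_rep <- 200
  rej <- withr::with_seed(17, vapply(seq_len(n_rep), function(i) {
    r <- c(rnorm(50, 0, 1), rnorm(50, 0, 3))
    check_assumptions(r, rep(c("a", "b"), each = 50))$levene_p < 0.05
  }, logical(1)))
  expect_gte(mean(rej), 0.9)
})

test_that("degenerate assumption-check inputs error", {
  expect_error(check_assumptions(rep(1, 10), rep(1:2, 5)), "constant")
  expect_error(check_assumptions(c(1, 2), rep(1, 2)), "at least 3")
  expect_error(check_assumptions(c(1, 2, 3), rep(1, 3)), "at least 2 groups")
  # identical values within each group: zero deviations from group medians
  expect_error(check_assumptions(rep(c(1, 5), each = 5),
                                 rep(c("a", "b"), each = 5)),
               "Levene test undefined")
})
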