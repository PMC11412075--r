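planted_matrix <- function(n_col = 20, offset = 1, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(16 * n_col, 0, noise), 16, n_col)
    m[9:16, ] <- m[9:16, ] + offset
    rownames(m) <- as.character(1:16)
    colnames(m) <- paste0("V", seq_len(n_col))
    m
  })
}

test_that("identical rows merge first at height zero", {
  m <- matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  tree <- cluster_families(m, B = 10, seed = 1)
  expect_equal(tree$hclust$height[1], 0)
  expect_setequal(tree$clades[[1]], c("a", "b"))
})

test_that("cluster_families validates input", {
  m <- planted_matrix()
  expect_error(cluster_families(m, B = 0), "at least 1")
  m2 <- m; m2[1, 1] <- NA
  expect_error(cluster_families(m2, B = 10), "missing")
  expect_error(cluster_families(m[1, , drop = FALSE], B = 10),
               "at least 2 families")
})

test_that("planted family groups get high bootstrap support", {
  tree <- cluster_families(planted_matrix(), B = 200, seed = 42)
  keys <- vapply(tree$clades, function(s) paste(sort(s), collapse = ","),
                 character(1))
  g1 <- paste(sort(as.character(1:8)), collapse = ",")
  g2 <- paste(sort(as.character(9:16)), collapse = ",")
  expect_true(all(c(g1, g2) %in% keys))
  expect_gte(tree$support[match(g1, keys)], 0.95)
  expect_gte(tree$support[match(g2, keys)], 0.95)
})

test_that("support is seed-reproducible and invariant to row order", {
  m <- planted_matrix(noise = 0.3, offset = 0.5)
  t1 <- cluster_families(m, B = 50, seed = 9)
  t2 <- cluster_families(m, B = 50, seed = 9)
  expect_identical(t1$support, t2$support)

  perm <- withr::with_seed(2, sample.int(nrow(m)))
  t3 <- cluster_families(m[perm, ], B = 50, seed = 9)
  key <- function(tr) vapply(tr$clades, function(s)
    paste(sort(s), collapse = ","), character(1))
  expect_setequal(key(t1), key(t3))
  expect_equal(t1$support[order(key(t1))], t3$support[order(key(t3))])
})

test_that("PCA satisfies its algebraic contracts", {
  withr::with_seed(31, {
    # two perfectly correlated columns: PC1 carries everything
    x <- rnorm(16)
    m2 <- cbind(a = x, b = 2 * x + 3)
    p2 <- pca_families(m2)
    expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-12)

    m <- matrix(rnorm(16 * 6), 16, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    p <- pca_families(m)
    expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
    # full reconstruction from all components
    rec <- p$scores %*% t(p$loadings)
    rec <- sweep(sweep(rec, 2, p$scale, `*`), 2, p$center, `+`)
    expect_lt(max(abs(rec - m)) / max(abs(m)), 1e-8)
    # deterministic sign convention
    for (k in seq_len(ncol(p$loadings))) {
      l <- p$loadings[, k]
      expect_gt(l[which.max(abs(l))], 0)
    }
  })
  m <- matrix(rnorm(32), 16, 2, dimnames = list(NULL, c("ok", "flat")))
  m[, 2] <- 5
  expect_error(pca_families(m), "zero-variance.*flat")
})

test_that("a planted two-factor structure is recovered", {
  hits <- 0L
  for (s in 1:40) {
    m <- withr::with_seed(1000 + s, {
      f1 <- rnorm(16)
      f2 <- rnorm(16)
      # orthogonalize in sample so the planted factors are identifiable
      # (otherwise chance factor correlation at n = 16 rotates the axes)
      f2 <- resid(lm(f2 ~ f1))
      f1 <- scale(f1)[, 1]; f2 <- scale(f2)[, 1]
      load <- sqrt(0.9)
      cbind(
        sapply(1:6, function(j) load * f1 + sqrt(0.1) * rnorm(16)),
        sapply(1:4, function(j) load * f2 + sqrt(0.1) * rnorm(16)))
    })
    colnames(m) <- paste0("V", 1:10)
    p <- pca_families(m)
    two_retained <- length(p$retained) == 2L
    # each block's variables must load together (same dominant component)
    dom <- apply(abs(p$loadings[, 1:2]), 1, which.max)
    blocks_ok <- length(unique(dom[1:6])) == 1L &&
      length(unique(dom[7:10])) == 1L && dom[1] != dom[7]
    if (two_retained && blocks_ok) hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # >= 95% of seeds
})

test_that("bh_adjust matches the hand-worked example and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      q <- bh_adjust(p)
      expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("correlation matrix obeys its invariants", {
  m <- planted_matrix(noise = 0.5, offset = 0.3)
  cm <- correlation_matrix(m)
  expect_equal(diag(cm$r), rep(1, ncol(m)), ignore_attr = TRUE)
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
  expect_true(all(is.na(diag(cm$q))))
  expect_false(any(diag(cm$significant)))
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  up <- upper.tri(cm$q)
  expect_true(all(cm$q[up] >= cm$p[up] - 1e-15))

  m2 <- m; m2[, 3] <- 7
  cm2 <- correlation_matrix(m2)
  expect_true(all(is.na(cm2$r[3, ])))
  expect_false(any(cm2$significant[3, ]))
  expect_error(correlation_matrix(m[1:3, ]), "at least 4 rows")
})
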