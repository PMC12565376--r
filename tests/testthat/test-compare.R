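test_that("the rank test matches a hand-computed H and degenerate ties", {
  same <- data.frame(group = rep(c("a", "b"), each = 4), value = rep(2, 8))
  out <- kruskal_wallis(same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  df <- data.frame(
    group = rep(c("a", "b"), each = 3),
    value = c(1, 2, 3, 101, 102, 103)
  )
  # oracle: H = 12/(n(n+1)) * sum R_j^2/n_j - 3(n+1), ranks 1..6, no ties
  h_oracle <- 12 / (6 * 7) * ((1 + 2 + 3)^2 / 3 + (4 + 5 + 6)^2 / 3) - 3 * 7
  out2 <- kruskal_wallis(df)
  expect_equal(out2$statistic, h_oracle, tolerance = 1e-12)
  expect_equal(out2$df, 1)

  expect_error(
    kruskal_wallis(data.frame(group = "a", value = 1:3)), "at least 2"
  )
})

test_that("H is invariant under strictly monotone transforms", {
  withr::with_seed(10, {
    df <- data.frame(
      group = rep(c("a", "b", "c"), each = 8),
      value = c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
    )
  })
  h1 <- kruskal_wallis(df)$statistic
  df$value <- exp(df$value)
  expect_equal(kruskal_wallis(df)$statistic, h1, tolerance = 1e-12)
})

test_that("pairwise EMD matrices are symmetric with zero diagonal", {
  withr::with_seed(11, {
    samples <- setNames(
      lapply(1:7, function(i) rgamma(60, 4, scale = 0.05 * i)),
      c("anger", "contempt", "disgust", "fear", "happiness", "sadness", "surprise")
    )
  })
  m <- pairwise_emd(samples)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(0, 7))
  off <- m[upper.tri(m)]
  expect_equal(length(off), 21)
  expect_true(all(off > 0))

  small <- c(samples[1:2], list(tiny = c(0.1, 0.2)))
  m2 <- pairwise_emd(small)
  expect_true(is.na(m2["tiny", "anger"]))
  expect_equal(attr(m2, "insufficient"), "tiny")
})

test_that("pairwise significance marks nest and respect separation", {
  withr::with_seed(12, {
    samples <- list(
      a = rgamma(200, 4, scale = 0.1),
      b = rgamma(200, 4, scale = 0.4),
      c = rgamma(200, 4, scale = 0.1)
    )
  })
  ps <- pairwise_significance(samples)
  expect_equal(unname(diag(ps$p)), rep(1, 3))
  expect_lt(ps$p["a", "b"], 0.01)
  expect_equal(ps$marks["a", "b"], "**")
  # every p<0.01 cell is also p<0.05: stars imply at least a circle
  expect_true(all(ps$p[ps$marks == "**"] < 0.05))

  ident <- list(a = 1:10, b = 1:10)
  psi <- pairwise_significance(ident)
  expect_equal(psi$p["a", "b"], 1)
  expect_equal(psi$marks["a", "b"], "")

  bh <- pairwise_significance(samples, adjust = "BH")
  expect_true(all(bh$p >= ps$p - 1e-12))
})
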