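test_that("questionnaire scoring respects bounds and reverse coding", {
  neo <- instrument("neophobia")
  maq <- instrument("meat_attachment")
  expect_equal(neo$score_range, c(10, 70))
  expect_equal(maq$score_range, c(16, 80))

  resp <- function(n_items, value) {
    data.frame(participant = "p1", item = seq_len(n_items), response = value)
  }
  # floors: all items at scale minimum with no reverse items
  expect_equal(unname(score_instrument(resp(16, 1), maq)), 16)
  # neophobia ceiling: all items at the maximum
  # (reverse-coded items at 7 reflect to 1, so answer the reverse items 1)
  r <- resp(10, 7)
  r$response[neo$reverse_items] <- 1
  expect_equal(unname(score_instrument(r, neo)), 70)
  # a reverse-coded 7-point item answered 2 contributes 6
  one_rev <- instrument("neophobia", reverse_items = 3)
  r <- resp(10, 1)
  r$response[3] <- 2
  expect_equal(unname(score_instrument(r, one_rev)), 9 * 1 + 6)

  bad <- resp(10, 8)
  expect_error(score_instrument(bad, neo), "out-of-scale")

  # property: random responses always score inside the instrument range
  set.seed(61)
  for (rep in 1:20) {
    r <- resp(10, sample(1:7, 10, replace = TRUE))
    total <- score_instrument(r, neo)
    expect_gte(total, 10); expect_lte(total, 70)
  }
})

test_that("feature summaries compute per-cell sample statistics", {
  tab <- likert_table(expand.grid(participant = c("p1", "p2"),
                                  product = c("A", "B"),
                                  feature = "soft",
                                  stringsAsFactors = FALSE) |>
                        transform(score = c(3L, 3L, 1L, 5L)))
  s <- summarize_features(tab)
  a <- s[s$product == "A", ]
  b <- s[s$product == "B", ]
  expect_equal(a$mean, 3); expect_equal(a$sd, 0)
  expect_equal(b$mean, 3); expect_equal(b$sd, sqrt(8), tolerance = 1e-12)
  expect_equal(b$n, 2)
})

test_that("one-way ANOVA across products matches the sums-of-squares oracle", {
  groups <- list(c(1, 2, 2, 3), c(3, 4, 4, 5), c(2, 2, 3, 3))
  tab <- likert_table(data.frame(
    participant = rep(sprintf("p%d", 1:4), 3),
    product = rep(c("A", "B", "C"), each = 4),
    feature = "chewy",
    score = as.integer(unlist(groups))))
  got <- feature_anova(tab, "chewy")
  expect_equal(got$F, anova_f_oracle(groups), tolerance = 1e-12)
  expect_equal(got$df, c(2, 9))

  # fully separated means are overwhelmingly significant
  sep <- likert_table(data.frame(
    participant = rep(sprintf("p%d", 1:3), 3),
    product = rep(c("A", "B", "C"), each = 3),
    feature = "hard",
    score = c(1L, 1L, 2L, 5L, 5L, 4L, 3L, 3L, 3L)))
  expect_lt(feature_anova(sep, "hard")$p_value, 1e-3)

  # F is invariant to adding a constant to every score
  shifted <- tab; shifted$score <- shifted$score + 1L
  expect_equal(feature_anova(likert_table(shifted, scale_points = 6),
                             "chewy")$F, got$F, tolerance = 1e-12)

  # zero total variance: flagged, not significant
  flat <- likert_table(data.frame(participant = rep(c("p1", "p2"), 2),
                                  product = rep(c("A", "B"), each = 2),
                                  feature = "moist", score = 3L))
  deg <- feature_anova(flat, "moist")
  expect_true(deg$degenerate)
  expect_false(deg$significant)
})

test_that("Spearman coefficient matches the rank formula at the published
           n = 8 configurations", {
  expect_equal(spearman_cor(1:5, 1:5)$rho, 1)
  # sum(d^2) = 12 at n = 8: rho = 1 - 72/504
  y <- c(3, 2, 1, 5, 4, 7, 6, 8); stopifnot(sum((1:8 - y)^2) == 12)
  s <- spearman_cor(1:8, y)
  expect_equal(s$rho, 1 - 6 * 12 / (8 * 63), tolerance = 1e-12)
  expect_equal(s$rho, 0.857142857, tolerance = 1e-8)
  expect_equal(s$method, "exact_permutation")
  # sum(d^2) = 6: rho = 0.928571...; exact p from full enumeration
  y2 <- c(2, 1, 4, 3, 6, 5, 7, 8); stopifnot(sum((1:8 - y2)^2) == 6)
  s2 <- spearman_cor(1:8, y2)
  expect_equal(s2$rho, 1 - 6 * 6 / (8 * 63), tolerance = 1e-12)
  expect_lt(s2$p_value, 0.005)
  expect_lt(s$p_value, 0.02)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("exact permutation p-values equal brute-force enumeration for
           n <= 7, including ties", {
  set.seed(62)
  for (n in 3:7) {
    for (rep in 1:3) {
      x <- rnorm(n)
      y <- if (rep == 3) sample(1:3, n, replace = TRUE) + rnorm(n, 0, 1e-6)
           else rnorm(n)
      y <- if (rep == 2) sample(c(1, 1, seq_len(n - 2) + 1)) else y  # ties
      got <- spearman_cor(x, y, method = "exact")
      expect_equal(got$p_value, spearman_p_oracle(x, y), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("Spearman is invariant to strictly monotone transforms", {
  set.seed(63)
  x <- rnorm(9); y <- rnorm(9)
  base <- spearman_cor(x, y)
  tr <- spearman_cor(exp(x), y^3 + 5 * y)
  expect_equal(tr$rho, base$rho, tolerance = 1e-12)
  expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
})

test_that("large samples fall back to the t approximation", {
  set.seed(64)
  x <- rnorm(12); y <- x + rnorm(12)
  s <- spearman_cor(x, y)
  expect_equal(s$method, "t_approximation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("stiffness-texture correlation matrix flags known links", {
  stiff <- c(PT = 380, PH = 340, PD = 210, PP = 110,
             AT = 130, AC = 120, AH = 115, AP = 50)
  prods <- names(stiff)
  fs <- rbind(
    data.frame(product = prods, feature = "brittle",
               mean = rank(stiff) / 2 + 1, sd = 0.5, n = 18),
    data.frame(product = prods, feature = "springy",
               mean = c(3, 2, 4, 1, 2, 4, 3, 3), sd = 0.5, n = 18))
  out <- stiffness_texture_correlations(stiff, fs)
  expect_equal(out$rho["stiffness", "brittle"], 1)
  sig <- out$significant_pairs
  expect_true(any(sig$var1 == "stiffness" & sig$var2 == "brittle" &
                    sig$sign == "positive"))
  expect_error(stiffness_texture_correlations(stiff, fs[fs$product != "AP", ]),
               "missing products")
})

test_that("likert tables reject out-of-scale scores", {
  bad <- data.frame(participant = "p1", product = "A", feature = "soft",
                    score = 6L)
  expect_error(likert_table(bad), "scale")
})
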