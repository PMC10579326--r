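test_that("Shapiro-Wilk gates the nonparametric path", {
  w <- shapiro_wilk(qnorm(ppoints(10)))
  expect_gt(w$W, 0.98)
  set.seed(4)
  skew <- rexp(50)
  expect_lt(shapiro_wilk(skew)$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "insufficient data")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)   # 3.857142...
  expect_identical(kw$df, 1L)
  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))$H, 0)
  four <- kruskal_wallis(split(rnorm(40), rep(1:4, 10)))
  expect_identical(four$df, 3L)
})

test_that("small-sample permutation p equals full enumeration", {
  set.seed(9)
  cases <- list(
    list(c(1, 2, 3), c(4, 5, 6)),
    list(c(0.4, 1.3, 0.07), c(0.06, 0.3, 2.2)),
    list(c(1, 5), c(2, 9), c(3, 4))
  )
  for (groups in cases) {
    pkg <- kruskal_wallis(groups, p_method = "permutation")
    orc <- kw_enum_oracle(groups)
    expect_equal(pkg$H, orc$H, tolerance = 1e-12)
    expect_equal(pkg$p, orc$p, tolerance = 1e-12)
  }
})

test_that("pairwise Wilcoxon p-values are exact for small tie-free groups", {
  res <- pairwise_wilcoxon_bh(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                              alternative = "less")
  expect_equal(res$pairs$p_raw, 1 / 20)    # most extreme of C(6,3)
  # cross-check against enumeration on random tie-free groups
  set.seed(14)
  for (i in 1:10) {
    g1 <- sample(100, 5); g2 <- sample(200, 6) + 0.5
    for (alt in c("less", "greater")) {
      pkg <- pairwise_wilcoxon_bh(list(x = g1, y = g2),
                                  alternative = alt)$pairs$p_raw
      expect_equal(pkg, wilcoxon_enum_oracle(g1, g2, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical groups are never significant", {
  res <- pairwise_wilcoxon_bh(list(a = 1:6, b = 1:6),
                              alternative = "greater")
  expect_gte(res$pairs$p_raw, 0.5)
})

test_that("Benjamini-Hochberg adjustment is step-up, monotone, capped", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))
  set.seed(6)
  p <- sort(runif(20))
  adj <- stats::p.adjust(p, method = "BH")
  expect_true(all(diff(adj) >= -1e-15))
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
})

test_that("adjusted pairwise matrix is symmetric and >= raw", {
  set.seed(31)
  groups <- split(rlnorm(48, rep(log(c(0.4, 0.3, 0.07, 0.06)), each = 12), 1),
                  rep(depth_levels(), each = 12))
  res <- pairwise_wilcoxon_bh(groups, alternative = "two.sided")
  expect_equal(res$p_adjusted, t(res$p_adjusted))
  off <- !is.na(res$p_raw)
  expect_true(all(res$p_adjusted[off] >= res$p_raw[off] - 1e-15))
})

test_that("per-pair one-sided directions can differ", {
  dir_fun <- function(a, b) if (a == "MPn_Pi") "less" else "greater"
  res <- pairwise_wilcoxon_bh(
    list(MPn_Pi = c(1, 2, 3), MPn_NO3 = c(10, 11, 12), MPn = c(4, 5, 6)),
    alternative = dir_fun)
  alts <- setNames(res$pairs$alternative,
                   paste(res$pairs$group1, res$pairs$group2))
  expect_identical(unname(alts["MPn_Pi MPn"]), "less")
  expect_identical(unname(alts["MPn_NO3 MPn"]), "greater")
})

test_that("Spearman screen ranks, ties and censored pairs correctly", {
  tab <- data.frame(x = 1:8, y = (1:8)^2, z = -(1:8),
                    w = c(NA, NA, NA, NA, NA, 1, 2, 3))
  res <- spearman_screen(tab)
  get <- function(a, b) res[res$param1 == a & res$param2 == b, ]
  expect_equal(get("x", "y")$rho, 1)
  expect_equal(get("x", "z")$rho, -1)
  expect_false(get("x", "w")$estimable)    # only 3 complete cases
  r <- spearman_screen(data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)))
  expect_equal(r$rho[1], 0.8, tolerance = 1e-12)
})
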