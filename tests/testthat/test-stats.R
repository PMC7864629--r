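test_that("t test matches the textbook formula and base R", {
  set.seed(61)
  x <- rnorm(12); y <- rnorm(15, 0.4)
  mine <- t_test2(x, y)
  base <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(base$statistic), tolerance = 1e-10)
  expect_equal(mine$p, base$p.value, tolerance = 1e-10)
  welch <- t_test2(x, y, var_equal = FALSE)
  basew <- t.test(x, y)
  expect_equal(welch$t, unname(basew$statistic), tolerance = 1e-10)
  expect_equal(welch$df, unname(basew$parameter), tolerance = 1e-10)
  paired <- t_test2(x[1:12], y[1:12], paired = TRUE)
  basep <- t.test(x[1:12], y[1:12], paired = TRUE)
  expect_equal(paired$p, basep$p.value, tolerance = 1e-10)
  # degenerate identical data: t = 0, p = 1
  z <- rep(2, 5)
  expect_equal(t_test2(z, z, paired = TRUE)$p, 1)
  expect_equal(t_test2(z, z)$p, 1)
})

test_that("t test p value agrees with a permutation oracle", {
  set.seed(62)
  x <- rnorm(8); y <- rnorm(8, 1)
  p_mine <- t_test2(x, y)$p
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(20000, {
    s <- sample(16, 8)
    abs(mean(pool[s]) - mean(pool[-s]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_mine - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 20000) +
              0.01)
})

test_that("one-way ANOVA with two groups satisfies F = t squared", {
  set.seed(63)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  a <- anova_oneway(c(x, y), rep(c("a", "b"), c(10, 12)))
  tt <- t_test2(x, y)
  expect_equal(a$f[1], tt$t^2, tolerance = 1e-10)
  expect_equal(a$p[1], tt$p, tolerance = 1e-10)
})

test_that("two-way ANOVA matches a brute-force projection oracle", {
  set.seed(64)
  d <- expand.grid(a = factor(1:2), b = factor(1:3))
  d <- d[rep(seq_len(6), each = 5), ]
  d$y <- rnorm(30)
  mine <- anova_twoway(d$y, d$a, d$b)
  # oracle: direct sum-coded linear model comparisons via lm()
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  full <- lm(y ~ a * b, data = d)
  rss <- function(m) sum(resid(m)^2)
  drop_a <- stats::drop1(full, scope = ~., test = "F")
  # drop1 on a sum-coded full model gives the Type III SS directly
  expect_equal(mine$ss[1], drop_a["a", "Sum of Sq"], tolerance = 1e-8)
  expect_equal(mine$ss[2], drop_a["b", "Sum of Sq"], tolerance = 1e-8)
  expect_equal(mine$ss[3], drop_a["a:b", "Sum of Sq"], tolerance = 1e-8)
  expect_equal(mine$ss[4], rss(full), tolerance = 1e-8)
})

test_that("two-way ANOVA handles balance identities and empty cells", {
  # identical replicated groups: all F ~ 0, p ~ 1
  d <- expand.grid(a = factor(1:2), b = factor(1:2), rep = 1:4)
  d$y <- 5
  r <- anova_twoway(d$y + rnorm(nrow(d), 0, 1e-8), d$a, d$b)
  expect_true(all(r$p[1:3] > 0.1))
  # additive effects with no noise: interaction SS exactly 0
  d$y <- as.integer(d$a) * 2 + as.integer(d$b) * 3
  r2 <- anova_twoway(d$y, d$a, d$b)
  expect_lt(r2$ss[3], 1e-18)
  # empty cell errors with the cell named
  d2 <- d[!(d$a == 1 & d$b == 2), ]
  expect_error(anova_twoway(d2$y, d2$a, d2$b), "empty cell")
})

test_that("repeated-measures ANOVA matches aov and the cell-means oracle", {
  set.seed(65)
  n_sub <- 15; k <- 8
  d <- expand.grid(subject = factor(seq_len(2 * n_sub)),
                   within = factor(seq_len(k)))
  d$group <- factor(ifelse(as.integer(d$subject) <= n_sub, "g1", "g2"))
  d$y <- rnorm(nrow(d)) + 0.4 * (d$group == "g2") +
    0.1 * as.integer(d$within) +
    0.15 * as.integer(d$within) * (d$group == "g2")
  mine <- anova_rm(d$y, d$group, d$within, d$subject)
  ref <- summary(aov(y ~ group * within + Error(subject / within),
                     data = d))
  btw <- ref[["Error: subject"]][[1]]
  wth <- ref[["Error: subject:within"]][[1]]
  expect_equal(mine$f[mine$effect == "group"], btw["group", "F value"],
               tolerance = 1e-6)
  expect_equal(mine$f[mine$effect == "within"], wth["within", "F value"],
               tolerance = 1e-6)
  expect_equal(mine$f[mine$effect == "group:within"],
               wth["group:within", "F value"], tolerance = 1e-6)
  expect_equal(mine$df, c(1, 2 * n_sub - 2, k - 1, k - 1,
                          (2 * n_sub - 2) * (k - 1)))
})

test_that("constant within-subject series give zero within-effect F", {
  d <- expand.grid(subject = factor(1:8), within = factor(1:4))
  d$group <- factor(rep(c("a", "b"), each = 4)[as.integer(d$subject)])
  base <- rnorm(8)
  d$y <- base[as.integer(d$subject)]  # no within-factor variation
  r <- anova_rm(d$y, d$group, d$within, d$subject)
  expect_true(is.nan(r$f[r$effect == "within"]) ||
                r$f[r$effect == "within"] < 1e-10)
})

test_that("two-timepoint interaction equals the squared paired-change t", {
  set.seed(66)
  d <- expand.grid(subject = factor(1:20), within = factor(1:2))
  d$group <- factor(rep(c("a", "b"), each = 10)[as.integer(d$subject)])
  d$y <- rnorm(nrow(d)) + (d$within == "2") * (d$group == "b") * 0.8
  r <- anova_rm(d$y, d$group, d$within, d$subject)
  # per-subject change scores, compared between groups
  wide <- reshape(d, idvar = c("subject", "group"), timevar = "within",
                  direction = "wide")
  ch <- wide$y.2 - wide$y.1
  tt <- t_test2(ch[wide$group == "a"], ch[wide$group == "b"])
  expect_equal(r$f[r$effect == "group:within"], tt$t^2, tolerance = 1e-8)
})

test_that("Fisher's protected LSD respects protection and matches direct t", {
  set.seed(67)
  g <- rep(c("a", "b", "c"), each = 10)
  y <- rnorm(30) + c(0, 0.2, 1.8)[match(g, c("a", "b", "c"))]
  res <- fisher_plsd(y, g)
  a <- anova_oneway(y, g)
  err <- a[a$effect == "error", ]
  for (i in seq_len(nrow(res))) {
    gi <- y[g == res$group1[i]]; gj <- y[g == res$group2[i]]
    se <- sqrt(err$ms * (1 / length(gi) + 1 / length(gj)))
    tt <- (mean(gi) - mean(gj)) / se
    expect_equal(res$t[i], tt, tolerance = 1e-8)
    expect_equal(res$p[i], 2 * pt(-abs(tt), err$df), tolerance = 1e-8)
  }
  # protection: near-identical groups return an empty result with a note
  y0 <- rnorm(30, 0, 1)
  a0 <- anova_oneway(y0, g)
  if (a0$p[1] >= 0.05) {
    r0 <- fisher_plsd(y0, g)
    expect_equal(nrow(r0), 0)
    expect_match(attr(r0, "note"), "omnibus")
  }
  # identical group means: no significant pairs even unprotected
  yc <- rep(rnorm(10), 3)
  rc <- fisher_plsd(yc, g, protected = FALSE)
  expect_false(any(rc$significant))
})

test_that("ANOVA results are invariant to group relabelling", {
  set.seed(68)
  y <- rnorm(24)
  a <- rep(c("x", "y"), each = 12)
  b <- rep(c("u", "v", "w"), 8)
  r1 <- anova_twoway(y, a, b)
  r2 <- anova_twoway(y, factor(a, levels = c("y", "x")),
                     factor(b, levels = c("w", "u", "v")))
  expect_equal(r1$ss, r2$ss, tolerance = 1e-9)
  expect_true(all(r1$ss >= 0))
  expect_true(all(r1$p[1:3] >= 0 & r1$p[1:3] <= 1))
})
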