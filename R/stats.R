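#' Student/Welch/paired t test
#'
#' Self-contained t test returning the statistic, degrees of freedom and
#' two-sided p value. The unpaired default is the pooled-variance Student
#' form; `var_equal = FALSE` gives the Welch form. When both groups have
#' zero variance and equal means the p value is 1 by convention.
#'
#' @param x,y Numeric vectors (`y` omitted for a one-sample test against
#'   `mu`).
#' @param paired Paired test on `x - y`.
#' @param var_equal Pooled-variance Student form (default TRUE).
#' @param mu Null value (default 0).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
t_test2 <- function(x, y = NULL, paired = FALSE, var_equal = TRUE, mu = 0) {
  if (paired) {
    if (is.null(y) || length(x) != length(y)) {
      stop("paired test needs two equal-length vectors")
    }
    d <- x - y
    return(t_test2(d, mu = mu))
  }
  if (is.null(y)) {
    n <- length(x)
    if (n < 2) stop("need n >= 2")
    s <- stats::sd(x)
    md <- mean(x) - mu
    if (s == 0) {
      return(list(t = if (md == 0) 0 else sign(md) * Inf, df = n - 1,
                  p = if (md == 0) 1 else 0, mean_diff = md))
    }
    tt <- md / (s / sqrt(n))
    return(list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
                mean_diff = md))
  }
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need n >= 2 per group")
  md <- mean(x) - mean(y) - mu
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = nx + ny - 2, p = if (md == 0) 1 else 0, mean_diff = md))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tt <- md / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), mean_diff = md)
}

# least-squares RSS of y on a design matrix via QR
rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# sum-to-zero dummy columns for a factor
effect_cols <- function(f) {
  f <- factor(f)
  k <- nlevels(f)
  if (k < 2) stop("factor needs >= 2 levels")
  C <- stats::contr.sum(k)
  C[as.integer(f), , drop = FALSE]
}

anova_row <- function(effect, ss, df, ms_error, df_error) {
  ms <- ss / df
  f <- ms / ms_error
  data.frame(effect = effect, ss = ss, df = df, ms = ms, f = f,
             p = stats::pf(f, df, df_error, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' One-way analysis of variance
#'
#' Self-contained fixed-effects one-way ANOVA (between-groups vs
#' within-groups decomposition). With two groups F equals the square of the
#' pooled-variance t statistic.
#'
#' @param value Numeric response.
#' @param group Group labels (>= 2 groups).
#' @return Data.frame of class `anova_result` with rows for the group
#'   effect and the error term (`ss`, `df`, `ms`, `f`, `p`).
#' @export
anova_oneway <- function(value, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  grand <- mean(value)
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((value - means[group])^2)
  df_b <- nlevels(group) - 1
  df_w <- length(value) - nlevels(group)
  out <- rbind(
    anova_row("group", ss_b, df_b, ss_w / df_w, df_w),
    data.frame(effect = "error", ss = ss_w, df = df_w, ms = ss_w / df_w,
               f = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Two-way analysis of variance with interaction
#'
#' Self-contained two-way fixed-effects ANOVA for possibly unbalanced
#' crossed designs. Sums of squares are Type III by default (each effect
#' adjusted for all others under sum-to-zero coding, the convention of the
#' legacy commercial packages); `ss_type = 2` adjusts main effects only for
#' each other.
#'
#' @param value Numeric response.
#' @param a,b Factors (crossed; every cell must be non-empty).
#' @param ss_type 3 (default) or 2.
#' @return Data.frame of class `anova_result` with rows `a`, `b`, `a:b`,
#'   `error`.
#' @export
anova_twoway <- function(value, a, b, ss_type = 3) {
  a <- factor(a); b <- factor(b)
  tab <- table(a, b)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s x %s", levels(a)[bad[1]], levels(b)[bad[2]]))
  }
  n <- length(value)
  Xa <- effect_cols(a)
  Xb <- effect_cols(b)
  Xab <- matrix(0, n, ncol(Xa) * ncol(Xb))
  k <- 0
  for (i in seq_len(ncol(Xa))) {
    for (j in seq_len(ncol(Xb))) {
      k <- k + 1
      Xab[, k] <- Xa[, i] * Xb[, j]
    }
  }
  one <- matrix(1, n, 1)
  X_full <- cbind(one, Xa, Xb, Xab)
  rss_full <- rss_of(value, X_full)
  df_err <- n - ncol(X_full)
  ms_err <- rss_full / df_err
  drop_ss <- function(drop) rss_of(value, X_full[, -drop, drop = FALSE]) -
    rss_full
  ia <- 1 + seq_len(ncol(Xa))
  ib <- max(ia) + seq_len(ncol(Xb))
  iab <- max(ib) + seq_len(ncol(Xab))
  if (ss_type == 3) {
    ss_a <- drop_ss(ia); ss_b <- drop_ss(ib)
  } else if (ss_type == 2) {
    X_ab_main <- cbind(one, Xa, Xb)
    ss_a <- rss_of(value, cbind(one, Xb)) - rss_of(value, X_ab_main)
    ss_b <- rss_of(value, cbind(one, Xa)) - rss_of(value, X_ab_main)
  } else stop("ss_type must be 2 or 3")
  ss_ab <- drop_ss(iab)
  out <- rbind(
    anova_row("a", ss_a, ncol(Xa), ms_err, df_err),
    anova_row("b", ss_b, ncol(Xb), ms_err, df_err),
    anova_row("a:b", ss_ab, ncol(Xab), ms_err, df_err),
    data.frame(effect = "error", ss = rss_full, df = df_err, ms = ms_err,
               f = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Mixed-design (repeated-measures) analysis of variance
#'
#' Univariate mixed-design ANOVA with one between-subjects factor (e.g.
#' genotype, unit = well or cell) and one within-subjects factor (e.g. day
#' in culture). The between effect is tested against subject-within-group
#' variation; the within and interaction effects against the
#' subject-by-within residual. Subjects with incomplete within-factor
#' series are dropped with a message. No sphericity correction is applied
#' (uncorrected degrees of freedom are reported).
#'
#' @param value Numeric response.
#' @param group Between-subjects factor.
#' @param within Within-subjects factor.
#' @param subject Subject (experimental-unit) identifier; each subject must
#'   belong to one group and be measured once per within level.
#' @return Data.frame of class `anova_result` with rows `group`,
#'   `subject(group)`, `within`, `group:within`, `error`.
#' @export
anova_rm <- function(value, group, within, subject) {
  d <- data.frame(y = value, g = factor(group), w = factor(within),
                  s = factor(subject))
  k <- nlevels(d$w)
  cnt <- table(d$s, d$w)
  complete <- rownames(cnt)[apply(cnt == 1, 1, all)]
  if (length(complete) < nrow(cnt)) {
    message(nrow(cnt) - length(complete),
            " subject(s) dropped for incomplete within-factor series")
    d <- d[d$s %in% complete, , drop = FALSE]
    d$s <- droplevels(d$s)
  }
  sg <- unique(d[, c("s", "g")])
  if (any(table(sg$s) > 1)) stop("subjects must belong to a single group")
  n_per_group <- table(sg$g)
  if (any(n_per_group < 2)) stop("need >= 2 subjects per group")
  n_s <- nlevels(d$s)
  n_g <- nlevels(d$g)
  grand <- mean(d$y)
  subj_mean <- tapply(d$y, d$s, mean)
  grp_of <- sg$g[match(names(subj_mean), sg$s)]
  grp_mean <- tapply(d$y, d$g, mean)
  w_mean <- tapply(d$y, d$w, mean)
  cell_mean <- tapply(d$y, list(d$g, d$w), mean)

  ss_between_subj <- k * sum((subj_mean - grand)^2)
  ss_group <- k * sum(n_per_group * (grp_mean - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  df_group <- n_g - 1
  df_subj <- n_s - n_g

  ss_within_total <- sum((d$y - subj_mean[d$s])^2)
  ss_within <- n_s * sum((w_mean - grand)^2)
  # residual (subject x within) computed exactly; interaction by subtraction
  # so the decomposition stays additive for unequal group sizes
  ss_resid <- sum((d$y - subj_mean[as.character(d$s)] -
                     cell_mean[cbind(as.character(d$g), as.character(d$w))] +
                     grp_mean[as.character(d$g)])^2)
  ss_inter <- ss_within_total - ss_within - ss_resid
  df_within <- k - 1
  df_inter <- (n_g - 1) * (k - 1)
  df_resid <- (n_s - n_g) * (k - 1)

  ms_subj <- ss_subj / df_subj
  ms_resid <- ss_resid / df_resid
  out <- rbind(
    anova_row("group", ss_group, df_group, ms_subj, df_subj),
    data.frame(effect = "subject(group)", ss = ss_subj, df = df_subj,
               ms = ms_subj, f = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE),
    anova_row("within", ss_within, df_within, ms_resid, df_resid),
    anova_row("group:within", ss_inter, df_inter, ms_resid, df_resid),
    data.frame(effect = "error", ss = ss_resid, df = df_resid,
               ms = ms_resid, f = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Fisher's protected least significant difference post hoc test
#'
#' Pairwise group comparisons using the omnibus ANOVA error term,
#' performed only when the omnibus F is significant (the "protection").
#' For groups i, j the least significant difference is
#' t(1-alpha/2, df_error) * sqrt(MS_error (1/n_i + 1/n_j)); pairwise p
#' values come from the corresponding pooled-error t statistic.
#'
#' @param value Numeric response.
#' @param group Group labels.
#' @param anova Optional precomputed [anova_oneway()] result supplying the
#'   omnibus p, MS_error and df_error; computed from the data when `NULL`.
#' @param alpha Protection/criterion level (default 0.05).
#' @param protected Apply the protection rule (default TRUE).
#' @return Data.frame of class `posthoc_result` (`group1`, `group2`,
#'   `mean_diff`, `lsd`, `t`, `p`, `significant`); zero rows with attribute
#'   `note` when the omnibus test is not significant.
#' @export
fisher_plsd <- function(value, group, anova = NULL, alpha = 0.05,
                        protected = TRUE) {
  group <- factor(group)
  if (is.null(anova)) anova <- anova_oneway(value, group)
  omni_p <- anova$p[1]
  err <- anova[anova$effect == "error", ]
  empty <- data.frame(group1 = character(0), group2 = character(0),
                      mean_diff = numeric(0), lsd = numeric(0),
                      t = numeric(0), p = numeric(0),
                      significant = logical(0))
  if (protected && !(is.finite(omni_p) && omni_p < alpha)) {
    attr(empty, "note") <- sprintf(
      "omnibus p = %.4g >= alpha = %g; protected LSD not performed",
      omni_p, alpha)
    class(empty) <- c("posthoc_result", "data.frame")
    return(empty)
  }
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  levs <- levels(group)
  tcrit <- stats::qt(1 - alpha / 2, err$df)
  rows <- list()
  for (i in seq_len(length(levs) - 1)) {
    for (j in (i + 1):length(levs)) {
      se <- sqrt(err$ms * (1 / ns[[i]] + 1 / ns[[j]]))
      diff <- means[[i]] - means[[j]]
      tt <- diff / se
      rows[[length(rows) + 1]] <- data.frame(
        group1 = levs[i], group2 = levs[j], mean_diff = diff,
        lsd = tcrit * se, t = tt,
        p = 2 * stats::pt(-abs(tt), err$df),
        significant = abs(diff) > tcrit * se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("posthoc_result", "data.frame")
  out
}
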