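#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()]:
#' `F = MSB / MSW` with the p-value from the F distribution. The
#' within-groups mean square and its degrees of freedom are returned so
#' LSD post hoc contrasts can reuse the pooled error term.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return a list with `F`, `p`, `msBetween`, `dfBetween`, `msError`,
#'   `dfError` and the group means `means`.
#' @examples
#' onewayAnova(list(c(1, 2), c(3, 4), c(5, 6)))$F  # 16
#' @export
onewayAnova <- function(groups) {
  if (length(groups) < 2L) stop("domain error: need at least 2 groups")
  if (any(lengths(groups) < 2L)) {
    stop("domain error: every group needs n >= 2")
  }
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  s <- summary(stats::aov(v ~ g))[[1L]]
  Fv <- s[["F value"]][1L]
  p <- s[["Pr(>F)"]][1L]
  if (is.na(Fv) && s[["Mean Sq"]][1L] == 0) {
    # identical group means with zero between-group variability
    Fv <- 0
    p <- 1
  }
  list(
    F = Fv, p = p,
    msBetween = s[["Mean Sq"]][1L], dfBetween = s[["Df"]][1L],
    msError = s[["Mean Sq"]][2L], dfError = s[["Df"]][2L],
    means = vapply(groups, mean, 0)
  )
}

#' Fisher's LSD post hoc contrasts
#'
#' Pairwise least-significant-difference t-tests reusing the ANOVA pooled
#' error term: `t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j))`, two-sided p
#' from t with the ANOVA error degrees of freedom. By definition LSD
#' applies no multiplicity correction; `adjust = "holm"` is available but
#' off by default.
#'
#' @param groups the same list of numeric vectors the ANOVA was run on.
#' @param msError,dfError pooled error mean square and df from
#'   [onewayAnova()].
#' @param adjust `"none"` (LSD proper, default) or `"holm"`.
#' @return a `data.frame(i, j, meanDiff, t, p)`, one row per pair.
#' @export
lsdPostHoc <- function(groups, msError, dfError, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L) stop("domain error: need at least 2 groups")
  if (!is.finite(msError) || msError < 0 || dfError < 1) {
    stop("domain error: invalid pooled error term")
  }
  m <- vapply(groups, mean, 0)
  n <- lengths(groups)
  pairs <- utils::combn(length(groups), 2L)
  res <- data.frame(
    i = pairs[1L, ], j = pairs[2L, ], meanDiff = NA_real_,
    t = NA_real_, p = NA_real_
  )
  for (r in seq_len(ncol(pairs))) {
    i <- pairs[1L, r]
    j <- pairs[2L, r]
    se <- sqrt(msError * (1 / n[i] + 1 / n[j]))
    res$meanDiff[r] <- m[i] - m[j]
    if (se == 0) {
      res$t[r] <- if (res$meanDiff[r] == 0) 0 else Inf * sign(res$meanDiff[r])
      res$p[r] <- if (res$meanDiff[r] == 0) 1 else 0
    } else {
      res$t[r] <- res$meanDiff[r] / se
      res$p[r] <- 2 * stats::pt(-abs(res$t[r]), dfError)
    }
  }
  if (adjust == "holm") res$p <- stats::p.adjust(res$p, "holm")
  res
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sample t-test (two-sided). The Welch correction is
#' off by default and available via `welch = TRUE`.
#'
#' @param x,y numeric vectors of length >= 2.
#' @param welch use the Welch unequal-variance form.
#' @return a list with `t`, `p`, `meanDiff` (`mean(x) - mean(y)`), `df`.
#' @examples
#' studentsT(c(1, 2, 3), c(2, 3, 4))$t  # -1.225
#' @export
studentsT <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("domain error: need n >= 2 per group")
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(
    t = unname(ht$statistic), p = ht$p.value,
    meanDiff = mean(x) - mean(y), df = unname(ht$parameter)
  )
}

#' Two-way mixed-effects intraclass correlation
#'
#' Consistency-form ICC from the two-way (subjects x conditions) ANOVA
#' decomposition: single measures `ICC(3,1) = (MS_R - MS_E) /
#' (MS_R + (k-1) MS_E)` and average measures `ICC(3,k) = (MS_R - MS_E) /
#' MS_R`, with 95% confidence intervals from F-distribution bounds on
#' `MS_R / MS_E`. The absolute-agreement form (which also charges the
#' condition variance to the error) is available via `type`.
#'
#' @param m complete numeric matrix, subjects in rows, conditions in
#'   columns; `>= 2` of each, no missing cells (no imputation).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf confidence level (default 0.95).
#' @return an [IccResult-class].
#' @export
iccTwoWayMixed <- function(m, type = c("consistency", "agreement"),
                           conf = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("domain error: missing cells are not allowed")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("domain error: need >= 2 subjects and >= 2 conditions")
  grand <- mean(m)
  rm <- rowMeans(m)
  cm <- colMeans(m)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sse <- sum((m - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "consistency") {
    single <- (msr - mse) / (msr + (k - 1) * mse)
    average <- (msr - mse) / msr
  } else {
    single <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    average <- (msr - mse) / (msr + (msc - mse) / n)
  }
  # CI bounds from F distribution on MS_R / MS_E (consistency form)
  a <- 1 - conf
  Fobs <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- Fobs / stats::qf(1 - a / 2, df1, df2)
  fu <- Fobs * stats::qf(1 - a / 2, df2, df1)
  ciS <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  ciA <- c(1 - 1 / fl, 1 - 1 / fu)
  new("IccResult",
    iccSingle = single, iccAverage = average,
    ciSingle = ciS, ciAverage = ciA,
    model = paste("two-way mixed,", type),
    nSubjects = n, nConditions = as.integer(k)
  )
}

#' Cohen's d with confidence intervals
#'
#' Pooled-SD independent-groups standardized mean difference:
#' `d = (mean(x) - mean(y)) / s_pooled`. The d interval uses the normal
#' approximation `SE = sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2)))`; the
#' raw-mean-difference interval uses the pooled-variance t distribution.
#'
#' @param x,y numeric vectors of length >= 2.
#' @param conf confidence level (default 0.95).
#' @return an [EffectSize-class].
#' @examples
#' cohensD(c(0, 2), c(1, 3))@cohensD  # -0.707
#' @export
cohensD <- function(x, y, conf = 0.95) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("domain error: need n >= 2 per group")
  md <- mean(x) - mean(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  sp <- sqrt(sp2)
  if (sp == 0) {
    if (md != 0) stop("undefined-d error: zero pooled variance with unequal means")
    d <- 0
  } else {
    d <- md / sp
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  seD <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  tq <- stats::qt(1 - (1 - conf) / 2, n1 + n2 - 2)
  seMd <- sp * sqrt(1 / n1 + 1 / n2)
  new("EffectSize",
    meanDifference = md, cohensD = d,
    ci95 = c(md - tq * seMd, md + tq * seMd),
    ciD = c(d - z * seD, d + z * seD),
    n1 = as.integer(n1), n2 = as.integer(n2)
  )
}

#' Pearson product-moment correlation
#'
#' `r` with the two-sided p-value from `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @return a list with `r`, `p`, `n`.
#' @examples
#' pearsonCorrelation(1:4, c(1, 3, 2, 4))$r  # 0.8
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("domain error: unequal lengths")
  if (length(x) < 3L) stop("domain error: need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("domain error: non-finite values")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-r error: zero variance")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}
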