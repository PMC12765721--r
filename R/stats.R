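## Method-comparison statistics relating clinical (TMQHPlI), planimetric
## (PLANItot/dark/light/volmap) and volumetric (VPI/AVPI) indices.
## Standard tests delegate to base R; Passing-Bablok, the rank AUC and the
## segmented growth-regime model are implemented here.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (3 <= n <= 5000, no
#' missing). A constant vector is an error, as in the backend.
#'
#' @param x numeric vector
#' @return list with `W` and `p`
#' @export
shapiroWilk <- function(x) {
  if (anyNA(x)) stop("missing values not allowed")
  if (length(x) < 3L || length(x) > 5000L) stop("need 3 <= n <= 5000")
  ht <- shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Tie-corrected rho (Pearson correlation of midranks) with a two-sided
#' t-approximation p-value, on pairwise-complete observations.
#'
#' @param x,y paired numeric vectors
#' @return list with `rho`, `p`, `n`; rho and p are NA (flagged via
#'   `degenerate = TRUE`) when either rank vector has zero variance
#' @export
spearmanRho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

## tie-corrected Friedman statistic (same formula as stats::friedman.test)
friedmanStat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  ties <- sum(unlist(lapply(split(r, row(r)), function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  })))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 1e-12) return(0)   # every block fully tied: no information
  num / den
}

#' Friedman test across repeated measures
#'
#' Tie-corrected Friedman statistic over complete blocks (rows = surfaces,
#' columns = measures). The p-value uses the exact within-block permutation
#' null when the permutation count (k!)^n does not exceed `exact_limit`
#' ("auto", recommended at small n where the chi-square approximation is
#' poor), otherwise the chi-square approximation with k-1 df.
#'
#' @param m numeric matrix, n blocks x k measures, complete
#' @param p.method "auto", "exact" or "chisq"
#' @param exact_limit maximum number of permutations enumerated
#' @return list with `chi2`, `p`, `df`, `method`
#' @export
friedmanTest <- function(m, p.method = c("auto", "exact", "chisq"),
                         exact_limit = 2e5) {
  p.method <- match.arg(p.method)
  m <- as.matrix(m)
  if (anyNA(m)) stop("incomplete blocks are not allowed (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (k < 3L) stop("need at least 3 measures")
  stat <- friedmanStat(m)
  nperm <- factorial(k)^n
  useExact <- switch(p.method,
    exact = TRUE,
    chisq = FALSE,
    auto = nperm <= exact_limit)
  if (useExact && nperm > exact_limit)
    stop("exact permutation null too large; use p.method = 'chisq'")
  if (useExact) {
    perms <- allPermutations(k)
    counter <- rep(1L, n)
    count <- 0L; total <- 0L
    repeat {
      mm <- m
      for (b in seq_len(n)) mm[b, ] <- m[b, perms[[counter[b]]]]
      if (friedmanStat(mm) >= stat - 1e-12) count <- count + 1L
      total <- total + 1L
      # odometer increment
      i <- 1L
      while (i <= n) {
        counter[i] <- counter[i] + 1L
        if (counter[i] <= length(perms)) break
        counter[i] <- 1L; i <- i + 1L
      }
      if (i > n) break
    }
    p <- count / total
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  list(chi2 = stat, p = p, df = k - 1L, method = method)
}

allPermutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- allPermutations(k - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' For each column pair of `m`, a paired Wilcoxon signed-rank test with
#' zero differences dropped; the exact null is used for n <= 25 non-zero
#' differences without ties in |d|, otherwise the normal approximation
#' with continuity correction. Bonferroni multiplies each p by the number
#' of pairs actually tested (capped at 1). All-zero differences give p = 1
#' flagged degenerate.
#'
#' @param m numeric matrix or data.frame, complete, columns = measures
#' @param pairs optional 2-column matrix of column indices; all pairs when
#'   NULL
#' @return data.frame with columns a, b, n, V, p, p_adj, degenerate
#' @export
wilcoxonPairwiseBonferroni <- function(m, pairs = NULL) {
  m <- as.matrix(m)
  if (is.null(pairs)) pairs <- t(combn(ncol(m), 2))
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(m)))
  nTests <- nrow(pairs)
  rows <- lapply(seq_len(nTests), function(i) {
    d <- m[, pairs[i, 1]] - m[, pairs[i, 2]]
    d <- d[d != 0 & !is.na(d)]
    if (length(d) == 0L)
      return(data.frame(a = nm[pairs[i, 1]], b = nm[pairs[i, 2]], n = 0L,
                        V = NA_real_, p = 1, degenerate = TRUE))
    exact <- length(d) <= 25L && !any(duplicated(abs(d)))
    ht <- suppressWarnings(
      wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
    data.frame(a = nm[pairs[i, 1]], b = nm[pairs[i, 2]], n = length(d),
               V = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nTests)
  out
}

#' Passing-Bablok method-comparison regression
#'
#' Non-parametric regression through the shifted median of all pairwise
#' slopes S_ij = (y_j - y_i)/(x_j - x_i), i < j (0/0 slopes and slopes of
#' exactly -1 excluded; the offset K counts slopes below -1), with the
#' binomial-quantile rank confidence interval of Passing & Bablok (1983).
#' Following common method-comparison practice for indices on different
#' scales, both variables are marginally standardized to z-scores first
#' when `use_zscores` is TRUE.
#'
#' @param x,y paired numeric vectors (n >= 10)
#' @param use_zscores standardize each variable to mean 0, SD 1 first
#' @param alpha CI level is 1 - alpha
#' @return list with `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `n`, `n_slopes`, `proportional_bias` (CI excludes 1),
#'   `constant_bias` (CI excludes 0)
#' @export
passingBablok <- function(x, y, use_zscores = TRUE, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 complete pairs")
  if (sd(x) == 0) stop("x has zero variance")
  if (use_zscores) {
    x <- (x - mean(x)) / sd(x)
    y <- (y - mean(y)) / sd(y)
  }
  ij <- t(combn(n, 2))
  dx <- x[ij[, 2]] - x[ij[, 1]]
  dy <- y[ij[, 2]] - y[ij[, 1]]
  S <- dy / dx                      # dx = 0 gives +-Inf, kept; 0/0 NaN
  S <- S[!is.nan(S)]
  S <- S[S != -1]
  N <- length(S)
  if (sum(is.finite(S)) < 10L) stop("fewer than 10 finite pairwise slopes")
  S <- sort(S)                      # sorts -Inf .. +Inf
  K <- sum(S < -1)
  med_at <- function(pos) {
    # shifted median of the sorted slopes at offset positions
    if (N %% 2L == 1L) S[(N + 1L) %/% 2L + pos]
    else mean(S[c(N %/% 2L + pos, N %/% 2L + 1L + pos)])
  }
  b <- med_at(K)
  w <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - w) / 2)
  M2 <- N - M1 + 1
  lo <- S[max(1L, M1 + K)]
  hi <- S[min(N, M2 + K)]
  a <- median(y - b * x)
  a_lo <- median(y - hi * x)
  a_hi <- median(y - lo * x)
  list(slope = b, intercept = a,
       slope_ci = c(lo, hi), intercept_ci = c(a_lo, a_hi),
       n = n, n_slopes = N,
       proportional_bias = (lo > 1 || hi < 1),
       constant_bias = (a_lo > 0 || a_hi < 0))
}

#' Empirical ROC and AUC by the rank (Mann-Whitney) identity
#'
#' @param scores numeric test variable (higher = more positive)
#' @param labels logical or 0/1 class labels
#' @return list with `auc`, `n_pos`, `n_neg`, and `roc` (data.frame of
#'   fpr/tpr over all empirical thresholds)
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  r <- rank(scores)                 # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  list(auc = auc, n_pos = n1, n_neg = n0,
       roc = data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr)))
}

#' ROC analysis of VPI against dichotomized planimetric coverage
#'
#' Dichotomizes coverage at the requested cut points (absolute coverage
#' thresholds in percent by default; empirical percentile splits with
#' `percentile_split = TRUE`) and evaluates the VPI as the test variable.
#' A dichotomization leaving one class empty is skipped with a warning.
#'
#' @param vpi numeric test variable
#' @param coverage planimetric coverage, percent
#' @param cuts dichotomization points, percent (default 10, 25, 50)
#' @param percentile_split interpret cuts as coverage percentiles
#' @return named list of [rocAUC()] results (one per usable cut)
#' @export
rocDichotomized <- function(vpi, coverage, cuts = c(10, 25, 50),
                            percentile_split = FALSE) {
  out <- list()
  for (ct in cuts) {
    t_abs <- if (percentile_split)
      quantile(coverage, ct / 100, na.rm = TRUE, names = FALSE) else ct
    lab <- coverage >= t_abs
    if (sum(lab, na.rm = TRUE) == 0L || sum(!lab, na.rm = TRUE) == 0L) {
      warning(sprintf("dichotomization at %g%% leaves one class empty; skipped",
                      ct))
      next
    }
    res <- rocAUC(vpi, lab)
    res$cut <- ct
    out[[sprintf("cut_%g", ct)]] <- res
  }
  out
}

#' Sample size for detecting a correlation
#'
#' Fisher-z formula n = ((z_(1-alpha/2) + z_(1-beta)) / atanh(r))^2 + 3,
#' rounded to the nearest integer.
#'
#' @param r expected correlation, 0 < r < 1
#' @param alpha two-sided type-I error rate
#' @param beta type-II error rate (power = 1 - beta)
#' @return integer sample size
#' @export
sampleSizeCorrelation <- function(r, alpha = 0.05, beta = 0.2) {
  if (!(r > 0 && r < 1)) stop("need 0 < r < 1")
  n <- ((qnorm(1 - alpha / 2) + qnorm(1 - beta)) / atanh(r))^2 + 3
  as.integer(round(n))
}

## continuous two-segment least squares at fixed breakpoint c
segmentedRSS <- function(x, y, c) {
  X <- cbind(1, x, pmax(x - c, 0))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Two-segment growth-regime model of volume vs coverage
#'
#' Fits VPI as a continuous piecewise-linear function of total planimetric
#' coverage, grid-searching the breakpoint over the data quantiles and
#' solving least squares within segments. If no breakpoint improves the
#' residual sum of squares over a single line by more than 1%, the
#' single-line model is returned flagged. Also reports the separate linear
#' fits of volume on dark and on light coverage and their slope ratio, the
#' two-tone contribution contrast.
#'
#' @param records data.frame with columns `plani_tot`, `vpi` and optionally
#'   `plani_dark`, `plani_light`
#' @param probs quantile grid for candidate breakpoints
#' @param n_boot bootstrap replicates for the breakpoint CI (0 = none)
#' @param seed RNG seed for the bootstrap
#' @return list with `breakpoint`, `slope_below`, `slope_above`,
#'   `slope_ratio`, `rss`, `rss_single`, `single_line` flag, `dark_fit`,
#'   `light_fit`, `dark_light_slope_ratio`, and optional `breakpoint_ci`
#' @export
contributionBreakpoint <- function(records, probs = seq(0.05, 0.95, 0.005),
                                   n_boot = 0L, seed = 1L) {
  records <- records[!is.na(records$plani_tot) & !is.na(records$vpi), ]
  records <- records[records$plani_tot > 0, ]
  if (nrow(records) < 20L)
    stop("need at least 20 records with positive total coverage")
  x <- records$plani_tot; y <- records$vpi

  fitOne <- function(x, y) {
    cand <- unique(quantile(x, probs, names = FALSE))
    cand <- cand[cand > min(x) & cand < max(x)]
    rss <- vapply(cand, function(c) segmentedRSS(x, y, c)$rss, 0)
    c_best <- cand[which.min(rss)]
    list(c = c_best, fit = segmentedRSS(x, y, c_best))
  }
  best <- fitOne(x, y)
  single <- stats::lm.fit(cbind(1, x), y)
  rss_single <- sum(single$residuals^2)
  tss <- sum((y - mean(y))^2)
  # a numerically perfect line is a single line regardless of the ratio
  single_line <- rss_single <= 1e-12 * tss ||
    (rss_single - best$fit$rss) / rss_single <= 0.01
  co <- best$fit$coef
  out <- list(
    breakpoint = if (single_line) NA_real_ else best$c,
    slope_below = unname(co[2]),
    slope_above = unname(co[2] + co[3]),
    slope_ratio = unname((co[2] + co[3]) / co[2]),
    rss = best$fit$rss, rss_single = rss_single,
    single_line = single_line)
  if (all(c("plani_dark", "plani_light") %in% names(records))) {
    fd <- stats::lm.fit(cbind(1, records$plani_dark), y)
    fl <- stats::lm.fit(cbind(1, records$plani_light), y)
    out$dark_fit <- unname(fd$coefficients)
    out$light_fit <- unname(fl$coefficients)
    out$dark_light_slope_ratio <-
      unname(fd$coefficients[2] / fl$coefficients[2])
  }
  if (n_boot > 0L) {
    set.seed(seed)
    bps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample(length(x), replace = TRUE)
      fitOne(x[idx], y[idx])$c
    }, 0)
    out$breakpoint_ci <- unname(quantile(bps, c(0.05, 0.95)))
  }
  out
}
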