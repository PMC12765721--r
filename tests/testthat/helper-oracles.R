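# Brute-force oracles for the method-comparison statistics. Each one
# re-derives the quantity by direct enumeration / first principles,
# independent of the implementation path it is checked against.

pbOracle <- function(x, y) {
  n <- length(x)
  S <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s <- if (dx == 0) Inf * sign(dy) else dy / dx
    if (s != -1) S <- c(S, s)
  }
  S <- sort(S)
  N <- length(S); K <- sum(S < -1)
  b <- if (N %% 2 == 1) S[(N + 1) / 2 + K]
       else (S[N / 2 + K] + S[N / 2 + 1 + K]) / 2
  list(slope = b, intercept = median(y - b * x))
}

wilcoxOracle <- function(d) {
  # exact two-sided signed-rank p by full sign enumeration
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p <- 2 * min(mean(Vs <= V), mean(Vs >= V))
  min(1, p)
}

aucOracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

friedmanPermOracle <- function(m) {
  # exhaustive within-block permutation null of the (tie-corrected)
  # statistic, computed through stats::friedman.test for independence
  stat <- function(mm) {
    s <- unname(suppressWarnings(friedman.test(mm)$statistic))
    if (is.na(s)) 0 else s   # fully tied blocks carry no information
  }
  s0 <- stat(m)
  k <- ncol(m); n <- nrow(m)
  perms <- plaquemetry:::allPermutations(k)
  counter <- rep(1L, n)
  count <- 0L; total <- 0L
  repeat {
    mm <- m
    for (b in seq_len(n)) mm[b, ] <- m[b, perms[[counter[b]]]]
    if (stat(mm) >= s0 - 1e-12) count <- count + 1L
    total <- total + 1L
    i <- 1L
    while (i <= n) {
      counter[i] <- counter[i] + 1L
      if (counter[i] <= length(perms)) break
      counter[i] <- 1L; i <- i + 1L
    }
    if (i > n) break
  }
  count / total
}
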