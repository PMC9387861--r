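# Independent oracles used across the suite. Each is written as a direct,
# naive transcription of the defining formula, never sharing code with the
# implementation it checks.

# exhaustive peak finder: test every interior sample, compute prominence by
# explicit left/right valley search
oracle_peaks <- function(v, min_prominence, sign = "positive") {
  if (sign == "negative") v <- -v
  n <- length(v)
  idx <- integer(0)
  prom <- numeric(0)
  for (i in 2:(n - 1)) {
    # strict local max, plateaus collapse to their leftmost sample
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if (j == n) next
    left_ok <- v[i - 1] < v[i]
    right_ok <- v[j + 1] < v[i]
    if (!(left_ok && right_ok)) next
    # left valley: min back to the nearest strictly higher sample (or start)
    k <- i - 1
    lmin <- v[k]
    while (k > 1 && v[k] <= v[i]) {
      k <- k - 1
      if (v[k] <= v[i]) lmin <- min(lmin, v[k])
    }
    # right valley
    k <- j + 1
    rmin <- v[k]
    while (k < n && v[k] <= v[i]) {
      k <- k + 1
      if (v[k] <= v[i]) rmin <- min(rmin, v[k])
    }
    p <- v[i] - max(lmin, rmin)
    if (p >= min_prominence) {
      idx <- c(idx, i)
      prom <- c(prom, p)
    }
  }
  list(index = idx, prominence = prom)
}

# exhaustive one-to-one assignment minimising total |error| subject to the
# gap bound, preferring more pairs; recursion over the (sorted) ref events
oracle_match <- function(rt, it, max_gap) {
  rt <- sort(rt); it <- sort(it)
  best <- list(npairs = -1L, cost = Inf, pairs = NULL)
  recurse <- function(i, used, pairs, cost) {
    if (i > length(rt)) {
      np <- nrow(pairs)
      if (np > best$npairs || (np == best$npairs && cost < best$cost)) {
        best <<- list(npairs = np, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1L, used, pairs, cost) # leave ref i unmatched
    for (j in seq_along(it)) {
      if (!used[j] && abs(rt[i] - it[j]) <= max_gap) {
        used2 <- used; used2[j] <- TRUE
        recurse(i + 1L, used2,
                rbind(pairs, data.frame(ref = rt[i], imu = it[j])),
                cost + abs(rt[i] - it[j]))
      }
    }
  }
  recurse(1L, rep(FALSE, length(it)), data.frame(ref = numeric(0), imu = numeric(0)), 0)
  best$pairs[order(best$pairs$ref), , drop = FALSE]
}

# textbook Kruskal-Wallis with tie correction
oracle_kw <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# from-scratch two-sample DSCF standardised statistic for one pair
oracle_dscf_pair <- function(x, y, k) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R2 <- sum(r[(n1 + 1):N])
  ties <- table(c(x, y))
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (v <= 0) return(list(W = 0, p = 1))
  W <- sqrt(2) * (R2 - n2 * (N + 1) / 2) / sqrt(v)
  list(W = W, p = stats::ptukey(abs(W), nmeans = k, df = Inf, lower.tail = FALSE))
}

# sort-based type-7 quantile IQR written out longhand
oracle_iqr <- function(x) {
  x <- sort(x)
  n <- length(x)
  qat <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  qat(0.75) - qat(0.25)
}
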