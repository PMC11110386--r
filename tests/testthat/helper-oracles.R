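# Independent brute-force oracles, deliberately written with plain loops
# and textbook formulas, against which the package implementations are
# checked.

# Exhaustive-split-search level detection: at every segment, scan all
# split positions with naive mean/SSE arithmetic, keep the candidates
# satisfying the minimum-duration / minimum-change acceptance rules, take
# the sum-of-squares minimiser among them, recurse. Returns the
# change-point days (first day of each new segment).
oracle_detect_levels <- function(x, min_len = 7, min_change = 0.25) {
  split_rec <- function(l, r) {
    if (r - l + 1 < 2 * min_len) return(integer(0))
    cand <- NULL
    for (s in (l + min_len - 1):(r - min_len)) {
      left <- x[l:s]
      right <- x[(s + 1):r]
      if (all(is.na(left)) || all(is.na(right))) next
      ml <- mean(left, na.rm = TRUE)
      mr <- mean(right, na.rm = TRUE)
      if (abs(mr - ml) < min_change - 1e-12) next
      sse <- sum((left - ml)^2, na.rm = TRUE) + sum((right - mr)^2, na.rm = TRUE)
      cand <- rbind(cand, c(s, sse))
    }
    if (is.null(cand)) return(integer(0))
    best <- cand[cand[, 2] <= min(cand[, 2]) + 1e-9, , drop = FALSE][1, ]
    s <- best[1]
    c(split_rec(l, s), s + 1, split_rec(s + 1, r))
  }
  sort(split_rec(1, length(x)))
}

# Two-sided Fisher p by full hypergeometric enumeration via binomial
# coefficients (point-probability rule, relative tie tolerance 1e-7).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  pobs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Fluctuation measure by explicit turning-point bookkeeping.
oracle_F <- function(w, s_min = 0, s_max = 5) {
  m <- length(w)
  bps <- 1
  lastdir <- 0
  for (i in 2:m) {
    di <- w[i] - w[i - 1]
    s <- if (di > 0) 1 else if (di < 0) -1 else 0
    if (s != 0) {
      if (lastdir != 0 && s != lastdir) bps <- c(bps, i - 1)
      lastdir <- s
    }
  }
  bps <- c(bps, m)
  total <- 0
  for (k in seq_len(length(bps) - 1)) {
    amp <- abs(w[bps[k + 1]] - w[bps[k]])
    dur <- bps[k + 1] - bps[k]
    if (dur > 0) total <- total + amp / dur
  }
  total / ((s_max - s_min) * (m - 1))
}

# Distribution measure by explicit double loop over sorted-value pairs.
oracle_D <- function(w, s_min = 0, s_max = 5) {
  m <- length(w)
  y <- sort(w)
  ideal <- s_min + (0:(m - 1)) * (s_max - s_min) / (m - 1)
  num <- 0
  den <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      span_i <- ideal[j] - ideal[i]
      span_y <- y[j] - y[i]
      num <- num + max(0, span_i - span_y)
      den <- den + span_i
    }
  }
  1 - num / den
}

# Yates-corrected chi-square, closed form N(|ad-bc| - N/2)^2 / (r1 r2 c1 c2).
oracle_yates_chi2 <- function(a, b, cc, d) {
  N <- a + b + cc + d
  N * (abs(a * d - b * cc) - N / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# Build a pair of binary series realising given 2x2 agreement counts
# (a = both 1, b = self 1 / informant 0, cc = self 0 / informant 1, d = both 0).
series_from_table <- function(a, b, cc, d) {
  list(self = c(rep(1, a), rep(1, b), rep(0, cc), rep(0, d)),
       informant = c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d)))
}

# Minimal change-point tibble for pairing tests.
cp_tbl <- function(day, delta, series) {
  tibble::tibble(day = as.integer(day), series = series, delta = delta,
                 direction = ifelse(delta > 0, "increase", "decrease"))
}
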