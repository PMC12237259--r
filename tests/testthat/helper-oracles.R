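# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (exhaustive floods, closed forms,
# direct scans) and never call the implementation paths they check.

# Exhaustive prominence-maxima oracle: for each strict-or-equal local
# maximum (8-connectivity), flood all pixels with value > v - tol; accept
# the candidate iff the flood reaches neither a pixel above v nor the
# territory of a previously accepted higher maximum. Plateaus are collapsed
# to one candidate (highest value first, then smallest linear index).
oracle_find_maxima_count <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  if (max(img) == min(img)) return(0L)
  neigh <- function(i) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    rr <- r + c(-1, -1, -1, 0, 0, 1, 1, 1)
    cc <- c + c(-1, 0, 1, -1, 1, -1, 0, 1)
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  cand <- which(vapply(seq_len(nr * nc), function(i)
    all(img[neigh(i)] <= img[i]), logical(1)))
  cand <- cand[order(-img[cand], cand)]
  claimed <- rep(FALSE, nr * nc)
  n_max <- 0L
  for (c0 in cand) {
    if (claimed[c0]) next
    v <- img[c0]
    region <- c0
    seen <- rep(FALSE, nr * nc)
    seen[c0] <- TRUE
    frontier <- c0
    rejected <- FALSE
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) for (q in neigh(p)) {
        if (img[q] > v) rejected <- TRUE
        else if (img[q] > v - tol && !seen[q]) {
          if (claimed[q]) rejected <- TRUE
          else { seen[q] <- TRUE; nxt <- c(nxt, q); region <- c(region, q) }
        }
      }
      frontier <- nxt
    }
    claimed[region] <- TRUE
    if (!rejected) n_max <- n_max + 1L
  }
  n_max
}

# Exhaustive Costes threshold scan: over descending candidate levels of
# channel a (paired with the orthogonal-regression partner level), find the
# highest level at which the correlation of pixels below BOTH levels is
# <= 0 or undefined.
oracle_costes_scan <- function(a, b, n_steps = 256) {
  x <- as.vector(a); y <- as.vector(b)
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  inter <- mean(y) - slope * mean(x)
  for (t1 in seq(max(x), min(x), length.out = n_steps)) {
    t2 <- inter + slope * t1
    sel <- x < t1 & y < t2
    if (sum(sel) < 2 || var(x[sel]) == 0 || var(y[sel]) == 0)
      return(c(t1, t2))
    if (cor(x[sel], y[sel]) <= 0) return(c(t1, t2))
  }
  c(min(x), inter + slope * min(x))
}

# Closed form of the deterministic depletion recurrence: cumulative released
# vesicles after n stimuli with pool N0, release fraction p, refill R.
oracle_cumulative_released <- function(N0, p, R, n) {
  i <- seq_len(n)
  # pool_i = (N0 - R/p) (1-p)^(i-1) + R/p ; released_i = p * pool_i
  if (p == 0) return(rep(0, n))
  cumsum(p * ((N0 - R / p) * (1 - p)^(i - 1) + R / p))
}

# Grubbs critical value from the t quantile (direct formula)
oracle_grubbs_crit <- function(n, alpha = 0.05) {
  tc <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
}

# moment-preservation scan oracle for the Tsai threshold: for each candidate
# bin fraction p, solve the two-level representation that matches the first
# two moments and score the third-moment mismatch; return the intensity at
# the best candidate.
oracle_moments_scan <- function(img, n_bins = 256) {
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1)
  h <- tabulate(bin + 1L, nbins = n_bins) / length(v)
  g <- seq_len(n_bins) - 1
  m1 <- sum(g * h); m2 <- sum(g^2 * h); m3 <- sum(g^3 * h)
  best <- NULL; best_err <- Inf
  csum <- cumsum(h)
  for (tb in seq_len(n_bins - 1)) {
    p <- csum[tb]
    if (p <= 0 || p >= 1) next
    # solve p z0 + (1-p) z1 = m1 ; p z0^2 + (1-p) z1^2 = m2
    # => z0 = m1 - sqrt((1-p)/p * (m2 - m1^2)), z1 = m1 + sqrt(p/(1-p) * cd)
    cd <- m2 - m1^2
    z0 <- m1 - sqrt((1 - p) / p * cd)
    z1 <- m1 + sqrt(p / (1 - p) * cd)
    err <- abs(p * z0^3 + (1 - p) * z1^3 - m3)
    if (err < best_err) { best_err <- err; best <- tb }
  }
  lo + (best - 0.5) / n_bins * (hi - lo)
}
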