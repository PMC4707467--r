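# Independent brute-force oracles. Each one deliberately re-derives its
# quantity from first principles with a different implementation strategy
# than the package, so agreement is evidence, not tautology.

# O(n^2) double-loop nucleotide distance sum
oracle_nds <- function(points) {
  n <- nrow(points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      s <- s + sqrt(sum((points[i, ] - points[j, ])^2))
    }
    out[i] <- s
  }
  out
}

# direct O(n k) truncated-Gaussian convolution with explicit index folding
oracle_smooth <- function(v, sigma, truncation = 4, boundary = "reflect") {
  n <- length(v)
  if (sigma == 0) return(v)
  h <- ceiling(truncation * sigma)
  w <- exp(-((-h):h)^2 / (2 * sigma^2))
  w <- w / sum(w)
  fold <- function(j) {
    while (j < 1 || j > n) {
      if (j < 1) j <- 1 - j
      if (j > n) j <- 2 * n + 1 - j
    }
    j
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in (-h):h) {
      j <- i + k
      j <- if (boundary == "nearest") min(max(j, 1), n) else fold(j)
      s <- s + w[k + h + 1] * v[j]
    }
    out[i] <- s
  }
  out
}

# exhaustive per-position neighbour scan for extremal plateaus
oracle_extrema <- function(v, include_endpoints = TRUE) {
  n <- length(v)
  if (n < 3 && !include_endpoints) return(integer(0))
  reps <- integer(0)
  for (i in seq_len(n)) {
    a <- i; while (a > 1L && v[a - 1L] == v[i]) a <- a - 1L
    b <- i; while (b < n && v[b + 1L] == v[i]) b <- b + 1L
    if (a == 1 && b == n) next  # constant curve
    if (a == 1 || b == n) {
      if (!include_endpoints) next
      rep <- if (a == 1) 1L else n
    } else {
      l <- v[a - 1]; r <- v[b + 1]
      if (!((l < v[i] && r < v[i]) || (l > v[i] && r > v[i]))) next
      rep <- a + (b - a) %/% 2L
    }
    reps <- c(reps, rep)
  }
  sort(unique(reps))
}

# Spearman via explicit midranks and the raw Pearson sum formula
oracle_spearman <- function(x, y) {
  midrank <- function(z) {
    vapply(z, function(zi) sum(z < zi) + (sum(z == zi) + 1) / 2, numeric(1))
  }
  a <- midrank(x); b <- midrank(y)
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# all-pairs interval-overlap evaluation
oracle_evaluate <- function(pred, known, tolerance = 0) {
  overlap <- function(a1, a2, b1, b2) a1 <= b2 && a2 >= b1
  known_hit <- logical(nrow(known))
  pred_hit <- logical(nrow(pred))
  for (k in seq_len(nrow(known)))
    for (p in seq_len(nrow(pred)))
      if (overlap(pred$start[p], pred$end[p],
                  known$start[k] - tolerance, known$end[k] + tolerance)) {
        known_hit[k] <- TRUE
        pred_hit[p] <- TRUE
      }
  list(n_known_hit = sum(known_hit), n_pred_hit = sum(pred_hit))
}

# random nested dot-bracket, for parse/render round-trips
random_nested_db <- function(n, p_open = 0.35) {
  repeat {
    chars <- character(0)
    depth <- 0
    open_at <- integer(0)
    i <- 1
    while (i <= n) {
      roll <- stats::runif(1)
      remaining <- n - i + 1
      if (depth > 0 && (roll < 0.3 || remaining <= depth)) {
        # close only if the pair spans >= 3 positions
        if (i - open_at[depth] >= 2) {
          chars[i] <- ")"; depth <- depth - 1
          open_at <- open_at[-length(open_at)]
        } else chars[i] <- "."
      } else if (roll < 0.3 + p_open && remaining > depth + 2) {
        chars[i] <- "("; depth <- depth + 1
        open_at <- c(open_at, i)
      } else chars[i] <- "."
      i <- i + 1
    }
    if (depth == 0) return(paste(chars, collapse = ""))
  }
}

# least-squares circle fit (Kasa): returns max radial residual
circle_residual <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  fit <- stats::lm.fit(cbind(2 * x, 2 * y, 1), x^2 + y^2)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  r <- sqrt(fit$coefficients[3] + a^2 + b^2)
  max(abs(sqrt((x - a)^2 + (y - b)^2) - r))
}

extdata <- function(f) system.file("extdata", f, package = "rnasites")
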