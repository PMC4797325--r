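# Independent brute-force oracles, coded from the textbook formulas and kept
# deliberately separate from the package implementations.

oracleWelchT <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

oracleWelchAnova <- function(groups) {
  k <- length(groups)
  n <- sapply(groups, length)
  m <- sapply(groups, mean)
  v <- sapply(groups, var)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sum(w))^2 / (n - 1))
  den <- 1 + 2 * (k - 2) * lambda / (k^2 - 1)
  Fstat <- num / den
  df2 <- (k^2 - 1) / (3 * lambda)
  pf(Fstat, k - 1, df2, lower.tail = FALSE)
}

oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# stepwise studentized-range procedure: ranges tested from widest to
# narrowest; a range contained in any non-rejected range is declared
# homogeneous without testing
oracleSNK <- function(groups, alpha = 0.05) {
  labels <- names(groups)
  n <- sapply(groups, length)
  m <- sapply(groups, mean)
  v <- sapply(groups, var)
  dfe <- sum(n - 1)
  mse <- sum((n - 1) * v) / dfe
  if (mse == 0) mse <- .Machine$double.eps
  ord <- order(m)
  k <- length(groups)
  accepted <- list()  # windows declared homogeneous, as c(i, j)
  out <- character()
  for (r in seq(k, 2)) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      blocked <- any(vapply(accepted, function(w)
        w[1] <= i && w[2] >= j, TRUE))
      if (blocked) {
        accepted[[length(accepted) + 1]] <- c(i, j)
        next
      }
      a <- ord[i]; b <- ord[j]
      q <- (m[b] - m[a]) / sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
      if (q >= qtukey(1 - alpha, r, dfe)) {
        out[[length(out) + 1]] <-
          paste(sort(c(labels[a], labels[b])), collapse = "|")
      } else {
        accepted[[length(accepted) + 1]] <- c(i, j)
      }
    }
  }
  sort(unique(out))
}

# canonicalize package SNK pairs to the oracle's alphabetical "A|B" form
canonPairs <- function(pairs) {
  sort(unique(vapply(pairs, function(p) {
    ab <- sort(strsplit(p, "-", fixed = TRUE)[[1]])
    paste(ab, collapse = "|")
  }, "", USE.NAMES = FALSE)))
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
oracleAverageLinkageHeights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

oracleStouffer <- function(p) {
  pnorm(sum(qnorm(1 - p)) / sqrt(length(p)), lower.tail = FALSE)
}
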