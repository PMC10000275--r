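# Independent oracles for the MIC machinery.
#
# oracle_char_matrix(): a from-scratch pure-R implementation of the same
# approximation (equipartition one axis, dynamic program over clump
# boundaries on the other), written independently of the C++ code path.
#
# brute_char_matrix(): exact maximization over ALL contiguous partitions
# of the optimized axis (no clump/superclump shortcut), feasible at small
# n. When the superclump cap is not binding the approximation is exact, so
# both must agree to machine precision.

oracle_equipartition <- function(v, y) {
  n <- length(v)
  grp <- integer(n)
  i <- 1L; cur <- 0L; size <- 0L
  desired <- n / y
  while (i <= n) {
    s <- 1L
    while (i + s <= n && v[i + s] == v[i]) s <- s + 1L
    if (size != 0L && abs(size + s - desired) >= abs(size - desired) &&
        cur < y - 1L) {
      cur <- cur + 1L
      size <- 0L
      desired <- (n - i + 1) / (y - cur)
    }
    grp[i:(i + s - 1L)] <- cur
    i <- i + s
    size <- size + s
  }
  grp
}

# row assignment of each point (x-sorted) given l-row y equipartition
oracle_rows <- function(y_by_x, l) {
  ys <- sort(y_by_x)
  g <- oracle_equipartition(ys, l)
  g[match(y_by_x, ys)]
}

oracle_entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# MI of a column partition given row labels; cuts = sorted end indices of
# columns over x-sorted points (last = n)
oracle_mi <- function(row, cuts, q) {
  n <- length(row)
  HQ <- oracle_entropy(tabulate(row + 1L, q), n)
  lo <- c(0L, head(cuts, -1L))
  gsum <- 0
  for (j in seq_along(cuts)) {
    seg <- row[(lo[j] + 1L):cuts[j]]
    np <- length(seg)
    gsum <- gsum - (np / n) * log2(np / n) +
      sum(vapply(tabulate(seg + 1L, q), function(cnt) {
        if (cnt == 0) 0 else (cnt / n) * log2(cnt / n)
      }, numeric(1)))
  }
  HQ + gsum
}

# exact best MI over all <=k contiguous columns, cuts anywhere between
# distinct x values (brute force; small n only)
brute_best_mi <- function(x, y, k, l) {
  ord <- order(x, y)
  xs <- x[ord]
  row <- oracle_rows(y[ord], l)
  q <- max(row) + 1L
  n <- length(x)
  # legal cut positions: between points with distinct x
  pos <- which(diff(xs) != 0)
  best <- -Inf
  for (kk in 2:k) {
    if (length(pos) < kk - 1) next
    combs <- utils::combn(pos, kk - 1)
    for (j in seq_len(ncol(combs))) {
      cuts <- c(combs[, j], n)
      best <- max(best, oracle_mi(row, cuts, q))
    }
  }
  best
}

brute_char_matrix <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(ceiling(n^alpha), 4)
  cap <- floor(B / 2)
  out <- matrix(NA_real_, cap - 1, cap - 1,
                dimnames = list(as.character(2:cap), as.character(2:cap)))
  for (k in 2:cap) {
    for (l in 2:cap) {
      if (k * l > B) next
      a <- brute_best_mi(x, y, k, l)
      b <- brute_best_mi(y, x, l, k)
      out[k - 1, l - 1] <- min(max(max(a, b) / log2(min(k, l)), 0), 1)
    }
  }
  out
}

# ---- independent pure-R implementation of the approximation ----

oracle_clumps <- function(xs, row) {
  n <- length(xs)
  lab <- as.numeric(row)
  fresh <- -1
  i <- 1L
  while (i <= n) {
    s <- 1L
    while (i + s <= n && xs[i + s] == xs[i]) s <- s + 1L
    if (s > 1L && length(unique(row[i:(i + s - 1L)])) > 1L) {
      lab[i:(i + s - 1L)] <- fresh
      fresh <- fresh - 1
    }
    i <- i + s
  }
  cumsum(c(0L, diff(lab) != 0))
}

# best MI for 2..kmax columns via DP over clump boundaries (vectorized)
oracle_dp <- function(row, clump, q, kmax) {
  n <- length(row)
  nc <- max(clump) + 1L
  # cumulative counts at clump ends: (nc+1) x q and totals
  cnt <- matrix(0, nc + 1, q)
  for (r in seq_len(q)) {
    cnt[, r] <- c(0, cumsum(tabulate(clump[row == r - 1L] + 1L, nc)))
  }
  tot <- rowSums(cnt)
  HQ <- oracle_entropy(cnt[nc + 1, ], n)
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  gfun <- function(s, t) {
    # s vector of start clump counts (0-based), scalar t
    np <- tot[t + 1L] - tot[s + 1L]
    g <- -xlx(np / n)
    for (r in seq_len(q)) {
      g <- g + xlx((cnt[t + 1L, r] - cnt[s + 1L, r]) / n)
    }
    g
  }
  kuse <- min(kmax, nc)
  Fm <- matrix(-Inf, kuse, nc) # Fm[cols, t]
  for (t in seq_len(nc)) Fm[1, t] <- gfun(0L, t)
  if (kuse >= 2) {
    for (cols in 2:kuse) {
      for (t in cols:nc) {
        s <- (cols - 1L):(t - 1L)
        Fm[cols, t] <- max(Fm[cols - 1L, s] + gfun(s, t))
      }
    }
  }
  # best over <= k columns, k = 2..kmax
  vapply(2:kmax, function(k) {
    HQ + max(Fm[seq_len(min(k, kuse)), nc])
  }, numeric(1))
}

oracle_half <- function(x, y, B, cpar, mi) {
  n <- length(x)
  ord <- order(x, y)
  xs <- x[ord]
  yo <- y[ord]
  for (l in 2:floor(B / 2)) {
    kmax <- floor(B / l)
    if (kmax < 2) next
    row <- oracle_rows(yo, l)
    q <- max(row) + 1L
    clump <- oracle_clumps(xs, row)
    khat <- max(cpar * kmax, 1)
    if (max(clump) + 1L > khat) {
      clump <- oracle_equipartition(as.numeric(clump), khat)
    }
    best <- oracle_dp(row, clump, q, kmax)
    for (k in 2:kmax) {
      mi[k - 1, l - 1] <- max(mi[k - 1, l - 1], best[k - 1], na.rm = TRUE)
    }
  }
  mi
}

oracle_char_matrix <- function(x, y, alpha = 0.6, cpar = 15,
                               both = TRUE) {
  n <- length(x)
  B <- max(ceiling(n^alpha), 4)
  cap <- floor(B / 2)
  mi <- matrix(NA_real_, cap - 1, cap - 1)
  computable <- outer(2:cap, 2:cap, function(k, l) k * l <= B)
  mi[computable] <- 0
  miA <- oracle_half(x, y, B, cpar, mi)
  miB <- if (both) oracle_half(y, x, B, cpar, mi) else miA
  out <- matrix(NA_real_, cap - 1, cap - 1,
                dimnames = list(as.character(2:cap), as.character(2:cap)))
  for (k in 2:cap) {
    for (l in 2:cap) {
      if (k * l > B) next
      v <- max(miA[k - 1, l - 1], miB[l - 1, k - 1])
      out[k - 1, l - 1] <- min(max(v / log2(min(k, l)), 0), 1)
    }
  }
  out
}
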