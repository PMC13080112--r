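# Independent brute-force oracles used to validate the package's
# implementations on small instances. These are deliberately naive and
# share no code with the package.

# Lempel-Ziv complexity by direct exhaustive-history parsing over
# character strings: the current word grows until it is no longer a
# substring of everything before its last character.
lzc_oracle <- function(symbols) {
  s <- paste(symbols, collapse = "")
  n <- nchar(s)
  if (n == 0) stop("empty")
  c_n <- 1L
  i <- 2L
  len <- 1L
  while (i + len - 1L <= n) {
    word <- substr(s, i, i + len - 1L)
    hist <- substr(s, 1L, i + len - 2L)
    if (grepl(word, hist, fixed = TRUE)) {
      len <- len + 1L
    } else {
      c_n <- c_n + 1L
      i <- i + len
      len <- 1L
    }
  }
  if (i <= n) c_n <- c_n + 1L   # trailing reproducible word
  c_n
}

# Batch form of the same exhaustive-history parse, vectorized across the
# rows of a sequence matrix so the full 4-symbol space up to length 10
# can be enumerated. Substring identity is tested by direct comparison of
# base-5 rolling codes over ALL candidate start positions (brute force,
# no shared code with the package). Agreement with the scalar
# lzc_oracle() is itself asserted in the test suite.
lzc_oracle_batch <- function(S) {
  m <- nrow(S)
  n <- ncol(S)
  pow5 <- 5^(0:n)
  # W[, t+1] = sum_{u<=t} s_u * 5^(u-1); codes stay below 2^53 for n<=10
  W <- matrix(0, m, n + 1)
  for (t in seq_len(n)) W[, t + 1] <- W[, t] + S[, t] * pow5[t]
  code <- function(a, b) (W[, b + 1] - W[, a]) / pow5[a]  # 5^(a-1)
  cnt <- rep(1L, m)        # first symbol
  wstart <- rep(2L, m)     # start of the current word
  if (n >= 2) {
    for (p in 2:n) {
      found <- rep(FALSE, m)
      for (L in unique(p - wstart + 1L)) {
        idx <- which(p - wstart + 1L == L)   # word start is p - L + 1 here
        if (p - L < 1L) next                 # no room in the history
        wcode <- code(p - L + 1L, p)[idx]
        for (a in seq_len(p - L)) {
          found[idx] <- found[idx] | (code(a, a + L - 1L)[idx] == wcode)
        }
      }
      cnt[!found] <- cnt[!found] + 1L
      wstart[!found] <- p + 1L
    }
  }
  cnt + as.integer(wstart <= n)              # trailing pending word
}

# Benjamini-Hochberg step-up written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Plug-in mutual information (bits) from scratch.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) {
      pij <- tab[i, j] / n
      mi <- mi + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
    }
  }
  mi
}

# Greedy mRMR (difference form) by exhaustive per-step maximization.
mrmr_oracle <- function(x, labels) {
  p <- ncol(x)
  feats <- colnames(x)
  sel <- integer(0)
  for (step in seq_len(p)) {
    cand <- setdiff(seq_len(p), sel)
    score <- sapply(cand, function(j) {
      rel <- mi_oracle(x[, j], labels)
      red <- if (length(sel) == 0) 0
      else mean(sapply(sel, function(s) mi_oracle(x[, j], x[, s])))
      rel - red
    })
    ord <- cand[order(-score, feats[cand])]
    sel <- c(sel, ord[1L])
  }
  feats[sel]
}

# Best achievable polarity-invariant 2-cluster GEV by exhaustive search
# over all assignments (tiny N_p only).
kmeans_oracle_gev <- function(maps) {
  np <- nrow(maps)
  maps_c <- maps - rowMeans(maps)
  gfp2 <- rowMeans(maps_c^2)
  w <- gfp2 / sum(gfp2)
  u <- maps_c / sqrt(rowSums(maps_c^2))
  best <- -Inf
  for (code in 0:(2^np - 1)) {
    cl <- as.integer(intToBits(code))[seq_len(np)] + 1L
    if (length(unique(cl)) < 2L) next
    gev <- 0
    ok <- TRUE
    ctr <- matrix(0, 2L, ncol(maps))
    for (j in 1:2) {
      uj <- maps_c[cl == j, , drop = FALSE]
      e <- eigen(crossprod(uj), symmetric = TRUE)
      v <- e$vectors[, 1L]
      v <- v - mean(v)
      nv <- sqrt(sum(v^2))
      if (nv == 0) { ok <- FALSE; break }
      ctr[j, ] <- v / nv
    }
    if (!ok) next
    # polarity-invariant reassignment to the better of the two centroids
    a <- abs(u %*% t(ctr))
    r <- pmax(a[, 1L], a[, 2L])
    gev <- sum(w * r^2)
    best <- max(best, gev)
  }
  best
}

# simple classification metric oracle
acc_oracle <- function(pred, truth) 100 * mean(as.character(pred) ==
                                                 as.character(truth))
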