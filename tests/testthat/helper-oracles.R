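# Independent brute-force oracles used to cross-check the compiled
# implementations. Deliberately simple and slow; applied only to small
# inputs.

# flood-fill connected-component labelling (queue-based, pure R)
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!isTRUE(mask[i, j]) || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        ni <- cur[1] + offs[k, 1]; nj <- cur[2] + offs[k, 2]
        if (ni >= 1 && nj >= 1 && ni <= nr && nj <= nc &&
            isTRUE(mask[ni, nj]) && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# two-sided Wilcoxon rank-sum P by full enumeration of group assignments
oracle_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# two-sided Fisher exact P by enumeration of all tables with fixed margins
oracle_fisher <- function(m) {
  m <- matrix(m, 2, 2)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force maximal-sphere local thickness on a small 3D mask:
# thickness(x) = max over all foreground p of 2*r(p) such that
# |x - p| <= r(p), with r(p) the distance to the nearest background voxel
oracle_thickness <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  bgi <- which(!mask, arr.ind = TRUE)
  # include the shell beyond the array as background
  r <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    d_edge <- min(p[1], p[2], p[3], d[1] + 1 - p[1], d[2] + 1 - p[2],
                  d[3] + 1 - p[3])
    d_bg <- if (nrow(bgi)) sqrt(min(colSums((t(bgi) - p)^2))) else Inf
    r[i] <- min(d_edge, d_bg)
  }
  th <- array(0, d)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    cover <- colSums((t(idx) - p)^2) <= r[i]^2 + 1e-9
    vals <- th[idx[cover, , drop = FALSE]]
    th[idx[cover, , drop = FALSE]] <- pmax(vals, 2 * r[i])
  }
  th
}

# exhaustive between-class-variance scan (independent of otsu_threshold's
# vectorised implementation)
oracle_otsu <- function(v, n_bins = 256) {
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  best <- -Inf; best_k <- 1
  for (k in seq_len(n_bins - 1)) {
    g1 <- v[bin <= k]; g2 <- v[bin > k]
    if (!length(g1) || !length(g2)) next
    bcv <- length(g1) * length(g2) * (mean(g1) - mean(g2))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  edges[best_k + 1]
}
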