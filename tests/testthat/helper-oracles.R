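# Independent brute-force oracles used to cross-check the implementation.

# AUC as the normalized Mann-Whitney pair count (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}

# Two-sample KS statistic by exhaustive ECDF comparison at all data points.
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Mann-Whitney U by double loop.
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# DeLong paired AUC-difference p-value from placement values (DeLong 1988).
oracle_delong_p <- function(s1, s2, labels) {
  pos <- labels == 1; neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  place <- function(s) {
    V10 <- vapply(s[pos], function(x) mean(psi(x, s[neg])), numeric(1))
    V01 <- vapply(s[neg], function(y) mean(psi(s[pos], y)), numeric(1))
    list(auc = mean(V10), V10 = V10, V01 = V01)
  }
  p1 <- place(s1); p2 <- place(s2)
  S10 <- stats::cov(cbind(p1$V10, p2$V10))
  S01 <- stats::cov(cbind(p1$V01, p2$V01))
  S <- S10 / m + S01 / n
  L <- c(1, -1)
  v <- drop(t(L) %*% S %*% L)
  z <- (p1$auc - p2$auc) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

# Percentage of unneighbored voxels by exhaustive neighbor enumeration.
oracle_pct_unneighbored <- function(labels, roi, H) {
  d <- dim(labels)
  out <- rep(NA_real_, H)
  for (h in seq_len(H)) {
    idx <- which(roi & labels == h, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    lonely <- 0
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]; found <- FALSE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (any(w < 1) || any(w > d)) next
        if (roi[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == h) found <- TRUE
      }
      if (!found) lonely <- lonely + 1
    }
    out[h] <- 100 * lonely / nrow(idx)
  }
  out
}

# Spatial interaction matrix by exhaustive ordered pair counting.
oracle_interaction <- function(labels, roi, H) {
  d <- dim(labels)
  counts <- matrix(0, H, H)
  idx <- which(roi, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]; a <- labels[v[1], v[2], v[3]]
    if (is.na(a) || a < 1) next
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > d)) next
      if (!roi[w[1], w[2], w[3]]) next
      b <- labels[w[1], w[2], w[3]]
      if (!is.na(b) && b >= 1) counts[a, b] <- counts[a, b] + 1
    }
  }
  rs <- rowSums(counts)
  out <- counts / ifelse(rs > 0, rs, NA_real_)
  out[rs == 0, ] <- NA_real_
  out
}

# Connected components of a label's voxel set under 26-connectivity (BFS).
oracle_n_components <- function(member) {
  d <- dim(member)
  seen <- array(FALSE, d)
  idx <- which(member)
  comp <- 0
  for (start in idx) {
    if (seen[start]) next
    comp <- comp + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      v <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        w <- v + c(dx, dy, dz)
        if (any(w < 1) || any(w > d)) next
        lin <- w[1] + d[1] * (w[2] - 1) + d[1] * d[2] * (w[3] - 1)
        if (member[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
  }
  comp
}
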