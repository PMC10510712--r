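## Linear assignment by the Jonker-Volgenant shortest augmenting path
## algorithm (O(n^3)). Used for frame-to-frame track linking, where the
## matrices are small (a handful of detections per connected component of
## the feasibility graph). Forbidden assignments are encoded as LAP_BIG.

LAP_BIG <- 1e15

solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n)       # row potentials
  v <- numeric(n + 1)   # column potentials; v[1] is the virtual column
  p <- integer(n + 1)   # p[j+1]: row currently matched to column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      js <- which(!used[-1L])
      cur <- cost[i0, js] - u[i0] - v[js + 1L]
      upd <- cur < minv[js + 1L]
      if (any(upd)) {
        minv[js[upd] + 1L] <- cur[upd]
        way[js[upd] + 1L] <- j0
      }
      k <- which.min(minv[js + 1L])
      j1 <- js[k]
      delta <- minv[j1 + 1L]
      uidx <- which(used)
      for (j in uidx) {
        if (p[j] > 0L || j == 1L) u[p[j]] <- u[p[j]] + delta
        v[j] <- v[j] - delta
      }
      nidx <- which(!used[-1L]) + 1L
      minv[nidx] <- minv[nidx] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    ## augment along the alternating path
    while (j0 != 0L) {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
    }
  }
  ## p[j+1] = row of column j; invert to row -> column
  out <- integer(n)
  out[p[-1L]] <- seq_len(n)
  out
}

## Minimum-cost frame-to-frame matching with unmatched alternatives.
## a, b: matrices of positions (rows = points, cols = coordinates).
## Returns an integer vector m of length nrow(a): m[i] = index in b linked
## to a-point i, or NA. The assignment minimizes total squared displacement
## among assignments whose links all have distance <= cap, and links every
## pair that can feasibly be linked (leaving two points unmatched always
## costs more than linking them).
match_points <- function(a, b, cap) {
  na <- nrow(a); nb <- nrow(b)
  m <- rep(NA_integer_, na)
  if (na == 0L || nb == 0L) return(m)
  cap2 <- cap^2
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  feas <- d2 <= cap2
  ## connected components of the bipartite feasibility graph keep the
  ## assignment problems tiny
  comp_a <- rep(0L, na); comp_b <- rep(0L, nb); nc <- 0L
  for (i in seq_len(na)) {
    if (comp_a[i] > 0L) next
    nc <- nc + 1L
    qa <- i
    while (length(qa)) {
      ia <- qa[1]; qa <- qa[-1]
      if (comp_a[ia] > 0L) next
      comp_a[ia] <- nc
      jb <- which(feas[ia, ] & comp_b == 0L)
      comp_b[jb] <- nc
      for (j in jb) qa <- c(qa, which(feas[, j] & comp_a == 0L))
    }
  }
  for (k in seq_len(nc)) {
    ia <- which(comp_a == k); jb <- which(comp_b == k)
    if (!length(jb)) next
    if (length(ia) == 1L && length(jb) == 1L) {
      if (feas[ia, jb]) m[ia] <- jb
      next
    }
    nA <- length(ia); nB <- length(jb); n <- nA + nB
    M <- matrix(LAP_BIG, n, n)
    M[seq_len(nA), seq_len(nB)] <- ifelse(feas[ia, jb, drop = FALSE],
                                          d2[ia, jb, drop = FALSE], LAP_BIG)
    M[cbind(seq_len(nA), nB + seq_len(nA))] <- cap2
    M[cbind(nA + seq_len(nB), seq_len(nB))] <- cap2
    M[nA + seq_len(nB), nB + seq_len(nA)] <- 0
    asg <- solve_lap(M)
    for (r in seq_len(nA)) {
      j <- asg[r]
      if (j <= nB && feas[ia[r], jb[j]]) m[ia[r]] <- jb[j]
    }
  }
  m
}
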