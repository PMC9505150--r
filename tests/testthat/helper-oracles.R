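# Independent brute-force oracles used to check the package's optimized
# implementations. These deliberately use naive explicit loops and stay
# structurally independent of the code under test.

# --- winding-number point-in-polygon ---------------------------------
pip_winding_oracle <- function(point, polygon) {
  n <- nrow(polygon)
  total <- 0
  for (e in seq_len(n)) {
    a <- polygon[e, ] - point
    b <- polygon[if (e == n) 1 else e + 1, ] - point
    ang <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    total <- total + ang
  }
  abs(total) > pi   # winding number != 0
}

# --- trilinear interpolation at one physical point -------------------
trilinear_oracle <- function(vol, pt) {
  u <- (pt - vol$origin_mm) / vol$spacing_mm
  d <- dim(vol$values)
  i0 <- pmin(pmax(floor(u), 0), d - 2)
  f <- u - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
    acc <- acc + wgt * vol$values[i0[1] + dx + 1, i0[2] + dy + 1,
                                  i0[3] + dz + 1]
  }
  acc
}

# --- texture-matrix builders (naive voxel/direction loops) ------------
oracle_dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

oracle_glcm <- function(lev, nlev) {
  d <- dim(lev)
  out <- array(0, c(nlev, nlev, 13))
  for (dd in 1:13) {
    off <- oracle_dirs13[dd, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- lev[x, y, z]
      if (is.na(i) || i == 0) next
      q <- c(x, y, z) + off
      if (any(q < 1) || any(q > d)) next
      j <- lev[q[1], q[2], q[3]]
      if (is.na(j) || j == 0) next
      out[i, j, dd] <- out[i, j, dd] + 1
      out[j, i, dd] <- out[j, i, dd] + 1
    }
  }
  out
}

oracle_glrlm <- function(lev, nlev) {
  d <- dim(lev)
  maxrun <- max(d)
  out <- array(0, c(nlev, maxrun, 13))
  inb <- function(q) all(q >= 1) && all(q <= d)
  at <- function(q) {
    v <- lev[q[1], q[2], q[3]]
    if (is.na(v)) 0 else v
  }
  for (dd in 1:13) {
    off <- oracle_dirs13[dd, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      p <- c(x, y, z)
      i <- at(p)
      if (i == 0) next
      prev <- p - off
      if (inb(prev) && at(prev) == i) next   # not a run start
      len <- 1
      q <- p + off
      while (inb(q) && at(q) == i) {
        len <- len + 1
        q <- q + off
      }
      out[i, len, dd] <- out[i, len, dd] + 1
    }
  }
  out
}

oracle_glszm <- function(lev, nlev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  neigh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]
  at <- function(q) {
    v <- lev[q[1], q[2], q[3]]
    if (is.na(v)) 0 else v
  }
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    p <- c(x, y, z)
    i <- at(p)
    if (i == 0 || seen[x, y, z]) next
    frontier <- list(p)
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(frontier)) {
      c0 <- frontier[[1]]
      frontier <- frontier[-1]
      size <- size + 1
      for (k in seq_len(nrow(neigh))) {
        q <- c0 + neigh[k, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && at(q) == i) {
          seen[q[1], q[2], q[3]] <- TRUE
          frontier[[length(frontier) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(i, size)
  }
  do.call(rbind, zones)
}

oracle_ngtdm_ngldm <- function(lev, nlev) {
  d <- dim(lev)
  s_i <- numeric(nlev); n_i <- numeric(nlev)
  dep <- matrix(0, nlev, 27)
  at <- function(q) {
    v <- lev[q[1], q[2], q[3]]
    if (is.na(v)) 0 else v
  }
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- at(c(x, y, z))
    if (i == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (any(q < 1) || any(q > d)) next
      v <- at(q)
      if (v > 0) nb <- c(nb, v)
    }
    if (length(nb)) {
      n_i[i] <- n_i[i] + 1
      s_i[i] <- s_i[i] + abs(i - mean(nb))
    }
    k <- sum(nb == i)
    dep[i, k + 1] <- dep[i, k + 1] + 1
  }
  list(ngtdm = cbind(n_i, s_i), ngldm = dep)
}

# --- AUC by explicit pairwise comparison ------------------------------
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# --- full-batch NCA gradient ascent on the same objective -------------
nca_objective_oracle <- function(x, y, w, lambda) {
  n <- nrow(x)
  tot <- 0
  for (i in 1:n) {
    k <- numeric(n)
    for (j in 1:n) {
      if (j == i) next
      k[j] <- exp(-sum(w^2 * abs(x[i, ] - x[j, ])))
    }
    if (sum(k) > 0)
      tot <- tot + sum(k[setdiff(which(y == y[i]), i)]) / sum(k)
  }
  tot / n - lambda * sum(w^2)
}

nca_batch_oracle <- function(x, y, lambda, iters = 300, step0 = 1) {
  n <- nrow(x); p <- ncol(x)
  w <- rep(1, p)
  obj <- nca_objective_oracle(x, y, w, lambda)
  step <- step0
  for (it in seq_len(iters)) {
    grad <- rep(0, p)
    for (i in 1:n) {
      k <- numeric(n)
      for (j in 1:n)
        if (j != i) k[j] <- exp(-sum(w^2 * abs(x[i, ] - x[j, ])))
      S <- sum(k)
      if (S <= 0) next
      pij <- k / S
      same <- y == y[i]; same[i] <- FALSE
      pi_i <- sum(pij[same])
      t1 <- rep(0, p); t2 <- rep(0, p)
      for (j in 1:n) {
        if (j == i || pij[j] == 0) next
        D <- abs(x[i, ] - x[j, ])
        t1 <- t1 + pij[j] * D
        if (same[j]) t2 <- t2 + pij[j] * D
      }
      grad <- grad + 2 * w * (pi_i * t1 - t2)
    }
    grad <- grad / n - 2 * lambda * w
    repeat {
      w_new <- w + step * grad
      obj_new <- nca_objective_oracle(x, y, w_new, lambda)
      if (obj_new >= obj - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    if (obj_new < obj) break
    if (obj_new - obj < 1e-10 && it > 20) { w <- w_new; obj <- obj_new; break }
    w <- w_new
    obj <- obj_new
    step <- step * 1.2
  }
  list(w = abs(w), objective = obj)
}

# --- exhaustive best single-threshold classifier ----------------------
best_stump_error_oracle <- function(x, y, w) {
  best <- Inf
  for (j in seq_len(ncol(x))) {
    cuts <- sort(unique(x[, j]))
    cuts <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2,
              cuts[length(cuts)] + 1)
    for (thr in cuts) for (dir in c(1, -1)) {
      pred <- if (dir == 1) x[, j] >= thr else x[, j] < thr
      err <- sum(w[pred != y]) / sum(w)
      best <- min(best, err)
    }
  }
  best
}
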