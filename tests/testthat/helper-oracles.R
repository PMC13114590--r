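# Independent brute-force oracles, deliberately written with plain loops so
# they share no code with the package implementations.

# O(n^2) concordance-counting AUC (ties count 1/2).
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Naive Davies-Bouldin from its definition.
oracle_db <- function(x, a) {
  ks <- sort(unique(a))
  cent <- lapply(ks, function(k) colMeans(x[a == k, , drop = FALSE]))
  s <- sapply(seq_along(ks), function(i) {
    m <- x[a == ks[i], , drop = FALSE]
    mean(apply(m, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  })
  tot <- 0
  for (i in seq_along(ks)) {
    best <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (s[i] + s[j]) / d)
    }
    tot <- tot + best
  }
  tot / length(ks)
}

# All 26 neighbor offsets / 13 unique directions for the loop oracles.
.offs26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
.offs26 <- .offs26[rowSums(abs(.offs26)) > 0, ]
.dirs13 <- .offs26[apply(.offs26, 1, function(o) { nz <- o[o != 0]; nz[1] > 0 }), ]

# Symmetric co-occurrence matrix by triple loop, one direction.
oracle_glcm_matrix <- function(disc, off, ng) {
  d <- dim(disc)
  m <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- disc[i, j, k]
    if (is.na(a)) next
    p <- c(i, j, k) + off
    if (any(p < 1) || any(p > d)) next
    b <- disc[p[1], p[2], p[3]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

# Dependence matrix (alpha = 0, 26-connectivity) by loops.
oracle_gldm_matrix <- function(disc, ng) {
  d <- dim(disc)
  rows <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- disc[i, j, k]
    if (is.na(a)) next
    dep <- 1
    for (r in seq_len(nrow(.offs26))) {
      p <- c(i, j, k) + .offs26[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- disc[p[1], p[2], p[3]]
      if (!is.na(b) && b == a) dep <- dep + 1
    }
    rows[[length(rows) + 1]] <- c(a, dep)
  }
  rw <- do.call(rbind, rows)
  m <- matrix(0, ng, max(rw[, 2]))
  for (q in seq_len(nrow(rw))) m[rw[q, 1], rw[q, 2]] <- m[rw[q, 1], rw[q, 2]] + 1
  m
}

# NGTD matrix quantities (n_i, s_i) by loops.
oracle_ngtdm <- function(disc, ng) {
  d <- dim(disc)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- disc[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(.offs26))) {
      p <- c(i, j, k) + .offs26[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- disc[p[1], p[2], p[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    n_i[a] <- n_i[a] + 1
    if (length(nb)) s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, s = s_i)
}

# Run-length matrix by explicit line walking, one direction.
oracle_glrlm_matrix <- function(disc, off, ng) {
  d <- dim(disc)
  runs <- list()
  visited <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- disc[i, j, k]
    if (is.na(a)) next
    prev <- c(i, j, k) - off
    pre_in <- all(prev >= 1) && all(prev <= d)
    if (pre_in && !is.na(disc[prev[1], prev[2], prev[3]]) &&
        disc[prev[1], prev[2], prev[3]] == a) next  # not a run start
    len <- 1
    cur <- c(i, j, k)
    repeat {
      nxt <- cur + off
      if (any(nxt < 1) || any(nxt > d)) break
      b <- disc[nxt[1], nxt[2], nxt[3]]
      if (is.na(b) || b != a) break
      len <- len + 1
      cur <- nxt
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  rw <- do.call(rbind, runs)
  m <- matrix(0, ng, max(rw[, 2]))
  for (q in seq_len(nrow(rw))) m[rw[q, 1], rw[q, 2]] <- m[rw[q, 1], rw[q, 2]] + 1
  m
}

# Zone (size) matrix via recursive flood fill.
oracle_glszm_matrix <- function(disc, ng) {
  d <- dim(disc)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (seen[i, j, k] || is.na(disc[i, j, k])) next
    g <- disc[i, j, k]
    stack <- list(c(i, j, k)); seen[i, j, k] <- TRUE; size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(.offs26))) {
        p <- v + .offs26[r, ]
        if (any(p < 1) || any(p > d)) next
        if (seen[p[1], p[2], p[3]]) next
        b <- disc[p[1], p[2], p[3]]
        if (!is.na(b) && b == g) {
          seen[p[1], p[2], p[3]] <- TRUE
          stack[[length(stack) + 1]] <- p
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  rw <- do.call(rbind, zones)
  m <- matrix(0, ng, max(rw[, 2]))
  for (q in seq_len(nrow(rw))) m[rw[q, 1], rw[q, 2]] <- m[rw[q, 1], rw[q, 2]] + 1
  m
}

# Small 3D discretized fixture with NA padding outside an irregular mask.
make_disc_fixture <- function(seed = 42, dims = c(4, 4, 2), ng = 4) {
  set.seed(seed)
  disc <- array(sample(seq_len(ng), prod(dims), replace = TRUE), dims)
  drop <- sample(prod(dims), round(prod(dims) * 0.2))
  disc[drop] <- NA_integer_
  if (all(is.na(disc))) disc[1] <- 1L
  disc
}

# Tiny synthetic lesion volume for extraction tests.
make_test_voi <- function(seed = 1, side = 12) {
  set.seed(seed)
  a <- array(rnorm(side^3, -300, 120), rep(side, 3))
  v <- ct_volume(a)
  m <- array(FALSE, rep(side, 3))
  ctr <- side / 2
  for (i in seq_len(side)) for (j in seq_len(side)) for (k in seq_len(side))
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= (side / 2 - 1.5)^2)
      m[i, j, k] <- TRUE
  list(vol = v, mask = m)
}

make_small_cohort_config <- function(n = 20, seed = 1, ...) {
  cohort_config(n_cases = n, seed = seed,
                diameter_range = c(9, 16), ...)
}
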