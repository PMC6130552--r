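# Independent brute-force oracles for graph metrics and communication
# measures. Deliberately naive: exhaustive path enumeration, explicit set
# computations, full partition search. Only usable on small graphs.

# random connected undirected graph as adjacency matrix
random_connected_graph <- function(n, p = 0.4, weighted = FALSE) {
  repeat {
    a <- matrix(0, n, n)
    up <- upper.tri(a)
    a[up] <- as.numeric(runif(sum(up)) < p)
    if (weighted) a[up] <- a[up] * runif(sum(up), 0.2, 1)
    a <- a + t(a)
    if (oracle_connected(a)) return(a)
  }
}

oracle_connected <- function(a) {
  n <- nrow(a)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(a[, frontier, drop = FALSE] > 0) > 0), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == n
}

# exhaustive simple-path shortest distances (length = 1/w, unit if binary)
oracle_apsp <- function(a) {
  n <- nrow(a)
  len <- ifelse(a > 0, 1 / a, Inf)
  best <- matrix(Inf, n, n); diag(best) <- 0
  dfs <- function(node, target, visited, acc) {
    if (acc >= best[visited[1], target]) return(invisible())
    if (node == target) {
      best[visited[1], target] <<- acc
      return(invisible())
    }
    for (nb in which(a[node, ] > 0))
      if (!(nb %in% visited))
        dfs(nb, target, c(visited, nb), acc + len[node, nb])
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    dfs(s, t, s, 0)
    best[t, s] <- best[s, t]
  }
  best
}

# shortest-path node sequence by independent Floyd-Warshall with next-hop
oracle_sp_nodes <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1 / a, Inf); diag(d) <- 0
  nxt <- matrix(NA_integer_, n, n)
  for (i in 1:n) for (j in 1:n) if (a[i, j] > 0) nxt[i, j] <- j
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) {
      d[i, j] <- d[i, k] + d[k, j]
      nxt[i, j] <- nxt[i, k]
    }
  path <- function(i, j) {
    if (i == j) return(i)
    if (is.na(nxt[i, j])) return(NULL)
    p <- i
    while (i != j) { i <- nxt[i, j]; p <- c(p, i) }
    p
  }
  list(d = d, path = path)
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  bin <- a > 0
  w_hat <- if (all(a %in% c(0, 1))) a else a / max(a)
  cs <- sapply(1:n, function(i) {
    nb <- which(bin[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in nb) for (y in nb) if (x < y && bin[x, y])
      tri <- tri + (w_hat[i, x] * w_hat[i, y] * w_hat[x, y])^(1 / 3)
    tri / (k * (k - 1) / 2)
  })
  mean(cs)
}

oracle_global_eff <- function(a) {
  d <- oracle_apsp(a)
  v <- d[upper.tri(d)]
  mean(1 / v)
}

oracle_local_eff <- function(a) {
  n <- nrow(a)
  mean(sapply(1:n, function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(a[nb, nb, drop = FALSE])
  }))
}

# Newman modularity of a given membership vector
oracle_q <- function(a, memb) {
  m2 <- sum(a)
  if (m2 == 0) return(NA_real_)
  s <- rowSums(a)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(a[idx, idx]) / m2 - (sum(s[idx]) / m2)^2
  }
  q
}

# exhaustive max-modularity over all set partitions (n <= 7)
oracle_best_q <- function(a) {
  n <- nrow(a)
  best <- -Inf
  gen <- function(i, memb, k) {
    if (i > n) { best <<- max(best, oracle_q(a, memb)); return(invisible()) }
    for (c in 1:(k + 1)) {
      memb[i] <- c
      gen(i + 1, memb, max(k, c))
    }
  }
  gen(1, integer(n), 0)
  best
}

oracle_matching <- function(a) {
  n <- nrow(a)
  m <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- setdiff(1:n, c(i, j))
    both <- a[i, k] > 0 & a[j, k] > 0
    num <- sum((a[i, k] + a[j, k])[both])
    den <- sum(a[i, k][a[i, k] > 0]) + sum(a[j, k][a[j, k] > 0])
    if (den > 0) m[i, j] <- m[j, i] <- num / den
  }
  m
}

# SI along an externally supplied node path
oracle_si_along <- function(a, path_nodes) {
  s <- rowSums(a)
  p <- 1
  for (step in seq_len(length(path_nodes) - 1)) {
    i <- path_nodes[step]; j <- path_nodes[step + 1]
    p <- p * a[i, j] / s[i]
  }
  -log2(p)
}

# MFPT by solving one linear system per target (independent formulation)
oracle_mfpt <- function(a) {
  n <- nrow(a)
  P <- a / rowSums(a)
  out <- matrix(0, n, n)
  for (j in 1:n) {
    idx <- setdiff(1:n, j)
    sol <- solve(diag(n - 1) - P[idx, idx], rep(1, n - 1))
    out[idx, j] <- sol
  }
  out
}
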