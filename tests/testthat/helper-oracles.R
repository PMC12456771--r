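# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the implementation it checks.

# brute-force mean k-nearest-neighbour distance (full distance matrix)
oracle_mean_knn <- function(p, k) {
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  unname(apply(d, 1, function(r) mean(sort(r)[seq_len(k)])))
}

# Prim's algorithm MST total weight (implementation uses Kruskal)
oracle_prim_weight <- function(p) {
  n <- nrow(p)
  d <- as.matrix(dist(p))
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    j <- which(!intree)[which.min(mind[!intree])]
    total <- total + mind[j]
    intree[j] <- TRUE
    mind <- pmin(mind, d[j, ])
  }
  unname(total)
}

# exhaustive minimum spanning-tree weight via Pruefer-sequence enumeration
# (every labeled tree on n nodes corresponds to one sequence in {1..n}^(n-2))
oracle_exhaustive_mst_weight <- function(p) {
  n <- nrow(p)
  d <- as.matrix(dist(p))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    deg <- tabulate(pr, n) + 1L
    w <- 0
    for (a in pr) {                 # standard Pruefer decode
      leaf <- match(1L, deg)        # smallest remaining leaf
      w <- w + d[leaf, a]
      deg[leaf] <- 0L
      deg[a] <- deg[a] - 1L
    }
    rem <- which(deg == 1L)
    w <- w + d[rem[1], rem[2]]
    if (w < best) best <- w
  }
  best
}

# unique tree path by depth-first search (implementation uses Dijkstra)
oracle_dfs_path <- function(edges, n, src, dst) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  stack <- list(src)
  seen <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  seen[src] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v == dst) break
    for (u in adj[[v]]) if (!seen[u]) {
      seen[u] <- TRUE
      parent[u] <- v
      stack[[length(stack) + 1]] <- u
    }
  }
  path <- dst
  while (path[1] != src) path <- c(parent[path[1]], path)
  as.integer(path)
}

# leading eigenvector by power iteration (implementation uses eigen())
oracle_power_direction <- function(p, iters = 400) {
  q <- sweep(p, 2, colMeans(p))
  C <- crossprod(q) / nrow(q)
  v <- c(1, 1, 1) / sqrt(3)
  for (i in seq_len(iters)) {
    v <- C %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- drop(v)
  if (v[2] < 0) v <- -v
  v
}

# small deterministic cloud helpers
rand_cloud <- function(n, seed, scale = 1) {
  set.seed(seed)
  matrix(runif(3 * n, 0, scale), ncol = 3)
}

# analytic quarter-circle polyline in the XY plane
quarter_circle <- function(r = 0.1, n = 20) {
  t <- seq(0, pi / 2, length.out = n)
  cbind(r * cos(t), r * sin(t), 0)
}

# dense noiseless vertical cylinder surface sample
cylinder_cloud <- function(radius = 0.002, height = 0.4, n = 20000, seed = 1) {
  set.seed(seed)
  phi <- runif(n, 0, 2 * pi)
  y <- runif(n, 0, height)
  cbind(radius * cos(phi), y, radius * sin(phi))
}
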