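# Independent brute-force oracles. These deliberately use naive loop
# implementations so they share no code path with the package.

# Term-by-term Kullback-Leibler style divergence.
oracle_rwe <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  s <- 0
  for (j in 1:5) s <- s + p[j] * log(p[j] / q[j])
  s
}

# Fagiolo directed clustering by explicit triple enumeration.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    tri <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          tri <- tri + (adj[i, j] + adj[j, i]) * (adj[i, h] + adj[h, i]) *
            (adj[j, h] + adj[h, j])
        }
      }
    }
    dt <- sum(adj[i, ]) + sum(adj[, i])
    db <- sum(adj[i, ] * adj[, i])
    den <- 2 * (dt * (dt - 1) - 2 * db)
    cc[i] <- if (den > 0) tri / den else 0
  }
  cc
}

# Floyd-Warshall all-pairs shortest paths.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_path_length <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  list(l_mean = mean(off[reach]), unreachable_fraction = 1 - mean(reach))
}

# Betweenness by exhaustive enumeration of every shortest path.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || !is.finite(d[s, t])) next
      interior_counts <- numeric(n)
      total <- 0
      stack <- list(list(node = s, path = integer(0)))
      while (length(stack) > 0) {
        fr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (fr$node == t) {
          total <- total + 1
          for (v in fr$path) interior_counts[v] <- interior_counts[v] + 1
          next
        }
        for (v in which(adj[fr$node, ] == 1)) {
          if (d[s, fr$node] + 1 + d[v, t] == d[s, t]) {
            newpath <- if (v == t) fr$path else c(fr$path, v)
            stack[[length(stack) + 1]] <- list(node = v, path = newpath)
          }
        }
      }
      bc <- bc + interior_counts / total
    }
  }
  bc
}

# One periodized analysis step by explicit double loop.
oracle_dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2
  out <- numeric(half)
  for (m in seq_len(half)) {
    pos <- 2 * m - 1
    acc <- 0
    for (k in seq_along(filt)) {
      acc <- acc + filt[k] * x[((pos - (k - 1) - 1) %% n) + 1]
    }
    out[m] <- acc
  }
  out
}

oracle_dwt <- function(x, levels, wavelet) {
  f <- wavelet_filters(wavelet)
  details <- list()
  approx <- x
  for (j in seq_len(levels)) {
    details[[j]] <- oracle_dwt_step(approx, f$dec_hi)
    approx <- oracle_dwt_step(approx, f$dec_lo)
  }
  list(details = details, approx = approx)
}
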