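# Independent oracles. These never call the package's BFS/Brandes/power
# iteration code paths: distances and shortest-path counts come from powers
# of the adjacency matrix, betweenness from the path-count identity,
# eigenvector centrality from dense eigendecomposition, and (for small
# graphs) geodesics from exhaustive recursive path enumeration.

# distances and shortest-path counts via matrix powers:
# walks of length d(s,t) are exactly the geodesics
oracle_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  P <- A
  L <- 1L
  repeat {
    new <- is.infinite(D) & P > 0
    if (any(new)) { D[new] <- L; S[new] <- P[new] }
    if (!any(is.infinite(D)) || L >= n) break
    P <- P %*% A
    L <- L + 1L
  }
  list(D = D, S = S)
}

oracle_lp <- function(A) {
  D <- oracle_paths(A)$D
  mean(D[upper.tri(D)])
}

oracle_betweenness <- function(A) {
  op <- oracle_paths(A)
  D <- op$D; S <- op$S
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    on_path <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
    contrib <- outer(S[, v], S[v, ]) / ifelse(S > 0, S, 1) * on_path
    contrib[v, ] <- 0; contrib[, v] <- 0; diag(contrib) <- 0
    sum(contrib) / 2
  }, numeric(1))
}

oracle_eigenvector <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(length(nb), 2)
  }, numeric(1))
}

# exhaustive simple-path enumeration (tiny graphs only): returns the
# number of geodesics s->t and, per intermediate node, geodesics through it
enumerate_geodesics <- function(A, s, t) {
  n <- nrow(A)
  best <- Inf; paths <- list()
  walk <- function(v, visited, len) {
    if (len > best) return()
    if (v == t) {
      if (len < best) { best <<- len; paths <<- list() }
      if (len == best) paths[[length(paths) + 1]] <<- visited
      return()
    }
    for (w in which(A[v, ] == 1))
      if (!(w %in% visited)) walk(w, c(visited, w), len + 1)
  }
  walk(s, s, 0)
  list(n_geodesics = length(paths), length = best, paths = paths)
}

brute_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    g <- enumerate_geodesics(A, s, t)
    if (g$n_geodesics == 0) next
    inner <- unlist(lapply(g$paths, function(p) p[-c(1, length(p))]))
    if (length(inner) > 0) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      bc[idx] <- bc[idx] + as.numeric(tab) / g$n_geodesics
    }
  }
  bc
}

# naive two-pass Pearson correlation
naive_correlation <- function(X) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  R <- matrix(1, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    cij <- sum((X[, i] - mu[i]) * (X[, j] - mu[j]))
    R[i, j] <- cij / sqrt(sum((X[, i] - mu[i])^2) * sum((X[, j] - mu[j])^2))
  }
  R
}

# all undirected graphs on n nodes (n small), as a list of 0/1 matrices
enumerate_graphs <- function(n, connected_only = TRUE) {
  npair <- choose(n, 2)
  ut <- which(upper.tri(matrix(0, n, n)))
  out <- vector("list", 2^npair)
  kept <- 0L
  for (code in 0:(2^npair - 1)) {
    bits <- bitwAnd(code, 2^(0:(npair - 1))) > 0
    A <- matrix(0L, n, n)
    A[ut] <- as.integer(bits)
    A <- A + t(A)
    if (connected_only && !metabnet::is_connected(A)) next
    kept <- kept + 1L
    out[[kept]] <- A
  }
  out[seq_len(kept)]
}
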