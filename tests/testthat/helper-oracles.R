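# Independent oracles and small shared fixtures. Each oracle is a plain,
# slow transcription of the definition, deliberately sharing no code with
# the implementation it checks.

# O(V^2) Dijkstra over the mesh edge list with Euclidean edge weights.
dijkstra_oracle <- function(mesh, source) {
  nv <- nrow(mesh$vertices)
  e <- mesh$edges
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  adj <- vector("list", nv)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, nv)
  dist[source] <- 0
  done <- rep(FALSE, nv)
  for (it in seq_len(nv)) {
    u <- which(!done)[which.min(dist[!done])]
    if (!length(u) || is.infinite(dist[u])) break
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; wt <- adj[[u]][r, 2]
      if (dist[u] + wt < dist[v]) dist[v] <- dist[u] + wt
    }
  }
  dist
}

# Breadth-first flood fill over a vertex subset; returns a list of
# components (sorted integer vectors), order-normalized.
flood_fill_oracle <- function(mesh, vertices) {
  inset <- logical(nrow(mesh$vertices))
  inset[vertices] <- TRUE
  seen <- logical(nrow(mesh$vertices))
  comps <- list()
  for (v0 in vertices) {
    if (seen[v0]) next
    queue <- v0
    seen[v0] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      nbr <- mesh$neighbors[[u]]
      nxt <- nbr[inset[nbr] & !seen[nbr]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# Normal-equations OLS with explicit covariance, one response at a time.
ols_oracle <- function(y, X, contrast) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  cc <- which(colnames(X) == contrast)
  se <- sqrt(s2 * XtXi[cc, cc])
  list(beta = beta[cc], t = beta[cc] / se, df = df)
}

normalize_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, integer(1)))]
}

# Shared small meshes (built once per test run).
ico0 <- build_icosphere(0, 1)
ico2 <- build_icosphere(2, 70)
ico3 <- build_icosphere(3, 70)
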