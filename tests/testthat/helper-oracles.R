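# Independent oracles used across the suite. Deliberately naive and
# dependency-free (base R only): components by BFS over an adjacency list,
# entropies by direct formula, exact tests by brute-force enumeration.

# component sizes of a graph given node ids and a 2-column character edge
# matrix, singletons included
oracle_component_sizes <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 0L) return(integer(0))
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    ia <- match(edges[, 1L], nodes); ib <- match(edges[, 2L], nodes)
    for (e in seq_len(nrow(edges))) {
      adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
      adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
    }
  }
  seen <- logical(n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]; size <- size + 1L
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

oracle_entropy <- function(nodes, edges) {
  cs <- oracle_component_sizes(nodes, edges)
  n <- sum(cs)
  if (n <= 1L || length(cs) <= 1L) return(0)
  p <- cs / n
  -sum(p * log(p)) / log(n)
}

# exact expected entropy at each grid rate by enumerating ALL removal
# subsets of size floor(k*N/K); feasible for N <= 7
oracle_failure_curve <- function(net, K) {
  nodes <- net$nodes; edges <- net$edges
  n <- length(nodes)
  vapply(0:(K - 1L), function(k) {
    nrem <- (k * n) %/% K
    if (nrem == 0L) return(oracle_entropy(nodes, edges))
    sets <- utils::combn(n, nrem)
    mean(apply(sets, 2L, function(rm) {
      keep <- nodes[-rm]
      ekeep <- edges[edges[, 1L] %in% keep & edges[, 2L] %in% keep, ,
                     drop = FALSE]
      oracle_entropy(keep, ekeep)
    }))
  }, numeric(1))
}

oracle_resilience <- function(net, K) 1 - mean(oracle_failure_curve(net, K))

# exact signed-rank p by enumerating all 2^n sign vectors
oracle_signed_rank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(w_all >= w_obs - 1e-9),
         less = mean(w_all <= w_obs + 1e-9),
         two_sided = {
           mid <- sum(r) / 2
           mean(abs(w_all - mid) >= abs(w_obs - mid) - 1e-9)
         })
}

# exact rank-sum p by enumerating all C(n1+n2, n1) assignments of the
# pooled ranks to sample x
oracle_rank_sum <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  switch(alternative,
         greater = mean(u_all >= u_obs - 1e-9),
         less = mean(u_all <= u_obs + 1e-9),
         two_sided = min(1, 2 * min(mean(u_all >= u_obs - 1e-9),
                                    mean(u_all <= u_obs + 1e-9))))
}

# exact Fisher p by enumerating all 2x2 tables with the observed margins
oracle_fisher <- function(tab, alternative) {
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - nn); hi <- min(k, m)
  support <- lo:hi
  logp <- function(x) {
    lchoose(m, x) + lchoose(nn, k - x) - lchoose(m + nn, k)
  }
  dens <- exp(vapply(support, logp, numeric(1)))
  x <- tab[1, 1]
  switch(alternative,
         greater = sum(dens[support >= x]),
         less = sum(dens[support <= x]),
         two_sided = sum(dens[dens <= dens[support == x] * (1 + 1e-7)]))
}
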