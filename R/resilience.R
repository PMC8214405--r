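# Deterministic sub-seed from a global seed plus string labels, so that
# per-clone computations are order-independent and parallelizable.
# Polynomial string hash modulo the Mersenne prime 2^31 - 1.
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), as.character(c(...))), collapse = "\r")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Failure grid for the resilience statistic
#'
#' Grid of node-failure rates f_k = k/K for k = 0, ..., K-1 (total removal
#' f = 1 is excluded), with M Monte-Carlo removal replicates per network and
#' a global RNG seed. Per-network seeds are derived from `seed` and the
#' network name so clone computations are order-independent.
#'
#' @param K number of grid steps (>= 2). Default 100.
#' @param M Monte-Carlo replicates per network (>= 1). Default 50.
#' @param seed integer RNG seed.
#' @return a `failure_grid` object.
#' @export
failure_grid <- function(K = 100L, M = 50L, seed = 1L) {
  K <- as.integer(K); M <- as.integer(M); seed <- as.integer(seed)
  if (K < 2L) stop("K must be >= 2")
  if (M < 1L) stop("M must be >= 1")
  structure(list(K = K, M = M, seed = seed), class = "failure_grid")
}

#' @export
print.failure_grid <- function(x, ...) {
  cat(sprintf("<failure_grid: K=%d rates (0..%g), M=%d replicates, seed=%d>\n",
              x$K, (x$K - 1) / x$K, x$M, x$seed))
  invisible(x)
}

#' Normalized Shannon entropy of component sizes
#'
#' `H = [-sum_i (c_i/N) ln(c_i/N)] / ln(N)` over component sizes `c_i`
#' (singletons included), with N the current node count. Defined as 0 for
#' networks with at most one node or exactly one component, and 1 when all
#' N >= 2 nodes are singletons.
#'
#' @param network a [ppi_network()].
#' @return entropy in \[0, 1\].
#' @export
component_entropy <- function(network) {
  cs <- component_sizes(network)
  entropy_from_sizes(cs)
}

entropy_from_sizes <- function(cs) {
  n <- sum(cs)
  if (n <= 1L || length(cs) <= 1L) return(0)
  p <- cs / n
  h <- -sum(p * log(p)) / log(n)
  min(max(h, 0), 1)
}

# integer-indexed view of a network for the Monte-Carlo kernel:
# list(n, edges0) with edges0 an E x 2 0-based integer matrix
network_index <- function(network) {
  e <- network$edges
  idx <- matrix(match(e, network$nodes), ncol = 2L)
  list(n = n_nodes(network), edges0 = idx - 1L, name = network$name)
}

# K x M entropy matrix for an indexed network under `grid`, seeded
mc_entropy_indexed <- function(ni, grid, seed) {
  if (ni$n < 1L) stop("cannot compute failure curve of empty network")
  with_seed(seed, mc_failure_entropy(ni$n, ni$edges0, grid$K, grid$M))
}

#' Monte-Carlo failure curve
#'
#' For each grid rate f_k, removes `floor(f_k * N)` nodes uniformly at
#' random and records the normalized component entropy of the remainder,
#' averaged over `grid$M` replicates. Implemented as checkpoints along M
#' random removal permutations (distributionally identical to independent
#' draws per rate). Deterministic given the grid seed and network name.
#'
#' @param network a [ppi_network()] with at least one node.
#' @param grid a [failure_grid()].
#' @return data frame with columns `f`, `mean_H`, `se_H`.
#' @export
failure_curve <- function(network, grid = failure_grid()) {
  stopifnot(inherits(network, "ppi_network"), inherits(grid, "failure_grid"))
  if (n_nodes(network) < 1L)
    stop("cannot compute failure curve of empty network")
  H <- mc_entropy_indexed(network_index(network), grid,
                          derive_seed(grid$seed, network$name))
  data.frame(
    f = (seq_len(grid$K) - 1L) / grid$K,
    mean_H = rowMeans(H),
    se_H = apply(H, 1L, stats::sd) / sqrt(grid$M)
  )
}

#' Network resilience score
#'
#' Resilience is one minus the mean normalized component-size entropy over
#' the failure grid: `R = 1 - (1/K) * sum_k mean_H(f_k)`. A network that
#' stays connected under any removal scores 1; one that is fully fragmented
#' at every rate scores 0.
#'
#' @param network a [ppi_network()] with at least one node.
#' @param grid a [failure_grid()].
#' @return a `resilience_score` object with elements `value`, `curve`
#'   (the [failure_curve()] data frame), `grid` and `network_name`.
#' @examples
#' net <- ppi_network(cbind(letters[1:3], letters[2:4]))
#' resilience_score(net, failure_grid(K = 10, M = 10, seed = 1))
#' @export
resilience_score <- function(network, grid = failure_grid()) {
  curve <- failure_curve(network, grid)
  structure(list(value = 1 - mean(curve$mean_H), curve = curve, grid = grid,
                 network_name = network$name),
            class = "resilience_score")
}

#' @export
print.resilience_score <- function(x, ...) {
  cat(sprintf("<resilience of '%s': %.4f (K=%d, M=%d, seed=%d)>\n",
              x$network_name, x$value, x$grid$K, x$grid$M, x$grid$seed))
  invisible(x)
}

# hot path used by ensembles and the pipeline: prune an indexed ancestor by
# a gene-id set and return the scalar resilience, without building
# intermediate ppi_network objects. `anc` = list(ids, ni) from ancestor_index().
ancestor_index <- function(network) {
  list(ids = network$nodes, ni = network_index(network))
}

prune_score_indexed <- function(anc, removed_ids, grid, seed) {
  n <- anc$ni$n
  rm_idx <- match(removed_ids, anc$ids)
  rm_idx <- rm_idx[!is.na(rm_idx)]
  keep <- rep(TRUE, n)
  keep[rm_idx] <- FALSE
  n2 <- n - length(rm_idx)
  if (n2 < 1L) return(NA_real_)
  e0 <- anc$ni$edges0
  ekeep <- keep[e0[, 1L] + 1L] & keep[e0[, 2L] + 1L]
  relab <- cumsum(keep) - 1L  # new 0-based index per old node
  e2 <- cbind(relab[e0[ekeep, 1L] + 1L], relab[e0[ekeep, 2L] + 1L])
  H <- with_seed(seed, mc_failure_entropy(n2, e2, grid$K, grid$M))
  1 - mean(rowMeans(H))
}

#' Resilience of evolved clone networks
#'
#' Prunes the ancestral network by each clone's disrupted-gene set and
#' scores the result on a common failure grid. Each clone's Monte-Carlo
#' draws use a seed derived from the grid seed and the clone's identity, so
#' results do not depend on evaluation order.
#'
#' @param ancestor ancestral [ppi_network()].
#' @param disruptions a [disruption_table()]; each clone's rows are its full
#'   disrupted-gene set at that generation.
#' @param grid a [failure_grid()].
#' @param clones optional roster data frame `(population, generation,
#'   clone)`; clones listed there but absent from the disruption table are
#'   scored with zero disruptions (i.e. the intact ancestor), anchoring
#'   early timepoints. See [clone_roster()].
#' @return data frame `(population, generation, clone, n_disrupted,
#'   resilience)` with one row per clone.
#' @export
evolved_resilience <- function(ancestor, disruptions, grid = failure_grid(),
                               clones = NULL) {
  anc <- ancestor_index(ancestor)
  dt <- data.table::as.data.table(as.data.frame(disruptions))
  population <- generation <- clone <- gene <- NULL
  sets <- dt[, list(genes = list(unique(gene))),
             by = list(population, generation, clone)]
  if (!is.null(clones)) {
    roster <- data.table::as.data.table(
      clones[, c("population", "generation", "clone")])
    extra <- roster[!sets, on = c("population", "generation", "clone")]
    if (nrow(extra)) {
      extra$genes <- replicate(nrow(extra), character(0), simplify = FALSE)
      sets <- rbind(sets, extra)
    }
  }
  sets <- sets[order(sets$population, sets$generation, sets$clone), ]
  res <- vapply(seq_len(nrow(sets)), function(i) {
    seed <- derive_seed(grid$seed, "evolved", sets$population[i],
                        sets$generation[i], sets$clone[i])
    prune_score_indexed(anc, sets$genes[[i]], grid, seed)
  }, numeric(1))
  data.frame(population = sets$population, generation = sets$generation,
             clone = sets$clone,
             n_disrupted = lengths(sets$genes),
             resilience = res, stringsAsFactors = FALSE)
}

#' Write resilience results as TSV
#' @param scores a `resilience_score` or a data frame of per-clone values.
#' @param path output file.
#' @param curve_path optional TSV for the per-rate entropy curve (only for a
#'   single `resilience_score`).
#' @return `path`, invisibly.
#' @export
write_resilience <- function(scores, path, curve_path = NULL) {
  if (inherits(scores, "resilience_score")) {
    df <- data.frame(network_name = scores$network_name,
                     resilience = scores$value, K = scores$grid$K,
                     M = scores$grid$M, seed = scores$grid$seed)
    if (!is.null(curve_path))
      data.table::fwrite(scores$curve, curve_path, sep = "\t")
  } else {
    df <- as.data.frame(scores)
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
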