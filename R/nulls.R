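#' Cross-population disruption weights
#'
#' For every disrupted gene, the number of distinct populations containing
#' at least one disruption of that gene (repeated disruptions within one
#' population count once). Genes never disrupted have weight 0 and are
#' ineligible for the weighted (scheme B) null.
#'
#' @param disruptions a [disruption_table()].
#' @return a `disruption_weights` object: named integer vector of weights
#'   over the disrupted genes.
#' @export
compute_population_weights <- function(disruptions) {
  df <- as.data.frame(disruptions)
  if (nrow(df) == 0L) stop("disruption table is empty")
  u <- unique(df[, c("gene", "population")])
  w <- table(u$gene)
  out <- as.integer(w)
  names(out) <- names(w)
  structure(out, class = "disruption_weights")
}

#' @export
print.disruption_weights <- function(x, ...) {
  cat(sprintf("<disruption_weights: %d eligible genes, max weight %d>\n",
              length(x), max(as.integer(x))))
  invisible(x)
}

#' Uniform (scheme A) null sample
#'
#' Samples `n` genes uniformly without replacement from ALL protein-coding
#' genes in the gene table -- essential genes included, which is what makes
#' this scheme permissive of biologically implausible networks.
#'
#' @param genes a [gene_table()].
#' @param n sample size.
#' @param seed integer seed; if `NULL`, uses the current RNG stream.
#' @return character vector of `n` distinct gene ids.
#' @export
sample_uniform_null <- function(genes, n, seed = NULL) {
  pool <- genes$gene
  if (n > length(pool))
    stop("cannot sample ", n, " genes from a universe of ", length(pool))
  if (n == 0L) return(character(0))
  draw <- function() sample(pool, n, replace = FALSE)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Frequency-weighted (scheme B) null sample
#'
#' Samples `n` genes without replacement from the genes disrupted in at
#' least one population, by sequential draws with per-draw probability
#' proportional to the cross-population disruption weight among the genes
#' still remaining (successive sampling).
#'
#' @param weights a [compute_population_weights()] result.
#' @param n sample size.
#' @param seed integer seed; if `NULL`, uses the current RNG stream.
#' @return character vector of `n` distinct gene ids.
#' @export
sample_weighted_null <- function(weights, n, seed = NULL) {
  w <- as.integer(weights)
  pool <- names(weights)[w > 0L]
  w <- w[as.integer(weights) > 0L]
  if (n > length(pool))
    stop("cannot sample ", n, " genes from ", length(pool), " eligible genes")
  if (n == 0L) return(character(0))
  draw <- function() sample(pool, n, replace = FALSE, prob = w)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Null ensemble of randomized-network resilience values
#'
#' For every evolved clone, draws `R` independent randomized disruption sets
#' of the same size as the clone's disrupted-gene set, prunes each from the
#' ancestral network and scores it on the same failure grid as the evolved
#' networks. Replicates are mutually independent; in particular, randomized
#' sets at later generations are NOT supersets of earlier ones (no
#' phylogenetic nesting).
#'
#' @param ancestor ancestral [ppi_network()].
#' @param genes a [gene_table()] (scheme A universe).
#' @param weights a [compute_population_weights()] result (scheme B pool);
#'   may be `NULL` for scheme A.
#' @param disruptions a [disruption_table()] defining the clones and their
#'   disruption counts.
#' @param scheme `"uniform_all"` (A) or `"weighted_disrupted"` (B).
#' @param R replicates per clone. Default 100.
#' @param grid a [failure_grid()]; the same grid must be used for the
#'   evolved networks.
#' @param seed global seed for the ensemble; per-replicate seeds are derived
#'   from (seed, population, generation, clone, scheme, replicate).
#' @param count `"all"` (default): a clone's n counts all its distinct
#'   disrupted genes, whether or not they are in the network;
#'   `"in_network"`: only genes present in the ancestor count.
#' @param clones optional roster of clones (see [evolved_resilience()]);
#'   clones without disruptions get n = 0 replicates (the intact ancestor).
#' @return data frame `(population, generation, clone, scheme, replicate,
#'   resilience)`.
#' @export
build_null_ensemble <- function(ancestor, genes, weights, disruptions,
                                scheme = c("uniform_all", "weighted_disrupted"),
                                R = 100L, grid = failure_grid(), seed = grid$seed,
                                count = c("all", "in_network"), clones = NULL) {
  scheme <- match.arg(scheme)
  count <- match.arg(count)
  if (scheme == "weighted_disrupted" && is.null(weights))
    stop("scheme 'weighted_disrupted' requires disruption weights")
  sizes <- clone_disruption_sizes(disruptions, ancestor, count, clones)
  anc <- ancestor_index(ancestor)
  nrep <- as.integer(R)
  if (nrep < 1L) stop("R must be >= 1")
  out <- vector("list", nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    n_i <- sizes$n_disrupted[i]
    vals <- numeric(nrep)
    for (r in seq_len(nrep)) {
      s <- derive_seed(seed, sizes$population[i], sizes$generation[i],
                       sizes$clone[i], scheme, r)
      vals[r] <- with_seed(s, {
        set <- if (scheme == "uniform_all")
          sample_uniform_null(genes, n_i)
        else
          sample_weighted_null(weights, n_i)
        # score draws continue on the same derived stream
        n <- anc$ni$n
        rm_idx <- match(set, anc$ids)
        rm_idx <- rm_idx[!is.na(rm_idx)]
        keep <- rep(TRUE, n)
        keep[rm_idx] <- FALSE
        n2 <- n - length(rm_idx)
        if (n2 < 1L) NA_real_ else {
          e0 <- anc$ni$edges0
          ekeep <- keep[e0[, 1L] + 1L] & keep[e0[, 2L] + 1L]
          relab <- cumsum(keep) - 1L
          e2 <- cbind(relab[e0[ekeep, 1L] + 1L], relab[e0[ekeep, 2L] + 1L])
          1 - mean(rowMeans(mc_failure_entropy(n2, e2, grid$K, grid$M)))
        }
      })
    }
    out[[i]] <- data.frame(
      population = sizes$population[i], generation = sizes$generation[i],
      clone = sizes$clone[i], scheme = scheme, replicate = seq_len(nrep),
      resilience = vals, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
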