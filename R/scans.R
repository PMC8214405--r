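#' Circular genomic distance between two genes
#'
#' Shortest distance along the circular chromosome between gene midpoints:
#' `d = min(|m_a - m_b|, L - |m_a - m_b|)`, so `0 <= d <= L/2`. Midpoints
#' are symmetric and strand-free anchors.
#'
#' @param gene_a,gene_b gene ids (vectorized, recycled).
#' @param genes a [gene_table()].
#' @return numeric distance(s) in bp.
#' @export
circular_distance <- function(gene_a, gene_b, genes) {
  L <- chrom_length(genes)
  ia <- match(gene_a, genes$gene)
  ib <- match(gene_b, genes$gene)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown gene(s): ",
         paste(unique(c(gene_a[is.na(ia)], gene_b[is.na(ib)])), collapse = ", "))
  dd <- abs(genes$midpoint[ia] - genes$midpoint[ib])
  pmin(dd, L - dd)
}

#' Single-gene disruption scan
#'
#' Simulates the disruption of every gene in the background network,
#' measuring `delta = R(G - g) - R(G)`. All scores (the background and every
#' single-removal network) use one common derived seed, a
#' common-random-numbers scheme that removes most Monte-Carlo noise from the
#' deltas. A positive delta means removing the gene INCREASES resilience.
#'
#' @param background a [ppi_network()] with at least 2 nodes.
#' @param grid a [failure_grid()].
#' @param genes optional [gene_table()]; when given, essentiality is joined
#'   in and the summary is split by it.
#' @return data frame `(background, gene, degree_in_background,
#'   delta_resilience[, essential])` with a `summary` attribute listing the
#'   fraction of genes with delta > 0 (overall and by essentiality) and the
#'   background resilience.
#' @export
single_gene_scan <- function(background, grid = failure_grid(), genes = NULL) {
  stopifnot(inherits(background, "ppi_network"))
  if (n_nodes(background) < 2L) stop("background network needs at least 2 nodes")
  anc <- ancestor_index(background)
  seed <- derive_seed(grid$seed, "scan", background$name)
  base <- prune_score_indexed(anc, character(0), grid, seed)
  deg <- node_degree(background)
  delta <- vapply(background$nodes, function(g)
    prune_score_indexed(anc, g, grid, seed) - base, numeric(1))
  out <- data.frame(background = background$name, gene = background$nodes,
                    degree_in_background = unname(deg[background$nodes]),
                    delta_resilience = unname(delta),
                    stringsAsFactors = FALSE)
  summ <- list(background_resilience = base,
               frac_delta_positive = mean(out$delta_resilience > 0))
  if (!is.null(genes)) {
    out$essential <- genes$essential[match(out$gene, genes$gene)]
    ess <- out$essential %in% TRUE
    summ$frac_delta_positive_essential <- mean(out$delta_resilience[ess] > 0)
    summ$frac_delta_positive_nonessential <-
      mean(out$delta_resilience[!ess] > 0)
  }
  attr(out, "summary") <- summ
  out
}

# split the final-generation disruptions of each clone into multi-gene
# deletion genes (deletion_block shared by >= 2 genes) vs single-gene
# disruptions; a gene hit by both classes appears once per class
final_generation_classes <- function(disruptions, generation = NULL) {
  df <- as.data.frame(disruptions)
  if (is.null(generation)) generation <- max(df$generation)
  df <- df[df$generation == generation, , drop = FALSE]
  if (nrow(df) == 0L) stop("no disruptions at generation ", generation)
  blk <- df$deletion_block
  blk_sizes <- tapply(df$gene, blk, function(g) length(unique(g)))
  multi_blocks <- names(blk_sizes)[blk_sizes >= 2L]
  is_multi <- !is.na(blk) & blk %in% multi_blocks
  list(multi = unique(df$gene[is_multi]),
       single = unique(df$gene[!is_multi]),
       generation = generation)
}

#' Degree comparison: multi-gene deletions vs single-gene disruptions
#'
#' Compares, in the ancestral network, the PPI degrees of genes knocked out
#' by multi-gene deletions against those disrupted by single-gene mutations
#' in the clones at the chosen generation (default the last). Genes absent
#' from the interactome count with degree 0; a gene hit by both classes is
#' counted once per class.
#'
#' @param ancestor ancestral [ppi_network()].
#' @param disruptions a [disruption_table()].
#' @param generation generation to analyse; default the maximum present.
#' @param alternative passed to [wilcoxon_rank_sum()] (x = multi-gene class).
#' @return a `ppi_test`; the per-gene table is attached as attribute
#'   `genes`.
#' @export
degree_by_mutation_class <- function(ancestor, disruptions, generation = NULL,
                                     alternative = "two_sided") {
  cls <- final_generation_classes(disruptions, generation)
  if (length(cls$multi) == 0L || length(cls$single) == 0L)
    stop("both mutation classes must be non-empty at generation ",
         cls$generation)
  deg_multi <- node_degree(ancestor, cls$multi)
  deg_single <- node_degree(ancestor, cls$single)
  out <- wilcoxon_rank_sum(as.numeric(deg_multi), as.numeric(deg_single),
                           alternative)
  out$test_name <- "degree_by_mutation_class"
  attr(out, "genes") <- data.frame(
    gene = c(names(deg_multi), names(deg_single)),
    class = rep(c("multi_gene_deletion", "single_gene_disruption"),
                c(length(deg_multi), length(deg_single))),
    degree = c(as.integer(deg_multi), as.integer(deg_single)),
    stringsAsFactors = FALSE)
  out
}

#' Genomic distances of interactions removed by each mutation class
#'
#' Every ancestral interaction with at least one disrupted endpoint (at the
#' chosen generation) is a "removed" interaction. Each removed interaction
#' is classified by the mutation class that removed it; if any disrupted
#' endpoint belongs to a multi-gene deletion block the interaction is
#' classified as multi-gene (deletion takes precedence; set
#' `deletion_precedence = FALSE` to classify by the first disrupted
#' endpoint's class instead). Endpoint-midpoint circular distances of the
#' two classes are compared by rank-sum.
#'
#' @param ancestor ancestral [ppi_network()].
#' @param disruptions a [disruption_table()].
#' @param genes a [gene_table()].
#' @param generation generation to analyse; default the maximum present.
#' @param alternative passed to [wilcoxon_rank_sum()] (x = multi-gene class).
#' @param deletion_precedence see above.
#' @return a `ppi_test`; the per-interaction distance table is attached as
#'   attribute `distances`, with class means in attribute `means`.
#' @export
removed_interaction_distances <- function(ancestor, disruptions, genes,
                                          generation = NULL,
                                          alternative = "two_sided",
                                          deletion_precedence = TRUE) {
  cls <- final_generation_classes(disruptions, generation)
  disrupted <- c(cls$multi, cls$single)
  e <- ancestor$edges
  hit1 <- e[, 1L] %in% disrupted
  hit2 <- e[, 2L] %in% disrupted
  removed <- hit1 | hit2
  if (!any(removed)) stop("no removed edges at generation ", cls$generation)
  e <- e[removed, , drop = FALSE]
  multi_hit <- (e[, 1L] %in% cls$multi) | (e[, 2L] %in% cls$multi)
  single_hit <- (e[, 1L] %in% cls$single) | (e[, 2L] %in% cls$single)
  class <- if (deletion_precedence) {
    ifelse(multi_hit, "multi_gene_deletion", "single_gene_disruption")
  } else {
    ifelse(single_hit, "single_gene_disruption", "multi_gene_deletion")
  }
  d <- circular_distance(e[, 1L], e[, 2L], genes)
  tab <- data.frame(gene_a = e[, 1L], gene_b = e[, 2L], class = class,
                    distance_bp = d, stringsAsFactors = FALSE)
  dm <- tab$distance_bp[tab$class == "multi_gene_deletion"]
  ds <- tab$distance_bp[tab$class == "single_gene_disruption"]
  if (length(dm) == 0L || length(ds) == 0L)
    stop("both interaction classes must be non-empty")
  out <- wilcoxon_rank_sum(dm, ds, alternative)
  out$test_name <- "removed_interaction_distances"
  attr(out, "distances") <- tab
  attr(out, "means") <- c(multi_gene_deletion = mean(dm),
                          single_gene_disruption = mean(ds))
  out
}

#' Essential-gene PPI enrichment
#'
#' One-sided rank-sum test that essential genes have more interactions than
#' nonessential genes (degrees in the given network over the whole gene
#' table; genes outside the interactome have degree 0).
#'
#' @param network a [ppi_network()].
#' @param genes a [gene_table()].
#' @return a `ppi_test`.
#' @export
essential_ppi_enrichment <- function(network, genes) {
  deg <- node_degree(network, genes$gene)
  ess <- genes$essential
  if (!any(ess) || all(ess)) stop("need both essential and nonessential genes")
  out <- wilcoxon_rank_sum(as.numeric(deg[ess]), as.numeric(deg[!ess]),
                           alternative = "greater")
  out$test_name <- "essential_ppi_enrichment"
  out
}

#' Disruption deficit in essential genes
#'
#' One-sided binomial test that essential genes harbour fewer disruptions
#' than expected from their share of protein-coding sequence: x = disruption
#' records hitting essential genes at the chosen generation, n = all
#' disruption records, p0 = essential bp / total coding bp.
#'
#' @param disruptions a [disruption_table()].
#' @param genes a [gene_table()].
#' @param generation generation to analyse; default the maximum present.
#' @return a `ppi_test` (alternative `"less"`).
#' @export
essential_disruption_deficit <- function(disruptions, genes,
                                         generation = NULL) {
  df <- as.data.frame(disruptions)
  if (is.null(generation)) generation <- max(df$generation)
  df <- df[df$generation == generation, , drop = FALSE]
  if (nrow(df) == 0L) stop("no disruptions at generation ", generation)
  ess <- genes$essential[match(df$gene, genes$gene)]
  p0 <- sum(genes$length[genes$essential]) / sum(genes$length)
  out <- binomial_tail(sum(ess), nrow(df), p0, alternative = "less")
  out$test_name <- "essential_disruption_deficit"
  out
}

#' Essentiality x parallel-evolution association
#'
#' Fisher's exact test (one-sided enrichment) for the overlap between the
#' essential genes and a supplied list of parallel-evolved genes.
#'
#' @param genes a [gene_table()].
#' @param parallel_genes character vector of gene ids under parallel
#'   evolution.
#' @return a `ppi_test`.
#' @export
essential_parallelism_test <- function(genes, parallel_genes) {
  ess <- genes$gene[genes$essential]
  par <- intersect(unique(parallel_genes), genes$gene)
  a <- length(intersect(ess, par))
  tab <- matrix(c(a, length(ess) - a,
                  length(par) - a,
                  nrow(genes) - length(ess) - (length(par) - a)),
                nrow = 2L)
  out <- fisher_exact_2x2(tab, alternative = "greater")
  out$test_name <- "essential_parallelism_test"
  out
}
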