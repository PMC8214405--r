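# In-code fixtures shared across test files.

path_graph <- function(ids = c("a", "b", "c", "d"), name = "path") {
  ppi_network(cbind(ids[-length(ids)], ids[-1L]), name = name)
}

star_graph <- function(n_leaves = 5L, name = "star") {
  ppi_network(cbind("hub", paste0("leaf", seq_len(n_leaves))), name = name)
}

complete_graph <- function(n = 5L, name = "complete") {
  ids <- sprintf("v%02d", seq_len(n))
  ppi_network(t(utils::combn(ids, 2L)), name = name)
}

edgeless_graph <- function(n = 8L, name = "edgeless") {
  ppi_network(matrix(character(0), ncol = 2L),
              nodes = sprintf("v%02d", seq_len(n)), name = name)
}

# Erdos-Renyi-ish random simple graph over n named nodes
random_graph <- function(n, p = 0.4, name = "rnd") {
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(pairs[keep, , drop = FALSE], nodes = ids, name = name)
}

# small gene table: k genes of length len laid head-to-tail on a circle
toy_gene_table <- function(k = 6L, len = 100L, L = k * len * 2L,
                           essential = rep(FALSE, k),
                           ids = sprintf("g%02d", seq_len(k))) {
  starts <- seq(1L, by = 2L * len, length.out = k)
  gene_table(data.frame(gene = ids, start = starts,
                        end = starts + len - 1L,
                        strand = rep(c("+", "-"), length.out = k),
                        essential = essential, stringsAsFactors = FALSE), L)
}

# reduced-scale config presets (see methods vignette for rationale)
test_config <- function(seed = 1L, ...) {
  simulation_config(n_genes = 400L, n_network_genes = 200L, seed = seed, ...)
}

# neutral calibration world: selection off, single-gene disruptions only
# (the paired test's null model assumes exchangeable independent
# disruptions; contiguous deletion blocks on the shared genome placement
# correlate populations and are a robustness question, not a calibration
# one -- see the methods vignette)
calibration_config <- function(seed) {
  simulation_config(n_genes = 120L, n_network_genes = 80L,
                    selection_gamma = 0, essential_protection = 0,
                    deletion_block_rate = 0,
                    timepoints = seq(0L, 25000L, 5000L), seed = seed)
}

calibration_pvalue <- function(seed, R = 8L, K = 5L, M = 5L,
                               config = calibration_config(seed)) {
  exp <- generate_experiment(config)
  roster <- clone_roster(exp)
  grid <- failure_grid(K, M, seed)
  ev <- evolved_resilience(exp$network, exp$disruptions, grid, roster)
  nu <- build_null_ensemble(exp$network, exp$genes, NULL, exp$disruptions,
                            scheme = "uniform_all", R = R, grid = grid,
                            clones = roster)
  paired_resilience_test(population_slopes(ev),
                         null_summary_slopes(nu))$p_value
}
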