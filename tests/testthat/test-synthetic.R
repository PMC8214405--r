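test_that("generate_network spans the degenerate and heavy-tailed regimes", {
  cfg0 <- simulation_config(n_genes = 40L, n_network_genes = 30L,
                            network_model = "erdos_renyi", er_p = 0, seed = 1)
  expect_equal(n_edges(generate_network(cfg0)), 0L)
  cfg1 <- simulation_config(n_genes = 20L, n_network_genes = 12L,
                            network_model = "erdos_renyi", er_p = 1, seed = 1)
  expect_equal(n_edges(generate_network(cfg1)), choose(12, 2))

  # duplication-divergence is heavier-tailed than a same-density ER graph:
  # the top-1% of nodes hold a larger share of the edges
  top_share <- function(net) {
    deg <- sort(node_degree(net), decreasing = TRUE)
    k <- max(1L, ceiling(length(deg) * 0.01))
    sum(deg[seq_len(k)]) / sum(deg)
  }
  shares <- vapply(1:5, function(s) {
    cfg_dd <- simulation_config(n_genes = 500L, n_network_genes = 500L,
                                seed = s)
    dd <- generate_network(cfg_dd)
    p_match <- n_edges(dd) / choose(500, 2)
    cfg_er <- simulation_config(n_genes = 500L, n_network_genes = 500L,
                                network_model = "erdos_renyi",
                                er_p = p_match, seed = s)
    er <- generate_network(cfg_er)
    top_share(dd) - top_share(er)
  }, numeric(1))
  expect_gt(mean(shares), 0)
  expect_gt(mean(shares > 0), 0.5)
})

test_that("generate_gene_table places genes legally and flags essentials by degree", {
  cfg <- simulation_config(n_genes = 150L, n_network_genes = 80L, seed = 7)
  net <- generate_network(cfg)
  gt <- generate_gene_table(cfg, net)
  expect_equal(nrow(gt), 150L)
  expect_true(all(gt$length > 0))
  expect_true(all(gt$start >= 1 & gt$end <= chrom_length(gt)))
  expect_lte(sum(gt$length), chrom_length(gt))
  # non-overlapping placement
  ord <- order(gt$start)
  expect_true(all(gt$start[ord][-1] > gt$end[ord][-nrow(gt)]))
  expect_equal(sum(gt$essential), round(cfg$essential_fraction * 150))

  # essential_fraction 0: no essential genes
  cfg0 <- simulation_config(n_genes = 50L, n_network_genes = 30L,
                            essential_fraction = 0, seed = 7)
  net0 <- generate_network(cfg0)
  expect_equal(sum(generate_gene_table(cfg0, net0)$essential), 0L)

  # enrichment factor 1: essentiality independent of degree (chi-square on
  # high/low degree split, pooled over sims)
  tab <- matrix(0, 2, 2)
  for (s in 1:6) {
    cfgi <- simulation_config(n_genes = 200L, n_network_genes = 150L,
                              essential_enrichment = 1,
                              essential_fraction = 0.25, seed = s)
    neti <- generate_network(cfgi)
    gti <- generate_gene_table(cfgi, neti)
    deg <- node_degree(neti, gti$gene)
    hi <- deg > stats::median(deg)
    tab <- tab + table(factor(hi, c(FALSE, TRUE)),
                       factor(gti$essential, c(FALSE, TRUE)))
  }
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("disruption histories honour rates, protection and lineage monotonicity", {
  base <- list(n_genes = 80L, n_network_genes = 50L,
               timepoints = seq(0L, 20000L, 5000L))

  # rate 0: empty table
  cfg0 <- do.call(simulation_config, c(base, list(
    populations = default_populations(base_rate = 0), clone_private_rate = 0,
    seed = 3)))
  exp0 <- generate_experiment(cfg0)
  expect_equal(nrow(exp0$disruptions), 0L)

  # essential_protection 1: no essential gene is ever disrupted
  cfg1 <- do.call(simulation_config, c(base, list(
    essential_protection = 1, essential_fraction = 0.3, seed = 5)))
  exp1 <- generate_experiment(cfg1)
  ess <- exp1$genes$gene[exp1$genes$essential]
  expect_equal(sum(exp1$disruptions$gene %in% ess), 0L)

  # lineage monotonicity: in every population the non-private disruption
  # core grows; clone sets at generation t contain the lineage set from the
  # previous timepoint (clone-private extras allowed on top)
  cfg2 <- do.call(simulation_config, c(base, list(seed = 11)))
  exp2 <- generate_experiment(cfg2)
  d <- as.data.frame(exp2$disruptions)
  for (pop in unique(d$population)) {
    dp <- d[d$population == pop, ]
    gens <- sort(unique(dp$generation))
    for (i in seq_along(gens)[-1]) {
      # the lineage core at a generation = intersection of its clones' sets
      core_prev <- Reduce(intersect,
                          split(dp$gene[dp$generation == gens[i - 1]],
                                dp$clone[dp$generation == gens[i - 1]]))
      for (cl_genes in split(dp$gene[dp$generation == gens[i]],
                             dp$clone[dp$generation == gens[i]])) {
        expect_true(all(core_prev %in% cl_genes))
      }
    }
  }
  # (population, generation, clone, gene) uniqueness is enforced on build
  expect_s3_class(exp2$disruptions, "disruption_table")
  # deletion blocks group contiguous genes and share a block id
  blk <- d[!is.na(d$deletion_block), ]
  if (nrow(blk) > 0) {
    one <- blk[blk$deletion_block == blk$deletion_block[1], ]
    expect_true(all(one$mutation_class == "large_deletion"))
  }
})

test_that("neutral histories sample disruption targets uniformly in degree", {
  # selection off: disrupted-gene degrees should match the gene-pool degree
  # distribution (rank-sum on pooled sims)
  set.seed(151)
  pvals <- vapply(1:4, function(s) {
    cfg <- simulation_config(n_genes = 100L, n_network_genes = 60L,
                             selection_gamma = 0, essential_protection = 0,
                             timepoints = seq(0L, 20000L, 5000L), seed = s * 17)
    exp <- generate_experiment(cfg)
    deg <- node_degree(exp$network, exp$genes$gene)
    hit <- unique(exp$disruptions$gene)
    wilcoxon_rank_sum(as.numeric(deg[hit]), as.numeric(deg))$p_value
  }, numeric(1))
  expect_gt(max(pvals), 0.05)      # not systematically extreme
  expect_gt(min(pvals), 1e-4)
})

test_that("selection_gamma steers disruptions away from hubs", {
  grab_degrees <- function(gamma, seed) {
    cfg <- simulation_config(n_genes = 100L, n_network_genes = 60L,
                             selection_gamma = gamma,
                             essential_protection = 0,
                             timepoints = seq(0L, 20000L, 5000L), seed = seed)
    exp <- generate_experiment(cfg)
    deg <- node_degree(exp$network, exp$genes$gene)
    mean(deg[unique(exp$disruptions$gene)])
  }
  neutral <- mean(vapply(1:4, function(s) grab_degrees(0, s), numeric(1)))
  selected <- mean(vapply(1:4, function(s) grab_degrees(3, s), numeric(1)))
  expect_lt(selected, neutral)
})

test_that("fitness trajectories follow the saturating power law", {
  cfg <- simulation_config(n_genes = 30L, n_network_genes = 20L,
                           fitness_b = 0.3, fitness_c = 0.001,
                           fitness_noise_sd = 0, seed = 2)
  fit <- simulate_fitness(cfg)
  expect_equal(unique(fit$fitness[fit$generation == 0]), 1)
  expect_equal(unique(fit$fitness[fit$generation == 50000]), 51^0.3)
  # b = 0: flat at 1
  cfg0 <- simulation_config(n_genes = 30L, n_network_genes = 20L,
                            fitness_b = 0, fitness_noise_sd = 0, seed = 2)
  expect_true(all(simulate_fitness(cfg0)$fitness == 1))
  # noise-free trajectories are monotone non-decreasing
  for (pop in unique(fit$population)) {
    tr <- fit$fitness[fit$population == pop][order(fit$generation[fit$population == pop])]
    expect_true(all(diff(tr) >= 0))
  }
})

test_that("generate_experiment writes a complete, re-readable TSV bundle quickly", {
  dir <- file.path(tempdir(), "synthexp")
  t0 <- Sys.time()
  cfg <- simulation_config(n_genes = 120L, n_network_genes = 80L,
                           timepoints = seq(0L, 20000L, 5000L), seed = 19)
  exp <- generate_experiment(cfg, dir = dir)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  expect_true(all(file.exists(file.path(dir, c(
    "edges.tsv", "genes.tsv", "disruptions.tsv", "fitness.tsv",
    "config.json")))))
  net <- read_edge_list(file.path(dir, "edges.tsv"), quiet = TRUE)
  expect_setequal(paste(net$edges[, 1], net$edges[, 2]),
                  paste(exp$network$edges[, 1], exp$network$edges[, 2]))
  gt <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(gt$gene, exp$genes$gene)
  dt <- read_disruptions(file.path(dir, "disruptions.tsv"), gt)
  expect_equal(nrow(dt), nrow(exp$disruptions))
  cfg_back <- read_simulation_config(file.path(dir, "config.json"))
  expect_equal(cfg_back$seed, cfg$seed)
  expect_equal(cfg_back$timepoints, cfg$timepoints)
  unlink(dir, recursive = TRUE)
})

test_that("stronger purifying selection widens the evolved-minus-null slope gap", {
  gap <- function(gamma, protection, seed) {
    cfg <- simulation_config(n_genes = 100L, n_network_genes = 60L,
                             selection_gamma = gamma,
                             essential_protection = protection,
                             timepoints = seq(0L, 25000L, 5000L), seed = seed)
    exp <- generate_experiment(cfg)
    roster <- clone_roster(exp)
    grid <- failure_grid(5L, 5L, seed)
    ev <- evolved_resilience(exp$network, exp$disruptions, grid, roster)
    nu <- build_null_ensemble(exp$network, exp$genes, NULL, exp$disruptions,
                              scheme = "uniform_all", R = 6L, grid = grid,
                              clones = roster)
    t <- paired_resilience_test(population_slopes(ev),
                                null_summary_slopes(nu))
    mean(attr(t, "differences"))
  }
  neutral <- mean(vapply(1:3, function(s) gap(0, 0, s * 7), numeric(1)))
  strong <- mean(vapply(1:3, function(s) gap(2, 0.9, s * 7), numeric(1)))
  expect_gt(strong, neutral)
})
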