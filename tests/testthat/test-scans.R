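test_that("circular_distance uses midpoints and the shorter arc", {
  gt <- gene_table(data.frame(gene = c("a", "b", "c"),
                              start = c(5, 85, 45), end = c(15, 95, 55),
                              strand = "+", essential = FALSE), 100)
  # midpoints 10, 90, 50
  expect_equal(circular_distance("a", "b", gt), 20)  # wraps the short way
  expect_equal(circular_distance("a", "a", gt), 0)
  expect_equal(circular_distance("a", "c", gt), 40)
  expect_error(circular_distance("a", "zz", gt), "zz")
  # symmetry and the L/2 bound on random gene pairs
  gt2 <- toy_gene_table(10L)
  set.seed(141)
  for (i in 1:20) {
    pair <- sample(gt2$gene, 2L)
    d1 <- circular_distance(pair[1], pair[2], gt2)
    expect_equal(d1, circular_distance(pair[2], pair[1], gt2))
    expect_lte(d1, chrom_length(gt2) / 2)
    expect_gte(d1, 0)
  }
})

test_that("single_gene_scan: complete graphs are inert, hubs are load-bearing", {
  grid <- failure_grid(5L, 40L, seed = 31L)
  k5 <- complete_graph(5L)
  scan_k5 <- single_gene_scan(k5, grid)
  expect_true(all(scan_k5$delta_resilience == 0))  # K5 -> K4, resilience 1

  star <- star_graph(5L)
  scan_star <- single_gene_scan(star, grid)
  d_hub <- scan_star$delta_resilience[scan_star$gene == "hub"]
  d_leaf <- scan_star$delta_resilience[scan_star$gene == "leaf1"]
  expect_lt(d_hub, 0)          # center removal shatters the star
  expect_lt(d_hub, d_leaf)     # and is worse than any leaf removal
  expect_lt(abs(d_leaf), 0.2)  # leaf removal leaves K_{1,4}

  # exact check of the hub delta via subset enumeration at N <= 7
  exact_base <- oracle_resilience(star, K = 5L)
  hubless <- prune_network(star, "hub")
  exact_hub <- oracle_resilience(hubless, K = 5L) - exact_base
  expect_lt(abs(d_hub - exact_hub), 0.15)
})

test_that("single_gene_scan deltas for an edgeless background are >= 0 and runs are reproducible", {
  grid <- failure_grid(4L, 10L, seed = 33L)
  el <- edgeless_graph(6L)
  scan_el <- single_gene_scan(el, grid)
  expect_true(all(scan_el$delta_resilience >= 0))
  # seed determinism
  expect_identical(single_gene_scan(el, grid)$delta_resilience,
                   scan_el$delta_resilience)
  # essentiality split in the summary
  gt <- toy_gene_table(6L, ids = el$nodes,
                       essential = c(TRUE, TRUE, rep(FALSE, 4)))
  summ <- attr(single_gene_scan(el, grid, gt), "summary")
  expect_true(all(c("frac_delta_positive", "frac_delta_positive_essential",
                    "frac_delta_positive_nonessential") %in% names(summ)))
})

test_that("degree_by_mutation_class splits classes by deletion blocks", {
  # star: hub degree 5, leaves degree 1. Multi-gene deletion takes two
  # leaves; single-gene mutations hit hub and another leaf.
  star <- star_graph(5L)
  ids <- c("hub", paste0("leaf", 1:5), "off1", "off2")
  gt <- toy_gene_table(8L, ids = ids)
  df <- data.frame(
    population = "p1", generation = 50000L, clone = "c1",
    gene = c("leaf1", "leaf2", "hub", "leaf3"),
    mutation_class = c("large_deletion", "large_deletion",
                       "nonsense_snp", "mob_insertion"),
    deletion_block = c("blk1", "blk1", NA, NA), stringsAsFactors = FALSE)
  dt <- disruption_table(df, gt)
  res <- degree_by_mutation_class(star, dt)
  tab <- attr(res, "genes")
  expect_setequal(tab$gene[tab$class == "multi_gene_deletion"],
                  c("leaf1", "leaf2"))
  expect_setequal(tab$gene[tab$class == "single_gene_disruption"],
                  c("hub", "leaf3"))
  # degrees {1,1} vs {5,1}: exact rank-sum branch
  expect_equal(res$method, "exact")

  # degree samples {5,5} vs {1,1} give one-sided p = 1/6 (rank-split
  # enumeration oracle); exercised through the same test the scan calls
  expect_equal(wilcoxon_rank_sum(c(5, 5), c(1, 1), "greater")$p_value, 1 / 6)
  expect_equal(oracle_rank_sum(c(5, 5), c(1, 1), "greater"), 1 / 6)

  # one-gene "blocks" are single-gene disruptions; with no block of >= 2
  # genes the multi class is empty and the comparison refuses to run
  df3 <- df
  df3$deletion_block <- c("blk1", "blk2", NA, NA)
  expect_error(degree_by_mutation_class(star, disruption_table(df3, gt)),
               "non-empty")

  # a gene hit by both classes is counted once per class
  df4 <- rbind(df, data.frame(population = "p1", generation = 50000L,
                              clone = "c2", gene = "leaf1",
                              mutation_class = "nonsense_snp",
                              deletion_block = NA, stringsAsFactors = FALSE))
  tab4 <- attr(degree_by_mutation_class(star, disruption_table(df4, gt)),
               "genes")
  expect_equal(sum(tab4$gene == "leaf1"), 2L)
})

test_that("degree_by_mutation_class errors when a class is empty", {
  star <- star_graph(3L)
  gt <- toy_gene_table(4L, ids = c("hub", paste0("leaf", 1:3)))
  df <- data.frame(population = "p1", generation = 1000L, clone = "c1",
                   gene = "leaf1", mutation_class = "nonsense_snp",
                   deletion_block = NA, stringsAsFactors = FALSE)
  expect_error(degree_by_mutation_class(star, disruption_table(df, gt)),
               "non-empty")
})

test_that("removed_interaction_distances classifies and measures removed edges", {
  # triangle a-b-c plus pendant c-d; genes spaced 1 kb apart on L = 10 kb
  ids <- c("a", "b", "c", "d")
  net <- ppi_network(cbind(c("a", "b", "c", "c"), c("b", "c", "a", "d")),
                     name = "toy")
  gt <- gene_table(data.frame(gene = ids, start = c(1, 1001, 2001, 3001),
                              end = c(100, 1100, 2100, 3100), strand = "+",
                              essential = FALSE), 10000)
  df <- data.frame(population = "p1", generation = 50000L, clone = "c1",
                   gene = c("a", "b", "d"),
                   mutation_class = c("large_deletion", "large_deletion",
                                      "small_indel"),
                   deletion_block = c("blk1", "blk1", NA),
                   stringsAsFactors = FALSE)
  dt <- disruption_table(df, gt)
  res <- removed_interaction_distances(net, dt, gt)
  tab <- attr(res, "distances")
  expect_equal(nrow(tab), 4L)  # all four edges touch a disrupted gene
  # deletion precedence: a-b, b-c, a-c are multi; c-d single
  expect_equal(sum(tab$class == "multi_gene_deletion"), 3L)
  expect_equal(tab$distance_bp[tab$class == "single_gene_disruption"], 1000)
  means <- attr(res, "means")
  expect_equal(unname(means["multi_gene_deletion"]),
               mean(c(1000, 1000, 2000)))

  # disruptions that remove no edges -> dedicated error
  df2 <- transform(df[3, ], deletion_block = NA_character_)
  net2 <- ppi_network(cbind("a", "b"))
  df2$gene <- "c"
  expect_error(removed_interaction_distances(net2, disruption_table(df2, gt), gt),
               "no removed edges")
})

test_that("essentiality diagnostics recover planted structure", {
  # essential genes given high degree on purpose
  star <- star_graph(8L)
  ids <- c("hub", paste0("leaf", 1:8), paste0("off", 1:3))
  gt <- toy_gene_table(12L, ids = ids,
                       essential = c(TRUE, rep(FALSE, 11)))
  enr <- essential_ppi_enrichment(star, gt)
  expect_equal(enr$alternative, "greater")
  expect_lt(enr$p_value, 0.3)  # hub is the single essential gene

  # disruption deficit: no essential gene hit among many records
  df <- data.frame(population = "p1", generation = 50000L, clone = "c1",
                   gene = paste0("leaf", 1:8), mutation_class = "nonsense_snp",
                   stringsAsFactors = FALSE)
  deficit <- essential_disruption_deficit(disruption_table(df, gt), gt)
  expect_equal(deficit$statistic, 0)
  expect_lt(deficit$p_value, 1)

  # parallelism: essential gene in the parallel list
  par_test <- essential_parallelism_test(gt, c("hub", "leaf1"))
  expect_equal(par_test$alternative, "greater")
  expect_equal(par_test$statistic, 1)
})
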