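#' Default 12-population design
#'
#' Twelve populations named like the arabinose marker populations of the
#' long-term evolution experiment. Six populations carry an elevated
#' point-mutation rate (`mutator_multiplier` > 1); rates are disruptions
#' per 5,000 generations per lineage and are order-of-magnitude
#' placeholders scaled to the synthetic gene universe, not estimates from
#' any real experiment.
#'
#' @param base_rate disruptions per 5,000 generations in a non-mutator.
#' @param mutator_multiplier rate multiplier for mutator populations.
#' @return data frame `(population, rate_per_5k, mutator_multiplier)`.
#' @export
default_populations <- function(base_rate = 1.5, mutator_multiplier = 4) {
  pops <- c(paste0("Ara+", 1:6), paste0("Ara-", 1:6))
  mutators <- c("Ara-1", "Ara-2", "Ara-3", "Ara-4", "Ara+3", "Ara+6")
  data.frame(population = pops, rate_per_5k = base_rate,
             mutator_multiplier = ifelse(pops %in% mutators,
                                         mutator_multiplier, 1),
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic evolution experiment
#'
#' The stated world: a scale-free-like interactome embedded in a larger
#' protein-coding gene universe on a circular chromosome; 12 independent
#' populations, each a single lineage accumulating gene disruptions over 11
#' timepoints to generation 50,000, sampled by 2 clones per timepoint;
#' heterogeneous rates (mutators, one transposon-burst population); a
#' purifying-selection knob (degree-biased sampling of disruption targets
#' plus rejection of essential-gene disruptions); and saturating fitness
#' trajectories `w(t) = (1 + c t)^b`.
#'
#' @param n_genes total protein-coding genes (>= `n_network_genes`).
#' @param n_network_genes genes encoding interactome proteins.
#' @param chrom_length circular chromosome length L in bp; default
#'   `1250 * n_genes` (about 80% coding density at ~1 kb genes).
#' @param network_model `"duplication_divergence"` (default),
#'   `"preferential_attachment"` or `"erdos_renyi"`.
#' @param dd_retain probability a duplicated node keeps each parent edge.
#' @param dd_attach probability the duplicate attaches to its parent.
#' @param er_p edge probability for the Erdos-Renyi model.
#' @param essential_fraction fraction of genes flagged essential; default
#'   541/4112, the essential share of a 4,112-gene bacterial genome.
#' @param essential_enrichment per-unit-degree odds factor biasing
#'   essentiality toward high-degree proteins; 1 = independent of degree.
#' @param populations data frame as from [default_populations()].
#' @param transposon_burst_population population with an elevated
#'   mobile-element insertion rate (`NULL` to disable).
#' @param burst_multiplier extra mob-insertion rate multiplier for the
#'   burst population.
#' @param selection_gamma degree-bias exponent >= 0: disruption candidates
#'   are drawn with probability proportional to `(degree + 1)^(-gamma)`.
#'   0 = neutral.
#' @param essential_protection probability a candidate essential-gene
#'   disruption is rejected (purifying selection). 0 = none.
#' @param deletion_block_rate probability a disruption event is a
#'   contiguous multi-gene deletion.
#' @param block_size_mean mean genes per deletion block (>= 2).
#' @param timepoints sampled generations; default 0 to 50,000 by 5,000.
#' @param clones_per_timepoint clones sampled per population per timepoint.
#' @param clone_private_rate clone-private disruption rate as a fraction of
#'   the lineage rate.
#' @param fitness_b,fitness_c parameters of `w(t) = (1 + c t)^b`.
#' @param fitness_noise_sd sd of multiplicative log-normal noise on fitness.
#' @param seed global seed; all randomness derives from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 400L, n_network_genes = 200L,
                              chrom_length = NULL,
                              network_model = c("duplication_divergence",
                                                "preferential_attachment",
                                                "erdos_renyi"),
                              dd_retain = 0.4, dd_attach = 0.7, er_p = 0.02,
                              essential_fraction = 541 / 4112,
                              essential_enrichment = 1.3,
                              populations = default_populations(),
                              transposon_burst_population = "Ara+1",
                              burst_multiplier = 3,
                              selection_gamma = 1,
                              essential_protection = 0.5,
                              deletion_block_rate = 0.15,
                              block_size_mean = 3,
                              timepoints = seq(0L, 50000L, by = 5000L),
                              clones_per_timepoint = 2L,
                              clone_private_rate = 0.1,
                              fitness_b = 0.3, fitness_c = 0.001,
                              fitness_noise_sd = 0.02,
                              seed = 1L) {
  network_model <- match.arg(network_model)
  if (n_genes < n_network_genes) stop("n_genes must be >= n_network_genes")
  if (is.null(chrom_length)) chrom_length <- 1250 * n_genes
  stopifnot(essential_fraction >= 0, essential_fraction <= 1,
            selection_gamma >= 0, essential_protection >= 0,
            essential_protection <= 1, all(populations$rate_per_5k >= 0),
            fitness_b >= 0, fitness_c >= 0, block_size_mean >= 2)
  cfg <- list(n_genes = as.integer(n_genes),
              n_network_genes = as.integer(n_network_genes),
              chrom_length = chrom_length, network_model = network_model,
              dd_retain = dd_retain, dd_attach = dd_attach, er_p = er_p,
              essential_fraction = essential_fraction,
              essential_enrichment = essential_enrichment,
              populations = populations,
              transposon_burst_population = transposon_burst_population,
              burst_multiplier = burst_multiplier,
              selection_gamma = selection_gamma,
              essential_protection = essential_protection,
              deletion_block_rate = deletion_block_rate,
              block_size_mean = block_size_mean,
              timepoints = sort(unique(as.integer(timepoints))),
              clones_per_timepoint = as.integer(clones_per_timepoint),
              clone_private_rate = clone_private_rate,
              fitness_b = fitness_b, fitness_c = fitness_c,
              fitness_noise_sd = fitness_noise_sd, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Read / write a simulation config as JSON
#' @param path file path.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$populations)) raw$populations <- as.data.frame(raw$populations)
  do.call(simulation_config, raw)
}

#' @rdname read_simulation_config
#' @param config a [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic interactome
#'
#' Default model is duplication-divergence: starting from a connected seed
#' pair, each new protein duplicates a random existing protein, retains
#' each of its interactions with probability `dd_retain`, and attaches to
#' its parent with probability `dd_attach`; duplicates that would end up
#' isolated are linked to their parent (interactome node sets contain only
#' interacting proteins). This produces the heavy-tailed degree
#' distributions typical of real interactomes.
#'
#' @param config a [simulation_config()].
#' @param seed seed; defaults to one derived from the config seed.
#' @return a [ppi_network()] over gene ids `g0001...`; name `"ancestor"`.
#' @export
generate_network <- function(config, seed = derive_seed(config$seed, "network")) {
  n <- config$n_network_genes
  if (n < 2L) stop("need at least 2 network genes")
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  edges <- with_seed(seed, {
    switch(config$network_model,
      erdos_renyi = {
        g <- igraph::sample_gnp(n, config$er_p)
        igraph::as_edgelist(g, names = FALSE)
      },
      preferential_attachment = {
        g <- igraph::sample_pa(n, power = 1, m = 2, directed = FALSE)
        igraph::as_edgelist(g, names = FALSE)
      },
      duplication_divergence = {
        adj <- vector("list", n)
        adj[[1L]] <- 2L; adj[[2L]] <- 1L
        for (v in 3:n) {
          parent <- sample.int(v - 1L, 1L)
          nb <- adj[[parent]]
          kept <- nb[stats::runif(length(nb)) < config$dd_retain]
          if (stats::runif(1) < config$dd_attach) kept <- c(kept, parent)
          if (length(kept) == 0L) kept <- parent
          adj[[v]] <- kept
          for (u in kept) adj[[u]] <- c(adj[[u]], v)
        }
        from <- rep.int(seq_len(n), lengths(adj))
        to <- unlist(adj)
        keep <- from < to
        cbind(from[keep], to[keep])
      })
  })
  if (nrow(edges) == 0L)
    return(ppi_network(matrix(character(0), ncol = 2), name = "ancestor"))
  ppi_network(cbind(ids[edges[, 1L]], ids[edges[, 2L]]), name = "ancestor")
}

#' Generate a synthetic gene table
#'
#' Places all `n_genes` genes on the circular chromosome in a random order
#' (so genomic position is independent of network topology), with
#' gamma-distributed lengths around ~950 bp and uniform intergenic gaps.
#' Essential flags are drawn without replacement with weights
#' `essential_enrichment^degree`, emulating the enrichment of essential
#' genes for protein-protein interactions.
#'
#' @param config a [simulation_config()].
#' @param network the ancestral [ppi_network()] (for degrees).
#' @param seed seed; defaults to one derived from the config seed.
#' @return a [gene_table()].
#' @export
generate_gene_table <- function(config, network,
                                seed = derive_seed(config$seed, "genes")) {
  n <- config$n_genes
  L <- config$chrom_length
  ids <- sprintf("g%04d", seq_len(n))
  with_seed(seed, {
    len <- pmax(150L, round(stats::rgamma(n, shape = 6, scale = 950 / 6)))
    if (sum(len) > L)
      stop("total gene span ", sum(len), " exceeds chromosome length ", L)
    slack <- L - sum(len)
    gaps <- as.vector(stats::rmultinom(1L, size = slack, prob = rep(1, n)))
    ord <- sample.int(n)           # random genomic order of gene ids
    starts <- integer(n); ends <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + len[ord[i]] - 1L    # no wrap by construction
      pos <- ends[i] + gaps[i] + 1L
    }
    df <- data.frame(gene = ids[ord], start = starts, end = ends,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     essential = FALSE, stringsAsFactors = FALSE)
    n_ess <- round(config$essential_fraction * n)
    if (n_ess > 0L) {
      deg <- node_degree(network, df$gene)
      w <- config$essential_enrichment^pmin(deg, 20L)
      ess_genes <- sample(df$gene, n_ess, prob = w)
      df$essential <- df$gene %in% ess_genes
    }
    gene_table(df, L)
  })
}

# one disruption event under the selection knobs; returns a character vector
# of genes (length > 1 for a deletion block) or NULL if rejected/exhausted.
# `state` is an environment holding: available (logical by gene index),
# block_counter. Consumes the current RNG stream.
draw_disruption_event <- function(config, genes, deg, genome_order, state,
                                  population, force_class = NULL) {
  avail <- which(state$available)
  if (length(avail) == 0L) return(NULL)
  w <- (deg[avail] + 1)^(-config$selection_gamma)
  g <- avail[sample.int(length(avail), 1L, prob = w)]
  if (!is.null(force_class)) {
    # transposon-burst events are single-gene mobile-element insertions
    if (genes$essential[g] &&
        stats::runif(1) < config$essential_protection) return(NULL)
    return(list(genes = g, class = force_class, block = NA_character_))
  }
  if (stats::runif(1) < config$deletion_block_rate) {
    size <- 2L + stats::rpois(1L, config$block_size_mean - 2)
    pos <- match(g, genome_order)
    run <- genome_order[((pos - 1L + seq_len(size) - 1L) %%
                           length(genome_order)) + 1L]
    block <- run[state$available[run]]
    ess <- genes$essential[block]
    if (any(stats::runif(length(block)) < config$essential_protection & ess))
      return(NULL)
    state$block_counter <- state$block_counter + 1L
    list(genes = block, class = "large_deletion",
         block = sprintf("%s_del%03d", population, state$block_counter))
  } else {
    if (genes$essential[g] &&
        stats::runif(1) < config$essential_protection) return(NULL)
    cls <- sample(c("nonsense_snp", "small_indel", "mob_insertion"), 1L,
                  prob = c(0.45, 0.35, 0.2))
    list(genes = g, class = cls, block = NA_character_)
  }
}

#' Simulate disruption histories for all populations
#'
#' Each population is a single lineage: between consecutive timepoints the
#' number of new disruption events is Poisson with the population's rate
#' (times its mutator multiplier; the transposon-burst population gets
#' additional mobile-element insertion events at `(burst_multiplier - 1)`
#' times its base rate). Candidate genes are drawn among not-yet-disrupted
#' genes with probability proportional to `(degree + 1)^(-selection_gamma)`;
#' candidate disruptions of essential genes are rejected with probability
#' `essential_protection` (the event is lost, emulating purifying
#' selection). With probability `deletion_block_rate` an event deletes a
#' contiguous block of genes (class `large_deletion`, shared block id). Each
#' clone at a timepoint carries the lineage's disruptions plus independent
#' clone-private ones.
#'
#' @param config a [simulation_config()].
#' @param network ancestral [ppi_network()].
#' @param genes a [gene_table()].
#' @param seed seed; defaults to one derived from the config seed.
#' @return a [disruption_table()]; each clone's rows are its complete
#'   disrupted-gene set at its generation (lineage sets are nested over
#'   generations).
#' @export
simulate_disruption_history <- function(config, network, genes,
                                        seed = derive_seed(config$seed,
                                                           "history")) {
  deg <- as.numeric(node_degree(network, genes$gene))
  genome_order <- order(genes$start)      # gene indices in genomic order
  rows <- list()
  for (p in seq_len(nrow(config$populations))) {
    pop <- config$populations$population[p]
    rate <- config$populations$rate_per_5k[p] *
      config$populations$mutator_multiplier[p]
    burst <- !is.null(config$transposon_burst_population) &&
      identical(pop, config$transposon_burst_population)
    burst_rate <- if (burst)
      config$populations$rate_per_5k[p] * (config$burst_multiplier - 1) else 0
    rows[[pop]] <- with_seed(derive_seed(seed, pop), {
      state <- new.env(parent = emptyenv())
      state$available <- rep(TRUE, nrow(genes))
      state$block_counter <- 0L
      lineage <- data.frame(gene = character(0), mutation_class = character(0),
                            deletion_block = character(0),
                            stringsAsFactors = FALSE)
      pop_rows <- list()
      tps <- config$timepoints
      for (ti in seq_along(tps)) {
        if (ti > 1L) {
          dt_gen <- (tps[ti] - tps[ti - 1L]) / 5000
          n_ev <- stats::rpois(1L, rate * dt_gen)
          n_burst <- if (burst_rate > 0) stats::rpois(1L, burst_rate * dt_gen)
                     else 0L
          for (ev in seq_len(n_ev + n_burst)) {
            hit <- draw_disruption_event(
              config, genes, deg, genome_order, state, pop,
              force_class = if (ev > n_ev) "mob_insertion" else NULL)
            if (is.null(hit)) next
            state$available[hit$genes] <- FALSE
            lineage <- rbind(lineage, data.frame(
              gene = genes$gene[hit$genes], mutation_class = hit$class,
              deletion_block = hit$block, stringsAsFactors = FALSE))
          }
        }
        for (cl in seq_len(config$clones_per_timepoint)) {
          clone_id <- sprintf("%s_t%d_c%d", pop, tps[ti], cl)
          private <- data.frame(gene = character(0),
                                mutation_class = character(0),
                                deletion_block = character(0),
                                stringsAsFactors = FALSE)
          if (ti > 1L && config$clone_private_rate > 0) {
            n_priv <- stats::rpois(1L, rate * config$clone_private_rate)
            # private disruptions do not enter the lineage
            snapshot <- state$available
            for (ev in seq_len(n_priv)) {
              hit <- draw_disruption_event(config, genes, deg, genome_order,
                                           state, pop)
              if (is.null(hit)) next
              state$available[hit$genes] <- FALSE
              private <- rbind(private, data.frame(
                gene = genes$gene[hit$genes], mutation_class = hit$class,
                deletion_block = hit$block, stringsAsFactors = FALSE))
            }
            state$available <- snapshot
          }
          both <- rbind(lineage, private)
          if (nrow(both) > 0L)
            pop_rows[[clone_id]] <- data.frame(
              population = pop, generation = tps[ti], clone = clone_id,
              gene = both$gene, mutation_class = both$mutation_class,
              deletion_block = both$deletion_block, stringsAsFactors = FALSE)
        }
      }
      if (length(pop_rows)) do.call(rbind, pop_rows) else NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) {
    do.call(rbind, c(rows, make.row.names = FALSE))
  } else {
    data.frame(population = character(0), generation = integer(0),
               clone = character(0), gene = character(0),
               mutation_class = character(0),
               deletion_block = character(0), stringsAsFactors = FALSE)
  }
  disruption_table(df, genes)
}

#' Simulate saturating mean-fitness trajectories
#'
#' `w(population, t) = (1 + c t)^b` with multiplicative log-normal noise of
#' sd `fitness_noise_sd` (set it to 0 for the noise-free curve, which is 1
#' at t = 0 and monotone non-decreasing).
#'
#' @param config a [simulation_config()].
#' @param seed seed; defaults to one derived from the config seed.
#' @return data frame `(population, generation, fitness)`.
#' @export
simulate_fitness <- function(config, seed = derive_seed(config$seed,
                                                        "fitness")) {
  grid <- expand.grid(population = config$populations$population,
                      generation = config$timepoints,
                      stringsAsFactors = FALSE)
  base <- (1 + config$fitness_c * grid$generation)^config$fitness_b
  noise <- if (config$fitness_noise_sd > 0) {
    with_seed(seed, exp(stats::rnorm(nrow(grid), 0, config$fitness_noise_sd)))
  } else rep(1, nrow(grid))
  data.frame(grid, fitness = base * noise, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic experiment
#'
#' Composes [generate_network()], [generate_gene_table()],
#' [simulate_disruption_history()] and [simulate_fitness()] from one config
#' seed, and optionally writes the four TSV inputs consumed by the pipeline.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, writes `edges.tsv`,
#'   `genes.tsv`, `disruptions.tsv`, `fitness.tsv` and `config.json`.
#' @return a `simulated_experiment` list: `network`, `genes`,
#'   `disruptions`, `fitness`, `config`.
#' @export
generate_experiment <- function(config, dir = NULL) {
  network <- generate_network(config)
  genes <- generate_gene_table(config, network)
  disruptions <- simulate_disruption_history(config, network, genes)
  fitness <- simulate_fitness(config)
  exp <- structure(list(network = network, genes = genes,
                        disruptions = disruptions, fitness = fitness,
                        config = config),
                   class = "simulated_experiment")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_list(network, file.path(dir, "edges.tsv"))
    write_gene_table(genes, file.path(dir, "genes.tsv"))
    write_disruptions(disruptions, file.path(dir, "disruptions.tsv"))
    data.table::fwrite(fitness, file.path(dir, "fitness.tsv"), sep = "\t")
    write_simulation_config(config, file.path(dir, "config.json"))
  }
  exp
}

#' Full clone roster of a simulated experiment
#'
#' All (population, generation, clone) combinations the design samples,
#' including clones that happen to carry zero disruptions (which the
#' record-style disruption table cannot list). Pass this to
#' [evolved_resilience()] and [build_null_ensemble()] so early timepoints
#' anchor the slopes.
#'
#' @param x a `simulated_experiment` or a [simulation_config()].
#' @return data frame `(population, generation, clone)`.
#' @export
clone_roster <- function(x) {
  config <- if (inherits(x, "simulated_experiment")) x$config else x
  stopifnot(inherits(config, "simulation_config"))
  g <- expand.grid(population = config$populations$population,
                   generation = config$timepoints,
                   k = seq_len(config$clones_per_timepoint),
                   stringsAsFactors = FALSE)
  data.frame(population = g$population, generation = g$generation,
             clone = sprintf("%s_t%d_c%d", g$population, g$generation, g$k),
             stringsAsFactors = FALSE)
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(paste0("<simulated_experiment: %d-node interactome, %d genes, ",
                     "%d populations, %d disruption records>\n"),
              n_nodes(x$network), nrow(x$genes),
              nrow(x$config$populations), nrow(x$disruptions)))
  invisible(x)
}
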