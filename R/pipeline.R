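#' Run the full resilience analysis
#'
#' Wires the modules into the complete analysis graph: evolved per-clone
#' resilience; uniform and frequency-weighted null ensembles on the same
#' failure grid; per-population slopes; the paired exact signed-rank
#' comparison for each scheme; the fitness-resilience correlation; degree
#' and genomic-distance diagnostics for multi-gene deletions; essentiality
#' tests; optionally the single-gene disruption scan. All tables are
#' written as TSV under `outdir` together with a JSON run manifest.
#'
#' @param network ancestral [ppi_network()].
#' @param genes a [gene_table()].
#' @param disruptions a [disruption_table()].
#' @param fitness optional data frame `(population, generation, fitness)`.
#' @param outdir output directory (created); `NULL` to skip writing.
#' @param grid the single [failure_grid()] used for every network in the
#'   run.
#' @param R null-ensemble replicates per clone per scheme.
#' @param schemes which null schemes to run.
#' @param alternative alternative for the paired tests (default
#'   `"greater"`: evolved networks lose resilience more slowly).
#' @param parallel_genes optional character vector of parallel-evolved
#'   genes for the essentiality x parallelism test.
#' @param scan run the single-gene disruption scan of the ancestor
#'   (quadratic in network size; off by default).
#' @param count how clone disruption counts size the randomized networks;
#'   see [build_null_ensemble()].
#' @param clones optional clone roster (see [clone_roster()]); clones
#'   listed there without disruption records anchor the series at the
#'   ancestor's resilience.
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with elements `evolved`, `nulls`, `slopes`,
#'   `tests`, `correlation`, `scan`, `manifest`.
#' @export
run_full_analysis <- function(network, genes, disruptions, fitness = NULL,
                              outdir = NULL, grid = failure_grid(),
                              R = 100L,
                              schemes = c("uniform_all", "weighted_disrupted"),
                              alternative = "greater", parallel_genes = NULL,
                              scan = FALSE, count = "all", clones = NULL,
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  say("resilience: scoring evolved clone networks (K=%d, M=%d, seed=%d)",
      grid$K, grid$M, grid$seed)
  evolved <- stage("evolved_resilience",
                   evolved_resilience(network, disruptions, grid, clones))
  n_absent <- length(setdiff(unique(disruptions$gene), network$nodes))
  say("resilience: %d clones scored; %d disrupted genes outside interactome",
      nrow(evolved), n_absent)

  weights <- if ("weighted_disrupted" %in% schemes)
    stage("weights", compute_population_weights(disruptions)) else NULL
  nulls <- list()
  for (sc in schemes) {
    say("nulls: scheme %s, R=%d replicates per clone", sc, R)
    nulls[[sc]] <- stage(paste0("null_", sc),
      build_null_ensemble(network, genes, weights, disruptions, scheme = sc,
                          R = R, grid = grid, count = count, clones = clones))
  }

  say("evostats: slopes and paired tests")
  ev_slopes <- stage("slopes", population_slopes(evolved))
  slope_tabs <- list(ev_slopes)
  tests <- list()
  for (sc in names(nulls)) {
    nu_slopes <- stage(paste0("null_slopes_", sc),
                       null_summary_slopes(nulls[[sc]]))
    slope_tabs[[length(slope_tabs) + 1L]] <- nu_slopes
    tt <- stage(paste0("paired_test_", sc),
                paired_resilience_test(ev_slopes, nu_slopes, alternative))
    tt$test_name <- paste0("paired_resilience_", sc)
    tests[[tt$test_name]] <- tt
  }
  slopes <- do.call(rbind, slope_tabs)

  correlation <- NULL
  if (!is.null(fitness)) {
    correlation <- stage("fitness_correlation",
                         fitness_resilience_correlation(evolved, fitness))
    tests[["fitness_resilience_correlation"]] <- correlation
  }

  tests[["degree_by_mutation_class"]] <- tryCatch(
    degree_by_mutation_class(network, disruptions),
    error = function(e) {
      say("scans: degree comparison skipped (%s)", conditionMessage(e)); NULL
    })
  tests[["removed_interaction_distances"]] <- tryCatch(
    removed_interaction_distances(network, disruptions, genes),
    error = function(e) {
      say("scans: distance comparison skipped (%s)", conditionMessage(e)); NULL
    })
  tests[["essential_ppi_enrichment"]] <- stage(
    "essential_ppi_enrichment", essential_ppi_enrichment(network, genes))
  tests[["essential_disruption_deficit"]] <- stage(
    "essential_disruption_deficit",
    essential_disruption_deficit(disruptions, genes))
  if (!is.null(parallel_genes))
    tests[["essential_parallelism_test"]] <- stage(
      "essential_parallelism_test",
      essential_parallelism_test(genes, parallel_genes))
  tests <- tests[!vapply(tests, is.null, logical(1))]

  scan_tab <- NULL
  if (isTRUE(scan)) {
    say("scans: single-gene disruption scan over %d genes", n_nodes(network))
    scan_tab <- stage("single_gene_scan",
                      single_gene_scan(network, grid, genes))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ppiresilience")),
    grid = list(K = grid$K, M = grid$M, seed = grid$seed),
    R = R, schemes = as.list(schemes), alternative = alternative,
    count = count,
    n_clones = nrow(evolved), n_genes = nrow(genes),
    n_network_nodes = n_nodes(network), n_network_edges = n_edges(network),
    n_disruption_records = nrow(disruptions),
    n_disrupted_genes_outside_network = n_absent,
    slope_estimator = "ols_all_clone_points",
    null_summary = "mean_of_replicate_slopes",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- list(evolved = evolved, nulls = nulls, slopes = slopes,
                 tests = tests, correlation = correlation, scan = scan_tab,
                 manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(evolved, file.path(outdir, "evolved_resilience.tsv"),
                       sep = "\t")
    for (sc in names(nulls))
      data.table::fwrite(nulls[[sc]],
                         file.path(outdir, paste0("nulls_", sc, ".tsv")),
                         sep = "\t")
    data.table::fwrite(slopes, file.path(outdir, "slopes.tsv"), sep = "\t")
    data.table::fwrite(tests_as_table(tests),
                       file.path(outdir, "tests.tsv"), sep = "\t")
    if (!is.null(scan_tab))
      data.table::fwrite(scan_tab, file.path(outdir, "single_gene_scan.tsv"),
                         sep = "\t")
    manifest$outputs <- list.files(outdir)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

tests_as_table <- function(tests) {
  do.call(rbind, lapply(tests, function(t) data.frame(
    test_name = t$test_name,
    statistic = t$statistic, p_value = t$p_value,
    alternative = t$alternative, n = paste(t$n, collapse = "x"),
    method = if (is.null(t$method)) NA_character_ else t$method,
    stringsAsFactors = FALSE)))
}

cli_usage <- "usage: ppiresilience <subcommand> [options]

subcommands:
  simulate    generate a synthetic experiment's TSV inputs
  resilience  score evolved clone networks
  nulls       build a randomized null ensemble
  analyze     run the full analysis pipeline
  scan        single-gene disruption scan of the ancestor
  report      print the test table of a finished run

common options:
  --edges PATH --genes PATH --disruptions PATH [--fitness PATH]
  --out DIR      output directory (default 'ppires_out')
  --K INT        failure-grid steps (default 100)
  --M INT        Monte-Carlo replicates (default 50)
  --R INT        null replicates per clone (default 100)
  --seed INT     global seed (default 1)
  --scheme S     uniform_all | weighted_disrupted | both (default both)
  --alternative A  greater | less | two_sided (default greater)
  --no-header    edge list file has no header line
  --config PATH  simulation config JSON (simulate)
"

cli_opts <- function(args) {
  opts <- list(); flags <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a %in% c("--no-header", "--scan")) {
      flags <- c(flags, sub("^--", "", a)); i <- i + 1L
    } else if (grepl("^--", a)) {
      if (i == length(args)) stop("missing value for ", a)
      opts[[sub("^--", "", a)]] <- args[[i + 1L]]
      i <- i + 2L
    } else stop("unexpected argument: ", a)
  }
  list(opts = opts, flags = flags)
}

#' Command-line entry point
#'
#' Subcommand-style CLI over the pipeline. Returns an exit code instead of
#' calling `quit()` so it is testable in-process; the installed
#' `exec/ppiresilience` script forwards the code to the shell. Exit codes:
#' 0 success, 2 validation error, 3 computation error.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return integer exit code, invisibly.
#' @export
ppi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[[1L]] %in% c("-h", "--help", "help")) {
    cat(cli_usage)
    return(invisible(0L))
  }
  sub <- args[[1L]]
  parsed <- tryCatch(cli_opts(args[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("error: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  o <- parsed$opts; flags <- parsed$flags
  num <- function(name, default) as.integer(o[[name]] %||% default)
  out <- o$out %||% "ppires_out"
  run <- function(expr) {
    tryCatch({ expr; invisible(0L) },
      validation_error = function(e) {
        message("validation error: ", conditionMessage(e)); invisible(2L)
      },
      error = function(e) {
        message("error: ", conditionMessage(e))
        invisible(if (grepl("read|column|missing|unknown|absent|duplicate",
                           conditionMessage(e))) 2L else 3L)
      })
  }
  load_inputs <- function() {
    for (need in c("edges", "genes", "disruptions"))
      if (is.null(o[[need]]))
        stop("--", need, " is required", call. = FALSE)
    net <- read_edge_list(o$edges, header = !("no-header" %in% flags))
    genes <- read_gene_table(o$genes)
    disr <- read_disruptions(o$disruptions, genes)
    fit <- if (!is.null(o$fitness))
      as.data.frame(data.table::fread(o$fitness, sep = "\t")) else NULL
    list(net = net, genes = genes, disr = disr, fit = fit)
  }
  grid <- failure_grid(K = num("K", 100L), M = num("M", 50L),
                       seed = num("seed", 1L))
  schemes <- switch(o$scheme %||% "both",
                    both = c("uniform_all", "weighted_disrupted"),
                    o$scheme)
  switch(sub,
    simulate = run({
      cfg <- if (!is.null(o$config)) read_simulation_config(o$config)
             else simulation_config(seed = num("seed", 1L))
      generate_experiment(cfg, dir = out)
      message("simulate: wrote synthetic experiment to ", out)
    }),
    resilience = run({
      x <- load_inputs()
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      ev <- evolved_resilience(x$net, x$disr, grid)
      write_resilience(ev, file.path(out, "evolved_resilience.tsv"))
      message("resilience: scored ", nrow(ev), " clones")
    }),
    nulls = run({
      x <- load_inputs()
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      w <- if (any(schemes == "weighted_disrupted"))
        compute_population_weights(x$disr) else NULL
      for (sc in schemes) {
        en <- build_null_ensemble(x$net, x$genes, w, x$disr, scheme = sc,
                                  R = num("R", 100L), grid = grid)
        data.table::fwrite(en, file.path(out, paste0("nulls_", sc, ".tsv")),
                           sep = "\t")
      }
      message("nulls: wrote ensembles for ", paste(schemes, collapse = ", "))
    }),
    analyze = run({
      x <- load_inputs()
      run_full_analysis(x$net, x$genes, x$disr, fitness = x$fit,
                        outdir = out, grid = grid, R = num("R", 100L),
                        schemes = schemes,
                        alternative = o$alternative %||% "greater",
                        scan = "scan" %in% flags)
      message("analyze: results in ", out)
    }),
    scan = run({
      x <- load_inputs()
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      tab <- single_gene_scan(x$net, grid, x$genes)
      data.table::fwrite(tab, file.path(out, "single_gene_scan.tsv"),
                         sep = "\t")
      message("scan: wrote ", nrow(tab), " records")
    }),
    report = run({
      path <- file.path(out, "tests.tsv")
      if (!file.exists(path)) stop("no tests.tsv under ", out, call. = FALSE)
      cat(paste(readLines(path), collapse = "\n"), "\n")
    }),
    {
      message("unknown subcommand: ", sub)
      cat(cli_usage)
      return(invisible(2L))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
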