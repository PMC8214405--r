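#' Gene table on a circular chromosome
#'
#' Validates and annotates a per-gene table with 1-based inclusive
#' coordinates on a circular chromosome of length `chrom_length`.
#' Wrap-around genes (end < start) are allowed; lengths and midpoints are
#' wrap-aware.
#'
#' @param df data frame with columns `gene`, `start`, `end`, `strand`
#'   (`+`/`-`) and logical `essential`.
#' @param chrom_length chromosome length L in bp.
#' @return a `gene_table` (data.frame subclass) with a computed `length`
#'   column and `midpoint` column; L stored in attribute `chrom_length`.
#' @export
gene_table <- function(df, chrom_length) {
  need <- c("gene", "start", "end", "strand", "essential")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  L <- as.numeric(chrom_length)
  if (!isTRUE(L >= 1)) stop("chrom_length must be a positive number")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene))
    stop("duplicate gene id(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  if (any(df$start < 1 | df$start > L | df$end < 1 | df$end > L))
    stop("gene coordinates outside [1, ", L, "]")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df$essential <- as.logical(df$essential)
  wrap <- df$end < df$start
  df$length <- ifelse(wrap, L - df$start + 1 + df$end, df$end - df$start + 1)
  # midpoint measured along the gene from its start, modulo L
  df$midpoint <- ((df$start - 1 + (df$length - 1) / 2) %% L) + 1
  structure(df, chrom_length = L, class = c("gene_table", "data.frame"))
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("<gene_table: %d genes (%d essential) on circular chromosome of %s bp>\n",
              nrow(x), sum(x$essential), format(attr(x, "chrom_length"),
                                                big.mark = ",")))
  NextMethod()
}

#' Chromosome length of a gene table
#' @param genes a [gene_table()].
#' @return length L in bp.
#' @export
chrom_length <- function(genes) attr(genes, "chrom_length")

#' Read a gene table from TSV
#'
#' Columns: `gene`, `start`, `end`, `strand`, `essential` (an optional
#' `length` column is ignored and recomputed). The chromosome length may be
#' given as an argument or embedded in a first comment line of the form
#' `# chrom_length=4629812`; files written by [write_gene_table()] carry it.
#'
#' @param path file path.
#' @param chrom_length chromosome length; if `NULL`, taken from the comment
#'   line, else from `max(end)` with a warning.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, chrom_length = NULL) {
  if (!file.exists(path)) stop("cannot read gene table: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(chrom_length) && grepl("^#\\s*chrom_length=", first))
    chrom_length <- as.numeric(sub("^#\\s*chrom_length=", "", first))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (is.null(chrom_length)) {
    chrom_length <- max(dt$end)
    warning("chrom_length not supplied; using max(end) = ", chrom_length)
  }
  gene_table(as.data.frame(dt), chrom_length)
}

#' Write a gene table as TSV (with chrom_length comment line)
#' @param genes a [gene_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  writeLines(sprintf("# chrom_length=%s",
                     format(chrom_length(genes), scientific = FALSE)), path)
  data.table::fwrite(
    genes[, c("gene", "start", "end", "strand", "essential", "length")],
    path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

MUTATION_CLASSES <- c("nonsense_snp", "small_indel", "mob_insertion",
                      "large_deletion")

#' Disruption table
#'
#' Per-clone records of disrupted genes. A clone's row set is its complete
#' set of disrupted genes at that generation (lineages accumulate
#' monotonically, so a clone repeats its ancestors' disruptions).
#'
#' @param df data frame with columns `population`, `generation`, `clone`,
#'   `gene`, `mutation_class` and optionally `deletion_block` (NA for
#'   non-deletion records; a shared block id groups genes lost in one
#'   multi-gene deletion).
#' @param genes a [gene_table()]; every disrupted gene must appear in it.
#' @return a `disruption_table` (data.frame subclass).
#' @export
disruption_table <- function(df, genes) {
  need <- c("population", "generation", "clone", "gene", "mutation_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("disruption table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"deletion_block" %in% names(df)) df$deletion_block <- NA_character_
  df$gene <- as.character(df$gene)
  df$generation <- as.integer(df$generation)
  if (any(df$generation < 0)) stop("generations must be >= 0")
  bad_class <- setdiff(unique(df$mutation_class), MUTATION_CLASSES)
  if (length(bad_class))
    stop("unknown mutation_class: ", paste(bad_class, collapse = ", "))
  unknown <- setdiff(unique(df$gene), genes$gene)
  if (length(unknown))
    stop("disrupted gene(s) absent from gene table: ",
         paste(unknown, collapse = ", "))
  key <- paste(df$population, df$generation, df$clone, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (population, generation, clone, gene) record(s)")
  structure(df, class = c("disruption_table", "data.frame"))
}

#' @export
print.disruption_table <- function(x, ...) {
  cat(sprintf("<disruption_table: %d records, %d populations, %d genes>\n",
              nrow(x), length(unique(x$population)),
              length(unique(x$gene))))
  NextMethod()
}

#' Read a disruption table from TSV
#' @param path file path.
#' @param genes a [gene_table()] used for validation.
#' @return a [disruption_table()].
#' @export
read_disruptions <- function(path, genes) {
  if (!file.exists(path)) stop("cannot read disruption table: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"))
  disruption_table(as.data.frame(dt), genes)
}

#' Write a disruption table as TSV
#' @param disruptions a [disruption_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_disruptions <- function(disruptions, path) {
  data.table::fwrite(as.data.frame(disruptions), path, sep = "\t")
  invisible(path)
}

# distinct disrupted genes per clone, the n that sizes randomized networks.
# `clones` is an optional roster data frame (population, generation, clone)
# adding clones with zero disruptions, which a record-style table cannot
# carry on its own.
clone_disruption_sizes <- function(disruptions, network = NULL,
                                   count = c("all", "in_network"),
                                   clones = NULL) {
  count <- match.arg(count)
  dt <- data.table::as.data.table(as.data.frame(disruptions))
  roster <- unique(dt[, c("population", "generation", "clone")])
  if (!is.null(clones)) {
    roster <- unique(rbind(roster,
                           data.table::as.data.table(
                             clones[, c("population", "generation", "clone")])))
  }
  if (count == "in_network") {
    stopifnot(!is.null(network))
    dt <- dt[dt$gene %in% network$nodes, ]
  }
  population <- generation <- clone <- gene <- NULL
  counts <- dt[, list(n_disrupted = data.table::uniqueN(gene)),
               by = list(population, generation, clone)]
  out <- merge(roster, counts,
               by = c("population", "generation", "clone"), all.x = TRUE)
  out$n_disrupted[is.na(out$n_disrupted)] <- 0L
  as.data.frame(out[order(out$population, out$generation, out$clone), ])
}
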