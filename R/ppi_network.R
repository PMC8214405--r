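#' @useDynLib ppiresilience, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

#' Construct a protein-protein interaction network
#'
#' An undirected simple graph over gene identifiers. Self-loops are dropped
#' and duplicate edges (in either orientation) are collapsed. By default the
#' node set is the union of edge endpoints, matching published interactomes
#' which list only interacting proteins; an explicit `nodes` vector may add
#' isolated nodes (as produced by [prune_network()], where neighbours of a
#' removed protein may survive as singletons).
#'
#' @param edges two-column character matrix or data frame of gene id pairs;
#'   may have zero rows.
#' @param nodes optional character vector of node ids; must contain every
#'   edge endpoint.
#' @param name label for the network (e.g. a clone id).
#' @return An object of class `ppi_network` with elements `nodes`, `edges`
#'   (E x 2 character matrix, canonical order within rows) and `name`.
#' @examples
#' net <- ppi_network(cbind(c("a", "b"), c("b", "c")))
#' n_nodes(net)
#' @export
ppi_network <- function(edges, nodes = NULL, name = "network") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) < 2L)
    stop("`edges` must have two columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  # canonical orientation, then dedupe
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(a[!dup], b[!dup])
  endpoint_nodes <- unique(c(edges))
  if (is.null(nodes)) {
    nodes <- sort(endpoint_nodes)
  } else {
    nodes <- unique(as.character(nodes))
    if (!all(endpoint_nodes %in% nodes))
      stop("every edge endpoint must appear in `nodes`")
  }
  structure(list(nodes = nodes, edges = edges, name = as.character(name)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network '%s': %d nodes, %d edges>\n",
              x$name, n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts
#' @param network a [ppi_network()].
#' @return integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Degree of genes in a network
#'
#' Number of incident edges; genes absent from the network have degree 0.
#'
#' @param network a [ppi_network()].
#' @param genes character vector of gene ids; default all network nodes.
#' @return named integer vector of degrees.
#' @export
node_degree <- function(network, genes = network$nodes) {
  idx <- match(c(network$edges), network$nodes)
  deg <- tabulate(idx, nbins = length(network$nodes))
  out <- integer(length(genes))
  hit <- match(genes, network$nodes)
  out[!is.na(hit)] <- deg[hit[!is.na(hit)]]
  names(out) <- genes
  out
}

#' Prune a network by a set of disrupted genes
#'
#' Removes the disrupted proteins and all their interactions from the
#' ancestral network, emulating loss-of-function mutations. Neighbours that
#' lose all interactions remain in the node set as singleton components.
#' Disrupted genes absent from the network are tolerated (disruption tables
#' routinely include genes outside the interactome); their count is attached
#' as attribute `n_absent`.
#'
#' @param ancestor a [ppi_network()]; not modified.
#' @param disrupted character vector of gene ids to remove (may be empty).
#' @param name label for the pruned network; default `ancestor$name`.
#' @return a new `ppi_network`.
#' @export
prune_network <- function(ancestor, disrupted, name = ancestor$name) {
  stopifnot(inherits(ancestor, "ppi_network"))
  disrupted <- unique(as.character(disrupted))
  in_net <- disrupted %in% ancestor$nodes
  keep_nodes <- setdiff(ancestor$nodes, disrupted)
  e <- ancestor$edges
  ekeep <- !(e[, 1L] %in% disrupted) & !(e[, 2L] %in% disrupted)
  out <- ppi_network(e[ekeep, , drop = FALSE], nodes = keep_nodes, name = name)
  attr(out, "n_absent") <- sum(!in_net)
  out
}

#' Read an undirected edge list from a TSV file
#'
#' Expects at least two tab-separated gene-identifier columns. Self-loops
#' are dropped and duplicate/reversed-duplicate edges collapsed; the counts
#' of dropped rows are attached as attributes `n_self_loops` and
#' `n_duplicates` and reported via `message()`.
#'
#' @param path file path.
#' @param header logical; whether the first line is a header (default TRUE).
#'   Header presence is an explicit flag, never guessed from content.
#' @param name network label; defaults to the file name.
#' @param quiet suppress the log message.
#' @return a [ppi_network()].
#' @export
read_edge_list <- function(path, header = TRUE,
                           name = basename(path), quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  dt <- data.table::fread(path, sep = "\t", header = header,
                          colClasses = "character")
  if (ncol(dt) < 2L)
    stop("edge list must have at least 2 columns, found ", ncol(dt))
  ga <- dt[[1L]]; gb <- dt[[2L]]
  n_self <- sum(ga == gb)
  canon <- paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
  n_dup <- sum(duplicated(canon[ga != gb]))
  net <- ppi_network(cbind(ga, gb), name = name)
  attr(net, "n_self_loops") <- n_self
  attr(net, "n_duplicates") <- n_dup
  if (!quiet && (n_self > 0L || n_dup > 0L))
    message(sprintf("read_edge_list: dropped %d self-loop(s), %d duplicate edge(s)",
                    n_self, n_dup))
  net
}

#' Write a network's edge list as TSV
#' @param network a [ppi_network()].
#' @param path output file.
#' @param header write a `gene_a\tgene_b` header line (default TRUE).
#' @return `path`, invisibly. Note isolated nodes are not representable in
#'   an edge list and are omitted.
#' @export
write_edge_list <- function(network, path, header = TRUE) {
  dt <- data.table::data.table(gene_a = network$edges[, 1L],
                               gene_b = network$edges[, 2L])
  data.table::fwrite(dt, path, sep = "\t", col.names = header)
  invisible(path)
}

# igraph view of a ppi_network, retaining isolated nodes
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    data.frame(from = network$edges[, 1L], to = network$edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = network$nodes)
}

#' Connected component sizes
#' @param network a [ppi_network()].
#' @return integer vector of component sizes (singletons included).
#' @export
component_sizes <- function(network) {
  if (n_nodes(network) == 0L) return(integer(0))
  as.integer(igraph::components(as_igraph(network))$csize)
}
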