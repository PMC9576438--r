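#' Construct a gene network
#'
#' A `gene_network` is an undirected, simple graph over opaque gene
#' identifiers. Self-loops are dropped, duplicate and reversed-duplicate
#' edges are collapsed, and the node order is fixed to the byte-wise
#' lexicographic sort of the identifiers so that every matrix and vector
#' derived from the network aligns deterministically.
#'
#' @param edges two-column character matrix or data frame of edge endpoints
#'   (may be empty).
#' @param nodes optional character vector of node identifiers; defaults to
#'   the identifiers appearing in `edges`. Extra identifiers become isolated
#'   nodes.
#' @return An object of class `gene_network` with elements `nodes` (sorted
#'   character vector) and `edges` (two-column character matrix, each row
#'   ordered so the first endpoint precedes the second in node order, rows
#'   sorted).
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop_rwrdr("'edges' must have exactly two columns")
  }
  storage.mode(edges) <- "character"
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  nodes <- lex_sort(unique(c(nodes, as.vector(edges))))
  if (nrow(edges) > 0L) {
    i <- match(edges[, 1L], nodes)
    j <- match(edges[, 2L], nodes)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    dup <- duplicated(cbind(lo, hi))
    lo <- lo[!dup]
    hi <- hi[!dup]
    ord <- order(lo, hi)
    edges <- cbind(nodes[lo[ord]], nodes[hi[ord]])
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Read an edge list
#'
#' Reads a network from a two-column tab-separated edge list (lines starting
#' with `#` are comments) or from a SIF file (`node relation node`,
#' whitespace-separated, middle token ignored). Self-loops and duplicate
#' edges are dropped; the number of dropped rows is reported via `message()`.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @return A [gene_network].
#' @export
load_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_rwrdr("edge-list file not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) stop_rwrdr("empty edge-list file: ", path)
  split_char <- if (dialect == "tsv") "\t" else "[ \t]+"
  fields <- strsplit(trimws(lines[data_idx]), split_char)
  want <- if (dialect == "tsv") 2L else 3L
  bad <- which(lengths(fields) != want)
  if (length(bad) > 0L) {
    stop_rwrdr(sprintf(
      "malformed edge-list row at line %d of %s: expected %d fields, got %d",
      data_idx[bad[1L]], path, want, lengths(fields)[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  edges <- if (dialect == "tsv") m else m[, c(1L, 3L), drop = FALSE]
  net <- gene_network(edges)
  dropped <- nrow(edges) - nrow(net$edges)
  if (dropped > 0L) {
    message(sprintf("load_edge_list: dropped %d self-loop/duplicate row(s)",
                    dropped))
  }
  net
}

#' Write an edge list
#'
#' Writes a [gene_network] as a two-column tab-separated edge list with a
#' `#from\tto` comment header, the dialect [load_edge_list] reads back.
#'
#' @param net a [gene_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  lines <- c("#from\tto",
             if (nrow(net$edges) > 0L)
               paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component of the
#' network. If several components tie for the largest size, the one
#' containing the lexicographically smallest node identifier wins.
#'
#' @param net a [gene_network].
#' @return A [gene_network] restricted to the winning component.
#' @export
largest_component <- function(net) {
  if (n_nodes(net) == 0L) stop_rwrdr("network is empty")
  comp <- igraph::components(as_igraph(net))
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # nodes are already in lexicographic order: the first node belonging to
    # any tied component identifies the winner
    first_member <- vapply(best, function(cid) {
      min(which(comp$membership == cid))
    }, integer(1L))
    best <- best[which.min(first_member)]
  }
  keep <- net$nodes[comp$membership == best]
  induced_network(net, keep)
}

# induced subgraph on a set of node identifiers (kept nodes stay even if
# they end up isolated)
induced_network <- function(net, keep) {
  keep <- intersect(net$nodes, keep)
  e <- net$edges
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  gene_network(e, nodes = keep)
}

#' Binary adjacency matrix
#'
#' @param net a [gene_network].
#' @param sparse return a sparse `Matrix` (default) or a dense base matrix.
#'   Both representations carry identical values and node-name dimnames.
#' @return An n-by-n symmetric 0/1 matrix with zero diagonal, rows and
#'   columns aligned to the network node order.
#' @export
adjacency_matrix <- function(net, sparse = TRUE) {
  n <- n_nodes(net)
  if (nrow(net$edges) == 0L) {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  } else {
    i <- match(net$edges[, 1L], net$nodes)
    j <- match(net$edges[, 2L], net$nodes)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
  }
  dimnames(A) <- list(net$nodes, net$nodes)
  if (sparse) A else as.matrix(A)
}

#' Column-stochastic transition matrix
#'
#' Divides each column of the binary adjacency matrix by the degree of the
#' corresponding node, so that every column sums to one and the matrix
#' drives the random walk as a left-multiplication on column vectors.
#'
#' @inheritParams adjacency_matrix
#' @return An n-by-n non-negative matrix whose columns each sum to 1.
#' @export
transition_matrix <- function(net, sparse = TRUE) {
  A <- adjacency_matrix(net, sparse = TRUE)
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    stop_rwrdr("network has isolated node(s); ",
               "take the largest connected component first ",
               "(see largest_component())")
  }
  P <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(P) <- dimnames(A)
  if (sparse) P else as.matrix(P)
}

#' Extract the subnetwork bridging two gene sets
#'
#' Returns the induced subgraph on every node that lies on at least one
#' shortest path of length at most `max_path_len` between a member of
#' `set_a` and a member of `set_b`. This is the local disease--drug gene
#' neighborhood used to inspect how a drug's targets reach a disease's
#' genes on the interactome.
#'
#' @param net a [gene_network].
#' @param set_a,set_b character vectors of gene identifiers; silently
#'   intersected with the network nodes.
#' @param max_path_len maximum shortest-path length (edge count), >= 1.
#' @return A [gene_network]; empty (with a warning) when no member of
#'   `set_a` reaches a member of `set_b` within `max_path_len` hops.
#' @export
bridge_subnetwork <- function(net, set_a, set_b, max_path_len) {
  stopifnot(max_path_len >= 1)
  a <- intersect(lex_sort(unique(set_a)), net$nodes)
  b <- intersect(lex_sort(unique(set_b)), net$nodes)
  if (length(a) == 0L && length(b) == 0L) {
    stop_rwrdr("neither gene set intersects the network")
  }
  if (length(a) == 0L || length(b) == 0L) {
    warning("one gene set has no node on the network; empty bridge subnetwork")
    return(gene_network(matrix(character(), ncol = 2L)))
  }
  g <- as_igraph(net)
  dA <- igraph::distances(g, v = a)      # |a| x n
  dB <- igraph::distances(g, v = b)      # |b| x n
  keep <- logical(n_nodes(net))
  for (ia in seq_along(a)) {
    for (ib in seq_along(b)) {
      dab <- dA[ia, b[ib]]
      if (is.finite(dab) && dab <= max_path_len) {
        # v lies on a shortest a-b path iff d(a,v) + d(v,b) == d(a,b)
        keep <- keep | (dA[ia, ] + dB[ib, ] == dab)
      }
    }
  }
  if (!any(keep)) {
    warning(sprintf(
      "no path of length <= %d between the two gene sets; empty subnetwork",
      max_path_len))
    return(gene_network(matrix(character(), ncol = 2L)))
  }
  induced_network(net, net$nodes[keep])
}
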