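#' Construct a gene network
#'
#' An undirected simple graph over gene symbols: no self-loops, no
#' duplicate edges, isolated nodes permitted. The substrate for network
#' enrichment analysis.
#'
#' @param edges two-column character matrix or data frame of edge
#'   endpoints (one row per edge, orientation irrelevant), or a
#'   zero-row object for an edgeless network.
#' @param nodes optional character vector of node symbols; the union of
#'   edge endpoints is always included, extra symbols become isolated
#'   nodes.
#' @return An object of class `gene_network` with components `nodes`
#'   (character), `edges` (m x 2 integer index matrix, each row
#'   `[i, 1] < [i, 2]`), and `degree` (named integer vector). Attributes
#'   `n_self_loops` and `n_duplicates` record what was dropped during
#'   canonicalization.
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- matrix(character(), ncol = 2L)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L && nrow(edges) > 0L) {
    usage_error("`edges` must have exactly two columns")
  }
  storage.mode(edges) <- "character"
  nodes <- unique(c(nodes, as.vector(edges)))
  nodes <- nodes[!is.na(nodes) & nzchar(nodes)]
  a <- match(edges[, 1L], nodes)
  b <- match(edges[, 2L], nodes)
  self <- !is.na(a) & !is.na(b) & a == b
  lo <- pmin(a, b)[!self]
  hi <- pmax(a, b)[!self]
  key <- (lo - 1) * length(nodes) + hi
  dup <- duplicated(key)
  idx <- cbind(lo[!dup], hi[!dup])
  net <- structure(
    list(
      nodes = nodes,
      edges = matrix(as.integer(idx), ncol = 2L),
      degree = .degree_from_edges(nodes, matrix(as.integer(idx), ncol = 2L))
    ),
    class = "gene_network",
    n_self_loops = sum(self),
    n_duplicates = sum(dup)
  )
  net
}

.degree_from_edges <- function(nodes, edges) {
  d <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = length(nodes))
  names(d) <- nodes
  d
}

.rebuild_network <- function(net, edge_idx) {
  edge_idx <- matrix(as.integer(edge_idx), ncol = 2L)
  net$edges <- edge_idx
  net$degree <- .degree_from_edges(net$nodes, edge_idx)
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d nodes, %d edges (mean degree %.2f)\n",
    length(x$nodes), nrow(x$edges),
    if (length(x$nodes)) 2 * nrow(x$edges) / length(x$nodes) else 0
  ))
  invisible(x)
}

#' Number of nodes / edges of a gene network
#' @param network a `gene_network`
#' @return integer count
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Node degrees of a gene network
#' @param network a `gene_network`
#' @return named integer vector, one entry per node (isolated nodes 0)
#' @export
network_degrees <- function(network) network$degree

#' Read a tab-separated edge list into a gene network
#'
#' Expects lines `geneA<TAB>geneB[<TAB>confidence]`; `#`-prefixed lines
#' and blank lines are ignored. Duplicate orientations are collapsed and
#' self-loops dropped; both are counted in the returned diagnostics.
#'
#' @param path file path (or connection) to read.
#' @param min_confidence optional numeric; rows with a third-column
#'   confidence below this value are skipped. Requires the confidence
#'   column to be present and numeric.
#' @return a `gene_network`; attributes `n_self_loops`, `n_duplicates`
#'   and `n_below_confidence` record dropped lines.
#' @export
read_edge_list <- function(path, min_confidence = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(gene_network())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    usage_error(sprintf(
      "malformed edge line %d: expected >=2 tab-separated fields",
      lineno[which(nf < 2L)[1L]]
    ))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  n_below <- 0L
  if (!is.null(min_confidence)) {
    if (any(nf < 3L)) {
      usage_error(sprintf(
        "line %d has no confidence column but min_confidence was given",
        lineno[which(nf < 3L)[1L]]
      ))
    }
    conf <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(conf)) {
      usage_error(sprintf(
        "non-numeric confidence on line %d", lineno[which(is.na(conf))[1L]]
      ))
    }
    drop <- conf < min_confidence
    n_below <- sum(drop)
    a <- a[!drop]
    b <- b[!drop]
  }
  net <- gene_network(cbind(a, b))
  attr(net, "n_below_confidence") <- n_below
  net
}

#' Write a gene network as a tab-separated edge list
#'
#' Edges are emitted lexicographically sorted (and each edge with its
#' endpoints in lexicographic order) for reproducible diffs.
#'
#' @param network a `gene_network`
#' @param path output file path
#' @param header optional character vector of metadata lines, written
#'   `#`-prefixed before the edges.
#' @return `path`, invisibly
#' @export
write_edge_list <- function(network, path, header = NULL) {
  a <- network$nodes[network$edges[, 1L]]
  b <- network$nodes[network$edges[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order(a, b)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(a[o], b[o], sep = "\t"), con)
  invisible(path)
}

#' Expand a protein-complex record into pairwise links
#'
#' Complex membership is binarized with the matrix (full clique) model:
#' every pair of distinct members becomes an undirected link. Records
#' with fewer than two members yield no links.
#'
#' @param members character vector of member gene symbols, or a complex
#'   record list with a `members` component.
#' @return a k*(k-1)/2 x 2 character matrix of unordered pairs.
#' @export
expand_complex <- function(members) {
  if (is.list(members)) members <- members$members
  members <- unique(as.character(members))
  k <- length(members)
  if (k < 2L) {
    return(matrix(character(), ncol = 2L))
  }
  t(combn(members, 2L))
}

#' Read complex-membership records
#'
#' Expects tab-separated lines `complex_id<TAB>member1;member2;...`
#' (semicolon-joined members); `#` comments ignored. Members are
#' deduplicated within a record.
#'
#' @param path file path to read
#' @return list of records, each `list(complex_id =, members =)`
#' @export
read_complex_records <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    usage_error(sprintf("malformed complex record on line %d", lineno[which(bad)[1L]]))
  }
  lapply(parts, function(p) {
    list(
      complex_id = p[[1L]],
      members = unique(strsplit(p[[2L]], ";", fixed = TRUE)[[1L]])
    )
  })
}

#' Build a gene network from complex records by clique expansion
#' @param records list of complex records (see [read_complex_records()])
#' @return a `gene_network` over the union of all expanded pairs
#' @export
complexes_to_network <- function(records) {
  pairs <- do.call(rbind, lapply(records, expand_complex))
  singletons <- unlist(lapply(records, function(r) r$members))
  gene_network(pairs, nodes = unique(singletons))
}

#' Merge gene networks
#'
#' Node set is the union of node sets; edge set the deduplicated union
#' of edge sets (mirrors merging a functional-coupling network with
#' curated pathway and complex links into one substrate).
#'
#' @param networks non-empty list of `gene_network` objects
#' @return the union `gene_network`
#' @export
union_networks <- function(networks) {
  if (inherits(networks, "gene_network")) networks <- list(networks)
  if (length(networks) == 0L) {
    usage_error("`networks` must be a non-empty list")
  }
  stopifnot(all(vapply(networks, inherits, TRUE, "gene_network")))
  nodes <- unique(unlist(lapply(networks, function(n) n$nodes)))
  pairs <- do.call(rbind, lapply(networks, function(n) {
    cbind(n$nodes[n$edges[, 1L]], n$nodes[n$edges[, 2L]])
  }))
  gene_network(pairs, nodes = nodes)
}

#' Degree-preserving randomization of a gene network
#'
#' Runs a double-edge-swap Markov chain: repeatedly pick two distinct
#' edges (a,b), (c,d), propose one of the two rewirings uniformly, and
#' reject proposals that would create a self-loop or duplicate an
#' existing edge. Every node keeps its degree and the edge count is
#' unchanged; the stationary distribution is uniform over simple graphs
#' with the given degree sequence reachable by swaps.
#'
#' @param network a `gene_network` with at least 2 edges (fewer returns
#'   an identical copy with a warning).
#' @param seed integer seed; the chain is deterministic given it. `NULL`
#'   uses (and advances) the current RNG state.
#' @param swap_factor the chain performs `swap_factor * n_edges`
#'   accepted swaps (default 10, a standard edge-swap burn-in). A safety
#'   cap of `10 * swap_factor * n_edges` total proposals guards against
#'   rigid graphs on which most proposals are rejected (a triangle
#'   admits none); hitting the cap returns the current state with a
#'   warning.
#' @return a rewired `gene_network` with identical node set, degree
#'   vector and edge count; attributes `swaps_accepted` and
#'   `swap_proposals` record chain effort.
#' @export
rewire <- function(network, seed = NULL, swap_factor = 10) {
  m <- n_edges(network)
  if (m < 2L) {
    warning("network has fewer than 2 edges; returning an identical copy")
    return(network)
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  target <- swap_factor * m
  cap <- 10 * target
  out <- .rewire_edges_cpp(network$edges - 1L, length(network$nodes),
                           target, cap)
  if (attr(out, "accepted") < target) {
    warning(sprintf(
      "proposal cap reached after %d accepted swaps (target %d); graph may be rigid",
      as.integer(attr(out, "accepted")), as.integer(target)
    ))
  }
  new_net <- .rebuild_network(network, out + 1L)
  attr(new_net, "swaps_accepted") <- attr(out, "accepted")
  attr(new_net, "swap_proposals") <- attr(out, "proposals")
  new_net
}
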