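# Independent oracles and small fixture builders, deliberately written
# without reusing the package's own code paths.

# All simple graphs on `n` labelled nodes with exactly the given degree
# sequence, found by brute-force enumeration of edge subsets. Returns a
# list of 2-column index matrices.
enum_realizations <- function(deg) {
  n <- length(deg)
  all_pairs <- t(combn(n, 2L))
  m <- sum(deg) / 2
  stopifnot(m == round(m))
  picks <- combn(nrow(all_pairs), m)
  out <- list()
  for (i in seq_len(ncol(picks))) {
    e <- all_pairs[picks[, i], , drop = FALSE]
    d <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
    if (all(d == deg)) out[[length(out) + 1L]] <- e
  }
  out
}

# Cross-link count by direct enumeration over an index edge matrix.
count_cross_oracle <- function(edges, a_idx, f_idx) {
  sum((edges[, 1L] %in% a_idx & edges[, 2L] %in% f_idx) |
        (edges[, 1L] %in% f_idx & edges[, 2L] %in% a_idx))
}

canon_key <- function(e) {
  e2 <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e2 <- e2[order(e2[, 1L], e2[, 2L]), , drop = FALSE]
  paste(e2[, 1L], e2[, 2L], sep = "-", collapse = ";")
}

# All accepted single double-edge swaps from a state, under the same
# validity rules as the implementation: no self-loops, no duplicate of
# any CURRENT edge (so a proposal reproducing the removed pair is a
# rejection, not a move).
swap_moves <- function(e) {
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  out <- list()
  m <- nrow(e)
  keys <- paste(e[, 1L], e[, 2L])
  ck <- canon_key(e)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    a <- e[i, 1L]; b <- e[i, 2L]; c <- e[j, 1L]; d <- e[j, 2L]
    for (opt in 1:2) {
      if (opt == 1L) { n1 <- c(a, d); n2 <- c(c, b) }
      else { n1 <- c(a, c); n2 <- c(b, d) }
      n1 <- sort(n1); n2 <- sort(n2)
      if (n1[1L] == n1[2L] || n2[1L] == n2[2L]) next
      k1 <- paste(n1[1L], n1[2L]); k2 <- paste(n2[1L], n2[2L])
      if (k1 == k2 || k1 %in% keys || k2 %in% keys) next
      e2 <- e; e2[i, ] <- n1; e2[j, ] <- n2
      if (canon_key(e2) == ck) next
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

# BFS over accepted swaps: every simple realization reachable from
# `start`, with its move count. A chain run for a fixed number of
# SUCCESSFUL swaps is the embedded jump chain of the randomization,
# i.e. a random walk on this state graph, so its stationary law weights
# each state by its move count.
swap_states <- function(start) {
  start <- cbind(pmin(start[, 1L], start[, 2L]),
                 pmax(start[, 1L], start[, 2L]))
  seen <- list()
  seen[[canon_key(start)]] <- start
  frontier <- list(start)
  while (length(frontier)) {
    nxt <- list()
    for (g in frontier) for (h in swap_moves(g)) {
      k <- canon_key(h)
      if (is.null(seen[[k]])) {
        seen[[k]] <- h
        nxt[[length(nxt) + 1L]] <- h
      }
    }
    frontier <- nxt
  }
  list(states = unname(seen),
       moves = vapply(seen, function(e) length(swap_moves(e)), 1L),
       keys = names(seen))
}

# Exact null moments of the cross-link count under the fixed-success
# swap chain: move-count-weighted mean and SD over reachable states.
exact_null_oracle <- function(start, a_idx, f_idx) {
  ss <- swap_states(start)
  cnt <- vapply(ss$states, count_cross_oracle, 1, a_idx, f_idx)
  w <- ss$moves / sum(ss$moves)
  mu <- sum(w * cnt)
  list(mu = mu, sigma = sqrt(sum(w * (cnt - mu)^2)), counts = cnt,
       weights = w, n_states = length(cnt))
}

# Benjamini-Hochberg by the literal step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Pearson chi-square statistic straight from the definition.
chi2_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Tiny graphs used across tests.
triangle_net <- function() {
  crosslink::gene_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
}

path_net <- function() {
  crosslink::gene_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
}

edge_key <- function(net) {
  a <- net$nodes[net$edges[, 1L]]
  b <- net$nodes[net$edges[, 2L]]
  sort(paste(pmin(a, b), pmax(a, b)))
}

# The 14 concordantly altered genes of the two-contrast comparison
# (overexpression vs vector; silencing vs scrambled), signed fold
# changes as published.
concordant_pairs <- function() {
  data.frame(
    gene = c("LRRC7", "WDR54", "ETS1", "TNFSF18", "CLIP4", "FBLN5",
             "TLN1", "GJA5", "TNXB", "ALCAM", "NTSR1", "NUP62CL",
             "EPYC", "SMARCD3"),
    fc_over = c(-32.3, -1.9, 3.9, 3.9, 2.3, 1.5, 1.8, 2.0, 7.1, 1.7,
                1.7, -1.7, -9.0, -4.1),
    fc_sil = c(1.6, 1.5, -1.5, -1.6, -1.5, -3.4, 1.9, 1.8, 1.6, 1.6,
               1.5, -1.5, -1.6, -1.6),
    stringsAsFactors = FALSE
  )
}
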