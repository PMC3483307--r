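#' Count network links between two gene sets
#'
#' The observed statistic of network enrichment analysis: the number of
#' network edges with one endpoint in set A and the other in set F. Each
#' qualifying edge counts exactly once; an edge with both endpoints in
#' the intersection of A and F also counts once. Symmetric in its two
#' set arguments. Genes absent from the network are ignored.
#'
#' @param network a `gene_network`
#' @param set_a,set_f character vectors of gene symbols or `gene_set`
#'   records
#' @return non-negative integer link count
#' @export
cross_link_count <- function(network, set_a, set_f) {
  in_a <- .membership(network, set_a)
  in_f <- .membership(network, set_f)
  .cross_links_cpp(network$edges - 1L, in_a, in_f)
}

.membership <- function(network, set) {
  if (inherits(set, "gene_set")) set <- set$members
  network$nodes %in% set
}

# Pool of n_perm independently rewired copies of a network's edge
# matrix. Sub-seeds are drawn from the master seed (counter-based via a
# single sample.int call) so permutations are reproducible and mutually
# independent.
.rewired_pool <- function(network, n_perm, seed, swap_factor = 10) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  m <- n_edges(network)
  target <- swap_factor * m
  cap <- 10 * target
  lapply(sub_seeds, function(s) {
    set.seed(s)
    .rewire_edges_cpp(network$edges - 1L, length(network$nodes),
                      target, cap)
  })
}

# Null link counts for one (A, F) pair over a rewired pool.
.null_counts <- function(pool, in_a, in_f) {
  vapply(pool, function(e) .cross_links_cpp(e, in_a, in_f), 1L)
}

#' Null mean and SD of the cross-link count under network randomization
#'
#' Generates `n_perm` independently rewired (degree-preserving) copies
#' of the network, counts A-F links in each exactly as the observed
#' statistic is counted, and returns the sample mean and sample SD
#' (denominator n_perm - 1) of those counts.
#'
#' @inheritParams cross_link_count
#' @param n_perm number of network permutations (default 50)
#' @param seed integer seed (deterministic given it)
#' @param swap_factor accepted swaps per permutation as a multiple of
#'   the edge count
#' @return list with `mu_null`, `sigma_null`, and the per-permutation
#'   `counts`
#' @export
null_moments <- function(network, set_a, set_f, n_perm = 50L, seed = 1L,
                         swap_factor = 10) {
  if (n_perm < 2L) usage_error("`n_perm` must be >= 2")
  pool <- .rewired_pool(network, n_perm, seed, swap_factor)
  counts <- .null_counts(pool, .membership(network, set_a),
                         .membership(network, set_f))
  list(mu_null = mean(counts), sigma_null = sd(counts), counts = counts)
}

#' NEA Z-score
#'
#' Standardizes the observed link count against the randomization null:
#' `z = (n_obs - mu_null) / sigma_null`. A zero null SD with
#' `n_obs != mu_null` has no defined Z under the normal approximation;
#' `NA` is returned and callers flag the pair `zero_sigma` (such pairs
#' are only assessable by the empirical FDR machinery). A zero SD with
#' `n_obs == mu_null` (a rigid graph) gives z = 0.
#'
#' @param n_obs observed link count
#' @param mu_null,sigma_null null mean and SD from [null_moments()]
#' @return numeric z (possibly `NA`)
#' @export
z_score <- function(n_obs, mu_null, sigma_null) {
  if (any(sigma_null < 0)) usage_error("`sigma_null` must be >= 0")
  ifelse(sigma_null > 0, (n_obs - mu_null) / sigma_null,
         ifelse(n_obs == mu_null, 0, NA_real_))
}

#' Two-sided normal p-value for a Z-score
#'
#' Under the null the Z-scores are approximately standard normal, so
#' `p = 2 * pnorm(-|z|)`. Direction (enriched vs depleted) is carried
#' separately by the sign of z.
#'
#' @param z numeric z-score(s)
#' @return two-sided p-value(s)
#' @export
z_to_p <- function(z) {
  2 * pnorm(-abs(z))
}

# Degree-matched random gene sets: bin all network nodes by degree
# (degree_bins quantile bins over the network degree distribution),
# count the template set's members per bin, and draw the same per-bin
# counts without replacement. Returns a list of character vectors.
.sample_degree_matched <- function(network, members, n_random,
                                   degree_bins = 5L) {
  deg <- network$degree
  br <- unique(quantile(deg, probs = seq(0, 1, length.out = degree_bins + 1L)))
  bin <- cut(deg, breaks = br, include.lowest = TRUE, labels = FALSE)
  member_bins <- bin[match(members, network$nodes)]
  member_bins <- member_bins[!is.na(member_bins)]
  need <- tabulate(member_bins, nbins = length(br) - 1L)
  nodes_by_bin <- split(network$nodes, bin)
  lapply(seq_len(n_random), function(i) {
    unlist(lapply(seq_along(need), function(b) {
      if (need[b] == 0L) return(character())
      pool <- nodes_by_bin[[as.character(b)]]
      pool[sample.int(length(pool), min(need[b], length(pool)))]
    }), use.names = FALSE)
  })
}

# Z matrix (sets_a x sets_f) over a shared rewired pool; also returns
# n_obs, mu, sigma matrices.
.nea_core <- function(network, sets_a, sets_f, pool) {
  mem_a <- lapply(sets_a, .membership, network = network)
  mem_f <- lapply(sets_f, .membership, network = network)
  nA <- length(mem_a); nF <- length(mem_f)
  n_obs <- matrix(0L, nA, nF)
  mu <- matrix(0, nA, nF)
  sg <- matrix(0, nA, nF)
  e_obs <- network$edges - 1L
  for (i in seq_len(nA)) {
    for (j in seq_len(nF)) {
      n_obs[i, j] <- .cross_links_cpp(e_obs, mem_a[[i]], mem_f[[j]])
      counts <- .null_counts(pool, mem_a[[i]], mem_f[[j]])
      mu[i, j] <- mean(counts)
      sg[i, j] <- sd(counts)
    }
  }
  z <- matrix(z_score(n_obs, mu, sg), nA, nF)
  list(n_obs = n_obs, mu = mu, sigma = sg, z = z)
}

#' Empirical FDR from degree-matched random gene sets
#'
#' Estimates how often randomly compiled gene sets of the same size and
#' degree composition as the AGS reach a given Z-score level against the
#' same FGS catalog:
#' `FDR(t) = mean over random sets of #\{|Z_random| >= t\} / #\{|Z_real| >= t\}`,
#' capped at 1. Random and real tests share one pool of rewired
#' networks. Returns `NA` when no real test reaches the threshold.
#'
#' @param network a `gene_network`
#' @param ags a `gene_set` (the altered gene set)
#' @param fgs_catalog an `fgs_catalog`
#' @param z_threshold Z magnitude at which to evaluate the FDR
#' @param n_random number of random degree-matched sets (>= 10)
#' @param seed integer seed
#' @param config a [run_config()] supplying n_perm, swap_factor and
#'   degree_bins
#' @return list with `fdr`, `real_z` (named vector of the AGS's Z per
#'   FGS), and `random_z` (n_random x n_FGS matrix)
#' @export
empirical_fdr <- function(network, ags, fgs_catalog, z_threshold = 3,
                          n_random = 50L, seed = 1L,
                          config = run_config(seed = seed)) {
  if (n_random < 10L) usage_error("`n_random` must be >= 10")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  pool <- .rewired_pool(network, config$n_perm, seed, config$swap_factor)
  set.seed(seed + 1L)
  rand_sets <- .sample_degree_matched(network, .set_members(ags),
                                      n_random, config$degree_bins)
  fgs_members <- lapply(fgs_catalog, .set_members)
  core_real <- .nea_core(network, list(.set_members(ags)), fgs_members, pool)
  core_rand <- .nea_core(network, rand_sets, fgs_members, pool)
  real_z <- setNames(core_real$z[1L, ], names(fgs_catalog))
  list(
    fdr = .fdr_at(z_threshold, real_z, core_rand$z),
    real_z = real_z,
    random_z = core_rand$z
  )
}

.fdr_at <- function(t, real_z, random_z) {
  n_real <- sum(abs(real_z) >= t, na.rm = TRUE)
  if (n_real == 0L) return(NA_real_)
  mean_rand <- mean(rowSums(abs(random_z) >= t, na.rm = TRUE))
  min(1, mean_rand / n_real)
}

.set_members <- function(set) {
  if (inherits(set, "gene_set")) set$members else as.character(set)
}

#' Gene-level network enrichment of a single gene against an AGS
#'
#' Tests whether one network gene (e.g. a pathway member) is
#' significantly linked to an altered gene set: counts its direct links
#' to AGS members and standardizes against the rewiring null. The call
#' criterion requires both at least `min_links` observed links and a
#' NEA p-value below 0.05. Single-gene sets are always flagged
#' `small_set`.
#'
#' @param network a `gene_network`
#' @param gene one gene symbol present in the network
#' @param ags a `gene_set` or character vector
#' @param min_links minimum observed links for a call (default 3)
#' @param n_perm,seed,swap_factor null-model parameters
#' @return list with `link_count`, `z`, `p`, `passes`, `flags`
#' @export
gene_level_nea <- function(network, gene, ags, min_links = 3L,
                           n_perm = 50L, seed = 1L, swap_factor = 10) {
  if (!gene %in% network$nodes) {
    usage_error(sprintf("gene '%s' is not in the network", gene))
  }
  link_count <- cross_link_count(network, gene, ags)
  nm <- null_moments(network, gene, ags, n_perm = n_perm, seed = seed,
                     swap_factor = swap_factor)
  z <- z_score(link_count, nm$mu_null, nm$sigma_null)
  p <- if (is.na(z)) NA_real_ else z_to_p(z)
  flags <- "small_set"
  if (nm$sigma_null == 0) flags <- c(flags, "zero_sigma")
  list(
    link_count = link_count,
    z = z,
    p = p,
    passes = link_count >= min_links && !is.na(p) && p < 0.05,
    flags = flags
  )
}

#' Run network enrichment analysis for AGS x FGS pairs
#'
#' The full NEA procedure: every AGS is tested against every FGS in the
#' catalog. One shared pool of `config$n_perm` rewired networks supplies
#' the null for all pairs (the randomization permutes the network, not
#' individual pairs). Each pair gets the observed link count, null mean
#' and SD, Z, two-sided normal p, a Benjamini-Hochberg FDR across the
#' whole result list, and (for `fdr_mode` `"empirical"` or `"both"`) an
#' empirical FDR at the pair's own |Z| from degree-matched random sets.
#' Pairs where either set has fewer than `config$min_fgs_size`
#' network-resident members are flagged `small_set`; pairs with a zero
#' null SD are flagged `zero_sigma` (z/p `NA` unless the observed count
#' equals the null mean).
#'
#' @param network a `gene_network`
#' @param ags_list a `gene_set`, or (named) list of them
#' @param fgs_catalog an `fgs_catalog` (non-empty)
#' @param config a [run_config()]; its `seed` drives all randomization
#' @return a data.frame of class `nea_result` with one row per AGS x FGS
#'   pair: `ags_id, fgs_id, n_obs, mu_null, sigma_null, z, p, fdr_bh,
#'   fdr_empirical, direction, flags`
#' @export
run_nea <- function(network, ags_list, fgs_catalog,
                    config = run_config()) {
  if (inherits(ags_list, "gene_set")) ags_list <- list(ags_list)
  if (length(ags_list) == 0L) usage_error("`ags_list` is empty")
  if (length(fgs_catalog) == 0L) usage_error("`fgs_catalog` is empty")
  ags_list <- lapply(ags_list, function(s) {
    if (!inherits(s, "gene_set")) s <- gene_set("ags", s, source = "ags")
    restrict_to_network(s, network)
  })
  ags_ids <- vapply(ags_list, `[[`, "", "set_id")
  if (anyDuplicated(ags_ids)) {
    ags_ids <- make.unique(ags_ids)
  }
  fgs_res <- lapply(fgs_catalog, restrict_to_network, network = network)
  fgs_ids <- names(fgs_catalog)

  pool <- .rewired_pool(network, config$n_perm, config$seed,
                        config$swap_factor)
  core <- .nea_core(network, lapply(ags_list, `[[`, "members"),
                    lapply(fgs_res, `[[`, "members"), pool)

  # empirical FDR: per AGS, one batch of degree-matched random sets;
  # each pair's empirical FDR is evaluated at its own |Z|.
  emp <- matrix(NA_real_, length(ags_list), length(fgs_res))
  if (config$fdr_mode %in% c("empirical", "both")) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    for (i in seq_along(ags_list)) {
      set.seed(config$seed + i)
      rand_sets <- .sample_degree_matched(network, ags_list[[i]]$members,
                                          config$n_random,
                                          config$degree_bins)
      rand_core <- .nea_core(network, rand_sets,
                             lapply(fgs_res, `[[`, "members"), pool)
      for (j in seq_along(fgs_res)) {
        zij <- core$z[i, j]
        if (!is.na(zij)) {
          emp[i, j] <- .fdr_at(abs(zij), core$z[i, ], rand_core$z)
        }
      }
    }
  }

  grid <- expand.grid(i = seq_along(ags_list), j = seq_along(fgs_res))
  small_a <- vapply(ags_list, function(s)
    length(s$members) < config$min_fgs_size, TRUE)
  small_f <- vapply(fgs_res, function(s)
    length(s$members) < config$min_fgs_size, TRUE)
  cov0_a <- vapply(ags_list, function(s) length(s$members) == 0L, TRUE)
  cov0_f <- vapply(fgs_res, function(s) length(s$members) == 0L, TRUE)

  z <- core$z[cbind(grid$i, grid$j)]
  z[cov0_a[grid$i] | cov0_f[grid$j]] <- NA_real_  # degenerate: no resident genes
  p <- ifelse(is.na(z), NA_real_, z_to_p(z))
  fdr_bh <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr_bh[ok] <- bh_fdr(p[ok])
  flags <- mapply(function(i, j, zz, sg) {
    f <- character()
    if (small_a[i] || small_f[j]) f <- c(f, "small_set")
    if (sg == 0) f <- c(f, "zero_sigma")
    if (cov0_a[i] || cov0_f[j]) f <- c(f, "no_coverage")
    paste(f, collapse = ",")
  }, grid$i, grid$j, z, core$sigma[cbind(grid$i, grid$j)])

  res <- data.frame(
    ags_id = ags_ids[grid$i],
    fgs_id = fgs_ids[grid$j],
    n_obs = core$n_obs[cbind(grid$i, grid$j)],
    mu_null = core$mu[cbind(grid$i, grid$j)],
    sigma_null = core$sigma[cbind(grid$i, grid$j)],
    z = z,
    p = p,
    fdr_bh = fdr_bh,
    fdr_empirical = emp[cbind(grid$i, grid$j)],
    direction = ifelse(is.na(z), NA_character_,
                       ifelse(z > 0, "enriched", "depleted")),
    flags = flags,
    stringsAsFactors = FALSE
  )
  attr(res, "config") <- config
  attr(res, "network_hash") <- network_hash(network)
  class(res) <- c("nea_result", "data.frame")
  res
}

#' Cheap content hash of a network's edge set
#'
#' Polynomial rolling hash (mod 2^31 - 1) over the lexicographically
#' sorted edge list; used to stamp result files with the identity of
#' the network they were computed on. Not cryptographic.
#'
#' @param network a `gene_network`
#' @return hexadecimal string
#' @export
network_hash <- function(network) {
  a <- network$nodes[network$edges[, 1L]]
  b <- network$nodes[network$edges[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order(a, b)
  bytes <- utf8ToInt(paste(a[o], b[o], sep = "\t", collapse = "\n"))
  m <- 2147483647
  h <- 0
  for (x in bytes) h <- (h * 127 + x) %% m
  sprintf("%08x", h)
}

#' Write NEA results with a provenance header
#'
#' @param results an `nea_result`
#' @param path output path
#' @param extra extra `#` header lines
#' @return `path`, invisibly
#' @export
write_nea_results <- function(results, path, extra = NULL) {
  cfg <- attr(results, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# crosslink nea_result",
    sprintf("# seed: %d", cfg$seed),
    sprintf("# n_perm: %d", cfg$n_perm),
    sprintf("# swap_factor: %d", cfg$swap_factor),
    sprintf("# fdr_mode: %s", cfg$fdr_mode),
    sprintf("# network_hash: %s", attr(results, "network_hash")),
    if (!is.null(extra)) paste0("# ", extra)
  ), con)
  write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
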