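#' Simulate a paired case/control expression experiment
#'
#' Emulates the statistical structure of a paired microarray design with
#' biological replicates: log2 intensity = gene baseline + pair
#' (replicate) effect + condition effect + Gaussian noise, exponentiated
#' to a positive linear scale. A fraction of genes carry a true signed
#' condition effect of `effect_log2` log2 units (random sign, applied to
#' the case samples). Pair effects are drawn from Gaussian(0, noise_sd),
#' so the paired analysis is genuinely advantageous over an unpaired
#' one.
#'
#' @param n_genes number of genes
#' @param n_pairs number of case/control pairs (default 3, a triplicate
#'   design)
#' @param frac_de fraction of genes with a true effect (default 0.05)
#' @param effect_log2 true |log2 fold change| of DE genes (default 1,
#'   i.e. 2-fold)
#' @param noise_sd SD of both the per-observation noise and the pair
#'   effects, log2 units (default 0.25)
#' @param seed integer seed (bit-reproducible given it)
#' @return list with `expr` (a `paired_expression`) and `truth`
#'   (list: `de_genes`, `effects` named signed log2 effects, generator
#'   parameters)
#' @export
simulate_expression <- function(n_genes, n_pairs = 3L, frac_de = 0.05,
                                effect_log2 = 1, noise_sd = 0.25,
                                seed = 1L) {
  if (frac_de < 0 || frac_de > 1) usage_error("`frac_de` must be in [0, 1]")
  if (noise_sd <= 0) usage_error("`noise_sd` must be > 0")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_de <- round(frac_de * n_genes)
  de_genes <- if (n_de > 0) sample(genes, n_de) else character()
  effects <- setNames(numeric(n_genes), genes)
  effects[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) * effect_log2

  baseline <- rnorm(n_genes, mean = 7, sd = 1.5)
  pair_eff <- rnorm(n_pairs, 0, noise_sd)
  log2_case <- baseline + rep(pair_eff, each = n_genes) + effects +
    rnorm(n_genes * n_pairs, 0, noise_sd)
  log2_ctrl <- baseline + rep(pair_eff, each = n_genes) +
    rnorm(n_genes * n_pairs, 0, noise_sd)
  values <- cbind(matrix(2^log2_case, n_genes, n_pairs),
                  matrix(2^log2_ctrl, n_genes, n_pairs))
  rownames(values) <- genes
  condition <- rep(c("case", "control"), each = n_pairs)
  pair <- rep(seq_len(n_pairs), times = 2L)
  colnames(values) <- paste(condition, pair, sep = "_")
  expr <- structure(list(values = values, condition = condition,
                         pair = pair),
                    class = "paired_expression")
  truth <- list(
    de_genes = sort(de_genes),
    effects = effects[effects != 0],
    params = list(n_genes = n_genes, n_pairs = n_pairs,
                  frac_de = frac_de, effect_log2 = effect_log2,
                  noise_sd = noise_sd, seed = seed)
  )
  list(expr = expr, truth = truth)
}

#' Simulate a configuration-model gene network
#'
#' Draws a degree sequence (Poisson with the requested mean, or a
#' truncated power law when `degree_exponent` is given), then matches
#' half-edge stubs uniformly at random. Pairings creating self-loops or
#' duplicate edges are rejected and the leftover stubs re-matched for a
#' bounded number of rounds; any stubs still unmatched are dropped with
#' a warning (the realized mean degree stays within a few percent of the
#' target for non-degenerate settings).
#'
#' @param n_nodes number of nodes (symbols `g0001`... so networks and
#'   expression simulations share a namespace)
#' @param mean_degree target mean degree (>= 1)
#' @param degree_exponent `NULL` for Poisson degrees, or a power-law
#'   exponent (e.g. 2.5) for heavy-tailed degrees truncated at
#'   `sqrt(n_nodes)`
#' @param seed integer seed
#' @param node_names optional character vector of node symbols
#' @return a `gene_network`
#' @export
simulate_network <- function(n_nodes, mean_degree, degree_exponent = NULL,
                             seed = 1L, node_names = NULL) {
  if (mean_degree < 1) usage_error("`mean_degree` must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nodes <- node_names %||% sprintf("g%04d", seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes)
  if (is.null(degree_exponent)) {
    deg <- rpois(n_nodes, mean_degree)
  } else {
    kmax <- max(2L, floor(sqrt(n_nodes)))
    support <- seq_len(kmax)
    w <- support^(-degree_exponent)
    deg <- sample(support, n_nodes, replace = TRUE, prob = w)
    deg <- round(deg * mean_degree / mean(deg))
    deg[deg < 0] <- 0L
  }
  if (sum(deg) %% 2 == 1) {
    i <- sample.int(n_nodes, 1L)
    deg[i] <- deg[i] + 1L
  }
  stubs <- rep(seq_len(n_nodes), times = deg)
  edges <- matrix(integer(), ncol = 2L)
  seen <- new.env(hash = TRUE)
  for (round in seq_len(25L)) {
    if (length(stubs) < 2L) break
    stubs <- stubs[sample.int(length(stubs))]
    half <- length(stubs) %/% 2L
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi)
    ok <- lo != hi & !duplicated(key) &
      !vapply(key, function(k) !is.null(seen[[k]]), TRUE)
    for (k in key[ok]) seen[[k]] <- TRUE
    edges <- rbind(edges, cbind(lo[ok], hi[ok]))
    stubs <- c(a[!ok], b[!ok], if (length(stubs) %% 2L) stubs[length(stubs)])
    if (!any(!ok) && length(stubs) < 2L) break
  }
  if (length(stubs) >= 2L) {
    warning(sprintf("%d stubs left unmatched and dropped", length(stubs)))
  }
  gene_network(cbind(nodes[edges[, 1L]], nodes[edges[, 2L]]),
               nodes = nodes)
}

#' Plant extra cross-links between two gene sets
#'
#' Adds `n_extra` new distinct A-F cross edges, chosen uniformly among
#' currently absent cross pairs, and records them as ground truth.
#' Degrees of touched nodes increase accordingly (edges are added, not
#' rewired, so truth accounting stays simple).
#'
#' @param network a `gene_network`
#' @param set_a,set_f character vectors of node symbols (inside the
#'   network)
#' @param n_extra number of cross edges to add (>= 0)
#' @param seed integer seed
#' @return list with `network` (the augmented `gene_network`) and
#'   `truth` (list: `added_edges`, `n_extra`, before/after cross-link
#'   counts)
#' @export
plant_enrichment <- function(network, set_a, set_f, n_extra, seed = 1L) {
  set_a <- .set_members(set_a)
  set_f <- .set_members(set_f)
  if (!all(c(set_a, set_f) %in% network$nodes)) {
    usage_error("both sets must lie inside the network")
  }
  before <- cross_link_count(network, set_a, set_f)
  if (n_extra == 0L) {
    return(list(network = network,
                truth = list(added_edges = matrix(character(), ncol = 2L),
                             n_extra = 0L, links_before = before,
                             links_after = before)))
  }
  ia <- match(set_a, network$nodes)
  jf <- match(set_f, network$nodes)
  cand <- expand.grid(a = ia, f = jf)
  cand <- cand[cand$a != cand$f, , drop = FALSE]
  lo <- pmin(cand$a, cand$f); hi <- pmax(cand$a, cand$f)
  key <- (lo - 1) * length(network$nodes) + hi
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]; key <- key[!dup]
  ekey <- (network$edges[, 1L] - 1) * length(network$nodes) +
    network$edges[, 2L]
  absent <- !(key %in% ekey)
  if (sum(absent) < n_extra) {
    usage_error(sprintf("only %d absent cross pairs; cannot add %d",
                        sum(absent), n_extra))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- sample(which(absent), n_extra)
  new_edges <- cbind(lo[pick], hi[pick])
  net2 <- .rebuild_network(network, rbind(network$edges, new_edges))
  added <- cbind(network$nodes[new_edges[, 1L]],
                 network$nodes[new_edges[, 2L]])
  list(
    network = net2,
    truth = list(added_edges = added, n_extra = n_extra,
                 links_before = before,
                 links_after = cross_link_count(net2, set_a, set_f))
  )
}

#' Generate a random gene-set catalog
#'
#' Sets of uniform-random sizes in `[size_low, size_high]`, members
#' drawn without replacement per set from the universe.
#'
#' @param n_sets number of sets
#' @param size_low,size_high inclusive size bounds
#' @param universe character vector to draw members from
#' @param seed integer seed
#' @return an `fgs_catalog`
#' @export
make_catalog <- function(n_sets, size_low, size_high, universe,
                         seed = 1L) {
  if (size_low < 1L) usage_error("`size_low` must be >= 1")
  if (size_high > length(universe)) {
    usage_error("`size_high` exceeds the universe size")
  }
  if (size_high < size_low) usage_error("`size_high` < `size_low`")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  records <- lapply(seq_len(n_sets), function(i) {
    size <- sample(seq(size_low, size_high), 1L)
    gene_set(sprintf("fgs_%02d", i), sample(universe, size),
             source = "custom",
             name = sprintf("synthetic functional set %d", i))
  })
  fgs_catalog(records)
}

#' Default configuration for an end-to-end synthetic study
#'
#' @param n_genes genes simulated (and network nodes)
#' @param n_pairs case/control pairs
#' @param frac_de fraction of genes with a planted expression effect
#' @param effect_log2 planted |log2 FC|
#' @param noise_sd log2 noise SD
#' @param mean_degree network mean degree
#' @param n_sets functional gene sets in the catalog
#' @param size_low,size_high FGS size bounds
#' @param n_extra planted extra cross-links between the true DE genes
#'   and the designated FGS
#' @return named list of generator settings
#' @export
study_config <- function(n_genes = 2000L, n_pairs = 3L, frac_de = 0.05,
                         effect_log2 = 1.5, noise_sd = 0.25,
                         mean_degree = 8, n_sets = 12L, size_low = 30L,
                         size_high = 50L, n_extra = 200L) {
  as.list(environment())
}

#' Generate a complete synthetic study with known ground truth
#'
#' End-to-end fixture emulating the real analysis: a paired expression
#' experiment with planted DE genes, a configuration-model network over
#' the same gene symbols, a random FGS catalog, and planted extra links
#' between the true DE genes and a designated FGS (`fgs_01`), so that
#' running [de_table()] -> [select_ags()] -> [run_nea()] recovers the
#' designated set for sufficiently strong settings.
#'
#' @param config a [study_config()] list
#' @param seed integer master seed
#' @return list with `expr`, `network`, `catalog`, `truth` (DE truth,
#'   planted pair, designated FGS id, sub-seeds)
#' @export
make_study <- function(config = study_config(), seed = 1L) {
  if (config$size_high > config$n_genes) {
    usage_error("FGS sizes exceed the gene universe")
  }
  sim <- simulate_expression(config$n_genes, config$n_pairs,
                             config$frac_de, config$effect_log2,
                             config$noise_sd, seed = seed)
  genes <- rownames(sim$expr$values)
  network <- simulate_network(config$n_genes, config$mean_degree,
                              seed = seed + 1L, node_names = genes)
  catalog <- make_catalog(config$n_sets, config$size_low,
                          config$size_high, genes, seed = seed + 2L)
  designated <- names(catalog)[1L]
  planted <- plant_enrichment(network, sim$truth$de_genes,
                              catalog[[designated]]$members,
                              config$n_extra, seed = seed + 3L)
  truth <- list(
    de_genes = sim$truth$de_genes,
    effects = sim$truth$effects,
    designated_fgs = designated,
    planted = planted$truth,
    config = config,
    seed = seed
  )
  list(expr = sim$expr, network = planted$network, catalog = catalog,
       truth = truth)
}

#' Write a synthetic study to a fixture directory
#'
#' Emits `expression.tsv`, `network.tsv`, `catalog.gmt` and
#' `truth.json` under `dir`.
#'
#' @param study a [make_study()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(study$expr, file.path(dir, "expression.tsv"),
                   header = "crosslink synthetic study")
  write_edge_list(study$network, file.path(dir, "network.tsv"),
                  header = "crosslink synthetic study")
  write_gmt(study$catalog, file.path(dir, "catalog.gmt"))
  truth <- study$truth
  truth$planted$added_edges <- apply(truth$planted$added_edges, 1L,
                                     paste, collapse = "|")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a synthetic study fixture
#' @param dir directory written by [write_study()]
#' @return list with `expr`, `network`, `catalog`, `truth`
#' @export
read_study <- function(dir) {
  list(
    expr = read_expression(file.path(dir, "expression.tsv")),
    network = read_edge_list(file.path(dir, "network.tsv")),
    catalog = read_gmt(file.path(dir, "catalog.gmt")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
}
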