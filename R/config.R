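#' Pipeline run configuration
#'
#' Collects the tunable parameters of the pipeline with defaults
#' matching the study design the package implements: 50 network
#' permutations for the null, 10x|E| accepted swaps per permutation,
#' AGS as top-100/top-900 by q, fold-change cutoff 1.5 with q < 0.05 for
#' threshold selection, small-set caution below 5 network-resident
#' genes, and a >= 3-link requirement for gene-level calls.
#'
#' @param seed master integer seed; every source of randomness derives
#'   from it
#' @param n_perm number of degree-preserving network permutations used
#'   to learn the null mean and SD (default 50)
#' @param swap_factor accepted double-edge swaps per permutation, as a
#'   multiple of the edge count (default 10)
#' @param top_n AGS list sizes for top-N selection (default c(100, 900))
#' @param fc_cut signed fold-change magnitude cutoff (default 1.5)
#' @param q_cut q-value cutoff (default 0.05)
#' @param min_fgs_size below this many network-resident members a set is
#'   flagged `small_set` (default 5)
#' @param min_gene_links minimum links for a gene-level NEA call
#'   (default 3)
#' @param fdr_mode which FDR(s) to attach to NEA results: `"bh"`,
#'   `"empirical"`, or `"both"` (default)
#' @param n_random random degree-matched gene sets for the empirical
#'   FDR (default 50)
#' @param degree_bins number of degree-distribution bins used to match
#'   connectivity when sampling random sets (default 5, i.e. quintiles)
#' @return a list of class `run_config`
#' @export
run_config <- function(seed = 1L, n_perm = 50L, swap_factor = 10L,
                       top_n = c(100L, 900L), fc_cut = 1.5,
                       q_cut = 0.05, min_fgs_size = 5L,
                       min_gene_links = 3L,
                       fdr_mode = c("both", "bh", "empirical"),
                       n_random = 50L, degree_bins = 5L) {
  fdr_mode <- match.arg(fdr_mode)
  if (n_perm < 2L) usage_error("`n_perm` must be >= 2")
  if (swap_factor < 1L) usage_error("`swap_factor` must be >= 1")
  if (fc_cut < 1) usage_error("`fc_cut` must be >= 1")
  if (q_cut <= 0 || q_cut > 1) usage_error("`q_cut` must be in (0, 1]")
  structure(
    list(seed = as.integer(seed), n_perm = as.integer(n_perm),
         swap_factor = as.integer(swap_factor),
         top_n = as.integer(top_n), fc_cut = fc_cut, q_cut = q_cut,
         min_fgs_size = as.integer(min_fgs_size),
         min_gene_links = as.integer(min_gene_links),
         fdr_mode = fdr_mode, n_random = as.integer(n_random),
         degree_bins = as.integer(degree_bins)),
    class = "run_config"
  )
}

#' Read a flat key=value configuration file
#'
#' One `key = value` per line, `#` comments allowed; keys must be
#' [run_config()] arguments. Values given on the command line (or as
#' `overrides`) take precedence over the file, which takes precedence
#' over defaults.
#'
#' @param path file path, or `NULL` for defaults only
#' @param overrides named list of overriding values
#' @return a `run_config`
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) usage_error(sprintf("bad config line: '%s'", ln))
      key <- trimws(kv[1L])
      val <- trimws(kv[2L])
      vals[[key]] <- if (key == "fdr_mode") val else
        as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]])
    }
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    usage_error(sprintf("unknown config key '%s'", unknown[1L]))
  }
  do.call(run_config, vals)
}
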