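#' Conventional gene-set over-representation by chi-square
#'
#' Builds the 2x2 contingency table (DE / not-DE) x (in set / out of
#' set) from marginal counts and applies Pearson's chi-square test
#' (df 1). No continuity correction by default; set `correct = TRUE` for
#' the Yates-corrected variant. When any expected cell is below 5 the
#' result carries a `small_expected` flag and the upper-tail
#' hypergeometric p is reported alongside as a safer alternative.
#'
#' @param k_de_in_set DE genes inside the set
#' @param set_size genes in the set (on the platform)
#' @param total_de DE genes on the platform
#' @param total_genes genes on the platform
#' @param correct apply Yates continuity correction (default FALSE)
#' @return list of class `contingency_result`: `table` (2x2), `chi2`,
#'   `p`, `p_hypergeom`, `odds_ratio`, `flags`
#' @export
contingency_enrichment <- function(k_de_in_set, set_size, total_de,
                                   total_genes, correct = FALSE) {
  k <- k_de_in_set
  cells <- c(k, set_size - k, total_de - k,
             total_genes - set_size - total_de + k)
  if (any(cells < 0)) {
    usage_error("inconsistent counts: a derived contingency cell is negative")
  }
  tab <- matrix(cells, nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("de", "non_de")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab == 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  flags <- character()
  if (any(expected < 5)) flags <- "small_expected"
  structure(
    list(table = tab, chi2 = chi2, p = p,
         p_hypergeom = hypergeometric_enrichment(k, set_size, total_de,
                                                 total_genes),
         odds_ratio = or, flags = flags),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "<contingency_result> chi2 = %.4g, p = %.3g (hypergeom p = %.3g), OR = %.3g%s\n",
    x$chi2, x$p, x$p_hypergeom, x$odds_ratio,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""
  ))
  invisible(x)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` where X counts DE genes in a random draw of `set_size`
#' genes from `total_genes` of which `total_de` are DE. Preferable to
#' the chi-square when expected counts are small.
#'
#' @inheritParams contingency_enrichment
#' @return p-value
#' @export
hypergeometric_enrichment <- function(k_de_in_set, set_size, total_de,
                                      total_genes) {
  if (k_de_in_set < 0 || set_size > total_genes ||
      total_de > total_genes || k_de_in_set > set_size ||
      k_de_in_set > total_de) {
    usage_error("inconsistent counts for hypergeometric test")
  }
  phyper(k_de_in_set - 1, total_de, total_genes - total_de, set_size,
         lower.tail = FALSE)
}

#' Count DE genes per functional category
#'
#' A gene annotated to several categories counts in each of them.
#'
#' @param de_genes character vector of DE gene symbols
#' @param category_map named list: category -> character vector of
#'   member genes
#' @return named integer vector of per-category DE counts
#' @export
category_counts <- function(de_genes, category_map) {
  vapply(category_map, function(members) {
    sum(de_genes %in% members)
  }, 1L)
}
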