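#' Signed fold change between two positive means
#'
#' The field's signed convention: the ratio r = case/control is reported
#' as r when r >= 1 and as -1/r when r < 1, so the magnitude is always
#' at least 1 and the sign gives the direction of change.
#'
#' @param mean_case,mean_control positive expression means (linear scale)
#' @return signed fold change, never in the open interval (-1, 1)
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    usage_error("expression means must be strictly positive")
  }
  r <- mean_case / mean_control
  ifelse(r >= 1, r, -1 / r)
}

#' Paired two-sided t-test on log-scale intensities
#'
#' Pairs are matched by position. The test is run on per-pair
#' differences of `log2` intensities (the customary scale for
#' microarray testing), df = n - 1. If every difference is identical
#' and nonzero the t statistic is infinite; the p-value is then floored
#' at `p_floor` and flagged rather than reported as 0, so downstream
#' ranking stays finite.
#'
#' @param case_values,control_values equal-length numeric vectors
#'   (positive linear-scale intensities), length >= 2
#' @param log2_transform test on log2 scale (default TRUE); set FALSE if
#'   inputs are already log-scale
#' @param p_floor lower bound for reported p (default 1e-12)
#' @return list with `t_stat`, `df`, `p`, and `zero_variance` flag
#' @export
paired_t <- function(case_values, control_values, log2_transform = TRUE,
                     p_floor = 1e-12) {
  if (length(case_values) != length(control_values)) {
    usage_error("case and control vectors must have equal length")
  }
  if (length(case_values) < 2L) {
    usage_error("need at least 2 pairs")
  }
  x <- if (log2_transform) log2(case_values) else case_values
  y <- if (log2_transform) log2(control_values) else control_values
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t_stat = 0, df = length(d) - 1L, p = 1,
                  zero_variance = FALSE))
    }
    return(list(t_stat = sign(d[1L]) * Inf, df = length(d) - 1L,
                p = p_floor, zero_variance = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p = max(tt$p.value, p_floor), zero_variance = FALSE)
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return q-values in the input order (monotone step-up, capped at 1)
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) && (anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))) {
    usage_error("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-gene paired differential expression table
#'
#' For each gene: signed fold change from linear-scale per-condition
#' means, paired t statistic and two-sided p on log2 intensities, and
#' Benjamini-Hochberg q across all genes. The t statistics are computed
#' vectorised across genes; they agree exactly with per-gene
#' [paired_t()] calls.
#'
#' @param expr a `paired_expression` object (see
#'   [simulate_expression()] / [read_expression()]) or a positive
#'   genes-x-samples matrix accompanied by `condition` and `pair`.
#' @param condition,pair only when `expr` is a bare matrix: a vector of
#'   `"case"`/`"control"` labels and an integer pairing index per column.
#' @param p_floor zero-variance p floor passed through to the test
#' @return a `de_table`: data.frame with columns `gene, fc, t, p, q,
#'   zero_variance`, sorted by q ascending, then |fc| descending, then
#'   gene; attribute `methods` records test, transform and FDR method.
#' @export
de_table <- function(expr, condition = NULL, pair = NULL,
                     p_floor = 1e-12) {
  if (inherits(expr, "paired_expression")) {
    values <- expr$values
    condition <- expr$condition
    pair <- expr$pair
  } else {
    values <- as.matrix(expr)
  }
  if (is.null(condition) || is.null(pair)) {
    usage_error("`condition` and `pair` are required with a bare matrix")
  }
  if (any(values <= 0)) usage_error("expression values must be positive")
  case_idx <- which(condition == "case")
  ctrl_idx <- which(condition == "control")
  if (length(case_idx) != length(ctrl_idx) || length(case_idx) < 2L) {
    usage_error("need equal numbers of case and control samples (>= 2 pairs)")
  }
  ctrl_idx <- ctrl_idx[match(pair[case_idx], pair[ctrl_idx])]
  if (anyNA(ctrl_idx)) usage_error("case/control pairing indices do not match")

  k <- length(case_idx)
  lc <- log2(values[, case_idx, drop = FALSE])
  lt <- log2(values[, ctrl_idx, drop = FALSE])
  d <- lc - lt
  mean_d <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mean_d)^2) / (k - 1))
  t_stat <- mean_d / (sd_d / sqrt(k))
  p <- 2 * pt(-abs(t_stat), df = k - 1)
  zero_var <- sd_d == 0 & mean_d != 0
  t_stat[sd_d == 0 & mean_d == 0] <- 0
  p[sd_d == 0 & mean_d == 0] <- 1
  p[zero_var] <- p_floor
  p <- pmax(p, p_floor)

  fc <- signed_fold_change(rowMeans(values[, case_idx, drop = FALSE]),
                           rowMeans(values[, ctrl_idx, drop = FALSE]))
  tab <- data.frame(
    gene = rownames(values) %||% as.character(seq_len(nrow(values))),
    fc = unname(fc), t = unname(t_stat), p = unname(p),
    q = unname(bh_fdr(p)), zero_variance = unname(zero_var),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$q, -abs(tab$fc), tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "methods") <- c(
    test = "paired t (two-sided, log2 scale)",
    fdr = "Benjamini-Hochberg",
    fc = "linear-scale mean ratio, signed convention"
  )
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Select an altered gene set (AGS) from a DE table
#'
#' Two selection modes mirror common practice: `top_n` takes the first
#' `n` genes under the table's deterministic order (q ascending, ties by
#' |FC| descending, then symbol); `threshold` takes every gene with
#' |FC| >= `fc_cut` and q <= `q_cut`.
#'
#' @param table a `de_table`
#' @param mode `"top_n"` or `"threshold"`
#' @param n list size for `top_n` (e.g. 100 or 900)
#' @param fc_cut,q_cut cutoffs for `threshold` mode (defaults 1.5, 0.05)
#' @param set_id identifier for the resulting gene set
#' @return a `gene_set` record (see [gene_set()]) with selection
#'   metadata in its `source` and `meta` fields
#' @export
select_ags <- function(table, mode = c("top_n", "threshold"), n = 100,
                       fc_cut = 1.5, q_cut = 0.05, set_id = NULL) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) usage_error("DE table is empty")
  if (mode == "top_n") {
    if (n < 1) usage_error("`n` must be >= 1")
    if (n > nrow(table)) {
      warning(sprintf("n = %d exceeds table size %d; returning all genes",
                      n, nrow(table)))
      n <- nrow(table)
    }
    genes <- table$gene[seq_len(n)]
    meta <- list(mode = "top_n", n = n)
    set_id <- set_id %||% sprintf("ags_top%d", n)
  } else {
    if (fc_cut < 1) usage_error("`fc_cut` must be >= 1")
    if (q_cut <= 0 || q_cut > 1) usage_error("`q_cut` must be in (0, 1]")
    sel <- (table$fc >= fc_cut | table$fc <= -fc_cut) & table$q <= q_cut
    genes <- table$gene[sel]
    meta <- list(mode = "threshold", fc_cut = fc_cut, q_cut = q_cut)
    set_id <- set_id %||% sprintf("ags_fc%.2g_q%.2g", fc_cut, q_cut)
  }
  gene_set(set_id, genes, source = "ags", name = set_id, meta = meta)
}

#' Classify direction concordance between two experimental contrasts
#'
#' For genes altered in both an overexpression and a silencing contrast
#' (signed fold changes): `tracking` when expression follows the
#' perturbed gene (up under overexpression, down under silencing),
#' `anti_tracking` when it opposes it in both, and `same_direction` when
#' both contrasts move it the same way regardless of the perturbation.
#'
#' @param pairs data.frame with columns `gene`, `fc_over`, `fc_sil`
#'   (signed fold changes, |fc| >= 1)
#' @return the input with an added factor column `concordance`
#' @export
classify_concordance <- function(pairs) {
  fc_over <- pairs$fc_over
  fc_sil <- pairs$fc_sil
  if (any(abs(fc_over) < 1) || any(abs(fc_sil) < 1)) {
    usage_error("signed fold changes must have |fc| >= 1")
  }
  lab <- ifelse(
    fc_over > 0 & fc_sil < 0, "tracking",
    ifelse(fc_over < 0 & fc_sil > 0, "anti_tracking", "same_direction")
  )
  pairs$concordance <- factor(
    lab, levels = c("tracking", "anti_tracking", "same_direction")
  )
  pairs
}

#' Fold change from qPCR cycle thresholds (delta-delta-Ct)
#'
#' DDCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control); relative expression is
#' 2^(-DDCt), reported under the signed fold-change convention.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   finite cycle-threshold values (target gene and reference gene, e.g.
#'   GAPDH, in the sample and control conditions)
#' @return signed fold change
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) usage_error("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  rel <- 2^(-ddct)
  signed_fold_change(rel, 1)
}

#' Read / write paired expression matrices
#'
#' Tab-separated format: first column `gene`, then case columns
#' `case_1..case_k` and control columns `control_1..control_k`; pairing
#' is by replicate index. `#`-prefixed metadata lines are ignored on
#' read and may be supplied on write.
#'
#' @param path file path
#' @return `read_expression` returns a `paired_expression` object:
#'   list with `values` (genes x samples matrix), `condition`, `pair`.
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || names(tab)[1L] != "gene") {
    usage_error("expression file must have a `gene` column then sample columns")
  }
  cols <- names(tab)[-1L]
  m <- regmatches(cols, regexec("^(case|control)_(\\d+)$", cols))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    usage_error(sprintf("unrecognized sample column '%s'", cols[which(bad)[1L]]))
  }
  condition <- vapply(m, `[[`, "", 2L)
  pair <- as.integer(vapply(m, `[[`, "", 3L))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$gene
  structure(list(values = values, condition = condition, pair = pair),
            class = "paired_expression")
}

#' @rdname read_expression
#' @param expr a `paired_expression` object
#' @param header optional character vector of metadata lines
#' @export
write_expression <- function(expr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  cols <- paste(expr$condition, expr$pair, sep = "_")
  writeLines(paste(c("gene", cols), collapse = "\t"), con)
  body <- cbind(rownames(expr$values),
                format(expr$values, trim = TRUE, digits = 10))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a DE table with a metadata header
#'
#' @param table a `de_table`
#' @param path output path
#' @param extra extra metadata lines for the `#` header
#' @return `path`, invisibly
#' @export
write_de_table <- function(table, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meths <- attr(table, "methods")
  writeLines(c(
    paste0("# crosslink de_table"),
    paste0("# ", names(meths), ": ", meths),
    if (!is.null(extra)) paste0("# ", extra)
  ), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a DE table written by [write_de_table()]
#' @param path file path
#' @return a `de_table`
#' @export
read_de_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(tab) <- c("de_table", "data.frame")
  tab
}
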