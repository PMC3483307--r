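#' Construct a gene set record
#'
#' A named gene set: an altered gene set (AGS) from a DE contrast or a
#' functional gene set (FGS) from a pathway/ontology source. Members are
#' deduplicated.
#'
#' @param set_id unique identifier within a catalog
#' @param members character vector of gene symbols
#' @param source source tag, e.g. `"kegg"`, `"go"`, `"c2"`, `"custom"`,
#'   `"ags"`
#' @param name human-readable name / description (defaults to `set_id`)
#' @param meta optional list of extra metadata (selection parameters...)
#' @return object of class `gene_set`
#' @export
gene_set <- function(set_id, members, source = "custom", name = set_id,
                     meta = list()) {
  structure(
    list(set_id = as.character(set_id),
         name = as.character(name),
         source = as.character(source),
         members = unique(as.character(members)),
         meta = meta),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d members\n",
              x$set_id, x$source, length(x$members)))
  invisible(x)
}

#' Construct a gene-set catalog
#'
#' @param records list of `gene_set` objects with unique `set_id`s
#' @return object of class `fgs_catalog` (a named list of records)
#' @export
fgs_catalog <- function(records) {
  ids <- vapply(records, `[[`, "", "set_id")
  if (anyDuplicated(ids)) {
    usage_error(sprintf("duplicate set id '%s'", ids[duplicated(ids)][1L]))
  }
  structure(setNames(records, ids), class = "fgs_catalog")
}

#' @export
print.fgs_catalog <- function(x, ...) {
  sizes <- vapply(x, function(r) length(r$members), 1L)
  cat(sprintf("<fgs_catalog> %d gene sets (sizes %s..%s)\n", length(x),
              if (length(x)) min(sizes) else "-",
              if (length(x)) max(sizes) else "-"))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Members are
#' deduplicated per set; sets with no members are kept but flagged
#' (`empty` in `meta$flags`).
#'
#' @param path file path
#' @param source source tag stored on every record (default `"custom"`)
#' @return an `fgs_catalog`
#' @export
read_gmt <- function(path, source = "custom") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(fgs_catalog(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    usage_error(sprintf("GMT line %d has fewer than 2 fields",
                        lineno[which(bad)[1L]]))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    usage_error(sprintf("duplicate gene set name '%s' in GMT",
                        ids[duplicated(ids)][1L]))
  }
  records <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    rec <- gene_set(p[[1L]], members, source = source, name = p[[2L]])
    if (length(members) == 0L) rec$meta$flags <- "empty"
    rec
  })
  fgs_catalog(records)
}

#' Write a catalog as GMT
#' @param catalog an `fgs_catalog`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(catalog, function(r) {
    paste(c(r$set_id, r$name, r$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene set to the nodes of a network
#'
#' Network enrichment only sees network-resident genes; this records how
#' much of a set the network covers.
#'
#' @param set a `gene_set`
#' @param network a `gene_network`
#' @return the set with `members` replaced by the intersection with the
#'   network's nodes; `meta$coverage` holds the covered fraction of the
#'   original membership (0 for an empty set, flagged), and
#'   `meta$original_size` the pre-restriction size.
#' @export
restrict_to_network <- function(set, network) {
  orig <- if (is.null(set$meta$original_size)) length(set$members) else
    set$meta$original_size
  inside <- intersect(set$members, network$nodes)
  set$members <- inside
  set$meta$original_size <- orig
  set$meta$coverage <- if (orig == 0L) 0 else length(inside) / orig
  if (length(inside) == 0L) {
    set$meta$flags <- union(set$meta$flags, "no_network_coverage")
  }
  set
}

#' Flag small gene sets in a catalog
#'
#' Sets with fewer than `min_size` network-resident members get a
#' `small_set` flag: the normal-approximation null is unreliable for
#' them, so downstream results are annotated rather than dropped.
#'
#' @param catalog an `fgs_catalog`
#' @param min_size minimum trustworthy size (default 5)
#' @param network optional `gene_network`; when given, size is counted
#'   after restriction to the network (the catalog itself is not
#'   restricted)
#' @return the catalog with `small_set` added to `meta$flags` where
#'   applicable
#' @export
flag_small_sets <- function(catalog, min_size = 5L, network = NULL) {
  if (min_size < 1L) usage_error("`min_size` must be >= 1")
  records <- lapply(catalog, function(r) {
    k <- if (is.null(network)) length(r$members) else
      length(intersect(r$members, network$nodes))
    if (k < min_size) {
      r$meta$flags <- union(r$meta$flags, "small_set")
    }
    r
  })
  fgs_catalog(records)
}
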