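#' Abundance tables
#'
#' Throughout gutage an abundance table is a wide tibble whose first column,
#' `feature_id`, holds unique feature identifiers (genes, KOs, CAGs, genera,
#' metabolites) and whose remaining columns are numeric per-sample values.
#' Relative-abundance tables are compositional: each sample column sums to 1
#' (or to 0 for an entirely absent sample). These helpers convert between the
#' tibble form used in pipelines and the plain numeric matrix (features as
#' rows, samples as columns) used internally.
#'
#' @param x For [as_abundance()], a numeric matrix with row names (features)
#'   and column names (samples), or a data frame whose first column is the
#'   feature identifier.
#' @param tbl An abundance tibble.
#'
#' @return [as_abundance()] returns an abundance tibble; [abundance_matrix()]
#'   returns a numeric matrix with features as rows and samples as columns.
#'
#' @examples
#' m <- matrix(c(1, 3, 1, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' as_abundance(m)
#' @name abundance
NULL

#' @rdname abundance
#' @export
as_abundance <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("abundance matrices need feature row names and sample column names")
    }
    out <- as_tibble(x, rownames = "feature_id")
  } else if (is.data.frame(x)) {
    out <- as_tibble(x)
    names(out)[1] <- "feature_id"
    out$feature_id <- as.character(out$feature_id)
  } else {
    abort("cannot interpret `x` as an abundance table")
  }
  validate_abundance(out)
  out
}

#' @rdname abundance
#' @export
abundance_matrix <- function(tbl) {
  validate_abundance(tbl)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$feature_id
  storage.mode(m) <- "double"
  m
}

validate_abundance <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort("an abundance table needs a feature_id column plus sample columns")
  }
  if (anyDuplicated(tbl[[1]])) abort("feature ids must be unique")
  if (anyDuplicated(names(tbl)[-1])) abort("sample ids must be unique")
  if (!all(vapply(tbl[-1], is.numeric, logical(1)))) {
    abort("sample columns must be numeric")
  }
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) abort("abundances must be nonnegative")
  invisible(tbl)
}

#' Normalize counts to relative abundances
#'
#' Divides each sample column by its total so that every sample profile sums
#' to one. Raw gene counts, mapped-read tallies and metabolite intensities all
#' pass through this step before compositional analyses.
#'
#' @param counts An abundance tibble (see [as_abundance()]) of nonnegative
#'   values; every sample must contain at least one positive entry.
#' @return An abundance tibble of the same shape with each sample summing to 1.
#' @examples
#' x <- as_abundance(matrix(c(2, 2, 1, 3), 2, 2,
#'                          dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' normalize_relative(x)
#' @export
normalize_relative <- function(counts) {
  m <- abundance_matrix(counts)
  tot <- colSums(m)
  bad <- colnames(m)[tot <= 0]
  if (length(bad) > 0) {
    abort(paste0("sample(s) with all-zero abundance cannot be normalized: ",
                 paste(bad, collapse = ", ")))
  }
  as_abundance(sweep(m, 2, tot, "/"))
}

#' Aggregate gene abundances into KO profiles
#'
#' The relative abundance of a KEGG Ortholog (KO) is the total of the relative
#' abundances of its member genes in each sample. Genes absent from the map
#' contribute to no KO; the output is deliberately not renormalized, so the
#' per-sample KO totals equal the mapped-gene totals exactly.
#'
#' @param genes Gene abundance tibble.
#' @param map A data frame with columns `feature_id` (gene) and `group_id`
#'   (KO); each gene may map to at most one group.
#' @return KO abundance tibble (one row per KO).
#' @export
aggregate_ko <- function(genes, map) {
  m <- abundance_matrix(genes)
  map <- validate_feature_map(map)
  if (nrow(map) == 0) {
    warn("empty feature map: returning an empty KO table")
    return(as_abundance(genes[0, , drop = FALSE]))
  }
  missing <- setdiff(map$feature_id, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("map refers to unknown gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  sub <- m[map$feature_id, , drop = FALSE]
  agg <- rowsum(sub, group = map$group_id)
  as_abundance(agg[order(rownames(agg)), , drop = FALSE])
}

#' Summarize cluster abundance as the member-gene median
#'
#' The abundance of a CAG or MGS in a sample is the median of the relative
#' abundances of its member genes in that sample (for even-sized clusters, the
#' midpoint of the two central values — the ordinary statistical median).
#'
#' @param genes Gene abundance tibble.
#' @param membership Data frame with columns `feature_id` (gene) and
#'   `group_id` (cluster).
#' @return Cluster abundance tibble (one row per cluster).
#' @export
mgs_abundance <- function(genes, membership) {
  m <- abundance_matrix(genes)
  membership <- validate_feature_map(membership)
  if (nrow(membership) == 0) abort("membership table is empty")
  missing <- setdiff(membership$feature_id, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("cluster(s) reference unknown gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  groups <- split(membership$feature_id, membership$group_id)
  out <- t(vapply(groups, function(ids) {
    apply(m[ids, , drop = FALSE], 2, median)
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  as_abundance(out[order(rownames(out)), , drop = FALSE])
}

validate_feature_map <- function(map) {
  if (!is.data.frame(map) || ncol(map) < 2) {
    abort("a feature map needs feature_id and group_id columns")
  }
  map <- as_tibble(map)
  if (!all(c("feature_id", "group_id") %in% names(map))) {
    names(map)[1:2] <- c("feature_id", "group_id")
  }
  map$feature_id <- as.character(map$feature_id)
  map$group_id <- as.character(map$group_id)
  if (anyDuplicated(map$feature_id)) {
    abort("each feature may map to at most one group")
  }
  map[, c("feature_id", "group_id")]
}

#' Read and write abundance tables as TSV
#'
#' Matrices are stored features-as-rows, samples-as-columns, tab-delimited
#' with a header row; the first column is the feature identifier. Values are
#' written with full double precision so a round trip is lossless well beyond
#' 12 significant digits.
#'
#' @param path File path.
#' @param tbl Abundance tibble to write.
#' @return [read_abundance()] returns an abundance tibble;
#'   [write_abundance()] returns `tbl` invisibly.
#' @export
read_abundance <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "feature_id"
  tbl$feature_id <- as.character(tbl$feature_id)
  validate_abundance(tbl)
  tbl
}

#' @rdname read_abundance
#' @export
write_abundance <- function(tbl, path) {
  validate_abundance(tbl)
  readr::write_tsv(tbl, path)
  invisible(tbl)
}
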