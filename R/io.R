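#' Read a feature-by-sample expression matrix
#'
#' Expression tables are tab-separated text: the first row holds sample
#' identifiers, the first column feature (gene or miRNA) identifiers, and the
#' body numeric expression values. Rows whose values are all zero are dropped
#' (unexpressed features carry no usable signal), and duplicate feature
#' identifiers are collapsed by averaging their rows, with a warning.
#'
#' @param path Path to a tab-separated expression file.
#' @param feature_kind Either `"gene"` or `"miRNA"`; stored as an attribute
#'   and used for validation messages only.
#' @return A numeric matrix (features x samples) with unique rownames and
#'   colnames and attribute `feature_kind`.
#' @export
read_expression <- function(path, feature_kind = c("gene", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file '", path, "' has no data body")
  }
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in '", path, "': ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  feature_ids <- as.character(raw[[1L]])
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                    dimnames = list(feature_ids, sample_ids)))
  bad <- which(is.na(values) & !(toupper(body) %in% c("NA", "NAN")))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values))
    stop("non-numeric value '", body[bad[1L]], "' at feature '",
         feature_ids[idx[1L]], "', sample '", sample_ids[idx[2L]],
         "' in '", path, "'")
  }
  if (!all(is.finite(values))) stop("non-finite values in '", path, "'")
  values <- drop_zero_rows(values)
  if (nrow(values) == 0L) stop("no non-zero ", feature_kind,
                               " rows left in '", path, "'")
  values <- collapse_duplicate_features(values)
  new_expression_matrix(values, feature_kind)
}

new_expression_matrix <- function(values, feature_kind) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("expression values must be finite")
  attr(values, "feature_kind") <- feature_kind
  values
}

drop_zero_rows <- function(values) {
  keep <- rowSums(values != 0) > 0L
  values[keep, , drop = FALSE]
}

collapse_duplicate_features <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  dups <- unique(ids[duplicated(ids)])
  warning("collapsing ", length(dups), " duplicated feature id(s) by mean: ",
          paste(utils::head(dups, 5L), collapse = ", "))
  collapsed <- rowsum(values, group = ids, reorder = FALSE) /
    as.vector(table(ids)[unique(ids)])
  # rowsum reorders groups by first occurrence; restore a matrix
  collapsed[unique(ids), , drop = FALSE]
}

#' Write an expression matrix as tab-separated text
#'
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' Two tab-separated columns: sample id and label, labels restricted to
#' `normal` / `cancer`.
#'
#' @param path Path to a phenotype TSV with a header row.
#' @return Named character vector mapping sample id to label.
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("phenotype file needs 2 columns (sample, label)")
  labels <- raw[[2L]]
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample id(s) in phenotype table")
  bad <- setdiff(unique(labels), c("normal", "cancer"))
  if (length(bad)) stop("unknown phenotype label(s): ",
                        paste(bad, collapse = ", "))
  stats::setNames(labels, ids)
}

#' @rdname read_phenotypes
#' @param phen Named character vector of labels.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(data.frame(sample = names(phen), label = unname(phen)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed pathway edge table
#'
#' Four tab-separated columns: source gene, target gene, interaction type
#' (`activate`, `inhibit` or `other`) and pathway id. Duplicate
#' (source, target, pathway) records are removed and self-loops dropped with
#' a warning.
#'
#' @param path Path to a 4-column TSV with a header row.
#' @return A `data.frame` with columns `source`, `target`, `type`, `pathway`.
#' @export
read_pathways <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 4L) {
    stop("pathway file needs 4 columns (source, target, type, pathway); got ",
         ncol(raw))
  }
  df <- data.frame(source = raw[[1L]], target = raw[[2L]], type = raw[[3L]],
                   pathway = raw[[4L]], stringsAsFactors = FALSE)
  validate_pathway_table(df)
}

validate_pathway_table <- function(df) {
  if (any(!nzchar(df$source)) || any(!nzchar(df$target))) {
    stop("empty gene id in pathway edge table")
  }
  df$type[!df$type %in% c("activate", "inhibit")] <- "other"
  loops <- df$source == df$target
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop pathway record(s)")
    df <- df[!loops, , drop = FALSE]
  }
  df <- df[!duplicated(df[c("source", "target", "pathway")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_pathways
#' @param edges Pathway edge `data.frame`.
#' @export
write_pathways <- function(edges, path) {
  utils::write.table(edges[c("source", "target", "type", "pathway")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target gene pair table
#'
#' Two tab-separated columns (miRNA id, gene id); duplicates are removed so
#' each regulatory pair appears once. A gene may be targeted by many miRNAs
#' and vice versa.
#'
#' @param path Path to a 2-column TSV with a header row.
#' @return A `data.frame` with columns `mirna`, `gene`, one row per pair.
#' @export
read_target_pairs <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("target pair file needs 2 columns (miRNA, gene)")
  df <- data.frame(mirna = raw[[1L]], gene = raw[[2L]],
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$mirna)) || any(!nzchar(df$gene))) {
    stop("empty id field in target pair table")
  }
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_target_pairs
#' @param pairs Target pair `data.frame`.
#' @export
write_target_pairs <- function(pairs, path) {
  utils::write.table(pairs[c("mirna", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an activity profile (subpathway x sample matrix)
#'
#' @param path TSV path; rows are miRNA-mediated subpathways, columns samples.
#' @export
read_activity_profile <- function(path) {
  x <- read_expression(path, feature_kind = "miRNA")
  attr(x, "feature_kind") <- NULL
  x
}

#' @rdname read_activity_profile
#' @param profile Numeric matrix of activity values.
#' @export
write_activity_profile <- function(profile, path) {
  write_expression(profile, path)
}

#' Write an evaluation report to JSON
#'
#' Serialises an [within_dataset_cv()] / [cross_dataset_cv()] report,
#' including per-instance records, aggregate metrics, feature frequencies and
#' the seed, so runs are fully reproducible and comparable.
#'
#' @param report An `evaluation_report` object.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$frequency <- as.list(out$frequency)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a complete input bundle from a directory
#'
#' Expects the five files a [generate_dataset()] `simulate` run writes:
#' `genes.tsv`, `mirnas.tsv`, `phenotypes.tsv`, `pathways.tsv`,
#' `target_pairs.tsv`.
#'
#' @param dir Directory containing the bundle files.
#' @return A list with elements `gene_expr`, `mir_expr`, `phen`, `pathways`,
#'   `pairs`.
#' @export
read_bundle <- function(dir) {
  list(
    gene_expr = read_expression(file.path(dir, "genes.tsv"), "gene"),
    mir_expr  = read_expression(file.path(dir, "mirnas.tsv"), "miRNA"),
    phen      = read_phenotypes(file.path(dir, "phenotypes.tsv")),
    pathways  = read_pathways(file.path(dir, "pathways.tsv")),
    pairs     = read_target_pairs(file.path(dir, "target_pairs.tsv"))
  )
}

#' @rdname read_bundle
#' @param bundle Bundle list as returned by [generate_dataset()].
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$gene_expr, file.path(dir, "genes.tsv"))
  write_expression(bundle$mir_expr, file.path(dir, "mirnas.tsv"))
  write_phenotypes(bundle$phen, file.path(dir, "phenotypes.tsv"))
  write_pathways(bundle$pathways, file.path(dir, "pathways.tsv"))
  write_target_pairs(bundle$pairs, file.path(dir, "target_pairs.tsv"))
  invisible(dir)
}
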