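#' Define miRNA-mediated subpathways (SDE target selection)
#'
#' A miRNA-mediated subpathway is a differentially expressed miRNA together
#' with its significantly differentially expressed (SDE), sign-discordant
#' target genes inside the GDPN. Three predicates select the genes of
#' miRNA j:
#'
#' * the miRNA itself is differentially expressed (`p < alpha_mir`),
#' * the target gene is differentially expressed (`p < alpha_gene`),
#' * the inverse-regulation constraint `t(miR_j) * t(g_i) < 0` holds, and
#'   the gene is a node of the GDPN.
#'
#' miRNAs left with no qualifying gene are dropped. Each retained definition
#' carries the genes' stationary walk weights and t-score signs, which is
#' everything the activity formula needs.
#'
#' @param mir_stats,gene_stats `diff_stats` for miRNAs and genes.
#' @param pairs miRNA-target pair `data.frame` (`mirna`, `gene`).
#' @param g GDPN graph.
#' @param weights Named stationary weight vector from [drw_walk()].
#' @param alpha_gene,alpha_mir Significance thresholds (default 0.05 each).
#' @return List of subpathway definitions, each a list with `mirna`,
#'   `genes`, `weights`, `signs`, `n`; ordered by descending gene count then
#'   miRNA id.
#' @export
select_sde_targets <- function(mir_stats, gene_stats, pairs, g, weights,
                               alpha_gene = 0.05, alpha_mir = 0.05) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty target pair table")
  gdpn_nodes <- gdpn_genes(g)
  sig_mirs <- rownames(mir_stats)[!mir_stats$degenerate &
                                    !is.na(mir_stats$p) &
                                    mir_stats$p < alpha_mir]
  defs <- list()
  for (mir in intersect(sig_mirs, unique(pairs$mirna))) {
    targets <- pairs$gene[pairs$mirna == mir]
    targets <- intersect(targets, rownames(gene_stats))
    if (length(targets) == 0L) next
    gs <- gene_stats[targets, , drop = FALSE]
    keep <- !gs$degenerate & !is.na(gs$p) & gs$p < alpha_gene &
      mir_stats[mir, "t"] * gs$t < 0 &
      targets %in% gdpn_nodes
    genes <- sort(targets[keep])
    if (length(genes) == 0L) next
    defs[[mir]] <- list(
      mirna = mir,
      genes = genes,
      weights = stats::setNames(unname(weights[genes]), genes),
      signs = stats::setNames(gene_stats[genes, "sign"], genes),
      n = length(genes)
    )
  }
  if (length(defs) == 0L) return(defs)
  sizes <- vapply(defs, `[[`, integer(1), "n")
  defs[order(-sizes, names(defs))]
}

#' Activity value of one miRNA-mediated subpathway
#'
#' Combines the member genes' z-scored expression into one value per sample:
#' the weighted, sign-corrected sum of z rows, scaled by the L2 norm of the
#' weights,
#' `a = sum_i w_i * s_i * z_i / sqrt(sum_i w_i^2)`.
#' With a single member gene this reduces exactly to `s * z(g)`. The scale
#' of the walk weights cancels, so only their relative sizes matter. A
#' `sum_sq` denominator variant (no radical) is available for comparison.
#'
#' @param def One subpathway definition from [select_sde_targets()].
#' @param z Gene z-score matrix from [zscore_rows()].
#' @param denominator `"l2"` (default) or `"sum_sq"`.
#' @return Numeric vector of activity values, one per sample, or `NULL`
#'   (with a warning) when every weight is zero.
#' @export
activity_value <- function(def, z, denominator = c("l2", "sum_sq")) {
  denominator <- match.arg(denominator)
  missing_genes <- setdiff(def$genes, rownames(z))
  if (length(missing_genes)) {
    stop("subpathway gene(s) missing from z-matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  w <- def$weights[def$genes]
  s <- def$signs[def$genes]
  denom <- if (denominator == "l2") sqrt(sum(w^2)) else sum(w^2)
  if (denom == 0) {
    warning("all walk weights zero for subpathway '", def$mirna,
            "'; dropping it")
    return(NULL)
  }
  zs <- z[def$genes, , drop = FALSE]
  as.vector(crossprod(zs, w * s)) / denom
}

#' Infer the full activity profile
#'
#' Stacks [activity_value()] rows for every subpathway definition into the
#' subpathway-by-sample matrix used as the classifier feature space. Row
#' order is descending member-gene count, ties broken by miRNA id, so runs
#' are reproducible.
#'
#' @param defs List of definitions from [select_sde_targets()].
#' @param z Gene z-score matrix.
#' @param denominator Passed to [activity_value()].
#' @return Numeric matrix (subpathways x samples) with attribute
#'   `definitions`.
#' @export
infer_activity_profile <- function(defs, z,
                                   denominator = c("l2", "sum_sq")) {
  denominator <- match.arg(denominator)
  if (length(defs) == 0L) stop("no subpathway definitions supplied")
  rows <- lapply(defs, activity_value, z = z, denominator = denominator)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("every subpathway was dropped")
  profile <- do.call(rbind, rows)
  dimnames(profile) <- list(names(rows), colnames(z))
  attr(profile, "definitions") <- defs[names(rows)]
  profile
}

#' Export subpathway definitions as JSON
#'
#' @param defs List of definitions.
#' @param path Output path.
#' @export
write_definitions <- function(defs, path) {
  out <- lapply(defs, function(d) {
    list(mirna = d$mirna, genes = d$genes,
         weights = unname(d$weights), signs = unname(d$signs), n = d$n)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
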