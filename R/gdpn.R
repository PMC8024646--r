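#' Virtual node identifier used in every GDPN
#' @export
VIRTUAL_NODE <- "__VIRTUAL__"

#' Build the global directed pathway network (GDPN)
#'
#' Merges a multi-pathway directed edge table into one gene graph: genes
#' occurring in several pathways become single nodes, and parallel edges
#' (same source and target in different pathways) collapse to one directed
#' edge whose provenance records every contributing pathway. A single
#' virtual node is then appended with an edge from every gene to it and from
#' it to every gene, which guarantees that each node has both incoming and
#' outgoing edges so the row-normalised transition matrix of the random walk
#' is well defined.
#'
#' Interaction direction alone defines the edges; activation/inhibition is
#' kept as edge metadata but does not change the topology.
#'
#' @param edges Pathway edge `data.frame` (columns `source`, `target`,
#'   `type`, `pathway`), e.g. from [read_pathways()].
#' @param restrict_to Optional character vector of gene ids; when given,
#'   only pathways containing at least one listed gene contribute edges.
#'   This couples the network to the dataset and is therefore opt-in.
#' @return An `igraph` directed graph with vertex names (gene ids plus
#'   `__VIRTUAL__`), edge attributes `type` and `provenance`, and graph
#'   attribute `virtual`.
#' @export
build_gdpn <- function(edges, restrict_to = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) stop("empty pathway edge table")
  edges <- validate_pathway_table(edges)
  if (!is.null(restrict_to)) {
    keep_pw <- unique(edges$pathway[edges$source %in% restrict_to |
                                      edges$target %in% restrict_to])
    if (length(keep_pw) == 0L) {
      stop("restriction gene set eliminates every pathway")
    }
    edges <- edges[edges$pathway %in% keep_pw, , drop = FALSE]
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  prov <- vapply(split(edges$pathway, key), function(p) {
    paste(sort(unique(p)), collapse = ",")
  }, character(1))
  typ <- vapply(split(edges$type, key), function(tt) tt[[1L]], character(1))
  uniq <- !duplicated(key)
  src <- edges$source[uniq]
  dst <- edges$target[uniq]
  ukey <- key[uniq]
  genes <- sort(unique(c(src, dst)))
  if (VIRTUAL_NODE %in% genes) stop("gene id collides with the virtual node")
  n <- length(genes)
  # deterministic node order: sorted genes, virtual last
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c(genes, VIRTUAL_NODE))
  real_edges <- rbind(src, dst)
  virt_edges <- rbind(c(genes, rep(VIRTUAL_NODE, n)),
                      c(rep(VIRTUAL_NODE, n), genes))
  g <- igraph::add_edges(g, as.vector(real_edges),
                         type = typ[ukey], provenance = prov[ukey])
  g <- igraph::add_edges(g, as.vector(virt_edges),
                         type = "virtual", provenance = "")
  g <- igraph::set_graph_attr(g, "virtual", VIRTUAL_NODE)
  g
}

#' Real (gene) nodes of a GDPN, excluding the virtual node
#'
#' @param g A GDPN graph.
#' @return Character vector of gene ids in node order.
#' @export
gdpn_genes <- function(g) {
  setdiff(igraph::V(g)$name, VIRTUAL_NODE)
}

gdpn_without_virtual <- function(g) {
  igraph::delete_vertices(g, VIRTUAL_NODE)
}

#' Export / import the GDPN edge list
#'
#' Three tab-separated columns: source, target and a comma-joined pathway
#' provenance list. Virtual-node edges are regenerated on import, so only
#' real edges are written.
#'
#' @param g A GDPN graph.
#' @param path Output TSV path.
#' @export
write_gdpn <- function(g, path) {
  el <- igraph::as_edgelist(gdpn_without_virtual(g))
  keep <- igraph::E(g)$type != "virtual"
  utils::write.table(
    data.frame(source = el[, 1L], target = el[, 2L],
               type = igraph::E(g)$type[keep],
               provenance = igraph::E(g)$provenance[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gdpn
#' @export
read_gdpn <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  edges <- data.frame(source = raw$source, target = raw$target,
                      type = raw$type, pathway = raw$provenance,
                      stringsAsFactors = FALSE)
  # provenance lists round-trip as composite pathway tokens
  build_gdpn(edges)
}

#' Scale-free diagnostics: log-log degree-distribution fit
#'
#' Fits a simple least-squares line to log10(frequency) versus log10(degree)
#' over the unbinned nonzero-degree frequency table of the real (non-virtual)
#' nodes, for in-, out- and total degree, and returns the coefficient of
#' determination of each fit. A heavy-tailed (approximately power-law)
#' degree distribution gives a high R-squared.
#'
#' @param g A GDPN graph.
#' @return Named numeric vector `c(in=, out=, total=)`; `NA` for a flavour
#'   with fewer than 3 distinct nonzero degrees.
#' @export
degree_powerlaw_r2 <- function(g) {
  core <- gdpn_without_virtual(g)
  fit_one <- function(mode) {
    k <- igraph::degree(core, mode = mode)
    k <- k[k > 0]
    if (length(unique(k)) < 3L) return(NA_real_)
    tab <- table(k)
    lx <- log10(as.numeric(names(tab)))
    ly <- log10(as.numeric(tab))
    fit <- stats::lm(ly ~ lx)
    summary(fit)$r.squared
  }
  c(`in` = fit_one("in"), out = fit_one("out"), total = fit_one("all"))
}
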