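#' Construct a known-interaction database from an edge list
#'
#' Undirected edges typed genetic or physical, deduplicated on
#' (unordered pair, type); self-pairs dropped.
#'
#' @param edges data.frame geneA, geneB, type.
#' @return data.frame of class `interaction_db`.
#' @export
interaction_db <- function(edges) {
  stopifnot(all(c("geneA", "geneB", "type") %in% names(edges)))
  if (!all(edges$type %in% c("genetic", "physical")))
    stop("interaction type must be 'genetic' or 'physical'")
  edges <- edges[edges$geneA != edges$geneB, , drop = FALSE]
  key <- paste(pmin(edges$geneA, edges$geneB),
               pmax(edges$geneA, edges$geneB), edges$type)
  out <- edges[!duplicated(key), c("geneA", "geneB", "type")]
  rownames(out) <- NULL
  class(out) <- c("interaction_db", "data.frame")
  out
}

#' Integrate eQTL-derived gene pairs with the known-interaction database
#'
#' The union graph of (i) one `eqtl_association` edge per unique
#' (LxT gene, cis gene) pair and (ii) every database edge, with typed nodes:
#' `lxt_gene` (treatment-response transcripts), `eqtl_cis_gene` (genes the
#' selected variants are cis to; a gene in both sets keeps the `lxt_gene`
#' label) and `known_interactor` (all remaining database genes). Parallel
#' genetic + physical edges between one pair are both retained; self-pairs
#' are dropped.
#'
#' @param eqtl_pairs data.frame with columns `lxt_gene`, `cis_gene`.
#' @param db an [interaction_db()] (or plain edge data.frame).
#' @return list of class `integrated_network`: `nodes` (node, type) and
#'   `edges` (from, to, type).
#' @export
build_network <- function(eqtl_pairs, db) {
  if (!nrow(eqtl_pairs)) stop("no eQTL gene pairs to anchor the network")
  pairs <- unique(eqtl_pairs[eqtl_pairs$lxt_gene != eqtl_pairs$cis_gene,
                             c("lxt_gene", "cis_gene"), drop = FALSE])
  db <- interaction_db(db)
  edges <- rbind(data.frame(from = pairs$lxt_gene, to = pairs$cis_gene,
                            type = "eqtl_association"),
                 data.frame(from = db$geneA, to = db$geneB, type = db$type))
  nodes <- unique(c(edges$from, edges$to))
  type <- rep("known_interactor", length(nodes))
  type[nodes %in% eqtl_pairs$cis_gene] <- "eqtl_cis_gene"
  type[nodes %in% eqtl_pairs$lxt_gene] <- "lxt_gene"
  structure(list(nodes = data.frame(node = nodes, type = type),
                 edges = edges),
            class = "integrated_network")
}

#' Connectivity filter for the integrated network
#'
#' Keeps (i) every eQTL-association gene (`lxt_gene` and `eqtl_cis_gene`
#' nodes) and (ii) known interactors with at least `min_links` distinct
#' eQTL-association gene neighbors one edge away via genetic or physical
#' interactions; all other nodes are dropped and the induced edges kept.
#' The filter is idempotent.
#'
#' @param net an `integrated_network`.
#' @param min_links minimum distinct eQTL-gene neighbors.
#' @return the filtered `integrated_network`.
#' @export
filter_network <- function(net, min_links = 5) {
  stopifnot(inherits(net, "integrated_network"))
  eqtl_genes <- net$nodes$node[net$nodes$type != "known_interactor"]
  known <- net$edges[net$edges$type != "eqtl_association", , drop = FALSE]
  touch <- rbind(data.frame(v = known$from, g = known$to),
                 data.frame(v = known$to, g = known$from))
  touch <- unique(touch[touch$g %in% eqtl_genes, ])
  links <- table(touch$v)
  keep_interactors <- names(links)[links >= min_links]
  keep <- net$nodes$node %in% c(eqtl_genes, keep_interactors)
  nodes <- net$nodes[keep, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% nodes$node &
                       net$edges$to %in% nodes$node, , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "integrated_network")
}

#' MCODE modularization of the integrated network
#'
#' Collapses the typed multigraph to a simple undirected graph and runs
#' [mcode_modules()]; module membership is mapped back to node types.
#'
#' @param net an `integrated_network`.
#' @param ... passed to [mcode_modules()].
#' @return a `module_set`; each module additionally carries `node_types`.
#' @export
modularize <- function(net, ...) {
  stopifnot(inherits(net, "integrated_network"))
  g <- igraph::simplify(igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$node)))
  ms <- mcode_modules(g, ...)
  for (i in seq_along(ms$modules))
    ms$modules[[i]]$node_types <-
      setNames(net$nodes$type[match(ms$modules[[i]]$nodes, net$nodes$node)],
               ms$modules[[i]]$nodes)
  ms
}

#' GO-term overrepresentation for a module
#'
#' One-sided hypergeometric (Fisher exact) test of each term's
#' overrepresentation in the module against the background, BH-corrected
#' across terms. The term universe is the annotation's genes intersected
#' with the background; terms annotating fewer than `min_term_size` universe
#' genes are skipped.
#'
#' @param module character vector of genes (must be a subset of background).
#' @param annotation data.frame gene, term.
#' @param background character vector of universe genes.
#' @param min_term_size skip terms smaller than this in the universe.
#' @return data.frame term, overlap, module_size, term_size, background_size,
#'   p, q — sorted by p.
#' @export
go_enrichment <- function(module, annotation, background,
                          min_term_size = 2) {
  if (!length(background)) stop("empty background")
  if (length(setdiff(module, background)))
    stop("module contains genes outside the background")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  universe <- intersect(background, unique(ann$gene))
  N <- length(universe)
  mod <- intersect(module, universe)
  m <- length(mod)
  terms <- split(ann$gene, ann$term)
  terms <- lapply(terms, unique)
  terms <- terms[lengths(terms) >= min_term_size]
  if (!length(terms) || m == 0)
    return(data.frame(term = character(0), overlap = integer(0),
                      module_size = integer(0), term_size = integer(0),
                      background_size = integer(0), p = numeric(0),
                      q = numeric(0)))
  out <- data.frame(
    term = names(terms),
    overlap = vapply(terms, function(g) length(intersect(g, mod)),
                     integer(1)),
    module_size = m,
    term_size = lengths(terms),
    background_size = N)
  out$p <- phyper(out$overlap - 1, out$term_size, N - out$term_size, m,
                  lower.tail = FALSE)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
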