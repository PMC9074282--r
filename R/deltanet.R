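#' Pairwise Pearson correlation network of delta-expression
#'
#' Computes all pairwise Pearson correlations of per-line delta-expression
#' across lines, with two-sided p-values from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)) and BH q-values over all pairs.
#' Zero-variance transcripts are excluded with a warning (their correlations
#' are undefined).
#'
#' @param delta lines x transcripts matrix (from [delta_expression()]).
#' @return list of class `correlation_network`: `r` (full correlation
#'   matrix), `n` (lines), `nodes`, `edges` (a, b, r, p, q over the upper
#'   triangle).
#' @export
correlation_network <- function(delta) {
  if (nrow(delta) < 3) stop("need >= 3 lines for correlation p-values")
  if (ncol(delta) < 2) stop("need >= 2 transcripts")
  sds <- apply(delta, 2, sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance transcripts: ",
            paste(colnames(delta)[sds == 0], collapse = ", "))
    delta <- delta[, sds > 0, drop = FALSE]
  }
  n <- nrow(delta)
  r <- cor(delta)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- pmin(pmax(r[ut], -1), 1)
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tv), n - 2)
  p[abs(rv) >= 1] <- 0
  edges <- data.frame(a = colnames(delta)[ut[, 1]],
                      b = colnames(delta)[ut[, 2]],
                      r = rv, p = p, q = bh_fdr(p))
  structure(list(r = r, n = n, nodes = colnames(delta), edges = edges),
            class = "correlation_network")
}

#' Dual edge filter: FDR and top-|r| quantile
#'
#' Retains edges satisfying BOTH q < `fdr` AND |r| at or above the
#' (1 - `top_frac`) quantile of |r| taken over ALL pairs (type-7 quantile;
#' ties at the boundary are all retained). The cut value is recorded in
#' `attr(, "filter")`.
#'
#' @param net a `correlation_network`.
#' @param fdr BH q-value threshold.
#' @param top_frac fraction of largest |r| retained by the quantile rule.
#' @return the network with filtered edges; empty edge set warns.
#' @export
filter_edges <- function(net, fdr = 0.05, top_frac = 0.10) {
  stopifnot(inherits(net, "correlation_network"))
  cut <- quantile(abs(net$edges$r), 1 - top_frac, names = FALSE, type = 7)
  keep <- net$edges$q < fdr & abs(net$edges$r) >= cut
  if (!any(keep)) warning("no edges survive the dual filter")
  net$edges <- net$edges[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  attr(net, "filter") <- list(fdr = fdr, top_frac = top_frac, cut = cut,
                              ties = "all retained at the boundary")
  net
}

#' Complete-linkage bi-clustering of the correlation matrix
#'
#' Agglomerates transcripts on the distance d = 1 - r with complete linkage;
#' the symmetric matrix takes the same leaf ordering on rows and columns.
#'
#' @param net a `correlation_network`.
#' @return an [stats::hclust] tree.
#' @export
bicluster <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  if (length(net$nodes) < 2) stop("need >= 2 nodes to cluster")
  hclust(as.dist(1 - net$r), method = "complete")
}

#' Export a dendrogram in Newick format
#' @param hc an `hclust` tree.
#' @param file output path.
#' @export
write_dendrogram_newick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}

#' Build an igraph from the edges of a (filtered) correlation network
#' @param net a `correlation_network`.
#' @return undirected simple igraph; edge attributes r, p, q retained.
#' @export
network_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

## ---------------------------------------------------------------------------
## MCODE (molecular complex detection)
## ---------------------------------------------------------------------------

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weight
#'
#' The weight of v is k * density of the highest k-core of the closed
#' neighborhood N[v], where k is that core's order; isolated vertices score
#' 0. This is the local-density vertex weighting of the MCODE algorithm.
#'
#' @param graph an undirected igraph.
#' @param v a vertex name or index.
#' @return numeric weight.
#' @export
mcode_vertex_weight <- function(graph, v) {
  nb <- igraph::ego(graph, order = 1, nodes = v)[[1]]
  if (length(nb) < 2) return(0)
  sub <- igraph::induced_subgraph(graph, nb)
  core <- igraph::coreness(sub)
  k <- max(core)
  if (k == 0) return(0)
  k * graph_density(igraph::induced_subgraph(sub, which(core >= k)))
}

#' @rdname mcode_vertex_weight
#' @return `mcode_vertex_weights`: named vector over all vertices.
#' @export
mcode_vertex_weights <- function(graph) {
  w <- vapply(seq_len(igraph::vcount(graph)),
              function(i) mcode_vertex_weight(graph, i), numeric(1))
  names(w) <- igraph::V(graph)$name
  w
}

#' MCODE module detection
#'
#' Seeds are unvisited vertices in decreasing weight order (ties broken by
#' vertex name). Each seed grows by breadth-first expansion to unvisited
#' neighbors whose weight is at least `seed weight * (1 - vwp)`; grown
#' vertices are marked visited. With `haircut`, vertices with fewer than two
#' within-module neighbors are pruned once. The module score is
#' (density * size) of the grown core; modules scoring at most `score_min`
#' are discarded. With `fluff`, neighbors outside any core whose closed
#' neighborhood density exceeds `fluff_density` are appended to the module
#' (they stay available to other modules and do not change the score).
#'
#' @param graph undirected igraph.
#' @param vwp vertex weight percentage (expansion tolerance).
#' @param fluff logical; append dense peripheral neighbors.
#' @param fluff_density closed-neighborhood density cutoff for fluff.
#' @param haircut logical; prune singly-connected core vertices.
#' @param score_min retain modules with score strictly greater than this.
#' @return list of class `module_set`: `modules` (each with `nodes`,
#'   `core_nodes`, `score`, `weights`) and `params`.
#' @export
mcode_modules <- function(graph, vwp = 0.2, fluff = TRUE,
                          fluff_density = 0.1, haircut = FALSE,
                          score_min = 4) {
  nv <- igraph::vcount(graph)
  params <- list(vwp = vwp, fluff = fluff, fluff_density = fluff_density,
                 haircut = haircut, score_min = score_min)
  if (nv == 0)
    return(structure(list(modules = list(), params = params),
                     class = "module_set"))
  w <- mcode_vertex_weights(graph)
  nbrs <- igraph::adjacent_vertices(graph, seq_len(nv))
  nbrs <- lapply(nbrs, as.integer)
  nhd_density <- vapply(seq_len(nv), function(i) {
    nb <- unique(c(i, nbrs[[i]]))
    graph_density(igraph::induced_subgraph(graph, nb))
  }, numeric(1))
  seen <- logical(nv)
  seed_order <- order(-w, names(w))
  modules <- list()
  for (s in seed_order) {
    if (seen[s]) next
    thr <- w[s] * (1 - vwp)
    member <- logical(nv)
    member[s] <- TRUE; seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      cand <- unique(unlist(nbrs[frontier]))
      cand <- cand[!seen[cand] & w[cand] >= thr]
      seen[cand] <- TRUE
      member[cand] <- TRUE
      frontier <- cand
    }
    core <- which(member)
    if (haircut && length(core) > 1) {
      sub <- igraph::induced_subgraph(graph, core)
      core <- core[igraph::degree(sub) >= 2]
    }
    if (length(core) < 2) next
    score <- graph_density(igraph::induced_subgraph(graph, core)) *
      length(core)
    nodes <- core
    if (fluff) {
      periph <- setdiff(unique(unlist(nbrs[core])), core)
      periph <- periph[nhd_density[periph] > fluff_density & !seen[periph]]
      nodes <- c(core, periph)
    }
    if (score > score_min)
      modules[[length(modules) + 1]] <-
        list(nodes = names(w)[sort(nodes)],
             core_nodes = names(w)[sort(core)],
             score = unname(score),
             weights = w[sort(nodes)])
  }
  structure(list(modules = modules, params = params), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s) (score > %s)\n",
              length(x$modules), x$params$score_min))
  for (i in seq_along(x$modules))
    cat(sprintf("  [%d] %d nodes (core %d), score %.2f\n", i,
                length(x$modules[[i]]$nodes),
                length(x$modules[[i]]$core_nodes), x$modules[[i]]$score))
  invisible(x)
}
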