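#' Candidate edges with Kruskal weights
#'
#' Lists every unordered gene pair with its influence value `v` and the graph
#' weight `w = 1 - |v|` used by the spanning-forest pruning (strong
#' correlation = low weight).
#'
#' @param im An `influence_matrix`.
#' @return A data frame with columns `gene_a`, `gene_b`, `v`, `w`, sorted by
#'   decreasing `|v|` with lexicographic `(gene_a, gene_b)` tie-break.
#' @export
edge_weights <- function(im) {
  stopifnot(inherits(im, "influence_matrix"))
  genes <- im$gene_ids
  if (length(genes) < 2L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      v = numeric(0), w = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- t(utils::combn(length(genes), 2L))
  v <- im$v[idx]
  df <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                   v = v, w = 1 - abs(v), stringsAsFactors = FALSE)
  df[order(-abs(df$v), df$gene_a, df$gene_b), , drop = FALSE]
}

#' Construct a regulatory network object
#'
#' @param nodes Character vector of gene ids.
#' @param edges Data frame with columns `gene_a`, `gene_b`, `v`.
#' @param threshold The `|v|` cutoff that produced the edge set.
#' @param mode `"forest"` or `"threshold"` (or `"unknown"` for networks read
#'   back from disk).
#' @return A `regulatory_network` object.
#' @export
regulatory_network <- function(nodes, edges, threshold, mode) {
  nodes <- as.character(nodes)
  if (any(edges$gene_a == edges$gene_b)) stop("self-edge in network")
  lo <- pmin(edges$gene_a, edges$gene_b)
  hi <- pmax(edges$gene_a, edges$gene_b)
  edges <- data.frame(gene_a = lo, gene_b = hi, v = edges$v,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(paste(edges$gene_a, edges$gene_b, sep = "\r"))) {
    stop("duplicate edge in network")
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold, mode = mode),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d edges (mode %s, threshold %s)\n",
              length(x$nodes), nrow(x$edges), x$mode, format(x$threshold)))
  invisible(x)
}

#' Prune candidate edges with thresholded Kruskal
#'
#' Processes candidate edges in decreasing `|v|` (equivalently increasing
#' `w = 1 - |v|`), stopping at the first edge whose `|v|` falls below the
#' threshold. In `"forest"` mode an edge joining two already-connected genes
#' is skipped (disjoint-set union), so the result is a minimum-weight spanning
#' forest of the above-threshold graph; in `"threshold"` mode every edge with
#' `|v| >= threshold` is kept. Retained edges carry their signed `v`.
#'
#' @param candidates Data frame with columns `gene_a`, `gene_b`, `v` (e.g.
#'   from [edge_weights()]); need not be pre-sorted.
#' @param threshold Real in `[0, 1]`; the minimum `|v|` an edge must reach.
#' @param mode `"forest"` (default) or `"threshold"`.
#' @param nodes Optional node universe; defaults to endpoints seen in
#'   `candidates`.
#' @return A `regulatory_network`.
#' @details Ties in `|v|` are broken by lexicographic `(gene_a, gene_b)`
#'   order, so output is deterministic.
#' @export
kruskal_threshold <- function(candidates, threshold, mode = c("forest", "threshold"),
                              nodes = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("parameter error: threshold must lie in [0, 1]")
  }
  lo <- pmin(candidates$gene_a, candidates$gene_b)
  hi <- pmax(candidates$gene_a, candidates$gene_b)
  cand <- data.frame(gene_a = lo, gene_b = hi, v = candidates$v,
                     stringsAsFactors = FALSE)
  cand <- cand[order(-abs(cand$v), cand$gene_a, cand$gene_b), , drop = FALSE]
  if (is.null(nodes)) nodes <- sort(unique(c(cand$gene_a, cand$gene_b)))

  keep <- logical(nrow(cand))
  if (mode == "threshold") {
    keep <- abs(cand$v) >= threshold
  } else {
    parent <- seq_along(nodes)
    names(parent) <- nodes
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(cand))) {
      if (abs(cand$v[r]) < threshold) break  # sorted: nothing later qualifies
      ra <- find(match(cand$gene_a[r], nodes))
      rb <- find(match(cand$gene_b[r], nodes))
      if (ra != rb) {
        parent[ra] <- rb
        keep[r] <- TRUE
      }
    }
  }
  regulatory_network(nodes, cand[keep, , drop = FALSE], threshold, mode)
}

#' Full inference pipeline: expression matrix to network
#'
#' Convenience wrapper chaining [discretize_matrix()], [influence_matrix()],
#' [edge_weights()] and [kruskal_threshold()].
#'
#' @param m Expression matrix, genes in rows.
#' @param k Number of discretization levels.
#' @param threshold Minimum `|v|` for a retained edge.
#' @param mode Pruning mode, see [kruskal_threshold()].
#' @param pair_mode,include_zero_votes,match See [influence_matrix()].
#' @param seed Unused by the deterministic pipeline; accepted for interface
#'   stability.
#' @return A list with elements `network` (`regulatory_network`) and
#'   `influence` (`influence_matrix`).
#' @export
infer_network <- function(m, k = 2L, threshold = 0.8,
                          mode = c("forest", "threshold"),
                          pair_mode = c("unordered", "ordered"),
                          include_zero_votes = TRUE,
                          match = c("strict", "sign"), seed = NULL) {
  mode <- match.arg(mode)
  d <- discretize_matrix(m, k = k, seed = seed)
  im <- influence_matrix(d, mode = match.arg(pair_mode),
                         include_zero_votes = include_zero_votes,
                         match = match.arg(match))
  net <- kruskal_threshold(edge_weights(im), threshold, mode = mode,
                           nodes = im$gene_ids)
  list(network = net, influence = im)
}
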