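#' Differential comparison of two inferred networks
#'
#' Contrasts two regulatory networks (e.g. diseased vs. normal) edge by edge.
#' Edges are keyed by unordered endpoint pair: shared edges are annotated with
#' the absolute influence difference `delta = |v_a - v_b|`, the rest are
#' partitioned by the network they came from. Shared edges whose sign flips
#' between conditions (promote in one, inhibit in the other) are flagged,
#' since a sign flip with similar strength is the kind of disruption that
#' generates condition-specific hypotheses.
#'
#' @param a,b `regulatory_network` objects; node sets may differ.
#' @param labels Character vector of length 2 naming the two conditions.
#' @return A `network_diff`: list with data frames `shared` (`gene_a`,
#'   `gene_b`, `v_a`, `v_b`, `delta`, `sign_flip`), `only_a`, `only_b`, and
#'   `labels`.
#' @export
diff_networks <- function(a, b, labels = c("A", "B")) {
  stopifnot(inherits(a, "regulatory_network"), inherits(b, "regulatory_network"),
            length(labels) == 2L)
  ea <- a$edges; eb <- b$edges
  ka <- paste(ea$gene_a, ea$gene_b, sep = "\r")
  kb <- paste(eb$gene_a, eb$gene_b, sep = "\r")
  common <- intersect(ka, kb)
  ia <- match(common, ka); ib <- match(common, kb)
  shared <- data.frame(
    gene_a = ea$gene_a[ia], gene_b = ea$gene_b[ia],
    v_a = ea$v[ia], v_b = eb$v[ib],
    delta = abs(ea$v[ia] - eb$v[ib]),
    sign_flip = sign(ea$v[ia]) != sign(eb$v[ib]),
    stringsAsFactors = FALSE
  )
  only_a <- ea[!(ka %in% kb), , drop = FALSE]
  only_b <- eb[!(kb %in% ka), , drop = FALSE]
  rownames(shared) <- rownames(only_a) <- rownames(only_b) <- NULL
  structure(list(shared = shared, only_a = only_a, only_b = only_b,
                 labels = as.character(labels)),
            class = "network_diff")
}

#' @export
print.network_diff <- function(x, ...) {
  cat(sprintf("network_diff (%s vs %s): %d shared, %d only in %s, %d only in %s\n",
              x$labels[1L], x$labels[2L], nrow(x$shared),
              nrow(x$only_a), x$labels[1L], nrow(x$only_b), x$labels[2L]))
  invisible(x)
}

#' Write a network diff report
#'
#' @param diff A `network_diff`.
#' @param path Output TSV path. Columns: `gene_a`, `gene_b`, `status`
#'   (`shared` or one of the condition labels), `v_a`, `v_b`, `delta`,
#'   `sign_flip`.
#' @param dot_path Optional Graphviz DOT output following the color
#'   convention: red = exclusive to the first network, green = exclusive to
#'   the second, black = shared (labelled with delta).
#' @param highlight Optional gene ids to fill yellow in the DOT output (e.g.
#'   genes with altered copy number).
#' @export
write_diff <- function(diff, path, dot_path = NULL, highlight = character(0)) {
  stopifnot(inherits(diff, "network_diff"))
  s <- diff$shared
  rows <- rbind(
    if (nrow(s) > 0L)
      data.frame(gene_a = s$gene_a, gene_b = s$gene_b, status = "shared",
                 v_a = s$v_a, v_b = s$v_b, delta = s$delta,
                 sign_flip = s$sign_flip, stringsAsFactors = FALSE),
    if (nrow(diff$only_a) > 0L)
      data.frame(gene_a = diff$only_a$gene_a, gene_b = diff$only_a$gene_b,
                 status = diff$labels[1L], v_a = diff$only_a$v, v_b = NA_real_,
                 delta = NA_real_, sign_flip = NA, stringsAsFactors = FALSE),
    if (nrow(diff$only_b) > 0L)
      data.frame(gene_a = diff$only_b$gene_a, gene_b = diff$only_b$gene_b,
                 status = diff$labels[2L], v_a = NA_real_, v_b = diff$only_b$v,
                 delta = NA_real_, sign_flip = NA, stringsAsFactors = FALSE)
  )
  if (is.null(rows)) {
    rows <- data.frame(gene_a = character(0), gene_b = character(0),
                       status = character(0), v_a = numeric(0), v_b = numeric(0),
                       delta = numeric(0), sign_flip = logical(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dot_path)) {
    nodes <- sort(unique(c(rows$gene_a, rows$gene_b)))
    out <- c(
      "graph network_diff {",
      sprintf("  \"%s\"%s;", nodes,
              ifelse(nodes %in% highlight,
                     " [style=filled, fillcolor=yellow]", "")),
      if (nrow(s) > 0L)
        sprintf("  \"%s\" -- \"%s\" [label=\"%.3f\"];", s$gene_a, s$gene_b, s$delta),
      if (nrow(diff$only_a) > 0L)
        sprintf("  \"%s\" -- \"%s\" [color=red];",
                diff$only_a$gene_a, diff$only_a$gene_b),
      if (nrow(diff$only_b) > 0L)
        sprintf("  \"%s\" -- \"%s\" [color=green];",
                diff$only_b$gene_a, diff$only_b$gene_b),
      "}"
    )
    writeLines(out, dot_path)
  }
  invisible(path)
}
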