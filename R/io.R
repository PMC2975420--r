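#' Read an expression matrix from delimited text
#'
#' Reads a tab- or comma-delimited gene-by-sample expression table. The first
#' row holds sample identifiers and the first column gene identifiers (or the
#' transpose, when `orientation = "genes-in-columns"`). The result is always
#' normalized to genes in rows.
#'
#' @param path Path to a TSV/CSV file. The delimiter is sniffed from the
#'   header line: tab if present, otherwise comma.
#' @param orientation Either `"genes-in-rows"` (default) or
#'   `"genes-in-columns"` (DREAM-style files place genes in columns).
#' @return A numeric matrix, genes in rows, with `rownames` = gene ids and
#'   `colnames` = sample ids, both preserved verbatim and case-sensitive.
#' @details Missing or non-numeric cells are a hard error (no imputation):
#'   vote tallies downstream would silently change under any fill-in rule.
#'   Duplicate gene or sample identifiers are rejected, as is a matrix with
#'   fewer than 2 samples.
#' @export
read_expression <- function(path, orientation = c("genes-in-rows", "genes-in-columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("format error: expression file needs a header line and at least one data row: ", path)
  }
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(
    text = lines, sep = sep, header = TRUE, check.names = FALSE,
    colClasses = "character", comment.char = "", quote = "\"",
    stringsAsFactors = FALSE
  )
  if (ncol(df) < 2L) stop("format error: no data columns found in ", path)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    vapply(seq_along(body), function(j) as.numeric(body[[j]]), numeric(nrow(body)))
  )
  vals <- matrix(vals, nrow = nrow(body), ncol = ncol(body))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "format error: non-numeric or missing value at row '%s', column '%s'",
      row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]
    ))
  }
  dimnames(vals) <- list(row_ids, col_ids)
  m <- if (orientation == "genes-in-columns") t(vals) else vals
  validate_expression(m)
  m
}

#' Validate an expression matrix
#'
#' @param m Numeric matrix, genes in rows, dimnames set.
#' @return `m`, invisibly, after checking invariants.
#' @keywords internal
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix requires gene (row) and sample (column) identifiers")
  }
  if (anyDuplicated(rownames(m))) {
    stop("format error: duplicate gene identifier: ",
         rownames(m)[duplicated(rownames(m))][1L])
  }
  if (anyDuplicated(colnames(m))) {
    stop("format error: duplicate sample identifier: ",
         colnames(m)[duplicated(colnames(m))][1L])
  }
  if (nrow(m) < 1L) stop("dimension error: at least 1 gene required")
  if (ncol(m) < 2L) stop("dimension error: at least 2 samples required")
  if (any(!is.finite(m))) stop("format error: non-finite expression value")
  invisible(m)
}

#' Write an expression (or discretized) matrix as TSV
#'
#' @param m Numeric or integer matrix with dimnames (genes in rows).
#' @param path Output path.
#' @param id_column Header label for the gene-id column.
#' @details Values are written with the shortest decimal representation that
#'   parses back to the identical double, so [read_expression()] round-trips
#'   losslessly.
#' @export
write_expression <- function(m, path, id_column = "gene") {
  body <- if (is.integer(m)) {
    matrix(as.character(m), nrow = nrow(m))
  } else {
    matrix(format_full(m), nrow = nrow(m))
  }
  lines <- c(
    paste(c(id_column, colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], body[i, ]), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

# shortest decimal string that round-trips to the same double
format_full <- function(x) {
  vapply(as.numeric(x), function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, "")
}

#' Read a DREAM-style gold standard
#'
#' Parses a three-column whitespace-separated edge list (`gene gene {0|1}`).
#' Pairs with indicator 1 become undirected edges; reciprocal directed
#' duplicates collapse to one edge; absent pairs are treated as 0.
#'
#' @param path Path to the gold-standard file.
#' @param universe Character vector of gene ids defining the candidate pairs.
#' @return A `gold_standard` object: list with `edges` (two-column character
#'   matrix, endpoints sorted within each row) and `universe`.
#' @export
read_gold_standard <- function(path, universe) {
  if (!file.exists(path)) stop("file not found: ", path)
  universe <- as.character(universe)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gold_standard(character(0), character(0), universe))
  parts <- strsplit(trimws(lines), "[ \t]+")
  n_tok <- lengths(parts)
  if (any(n_tok != 3L)) {
    stop("format error: gold standard line without exactly 3 fields: ",
         lines[which(n_tok != 3L)[1L]])
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  ind <- vapply(parts, `[[`, "", 3L)
  if (!all(ind %in% c("0", "1"))) {
    stop("format error: gold standard indicator must be 0 or 1")
  }
  missing_ids <- setdiff(c(a, b), universe)
  if (length(missing_ids) > 0L) {
    stop("reference error: gold standard gene not in universe: ", missing_ids[1L])
  }
  if (any(a == b)) stop("format error: self-pair in gold standard: ", a[a == b][1L])
  keep <- ind == "1"
  gold_standard(a[keep], b[keep], universe)
}

#' Construct a gold standard from endpoint vectors
#'
#' @param a,b Character vectors of edge endpoints (directed duplicates and
#'   repeated pairs collapse).
#' @param universe Character vector of all gene ids.
#' @return A `gold_standard` object.
#' @export
gold_standard <- function(a, b, universe) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("duplicate gene id in universe")
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("endpoint vectors differ in length")
  if (any(a == b)) stop("format error: self-pair")
  if (!all(c(a, b) %in% universe)) {
    stop("reference error: edge endpoint not in universe")
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  edges <- cbind(lo[keep], hi[keep])
  colnames(edges) <- c("gene_a", "gene_b")
  o <- order(edges[, 1L], edges[, 2L])
  structure(
    list(edges = edges[o, , drop = FALSE], universe = universe),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d undirected edges over %d genes (%d candidate pairs)\n",
              nrow(x$edges), length(x$universe),
              choose(length(x$universe), 2L)))
  invisible(x)
}

#' Write a regulatory network to disk
#'
#' @param network A `regulatory_network` (see [kruskal_threshold()]).
#' @param path Output path.
#' @param format `"tsv"` (edge-list, round-trips through [read_network()]),
#'   `"sif"` (Cytoscape simple interaction format, relation = promote/inhibit)
#'   or `"dot"` (Graphviz).
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  sign_lab <- ifelse(e$v < 0, "inhibit", "promote")
  out <- switch(format,
    tsv = c(
      "gene_a\tgene_b\tv\tsign",
      if (nrow(e) > 0L)
        sprintf("%s\t%s\t%s\t%s", e$gene_a, e$gene_b, format_full(e$v), sign_lab)
    ),
    sif = if (nrow(e) > 0L) sprintf("%s %s %s", e$gene_a, sign_lab, e$gene_b) else character(0),
    dot = c(
      "graph regulatory_network {",
      sprintf("  \"%s\";", network$nodes),
      if (nrow(e) > 0L)
        sprintf("  \"%s\" -- \"%s\" [label=\"%.3f\", style=%s];",
                e$gene_a, e$gene_b, e$v,
                ifelse(e$v < 0, "dashed", "solid")),
      "}"
    )
  )
  writeLines(out, path)
  invisible(path)
}

#' Read a regulatory network from edge-list TSV
#'
#' Inverse of [write_network()] with `format = "tsv"`.
#'
#' @param path Path to an edge-list TSV (`gene_a gene_b v sign` header).
#' @param nodes Optional character vector of node ids; defaults to the union
#'   of edge endpoints.
#' @return A `regulatory_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric", "character"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "v") %in% colnames(df))) {
    stop("format error: network TSV requires columns gene_a, gene_b, v")
  }
  if (is.null(nodes)) nodes <- sort(unique(c(df$gene_a, df$gene_b)))
  regulatory_network(
    nodes = nodes,
    edges = data.frame(gene_a = df$gene_a, gene_b = df$gene_b, v = df$v,
                       stringsAsFactors = FALSE),
    threshold = NA_real_, mode = "unknown"
  )
}
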