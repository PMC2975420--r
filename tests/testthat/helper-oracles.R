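# Independent brute-force oracles. These re-derive expected values by
# exhaustive enumeration and deliberately share no code with the package.

# Exact 1-D k-means by enumerating every contiguous partition of the sorted
# distinct values into at most k groups (n <= 12, k <= 3 scale).
oracle_kmeans_1d <- function(values, k) {
  uniq <- sort(unique(values))
  m <- length(uniq)
  k_eff <- min(k, m)
  sse_of <- function(groups) {
    sum(vapply(groups, function(g) {
      xs <- values[values %in% g]
      sum((xs - mean(xs))^2)
    }, 0))
  }
  best <- NULL
  best_sse <- Inf
  if (k_eff == m) {
    boundaries_list <- list(seq_len(m))
  } else {
    cuts <- utils::combn(m - 1L, k_eff - 1L, simplify = FALSE)
    boundaries_list <- lapply(cuts, function(cc) c(cc, m))
  }
  for (bounds in boundaries_list) {
    groups <- mapply(function(lo, hi) uniq[lo:hi],
                     c(1L, head(bounds, -1L) + 1L), bounds, SIMPLIFY = FALSE)
    s <- sse_of(groups)
    if (s < best_sse - 1e-12) { best_sse <- s; best <- groups }
  }
  labels <- integer(length(values))
  for (i in seq_along(best)) labels[values %in% best[[i]]] <- i - 1L
  labels
}

# Vote tallies by explicit double loop over sample pairs.
oracle_tally <- function(levels_x, levels_y, pairs) {
  p <- n <- q <- u <- 0L
  for (r in seq_len(nrow(pairs))) {
    dx <- levels_x[pairs[r, 2L]] - levels_x[pairs[r, 1L]]
    dy <- levels_y[pairs[r, 2L]] - levels_y[pairs[r, 1L]]
    if (dx == dy && dx != 0) p <- p + 1L
    else if (dx == -dy && dx != 0) n <- n + 1L
    else if (dx == 0 && dy == 0) q <- q + 1L
    else u <- u + 1L
  }
  list(p_same = p, n_opposed = n, q_zero = q, u_mixed = u, total = nrow(pairs))
}

# Minimum spanning tree by enumerating every (n-1)-edge subset (<= 7 nodes).
# Returns the edge rows of the minimum-total-weight spanning tree.
oracle_mst <- function(nodes, edges_df, weight_col = "w") {
  n <- length(nodes)
  if (nrow(edges_df) < n - 1L) stop("graph too sparse for a spanning tree")
  combos <- utils::combn(nrow(edges_df), n - 1L, simplify = FALSE)
  spans <- function(rows) {
    comp <- seq_len(n)
    for (r in rows) {
      a <- match(edges_df$gene_a[r], nodes)
      b <- match(edges_df$gene_b[r], nodes)
      ca <- comp[a]; cb <- comp[b]
      if (ca == cb) return(FALSE)  # cycle
      comp[comp == cb] <- ca
    }
    length(unique(comp)) == 1L
  }
  best <- NULL; best_w <- Inf
  for (rows in combos) {
    if (!spans(rows)) next
    w <- sum(edges_df[[weight_col]][rows])
    if (w < best_w - 1e-12) { best_w <- w; best <- rows }
  }
  edges_df[sort(best), , drop = FALSE]
}

# AUROC by explicit confusion-matrix sweep over every distinct score cut,
# trapezoidal integration of the ROC points.
oracle_auroc <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    called <- scores >= cuts[i]
    tpr[i] <- sum(called & labels == 1L) / n_pos
    fpr[i] <- sum(called & labels == 0L) / n_neg
  }
  sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}

# Average precision by explicit loop down a strict ranking of labels.
oracle_aupr <- function(labels_in_order) {
  tp <- 0L
  precisions <- c()
  for (i in seq_along(labels_in_order)) {
    if (labels_in_order[i] == 1L) {
      tp <- tp + 1L
      precisions <- c(precisions, tp / i)
    }
  }
  mean(precisions)
}
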