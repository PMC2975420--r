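#' Exact 1-D k-means labels
#'
#' Assigns each value an activation level in `0..k-1` by the sum-of-squared-
#' error-minimizing clustering of the values into at most `k` groups. In one
#' dimension the optimal clusters are contiguous runs of the sorted values, so
#' the global optimum is found by dynamic programming over contiguous
#' partitions of the distinct values — no random initialization, no restarts,
#' fully deterministic. Levels are ordered by cluster mean: a sample with a
#' higher raw value never gets a lower level.
#'
#' @param values Numeric vector (one gene's profile across samples).
#' @param k Number of levels, integer >= 1. When the vector has fewer distinct
#'   values than `k`, the number of occupied levels equals the number of
#'   distinct values.
#' @param seed Ignored by the exact solver; accepted so callers can pass one
#'   uniformly across stochastic and deterministic stages.
#' @return Integer vector of labels in `[0, k-1]`, same length as `values`.
#' @details Tied raw values always receive the same label: the partition is
#'   computed over distinct values with multiplicity weights, so a boundary
#'   can never split a tie.
#' @export
kmeans_1d <- function(values, k, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("parameter error: k must be an integer >= 1")
  }
  k <- as.integer(k)
  if (length(values) == 0L) stop("parameter error: empty value vector")
  if (any(!is.finite(values))) stop("format error: non-finite value")
  uniq <- sort(unique(values))
  m <- length(uniq)
  w <- as.numeric(table(factor(values, levels = uniq)))
  k_eff <- min(k, m)
  boundaries <- kmeans_1d_partition(uniq, w, k_eff)
  # boundaries[i] = last distinct-value index of cluster i; clusters sorted ascending
  level_of <- rep.int(seq_len(k_eff) - 1L, diff(c(0L, boundaries)))
  level_of[match(values, uniq)]
}

# DP over contiguous partitions of weighted distinct values.
# Returns the right boundary index of each of k clusters (ascending).
kmeans_1d_partition <- function(uniq, w, k) {
  m <- length(uniq)
  if (k >= m) return(seq_len(m))
  cw <- cumsum(w)
  cs <- cumsum(w * uniq)
  cs2 <- cumsum(w * uniq^2)
  sse <- function(i, j) {
    W <- cw[j] - if (i > 1L) cw[i - 1L] else 0
    S <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    S2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    S2 - S^2 / W
  }
  cost <- matrix(Inf, nrow = m, ncol = k)
  back <- matrix(0L, nrow = m, ncol = k)
  for (j in seq_len(m)) cost[j, 1L] <- sse(1L, j)
  if (k > 1L) {
    for (c in 2L:k) {
      for (j in c:m) {
        best <- Inf; arg <- 0L
        for (s in (c - 1L):(j - 1L)) {  # last index of cluster c-1
          val <- cost[s, c - 1L] + sse(s + 1L, j)
          if (val < best - 1e-12) { best <- val; arg <- s }
        }
        cost[j, c] <- best
        back[j, c] <- arg
      }
    }
  }
  bounds <- integer(k)
  bounds[k] <- m
  if (k > 1L) {
    for (c in k:2L) bounds[c - 1L] <- back[bounds[c], c]
  }
  bounds
}

#' Discretize an expression matrix gene-by-gene
#'
#' Each gene's profile across all samples is treated as one independent
#' dataset and clustered with [kmeans_1d()], producing an integer activation
#' level in `0..k-1` per cell.
#'
#' @param m Numeric expression matrix, genes in rows (see [read_expression()]).
#' @param k Number of activation levels per gene (default 2).
#' @param seed Passed through to [kmeans_1d()]; unused by the exact solver.
#' @return Integer matrix of the same shape and dimnames, with attribute `k`.
#' @export
discretize_matrix <- function(m, k = 2L, seed = NULL) {
  validate_expression(m)
  out <- t(apply(m, 1L, kmeans_1d, k = k, seed = seed))
  dimnames(out) <- dimnames(m)
  storage.mode(out) <- "integer"
  attr(out, "k") <- as.integer(k)
  out
}
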