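#' Enumerate sample pairs
#'
#' @param n_samples Number of samples, >= 1.
#' @param mode `"unordered"` (all `C(n,2)` index pairs with i < j, the
#'   default) or `"ordered"` (all `n(n-1)` directed pairs). The influence
#'   value is provably identical under either mode; ordered is kept because
#'   some study designs count directed comparisons.
#' @return Integer matrix with columns `a`, `b`, one row per pair.
#' @export
enumerate_sample_pairs <- function(n_samples, mode = c("unordered", "ordered")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != floor(n_samples)) {
    stop("parameter error: n_samples must be an integer >= 1")
  }
  n <- as.integer(n_samples)
  if (n < 2L) {
    out <- matrix(integer(0), ncol = 2L)
  } else if (mode == "unordered") {
    out <- t(utils::combn(n, 2L))
  } else {
    g <- expand.grid(a = seq_len(n), b = seq_len(n))
    g <- g[g$a != g$b, , drop = FALSE]
    out <- as.matrix(g[order(g$a, g$b), , drop = FALSE])
  }
  dimnames(out) <- list(NULL, c("a", "b"))
  out
}

#' Tally change-correlation votes for one gene pair
#'
#' For each sample pair `(a, b)` the activation changes `dx = x[b] - x[a]` and
#' `dy = y[b] - y[a]` are classified into one of four categories:
#' * `p_same` — equal, non-zero changes (`dx == dy != 0`); evidence that the
#'   genes move together.
#' * `n_opposed` — equal-magnitude, opposing-signed changes (`dx == -dy != 0`);
#'   evidence for inhibition.
#' * `q_zero` — both changes zero; counted as (weak) positive evidence, since
#'   neither gene moved.
#' * `u_mixed` — everything else.
#'
#' @param levels_x,levels_y Integer level vectors of equal length.
#' @param pairs Index-pair matrix from [enumerate_sample_pairs()].
#' @param match `"strict"` (default): changes must match in magnitude and
#'   sign. `"sign"`: only signs are compared (relevant for k > 2).
#' @return A `pair_tally`: list with counts `p_same`, `n_opposed`, `q_zero`,
#'   `u_mixed` and `total`; the four counts always sum to `total`.
#' @export
tally_pair <- function(levels_x, levels_y, pairs, match = c("strict", "sign")) {
  match <- match.arg(match)
  if (length(levels_x) != length(levels_y)) {
    stop("dimension error: level vectors differ in length")
  }
  dx <- levels_x[pairs[, 2L]] - levels_x[pairs[, 1L]]
  dy <- levels_y[pairs[, 2L]] - levels_y[pairs[, 1L]]
  if (match == "sign") { dx <- sign(dx); dy <- sign(dy) }
  p <- sum(dx == dy & dx != 0)
  n <- sum(dx == -dy & dx != 0)
  q <- sum(dx == 0 & dy == 0)
  total <- nrow(pairs)
  pair_tally(p, n, q, total - p - n - q, total)
}

#' @rdname tally_pair
#' @param p_same,n_opposed,q_zero,u_mixed,total Vote counts.
#' @export
pair_tally <- function(p_same, n_opposed, q_zero, u_mixed, total) {
  t <- list(p_same = p_same, n_opposed = n_opposed, q_zero = q_zero,
            u_mixed = u_mixed, total = total)
  if (any(unlist(t) < 0)) stop("invalid tally: negative count")
  if (p_same + n_opposed + q_zero + u_mixed != total) {
    stop("invalid tally: counts do not sum to total")
  }
  structure(t, class = "pair_tally")
}

#' Influence value from a vote tally
#'
#' The degree of correlation between two genes: the net vote fraction over all
#' sample pairs. With zero-change votes included (the default),
#' `v = (p_same + q_zero - n_opposed) / total`; with them excluded,
#' `v = (p_same - n_opposed) / total`. A negative `v` indicates an inhibiting
#' relation, a positive `v` a promoting one; `|v|` is the evidence strength.
#'
#' @param t A `pair_tally`.
#' @param include_zero_votes Count both-unchanged sample pairs as positive
#'   votes (default `TRUE`).
#' @return Signed real in `[-1, 1]`.
#' @export
influence_value <- function(t, include_zero_votes = TRUE) {
  stopifnot(inherits(t, "pair_tally"))
  if (t$total == 0) stop("undefined-value error: tally over zero sample pairs")
  num <- t$p_same - t$n_opposed + if (include_zero_votes) t$q_zero else 0
  num / t$total
}

#' Influence matrix over all gene pairs
#'
#' Tallies change-correlation votes for every unordered gene pair and computes
#' the influence value `v`. The computation is vectorized: per delta value the
#' genes-by-sample-pairs indicator matrices are cross-multiplied, so no
#' explicit loop over the `C(genes, 2)` pairs is materialized.
#'
#' @param d Integer level matrix from [discretize_matrix()] (genes in rows).
#' @param mode Sample-pair mode, see [enumerate_sample_pairs()].
#' @param include_zero_votes See [influence_value()].
#' @param match See [tally_pair()].
#' @return An `influence_matrix`: list with `gene_ids`, symmetric numeric
#'   matrix `v` (diagonal `NA`), tally matrices `p_same`, `n_opposed`,
#'   `q_zero`, `u_mixed`, scalar `total`, and the parameters used.
#' @export
influence_matrix <- function(d, mode = c("unordered", "ordered"),
                             include_zero_votes = TRUE,
                             match = c("strict", "sign")) {
  mode <- match.arg(mode)
  match <- match.arg(match)
  if (ncol(d) < 2L) stop("dimension error: at least 2 samples required")
  genes <- rownames(d)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(d)))
  pairs <- enumerate_sample_pairs(ncol(d), mode)
  delta <- d[, pairs[, 2L], drop = FALSE] - d[, pairs[, 1L], drop = FALSE]
  if (match == "sign") delta <- sign(delta)
  total <- nrow(pairs)

  ind <- function(x) {
    m <- matrix(as.numeric(x), nrow = nrow(delta))
    m
  }
  q <- ind(delta == 0) %*% t(ind(delta == 0))
  nd <- sort(unique(delta[delta != 0]))
  p <- matrix(0, nrow(delta), nrow(delta))
  n <- matrix(0, nrow(delta), nrow(delta))
  for (dv in nd) {
    e_d <- ind(delta == dv)
    p <- p + e_d %*% t(e_d)
    if (dv > 0 && -dv %in% nd) {
      cross <- e_d %*% t(ind(delta == -dv))
      n <- n + cross + t(cross)
    }
  }
  u <- total - p - n - q
  v <- (p - n + if (include_zero_votes) q else 0) / total
  diag(v) <- NA_real_
  dimnames(v) <- dimnames(p) <- dimnames(n) <- dimnames(q) <- dimnames(u) <-
    list(genes, genes)
  structure(
    list(gene_ids = genes, v = v,
         p_same = p, n_opposed = n, q_zero = q, u_mixed = u, total = total,
         mode = mode, include_zero_votes = include_zero_votes, match = match),
    class = "influence_matrix"
  )
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("influence_matrix: %d genes, %d sample pairs (%s mode, zero votes %s)\n",
              length(x$gene_ids), x$total, x$mode,
              if (x$include_zero_votes) "on" else "off"))
  invisible(x)
}

#' Extract the tally for one gene pair from an influence matrix
#'
#' @param im An `influence_matrix`.
#' @param x,y Gene ids or indices.
#' @return A `pair_tally`.
#' @export
pair_tally_of <- function(im, x, y) {
  stopifnot(inherits(im, "influence_matrix"))
  pair_tally(im$p_same[x, y], im$n_opposed[x, y], im$q_zero[x, y],
             im$u_mixed[x, y], im$total)
}
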