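#' Rank candidate gene pairs by evidence strength
#'
#' Orders all candidate pairs by decreasing `|v|`, with lexicographic
#' `(gene_a, gene_b)` tie-break, as required by the ROC/PR scoring.
#'
#' @param im An `influence_matrix`.
#' @return Data frame `gene_a`, `gene_b`, `v`, `score = |v|`, best first.
#' @export
rank_predictions <- function(im) {
  ew <- edge_weights(im)
  data.frame(gene_a = ew$gene_a, gene_b = ew$gene_b, v = ew$v,
             score = abs(ew$v), stringsAsFactors = FALSE)
}

# 0/1 labels of a ranking against a gold standard, in ranking order
gold_labels <- function(ranking, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  lo <- pmin(ranking$gene_a, ranking$gene_b)
  hi <- pmax(ranking$gene_a, ranking$gene_b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) stop("ranking contains duplicate pairs")
  gkey <- paste(gold$edges[, 1L], gold$edges[, 2L], sep = "\r")
  if (!all(gkey %in% key)) {
    stop("ranking does not cover every gold-standard pair")
  }
  as.integer(key %in% gkey)
}

#' Area under the ROC curve of a ranked edge prediction
#'
#' @param ranking Data frame from [rank_predictions()] covering every
#'   candidate pair of the gold universe; must carry a `score` column.
#' @param gold A `gold_standard`.
#' @return AUROC in `[0, 1]`. Tied scores are handled by trapezoidal
#'   averaging over the tied block (mid-rank Mann-Whitney statistic).
#' @export
auroc <- function(ranking, gold) {
  labels <- gold_labels(ranking, gold)
  auroc_from_scores(ranking$score, labels)
}

auroc_from_scores <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined-metric error: gold standard needs at least one edge and one non-edge")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve of a ranked edge prediction
#'
#' Average precision: descending the ranking, precision is recorded at each
#' recall step (each true edge encountered) and averaged.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(ranking, gold) {
  labels <- gold_labels(ranking, gold)
  o <- order(-ranking$score)
  aupr_from_order(labels[o])
}

aupr_from_order <- function(labels_in_order) {
  n_pos <- sum(labels_in_order == 1L)
  if (n_pos == 0L) stop("undefined-metric error: gold standard has no edges")
  hits <- which(labels_in_order == 1L)
  mean(seq_along(hits) / hits)
}

#' Empirical random-network p-values for AUROC and AUPR
#'
#' Draws `n_null` uniformly random rankings of the candidate pairs
#' (equivalent to scoring random networks of the same size against the gold
#' standard) and reports the add-one tail probabilities
#' `p = (1 + #(null >= observed)) / (1 + n_null)`, so p is never zero and the
#' combined score stays finite.
#'
#' @param auroc_obs,aupr_obs Observed metric values.
#' @param n_pairs Number of candidate pairs in the universe.
#' @param n_edges Number of gold-standard edges (positives).
#' @param n_null Number of random rankings (default 10000; raise towards
#'   100000 for publication-grade tails).
#' @param seed Integer seed; the draw is reproducible.
#' @return List with `auroc_p`, `aupr_p`, `n_null` and the null samples
#'   (`null_auroc`, `null_aupr`).
#' @export
empirical_pvalues <- function(auroc_obs, aupr_obs, n_pairs, n_edges,
                              n_null = 10000L, seed = 1L) {
  if (n_null < 1L) stop("parameter error: n_null must be >= 1")
  if (n_edges < 1L || n_edges >= n_pairs) {
    stop("undefined-metric error: need 1 <= n_edges < n_pairs")
  }
  set.seed(seed)
  n_neg <- n_pairs - n_edges
  null_auroc <- numeric(n_null)
  null_aupr <- numeric(n_null)
  for (i in seq_len(n_null)) {
    pos <- sort.int(sample.int(n_pairs, n_edges))
    # a random ranking is fully determined by the positions of the positives
    null_auroc[i] <- (sum(n_pairs + 1 - pos) - n_edges * (n_edges + 1) / 2) /
      (n_edges * n_neg)
    null_aupr[i] <- mean(seq_len(n_edges) / pos)
  }
  eps <- 1e-12  # guard against float noise in >= comparisons
  list(
    auroc_p = (1 + sum(null_auroc >= auroc_obs - eps)) / (1 + n_null),
    aupr_p = (1 + sum(null_aupr >= aupr_obs - eps)) / (1 + n_null),
    n_null = n_null, null_auroc = null_auroc, null_aupr = null_aupr
  )
}

#' Combined log-transformed score
#'
#' `score = -log10(auroc_p * aupr_p) / 2`: the average order of magnitude of
#' the two tail probabilities.
#'
#' @param auroc_p,aupr_p p-values in `(0, 1]`.
#' @return Non-negative real.
#' @export
combined_score <- function(auroc_p, aupr_p) {
  if (any(c(auroc_p, aupr_p) <= 0) || any(c(auroc_p, aupr_p) > 1)) {
    stop("domain error: p-values must lie in (0, 1]")
  }
  -log10(auroc_p * aupr_p) / 2
}

#' Score a ranked prediction against a gold standard
#'
#' Orchestrates [auroc()], [aupr()], [empirical_pvalues()] and
#' [combined_score()] into one evaluation result.
#'
#' @inheritParams auroc
#' @param n_null,seed See [empirical_pvalues()].
#' @return An `evaluation_result`: list with `auroc`, `aupr`, `auroc_p`,
#'   `aupr_p`, `score`, `n_null`.
#' @export
evaluate_ranking <- function(ranking, gold, n_null = 10000L, seed = 1L) {
  a_roc <- auroc(ranking, gold)
  a_pr <- aupr(ranking, gold)
  p <- empirical_pvalues(a_roc, a_pr, n_pairs = nrow(ranking),
                         n_edges = nrow(gold$edges), n_null = n_null, seed = seed)
  structure(
    list(auroc = a_roc, aupr = a_pr, auroc_p = p$auroc_p, aupr_p = p$aupr_p,
         score = combined_score(p$auroc_p, p$aupr_p), n_null = p$n_null),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "evaluation_result: AUROC %.4f (p = %.4g), AUPR %.4f (p = %.4g), score %.4f [%d nulls]\n",
    x$auroc, x$auroc_p, x$aupr, x$aupr_p, x$score, x$n_null))
  invisible(x)
}

#' Average evaluation results across same-sized networks
#'
#' Arithmetic mean of the AUROC and AUPR p-values across results, then the
#' combined score of the two means — the pooling used to summarize several
#' networks of the same size with a single number.
#'
#' @param results Non-empty list of `evaluation_result` objects.
#' @return An `evaluation_result` with averaged p-values and pooled score;
#'   `auroc`/`aupr` are the means of the per-result metrics.
#' @export
average_scores <- function(results) {
  if (length(results) == 0L) stop("parameter error: empty result list")
  stopifnot(all(vapply(results, inherits, TRUE, "evaluation_result")))
  auroc_p <- mean(vapply(results, `[[`, 0, "auroc_p"))
  aupr_p <- mean(vapply(results, `[[`, 0, "aupr_p"))
  structure(
    list(auroc = mean(vapply(results, `[[`, 0, "auroc")),
         aupr = mean(vapply(results, `[[`, 0, "aupr")),
         auroc_p = auroc_p, aupr_p = aupr_p,
         score = combined_score(auroc_p, aupr_p),
         n_null = sum(vapply(results, `[[`, 0L, "n_null"))),
    class = "evaluation_result"
  )
}
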