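ranking_of <- function(scores, labels) {
  n <- length(scores)
  ids <- sprintf("P%02d", seq_len(n))
  universe <- c(ids, "Z")
  gold <- gold_standard(ids[labels == 1L], rep("Z", sum(labels)), universe)
  # candidate pairs: each id paired with hub Z, plus filler pairs among ids
  # are avoided by restricting the ranking to the id-Z pairs
  ranking <- data.frame(gene_a = ids, gene_b = "Z", v = scores, score = scores,
                        stringsAsFactors = FALSE)
  list(ranking = ranking[order(-ranking$score, ranking$gene_a), ], gold = gold)
}

test_that("rank_predictions orders by |v| with lexicographic tie-break", {
  v <- matrix(NA_real_, 4, 4, dimnames = list(paste0("G", 1:4), paste0("G", 1:4)))
  v["G1", "G2"] <- v["G2", "G1"] <- -0.9
  v["G1", "G3"] <- v["G3", "G1"] <- 0.5
  v["G2", "G3"] <- v["G3", "G2"] <- 0.5
  v["G1", "G4"] <- v["G4", "G1"] <- 0.1
  v["G2", "G4"] <- v["G4", "G2"] <- 0
  v["G3", "G4"] <- v["G4", "G3"] <- 0
  im <- structure(list(gene_ids = paste0("G", 1:4), v = v), class = "influence_matrix")
  r <- rank_predictions(im)
  expect_equal(r$score[1], 0.9)
  expect_equal(paste(r$gene_a[2:3], r$gene_b[2:3]), c("G1 G3", "G2 G3"))
  expect_equal(r$score[4], 0.1)
})

test_that("AUROC handles perfect, inverted and interleaved rankings", {
  perfect <- ranking_of(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L))
  expect_equal(auroc(perfect$ranking, perfect$gold), 1.0)
  inverted <- ranking_of(c(0.9, 0.8, 0.2, 0.1), c(0L, 0L, 1L, 1L))
  expect_equal(auroc(inverted$ranking, inverted$gold), 0.0)
  # (TP, FP, TP, FP) with 2 positives and 2 negatives -> 0.75
  inter <- ranking_of(c(0.9, 0.8, 0.7, 0.6), c(1L, 0L, 1L, 0L))
  expect_equal(auroc(inter$ranking, inter$gold), 0.75)
  # all-tied scores: no discrimination -> 0.5 by trapezoidal averaging
  tied <- ranking_of(rep(0.5, 4), c(1L, 0L, 1L, 0L))
  expect_equal(auroc(tied$ranking, tied$gold), 0.5)
})

test_that("AUPR handles perfect and interleaved rankings", {
  perfect <- ranking_of(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L))
  expect_equal(aupr(perfect$ranking, perfect$gold), 1.0)
  single <- ranking_of(c(0.9, 0.5, 0.4), c(1L, 0L, 0L))
  expect_equal(aupr(single$ranking, single$gold), 1.0)
  inter <- ranking_of(c(0.9, 0.8, 0.7, 0.6), c(1L, 0L, 1L, 0L))
  expect_equal(aupr(inter$ranking, inter$gold), (1 + 2 / 3) / 2)
})

test_that("metrics refuse degenerate gold standards", {
  allpos <- ranking_of(c(0.9, 0.8), c(1L, 1L))
  expect_error(auroc(allpos$ranking, allpos$gold), "undefined-metric")
})

test_that("AUROC and AUPR match the confusion-sweep oracle on every small instance", {
  set.seed(5)
  for (n in 3:8) {
    scores <- sort(sample(seq(0.01, 0.99, by = 0.01), n), decreasing = TRUE)
    for (mask in 1:(2^n - 2)) {  # every labeling with >= 1 positive and negative
      labels <- as.integer(intToBits(mask))[1:n]
      inst <- ranking_of(scores, labels)
      expect_equal(auroc(inst$ranking, inst$gold), oracle_auroc(scores, labels))
      o <- order(-scores)
      expect_equal(aupr(inst$ranking, inst$gold), oracle_aupr(labels[o]))
    }
  }
})

test_that("reversing a tie-free ranking complements the AUROC", {
  set.seed(8)
  scores <- sample(seq(0.01, 0.99, 0.01), 12)
  labels <- c(rep(1L, 4), rep(0L, 8))
  a <- ranking_of(scores, labels)
  b <- ranking_of(1 - scores, labels)
  expect_equal(auroc(a$ranking, a$gold) + auroc(b$ranking, b$gold), 1)
})

test_that("a uniformly random ranking scores near AUROC 0.5", {
  set.seed(13)
  n <- 200; n_pos <- 40
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  aucs <- replicate(30, {
    scores <- sample(seq_len(n)) / n
    auroc_vals <- ranking_of(scores, labels)
    auroc(auroc_vals$ranking, auroc_vals$gold)
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("empirical p-values use the add-one estimator and are reproducible", {
  # observed above every achievable null -> floor p = 1/(n_null + 1)
  p_hi <- empirical_pvalues(1.01, 1.01, n_pairs = 45, n_edges = 5,
                            n_null = 99, seed = 4)
  expect_equal(p_hi$auroc_p, 1 / 100)
  expect_equal(p_hi$aupr_p, 1 / 100)
  # observed at or below every null -> p = 1
  p_lo <- empirical_pvalues(-0.1, -0.1, n_pairs = 45, n_edges = 5,
                            n_null = 99, seed = 4)
  expect_equal(p_lo$auroc_p, 1)
  expect_equal(p_lo$aupr_p, 1)
  # determinism
  a <- empirical_pvalues(0.7, 0.3, 45, 5, n_null = 200, seed = 42)
  b <- empirical_pvalues(0.7, 0.3, 45, 5, n_null = 200, seed = 42)
  expect_identical(a, b)
  # observed at the null median -> p near 0.5 (binomial bound)
  big <- empirical_pvalues(0.5, 0.5, 100, 10, n_null = 2000, seed = 6)
  med <- median(big$null_auroc)
  p_med <- empirical_pvalues(med, med, 100, 10, n_null = 2000, seed = 6)$auroc_p
  expect_lt(abs(p_med - 0.5), 3 * sqrt(0.25 / 2000) + 0.05)
})

test_that("the combined score reproduces every published score triple to 4 significant figures", {
  tab <- published_score_table()
  got <- combined_score(tab$auroc_p, tab$aupr_p)
  expect_equal(signif(got, 4), signif(tab$score, 4), tolerance = 1e-8)
  expect_equal(combined_score(0.1, 0.1), 1.0)
  expect_error(combined_score(0, 0.1), "domain error")
})

test_that("average_scores pools p-values then recombines", {
  r1 <- structure(list(auroc = 0.8, aupr = 0.5, auroc_p = 0.2, aupr_p = 0.01,
                       score = combined_score(0.2, 0.01), n_null = 100L),
                  class = "evaluation_result")
  r2 <- structure(list(auroc = 0.6, aupr = 0.3, auroc_p = 0.4, aupr_p = 0.03,
                       score = combined_score(0.4, 0.03), n_null = 100L),
                  class = "evaluation_result")
  expect_equal(average_scores(list(r1))$score, r1$score)
  avg <- average_scores(list(r1, r2))
  expect_equal(avg$auroc_p, 0.3)
  expect_equal(avg$aupr_p, 0.02)
  expect_equal(avg$score, combined_score(0.3, 0.02))
  five <- average_scores(rep(list(r1), 5))
  expect_equal(five$score, r1$score)
  expect_error(average_scores(list()), "parameter error")
})
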