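# Shared fixtures, built in code.

# The 5-gene x 9-sample pre-discretized in-silico example matrix.
table3_matrix <- function() {
  m <- rbind(
    G1 = c(0.105, 0.034, 0.927, 0.088, 0.015, 0.049, 0.102, 0.105, 0.018),
    G2 = c(0.877, 0.804, 0.000, 0.864, 0.870, 0.981, 0.837, 0.873, 0.797),
    G3 = c(0.054, 0.000, 0.838, 0.000, 0.103, 0.000, 0.069, 0.000, 0.085),
    G4 = c(0.386, 0.310, 0.611, 0.243, 0.083, 0.432, 0.440, 0.394, 0.364),
    G5 = c(0.801, 0.808, 0.748, 0.903, 0.793, 0.000, 0.880, 0.741, 0.686)
  )
  colnames(m) <- c("wt", paste0("G", 1:8, "(-/-)"))
  m
}

# The published k = 2 discretization of the same matrix (note: row G4 as
# printed is not the SSE-optimal partition; see test-discretize.R).
table3_discrete <- function() {
  d <- rbind(
    G1 = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    G2 = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L),
    G3 = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    G4 = c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 1L, 1L),
    G5 = c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L)
  )
  colnames(d) <- c("wt", paste0("G", 1:8, "(-/-)"))
  d
}

# The published per-size score table: score, AUPR p average, AUROC p average.
published_score_table <- function() {
  data.frame(
    size = rep(c(10L, 50L, 100L), each = 4L),
    type = rep(c("empty", "trajectories", "heterozygous", "null-mutant"), 3L),
    score = c(1.1816, 1.6298, 2.2401, 2.8198,
              2.4438, 2.6700, 2.6207, 14.152,
              5.2312, 3.8264, 5.2881, 37.911),
    aupr_p = c(8.5675e-03, 2.1759e-03, 3.6441e-04, 4.1550e-05,
               2.6065e-05, 6.1865e-06, 7.7215e-06, 5.2984e-26,
               6.8572e-11, 4.7395e-08, 6.3523e-11, 1.0263e-71),
    auroc_p = c(5.0578e-01, 2.5279e-01, 9.0845e-02, 5.5198e-02,
                4.9687e-01, 7.3901e-01, 7.4297e-01, 9.3634e-04,
                5.0297e-01, 4.6923e-01, 4.1762e-01, 1.4694e-05)
  )
}

write_expression_file <- function(m, path = tempfile(fileext = ".tsv")) {
  airnet::write_expression(m, path)
  path
}

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_samples), nrow = n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

random_levels <- function(n_genes, n_samples, k, seed) {
  set.seed(seed)
  matrix(sample.int(k, n_genes * n_samples, replace = TRUE) - 1L,
         nrow = n_genes,
         dimnames = list(paste0("G", seq_len(n_genes)),
                         paste0("S", seq_len(n_samples))))
}
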