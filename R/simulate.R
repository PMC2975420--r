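#' Sample a random signed truth network
#'
#' Draws `n_edges` distinct unordered gene pairs uniformly at random; each
#' edge is independently signed negative (inhibiting) with probability
#' `sign_fraction`.
#'
#' @param n_genes Number of genes (ids `G1..Gn`).
#' @param n_edges Number of edges, `0 <= n_edges <= C(n_genes, 2)`.
#' @param sign_fraction Probability an edge is inhibiting (default 0.3 — a
#'   minority of repressing links, the usual picture in curated regulatory
#'   networks).
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A `gold_standard` whose `edges` matrix carries an extra attribute
#'   `sign` (+1/-1 per edge, aligned with the rows).
#' @export
random_truth_network <- function(n_genes, n_edges, sign_fraction = 0.3, seed = 1L) {
  max_edges <- choose(n_genes, 2L)
  if (n_edges < 0 || n_edges > max_edges) {
    stop("parameter error: n_edges must lie in [0, C(n_genes, 2)]")
  }
  genes <- paste0("G", seq_len(n_genes))
  set.seed(seed)
  all_pairs <- t(utils::combn(n_genes, 2L))
  pick <- sort.int(sample.int(nrow(all_pairs), n_edges))
  signs <- ifelse(stats::runif(n_edges) < sign_fraction, -1L, 1L)
  a <- genes[all_pairs[pick, 1L]]
  b <- genes[all_pairs[pick, 2L]]
  gs <- gold_standard(a, b, genes)
  # gold_standard() sorts rows by (lo, hi); realign signs to that order
  o <- order(pmin(a, b), pmax(a, b))
  attr(gs$edges, "sign") <- signs[o]
  gs
}

#' Simulate an expression study with known ground truth
#'
#' Generates a steady-state perturbation study: one wild-type sample plus one
#' sample per gene perturbation (or per replicate). Each gene draws a baseline
#' expression level; in a perturbation sample the targeted gene is forced to 0
#' (`"null-mutant"`) or halved (`"knockdown"`), and every direct neighbor in
#' the truth network shifts by `coupling * its own baseline` — downward for a
#' promoting edge, upward for an inhibiting one (one-hop propagation).
#' Gaussian measurement noise is added everywhere and values are clipped at 0
#' to resemble expression intensities.
#'
#' @param truth A signed `gold_standard` from [random_truth_network()].
#' @param design `"null-mutant"`, `"knockdown"` or `"replicates"` (the last
#'   yields noisy wild-type replicates only — no perturbation signal).
#' @param coupling Shift magnitude as a fraction of the neighbor's baseline,
#'   in `[0, 1]` (default 0.8: strong, near-complete propagation).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.01, small relative to baselines drawn in `[0.25, 1]`).
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @param n_replicates Number of replicate samples when
#'   `design = "replicates"` (defaults to the number of genes).
#' @return A `synthetic_study`: list with `truth`, `expression` (matrix,
#'   genes in rows), `design` (label per sample) and `params`.
#' @export
simulate_expression <- function(truth, design = c("null-mutant", "knockdown", "replicates"),
                                coupling = 0.8, noise_sd = 0.01, seed = 1L,
                                n_replicates = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(truth, "gold_standard"))
  if (coupling < 0 || coupling > 1) stop("parameter error: coupling must lie in [0, 1]")
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")
  genes <- truth$universe
  n <- length(genes)
  set.seed(seed)
  baseline <- stats::runif(n, 0.25, 1)
  names(baseline) <- genes
  signs <- attr(truth$edges, "sign")
  if (is.null(signs)) signs <- rep.int(1L, nrow(truth$edges))

  perturb_column <- function(target, factor) {
    x <- baseline
    x[target] <- x[target] * factor
    for (e in seq_len(nrow(truth$edges))) {
      a <- truth$edges[e, 1L]; b <- truth$edges[e, 2L]
      nb <- if (a == target) b else if (b == target) a else next
      x[nb] <- x[nb] - signs[e] * coupling * baseline[nb]
    }
    x
  }

  if (design == "replicates") {
    if (is.null(n_replicates)) n_replicates <- n
    cols <- c(list(wt = baseline),
              stats::setNames(replicate(n_replicates, baseline, simplify = FALSE),
                              paste0("rep", seq_len(n_replicates))))
    labels <- c("wild-type", rep.int("replicate", n_replicates))
  } else {
    factor <- if (design == "null-mutant") 0 else 0.5
    cols <- c(list(wt = baseline),
              stats::setNames(lapply(genes, perturb_column, factor = factor),
                              paste0(genes, "(-/-)")))
    labels <- c("wild-type", rep.int(design, n))
  }
  expr <- do.call(cbind, cols)
  expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd),
                        nrow = nrow(expr))
  expr[expr < 0] <- 0
  rownames(expr) <- genes
  structure(
    list(truth = truth, expression = expr,
         design = stats::setNames(labels, colnames(expr)),
         params = list(coupling = coupling, noise_sd = noise_sd, seed = seed,
                       design = design)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes x %d samples (%s design, coupling %.2f, noise sd %.3g)\n",
              nrow(x$expression), ncol(x$expression), x$params$design,
              x$params$coupling, x$params$noise_sd))
  invisible(x)
}
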