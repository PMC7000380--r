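#' Exact Poisson-binomial tail probability
#'
#' Tail of the distribution of a sum of independent Bernoulli variables with
#' unequal success probabilities, computed by the exact dynamic-programming
#' convolution recurrence (no normal approximation).
#'
#' @param probs Numeric vector of per-trial success probabilities in \[0, 1\].
#' @param x Integer count, `0 <= x <= length(probs)`.
#' @param side `"ge"` for `P(X >= x)`, `"le"` for `P(X <= x)`.
#' @return A single probability.
#' @export
poisson_binomial_tail <- function(probs, x, side = c("ge", "le")) {
  side <- match.arg(side)
  probs <- as.numeric(probs)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probs must be in [0, 1]")
  }
  if (x < 0 || x > length(probs)) stop("count x out of range [0, n]")
  pb_tail_cpp(probs, as.integer(x), side == "le")[1]
}

#' Test one gene pair for co-occurrence / mutual exclusivity
#'
#' The observed number of samples methylated in both genes is compared with
#' its exact null distribution under the fitted background: per sample the
#' joint null probability is the product of the two genes' background
#' probabilities, and the overlap count is Poisson-binomial across samples.
#' `p_co` is the upper tail (at least the observed overlap: co-occurrence),
#' `p_me` the lower tail (at most the observed: mutual exclusivity).
#'
#' @param model A `come_background` fit covering both genes.
#' @param bm The binary alteration matrix the model was fitted to.
#' @param gene_a,gene_b Gene identifiers.
#' @return A one-row tibble: canonical `gene_a`/`gene_b`, `overlap`,
#'   `expected`, `p_co`, `p_me`.
#' @export
test_pair <- function(model, bm, gene_a, gene_b) {
  for (gene in c(gene_a, gene_b)) {
    if (!(gene %in% rownames(bm)) || !(gene %in% rownames(model$prob))) {
      stop("gene absent from matrix or background model: ", gene)
    }
  }
  joint <- model$prob[gene_a, ] * model$prob[gene_b, ]
  x <- sum(bm[gene_a, ] == 1 & bm[gene_b, ] == 1)
  key <- canonical_pair(gene_a, gene_b)
  tibble(gene_a = key$gene_a, gene_b = key$gene_b,
         overlap = as.integer(x), expected = sum(joint),
         p_co = poisson_binomial_tail(joint, x, "ge"),
         p_me = poisson_binomial_tail(joint, x, "le"))
}

#' Test all gene pairs and call CO/ME events
#'
#' Runs the background-calibrated pair test on every unordered gene pair,
#' then controls the false discovery rate by Benjamini-Hochberg separately
#' within the co-occurrence and the mutual-exclusivity p-value families.  A
#' pair is called `CO` when `q_co <= q_threshold`, `ME` when
#' `q_me <= q_threshold`; if both families pass, the smaller raw p-value
#' decides and an exact tie is called `none`.
#'
#' @param bm Binary alteration matrix (genes x samples), typically after
#'   [filter_genes()].
#' @param model Optional pre-fitted `come_background`; fitted here if `NULL`.
#' @param q_threshold FDR threshold for event calls (default 0.05).
#' @return A tibble with one row per unordered pair, ordered by the canonical
#'   pair key: `gene_a`, `gene_b`, `overlap`, `expected`, `p_co`, `p_me`,
#'   `q_co`, `q_me`, `call`.
#' @export
test_all_pairs <- function(bm, model = NULL, q_threshold = 0.05) {
  stopifnot(is.matrix(bm), nrow(bm) >= 2)
  if (is.null(model)) model <- estimate_background(bm)
  P <- model$prob[rownames(bm), colnames(bm), drop = FALSE]
  res <- pair_tests_cpp(P, bm)
  genes <- rownames(bm)
  key <- canonical_pair(genes[res$i], genes[res$j])
  out <- tibble(gene_a = key$gene_a, gene_b = key$gene_b,
                overlap = res$overlap, expected = res$expected,
                p_co = res$p_co, p_me = res$p_me)
  out$q_co <- p.adjust(out$p_co, method = "BH")
  out$q_me <- p.adjust(out$p_me, method = "BH")
  call <- rep("none", nrow(out))
  co_hit <- out$q_co <= q_threshold
  me_hit <- out$q_me <= q_threshold
  call[co_hit & !me_hit] <- "CO"
  call[me_hit & !co_hit] <- "ME"
  both <- co_hit & me_hit
  if (any(both)) {
    call[both & out$p_co < out$p_me] <- "CO"
    call[both & out$p_me < out$p_co] <- "ME"
    # exact tie stays "none"
  }
  out$call <- call
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
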