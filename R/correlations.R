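#' Expression and methylation correlations for event gene pairs
#'
#' For each gene pair, Pearson correlation of the two genes' expression
#' profiles (`r_expr`) and of their promoter beta profiles (`r_meth`) over
#' the samples shared between the matrices, using pairwise-complete
#' observations.  Pairs with fewer than 3 shared complete samples get `NA`.
#'
#' @param events Tibble with `gene_a`, `gene_b` columns (e.g. from
#'   [test_all_pairs()]).
#' @param expr Gene-by-sample expression matrix.
#' @param gm Gene-by-sample promoter beta matrix.
#' @return `events` with `r_expr` and `r_meth` columns appended.
#' @export
pair_correlations <- function(events, expr, gm) {
  shared_e <- intersect(colnames(expr), colnames(gm))
  pair_r <- function(mat, a, b) {
    if (!(a %in% rownames(mat)) || !(b %in% rownames(mat))) return(NA_real_)
    x <- mat[a, ]; y <- mat[b, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  out <- as_tibble(events)
  out$r_expr <- unname(mapply(function(a, b) pair_r(expr, a, b),
                              out$gene_a, out$gene_b))
  out$r_meth <- unname(mapply(function(a, b) pair_r(gm, a, b),
                              out$gene_a, out$gene_b))
  out
}

#' Per-gene expression-methylation correlation
#'
#' Pearson correlation between a gene's expression and its own promoter beta
#' across the samples present in both matrices (pairwise complete).  Promoter
#' hypermethylation that silences transcription shows up as negative values.
#'
#' @param genes Gene identifiers.
#' @param expr Gene-by-sample expression matrix.
#' @param gm Gene-by-sample promoter beta matrix.
#' @return A tibble with `gene_id` and `r_expr_meth`.
#' @export
expr_meth_correlation <- function(genes, expr, gm) {
  shared <- intersect(colnames(expr), colnames(gm))
  r <- vapply(genes, function(g) {
    if (!(g %in% rownames(expr)) || !(g %in% rownames(gm))) return(NA_real_)
    x <- expr[g, shared]; y <- gm[g, shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }, numeric(1))
  tibble(gene_id = genes, r_expr_meth = unname(r))
}

#' Compare a gene set's correlation statistic with random gene sets
#'
#' Computes the per-gene expression-methylation correlation for the observed
#' gene set and for `n_random` seeded random gene sets of equal size drawn
#' without replacement from the gene universe shared by both matrices, then
#' compares the two samples of correlation values with an independent
#' two-sample (Welch) t-test.
#'
#' @param observed_genes Gene identifiers of the observed (event) set.
#' @param expr,gm Expression and promoter beta matrices.
#' @param n_random Number of random gene sets pooled into the comparison
#'   sample (default 1).
#' @param seed Integer seed controlling the random draws.
#' @return A one-row tibble: `t`, `p_value`, `mean_observed`, `mean_random`,
#'   `n_observed`, `n_random_values`.
#' @export
compare_correlation_to_random <- function(observed_genes, expr, gm,
                                          n_random = 1, seed = 1) {
  stopifnot(n_random >= 1)
  universe <- intersect(rownames(expr), rownames(gm))
  size <- length(observed_genes)
  if (size > length(universe)) {
    stop("random set size exceeds the gene universe")
  }
  obs <- expr_meth_correlation(observed_genes, expr, gm)$r_expr_meth
  obs <- obs[!is.na(obs)]
  set.seed(seed)
  rnd <- unlist(lapply(seq_len(n_random), function(i) {
    draw <- sample(universe, size, replace = FALSE)
    expr_meth_correlation(draw, expr, gm)$r_expr_meth
  }))
  rnd <- rnd[!is.na(rnd)]
  if (length(obs) < 2 || length(rnd) < 2) {
    stop("need at least 2 non-missing correlations per group")
  }
  if (sd(obs) == 0 && sd(rnd) == 0) {
    tt <- list(statistic = c(t = 0),
               p.value = if (mean(obs) == mean(rnd)) 1 else 0)
  } else {
    tt <- t.test(obs, rnd, var.equal = FALSE)
  }
  tibble(t = unname(tt$statistic), p_value = tt$p.value,
         mean_observed = mean(obs), mean_random = mean(rnd),
         n_observed = length(obs), n_random_values = length(rnd))
}
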