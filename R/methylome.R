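#' Collapse probe-level beta values to gene promoter methylation
#'
#' For each gene the promoter region classes are scanned in priority order
#' `TSS1500`, `TSS200`, `FirstExon`, `UTR5`; the first class with at least one
#' probe present in the beta matrix is selected, and the gene's value in each
#' sample is the mean of that class's non-missing probe betas.  Genes with no
#' promoter probe are omitted; a gene-sample cell is missing when all selected
#' probes are missing in that sample.
#'
#' @param beta Probe-by-sample beta matrix (values in \[0, 1\]).
#' @param manifest Probe manifest tibble from [read_manifest()].
#' @return A gene-by-sample matrix of promoter-average betas, with a
#'   `provenance` attribute (tibble: `gene_id`, `region_class`, `n_probes`).
#' @export
aggregate_promoter <- function(beta, manifest) {
  stopifnot(is.matrix(beta))
  priority <- c("TSS1500", "TSS200", "FirstExon", "UTR5")
  man <- manifest[manifest$region_class %in% priority &
                    manifest$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(man) == 0) {
    stop("no manifest probe with a promoter region class matches the beta matrix")
  }
  man$region_class <- factor(man$region_class, levels = priority)
  genes <- sort(unique(man$gene_id))
  values <- matrix(NA_real_, nrow = length(genes), ncol = ncol(beta),
                   dimnames = list(genes, colnames(beta)))
  prov_class <- character(length(genes))
  prov_n <- integer(length(genes))
  by_gene <- split(man, man$gene_id)
  for (i in seq_along(genes)) {
    sub <- by_gene[[genes[i]]]
    cls <- priority[min(as.integer(sub$region_class))]
    probes <- sub$probe_id[sub$region_class == cls]
    block <- beta[probes, , drop = FALSE]
    cnt <- colSums(!is.na(block))
    mn <- colSums(block, na.rm = TRUE) / cnt    # NaN where cnt == 0
    mn[cnt == 0] <- NA_real_
    values[i, ] <- mn
    prov_class[i] <- cls
    prov_n[i] <- length(probes)
  }
  attr(values, "provenance") <- tibble(gene_id = genes,
                                       region_class = prov_class,
                                       n_probes = prov_n)
  values
}

#' Dichotomize promoter methylation into a binary alteration matrix
#'
#' A gene is called methylated (1) in a sample when its promoter-average beta
#' strictly exceeds the threshold, unmethylated (0) otherwise.  Missing betas
#' are imputed as unmethylated; the number of imputed cells is reported via a
#' message.
#'
#' @param gm Gene-by-sample promoter beta matrix.
#' @param threshold Beta cutoff in (0, 1); default 0.3.
#' @return An integer 0/1 matrix with a `threshold` attribute.
#' @export
binarize <- function(gm, threshold = 0.3) {
  stopifnot(is.matrix(gm), threshold > 0, threshold < 1)
  n_missing <- sum(is.na(gm))
  bm <- (gm > threshold) * 1L
  bm[is.na(bm)] <- 0L
  storage.mode(bm) <- "integer"
  if (n_missing > 0) {
    message(sprintf("binarize: %d missing beta cell(s) imputed as unmethylated (0)",
                    n_missing))
  }
  all_missing <- rowSums(!is.na(gm)) == 0
  if (any(all_missing)) {
    warning(sprintf("%d gene(s) with all betas missing set to all-zero rows",
                    sum(all_missing)))
  }
  attr(bm, "threshold") <- threshold
  bm
}

#' Filter genes by alteration frequency
#'
#' Removes genes whose methylation frequency lies outside
#' `[min_freq, max_freq]` before pairwise testing (near-constant rows carry no
#' co-occurrence information and break background margin fitting).
#'
#' @param bm Binary alteration matrix (genes x samples).
#' @param min_freq,max_freq Inclusive frequency bounds, `0 <= min_freq <
#'   max_freq <= 1`.
#' @return The filtered binary matrix, gene order preserved.
#' @export
filter_genes <- function(bm, min_freq = 0.05, max_freq = 0.95) {
  stopifnot(is.matrix(bm), min_freq >= 0, max_freq <= 1, min_freq < max_freq)
  f <- rowMeans(bm)
  keep <- f >= min_freq & f <= max_freq
  if (!any(keep)) {
    stop("no gene passes the frequency filter; relax min_freq/max_freq")
  }
  out <- bm[keep, , drop = FALSE]
  attr(out, "threshold") <- attr(bm, "threshold")
  out
}
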