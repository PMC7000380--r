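#' Fit the margin-calibrated independence background
#'
#' Models the probability that gene g is methylated in sample s as
#' `plogis(u_g + v_s)` — a gene effect plus a sample effect on the logit
#' scale — and calibrates the effects so that every gene's expected number of
#' methylated samples matches its observed row sum and every sample's
#' expected number of methylated genes matches its observed column sum.  This
#' is the null model "alterations are independent given per-gene rates and
#' per-sample methylation load" that the pairwise CO/ME test conditions on.
#'
#' Fitting alternates damped Newton updates on the gene effects (given the
#' sample effects) and on the sample effects (given the gene effects) from
#' the deterministic start `u = v = 0`, until both margin residual maxima
#' drop below `tol`.
#'
#' @param bm Binary alteration matrix (genes x samples), ideally after
#'   [filter_genes()].  Margins equal to 0 or the dimension limit are clipped
#'   to 0.5 away from the boundary with a warning.
#' @param tol Maximum absolute margin residual required for convergence.
#' @param max_iter Maximum number of alternating sweeps.
#' @return An object of class `come_background`: gene/sample effects, the
#'   fitted probability matrix, iteration count and final residual.
#' @export
estimate_background <- function(bm, tol = 1e-6, max_iter = 5000) {
  stopifnot(is.matrix(bm))
  if (all(bm == 0) || all(bm == 1)) {
    stop("degenerate all-0 or all-1 matrix: background model is unidentifiable")
  }
  g <- nrow(bm); n <- ncol(bm)
  r <- rowSums(bm); cns <- colSums(bm)
  clip <- FALSE
  if (any(r <= 0 | r >= n)) {
    r <- pmin(pmax(r, 0.5), n - 0.5); clip <- TRUE
  }
  if (any(cns <= 0 | cns >= g)) {
    cns <- pmin(pmax(cns, 0.5), g - 0.5); clip <- TRUE
  }
  if (clip) {
    warning("boundary margins clipped to 0.5 away from their limits")
    # clipping breaks the shared total (sum of row targets must equal sum of
    # column targets); rescale the column targets to restore consistency
    cns <- pmin(pmax(cns * sum(r) / sum(cns), 0.25), g - 0.25)
  }

  u <- rep(0, g); v <- rep(0, n)
  newton <- function(eff, other, target) {
    # damped Newton matching sum(plogis(eff_i + other)) to target_i, run to
    # convergence for this block (the other block held fixed); the 1-D
    # problems are separable and each target function is strictly increasing
    for (it in seq_len(50)) {
      P <- stats::plogis(outer(eff, other, "+"))
      resid <- target - rowSums(P)
      if (max(abs(resid)) <= tol / 4) break
      deriv <- rowSums(P * (1 - P))
      step <- resid / pmax(deriv, 1e-12)
      eff <- eff + pmin(pmax(step, -4), 4)
    }
    eff
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    u <- newton(u, v, r)
    v <- newton(v, u, cns)
    P <- stats::plogis(outer(u, v, "+"))
    res <- max(max(abs(rowSums(P) - r)), max(abs(colSums(P) - cns)))
    if (res <= tol) break
    if (iter >= max_iter) {
      stop(sprintf("background fit did not converge after %d sweeps (max margin residual %.3g)",
                   iter, res))
    }
  }
  dimnames(P) <- dimnames(bm)
  structure(list(gene_effects = setNames(u, rownames(bm)),
                 sample_effects = setNames(v, colnames(bm)),
                 prob = P, iterations = iter, max_residual = res, tol = tol),
            class = "come_background")
}

#' @export
print.come_background <- function(x, ...) {
  cat(sprintf("<come_background> %d genes x %d samples; %d sweeps, max margin residual %.3g\n",
              length(x$gene_effects), length(x$sample_effects),
              x$iterations, x$max_residual))
  invisible(x)
}

#' Tidy a fitted background model
#'
#' @param x A `come_background` object.
#' @param ... Unused.
#' @return A tibble with one row per gene or sample effect: `term`
#'   (`"gene"`/`"sample"`), `id`, `effect` (logit scale).
#' @export
tidy.come_background <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "gene", id = names(x$gene_effects),
           effect = unname(x$gene_effects)),
    tibble(term = "sample", id = names(x$sample_effects),
           effect = unname(x$sample_effects))
  )
}

#' @rdname tidy.come_background
#' @export
glance.come_background <- function(x, ...) {
  tibble(n_genes = length(x$gene_effects),
         n_samples = length(x$sample_effects),
         iterations = x$iterations,
         max_residual = x$max_residual,
         converged = x$max_residual <= x$tol)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
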