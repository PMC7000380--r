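#' Per-gene tumor-versus-normal Welch t statistics
#'
#' Row-wise two-sample Welch t statistic (unequal variances) comparing tumor
#' against normal samples, pairwise-complete over missing values.  Group
#' variances are floored at 1e-12 so zero-variance degenerate groups yield a
#' large finite statistic instead of infinity.
#'
#' @param values Gene-by-sample numeric matrix (promoter beta or expression).
#' @param is_tumor Logical vector aligned with the columns of `values`.
#' @return Tibble: `gene_id`, `t` (positive = higher in tumor), `n_tumor`,
#'   `n_normal`.  Genes with fewer than 2 non-missing samples in either
#'   group get `NA`.
#' @export
differential_stats <- function(values, is_tumor) {
  stopifnot(is.matrix(values), length(is_tumor) == ncol(values))
  grp <- function(mat) {
    n <- rowSums(!is.na(mat))
    m <- rowMeans(mat, na.rm = TRUE)
    v <- apply(mat, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) NA_real_ else var(x)
    })
    list(n = n, m = m, v = pmax(v, 1e-12))
  }
  t1 <- grp(values[, is_tumor, drop = FALSE])
  t0 <- grp(values[, !is_tumor, drop = FALSE])
  ok <- t1$n >= 2 & t0$n >= 2
  tt <- (t1$m - t0$m) / sqrt(t1$v / t1$n + t0$v / t0$n)
  tt[!ok] <- NA_real_
  n_floored <- sum(ok & (t1$v <= 1e-12 | t0$v <= 1e-12), na.rm = TRUE)
  if (n_floored > 0) {
    message(sprintf("differential_stats: variance floored at 1e-12 for %d gene-group(s)",
                    n_floored))
  }
  tibble(gene_id = rownames(values), t = unname(tt),
         n_tumor = unname(t1$n), n_normal = unname(t0$n))
}

#' Combine methylation and expression statistics into node weights
#'
#' The node weight is `(|t_meth| + |t_expr|) / 2` when both statistics are
#' available, otherwise the available one; genes lacking both are dropped.
#'
#' @param t_meth,t_expr Tibbles from [differential_stats()] on promoter beta
#'   and expression respectively (either may be `NULL`).
#' @return Tibble: `gene_id`, `t_meth`, `t_expr`, `weight`.
#' @export
node_statistics <- function(t_meth = NULL, t_expr = NULL) {
  if (is.null(t_meth) && is.null(t_expr)) stop("need at least one statistic table")
  tm <- if (is.null(t_meth)) tibble(gene_id = character(), t = numeric()) else t_meth
  te <- if (is.null(t_expr)) tibble(gene_id = character(), t = numeric()) else t_expr
  out <- dplyr::full_join(
    dplyr::select(tm, gene_id = "gene_id", t_meth = "t"),
    dplyr::select(te, gene_id = "gene_id", t_expr = "t"),
    by = "gene_id"
  )
  w <- ifelse(!is.na(out$t_meth) & !is.na(out$t_expr),
              (abs(out$t_meth) + abs(out$t_expr)) / 2,
              ifelse(!is.na(out$t_meth), abs(out$t_meth), abs(out$t_expr)))
  out$weight <- w
  out[!is.na(out$weight) & is.finite(out$weight), , drop = FALSE]
}

# adjacency list of a come_network (undirected, types collapsed)
.adjacency <- function(net) {
  ed <- unique(net$edges[c("gene_a", "gene_b")])
  adj <- lapply(setNames(vector("list", length(net$nodes)), net$nodes),
                function(x) character())
  for (k in seq_len(nrow(ed))) {
    a <- ed$gene_a[k]; b <- ed$gene_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Greedy seeded expansion.  Edge weight w_ij = (w_i + w_j)/2; the reported
# module score is the mean induced-edge weight.  A neighboring gene is
# admissible while its own weight exceeds the midpoint between the module's
# current mean node weight and the universe mean node weight `wbar` — so
# signal-level genes keep joining (even when they do not raise the mean),
# background-level genes never do, and expansion terminates on its own.
# Among admissible candidates the highest-weight one is added (ties
# alphabetical).  Returns candidate modules; shared by the observed run and
# the permutation runs.
.greedy_modules <- function(adj, w, min_size, max_size, wbar = NULL,
                            seed_frac = 0.01, min_seeds = 5) {
  nodes <- names(adj)
  if (is.null(wbar)) wbar <- mean(w[nodes])
  n_seed <- max(min_seeds, ceiling(seed_frac * length(nodes)))
  n_seed <- min(n_seed, length(nodes))
  seeds <- nodes[order(-w[nodes], nodes)][seq_len(n_seed)]
  # only above-baseline nodes may seed: every member then stays above the
  # baseline, so a weak seed cannot drag itself into a strong module
  seeds <- seeds[w[seeds] > wbar + 1e-12]
  out <- list()
  for (sd_gene in seeds) {
    members <- sd_gene
    in_mod <- setNames(logical(length(nodes)), nodes)
    in_mod[sd_gene] <- TRUE
    esum <- 0; ecnt <- 0
    wsum <- w[[sd_gene]]
    repeat {
      if (length(members) >= max_size) break
      cand <- unique(unlist(adj[members], use.names = FALSE))
      cand <- cand[!in_mod[cand]]
      if (length(cand) == 0) break
      threshold <- (wsum / length(members) + wbar) / 2
      cand <- cand[w[cand] > threshold + 1e-12]
      if (length(cand) == 0) break    # no admissible addition left
      cand <- sort(cand)              # deterministic tie-break: alphabetical
      best <- cand[which.max(w[cand])]
      nb <- adj[[best]]
      touching <- nb[in_mod[nb]]
      members <- c(members, best)
      in_mod[best] <- TRUE
      esum <- esum + sum((w[[best]] + w[touching]) / 2)
      ecnt <- ecnt + length(touching)
      wsum <- wsum + w[[best]]
    }
    if (length(members) >= min_size && ecnt > 0) {
      out[[length(out) + 1]] <- list(seed = sd_gene,
                                     members = sort(members),
                                     score = esum / ecnt,
                                     stat = esum)
    }
  }
  if (length(out) == 0) return(out)
  # deduplicate overlapping modules, keeping the higher total edge weight
  ord <- order(-vapply(out, `[[`, numeric(1), "stat"))
  kept <- list(); used <- character()
  for (i in ord) {
    if (length(intersect(out[[i]]$members, used)) == 0) {
      kept[[length(kept) + 1]] <- out[[i]]
      used <- c(used, out[[i]]$members)
    }
  }
  kept
}

#' Detect functional epigenetic modules
#'
#' Searches the CO/ME network for connected subnetworks whose genes carry
#' coordinated differential-methylation / differential-expression signal.
#' Seeds are the top 1% of nodes by combined weight (at least 5); each seed
#' is expanded greedily, at every step admitting the highest-weight
#' neighboring gene whose weight still exceeds the midpoint between the
#' module's mean node weight and the mean weight of the whole statistics
#' universe, stopping when no admissible neighbor remains or `max_size` is
#' reached.  The module score is the mean over induced edges of
#' `(w_i + w_j) / 2`; the test statistic is the total induced edge weight,
#' which also rewards module extent.  Overlapping modules are deduplicated
#' in favor of the higher total edge weight.  Significance is assessed by
#' permuting the node statistics over the network `n_perm` times, re-running
#' the full search, and comparing each observed module's total edge weight
#' with the permutation maxima:
#' `p_perm = (1 + #\{permuted max >= observed\}) / (1 + n_perm)`.
#'
#' @param net A `come_network`.
#' @param stats Node statistics from [node_statistics()]; must cover at
#'   least 50% of the network's nodes (uncovered nodes get weight 0).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size,max_size Module size bounds (defaults 4 and 50).
#' @param seed Integer seed for the permutations.
#' @param alpha Significance threshold on `p_perm` (default 0.05).
#' @return Tibble of significant modules: `seed_gene`, `members`
#'   (list-column), `size`, `score`, `p_perm`.
#' @export
detect_modules <- function(net, stats, n_perm = 1000, min_size = 4,
                           max_size = 50, seed = 1, alpha = 0.05) {
  if (length(net$nodes) == 0) stop("empty network")
  covered <- mean(net$nodes %in% stats$gene_id)
  if (covered < 0.5) {
    stop(sprintf("node statistics cover only %.0f%% of network nodes (need >= 50%%)",
                 100 * covered))
  }
  w <- setNames(rep(0, length(net$nodes)), net$nodes)
  idx <- match(stats$gene_id, net$nodes)
  w[idx[!is.na(idx)]] <- stats$weight[!is.na(idx)]
  # baseline signal level: mean weight over the whole statistics universe,
  # so a network made entirely of signal genes can still carry modules
  wbar <- mean(stats$weight)
  adj <- .adjacency(net)
  observed <- .greedy_modules(adj, w, min_size, max_size, wbar = wbar)
  if (length(observed) == 0) {
    return(tibble(seed_gene = character(), members = list(),
                  size = integer(), score = numeric(), p_perm = numeric()))
  }
  set.seed(seed)
  perm_max <- vapply(seq_len(n_perm), function(i) {
    wp <- setNames(sample(unname(w)), names(w))
    mods <- .greedy_modules(adj, wp, min_size, max_size, wbar = wbar)
    if (length(mods) == 0) -Inf else max(vapply(mods, `[[`, numeric(1), "stat"))
  }, numeric(1))
  out <- tibble(
    seed_gene = vapply(observed, `[[`, character(1), "seed"),
    members = lapply(observed, `[[`, "members"),
    size = vapply(observed, function(m) length(m$members), integer(1)),
    score = vapply(observed, `[[`, numeric(1), "score"),
    total_edge_weight = vapply(observed, `[[`, numeric(1), "stat")
  )
  out$p_perm <- vapply(out$total_edge_weight, function(s) {
    (1 + sum(perm_max >= s - 1e-12)) / (1 + n_perm)
  }, numeric(1))
  out <- out[out$p_perm <= alpha, , drop = FALSE]
  out[order(out$p_perm, -out$score), , drop = FALSE]
}

#' Direction report for a module
#'
#' Classifies each module gene into a quadrant by the signs of its
#' methylation and expression statistics and reports the fraction that is
#' hypermethylated and down-regulated (`t_meth > 0`, `t_expr < 0`) —
#' epigenetically repressed genes.
#'
#' @param members Character vector of module gene identifiers.
#' @param stats Node statistics tibble from [node_statistics()].
#' @return List with `genes` (tibble: `gene_id`, `t_meth`, `t_expr`,
#'   `quadrant`) and `fraction_hyper_down`.
#' @export
module_direction_report <- function(members, stats) {
  st <- stats[match(members, stats$gene_id), , drop = FALSE]
  quadrant <- paste0(ifelse(st$t_meth > 0, "hyper", "hypo"), "_",
                     ifelse(st$t_expr < 0, "down", "up"))
  quadrant[is.na(st$t_meth) | is.na(st$t_expr)] <- NA_character_
  genes <- tibble(gene_id = members, t_meth = st$t_meth, t_expr = st$t_expr,
                  quadrant = quadrant)
  ok <- !is.na(quadrant)
  list(genes = genes,
       fraction_hyper_down = if (any(ok)) mean(quadrant[ok] == "hyper_down")
                             else NA_real_)
}
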