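#' Build the event-by-sample occurrence matrix
#'
#' Rows are frequent CO/ME events (identified as `geneA|geneB|type`), columns
#' are samples; entries are per-sample event occurrence.
#'
#' @param frequent Tibble with `gene_a`, `gene_b`, `type` (e.g. from
#'   [select_frequent()]).
#' @param bm Binary alteration matrix covering the samples to profile.
#' @return Integer 0/1 matrix, events x samples.
#' @export
event_sample_matrix <- function(frequent, bm) {
  stopifnot(nrow(frequent) >= 1)
  rows <- lapply(seq_len(nrow(frequent)), function(k) {
    event_occurrence(bm, c(frequent$gene_a[k], frequent$gene_b[k]),
                     frequent$type[k])
  })
  esm <- do.call(rbind, rows)
  rownames(esm) <- paste(frequent$gene_a, frequent$gene_b, frequent$type,
                         sep = "|")
  colnames(esm) <- colnames(bm)
  storage.mode(esm) <- "integer"
  esm
}

# k-means labels for one subsample, with a degenerate-data fallback when
# there are no more distinct profiles than clusters
.kmeans_labels <- function(x, k) {
  keys <- apply(x, 1, paste, collapse = ",")
  nu <- length(unique(keys))
  if (nu <= k) return(as.integer(factor(keys, levels = unique(keys))))
  km <- suppressWarnings(kmeans(x, centers = k, nstart = 10, iter.max = 100))
  km$cluster
}

#' Consensus clustering of samples on event profiles
#'
#' For each candidate k, `n_reps` random subsamples of
#' `ceiling(subsample * n)` samples are clustered with k-means (Euclidean on
#' the 0/1 profiles; 10 random restarts per run); the consensus matrix entry
#' for a sample pair is the fraction of co-clusterings among the runs where
#' both were sampled.  Final labels per k come from average-linkage
#' hierarchical clustering of `1 - consensus` cut at k.  Fully seeded and
#' deterministic.
#'
#' @param esm Event-by-sample 0/1 matrix from [event_sample_matrix()].
#' @param k_range Candidate cluster numbers (default 2:8).
#' @param n_reps Subsampling replicates per k (default 100).
#' @param subsample Fraction of samples drawn per replicate (default 0.8).
#' @param seed Integer seed.
#' @return A `come_consensus` object: consensus matrices, labels,
#'   average silhouette and CDF (delta-)areas per k, and the k chosen by
#'   each selection method.
#' @export
consensus_cluster <- function(esm, k_range = 2:8, n_reps = 100,
                              subsample = 0.8, seed = 1) {
  n <- ncol(esm)
  stopifnot(n >= 10, max(k_range) < n * subsample)
  x <- t(esm) * 1.0
  samples <- colnames(esm)
  m_sub <- ceiling(subsample * n)
  consensus <- list(); labels <- list()
  sil <- setNames(numeric(length(k_range)), k_range)
  never <- FALSE
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n); tog <- matrix(0, n, n)
    for (r in seq_len(n_reps)) {
      set.seed(derive_seed(seed, k * 100000 + r))
      idx <- sort(sample.int(n, m_sub))
      cl <- .kmeans_labels(x[idx, , drop = FALSE], k)
      tog[idx, idx] <- tog[idx, idx] + 1
      for (g in unique(cl)) {
        ii <- idx[cl == g]
        co[ii, ii] <- co[ii, ii] + 1
      }
    }
    cons <- co / tog
    if (any(tog == 0)) {
      never <- TRUE
      cons[tog == 0] <- 0.5
    }
    diag(cons) <- 1
    dimnames(cons) <- list(samples, samples)
    d <- as.dist(1 - cons)
    hc <- hclust(d, method = "average")
    lab <- cutree(hc, k = k)
    consensus[[as.character(k)]] <- cons
    labels[[as.character(k)]] <- setNames(as.integer(lab), samples)
    sw <- cluster::silhouette(as.integer(lab), d)
    sil[ki] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
  }
  if (never) warning("sample pair(s) never co-sampled; consensus imputed 0.5")
  areas <- vapply(as.character(k_range), function(k) {
    v <- consensus[[k]][upper.tri(consensus[[k]])]
    cdf_area(v)
  }, numeric(1))
  delta <- numeric(length(k_range))
  delta[1] <- areas[1]
  if (length(k_range) > 1) {
    for (i in 2:length(k_range)) {
      delta[i] <- (areas[i] - areas[i - 1]) / areas[i - 1]
    }
  }
  names(delta) <- names(areas) <- as.character(k_range)
  obj <- structure(list(k_range = k_range, consensus = consensus,
                        labels = labels, silhouette = sil,
                        cdf_area = areas, delta_area = delta,
                        sample_ids = samples, seed = seed),
                   class = "come_consensus")
  obj$chosen_k <- list(cdf_elbow = choose_k(obj, "cdf_elbow"),
                       silhouette = choose_k(obj, "silhouette"))
  obj
}

# area under the empirical CDF of consensus values over [0, 1]
cdf_area <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n == 0) return(NA_real_)
  # integral of ECDF: sum over gaps between consecutive sorted values
  xs <- c(v, 1)
  steps <- diff(c(0, xs))
  heights <- c(0, seq_len(n)) / n
  sum(steps * heights)
}

#' @export
print.come_consensus <- function(x, ...) {
  cat(sprintf("<come_consensus> %d samples, k in {%s}; chosen k: cdf_elbow=%d, silhouette=%d\n",
              length(x$sample_ids), paste(x$k_range, collapse = ","),
              x$chosen_k$cdf_elbow, x$chosen_k$silhouette))
  invisible(x)
}

#' Choose the number of clusters
#'
#' `"silhouette"` picks the k with the maximum average silhouette width on
#' the distance `1 - consensus`.  `"cdf_elbow"` walks k upward from the
#' minimum and keeps going while the relative increase of the consensus-CDF
#' area is at least `prop` (default 0.1) — the proportional-area-change
#' operationalization of the visual CDF-elbow rule.  Ties break toward
#' smaller k.
#'
#' @param cr A `come_consensus` object.
#' @param method `"cdf_elbow"` or `"silhouette"`.
#' @param prop Proportional-area threshold for the elbow rule.
#' @return The chosen k (integer).
#' @export
choose_k <- function(cr, method = c("silhouette", "cdf_elbow"), prop = 0.1) {
  method <- match.arg(method)
  ks <- cr$k_range
  if (method == "silhouette") {
    best <- max(cr$silhouette, na.rm = TRUE)
    return(ks[which(cr$silhouette >= best - 1e-12)[1]])
  }
  chosen <- ks[1]
  if (length(ks) > 1) {
    for (i in 2:length(ks)) {
      if (!is.na(cr$delta_area[i]) && cr$delta_area[i] >= prop) {
        chosen <- ks[i]
      } else {
        break
      }
    }
  }
  chosen
}

#' Per-cluster event enrichment
#'
#' Hypergeometric enrichment of each event's occurrences inside a cluster
#' relative to the whole cohort; the top `top_n` events per cluster by
#' ascending p-value (ties by event id) are returned.
#'
#' @param esm Event-by-sample 0/1 matrix.
#' @param labels Named integer cluster labels covering the samples of `esm`.
#' @param top_n Events reported per cluster (default 15).
#' @return Tibble: `cluster`, `event_id`, `in_cluster`, `cluster_size`,
#'   `total_occurrences`, `p_hyper`, `rank`.
#' @export
cluster_event_enrichment <- function(esm, labels, top_n = 15) {
  stopifnot(all(colnames(esm) %in% names(labels)))
  labels <- labels[colnames(esm)]
  n <- ncol(esm)
  total <- rowSums(esm)
  out <- lapply(sort(unique(labels)), function(cl) {
    idx <- labels == cl
    q <- rowSums(esm[, idx, drop = FALSE])
    p <- phyper(q - 1, total, n - total, sum(idx), lower.tail = FALSE)
    df <- tibble(cluster = cl, event_id = rownames(esm),
                 in_cluster = as.integer(q), cluster_size = sum(idx),
                 total_occurrences = as.integer(total),
                 p_hyper = unname(p))
    df <- df[order(df$p_hyper, df$event_id), , drop = FALSE]
    df <- head(df, top_n)
    df$rank <- seq_len(nrow(df))
    df
  })
  dplyr::bind_rows(out)
}

#' Tidy consensus-clustering results
#'
#' @param x A `come_consensus` object.
#' @param k Which k's labels to return; defaults to the silhouette choice.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `cluster`.
#' @export
tidy.come_consensus <- function(x, k = NULL, ...) {
  k <- k %||% x$chosen_k$silhouette
  lab <- x$labels[[as.character(k)]]
  tibble(sample_id = names(lab), cluster = unname(lab))
}

#' @rdname tidy.come_consensus
#' @export
glance.come_consensus <- function(x, ...) {
  tibble(k = x$k_range,
         avg_silhouette = unname(x$silhouette),
         cdf_area = unname(x$cdf_area),
         delta_area = unname(x$delta_area),
         chosen_by_silhouette = x$k_range == x$chosen_k$silhouette,
         chosen_by_cdf_elbow = x$k_range == x$chosen_k$cdf_elbow)
}
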