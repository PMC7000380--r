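#' Per-sample occurrence of a CO/ME event
#'
#' A co-occurrence event occurs in a sample when both genes are methylated;
#' a mutual-exclusivity event occurs when exactly one of the two genes is
#' methylated.
#'
#' @param bm Binary alteration matrix (genes x samples).
#' @param pair Character vector of the two gene identifiers.
#' @param type `"CO"` or `"ME"`.
#' @return Named integer 0/1 vector over the samples of `bm`.
#' @export
event_occurrence <- function(bm, pair, type = c("CO", "ME")) {
  type <- match.arg(type)
  missing_genes <- setdiff(pair, rownames(bm))
  if (length(missing_genes) > 0) {
    stop("gene absent from binary matrix: ", paste(missing_genes, collapse = ", "))
  }
  a <- bm[pair[1], ]; b <- bm[pair[2], ]
  occ <- if (type == "CO") as.integer(a == 1 & b == 1) else as.integer(a + b == 1)
  setNames(occ, colnames(bm))
}

#' Tumor-versus-normal differential occurrence (Fisher's exact test)
#'
#' Builds the 2x2 table (a = tumor samples where the event occurred, b =
#' tumor without, c = normal with, d = normal without) and evaluates whether
#' occurrence differs between tumor and normal samples with a two-sided
#' Fisher exact test (summing hypergeometric probabilities of tables as or
#' less probable than observed).
#'
#' @param occurrence Named 0/1 vector from [event_occurrence()].
#' @param clinical Clinical tibble with `sample_id` and `is_tumor` covering
#'   the occurrence samples.
#' @param alpha Per-event, per-cancer significance level (default 0.05,
#'   unadjusted; cross-cancer recurrence acts as the replication filter).
#' @return One-row tibble: `a`, `b`, `c`, `d`, `p_fisher`, `differential`.
#'   With zero normal samples the event is non-assessable: a warning is
#'   raised and `p_fisher`/`differential` are `NA`.
#' @export
fisher_differential <- function(occurrence, clinical, alpha = 0.05) {
  cl <- clinical[match(names(occurrence), clinical$sample_id), ]
  if (any(is.na(cl$sample_id))) {
    stop("occurrence sample(s) missing from the clinical table")
  }
  tum <- cl$is_tumor
  if (!any(tum)) stop("no tumor sample: malformed design")
  a <- sum(occurrence == 1 & tum)
  b <- sum(occurrence == 0 & tum)
  cc <- sum(occurrence == 1 & !tum)
  d <- sum(occurrence == 0 & !tum)
  if (cc + d == 0) {
    warning("no normal sample: event non-assessable")
    return(tibble(a = a, b = b, c = cc, d = d,
                  p_fisher = NA_real_, differential = NA))
  }
  p <- fisher.test(matrix(c(a, cc, b, d), nrow = 2))$p.value
  tibble(a = a, b = b, c = cc, d = d, p_fisher = p,
         differential = p <= alpha)
}

#' Differential-occurrence filtering of events across cancers
#'
#' For every called event in every cancer, computes the per-sample occurrence
#' on that cancer's binary matrix (tumor and normal samples) and the Fisher
#' differential-occurrence record.
#'
#' @param events_by_cancer Named list (by cancer type) of event tibbles with
#'   `gene_a`, `gene_b`, `call` in \{CO, ME\} (rows with `call == "none"` are
#'   ignored), e.g. outputs of [test_all_pairs()].
#' @param bm_by_cancer Named list of binary matrices covering tumor and
#'   normal samples of each cancer.
#' @param clinical Clinical tibble covering all samples.
#' @param alpha Fisher significance level per cancer.
#' @return Tibble with one row per (event, cancer): pair, `type`, `cancer`,
#'   the contingency counts, `p_fisher`, `differential`.
#' @export
differential_events <- function(events_by_cancer, bm_by_cancer, clinical,
                                alpha = 0.05) {
  stopifnot(length(events_by_cancer) >= 1,
            all(names(events_by_cancer) %in% names(bm_by_cancer)))
  rows <- lapply(names(events_by_cancer), function(cancer) {
    ev <- events_by_cancer[[cancer]]
    ev <- ev[ev$call %in% c("CO", "ME"), , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    bm <- bm_by_cancer[[cancer]]
    cl <- clinical[clinical$sample_id %in% colnames(bm), ]
    recs <- lapply(seq_len(nrow(ev)), function(k) {
      occ <- event_occurrence(bm, c(ev$gene_a[k], ev$gene_b[k]), ev$call[k])
      fisher_differential(occ, cl, alpha)
    })
    dplyr::bind_cols(
      tibble(gene_a = ev$gene_a, gene_b = ev$gene_b, type = ev$call,
             cancer = cancer,
             p_value = if ("p_co" %in% colnames(ev)) {
               ifelse(ev$call == "CO", ev$p_co, ev$p_me)
             } else NA_real_,
             q_value = if ("q_co" %in% colnames(ev)) {
               ifelse(ev$call == "CO", ev$q_co, ev$q_me)
             } else NA_real_),
      dplyr::bind_rows(recs)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  type = character(), cancer = character(),
                  p_value = numeric(), q_value = numeric(),
                  a = integer(), b = integer(), c = integer(), d = integer(),
                  p_fisher = numeric(), differential = logical()))
  }
  out
}

#' Select frequently occurring events across cancers
#'
#' Retains events that were significantly differentially occurring in at
#' least `min_cancers` different cancer types.
#'
#' @param events Tibble from [differential_events()] (one row per event and
#'   cancer, with a `differential` flag).
#' @param min_cancers Minimum number of supporting cancers (default 3).
#' @return One row per retained event: pair, `type`,
#'   `n_cancers_differential`, `cancers` (comma-joined, sorted), ordered by
#'   descending support then canonical pair.  Empty with a warning when no
#'   event qualifies.
#' @export
select_frequent <- function(events, min_cancers = 3) {
  ev <- events[!is.na(events$differential) & events$differential, , drop = FALSE]
  out <- ev |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$type) |>
    dplyr::summarise(
      n_cancers_differential = dplyr::n_distinct(.data$cancer),
      cancers = paste(sort(unique(.data$cancer)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_cancers_differential >= min_cancers) |>
    dplyr::arrange(dplyr::desc(.data$n_cancers_differential),
                   .data$gene_a, .data$gene_b, .data$type)
  if (nrow(out) == 0) {
    warning("no event is differential in >= ", min_cancers, " cancers")
  }
  out
}
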