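#' Kaplan-Meier product-limit curves
#'
#' @param records Tibble with `time` (days, > 0), `event` (0/1) and
#'   optionally `group`.
#' @return A `come_km` tibble: one row per distinct event/censoring time and
#'   group with `n_risk`, `n_event`, `n_censor` and the product-limit
#'   `survival` estimate.
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(c("time", "event") %in% colnames(records)))
  if (any(records$time <= 0)) stop("non-positive survival time")
  grp <- if ("group" %in% colnames(records)) as.character(records$group)
         else rep("all", nrow(records))
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ grp)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), "grp=all")
            else fit$strata
  out <- tibble(
    group = sub("^grp=", "", rep(names(strata), strata)),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  class(out) <- c("come_km", class(out))
  out
}

#' Multi-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance, referred to a chi-square distribution with G - 1 degrees of
#' freedom.
#'
#' @param records Tibble with `time`, `event` and `group` (>= 2 non-empty
#'   groups).
#' @return One-row tibble: `chi2`, `df`, `p_value`, `n_groups`, `n_events`.
#'   With zero events in all groups combined, `chi2 = 0`, `p = 1`.
#' @export
logrank_test <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% colnames(records)))
  grp <- as.character(records$group)
  groups <- unique(grp)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(records$time <= 0)) stop("non-positive survival time")
  df <- length(groups) - 1
  if (sum(records$event) == 0) {
    return(tibble(chi2 = 0, df = df, p_value = 1,
                  n_groups = length(groups), n_events = 0L))
  }
  sd_fit <- survival::survdiff(survival::Surv(records$time, records$event) ~ grp)
  tibble(chi2 = unname(sd_fit$chisq), df = df,
         p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
         n_groups = length(groups), n_events = sum(records$event))
}

#' Survival stratified by a single CO/ME event
#'
#' Splits samples by per-sample event occurrence (1 vs 0) and runs the
#' two-group log-rank test on the progression-free interval.
#'
#' @param pair Character vector of the two gene identifiers.
#' @param type `"CO"` or `"ME"`.
#' @param bm Binary alteration matrix covering the samples.
#' @param clinical Clinical tibble with `sample_id`, `pfi_time`, `pfi_event`.
#' @return One-row tibble: `chi2`, `df`, `p_value`, `n_with`, `n_without`.
#' @export
event_stratified_survival <- function(pair, type, bm, clinical) {
  occ <- event_occurrence(bm, pair, type)
  cl <- clinical[match(names(occ), clinical$sample_id), ]
  ok <- !is.na(cl$sample_id) & !is.na(cl$pfi_time) & !is.na(cl$pfi_event) &
    cl$pfi_time > 0
  occ <- occ[ok]; cl <- cl[ok, ]
  n1 <- sum(occ == 1); n0 <- sum(occ == 0)
  if (n1 == 0) stop("empty stratum: no sample with event occurrence")
  if (n0 == 0) stop("empty stratum: no sample without event occurrence")
  res <- logrank_test(tibble(time = cl$pfi_time, event = cl$pfi_event,
                             group = ifelse(occ == 1, "with", "without")))
  tibble(chi2 = res$chi2, df = res$df, p_value = res$p_value,
         n_with = n1, n_without = n0)
}

#' Kruskal-Wallis H test
#'
#' Rank-based comparison of a continuous variable across groups with tie
#' correction, chi-square reference with G - 1 df.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @return One-row tibble: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.factor(as.character(groups[ok]))
  if (nlevels(groups) < 2) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Pearson chi-square test of association
#'
#' Pearson chi-square on a two-way count table without continuity
#' correction, df = (r - 1)(c - 1).
#'
#' @param table A matrix of counts with all row and column margins > 0.
#' @return One-row tibble: `chi2`, `df`, `p_value`.
#' @export
chi_square_assoc <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Clinical-feature association with subtypes
#'
#' Continuous features are tested across clusters with Kruskal-Wallis,
#' categorical features with the Pearson chi-square test on the
#' cluster-by-level count table.
#'
#' @param labels Tibble with `sample_id`, `cluster`.
#' @param clinical Clinical tibble.
#' @param features Character vector of clinical column names to test.
#' @return Tibble: `feature`, `test`, `statistic`, `df`, `p_value`.
#' @export
clinical_associations <- function(labels, clinical,
                                  features = c("age", "gender",
                                               "histological_type", "grade",
                                               "stage")) {
  cl <- dplyr::inner_join(labels, clinical, by = "sample_id")
  rows <- lapply(intersect(features, colnames(cl)), function(f) {
    v <- cl[[f]]
    ok <- !is.na(v)
    if (sum(ok) == 0 || length(unique(cl$cluster[ok])) < 2) return(NULL)
    if (is.numeric(v)) {
      res <- kruskal_wallis(v[ok], cl$cluster[ok])
      tibble(feature = f, test = "kruskal_wallis", statistic = res$H,
             df = res$df, p_value = res$p_value)
    } else {
      tab <- table(cl$cluster[ok], v[ok])
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2 || ncol(tab) < 2) return(NULL)
      res <- chi_square_assoc(tab)
      tibble(feature = f, test = "chi_square", statistic = res$chi2,
             df = res$df, p_value = res$p_value)
    }
  })
  dplyr::bind_rows(rows)
}
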