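#' Plot Kaplan-Meier curves
#'
#' @param object A `come_km` tibble from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot: step survival curves per group.
#' @export
autoplot.come_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(group = unique(object$group), time = 0, survival = 1),
    tibble(group = object$group, time = object$time,
           survival = object$survival)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Progression-free survival",
                  color = "Group") +
    ggplot2::theme_minimal()
}

#' Plot consensus-clustering diagnostics
#'
#' @param object A `come_consensus` object.
#' @param type `"cdf"` for the consensus CDF curves per k, `"delta"` for the
#'   relative delta-area curve, `"silhouette"` for average silhouette per k.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.come_consensus <- function(object, type = c("cdf", "delta",
                                                     "silhouette"), ...) {
  type <- match.arg(type)
  if (type == "cdf") {
    df <- dplyr::bind_rows(lapply(as.character(object$k_range), function(k) {
      v <- sort(object$consensus[[k]][upper.tri(object$consensus[[k]])])
      tibble(k = k, value = v, cdf = seq_along(v) / length(v))
    }))
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cdf,
                                            color = .data$k)) +
             ggplot2::geom_step() +
             ggplot2::labs(x = "Consensus index", y = "CDF", color = "k") +
             ggplot2::theme_minimal())
  }
  gl <- glance(object)
  if (type == "delta") {
    ggplot2::ggplot(gl, ggplot2::aes(x = .data$k, y = .data$delta_area)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0.1, linetype = "dashed") +
      ggplot2::labs(x = "k", y = "Relative change in CDF area") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(gl, ggplot2::aes(x = .data$k, y = .data$avg_silhouette)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "k", y = "Average silhouette width") +
      ggplot2::theme_minimal()
  }
}

#' Plot hub cancer-gene fraction against top-N degree rank
#'
#' @param hubs Tibble from [hub_table()].
#' @return A ggplot of the cumulative flagged fraction by prefix size.
#' @export
plot_hub_fractions <- function(hubs) {
  ggplot2::ggplot(hubs, ggplot2::aes(x = .data$rank,
                                     y = .data$fraction_flagged)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Top N genes by degree",
                  y = "Fraction cancer genes / TSGs") +
    ggplot2::theme_minimal()
}

#' Plot pairwise correlations by event type
#'
#' @param events Tibble from [pair_correlations()] with a `call` or `type`
#'   column.
#' @param which `"r_expr"` or `"r_meth"`.
#' @return A ggplot boxplot of the correlation by event type.
#' @export
plot_pair_correlations <- function(events, which = c("r_expr", "r_meth")) {
  which <- match.arg(which)
  type_col <- if ("type" %in% colnames(events)) "type" else "call"
  df <- events[!is.na(events[[which]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[type_col]],
                                   y = .data[[which]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Event type",
                  y = if (which == "r_expr") "Expression correlation (r)"
                      else "Methylation correlation (r)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
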