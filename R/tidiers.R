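# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dbRDA fit: one row per constrained (CAP) axis
#'
#' @param x A `dbrda_fit`.
#' @param ... Unused.
#' @return Tibble with `axis`, `eigenvalue`, `prop_constrained`.
#' @export
tidy.dbrda_fit <- function(x, ...) {
  ev <- x$eigenvalues$constrained
  tibble::tibble(axis = paste0("CAP", seq_along(ev)),
                 eigenvalue = ev,
                 prop_constrained = ev / sum(ev))
}

#' One-row model summary of a dbRDA fit
#'
#' @param x A `dbrda_fit`.
#' @param ... Unused.
#' @return Tibble with `R`, `F`, `df_model`, `df_residual`, `p_perm`,
#'   `n_perm`, `method`, `n_samples`.
#' @export
glance.dbrda_fit <- function(x, ...) {
  tibble::tibble(R = x$R, F = x$F, df_model = x$df_model,
                 df_residual = x$df_residual, p_perm = x$p_perm,
                 n_perm = x$n_perm, method = x$method, n_samples = x$n_samples)
}

#' Tidy an ANOSIM fit: one row per group with its size
#' @param x An `anosim_fit`.
#' @param ... Unused.
#' @return Tibble with `group`, `n`.
#' @export
tidy.anosim_fit <- function(x, ...) {
  tibble::tibble(group = names(x$groups), n = as.integer(x$groups))
}

#' One-row summary of an ANOSIM fit
#' @param x An `anosim_fit`.
#' @param ... Unused.
#' @return Tibble with `R`, `p_perm`, `n_perm`, `method`, `n_samples`.
#' @export
glance.anosim_fit <- function(x, ...) {
  tibble::tibble(R = x$R, p_perm = x$p_perm, n_perm = x$n_perm,
                 method = x$method, n_samples = x$n_samples)
}

#' Ordination plot of dbRDA site scores
#'
#' Scatter of the first two CAP axes (or CAP1 against zero when the model
#' has a single constrained axis), optionally coloured by a grouping
#' variable such as culture or cTPut status.
#'
#' @param object A `dbrda_fit`.
#' @param groups Optional vector or sample-sheet column to colour by; a
#'   data frame with `sample_id` is joined on sample id.
#' @param group_col Column of `groups` to use when it is a data frame
#'   (default `"culture"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dbrda_fit <- function(object, groups = NULL, group_col = "culture", ...) {
  sc <- object$site_scores
  if (!"CAP2" %in% names(sc)) sc$CAP2 <- 0
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      sc$group <- groups[[group_col]][match(sc$sample_id, groups$sample_id)]
    } else {
      sc$group <- groups
    }
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$CAP1, y = .data$CAP2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::labs(x = "CAP1", y = "CAP2",
                  subtitle = sprintf("R = %.3f, F(%d,%d) = %.2f, p = %.3g",
                                     object$R, object$df_model,
                                     object$df_residual, object$F, object$p_perm)) +
    ggplot2::theme_minimal()
  if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2.5)
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
}

#' Violin/jitter plot of per-gene positive and negative edge counts
#'
#' @param counts Output of [edge_counts()], or a named list of such tibbles
#'   (one per condition) to facet the comparison.
#' @return A ggplot object.
#' @export
plot_edge_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- list(all = counts)
  long <- dplyr::bind_rows(purrr::imap(counts, function(d, nm) {
    tidyr::pivot_longer(dplyr::mutate(d, condition = nm),
                        c("n_pos", "n_neg"),
                        names_to = "edge_sign", values_to = "n")
  }))
  long$edge_sign <- ifelse(long$edge_sign == "n_pos", "positive", "negative")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$edge_sign, y = .data$n,
                                     colour = .data$edge_sign)) +
    ggplot2::geom_violin(fill = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::scale_colour_manual(values = c(positive = "firebrick",
                                            negative = "steelblue"),
                                 guide = "none") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "correlations per gene") +
    ggplot2::theme_minimal()
}

#' Heatmap of a (Ward-ordered) correlation matrix
#'
#' @param hm Output of [heatmap_order()], or a plain matrix (ordered as-is).
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(hm) {
  m <- if (is.list(hm)) hm$matrix else hm
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$rho <- m[cbind(df$row, df$col)]
  df$row_id <- factor(rownames(m)[df$row], levels = rev(rownames(m)))
  df$col_id <- factor(colnames(m)[df$col], levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_id, y = .data$row_id,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
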