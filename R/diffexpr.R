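# Per-gene and per-pathway condition contrasts with FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min_(j >= i) p_(j) * m / j, capped at 1,
#' mapped back to input order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    rlang::abort("bh_fdr: p-values must lie in [0, 1] with no NAs")
  }
  stats::p.adjust(p, method = "BH")
}

contrast_core <- function(m, group_pos, test, pseudocount, q_threshold, id_col) {
  all_zero <- rowSums(m) == 0
  if (any(all_zero)) {
    rlang::inform(sprintf("%d feature(s) all-zero in both conditions excluded",
                          sum(all_zero)))
    m <- m[!all_zero, , drop = FALSE]
  }
  if (nrow(m) == 0) rlang::abort("no non-zero features to contrast")
  a <- m[, group_pos, drop = FALSE]
  b <- m[, !group_pos, drop = FALSE]
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (test == "mann_whitney") {
      if (length(unique(c(xa, xb))) == 1) {
        list(statistic = length(xa) * length(xb) / 2, p = 1)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE, correct = TRUE))
        list(statistic = unname(wt$statistic), p = wt$p.value)
      }
    } else {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        list(statistic = 0, p = if (mean(xa) == mean(xb)) 1 else 0)
      } else {
        tt <- stats::t.test(xa, xb)
        list(statistic = unname(tt$statistic), p = tt$p.value)
      }
    }
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- tibble::tibble(
    !!id_col := rownames(m),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p = p,
    q = bh_fdr(p),
    mean_pos = unname(rowMeans(a)),
    mean_neg = unname(rowMeans(b)),
    log2FC = unname(log2((rowMeans(a) + pseudocount) /
                           (rowMeans(b) + pseudocount)))
  )
  out$significant <- out$q < q_threshold
  out
}

#' Per-gene contrast between cTPut-positive and cTPut-negative samples
#'
#' One test per gene (Mann-Whitney by default, Welch t optional), BH
#' adjustment over all tested genes, and a fold change
#' `log2FC = log2((mean_pos + pc) / (mean_neg + pc))`. Genes that are
#' all-zero in both conditions are excluded (count reported).
#'
#' @param counts Count tibble (typically standardized).
#' @param samples Sample sheet; `ctput_status` defines the two conditions.
#' @param test `"mann_whitney"` or `"t"` (Welch).
#' @param pseudocount Added to both means for the fold change.
#' @param q_threshold Significance threshold on q.
#' @return Tibble with `gene_id`, `statistic`, `p`, `q`, `mean_pos`,
#'   `mean_neg`, `log2FC`, `significant`; attribute `test` records the test.
#' @export
contrast_genes <- function(counts, samples, test = c("mann_whitney", "t"),
                           pseudocount = 1, q_threshold = 0.05) {
  test <- match.arg(test)
  validate_counts(counts); validate_samples(samples, counts)
  m <- count_matrix(counts)
  status <- samples$ctput_status[match(colnames(m), samples$sample_id)]
  if (sum(status) < 3 || sum(!status) < 3) {
    rlang::abort("contrast_genes: both conditions need >= 3 samples")
  }
  out <- contrast_core(m, status, test, pseudocount, q_threshold, "gene_id")
  attr(out, "test") <- test
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Pathway-level contrast
#'
#' Pathway expression is the per-sample sum of member-gene expression (a
#' gene in several pathways contributes to each); the contrast then follows
#' [contrast_genes()] at pathway level with BH across pathways.
#'
#' @param counts Count tibble.
#' @param samples Sample sheet.
#' @param catalog Long-format pathway catalog.
#' @inheritParams contrast_genes
#' @return Tibble like [contrast_genes()] with `pathway_id` instead of
#'   `gene_id`.
#' @export
contrast_pathways <- function(counts, samples, catalog,
                              test = c("mann_whitney", "t"),
                              pseudocount = 1, q_threshold = 0.05) {
  test <- match.arg(test)
  validate_counts(counts); validate_samples(samples, counts)
  m <- count_matrix(counts)
  pws <- unique(catalog$pathway_id)
  rows <- lapply(pws, function(pw) {
    genes <- intersect(catalog$gene_id[catalog$pathway_id == pw], rownames(m))
    if (length(genes) == 0) return(NULL)
    colSums(m[genes, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep)) {
    rlang::warn(sprintf("%d empty pathway(s) skipped", sum(!keep)))
  }
  pm <- do.call(rbind, rows[keep])
  rownames(pm) <- pws[keep]
  status <- samples$ctput_status[match(colnames(pm), samples$sample_id)]
  if (sum(status) < 3 || sum(!status) < 3) {
    rlang::abort("contrast_pathways: both conditions need >= 3 samples")
  }
  out <- contrast_core(pm, status, test, pseudocount, q_threshold, "pathway_id")
  attr(out, "test") <- test
  attr(out, "pseudocount") <- pseudocount
  out
}
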