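# Library-size standardization and simple transforms.
#
# "Standardized to N reads" supports two readings: deterministic
# proportional scaling (default; preserves within-sample proportions and
# therefore every rank-based statistic downstream) and multinomial
# downsampling (rarefaction to exactly N integer reads, seeded).

#' Standardize each sample to a fixed total
#'
#' @param counts Count tibble.
#' @param target_total Target per-sample total (e.g. 3000 for the symbiont
#'   compartment, 5000 for Cardinium).
#' @param mode `"scale"` (multiply each column by `target/total`; real-valued
#'   output) or `"downsample"` (multinomial subsample of exactly
#'   `target_total` reads; requires integer totals at or above the target).
#' @param seed Seed used in downsample mode.
#' @return A count tibble with attributes `normalization` (method tag) and,
#'   in downsample mode, `seed`.
#' @export
standardize_counts <- function(counts, target_total, mode = c("scale", "downsample"),
                               seed = 1L) {
  mode <- match.arg(mode)
  validate_counts(counts)
  stopifnot(target_total > 0)
  m <- count_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    rlang::abort(paste0("standardize_counts: zero-total sample(s): ",
                        paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  if (mode == "scale") {
    m <- sweep(m, 2, target_total / totals, `*`)
  } else {
    if (any(totals < target_total)) {
      rlang::abort(paste0("downsample: sample total below target for: ",
                          paste(colnames(m)[totals < target_total], collapse = ", ")))
    }
    if (any(m != round(m))) {
      rlang::abort("downsample requires integer counts")
    }
    m <- with_seed(seed, {
      apply_cols <- vapply(seq_len(ncol(m)), function(j) {
        stats::rmultinom(1, size = target_total, prob = m[, j])[, 1]
      }, numeric(nrow(m)))
      dimnames(apply_cols) <- dimnames(m)
      apply_cols
    })
  }
  out <- as_counts(m, attr(counts, "compartment"))
  attr(out, "normalization") <- paste0("standardize:", mode, ":", target_total)
  if (mode == "downsample") attr(out, "seed") <- as.integer(seed)
  out
}

#' Symbiont-to-host relative abundance per sample
#'
#' The ratio of symbiont mapped reads to host mapped reads, the study's
#' indicator of symbiont expression level.
#'
#' @param sym_reads Per-sample symbiont read totals (named numeric vector
#'   or count tibble, in which case column sums are used).
#' @param host_reads Per-sample host read totals, same samples.
#' @return Tibble with `sample_id` and `rel_abundance`.
#' @export
relative_abundance <- function(sym_reads, host_reads) {
  tot <- function(x) if (is.data.frame(x)) colSums(count_matrix(x)) else x
  s <- tot(sym_reads); h <- tot(host_reads)
  if (!is.null(names(s)) && !is.null(names(h))) {
    shared <- intersect(names(s), names(h))
    if (length(shared) == 0) rlang::abort("relative_abundance: no shared samples")
    s <- s[shared]; h <- h[shared]
  } else if (length(s) != length(h)) {
    rlang::abort("relative_abundance: length mismatch")
  }
  if (any(h <= 0)) rlang::abort("relative_abundance: host total must be > 0")
  if (any(s < 0)) rlang::abort("relative_abundance: negative symbiont total")
  tibble::tibble(sample_id = names(s) %||% as.character(seq_along(s)),
                 rel_abundance = as.numeric(s / h))
}

#' Per-sample Shannon diversity of gene expression
#'
#' H = -sum p_i log p_i over genes with p_i > 0, per sample.
#'
#' @param counts Count tibble.
#' @param base `"e"` (natural log, default) or `"2"` (bits).
#' @return Tibble with `sample_id` and `shannon`.
#' @export
shannon_diversity <- function(counts, base = c("e", "2")) {
  base <- match.arg(as.character(base[1]), c("e", "2"))
  validate_counts(counts)
  m <- count_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    rlang::abort(paste0("shannon_diversity: all-zero sample(s): ",
                        paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  logb <- if (base == "e") log else log2
  h <- vapply(seq_len(ncol(m)), function(j) {
    p <- m[, j] / totals[j]
    p <- p[p > 0]
    -sum(p * logb(p))
  }, numeric(1))
  tibble::tibble(sample_id = colnames(m), shannon = h)
}

#' Elementwise log transform with pseudocount
#'
#' @param counts Count tibble.
#' @param base 2 or 10.
#' @param pseudocount Added before the log; must be positive if zeros are
#'   present.
#' @return Transformed count tibble with a `normalization` attribute.
#' @export
log_transform <- function(counts, base = 2, pseudocount = 1) {
  validate_counts(counts)
  stopifnot(base %in% c(2, 10), pseudocount >= 0)
  m <- count_matrix(counts)
  if (pseudocount == 0 && any(m == 0)) {
    rlang::abort("log_transform: zeros present; use a positive pseudocount")
  }
  m <- log(m + pseudocount, base = base)
  out <- as_counts(m, attr(counts, "compartment"))
  attr(out, "normalization") <- sprintf("log%d+%g", base, pseudocount)
  out
}

#' Preprocess qPCR copy-number values
#'
#' Values below the detection limit are replaced with zero, then everything
#' is log10(x + 1) transformed — the study's handling of per-mite / per-egg
#' symbiont copy numbers with a detection threshold of 10 copies.
#'
#' @param values Non-negative copy numbers.
#' @param detection_limit Positive detection threshold (default 10).
#' @return Numeric vector of log10-transformed values.
#' @export
qpcr_preprocess <- function(values, detection_limit = 10) {
  stopifnot(detection_limit > 0)
  if (any(values < 0)) rlang::abort("qpcr_preprocess: negative input")
  values[values < detection_limit] <- 0
  log10(values + 1)
}
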