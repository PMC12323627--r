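#' @importFrom rlang %||% abort warn inform .data :=
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows distinct rename n across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor sd var quantile pnorm qnbinom rnorm runif setNames
#'   p.adjust t.test wilcox.test hclust as.dist dist fisher.test rlnorm
#'   complete.cases model.matrix
#' @importFrom utils head combn
NULL

# Column layout shared by all count tables: first column `gene_id`, one
# numeric column per sample.

#' Convert a count tibble to a numeric matrix (genes x samples)
#'
#' @param counts A count tibble with a `gene_id` column followed by one
#'   numeric column per sample.
#' @return Numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts$gene_id)
  m
}

#' Convert a genes x samples matrix to a count tibble
#'
#' @param m Numeric matrix with gene row names and sample column names.
#' @param compartment Optional compartment label stored as an attribute.
#' @return A tibble with `gene_id` plus one column per sample.
#' @export
as_counts <- function(m, compartment = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  if (!is.null(compartment)) attr(out, "compartment") <- compartment
  out
}

sample_ids <- function(counts) {
  nm <- names(counts)
  nm[nm != "gene_id"]   # keeps duplicates so validation can catch them
}

#' Validate a count tibble
#'
#' Checks the invariants every expression table must satisfy: unique gene
#' and sample identifiers, numeric counts, no missing values, all counts
#' non-negative.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param compartment Optional label used in error messages.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts, compartment = NULL) {
  lbl <- if (is.null(compartment)) "count table" else paste0(compartment, " count table")
  if (!is.data.frame(counts) || names(counts)[1] != "gene_id") {
    rlang::abort(paste0(lbl, ": first column must be 'gene_id'"))
  }
  dup_g <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup_g) > 0) {
    rlang::abort(paste0(lbl, ": duplicated gene id(s): ",
                        paste(unique(dup_g), collapse = ", ")))
  }
  sids <- sample_ids(counts)
  dup_s <- sids[duplicated(sids)]
  if (length(dup_s) > 0) {
    rlang::abort(paste0(lbl, ": duplicated sample id(s): ",
                        paste(unique(dup_s), collapse = ", ")))
  }
  if (length(sids) == 0) rlang::abort(paste0(lbl, ": no sample columns"))
  m <- as.matrix(counts[sids])
  if (!is.numeric(m)) rlang::abort(paste0(lbl, ": counts must be numeric"))
  if (anyNA(m)) rlang::abort(paste0(lbl, ": missing values are not permitted"))
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf("%s: negative count at gene '%s', sample '%s'",
                         lbl, counts$gene_id[bad[1, 1]], sids[bad[1, 2]]))
  }
  invisible(counts)
}

#' Validate a sample sheet against count tables
#'
#' @param samples Tibble with columns `sample_id`, `culture`, `ctput_status`
#'   (logical), `replicate`.
#' @param counts Optional count tibble whose samples must all be described.
#' @return The sample sheet, invisibly.
#' @export
validate_samples <- function(samples, counts = NULL) {
  need <- c("sample_id", "culture", "ctput_status", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    rlang::abort(paste0("sample sheet: missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    rlang::abort("sample sheet: duplicated sample_id")
  }
  map <- unique(samples[c("culture", "ctput_status")])
  if (anyDuplicated(map$culture)) {
    rlang::abort("sample sheet: a culture maps to more than one ctput_status")
  }
  if (!is.null(counts)) {
    missing_s <- setdiff(sample_ids(counts), samples$sample_id)
    if (length(missing_s) > 0) {
      rlang::abort(paste0("sample(s) absent from sample sheet: ",
                          paste(missing_s, collapse = ", ")))
    }
  }
  invisible(samples)
}

# derive a reproducible child seed from a global seed and a stage name,
# kept inside the 32-bit integer range
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}
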