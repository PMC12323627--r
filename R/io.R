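#' Read a gene-by-sample count table
#'
#' Reads a tab-separated count table whose first column holds gene
#' identifiers and whose header row holds sample identifiers, and validates
#' it (unique ids, non-negative complete counts).
#'
#' @param path Path to a TSV file.
#' @param compartment Compartment label (`"host"`, `"SOL"`, `"cTPut"`, or any
#'   other tag); stored as the `compartment` attribute of the result.
#' @return A count tibble: `gene_id` plus one numeric column per sample, in
#'   file order.
#' @export
read_counts <- function(path, compartment = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("count table not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "gene_id"
  tab$gene_id <- as.character(tab$gene_id)
  validate_counts(tab, compartment)
  if (!is.null(compartment)) attr(tab, "compartment") <- compartment
  tab
}

#' Write a count table to TSV
#'
#' @param counts Count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `culture`, `ctput_status` (logical or
#' TRUE/FALSE strings), `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("sample sheet not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    culture = readr::col_character(),
    ctput_status = readr::col_logical(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  validate_samples(tab)
  tab
}

#' Write a sample sheet to TSV
#' @param samples Sample-sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_samples(samples)
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' A gene may belong to several pathways; that multiplicity is kept and is
#' meaningful to downstream network scoring.
#'
#' @param path Path to a GMT file.
#' @return A long-format pathway catalog: tibble with columns `pathway_id`,
#'   `description`, `gene_id` (one row per membership).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(pathway_id = character(), description = character(),
                          gene_id = character()))
  }
  rows <- purrr::map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      rlang::abort(paste0("GMT: pathway '", parts[1], "' has an empty member list"))
    }
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      rlang::abort(paste0("GMT: pathway '", parts[1], "' has an empty member list"))
    }
    tibble::tibble(pathway_id = parts[1], description = parts[2], gene_id = genes)
  })
  catalog <- dplyr::bind_rows(rows)
  if (anyDuplicated(catalog[c("pathway_id", "gene_id")])) {
    catalog <- dplyr::distinct(catalog, .data$pathway_id, .data$gene_id, .keep_all = TRUE)
  }
  catalog
}

#' Write a pathway catalog to a GMT file
#' @param catalog Long-format catalog tibble (`pathway_id`, `description`,
#'   `gene_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(all(c("pathway_id", "gene_id") %in% names(catalog)))
  if (!"description" %in% names(catalog)) catalog$description <- catalog$pathway_id
  split_by <- split(catalog, factor(catalog$pathway_id, levels = unique(catalog$pathway_id)))
  lines <- purrr::map_chr(split_by, function(d) {
    paste(c(d$pathway_id[1], d$description[1], d$gene_id), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

edge_columns <- c("source_gene", "source_compartment", "target_gene",
                  "target_compartment", "rho", "p_perm", "sign", "pathway_context")

#' Write an edge table
#'
#' TSV keeps all columns (rho, permutation p, sign, pathway context). SIF is
#' the Cytoscape simple-interaction format with interaction labels `"pos"`
#' and `"neg"` taken from the edge sign.
#'
#' @param edges Edge tibble as produced by [correlate_compartments()].
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path, format = c("tsv", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) rlang::abort(
                       paste0("unknown edge format: ", format[1])))
  miss <- setdiff(setdiff(edge_columns, "pathway_context"), names(edges))
  if (length(miss) > 0) {
    rlang::abort(paste0("edge table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"pathway_context" %in% names(edges)) edges$pathway_context <- NA_character_
  if (format == "tsv") {
    readr::write_tsv(edges[edge_columns], path, progress = FALSE)
  } else {
    lines <- sprintf("%s\t%s\t%s", edges$source_gene,
                     ifelse(edges$sign > 0, "pos", "neg"), edges$target_gene)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an edge table written by [write_edges()] in TSV format
#' @param path Path to a TSV edge file.
#' @return Edge tibble.
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source_gene = readr::col_character(),
    source_compartment = readr::col_character(),
    target_gene = readr::col_character(),
    target_compartment = readr::col_character(),
    rho = readr::col_double(),
    p_perm = readr::col_double(),
    sign = readr::col_integer(),
    pathway_context = readr::col_character()
  ), progress = FALSE)
}
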