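# Permutation-based Spearman edge calling between expression compartments
# and the per-gene network scores used for hub detection.

#' Settings for edge calling and hub scoring
#'
#' @param n_perm Number of Monte Carlo permutations (exact enumeration is
#'   used automatically for n <= 7 samples).
#' @param alpha Permutation p-value threshold for retaining an edge.
#' @param rho_min,rho_max Absolute-correlation window for retained edges;
#'   the hub analysis of the study used `rho_min = 0.75`.
#' @param seed Seed for the permutation stream.
#' @param strength_mode `"pathway_instance"` (each partner-gene x pathway
#'   membership is one counted edge) or `"abs_rho"` (strength is the sum of
#'   absolute correlations over distinct partners).
#' @param min_strength Strict lower bound on `s_strength` for [filter_hubs()]
#'   (the study used 100 against its full-size host gene set).
#' @return A `corr_config` list.
#' @export
corr_config <- function(n_perm = 9999, alpha = 0.05, rho_min = 0, rho_max = 1,
                        seed = 1L, strength_mode = c("pathway_instance", "abs_rho"),
                        min_strength = 100) {
  strength_mode <- match.arg(strength_mode)
  stopifnot(n_perm >= 99, rho_min >= 0, rho_min <= rho_max, rho_max <= 1,
            alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 rho_min = rho_min, rho_max = rho_max, seed = as.integer(seed),
                 strength_mode = strength_mode, min_strength = min_strength),
            class = "corr_config")
}

# all permutations of 1..n (n! rows); used for exact tests at small n
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman correlation with a permutation p-value
#'
#' rho is the Pearson correlation of average-ranked data. The p-value is
#' two-sided: the proportion of permutations whose |rho| reaches the
#' observed |rho|. All n! permutations are enumerated when n <= 7;
#' otherwise `n_perm` Monte Carlo draws are used with the add-one
#' correction p = (1 + extreme) / (1 + n_perm), so p is never 0.
#'
#' @param x,y Numeric vectors over the same samples, length >= 4, each with
#'   at least two distinct values.
#' @param n_perm Monte Carlo permutation count.
#' @param seed Seed for the Monte Carlo stream (ignored in exact mode).
#' @return List with `rho`, `p_perm`, `method` ("exact" or "monte_carlo"),
#'   and `n_perm` (permutations actually used).
#' @export
spearman_perm <- function(x, y, n_perm = 9999, seed = 1L) {
  n <- length(x)
  if (length(y) != n) rlang::abort("spearman_perm: length mismatch")
  if (n < 4) rlang::abort("spearman_perm: need n >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::abort("spearman_perm: constant vector; rho undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tol <- 1e-12
  if (n <= 7) {
    P <- all_perms(n)
    rstars <- as.vector(stats::cor(rx, t(matrix(ry[P], nrow(P), n))))
    p <- mean(abs(rstars) >= abs(rho) - tol)
    list(rho = rho, p_perm = p, method = "exact", n_perm = nrow(P))
  } else {
    extreme <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(rx, sample(ry))) >= abs(rho) - tol
      }, logical(1)))
    })
    list(rho = rho, p_perm = (1 + extreme) / (1 + n_perm),
         method = "monte_carlo", n_perm = as.integer(n_perm))
  }
}

# resolve a sample subset: NULL, "ctput_positive"/"ctput_negative" (needs a
# sample sheet), or an explicit character vector of sample ids
resolve_subset <- function(shared, subset, samples) {
  if (is.null(subset)) return(shared)
  if (is.character(subset) && length(subset) == 1 &&
      subset %in% c("ctput_positive", "ctput_negative")) {
    if (is.null(samples)) rlang::abort("subset by cTPut status needs a sample sheet")
    keep <- samples$sample_id[samples$ctput_status == (subset == "ctput_positive")]
    return(intersect(shared, keep))
  }
  intersect(shared, subset)
}

rank_rows <- function(m) t(apply(m, 1, rank))

#' Full Spearman correlation matrix between two compartments
#'
#' @param a,b Count tibbles.
#' @param samples Optional sample sheet (needed for status subsets).
#' @param subset `NULL`, `"ctput_positive"`, `"ctput_negative"`, or sample ids.
#' @return Numeric matrix (genes of `a` x genes of `b`) of Spearman rho;
#'   rows/columns for zero-variance genes are dropped with a warning.
#' @export
spearman_matrix <- function(a, b, samples = NULL, subset = NULL) {
  prep <- prep_pair(a, b, samples, subset)
  stats::cor(t(prep$ra), t(prep$rb))
}

prep_pair <- function(a, b, samples = NULL, subset = NULL, min_n = 4) {
  validate_counts(a); validate_counts(b)
  shared <- intersect(sample_ids(a), sample_ids(b))
  shared <- resolve_subset(shared, subset, samples)
  if (length(shared) < min_n) {
    rlang::abort(sprintf("need at least %d shared samples, got %d", min_n, length(shared)))
  }
  ma <- count_matrix(a)[, shared, drop = FALSE]
  mb <- count_matrix(b)[, shared, drop = FALSE]
  drop_constant <- function(m, lbl) {
    keep <- apply(m, 1, function(r) length(unique(r)) > 1)
    if (any(!keep)) {
      rlang::warn(sprintf("%d zero-variance gene(s) skipped in %s", sum(!keep), lbl))
    }
    m[keep, , drop = FALSE]
  }
  ma <- drop_constant(ma, "first compartment")
  mb <- drop_constant(mb, "second compartment")
  if (nrow(ma) == 0 || nrow(mb) == 0) rlang::abort("no variable genes left")
  list(ra = rank_rows(ma), rb = rank_rows(mb), samples = shared,
       comp_a = attr(a, "compartment") %||% "A",
       comp_b = attr(b, "compartment") %||% "B")
}

#' Call significant cross-compartment correlation edges
#'
#' Tests every gene pair between two compartments with permutation-based
#' Spearman correlation and retains edges with `p_perm < alpha` and
#' `rho_min <= |rho| <= rho_max`. One shared permutation stream is used for
#' the whole matrix: each permutation reshuffles the sample alignment of
#' the second compartment, which preserves the marginal validity of every
#' pairwise p-value. Exact enumeration replaces Monte Carlo when the
#' number of shared samples is <= 7.
#'
#' @param a,b Count tibbles (the `compartment` attribute, when present,
#'   labels the edge endpoints).
#' @param config A [corr_config()].
#' @param samples Optional sample sheet.
#' @param subset Sample subset (see [spearman_matrix()]); the study called
#'   symbiont-symbiont edges on the 14 cTPut-positive samples only.
#' @return Edge tibble: `source_gene`, `source_compartment`, `target_gene`,
#'   `target_compartment`, `rho`, `p_perm`, `sign`, `pathway_context` (NA),
#'   with attributes `n_samples`, `n_perm`, `method`, `seed`.
#' @export
correlate_compartments <- function(a, b, config = corr_config(),
                                   samples = NULL, subset = NULL) {
  stopifnot(inherits(config, "corr_config"))
  prep <- prep_pair(a, b, samples, subset)
  ra <- prep$ra; rb <- prep$rb
  n <- length(prep$samples)
  rho <- stats::cor(t(ra), t(rb))
  tol <- 1e-12
  thr <- abs(rho) - tol
  counts <- matrix(0L, nrow(rho), ncol(rho))
  if (n <= 7) {
    P <- all_perms(n)
    for (k in seq_len(nrow(P))) {
      rstar <- stats::cor(t(ra), t(rb[, P[k, ], drop = FALSE]))
      counts <- counts + (abs(rstar) >= thr)
    }
    p <- counts / nrow(P)
    method <- "exact"; n_perm <- nrow(P)
  } else {
    counts <- with_seed(config$seed, {
      acc <- counts
      for (k in seq_len(config$n_perm)) {
        rstar <- stats::cor(t(ra), t(rb[, sample(n), drop = FALSE]))
        acc <- acc + (abs(rstar) >= thr)
      }
      acc
    })
    p <- (1 + counts) / (1 + config$n_perm)
    method <- "monte_carlo"; n_perm <- config$n_perm
  }
  keep <- which(p < config$alpha & abs(rho) >= config$rho_min &
                  abs(rho) <= config$rho_max + tol, arr.ind = TRUE)
  rho_kept <- rho[keep]
  edges <- tibble::tibble(
    source_gene = rownames(rho)[keep[, 1]],
    source_compartment = prep$comp_a,
    target_gene = colnames(rho)[keep[, 2]],
    target_compartment = prep$comp_b,
    rho = rho_kept,
    p_perm = p[keep],
    sign = ifelse(rho_kept > 0, 1L, -1L),
    pathway_context = NA_character_
  )
  edges <- dplyr::arrange(edges, .data$p_perm, dplyr::desc(abs(.data$rho)))
  attr(edges, "n_samples") <- n
  attr(edges, "n_perm") <- n_perm
  attr(edges, "method") <- method
  attr(edges, "seed") <- config$seed
  edges
}

# long view of an edge table from the side of one focal compartment
focal_edges <- function(edges, focal_compartment) {
  fwd <- dplyr::filter(edges, .data$source_compartment == focal_compartment)
  rev <- dplyr::filter(edges, .data$target_compartment == focal_compartment,
                       .data$source_compartment != focal_compartment)
  dplyr::bind_rows(
    dplyr::transmute(fwd, gene_id = .data$source_gene,
                     partner_gene = .data$target_gene,
                     rho = .data$rho, sign = .data$sign),
    dplyr::transmute(rev, gene_id = .data$target_gene,
                     partner_gene = .data$source_gene,
                     rho = .data$rho, sign = .data$sign)
  )
}

#' Per-gene network scores (N, S_type, S_strength)
#'
#' For each focal-compartment gene: `n_partners` is the number of distinct
#' partner genes; `s_type` is the signed sum (+1 per positive, -1 per
#' negative) over counted edges; `s_strength` is the total over counted
#' edges. In `"pathway_instance"` mode each (partner gene, pathway
#' membership) is one counted edge — a partner belonging to four pathways
#' contributes four counted edges — so `s_strength` is the counted-edge
#' total; partners absent from the catalog count once, with a warning. In
#' `"abs_rho"` mode counted edges are the distinct partners and
#' `s_strength` is the sum of |rho|.
#'
#' @param edges Edge tibble.
#' @param focal_compartment Compartment whose genes are scored.
#' @param catalog Long-format pathway catalog (required for
#'   `"pathway_instance"` mode); memberships of the partner genes.
#' @param mode Strength mode.
#' @param universe Optional gene ids to report even when they have no
#'   edges (scores 0).
#' @return Tibble with `gene_id`, `n_partners`, `s_type`, `s_strength`.
#' @export
gene_stats <- function(edges, focal_compartment, catalog = NULL,
                       mode = c("pathway_instance", "abs_rho"),
                       universe = NULL) {
  mode <- match.arg(mode)
  fe <- focal_edges(edges, focal_compartment)
  fe <- dplyr::distinct(fe, .data$gene_id, .data$partner_gene, .keep_all = TRUE)
  if (mode == "pathway_instance") {
    if (is.null(catalog)) rlang::abort("pathway_instance mode needs a catalog")
    mult <- dplyr::count(catalog, .data$gene_id, name = "k")
    fe <- dplyr::left_join(fe, mult, by = c(partner_gene = "gene_id"))
    n_missing <- sum(is.na(fe$k))
    if (n_missing > 0) {
      rlang::warn(sprintf(
        "%d partner gene(s) absent from the pathway catalog; counted once", n_missing))
      fe$k[is.na(fe$k)] <- 1L
    }
    out <- fe |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(n_partners = dplyr::n_distinct(.data$partner_gene),
                       s_type = sum(.data$sign * .data$k),
                       s_strength = sum(.data$k), .groups = "drop")
  } else {
    out <- fe |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(n_partners = dplyr::n_distinct(.data$partner_gene),
                       s_type = sum(.data$sign),
                       s_strength = sum(abs(.data$rho)), .groups = "drop")
  }
  if (!is.null(universe)) {
    zero <- tibble::tibble(gene_id = setdiff(universe, out$gene_id),
                           n_partners = 0L, s_type = 0, s_strength = 0)
    out <- dplyr::bind_rows(out, zero)
    out <- out[match(universe, out$gene_id), ]
    out <- out[!is.na(out$gene_id), ]
  }
  attr(out, "strength_mode") <- mode
  out
}

#' Retain hub genes by total strength
#'
#' Keeps genes whose `s_strength` strictly exceeds `min_strength` (the
#' study's cutoff was 100; a gene at exactly the cutoff is excluded).
#'
#' @param stats Output of [gene_stats()].
#' @param min_strength Strict lower bound; defaults to the value in `config`.
#' @param config Optional [corr_config()] providing the default.
#' @return Filtered stats tibble, sorted by decreasing strength.
#' @export
filter_hubs <- function(stats, min_strength = NULL, config = corr_config()) {
  min_strength <- min_strength %||% config$min_strength
  out <- dplyr::filter(stats, .data$s_strength > min_strength)
  dplyr::arrange(out, dplyr::desc(.data$s_strength))
}

#' Per-gene positive/negative edge counts
#'
#' @param edges Edge tibble.
#' @param focal_compartment Compartment whose genes are counted.
#' @return Tibble with `gene_id`, `n_pos`, `n_neg`.
#' @export
edge_counts <- function(edges, focal_compartment) {
  fe <- focal_edges(edges, focal_compartment)
  fe <- dplyr::distinct(fe, .data$gene_id, .data$partner_gene, .keep_all = TRUE)
  fe |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_pos = sum(.data$sign > 0), n_neg = sum(.data$sign < 0),
                     .groups = "drop")
}

#' Paired comparison of per-gene correlation counts between conditions
#'
#' Genes are paired by id across the two conditions; genes present in only
#' one condition are dropped (count reported). A paired t-test is run
#' separately on the positive and on the negative counts. When the paired
#' differences have zero variance the t statistic is 0 (all differences
#' zero) or +/-Inf (constant nonzero difference), with `p` 1 or 0 and a
#' warning.
#'
#' @param counts_a,counts_b Outputs of [edge_counts()] for the two
#'   conditions.
#' @return Tibble with one row per edge sign: `edge_sign`, `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `n_pairs`, `n_dropped`.
#' @export
compare_edge_counts <- function(counts_a, counts_b) {
  joined <- dplyr::inner_join(counts_a, counts_b, by = "gene_id",
                              suffix = c("_a", "_b"))
  n_dropped <- nrow(counts_a) + nrow(counts_b) - 2 * nrow(joined)
  if (nrow(joined) < 2) rlang::abort("compare_edge_counts: fewer than 2 paired genes")
  one <- function(xa, xb, lbl) {
    d <- xa - xb
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        t <- 0; p <- 1
      } else {
        rlang::warn(paste0(lbl, " counts: paired differences have zero variance"))
        t <- sign(mean(d)) * Inf; p <- 0
      }
      df <- length(d) - 1
    } else {
      tt <- stats::t.test(xa, xb, paired = TRUE)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    tibble::tibble(edge_sign = lbl, t = t, df = df, p = p,
                   mean_a = mean(xa), mean_b = mean(xb),
                   n_pairs = length(d), n_dropped = n_dropped)
  }
  dplyr::bind_rows(one(joined$n_pos_a, joined$n_pos_b, "positive"),
                   one(joined$n_neg_a, joined$n_neg_b, "negative"))
}

#' Ward-clustered ordering of a correlation matrix
#'
#' Orders rows and columns by Ward-linkage hierarchical clustering on the
#' Euclidean distance between correlation profiles; values are unchanged.
#' The reordered matrix is what heatmap renderers consume.
#'
#' @param rho Numeric correlation matrix (square or rectangular), no NAs.
#' @return List with `matrix` (reordered), `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust` (NULL for single-row/column inputs).
#' @export
heatmap_order <- function(rho) {
  if (!is.matrix(rho)) rho <- as.matrix(rho)
  if (anyNA(rho)) rlang::abort("heatmap_order: NA correlation entries")
  cl <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hclust = NULL))
    hc <- stats::hclust(stats::dist(m), method = "ward.D2")
    list(order = hc$order, hclust = hc)
  }
  r <- cl(rho); cc <- cl(t(rho))
  list(matrix = rho[r$order, cc$order, drop = FALSE],
       row_order = r$order, col_order = cc$order,
       row_hclust = r$hclust, col_hclust = cc$hclust)
}
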