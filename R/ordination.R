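# Distances, distance-based redundancy analysis (dbRDA) with Monte Carlo
# permutation tests, forward model selection, ANOSIM, and the per-pathway
# model-comparison ledger.
#
# dbRDA follows the principal-coordinate route: Gower-center the squared
# distances, project the positive-eigenvalue coordinates onto the predictor
# space. Explained variability R is the multivariate regression R^2 on those
# coordinates (so R is always in [0, 1] even for semi-metric distances); the
# pseudo-F is trace-based on the full Gower matrix, which makes it identical
# to the PERMANOVA pseudo-F computed from within/between sums of squared
# distances when the predictor is a group factor.

#' Bray-Curtis dissimilarity between samples
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over genes.
#'
#' @param counts Count tibble (samples are columns).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(counts) {
  validate_counts(counts)
  m <- t(count_matrix(counts))  # samples x genes
  n <- nrow(m)
  if (n < 2) rlang::abort("bray_curtis: need at least 2 samples")
  tot <- rowSums(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      denom <- tot[i] + tot[j]
      if (denom == 0) {
        rlang::abort(sprintf("bray_curtis: samples '%s' and '%s' are both all-zero",
                             rownames(m)[i], rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  stats::as.dist(d)
}

#' Robust centered log-ratio (rclr) transform
#'
#' Per sample, positive counts are log-transformed and centered on the mean
#' log of the positive entries only (the geometric mean over nonzero
#' parts); zeros stay 0 after centering. This is the stated zero
#' convention, a deliberate simplification of matrix-completion-based
#' robust Aitchison estimators.
#'
#' @param counts Count tibble.
#' @return Samples x genes numeric matrix of rclr values.
#' @export
rclr_transform <- function(counts) {
  validate_counts(counts)
  m <- t(count_matrix(counts))
  zero_rows <- rowSums(m > 0) == 0
  if (any(zero_rows)) {
    rlang::abort(paste0("rclr: all-zero sample(s): ",
                        paste(rownames(m)[zero_rows], collapse = ", ")))
  }
  t(apply(m, 1, function(x) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- log(x[pos]) - mean(log(x[pos]))
    out
  }))
}

#' Robust Aitchison distance between samples
#'
#' Euclidean distance on [rclr_transform()]ed samples; a metric (it is
#' Euclidean on the transformed rows).
#'
#' @param counts Count tibble.
#' @return A `dist` object over samples.
#' @export
robust_aitchison <- function(counts) {
  stats::dist(rclr_transform(counts))
}

#' Gower-centered matrix of a distance object
#'
#' G = -1/2 J (d o d) J with J = I - 11'/n; symmetric with zero row sums.
#' Its eigenvectors scaled by the square roots of the positive eigenvalues
#' are the classical principal coordinates.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @return Numeric n x n matrix.
#' @export
gower_center <- function(d) {
  dm <- as.matrix(d)
  if (max(abs(dm - t(dm))) > 1e-12) rlang::abort("gower_center: asymmetric input")
  n <- nrow(dm)
  a <- -0.5 * dm^2
  a <- sweep(a, 1, rowMeans(a))
  a <- sweep(a, 2, colMeans(a))
  # second sweep used column means of the row-swept matrix, which completes
  # the double centering: J A J
  a
}

# design matrix from a predictor table/vector: expand factors, drop the
# intercept, center columns, drop aliased (rank-deficient) columns
build_design <- function(predictors, n) {
  if (is.null(dim(predictors))) predictors <- data.frame(x = predictors)
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != n) rlang::abort("predictor rows must match distance samples")
  chr <- vapply(predictors, is.character, logical(1))
  predictors[chr] <- lapply(predictors[chr], factor)
  X <- stats::model.matrix(~ ., data = predictors)[, -1, drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[seq(q$rank + 1, ncol(X))]]
    rlang::warn(paste0("dropping aliased predictor column(s): ",
                       paste(dropped, collapse = ", ")))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  X
}

trace_HG <- function(X, G) {
  # tr(H G H) = tr(H G) for projector H = X (X'X)^-1 X'
  Q <- qr.Q(qr(X))
  sum((t(Q) %*% G) * t(Q))
}

#' Distance-based redundancy analysis with a permutation test
#'
#' Fits predictors to the principal coordinates of an arbitrary
#' dissimilarity matrix. `R` is the fraction of positive inertia explained;
#' the pseudo-F is trace-based (McArdle-Anderson), so with a single group
#' factor it equals the PERMANOVA pseudo-F. Significance comes from a
#' Monte Carlo permutation test that reshuffles the sample rows of the
#' predictors (10,000 permutations by default); all distinct permutations
#' are enumerated instead when the sample count is <= 7.
#'
#' @param d `dist` object or symmetric distance matrix over samples.
#' @param predictors Vector, factor, or samples x variables table. A
#'   `sample_id` column, when present, is used to align rows with `d`.
#' @param n_perm Permutation count.
#' @param seed Seed for the permutation stream.
#' @return A `dbrda_fit` object: `R`, `F`, `df_model`, `df_residual`,
#'   `p_perm`, eigenvalues (constrained; positive and negative unconstrained),
#'   `site_scores` (CAP axes), `n_samples`, `n_perm`, `method`, `seed`.
#' @export
dbrda <- function(d, predictors, n_perm = 10000, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm) %||% as.character(seq_len(n))
  if (is.data.frame(predictors) && "sample_id" %in% names(predictors)) {
    idx <- match(ids, predictors$sample_id)
    if (anyNA(idx)) rlang::abort("predictors missing sample(s) present in d")
    predictors <- predictors[idx, setdiff(names(predictors), "sample_id"), drop = FALSE]
  }
  X <- build_design(predictors, n)
  q <- ncol(X)
  if (n <= q) rlang::abort("dbrda: need n_samples > n_predictors")
  saturated <- n == q + 1   # zero residual df: R is defined, F is not

  G <- gower_center(dm)
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  neg <- eg$values < -tol
  Y <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), sum(pos))
  rownames(Y) <- ids

  qrX <- qr(X)
  fitted <- qr.fitted(qrX, Y)
  ss_fit <- sum(fitted^2)
  ss_tot_pos <- sum(eg$values[pos])
  R <- ss_fit / ss_tot_pos

  trG <- sum(diag(G))
  trHG <- trace_HG(X, G)
  df_model <- q
  df_residual <- n - q - 1
  f_stat <- if (saturated) NaN else {
    (trHG / df_model) / ((trG - trHG) / df_residual)
  }

  f_from_perm <- function(perm) {
    tr <- trace_HG(X[perm, , drop = FALSE], G)
    (tr / df_model) / ((trG - tr) / df_residual)
  }
  ftol <- 1e-12
  if (saturated) {
    p_perm <- NA_real_; method <- "saturated"; used <- 0L
  } else if (factorial(n) <= max(n_perm, 720) && n <= 7) {
    P <- all_perms(n)
    fs <- vapply(seq_len(nrow(P)), function(k) f_from_perm(P[k, ]), numeric(1))
    p_perm <- mean(fs >= f_stat - ftol)
    method <- "exact"; used <- nrow(P)
  } else {
    extreme <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) {
        f_from_perm(sample(n)) >= f_stat - ftol
      }, logical(1)))
    })
    p_perm <- (1 + extreme) / (1 + n_perm)
    method <- "monte_carlo"; used <- n_perm
  }

  sv <- svd(fitted)
  keep <- sv$d > max(sv$d[1], 0) * 1e-8
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  colnames(scores) <- paste0("CAP", seq_len(ncol(scores)))
  site_scores <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                  tibble::as_tibble(scores))

  structure(list(R = R, F = f_stat, df_model = df_model, df_residual = df_residual,
                 p_perm = p_perm, n_perm = used, method = method,
                 eigenvalues = list(constrained = sv$d[keep]^2,
                                    positive = eg$values[pos],
                                    negative = eg$values[neg]),
                 site_scores = site_scores, terms = colnames(X),
                 n_samples = n, seed = as.integer(seed)),
            class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat("dbRDA fit:", x$n_samples, "samples,", x$df_model, "constrained df\n")
  cat(sprintf("  R = %.4f, F(%d,%d) = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$df_model, x$df_residual, x$F, x$p_perm, x$method, x$n_perm))
  invisible(x)
}

#' Forward selection of predictors for dbRDA
#'
#' Greedy forward-only selection. At each step every remaining candidate
#' is scored by the incremental (partial) pseudo-F given the already
#' selected terms, against one shared permutation stream. Under the
#' default `"maxstat"` entry rule the best candidate's F is compared with
#' the permutation distribution of the per-permutation *best* candidate F
#' (a Westfall-Young style family-wise test), so with many candidate gene
#' vectors the probability of admitting pure noise at a step stays near
#' `alpha_enter` regardless of pool size. The `"marginal"` rule instead
#' admits the candidate with the smallest per-candidate permutation p
#' among those below `alpha_enter`; with gene-sized pools it will admit
#' noise at almost every step and is kept for small curated pools.
#' Aliased candidates (no rank increase) never enter; ties are broken by
#' larger incremental explained inertia, then input order. Selection stops
#' when no candidate qualifies.
#'
#' @param d Distance object/matrix over samples.
#' @param candidates Samples x variables numeric table (each column one
#'   candidate), optionally with a `sample_id` column for alignment.
#' @param alpha_enter Entry threshold on the permutation p-value.
#' @param n_perm Permutations per step.
#' @param seed Seed; each step uses a derived child seed.
#' @param entry `"maxstat"` (family-wise, default) or `"marginal"`.
#' @return Tibble with one row per accepted step: `step`, `variable`,
#'   `p_enter` (the p-value governing entry under the chosen rule),
#'   `p_marginal`, `F_enter`, `R_cum`; the selected variable names are in
#'   the `selected` attribute (possibly empty).
#' @export
forward_select <- function(d, candidates, alpha_enter = 0.05, n_perm = 999,
                           seed = 1L, entry = c("maxstat", "marginal")) {
  entry <- match.arg(entry)
  dm <- as.matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm) %||% as.character(seq_len(n))
  if (is.data.frame(candidates) && "sample_id" %in% names(candidates)) {
    idx <- match(ids, candidates$sample_id)
    if (anyNA(idx)) rlang::abort("candidates missing sample(s) present in d")
    candidates <- candidates[idx, setdiff(names(candidates), "sample_id"), drop = FALSE]
  }
  C <- as.matrix(as.data.frame(candidates))
  if (nrow(C) != n) rlang::abort("candidate rows must match distance samples")
  if (ncol(C) < 1) rlang::abort("forward_select: need at least one candidate")
  storage.mode(C) <- "double"
  C <- scale(C, center = TRUE, scale = FALSE)

  G <- gower_center(dm)
  eg <- eigen(G, symmetric = TRUE)
  tolv <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tolv
  Y <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), sum(pos))
  ss_tot_pos <- sum(eg$values[pos])
  trG <- sum(diag(G))

  Qsel <- matrix(0, n, 0)   # orthonormal basis of selected columns
  trHG_sel <- 0
  remaining <- seq_len(ncol(C))
  steps <- list()
  rank_tol <- 1e-8

  # incremental explained trace of G when each column of xmat joins
  # span(Qb); NA marks an aliased (rank-preserving) column
  incr_cols <- function(xmat, Qb) {
    E <- xmat - Qb %*% crossprod(Qb, xmat)
    n2 <- colSums(E^2)
    valid <- n2 > (rank_tol * pmax(1, sqrt(colSums(xmat^2))))^2
    out <- rep(NA_real_, ncol(xmat))
    if (any(valid)) {
      U <- sweep(E[, valid, drop = FALSE], 2, sqrt(n2[valid]), `/`)
      out[valid] <- colSums(U * (G %*% U))
    }
    out
  }

  step <- 0L
  while (length(remaining) > 0 && ncol(Qsel) + 2 < n) {
    step <- step + 1L
    df_res_new <- n - (ncol(Qsel) + 1) - 1
    f_of <- function(dtr) dtr / ((trG - trHG_sel - dtr) / df_res_new)
    dtr_obs <- incr_cols(C[, remaining, drop = FALSE], Qsel)
    usable <- !is.na(dtr_obs)           # aliased candidates never enter
    if (!any(usable)) break
    f_obs <- f_of(dtr_obs)
    # one shared permutation stream per step: every candidate is scored
    # against the same reshuffles, which keeps each p-value marginally
    # valid and lets the whole step run as matrix operations
    perm_res <- with_seed(child_seed(seed, paste0("fs", step)), {
      acc <- integer(length(remaining))
      max_extreme <- 0L
      f_best <- max(f_obs[usable])
      for (k in seq_len(n_perm)) {
        prm <- sample(n)
        f_p <- f_of(incr_cols(C[prm, remaining, drop = FALSE], Qsel))
        acc <- acc + as.integer(!is.na(f_p) & f_p >= f_obs - 1e-12)
        if (max(f_p, na.rm = TRUE) >= f_best - 1e-12) {
          max_extreme <- max_extreme + 1L
        }
      }
      list(acc = acc, max_extreme = max_extreme)
    })
    ps <- (1 + perm_res$acc) / (1 + n_perm)
    p_step <- (1 + perm_res$max_extreme) / (1 + n_perm)
    ok <- if (entry == "maxstat") {
      # only the step's best candidate is eligible, gated by the
      # family-wise max-F p-value
      usable & p_step < alpha_enter &
        seq_along(remaining) %in% which(usable)[order(-f_obs[usable])][1]
    } else {
      usable & ps < alpha_enter
    }
    if (!any(ok)) break
    cand <- which(ok)
    best <- cand[order(ps[cand], -dtr_obs[cand])][1]
    j <- remaining[best]
    # update basis
    e <- C[, j] - Qsel %*% crossprod(Qsel, C[, j])
    Qsel <- cbind(Qsel, e / sqrt(sum(e^2)))
    trHG_sel <- trHG_sel + dtr_obs[best]
    r_cum <- sum((crossprod(Qsel, Y))^2) / ss_tot_pos
    steps[[step]] <- tibble::tibble(step = step,
                                    variable = colnames(C)[j],
                                    p_enter = if (entry == "maxstat") p_step else ps[best],
                                    p_marginal = ps[best],
                                    F_enter = f_obs[best],
                                    R_cum = r_cum)
    remaining <- setdiff(remaining, j)
  }
  out <- if (length(steps) > 0) dplyr::bind_rows(steps) else {
    tibble::tibble(step = integer(), variable = character(),
                   p_enter = numeric(), p_marginal = numeric(),
                   F_enter = numeric(), R_cum = numeric())
  }
  attr(out, "selected") <- out$variable
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2 dissimilarity pairs ranked with average ties. Significance
#' by permuting group labels; exact enumeration of all distinct labelings
#' when n <= 7.
#'
#' @param d Distance object/matrix over samples.
#' @param groups Group labels, one per sample, each group of size >= 2.
#' @param n_perm Monte Carlo permutation count.
#' @param seed Seed.
#' @return An `anosim_fit` object: `R`, `p_perm`, `n_perm`, `method`,
#'   `n_samples`, `groups`.
#' @export
anosim <- function(d, groups, n_perm = 9999, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) rlang::abort("anosim: one label per sample required")
  if (nlevels(droplevels(groups)) < 2) rlang::abort("anosim: need >= 2 groups")
  if (any(table(groups) < 2)) rlang::abort("anosim: every group needs >= 2 members")
  iu <- which(upper.tri(dm))
  r <- rank(dm[iu])
  M <- length(r)
  same <- (matrix(groups, n, n) == matrix(groups, n, n, byrow = TRUE))[iu]
  stat <- function(same_vec) {
    mean(r[!same_vec]) - mean(r[same_vec])
  }
  denom <- M / 2
  R_obs <- stat(same) / denom
  same_for <- function(perm) {
    g <- groups[perm]
    (matrix(g, n, n) == matrix(g, n, n, byrow = TRUE))[iu]
  }
  tol <- 1e-12
  if (n <= 7) {
    P <- all_perms(n)
    labs <- apply(P, 1, function(p) paste(groups[p], collapse = "\r"))
    P <- P[!duplicated(labs), , drop = FALSE]
    rs <- vapply(seq_len(nrow(P)), function(k) stat(same_for(P[k, ])) / denom,
                 numeric(1))
    p <- mean(rs >= R_obs - tol)
    method <- "exact"; used <- nrow(P)
  } else {
    extreme <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) {
        stat(same_for(sample(n))) / denom >= R_obs - tol
      }, logical(1)))
    })
    p <- (1 + extreme) / (1 + n_perm)
    method <- "monte_carlo"; used <- n_perm
  }
  structure(list(R = R_obs, p_perm = p, n_perm = used, method = method,
                 n_samples = n, groups = table(groups), seed = as.integer(seed)),
            class = "anosim_fit")
}

#' @export
print.anosim_fit <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations), %d samples\n",
              x$R, x$p_perm, x$method, x$n_perm, x$n_samples))
  invisible(x)
}

#' Mann-Whitney U test with z statistic
#'
#' U is the smaller of the two U statistics. z uses the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction. When the pooled size is <= 12, the two-sided p-value is
#' computed exactly by enumerating all group assignments of the pooled
#' ranks (the probability of a min-U at or below the observed one).
#'
#' @param x,y Numeric samples.
#' @return List with `U`, `z`, `p`, `method`, `n1`, `n2`.
#' @export
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) rlang::abort("mann_whitney_z: empty input")
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- if (v <= 0) 0 else max(0, abs(U - mu) - 0.5) / sqrt(v)
  if (n <= 12) {
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2, function(idx) {
      u1 <- sum(r[idx]) - n1 * (n1 + 1) / 2
      min(u1, n1 * n2 - u1)
    })
    p <- mean(us <= U + 1e-12)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-z)
    p <- min(1, p)
    method <- "normal"
  }
  list(U = U, z = z, p = p, method = method, n1 = n1, n2 = n2)
}

#' Per-pathway dbRDA model-comparison ledger
#'
#' For each pathway, host gene expression restricted to the pathway's
#' members is the response (as a distance), and symbiont genes are the
#' candidate predictors entering forward selection — fitted separately on
#' the cTPut-positive and cTPut-negative sample subsets. The ledger row
#' carries each partial model's R, F and df and their difference
#' dR = R_with - R_without; rows are sorted by dR, descending.
#'
#' @param host,sol Count tibbles for the host and symbiont compartments.
#' @param catalog Long-format pathway catalog of host genes.
#' @param samples Sample sheet.
#' @param distance `"rclr"` (robust Aitchison, default) or `"braycurtis"`.
#' @param candidate_pool Optional character vector of symbiont gene ids to
#'   offer to forward selection (default: all), or a single integer: the
#'   top-k symbiont genes by variance within each subset.
#' @param alpha_enter,n_perm,seed Forward-selection settings; `n_perm` is
#'   also used for each final model's permutation test.
#' @param min_genes Pathways with fewer member genes present are skipped
#'   with a warning.
#' @param entry Forward-selection entry rule (see [forward_select()]).
#' @return Tibble with one row per pathway: df, R, F per condition subset,
#'   and `dR`.
#' @export
pathway_ledger <- function(host, sol, catalog, samples,
                           distance = c("rclr", "braycurtis"),
                           candidate_pool = NULL, alpha_enter = 0.05,
                           n_perm = 999, seed = 1L, min_genes = 2,
                           entry = c("maxstat", "marginal")) {
  distance <- match.arg(distance)
  entry <- match.arg(entry)
  validate_samples(samples, host)
  dist_fun <- if (distance == "rclr") robust_aitchison else bray_curtis
  subsets <- list(with = samples$sample_id[samples$ctput_status],
                  without = samples$sample_id[!samples$ctput_status])
  if (any(lengths(subsets) < 3)) rlang::abort("each condition subset needs >= 3 samples")
  subsets <- lapply(subsets, intersect, x = sample_ids(host))
  sol_m <- count_matrix(sol)

  # the selection seed is shared between the two condition subsets so that
  # identical data yield identical selections (and hence dR = 0)
  fit_one <- function(path_counts, sub, seed_tag) {
    sub <- intersect(sub, sample_ids(sol))
    d <- dist_fun(path_counts[c("gene_id", sub)])
    cand_m <- t(sol_m[, sub, drop = FALSE])
    if (!is.null(candidate_pool)) {
      if (is.numeric(candidate_pool) && length(candidate_pool) == 1) {
        v <- apply(cand_m, 2, stats::var)
        cand_m <- cand_m[, order(-v)[seq_len(min(candidate_pool, ncol(cand_m)))],
                         drop = FALSE]
      } else {
        cand_m <- cand_m[, intersect(candidate_pool, colnames(cand_m)), drop = FALSE]
      }
    }
    sel <- forward_select(d, as.data.frame(cand_m), alpha_enter = alpha_enter,
                          n_perm = n_perm, seed = child_seed(seed, seed_tag),
                          entry = entry)
    vars <- attr(sel, "selected")
    n_sub <- length(sub)
    if (length(vars) == 0) {
      return(list(R = 0, F = NA_real_, df_model = 0L,
                  df_residual = n_sub - 1L, selected = character()))
    }
    fit <- dbrda(d, as.data.frame(cand_m[, vars, drop = FALSE]),
                 n_perm = n_perm, seed = child_seed(seed, paste0(seed_tag, "_fit")))
    list(R = fit$R, F = fit$F, df_model = fit$df_model,
         df_residual = fit$df_residual, selected = vars)
  }

  rows <- list()
  for (pw in unique(catalog$pathway_id)) {
    genes <- intersect(catalog$gene_id[catalog$pathway_id == pw], host$gene_id)
    if (length(genes) < min_genes) {
      rlang::warn(sprintf("pathway '%s' skipped: %d gene(s) present", pw, length(genes)))
      next
    }
    pc <- host[host$gene_id %in% genes, , drop = FALSE]
    w <- fit_one(pc, subsets$with, pw)
    wo <- fit_one(pc, subsets$without, pw)
    rows[[pw]] <- tibble::tibble(
      pathway_id = pw, n_genes = length(genes),
      df_model_with = w$df_model, df_residual_with = w$df_residual,
      R_with = w$R, F_with = w$F,
      df_model_without = wo$df_model, df_residual_without = wo$df_residual,
      R_without = wo$R, F_without = wo$F,
      dR = w$R - wo$R
    )
  }
  if (length(rows) == 0) rlang::abort("pathway_ledger: no usable pathway")
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$dR))
  attr(out, "distance") <- distance
  out
}
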