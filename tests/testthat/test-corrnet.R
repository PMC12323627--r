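# independent brute-force enumeration of the permutation null used as an
# oracle against spearman_perm's exact mode
enum_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- gtools_permutations(n)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  rs <- apply(perms, 1, function(p) abs(cor(rx, ry[p])))
  mean(rs >= obs - 1e-12)
}

# minimal recursive permutation generator, independent of the package's
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub), n - 1))
  }))
}

test_that("spearman_perm recovers monotone relations and rejects degenerate input", {
  expect_equal(spearman_perm(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_perm(1:4, c(40, 30, 20, 10))$rho, -1)
  expect_error(spearman_perm(1:3, 1:3), "n >= 4")
  expect_error(spearman_perm(rep(1, 5), 1:5), "constant")
  expect_error(spearman_perm(1:4, 1:5), "length")
})

test_that("exact mode equals full enumeration over all rank permutations", {
  cases <- list(
    list(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3)),
    list(x = c(5, 1, 9, 4), y = c(3, 3, 7, 1)),   # ties in y
    list(x = c(1, 2, 3, 4, 5), y = c(2, 5, 3, 1, 4)),
    list(x = c(0.3, 1.2, -4, 2, 8, 5), y = c(1, 0, 2, 4, 3, 9))
  )
  for (cs in cases) {
    got <- spearman_perm(cs$x, cs$y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_perm, enum_spearman_p(cs$x, cs$y))
    # symmetry in the arguments
    rev <- spearman_perm(cs$y, cs$x)
    expect_equal(rev$rho, got$rho)
    expect_equal(rev$p_perm, got$p_perm)
  }
})

test_that("Monte Carlo p-values stay inside their attainable range", {
  set.seed(77)
  for (i in 1:20) {
    r <- spearman_perm(rnorm(12), rnorm(12), n_perm = 99, seed = i)
    expect_gte(r$p_perm, 1 / 100)
    expect_lte(r$p_perm, 1)
  }
})

test_that("edge calling finds a single perfect pair and enforces preconditions", {
  n <- 14
  x <- seq_len(n) + 0.5
  a <- as_counts(matrix(x, 1, n, dimnames = list("gA", paste0("s", 1:n))), "SOL")
  b <- as_counts(matrix(2 * x, 1, n, dimnames = list("gB", paste0("s", 1:n))), "cTPut")
  e <- correlate_compartments(a, b, corr_config(n_perm = 999, seed = 1))
  expect_equal(nrow(e), 1)
  expect_equal(e$rho, 1)
  expect_equal(e$sign, 1L)
  expect_identical(e$source_compartment, "SOL")

  a3 <- as_counts(matrix(1:3, 1, 3, dimnames = list("gA", paste0("s", 1:3))))
  b3 <- as_counts(matrix(1:3, 1, 3, dimnames = list("gB", paste0("s", 1:3))))
  expect_error(correlate_compartments(a3, b3, corr_config(n_perm = 99)),
               "at least 4")

  # zero-variance genes are skipped with a warning, not an error
  am <- rbind(gA = x, gC = rep(7, n))
  colnames(am) <- paste0("s", 1:n)
  expect_warning(
    correlate_compartments(as_counts(am), b, corr_config(n_perm = 99, seed = 1)),
    "zero-variance")
})

test_that("edge retention respects the rho window and alpha", {
  set.seed(21)
  a <- random_counts(15, 14, seed = 21, compartment = "host")
  b <- random_counts(10, 14, seed = 22, compartment = "SOL")
  cfg <- corr_config(n_perm = 199, alpha = 0.3, rho_min = 0.2, rho_max = 0.9, seed = 5)
  e <- correlate_compartments(a, b, cfg)
  if (nrow(e) > 0) {
    expect_true(all(abs(e$rho) >= 0.2 & abs(e$rho) <= 0.9))
    expect_true(all(e$p_perm < 0.3))
    expect_true(all(e$sign == ifelse(e$rho > 0, 1, -1)))
  }
  full <- spearman_matrix(a, b)
  # every qualifying pair must appear: re-derive the retained set from the
  # full rho matrix and per-pair tests
  for (k in seq_len(nrow(e))) {
    expect_equal(e$rho[k], full[e$source_gene[k], e$target_gene[k]])
  }
})

test_that("null edge rate on independent noise is near alpha", {
  a <- random_counts(50, 14, seed = 31, lambda = 50, compartment = "host")
  b <- random_counts(50, 14, seed = 32, lambda = 50, compartment = "SOL")
  e <- correlate_compartments(a, b, corr_config(n_perm = 999, seed = 7))
  frac <- nrow(e) / (50 * 50)
  se <- sqrt(0.05 * 0.95 / 2500)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("gene scores follow their definitions in both strength modes", {
  edges <- tibble::tibble(
    source_gene = c("solA", "solA", "solA"), source_compartment = "SOL",
    target_gene = c("h1", "h2", "h3"), target_compartment = "host",
    rho = c(0.8, 0.9, -0.76), p_perm = 0.01, sign = c(1L, 1L, -1L),
    pathway_context = NA_character_)
  gs <- gene_stats(edges, "SOL", mode = "abs_rho")
  expect_equal(gs$n_partners, 3L)
  expect_equal(gs$s_type, 1)
  expect_equal(gs$s_strength, 2.46)

  catalog <- tibble::tibble(
    pathway_id = c("p1", "p2", "p3", "p4"), description = "d",
    gene_id = rep("h1", 4))
  one <- edges[1, ]
  gp <- gene_stats(one, "SOL", catalog = catalog, mode = "pathway_instance")
  expect_equal(gp$n_partners, 1L)
  expect_equal(gp$s_type, 4)
  expect_equal(gp$s_strength, 4)

  # a partner absent from the catalog counts once, with a warning
  expect_warning(
    gm <- gene_stats(edges, "SOL", catalog = catalog, mode = "pathway_instance"),
    "absent")
  expect_equal(gm$s_strength, 4 + 1 + 1)
  expect_equal(gm$s_type, 4 + 1 - 1)

  # genes without edges report zeros through the universe argument
  gz <- gene_stats(edges, "SOL", mode = "abs_rho", universe = c("solA", "solZ"))
  z <- gz[gz$gene_id == "solZ", ]
  expect_equal(z$n_partners, 0L)
  expect_equal(z$s_type, 0)
  expect_equal(z$s_strength, 0)
})

test_that("score conservation and bounds hold on called edges", {
  sim <- simulate_expression(tiny_sim_config(seed = 6))
  cfg <- corr_config(n_perm = 199, seed = 3)
  e <- suppressWarnings(correlate_compartments(
    sim$host, sim$sol, cfg, samples = sim$samples, subset = "ctput_positive"))
  gs_pi <- suppressWarnings(gene_stats(e, "SOL", catalog = sim$pathways,
                                       mode = "pathway_instance"))
  # conservation: total counted edges equal the catalog-expanded edge count
  mult <- table(sim$pathways$gene_id)
  k <- unname(ifelse(e$source_gene %in% names(mult),
                     as.integer(mult[e$source_gene]), 1L))
  expect_equal(sum(gs_pi$s_strength), sum(k))
  expect_true(all(abs(gs_pi$s_type) <= gs_pi$s_strength))

  gs_ar <- gene_stats(e, "SOL", mode = "abs_rho")
  counted <- gs_ar$n_partners
  expect_true(all(gs_ar$s_strength <= counted + 1e-12))
  expect_true(all(gs_ar$s_strength >= min(abs(e$rho)) * counted - 1e-12))
  expect_true(all(abs(gs_ar$s_type) <= counted))
})

test_that("hub filtering is strict and matches a brute-force scan", {
  stats <- tibble::tibble(gene_id = c("a", "b", "c"),
                          n_partners = c(5L, 9L, 2L),
                          s_type = c(1, -3, 2),
                          s_strength = c(100, 100.5, 250))
  out <- filter_hubs(stats, min_strength = 100)
  expect_setequal(out$gene_id, c("b", "c"))

  set.seed(9)
  rnd <- tibble::tibble(gene_id = paste0("g", 1:200),
                        n_partners = rpois(200, 3),
                        s_type = rpois(200, 2) - 2,
                        s_strength = runif(200, 0, 200))
  thr <- 100
  brute <- rnd$gene_id[vapply(seq_len(200), function(i) rnd$s_strength[i] > thr,
                              logical(1))]
  expect_setequal(filter_hubs(rnd, min_strength = thr)$gene_id, brute)
})

test_that("paired comparison of edge counts matches the textbook formula", {
  a <- tibble::tibble(gene_id = paste0("g", 1:5),
                      n_pos = c(10, 12, 9, 14, 11), n_neg = c(3, 4, 2, 5, 3))
  b <- tibble::tibble(gene_id = paste0("g", 1:5),
                      n_pos = c(12, 15, 11, 15, 16), n_neg = c(4, 4, 4, 7, 6))
  res <- compare_edge_counts(a, b)
  d <- a$n_pos - b$n_pos
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t[res$edge_sign == "positive"], t_manual)
  expect_equal(res$df[res$edge_sign == "positive"], 4)
  expect_equal(res$mean_a[res$edge_sign == "positive"], mean(a$n_pos))

  same <- compare_edge_counts(a, a)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$p, c(1, 1))

  shifted <- dplyr::mutate(a, n_pos = n_pos + 2, n_neg = n_neg + 1)
  # one warning per edge sign
  expect_warning(expect_warning(res2 <- compare_edge_counts(shifted, a),
                                "zero variance"),
                 "zero variance")
  expect_true(all(is.infinite(res2$t)))
  expect_equal(res2$p, c(0, 0))

  expect_error(compare_edge_counts(a[1, ], b[1, ]), "fewer than 2")
})

test_that("Ward ordering makes planted blocks contiguous and is idempotent", {
  set.seed(14)
  blocks <- list(1:4, 5:8, 9:12)
  rho <- matrix(rnorm(144, 0, 0.05), 12, 12)
  for (b in blocks) rho[b, b] <- rho[b, b] + 0.9
  dimnames(rho) <- list(paste0("r", 1:12), paste0("c", 1:12))
  hm <- heatmap_order(rho)
  member <- rep(1:3, each = 4)
  ordered_member <- member[hm$row_order]
  expect_equal(length(rle(ordered_member)$lengths), 3)

  again <- heatmap_order(hm$matrix)
  expect_equal(again$matrix, hm$matrix)

  two <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(sort(heatmap_order(two)$row_order), 1:2)
  bad <- rho; bad[1, 1] <- NaN
  expect_error(heatmap_order(bad), "NA")
})
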