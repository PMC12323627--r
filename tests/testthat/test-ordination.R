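test_that("Bray-Curtis has its closed forms and matches vegan", {
  m <- as_counts(matrix(c(2, 1, 0, 1, 1, 2), 3, 2,
                        dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
  expect_equal(as.matrix(bray_curtis(m))["s1", "s2"], 3 / 7)

  same <- as_counts(matrix(c(4, 6, 4, 6), 2, 2,
                           dimnames = list(c("g1", "g2"), c("a", "b"))))
  expect_equal(as.matrix(bray_curtis(same))["a", "b"], 0)

  disjoint <- as_counts(matrix(c(5, 0, 0, 3), 2, 2,
                               dimnames = list(c("g1", "g2"), c("a", "b"))))
  expect_equal(as.matrix(bray_curtis(disjoint))["a", "b"], 1)

  counts <- random_counts(25, 9, seed = 19)
  ours <- bray_curtis(counts)
  ref <- vegan::vegdist(t(count_matrix(counts)), method = "bray")
  expect_equal(as.matrix(ours), as.matrix(ref), tolerance = 1e-12)
  expect_true(all(as.vector(ours) >= 0 & as.vector(ours) <= 1))

  zz <- as_counts(matrix(c(0, 0, 0, 0, 1, 2), 2, 3,
                         dimnames = list(c("g1", "g2"), c("a", "b", "c"))))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("rclr centers on the geometric mean of positive parts only", {
  one <- as_counts(matrix(1, 4, 1, dimnames = list(paste0("g", 1:4), "s1")))
  expect_equal(unname(rclr_transform(one)[1, ]), rep(0, 4))

  g <- as_counts(matrix(c(1, 10, 100), 3, 1,
                        dimnames = list(paste0("g", 1:3), "s1")))
  expect_equal(unname(rclr_transform(g)[1, ]), c(-log(10), 0, log(10)))

  z <- as_counts(matrix(c(0, 10, 1000), 3, 1,
                        dimnames = list(paste0("g", 1:3), "s1")))
  expect_equal(unname(rclr_transform(z)[1, ]), c(0, log(0.1), log(10)))

  # Euclidean on rclr rows, hence the triangle inequality holds
  counts <- random_counts(15, 7, seed = 23, lambda = 3)
  d <- as.matrix(robust_aitchison(counts))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("Gower centering reproduces classical principal coordinates", {
  # two points at distance delta: single positive eigenvalue delta^2 / 2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  G2 <- gower_center(d2)
  expect_equal(sort(eigen(G2)$values, decreasing = TRUE)[1], 9 / 2)

  set.seed(41)
  X <- matrix(rnorm(24), 6, 4)
  G <- gower_center(dist(X))
  expect_lt(max(abs(rowSums(G))), 1e-10)
  expect_equal(G, t(G))
  # PCoA of Euclidean distances == PCA of the centered data
  ev <- eigen(G, symmetric = TRUE)$values
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pca_ev <- eigen(tcrossprod(Xc), symmetric = TRUE)$values
  expect_equal(sort(ev, decreasing = TRUE)[1:4], sort(pca_ev, decreasing = TRUE)[1:4],
               tolerance = 1e-10)

  expect_error(gower_center(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})

test_that("dbRDA equals least-squares R^2 on Euclidean distances", {
  for (s in 1:5) {
    set.seed(100 + s)
    Y <- matrix(rnorm(8 * 3), 8, 3)
    x <- rnorm(8)
    fit <- dbrda(dist(Y), data.frame(x = x), n_perm = 99, seed = s)
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    ls <- lm(Yc ~ x)
    r2 <- sum(fitted(ls)^2) / sum(Yc^2)
    expect_equal(fit$R, r2, tolerance = 1e-8)
    expect_equal(fit$df_model + fit$df_residual, 8 - 1)
  }
})

test_that("dbRDA pseudo-F equals the direct PERMANOVA formula on Bray-Curtis", {
  for (s in 1:5) {
    counts <- random_counts(12, 6, seed = 300 + s, lambda = 12)
    d <- bray_curtis(counts)
    grp <- factor(rep(c("a", "b"), each = 3))
    fit <- dbrda(d, data.frame(g = grp), n_perm = 99, seed = s)
    dm <- as.matrix(d)^2
    n <- 6
    sst <- sum(dm[upper.tri(dm)]) / n
    ssw <- 0
    for (lev in levels(grp)) {
      idx <- which(grp == lev)
      ssw <- ssw + sum(dm[idx, idx][upper.tri(dm[idx, idx])]) / length(idx)
    }
    f_direct <- ((sst - ssw) / 1) / (ssw / (n - 2))
    expect_equal(fit$F, f_direct, tolerance = 1e-10)
    # and vegan's adonis2 agrees with both
    ref <- vegan::adonis2(d ~ grp, permutations = 9)
    expect_equal(fit$F, ref$F[1], tolerance = 1e-10)
  }
})

test_that("dbRDA saturates with a full dummy basis and resists aliasing", {
  counts <- random_counts(10, 6, seed = 55)
  d <- bray_curtis(counts)
  dummies <- data.frame(f = factor(paste0("lvl", 1:6)))
  fit <- dbrda(d, dummies, n_perm = 99, seed = 1)
  expect_equal(fit$R, 1, tolerance = 1e-10)
  expect_equal(fit$df_residual, 0)
  expect_identical(fit$method, "saturated")

  set.seed(61)
  x <- rnorm(6)
  base_fit <- dbrda(d, data.frame(x = x), n_perm = 99, seed = 2)
  scaled_fit <- dbrda(d, data.frame(x = 10 * x), n_perm = 99, seed = 2)
  expect_equal(base_fit$R, scaled_fit$R, tolerance = 1e-12)
  expect_warning(
    alias_fit <- dbrda(d, data.frame(x = x, x2 = 2 * x), n_perm = 99, seed = 2),
    "aliased")
  expect_equal(alias_fit$R, base_fit$R, tolerance = 1e-12)
  expect_equal(alias_fit$df_model, 1)

  # over-parameterized input: centered design is rank-deficient, aliased
  # columns are dropped and the fit saturates
  expect_warning(
    over_fit <- dbrda(d, data.frame(a = rnorm(6), b = rnorm(6), c = rnorm(6),
                                    e = rnorm(6), f = rnorm(6), g = rnorm(6)),
                      n_perm = 99),
    "aliased")
  expect_equal(over_fit$df_model, 5)
  expect_identical(over_fit$method, "saturated")
})

test_that("dbRDA permutation p-values are valid under the null", {
  set.seed(71)
  counts <- random_counts(20, 12, seed = 71)
  d <- bray_curtis(counts)
  rej <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    x <- rnorm(12)
    dbrda(d, data.frame(x = x), n_perm = 99, seed = i)$p_perm < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 4 * se)
})

test_that("forward selection admits signal first and rarely admits noise", {
  # pure noise: the family-wise entry rule keeps the selected set empty in
  # about (1 - alpha) of runs
  empty <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    Y <- matrix(rnorm(10 * 4), 10, 4)
    cand <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    sel <- forward_select(dist(Y), cand, n_perm = 99, seed = s)
    nrow(sel) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)

  # one strong planted predictor among noise is selected, and first
  hits <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    x <- rnorm(12)
    Y <- cbind(x + rnorm(12, 0, 0.2), -x + rnorm(12, 0, 0.2), rnorm(12))
    cand <- data.frame(noise1 = rnorm(12), planted = x, noise2 = rnorm(12))
    sel <- forward_select(dist(Y), cand, n_perm = 199, seed = s)
    nrow(sel) >= 1 && sel$variable[1] == "planted"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # duplicated candidates: only one copy can ever enter
  set.seed(91)
  x <- rnorm(10)
  Y <- cbind(x, x) + matrix(rnorm(20, 0, 0.1), 10, 2)
  sel <- forward_select(dist(Y), data.frame(x1 = x, x2 = x), n_perm = 199, seed = 4)
  expect_lte(nrow(sel), 1)
})

test_that("ANOSIM matches its definition, enumeration, and vegan", {
  # complete separation: R = 1
  pts <- as_counts(matrix(c(1, 1, 2, 2, 50, 60, 55, 65), 1, 8,
                          dimnames = list("g1", paste0("s", 1:8))))
  d8 <- dist(as.vector(count_matrix(pts)))
  attr(d8, "Labels") <- paste0("s", 1:8)
  fit <- anosim(d8, rep(c("a", "b"), each = 4), n_perm = 199, seed = 1)
  expect_equal(fit$R, 1)

  # identical points: all ranks tie, R = 0
  d0 <- dist(rep(0, 6))
  expect_equal(anosim(d0, rep(c("a", "b"), each = 3))$R, 0)

  # n = 6, two groups of 3: p equals enumeration over all 20 labelings
  set.seed(17)
  X <- matrix(rnorm(12), 6, 2)
  d6 <- dist(X)
  g <- rep(c("a", "b"), each = 3)
  fit6 <- anosim(d6, g)
  expect_identical(fit6$method, "exact")
  expect_equal(fit6$n_perm, 20)
  anosim_R <- function(dmat, groups) {
    iu <- which(upper.tri(dmat))
    r <- rank(dmat[iu])
    same <- (outer(groups, groups, "==") )[iu]
    (mean(r[!same]) - mean(r[same])) / (length(r) / 2)
  }
  dm <- as.matrix(d6)
  combos <- combn(6, 3)
  rs <- apply(combos, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    anosim_R(dm, gg)
  })
  expect_equal(fit6$p_perm, mean(rs >= fit6$R - 1e-12))
  ref <- vegan::anosim(d6, g, permutations = 19)
  expect_equal(fit6$R, unname(ref$statistic), tolerance = 1e-12)
  expect_true(abs(fit6$R) <= 1)

  expect_error(anosim(d6, c("a", "a", "a", "a", "a", "b")), ">= 2 members")
})

test_that("Mann-Whitney U and z follow the tie-corrected formulas", {
  # identical values: U at its mean, z forced to 0
  r <- mann_whitney_z(rep(3, 4), rep(3, 5))
  expect_equal(r$U, 4 * 5 / 2)
  expect_equal(r$z, 0)

  # complete separation at n = 3 + 3: exact two-sided p = 2/20
  r2 <- mann_whitney_z(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r2$U, 0)
  expect_identical(r2$method, "exact")
  expect_equal(r2$p, 0.1)

  # hand-worked 5 + 5 example against the direct formula
  x <- c(1.1, 2.3, 3.1, 4.8, 5.2)
  y <- c(2.9, 6.1, 7.4, 8.8, 9.9)
  r3 <- mann_whitney_z(x, y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U1 <- sum(rk[1:5]) - 5 * 6 / 2
  U <- min(U1, 25 - U1)
  v <- 5 * 5 / 12 * (11 - 0)      # no ties
  z_direct <- (abs(U - 12.5) - 0.5) / sqrt(v)
  expect_equal(r3$U, U)
  expect_equal(r3$z, z_direct)
  # wilcox.test agrees on the statistic (it reports U of the first sample)
  w <- suppressWarnings(wilcox.test(x, y))
  expect_equal(min(unname(w$statistic), 25 - unname(w$statistic)), r3$U)

  expect_error(mann_whitney_z(numeric(0), 1:3), "empty")
})

test_that("the pathway ledger is antisymmetric-consistent and exact on equal data", {
  set.seed(83)
  samples <- four_culture_samples(3)
  n_host <- 24
  half <- matrix(rpois(n_host * 6, 30), n_host, 6)
  hostm <- cbind(half, half)  # positive and negative samples identical
  dimnames(hostm) <- list(sprintf("h%02d", 1:n_host), samples$sample_id)
  solm <- matrix(rpois(8 * 6, 40), 8, 6)
  solm <- cbind(solm, solm)
  dimnames(solm) <- list(sprintf("sol%02d", 1:8), samples$sample_id)
  catalog <- tibble::tibble(
    pathway_id = rep(c("pwA", "pwB"), each = 12), description = "d",
    gene_id = sprintf("h%02d", 1:24))
  led <- pathway_ledger(as_counts(hostm, "host"), as_counts(solm, "SOL"),
                        catalog, samples, n_perm = 99, seed = 2)
  expect_equal(led$dR, rep(0, 2))
  expect_equal(led$R_with, led$R_without)
  # dR always recomputable from its two R columns
  expect_equal(led$dR, led$R_with - led$R_without, tolerance = 1e-12)
  # df accounting within each partial model (6 samples per condition subset)
  expect_equal(led$df_model_with + led$df_residual_with, rep(5, 2))

  small_cat <- tibble::tibble(pathway_id = "tiny", description = "d",
                              gene_id = "h01")
  expect_warning(
    expect_error(pathway_ledger(as_counts(hostm, "host"), as_counts(solm, "SOL"),
                                small_cat, samples, n_perm = 99, seed = 2),
                 "no usable pathway"),
    "skipped")
})
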