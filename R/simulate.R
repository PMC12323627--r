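# Synthetic tripartite meta-transcriptome generator.
#
# Counts are drawn through a latent-factor Gaussian copula with negative
# binomial marginals: planted cross-compartment blocks share a per-sample
# latent factor, so the rank (Spearman) correlation between planted genes is
# controlled directly by the block loading, which is what the downstream
# permutation tests measure.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Define a planted cross-compartment correlation block
#'
#' Genes listed on the two sides of a block share one latent factor per
#' sample, giving every cross pair a latent correlation of
#' `sign * loading^2`.
#'
#' @param name Block label.
#' @param from_compartment,to_compartment Compartment labels
#'   (`"host"`, `"SOL"`, `"cTPut"`).
#' @param from_genes,to_genes Integer indices of member genes within each
#'   compartment.
#' @param loading Factor loading in (0, 1].
#' @param sign `+1` or `-1`: sign of the cross-compartment correlation.
#' @param condition `"both"`, `"pos"`, or `"neg"`: samples in which the
#'   factor is active (by cTPut status). Outside that subset the member
#'   genes are independent noise.
#' @return A `sim_block` list.
#' @export
sim_block <- function(name, from_compartment, from_genes, to_compartment,
                      to_genes, loading = 0.9, sign = 1L,
                      condition = c("both", "pos", "neg")) {
  condition <- match.arg(condition)
  stopifnot(loading > 0, loading <= 1, sign %in% c(-1L, 1L, -1, 1))
  structure(list(name = name,
                 from_compartment = from_compartment, from_genes = as.integer(from_genes),
                 to_compartment = to_compartment, to_genes = as.integer(to_genes),
                 loading = loading, sign = as.integer(sign), condition = condition),
            class = "sim_block")
}

default_blocks <- function() {
  # host index ranges are placed inside single pathway chunks of the
  # default catalog (chunks of 50 with a 10-gene borrow zone at the start
  # of the next chunk), so each block maps to exactly one pathway
  list(
    sim_block("host_sol_shared", "host", 1:20, "SOL", 1:8,
              loading = 0.9, sign = 1L, condition = "both"),
    sim_block("host_sol_pos", "host", 61:80, "SOL", 9:16,
              loading = 0.9, sign = 1L, condition = "pos"),
    sim_block("host_sol_neg", "host", 111:130, "SOL", 17:24,
              loading = 0.9, sign = 1L, condition = "neg"),
    sim_block("host_sol_negative_sign", "host", 161:175, "SOL", 25:30,
              loading = 0.9, sign = -1L, condition = "both"),
    sim_block("sol_ctput_pos", "SOL", 31:38, "cTPut", 1:8,
              loading = 0.9, sign = 1L, condition = "pos")
  )
}

#' Configuration for the tripartite simulator
#'
#' Defaults emulate the study design: four mite cultures, two carrying the
#' Cardinium symbiont (5L, 5S) and two without it (5Pi, 5Tk), seven
#' replicates each (28 samples), with compartment sizes scaled down from
#' the real meta-transcriptomes (5,838 host KEGG genes / 1,273 symbiont
#' genes) so that full pipeline runs stay fast. The Cardinium compartment
#' is emitted only for cTPut-positive samples: in the negative cultures the
#' symbiont is absent, not merely unexpressed.
#'
#' @param cultures_pos,cultures_neg Culture labels with/without cTPut.
#' @param n_reps Replicates per culture.
#' @param n_host,n_sol,n_ctput Genes per compartment.
#' @param blocks List of [sim_block()] objects; `default_blocks()` plants
#'   shared, condition-specific and negative-sign host-SOL blocks plus a
#'   SOL-cTPut block, all at loading 0.9.
#' @param nb_size Negative-binomial size (inverse dispersion) of counts.
#' @param baseline_meanlog,baseline_sdlog Log-normal law of per-gene
#'   baseline mean counts.
#' @param libsize_sdlog Log-normal spread of per-sample library-size
#'   factors (mean 1 on the log scale).
#' @param sol_multiplier Multiplier (< 1) applied to all SOL gene means in
#'   cTPut-positive samples, lowering SOL relative abundance there.
#' @param n_pathways Number of synthetic host pathways (consecutive chunks).
#' @param pathway_overlap Number of genes each pathway shares with the next
#'   one (membership multiplicity for network scoring).
#' @param seed Integer seed; the whole simulation is a pure function of the
#'   configuration including this seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cultures_pos = c("5L", "5S"),
                       cultures_neg = c("5Pi", "5Tk"),
                       n_reps = 7,
                       n_host = 500, n_sol = 200, n_ctput = 150,
                       blocks = default_blocks(),
                       nb_size = 3,
                       baseline_meanlog = log(30), baseline_sdlog = 1,
                       libsize_sdlog = 0.3,
                       sol_multiplier = 0.4,
                       n_pathways = 10, pathway_overlap = 10,
                       seed = 1L) {
  stopifnot(n_reps >= 1, n_host >= 1, n_sol >= 1, n_ctput >= 1,
            sol_multiplier > 0, nb_size > 0, n_pathways >= 1)
  cfg <- list(cultures_pos = cultures_pos, cultures_neg = cultures_neg,
              n_reps = n_reps,
              n_genes = c(host = n_host, SOL = n_sol, cTPut = n_ctput),
              blocks = blocks, nb_size = nb_size,
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              libsize_sdlog = libsize_sdlog, sol_multiplier = sol_multiplier,
              n_pathways = n_pathways, pathway_overlap = pathway_overlap,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  for (b in cfg$blocks) {
    for (side in c("from", "to")) {
      comp <- b[[paste0(side, "_compartment")]]
      idx <- b[[paste0(side, "_genes")]]
      if (!comp %in% names(cfg$n_genes)) {
        rlang::abort(paste0("block '", b$name, "': unknown compartment ", comp))
      }
      if (any(idx < 1) || any(idx > cfg$n_genes[[comp]])) {
        rlang::abort(paste0("block '", b$name, "': planted ", comp,
                            " gene index outside 1..", cfg$n_genes[[comp]]))
      }
    }
  }
  cfg
}

gene_ids_for <- function(compartment, n) {
  prefix <- c(host = "host", SOL = "sol", cTPut = "ct")[[compartment]]
  sprintf("%s_%04d", prefix, seq_len(n))
}

# latent Gaussian matrix for one compartment: iid noise, overwritten for
# block members with loading * factor + sqrt(1 - loading^2) * noise
latent_for_compartment <- function(comp, cfg, n_samples, factors, active) {
  n_g <- cfg$n_genes[[comp]]
  z <- matrix(stats::rnorm(n_g * n_samples), nrow = n_g)
  for (bi in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[bi]]
    for (side in c("from", "to")) {
      if (b[[paste0(side, "_compartment")]] != comp) next
      idx <- b[[paste0(side, "_genes")]]
      lam <- b$loading
      s <- if (side == "to") b$sign else 1L
      act <- active[[bi]]
      f <- factors[[bi]]
      for (g in idx) {
        z[g, act] <- s * lam * f[act] + sqrt(1 - lam^2) * z[g, act]
      }
    }
  }
  z
}

#' Simulate a tripartite meta-transcriptome with planted structure
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `host`, `sol`,
#'   `ctput` (count tibbles; `ctput` has columns only for cTPut-positive
#'   samples), `samples` (sample sheet), `pathways` (long-format catalog of
#'   host genes), and `truth` (planted pair list and generator parameters).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cultures <- c(cfg$cultures_pos, cfg$cultures_neg)
  status <- c(rep(TRUE, length(cfg$cultures_pos)), rep(FALSE, length(cfg$cultures_neg)))
  samples <- tibble::tibble(
    sample_id = as.vector(t(outer(cultures, seq_len(cfg$n_reps), paste, sep = "_"))),
    culture = rep(cultures, each = cfg$n_reps),
    ctput_status = rep(status, each = cfg$n_reps),
    replicate = rep(seq_len(cfg$n_reps), times = length(cultures))
  )
  n_s <- nrow(samples)
  pos <- samples$ctput_status

  out <- with_seed(cfg$seed, {
    # per-block latent factors and activity masks
    factors <- lapply(cfg$blocks, function(b) stats::rnorm(n_s))
    active <- lapply(cfg$blocks, function(b) {
      switch(b$condition, both = rep(TRUE, n_s), pos = pos, neg = !pos)
    })
    libsize <- stats::rlnorm(n_s, meanlog = 0, sdlog = cfg$libsize_sdlog)

    counts <- list()
    for (comp in c("host", "SOL", "cTPut")) {
      n_g <- cfg$n_genes[[comp]]
      baseline <- stats::rlnorm(n_g, cfg$baseline_meanlog, cfg$baseline_sdlog)
      z <- latent_for_compartment(comp, cfg, n_s, factors, active)
      mu <- outer(baseline, libsize)
      if (comp == "SOL") mu[, pos] <- mu[, pos] * cfg$sol_multiplier
      m <- matrix(stats::qnbinom(stats::pnorm(z), size = cfg$nb_size, mu = mu),
                  nrow = n_g)
      rownames(m) <- gene_ids_for(comp, n_g)
      colnames(m) <- samples$sample_id
      if (comp == "cTPut") m <- m[, pos, drop = FALSE]
      counts[[comp]] <- m
    }
    counts
  })

  host_ids <- rownames(out$host)
  pathways <- synthetic_pathways(host_ids, cfg$n_pathways, cfg$pathway_overlap)

  ids_of <- function(comp, idx) {
    switch(comp, host = rownames(out$host)[idx],
           SOL = rownames(out$SOL)[idx], cTPut = rownames(out$cTPut)[idx])
  }
  pairs <- dplyr::bind_rows(lapply(cfg$blocks, function(b) {
    tidyr::expand_grid(from_gene = ids_of(b$from_compartment, b$from_genes),
                       to_gene = ids_of(b$to_compartment, b$to_genes)) |>
      dplyr::mutate(block = b$name,
                    from_compartment = b$from_compartment,
                    to_compartment = b$to_compartment,
                    latent_rho = b$sign * b$loading^2,
                    sign = b$sign, loading = b$loading, condition = b$condition)
  }))

  truth <- list(
    pairs = pairs,
    blocks = lapply(cfg$blocks, unclass),
    sol_multiplier = cfg$sol_multiplier,
    seed = cfg$seed,
    n_genes = as.list(cfg$n_genes),
    n_samples = n_s
  )

  structure(list(host = as_counts(out$host, "host"),
                 sol = as_counts(out$SOL, "SOL"),
                 ctput = as_counts(out$cTPut, "cTPut"),
                 samples = samples, pathways = pathways, truth = truth),
            class = "sim_result")
}

# consecutive chunks of the host genes, each pathway also borrowing the
# first `overlap` genes of the next chunk (membership multiplicity)
synthetic_pathways <- function(gene_ids, n_pathways, overlap) {
  n <- length(gene_ids)
  size <- ceiling(n / n_pathways)
  rows <- lapply(seq_len(n_pathways), function(i) {
    core <- seq((i - 1) * size + 1, min(i * size, n))
    nxt <- if (i < n_pathways && overlap > 0) {
      seq(i * size + 1, min(i * size + overlap, n))
    } else integer(0)
    idx <- unique(c(core, nxt))
    tibble::tibble(pathway_id = sprintf("PW%02d", i),
                   description = sprintf("synthetic host pathway %d", i),
                   gene_id = gene_ids[idx])
  })
  dplyr::bind_rows(rows)
}

#' Write a simulation to disk in the package's exchange formats
#'
#' Emits `host.tsv`, `sol.tsv`, `ctput.tsv`, `samples.tsv`,
#' `pathways.gmt` and `truth.json` under `outdir`.
#'
#' @param sim A `sim_result` from [simulate_expression()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$host, file.path(outdir, "host.tsv"))
  write_counts(sim$sol, file.path(outdir, "sol.tsv"))
  write_counts(sim$ctput, file.path(outdir, "ctput.tsv"))
  write_sample_sheet(sim$samples, file.path(outdir, "samples.tsv"))
  write_gmt(sim$pathways, file.path(outdir, "pathways.gmt"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}
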