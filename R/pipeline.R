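# One-shot orchestration of the whole analysis on simulated or on-disk
# inputs: standardization, abundance/diversity tests, ordination, edge
# calling, network scores, the pathway ledger, and condition contrasts.

#' Configuration for [full_run()]
#'
#' Every stage draws its seed deterministically from `seed` and the stage
#' name, so a run is a pure function of its configuration.
#'
#' @param simulate If `TRUE` inputs come from [simulate_expression()];
#'   otherwise `paths` must name existing files.
#' @param sim A [sim_config()] (its `seed` is overridden by `seed`).
#' @param paths Named list with `host`, `sol`, `ctput`, `samples`,
#'   `pathways` when `simulate = FALSE`.
#' @param sol_target,ctput_target Standardization totals (study values:
#'   3,000 symbiont reads, 5,000 Cardinium reads).
#' @param standardize_mode `"scale"` or `"downsample"`.
#' @param corr A [corr_config()] for the full edge network.
#' @param hub_rho_min,hub_min_strength Hub-analysis window and strength
#'   cutoff (the study used 0.75 and 100 at full compartment sizes;
#'   strength scales with the partner compartment, so scaled-down runs
#'   should scale the cutoff too).
#' @param ledger_n_perm,ledger_candidates Permutations and candidate pool
#'   (top-k symbiont genes by variance) for the per-pathway dbRDA ledger.
#' @param dbrda_n_perm Permutations for the whole-compartment dbRDA models.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(), paths = list(),
                       sol_target = 3000, ctput_target = 5000,
                       standardize_mode = c("scale", "downsample"),
                       corr = corr_config(n_perm = 999),
                       hub_rho_min = 0.75, hub_min_strength = 100,
                       ledger_n_perm = 199, ledger_candidates = 20,
                       dbrda_n_perm = 999, seed = 1L) {
  standardize_mode <- match.arg(standardize_mode)
  structure(list(simulate = simulate, sim = sim, paths = paths,
                 sol_target = sol_target, ctput_target = ctput_target,
                 standardize_mode = standardize_mode, corr = corr,
                 hub_rho_min = hub_rho_min, hub_min_strength = hub_min_strength,
                 ledger_n_perm = ledger_n_perm, ledger_candidates = ledger_candidates,
                 dbrda_n_perm = dbrda_n_perm, seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(config) {
  if (config$simulate) {
    cfg <- config$sim
    cfg$seed <- child_seed(config$seed, "simulate")
    sim <- simulate_expression(cfg)
    list(host = sim$host, sol = sim$sol, ctput = sim$ctput,
         samples = sim$samples, pathways = sim$pathways, truth = sim$truth)
  } else {
    for (nm in c("host", "sol", "ctput", "samples", "pathways")) {
      p <- config$paths[[nm]]
      if (is.null(p) || !file.exists(p %||% "")) {
        rlang::abort(paste0("full_run: missing input '", nm, "': ",
                            p %||% "<unset>"))
      }
    }
    list(host = read_counts(config$paths$host, "host"),
         sol = read_counts(config$paths$sol, "SOL"),
         ctput = read_counts(config$paths$ctput, "cTPut"),
         samples = read_sample_sheet(config$paths$samples),
         pathways = read_gmt(config$paths$pathways),
         truth = NULL)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("full_run stage '", name, "' failed: ",
                        conditionMessage(e)))
  })
}

#' Run the complete analysis and write all result tables
#'
#' Chains the pipeline on one input set: standardize the symbiont
#' compartments, test symbiont relative abundance and Shannon diversity
#' between conditions, fit the whole-compartment dbRDA models and ANOSIM,
#' call cross-compartment correlation edges (symbiont-Cardinium on the
#' cTPut-positive samples; host-symbiont per condition), score genes and
#' filter hubs, compare per-gene edge counts between conditions, build the
#' per-pathway dbRDA ledger, and run the per-gene and per-pathway
#' contrasts. Everything is written as TSV (edges also as SIF) plus a JSON
#' manifest of seeds and parameters.
#'
#' @param config A [run_config()].
#' @param outdir Output directory, created if needed.
#' @return Named list of all in-memory results (also written under
#'   `outdir`), invisibly.
#' @export
full_run <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- stage("inputs", load_inputs(config))
  samples <- inp$samples
  res <- list(samples = samples)

  sol_std <- stage("standardize", standardize_counts(
    inp$sol, config$sol_target, mode = config$standardize_mode,
    seed = child_seed(config$seed, "standardize_sol")))
  ct_std <- stage("standardize", standardize_counts(
    inp$ctput, config$ctput_target, mode = config$standardize_mode,
    seed = child_seed(config$seed, "standardize_ct")))

  # relative abundance + diversity, compared between conditions
  res$abundance <- stage("abundance", {
    ra <- relative_abundance(inp$sol, inp$host)
    ra$ctput_status <- samples$ctput_status[match(ra$sample_id, samples$sample_id)]
    ra
  })
  res$abundance_test <- stage("abundance", {
    mw <- mann_whitney_z(res$abundance$rel_abundance[!res$abundance$ctput_status],
                         res$abundance$rel_abundance[res$abundance$ctput_status])
    tibble::tibble(comparison = "SOL relative abundance, cTPut-negative vs positive",
                   U = mw$U, z = mw$z, p = mw$p, method = mw$method)
  })
  res$diversity <- stage("diversity", {
    h <- shannon_diversity(sol_std)
    h$ctput_status <- samples$ctput_status[match(h$sample_id, samples$sample_id)]
    h
  })
  res$diversity_test <- stage("diversity", {
    mw <- mann_whitney_z(res$diversity$shannon[!res$diversity$ctput_status],
                         res$diversity$shannon[res$diversity$ctput_status])
    tibble::tibble(comparison = "SOL Shannon diversity, cTPut-negative vs positive",
                   U = mw$U, z = mw$z, p = mw$p, method = mw$method)
  })

  # whole-compartment ordination models
  d_sol <- stage("dbrda", bray_curtis(sol_std))
  status_tbl <- samples[match(attr(d_sol, "Labels"), samples$sample_id), ]
  res$dbrda_status_fit <- stage("dbrda", dbrda(
    d_sol, data.frame(ctput = status_tbl$ctput_status),
    n_perm = config$dbrda_n_perm, seed = child_seed(config$seed, "dbrda_status")))
  res$dbrda_culture_fit <- stage("dbrda", dbrda(
    d_sol, data.frame(culture = status_tbl$culture),
    n_perm = config$dbrda_n_perm, seed = child_seed(config$seed, "dbrda_culture")))
  res$dbrda_models <- dplyr::bind_rows(
    dplyr::mutate(glance(res$dbrda_status_fit), model = "SOL ~ ctput_status", .before = 1),
    dplyr::mutate(glance(res$dbrda_culture_fit), model = "SOL ~ culture", .before = 1))
  res$anosim <- stage("anosim", {
    fit <- anosim(d_sol, ifelse(status_tbl$ctput_status, "pos", "neg"),
                  n_perm = config$dbrda_n_perm,
                  seed = child_seed(config$seed, "anosim"))
    glance(fit)
  })

  # symbiont-Cardinium network on the cTPut-positive samples
  cfg_edges <- config$corr
  cfg_edges$seed <- child_seed(config$seed, "edges_sol_ct")
  res$edges_sol_ctput <- stage("correlate", correlate_compartments(
    sol_std, ct_std, cfg_edges, samples = samples, subset = "ctput_positive"))

  # host-symbiont networks per condition
  edges_cond <- lapply(c(pos = "ctput_positive", neg = "ctput_negative"),
                       function(sub) {
    cfg <- config$corr
    cfg$seed <- child_seed(config$seed, paste0("edges_host_sol_", sub))
    stage("correlate", correlate_compartments(inp$host, sol_std, cfg,
                                              samples = samples, subset = sub))
  })
  res$edges_host_sol_pos <- edges_cond$pos
  res$edges_host_sol_neg <- edges_cond$neg

  res$edge_count_test <- stage("edge_counts", compare_edge_counts(
    edge_counts(edges_cond$pos, "host"), edge_counts(edges_cond$neg, "host")))

  # hub scoring of symbiont genes against host pathways, per condition
  res$hub_stats <- stage("netstats", {
    hub <- lapply(edges_cond, function(e) {
      e <- e[abs(e$rho) >= config$hub_rho_min, , drop = FALSE]
      gene_stats(e, "SOL", catalog = inp$pathways, mode = "pathway_instance")
    })
    dplyr::bind_rows(dplyr::mutate(hub$pos, condition = "ctput_positive"),
                     dplyr::mutate(hub$neg, condition = "ctput_negative"))
  })
  res$hubs <- stage("netstats", {
    dplyr::group_by(res$hub_stats, .data$condition) |>
      dplyr::group_modify(~ filter_hubs(.x, min_strength = config$hub_min_strength)) |>
      dplyr::ungroup()
  })

  res$pathway_ledger <- stage("ledger", pathway_ledger(
    inp$host, sol_std, inp$pathways, samples,
    distance = "rclr", candidate_pool = config$ledger_candidates,
    n_perm = config$ledger_n_perm,
    seed = child_seed(config$seed, "ledger")))

  res$gene_contrasts <- stage("diffexpr", contrast_genes(sol_std, samples))
  res$pathway_contrasts <- stage("diffexpr", contrast_pathways(
    inp$host, samples, inp$pathways))

  # outputs
  stage("write", {
    tsv <- function(x, nm) readr::write_tsv(x, file.path(outdir, nm), progress = FALSE)
    tsv(samples, "samples.tsv")
    tsv(res$abundance, "relative_abundance.tsv")
    tsv(res$abundance_test, "relative_abundance_test.tsv")
    tsv(res$diversity, "shannon_diversity.tsv")
    tsv(res$diversity_test, "shannon_diversity_test.tsv")
    tsv(res$dbrda_models, "dbrda_models.tsv")
    tsv(res$anosim, "anosim.tsv")
    write_edges(res$edges_sol_ctput, file.path(outdir, "edges_sol_ctput.tsv"), "tsv")
    write_edges(res$edges_sol_ctput, file.path(outdir, "edges_sol_ctput.sif"), "sif")
    write_edges(res$edges_host_sol_pos, file.path(outdir, "edges_host_sol_pos.tsv"), "tsv")
    write_edges(res$edges_host_sol_neg, file.path(outdir, "edges_host_sol_neg.tsv"), "tsv")
    tsv(res$edge_count_test, "edge_count_test.tsv")
    tsv(res$hub_stats, "hub_stats.tsv")
    tsv(res$hubs, "hubs.tsv")
    tsv(res$pathway_ledger, "pathway_ledger.tsv")
    tsv(res$gene_contrasts, "gene_contrasts.tsv")
    tsv(res$pathway_contrasts, "pathway_contrasts.tsv")
    manifest <- list(
      package = "symbionet",
      version = as.character(utils::packageVersion("symbionet")),
      seed = config$seed,
      simulate = config$simulate,
      parameters = list(
        sol_target = config$sol_target, ctput_target = config$ctput_target,
        standardize_mode = config$standardize_mode,
        corr = unclass(config$corr),
        hub_rho_min = config$hub_rho_min,
        hub_min_strength = config$hub_min_strength,
        ledger_n_perm = config$ledger_n_perm,
        ledger_candidates = config$ledger_candidates,
        dbrda_n_perm = config$dbrda_n_perm,
        sim = if (config$simulate) {
          c(unclass(config$sim)[c("n_reps", "nb_size", "libsize_sdlog",
                                  "sol_multiplier", "n_pathways",
                                  "pathway_overlap")],
            list(n_genes = as.list(config$sim$n_genes)))
        } else NULL
      ),
      stage_seeds = list(
        simulate = child_seed(config$seed, "simulate"),
        edges_sol_ct = child_seed(config$seed, "edges_sol_ct"),
        ledger = child_seed(config$seed, "ledger")
      )
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(res)
}
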