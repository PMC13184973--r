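#' Run the full small-scale biogeography pipeline
#'
#' Config-driven orchestration of the package's analysis stages on a
#' synthetic or user-supplied count table. Every stage writes a tidy TSV
#' into `outdir` (doubles at 6 significant digits, so reruns with the same
#' config and seed are byte-identical) and the run ends with a manifest
#' recording the config, seed, package version and the MD5 digest of every
#' output file.
#'
#' Stages (any subset, executed in this order):
#' \describe{
#'   \item{simulate}{generate a synthetic community from `preset` /
#'     `simulate` overrides; writes `counts.tsv`, `metadata.tsv`,
#'     `physical.tsv`, `truth.tsv`. Skipped when `counts` / `metadata`
#'     paths are given instead.}
#'   \item{alpha}{per-section alpha diversity (`alpha.tsv`).}
#'   \item{beta}{distance-decay table for the total community and, when
#'     >= 2 sections, the core/satellite subsets (`beta.tsv`), plus the
#'     core partition (`core.tsv`).}
#'   \item{trends}{per-taxon spatial trend classification (`trends.tsv`).}
#'   \item{neighborhood}{expected cells and richness per neighbourhood
#'     query (`neighborhood.tsv`); needs physical data.}
#'   \item{resample}{strategy sweep over `k_values` x `strategies`
#'     (`resample_alpha.tsv`, `resample_beta.tsv`, `resample_env.tsv`).}
#'   \item{cooccur}{equalised co-occurrence sweep over the same conditions
#'     (`cooccurrence.tsv`).}
#'   \item{sar}{randomised SAR curve + PL/LPL comparison (`sar_curve.tsv`,
#'     `scaling_fits.tsv`).}
#'   \item{breakpoint}{slope-change fit of the total-community distance
#'     decay (`breakpoint.tsv`).}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Recognised keys: `seed`, `preset`, `simulate` (list of
#'   [synthetic_config()] overrides), `counts`/`metadata`/`physical` (input
#'   TSV paths), `stages`, `depth`, `alpha_level`, `k_values`, `strategies`,
#'   `iterations`, `areas_um2`, `radii_um`, `n_sar`, `n_boot`,
#'   `cooccur_n_select`, `cooccur_iterations`.
#' @param outdir output directory (created if missing).
#' @param verbose print stage progress to stderr.
#' @return the manifest, invisibly (also written to `manifest.yaml`).
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "alpha", "beta", "trends",
                                 "neighborhood", "resample", "cooccur",
                                 "sar", "breakpoint")
  say <- function(...) if (verbose) message("[biofilmgeo] ", ...)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_fixed(df, path)
    outputs <<- c(outputs, path)
    path
  }

  physical <- NULL
  if (!is.null(config$counts)) {
    counts <- read_count_table(config$counts)
    meta <- read_section_metadata(config$metadata)
    if (!is.null(config$physical)) physical <- read_section_physical(config$physical)
  } else {
    say("stage simulate")
    sim_args <- config$simulate %||% list()
    sim_args$seed <- derive_seed(seed, "simulate")
    cfg <- if (!is.null(config$preset))
      do.call(environment_preset, c(list(name = config$preset), sim_args))
    else do.call(synthetic_config, sim_args)
    sim <- generate_biofilm(cfg)
    counts <- sim$counts; meta <- sim$metadata; physical <- sim$physical
    if ("simulate" %in% stages) {
      p <- file.path(outdir, "counts.tsv")
      write_count_table(counts, p); outputs <- c(outputs, p)
      emit(meta, "metadata.tsv")
      emit(physical, "physical.tsv")
      emit(sim$truth, "truth.tsv")
    }
  }

  depth <- as.integer(config$depth %||% min(colSums(counts)))
  alpha_level <- config$alpha_level %||% 0.05

  if ("alpha" %in% stages) {
    say("stage alpha")
    a <- alpha_diversity(counts)
    a$position_cm <- meta$position_cm[match(a$section_id, meta$section_id)]
    a$side <- meta$side[match(a$section_id, meta$section_id)]
    emit(a, "alpha.tsv")
  }

  dd_total <- NULL
  if (any(c("beta", "breakpoint") %in% stages)) {
    say("stage beta")
    dd_total <- distance_decay(counts, meta)
    dd_total$subset <- "total"
  }
  if ("beta" %in% stages) {
    part <- core_satellite_partition(counts)
    emit(part$rank_scores[, c("taxon_id", "occupancy", "mean_rel_abundance")],
         "core.tsv")
    beta_tabs <- list(dd_total)
    for (ss in c("core", "satellite")) {
      taxa <- if (ss == "core") part$core_taxa else part$satellite_taxa
      if (length(taxa) >= 1L) {
        dd <- tryCatch(suppressWarnings(distance_decay(counts, meta, subset_taxa = taxa)),
                       error = function(e) NULL)
        if (!is.null(dd)) { dd$subset <- ss; beta_tabs[[length(beta_tabs) + 1L]] <- dd }
      }
    }
    emit(do.call(rbind, beta_tabs), "beta.tsv")
  }

  if ("trends" %in% stages) {
    say("stage trends")
    emit(classify_trends(counts, meta, alpha_level = alpha_level), "trends.tsv")
  }

  if ("neighborhood" %in% stages && !is.null(physical)) {
    say("stage neighborhood")
    emit(neighborhood_richness_profile(
      counts, physical,
      areas_um2 = unlist(config$areas_um2 %||% c(10, 1e6)),
      radii_um = unlist(config$radii_um %||% c(5, 20))), "neighborhood.tsv")
  }

  k_values <- unlist(config$k_values %||% c(2L, 5L, 10L))
  strategies <- unlist(config$strategies %||% c("contiguous", "discontiguous"))
  iterations <- as.integer(config$iterations %||% 3L)

  sweep_res <- NULL
  if (any(c("resample", "cooccur") %in% stages)) {
    say("stage resample")
    sweep_res <- strategy_sweep(counts, meta, k_values = k_values,
                                strategies = strategies, depth = depth,
                                iterations = iterations,
                                seed = derive_seed(seed, "resample"))
  }
  if ("resample" %in% stages) {
    emit(sweep_res$alpha, "resample_alpha.tsv")
    if (!is.null(sweep_res$beta)) emit(sweep_res$beta, "resample_beta.tsv")
    emit(sweep_res$environment, "resample_env.tsv")
  }

  if ("cooccur" %in% stages) {
    say("stage cooccur")
    conditions <- list()
    for (strat in strategies) for (k in k_values) {
      plan <- sampling_plan(strategy = strat, k = k, rarefaction_depth = depth,
                            iterations = 1L,
                            seed = derive_seed(seed, "cooccur", strat, k))
      conditions[[paste0(strat, "_k", k)]] <- apply_plan(counts, meta, plan)
    }
    n_avail <- min(vapply(conditions, function(cd)
      min(vapply(cd, function(s) ncol(s$counts), integer(1))), integer(1)))
    n_select <- as.integer(config$cooccur_n_select %||% n_avail)
    emit(equalized_sweep(conditions, n_select = min(n_select, n_avail),
                         iterations = as.integer(config$cooccur_iterations %||% 20L),
                         seed = derive_seed(seed, "cooccur-sweep"),
                         alpha_level = alpha_level), "cooccurrence.tsv")
  }

  if ("sar" %in% stages) {
    say("stage sar")
    pa <- presence_absence(counts)
    areas <- meta$area_cm2[match(colnames(counts), meta$section_id)]
    curve <- sar_random(pa, areas / sum(areas), n_perm = 50L,
                        seed = derive_seed(seed, "sar-curve"))
    emit(as.data.frame(curve), "sar_curve.tsv")
    cmp <- compare_laws(counts, meta, n_sar = as.integer(config$n_sar %||% 50L),
                        seed = derive_seed(seed, "sar-compare"))
    res <- cmp$results
    res$win_fraction_pl <- cmp$win_fraction_pl
    res$win_fraction_lpl <- cmp$win_fraction_lpl
    emit(res, "scaling_fits.tsv")
  }

  if ("breakpoint" %in% stages) {
    say("stage breakpoint")
    bp <- breakpoint_fit(dd_total$distance_cm, dd_total$dissimilarity,
                         n_boot = as.integer(config$n_boot %||% 50L),
                         seed = derive_seed(seed, "breakpoint"))
    emit(data.frame(breakpoint_cm = bp$breakpoint_cm,
                    breakpoint_se_cm = bp$breakpoint_se_cm,
                    slope_left = bp$slope_left, slope_right = bp$slope_right,
                    intercept = bp$intercept, sse = bp$sse,
                    sse_single_line = bp$sse_single_line,
                    supported = bp$supported), "breakpoint.tsv")
  }

  manifest <- list(
    package = "biofilmgeo",
    version = as.character(utils::packageVersion("biofilmgeo")),
    seed = seed,
    stages = as.list(stages),
    config = config,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  say("done: ", length(outputs), " output files")
  invisible(manifest)
}
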