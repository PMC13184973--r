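#' Merge the two sides of each bisected section
#'
#' Sums counts over the side1/side2 pair at each axial position, mimicking
#' the common strategy of sampling whole pipe sections rather than separated
#' halves. Metadata areas are summed and the side is set to `merged`.
#'
#' @param counts count matrix (taxa x sections).
#' @param meta section metadata; every axial position must carry exactly one
#'   `side1` and one `side2` section (already-merged input is returned
#'   unchanged).
#' @return list with merged `counts` and `meta`. Merged section ids strip a
#'   trailing `_side1`/`_side2` suffix when the pair shares a stem,
#'   otherwise `pos<k>` ids are generated in axial order.
#' @export
merge_sides <- function(counts, meta) {
  counts <- validate_count_table(counts)
  meta <- validate_section_metadata(meta, counts)
  meta <- meta[meta$section_id %in% colnames(counts), ]
  if (all(meta$side == "merged")) return(list(counts = counts[, meta$section_id, drop = FALSE], meta = meta))
  split_pos <- split(meta, meta$position_cm)
  bad <- Filter(function(g) nrow(g) != 2L || !setequal(g$side, c("side1", "side2")),
                split_pos)
  if (length(bad))
    stop("unpaired sections at position(s): ",
         paste(vapply(bad, function(g) paste(g$section_id, collapse = "+"),
                      character(1)), collapse = ", "))
  split_pos <- split_pos[order(as.numeric(names(split_pos)))]
  stems <- vapply(seq_along(split_pos), function(k) {
    g <- split_pos[[k]]
    st <- unique(sub("_side[12]$", "", g$section_id))
    if (length(st) == 1L && !st %in% g$section_id) st else sprintf("pos%04d", k)
  }, character(1))
  groups <- stats::setNames(lapply(split_pos, function(g) g$section_id), stems)
  merged_counts <- merge_counts(counts, groups)
  merged_meta <- do.call(rbind, lapply(seq_along(split_pos), function(k) {
    g <- split_pos[[k]]
    data.frame(section_id = stems[k], position_cm = g$position_cm[1L],
               side = "merged", length_cm = g$length_cm[1L],
               area_cm2 = sum(g$area_cm2),
               environment = if ("environment" %in% names(g)) g$environment[1L] else NA,
               stringsAsFactors = FALSE)
  }))
  list(counts = merged_counts, meta = merged_meta)
}

#' Build pooling groups of sections
#'
#' Partitions the sections of `meta` into groups of `k` according to a
#' sampling strategy: `"contiguous"` pools consecutive runs of `k` sections
#' in axial order; `"discontiguous"` pools a uniformly random partition into
#' groups of `k` (seeded). When `k` does not divide the number of sections,
#' the trailing remainder forms a final smaller group.
#'
#' @param meta section metadata (axial order taken from `position_cm`, ties
#'   broken by section id).
#' @param strategy `"contiguous"` or `"discontiguous"` (`"original"` is
#'   accepted as an alias for k = 1 pass-through grouping).
#' @param k sections per sample, `1 <= k <= nrow(meta)`.
#' @param seed seed for the random partition (discontiguous only).
#' @return named list of character vectors of section ids.
#' @export
build_groups <- function(meta, strategy = c("contiguous", "discontiguous", "original"),
                         k = 1L, seed = NULL) {
  strategy <- match.arg(strategy)
  n <- nrow(meta)
  if (k < 1L || k > n) stop("k must be between 1 and the number of sections (", n, ")")
  ord <- order(meta$position_cm, meta$section_id)
  ids <- meta$section_id[ord]
  if (strategy == "original") k <- 1L
  if (strategy == "discontiguous" && k > 1L) {
    set_seed_if(seed)
    ids <- sample(ids)
  }
  idx <- ceiling(seq_len(n) / k)
  groups <- split(ids, idx)
  # singleton groups keep their section id so k = 1 is a pure relabel-free
  # pass-through; larger pools get synthetic ids
  names(groups) <- if (k == 1L) unlist(groups, use.names = FALSE)
                   else sprintf("pool%03d", seq_along(groups))
  groups
}

#' Define a simulated sampling plan
#'
#' Bundles the parameters of one alternative sampling strategy: whether the
#' two pipe sides are first merged, how many (merged) sections are pooled
#' into each simulated sample and how (contiguous vs discontiguous), the
#' fixed sequencing depth each pooled sample is rarefied to, and how many
#' replicate draws to generate.
#'
#' @param strategy `"original"`, `"contiguous"` or `"discontiguous"`.
#' @param k sections per sample (ignored for `"original"`, which is the
#'   identity pass-through, k = 1).
#' @param merge_sides merge side pairs before pooling (default TRUE).
#' @param rarefaction_depth reads per simulated sample.
#' @param iterations number of replicate sample sets.
#' @param seed master seed.
#' @return list of class `sampling_plan`.
#' @export
sampling_plan <- function(strategy = c("original", "contiguous", "discontiguous"),
                          k = 1L, merge_sides = TRUE, rarefaction_depth,
                          iterations = 1L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "original") k <- 1L
  stopifnot(k >= 1L, iterations >= 1L, rarefaction_depth >= 0)
  structure(list(strategy = strategy, k = as.integer(k),
                 merge_sides = isTRUE(merge_sides),
                 rarefaction_depth = as.integer(rarefaction_depth),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Apply a sampling plan to a count table
#'
#' Per iteration: optionally merge side pairs, build pooling groups, sum the
#' member sections' counts, and rarefy every pooled sample to the plan's
#' depth. Contiguous grouping is fixed across iterations (only the
#' rarefaction draw varies); discontiguous grouping is re-randomised each
#' iteration. All randomness derives from the plan's seed.
#'
#' @param counts count matrix (taxa x sections).
#' @param meta section metadata.
#' @param plan a [sampling_plan()].
#' @return list of length `iterations`; each element a list with the pooled,
#'   rarefied `counts` matrix, the `groups` used, `sample_area_fraction`
#'   (named vector, per-sample area over total environment area) and the
#'   `iteration` index.
#' @export
apply_plan <- function(counts, meta, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  counts <- validate_count_table(counts)
  meta <- validate_section_metadata(meta, counts)
  if (plan$merge_sides) {
    ms <- merge_sides(counts, meta)
    counts <- ms$counts; meta <- ms$meta
  } else {
    counts <- counts[, meta$section_id, drop = FALSE]
  }
  total_area <- sum(meta$area_cm2)
  out <- vector("list", plan$iterations)
  for (it in seq_len(plan$iterations)) {
    gseed <- derive_seed(plan$seed, "groups", plan$strategy, plan$k, it)
    groups <- build_groups(meta, strategy = plan$strategy, k = plan$k, seed = gseed)
    pooled <- merge_counts(counts, groups)
    shallow <- colSums(pooled) < plan$rarefaction_depth
    if (any(shallow))
      stop("rarefaction depth ", plan$rarefaction_depth,
           " infeasible for pooled sample(s): ",
           paste(colnames(pooled)[shallow], collapse = ", "))
    rare <- rarefy_table(pooled, plan$rarefaction_depth,
                         seed = derive_seed(plan$seed, "rarefy-iter", it),
                         iteration = it)
    area_frac <- vapply(groups, function(g)
      sum(meta$area_cm2[match(g, meta$section_id)]) / total_area, numeric(1))
    out[[it]] <- list(counts = rare, groups = groups,
                      sample_area_fraction = area_frac, iteration = it,
                      plan = plan)
  }
  out
}

#' Sweep sampling strategies and sample sizes
#'
#' Runs [apply_plan()] over a grid of strategies and pooling sizes and
#' summarises, per iteration: each simulated sample's alpha diversity,
#' pairwise Bray-Curtis dissimilarities among samples, and the
#' whole-environment richness of the rarefied sample set (number of taxa
#' detected anywhere, i.e. at the fixed per-sample depth the total
#' sequencing effort shrinks as k grows).
#'
#' @param counts count matrix.
#' @param meta section metadata.
#' @param k_values integer vector of sections-per-sample values.
#' @param strategies subset of `c("contiguous", "discontiguous")`.
#' @param depth rarefaction depth per simulated sample.
#' @param iterations replicate sample sets per combination.
#' @param seed master seed.
#' @param merge_sides merge side pairs first (default TRUE).
#' @return list of three long-format data frames keyed by
#'   `(strategy, k, iteration)`: `alpha` (per sample), `beta` (per sample
#'   pair) and `environment` (one row per iteration with
#'   `whole_env_richness`, `n_samples`, `mean_area_fraction`).
#' @export
strategy_sweep <- function(counts, meta, k_values,
                           strategies = c("contiguous", "discontiguous"),
                           depth, iterations = 10L, seed = 1L,
                           merge_sides = TRUE) {
  alpha <- list(); beta <- list(); env <- list()
  for (strat in strategies) for (k in k_values) {
    plan <- sampling_plan(strategy = strat, k = k, merge_sides = merge_sides,
                          rarefaction_depth = depth, iterations = iterations,
                          seed = derive_seed(seed, "sweep", strat, k))
    sets <- apply_plan(counts, meta, plan)
    for (set in sets) {
      key <- data.frame(strategy = strat, k = k, iteration = set$iteration,
                        stringsAsFactors = FALSE)
      a <- alpha_diversity(set$counts)
      a$area_fraction <- set$sample_area_fraction[a$section_id]
      alpha[[length(alpha) + 1L]] <- cbind(key[rep(1L, nrow(a)), ], a)
      if (ncol(set$counts) >= 2L) {
        bc <- bray_curtis_matrix(set$counts)
        b <- data.frame(dissimilarity = as.vector(bc))
        beta[[length(beta) + 1L]] <- cbind(key[rep(1L, nrow(b)), ], b)
      }
      env[[length(env) + 1L]] <- cbind(key, data.frame(
        whole_env_richness = sum(rowSums(set$counts) > 0),
        n_samples = ncol(set$counts),
        mean_area_fraction = mean(set$sample_area_fraction)))
    }
  }
  list(alpha = do.call(rbind, alpha),
       beta = if (length(beta)) do.call(rbind, beta) else NULL,
       environment = do.call(rbind, env))
}
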