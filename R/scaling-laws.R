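#' Exact species accumulation (species-area) curve
#'
#' Expected richness when drawing `n` of the `N` available samples uniformly
#' without replacement: `E[S(n)] = S - sum_i C(N - o_i, n) / C(N, n)`, where
#' `o_i` is the number of samples occupied by taxon i. The area coordinate
#' of `n` samples is `n * mean(areas_per_sample)` (the mean total area over
#' all n-subsets).
#'
#' @param pa logical or 0/1 presence/absence matrix (taxa x samples).
#' @param areas_per_sample per-sample areas (any unit: cm^2 or fractions of
#'   the total environment area); defaults to `1/N` each so the curve is
#'   indexed by the fraction of samples drawn.
#' @return data frame of class `sar_curve` with `n_samples`, `area`,
#'   `expected_richness`, `richness_sd` (NA for the exact curve).
#' @export
#' @examples
#' pa <- rbind(A = c(TRUE, TRUE, TRUE), B = c(TRUE, FALSE, FALSE))
#' sar_exact(pa)$expected_richness[1] # 2 - 2/3
sar_exact <- function(pa, areas_per_sample = NULL) {
  if (!is.matrix(pa) || nrow(pa) < 1L || ncol(pa) < 2L)
    stop("need a taxa x samples matrix with >= 2 samples")
  pa <- pa > 0
  N <- ncol(pa)
  areas_per_sample <- areas_per_sample %||% rep(1 / N, N)
  if (length(areas_per_sample) != N) stop("areas_per_sample length mismatch")
  occ <- rowSums(pa)
  S <- sum(occ > 0)
  occ <- occ[occ > 0]
  expected <- vapply(seq_len(N), function(n) {
    S - sum(exp(lchoose(N - occ, n) - lchoose(N, n)))
  }, numeric(1))
  structure(data.frame(n_samples = seq_len(N),
                       area = seq_len(N) * mean(areas_per_sample),
                       expected_richness = expected,
                       richness_sd = NA_real_),
            class = c("sar_curve", "data.frame"))
}

#' Randomised species accumulation curve
#'
#' Mean and s.d. of cumulative richness over `n_perm` random orderings of
#' the samples, with the mean cumulative area as the x-coordinate (so
#' unequal sample areas are handled exactly).
#'
#' @param pa presence/absence matrix (taxa x samples).
#' @param areas_per_sample per-sample areas (default `1/N` each).
#' @param n_perm number of random orderings (>= 1).
#' @param seed integer seed or NULL.
#' @return `sar_curve` data frame with `n_samples`, `area`,
#'   `expected_richness`, `richness_sd`.
#' @export
sar_random <- function(pa, areas_per_sample = NULL, n_perm = 100L, seed = NULL) {
  if (!is.matrix(pa) || nrow(pa) < 1L || ncol(pa) < 1L) stop("empty matrix")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pa <- pa > 0
  N <- ncol(pa)
  areas_per_sample <- areas_per_sample %||% rep(1 / N, N)
  set_seed_if(seed)
  pa <- pa[rowSums(pa) > 0L, , drop = FALSE]   # absent taxa never accumulate
  rich <- matrix(0, n_perm, N)
  areas <- matrix(0, n_perm, N)
  for (b in seq_len(n_perm)) {
    ord <- if (N > 1L) sample.int(N) else 1L
    # cumulative richness via each taxon's first detection along the ordering
    first <- max.col(pa[, ord, drop = FALSE], ties.method = "first")
    rich[b, ] <- cumsum(tabulate(first, nbins = N))
    areas[b, ] <- cumsum(areas_per_sample[ord])
  }
  structure(data.frame(n_samples = seq_len(N),
                       area = colMeans(areas),
                       expected_richness = colMeans(rich),
                       richness_sd = if (n_perm > 1L) apply(rich, 2L, stats::sd)
                                     else rep(NA_real_, N)),
            class = c("sar_curve", "data.frame"))
}

pl_predict <- function(pars, A) pars[["c"]] * A^pars[["z"]]
lpl_predict <- function(pars, A)
  pmax(pars[["b"]] + pars[["c"]] * log(A), 1e-10)^pars[["z"]]

#' Fit a species-area scaling law to an accumulation curve
#'
#' Fits either the power law `R = c * A^z` (`law = "PL"`) or the logarithmic
#' power law `R = [b + c * log(A)]^z` (`law = "LPL"`, natural log) to the
#' `(area, expected_richness)` points of a SAR curve by nonlinear least
#' squares (Levenberg-Marquardt). `z` is the spatial turnover exponent. The
#' PL fit is initialised from the log-log linear regression; the LPL fit
#' starts from the linear regression of R on log(A) and a multistart over
#' `z` in {0.5, 1, 2}, with the base `b + c*log(A)` floored at a small
#' positive value over the observed areas so the law stays real-valued.
#' RMSE is the root mean squared residual against the curve points.
#'
#' @param curve a `sar_curve` (or any data frame with `area` and
#'   `expected_richness`), all areas > 0; >= 3 points for PL, >= 4 for LPL.
#' @param law `"PL"` or `"LPL"`.
#' @return list of class `scaling_law_fit`: `law`, `c`, `z`, `b` (NA for
#'   PL), `rmse`, `converged`.
#' @export
#' @examples
#' a <- seq(0.05, 1, by = 0.05)
#' fit_scaling_law(data.frame(area = a, expected_richness = 10 * a^0.25), "PL")
fit_scaling_law <- function(curve, law = c("PL", "LPL")) {
  law <- match.arg(law)
  A <- curve$area; R <- curve$expected_richness
  keep <- is.finite(A) & is.finite(R)
  A <- A[keep]; R <- R[keep]
  if (any(A <= 0)) stop("areas must be > 0")
  if (length(A) < (if (law == "PL") 3L else 4L))
    stop("too few curve points for ", law)
  if (law == "PL") {
    pos <- R > 0
    init <- stats::lm(log(R[pos]) ~ log(A[pos]))$coefficients
    fit <- tryCatch(minpack.lm::nlsLM(
      R ~ c0 * A^z, start = list(c0 = exp(unname(init[1L])), z = unname(init[2L])),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      pars <- c(c = exp(unname(init[1L])), z = unname(init[2L]))
      pred <- pl_predict(pars, A)
      return(structure(list(law = "PL", c = pars[["c"]], z = pars[["z"]],
                            b = NA_real_,
                            rmse = sqrt(mean((R - pred)^2)), converged = FALSE),
                       class = "scaling_law_fit"))
    }
    cf <- stats::coef(fit)
    pred <- cf[["c0"]] * A^cf[["z"]]
    return(structure(list(law = "PL", c = cf[["c0"]], z = cf[["z"]],
                          b = NA_real_, rmse = sqrt(mean((R - pred)^2)),
                          converged = TRUE),
                     class = "scaling_law_fit"))
  }
  # LPL: multistart over z
  lin <- stats::lm(R ~ log(A))$coefficients
  best <- NULL
  for (z0 in c(0.5, 1, 2)) {
    lin_z <- stats::lm(I(pmax(R, 1e-10)^(1 / z0)) ~ log(A))$coefficients
    start <- list(b = unname(lin_z[1L]), c0 = unname(lin_z[2L]), z = z0)
    if (z0 == 1) start <- list(b = unname(lin[1L]), c0 = unname(lin[2L]), z = 1)
    fit <- tryCatch(minpack.lm::nlsLM(
      R ~ pmax(b + c0 * log(A), 1e-10)^z, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    pred <- pmax(lin[1L] + lin[2L] * log(A), 1e-10)
    return(structure(list(law = "LPL", c = unname(lin[2L]), z = 1,
                          b = unname(lin[1L]), rmse = sqrt(mean((R - pred)^2)),
                          converged = FALSE),
                     class = "scaling_law_fit"))
  }
  cf <- stats::coef(best$fit)
  pred <- pmax(cf[["b"]] + cf[["c0"]] * log(A), 1e-10)^cf[["z"]]
  structure(list(law = "LPL", c = cf[["c0"]], z = cf[["z"]], b = cf[["b"]],
                 rmse = sqrt(mean((R - pred)^2)), converged = TRUE),
            class = "scaling_law_fit")
}

#' @export
print.scaling_law_fit <- function(x, ...) {
  if (x$law == "PL")
    cat(sprintf("PL fit: R = %.4g * A^%.4g (rmse %.4g)%s\n", x$c, x$z, x$rmse,
                if (x$converged) "" else " [not converged]"))
  else
    cat(sprintf("LPL fit: R = [%.4g + %.4g log A]^%.4g (rmse %.4g)%s\n",
                x$b, x$c, x$z, x$rmse,
                if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Predict richness from a fitted scaling law
#'
#' @param object a `scaling_law_fit`.
#' @param area areas at which to predict.
#' @param ... unused.
#' @return predicted richness.
#' @export
predict.scaling_law_fit <- function(object, area, ...) {
  if (object$law == "PL") pl_predict(c(c = object$c, z = object$z), area)
  else lpl_predict(c(b = object$b, c = object$c, z = object$z), area)
}

#' Compare PL and LPL fits over randomised SAR curves
#'
#' Builds `n_sar` randomised species accumulation curves from the
#' presence/absence structure of a count table (fresh sub-seeds per curve,
#' each curve the average of `n_perm_per_curve` random sample orderings),
#' fits both scaling laws to every curve, and reports the paired RMSE
#' distributions and each law's win fraction (strictly lower RMSE).
#'
#' @param counts count matrix (taxa x samples/sections).
#' @param meta optional metadata supplying `area_cm2` per sample; when NULL
#'   areas are equal fractions of the total.
#' @param n_sar number of randomised curves (default 100).
#' @param n_perm_per_curve orderings averaged per curve (default 10).
#' @param seed master seed.
#' @return list with `results` (data frame: curve, rmse_pl, rmse_lpl, z_pl,
#'   z_lpl), `win_fraction_pl`, `win_fraction_lpl`.
#' @export
compare_laws <- function(counts, meta = NULL, n_sar = 100L,
                         n_perm_per_curve = 10L, seed = 1L) {
  counts <- validate_count_table(counts)
  pa <- presence_absence(counts)
  areas <- NULL
  if (!is.null(meta)) {
    areas <- meta$area_cm2[match(colnames(counts), meta$section_id)]
    areas <- areas / sum(areas)
  }
  rows <- lapply(seq_len(n_sar), function(i) {
    curve <- sar_random(pa, areas, n_perm = n_perm_per_curve,
                        seed = derive_seed(seed, "sar", i))
    fpl <- fit_scaling_law(curve, "PL")
    flpl <- fit_scaling_law(curve, "LPL")
    data.frame(curve = i, rmse_pl = fpl$rmse, rmse_lpl = flpl$rmse,
               z_pl = fpl$z, z_lpl = flpl$z)
  })
  results <- do.call(rbind, rows)
  list(results = results,
       win_fraction_pl = mean(results$rmse_pl < results$rmse_lpl),
       win_fraction_lpl = mean(results$rmse_lpl < results$rmse_pl))
}

#' Spatial turnover as a function of sampling strategy and sample size
#'
#' For each (strategy, k, iteration): applies the sampling plan, builds a
#' randomised SAR curve over the simulated samples, fits both scaling laws
#' and records their turnover exponents `z` and RMSEs.
#'
#' @param counts count matrix.
#' @param meta section metadata.
#' @param k_values sections per sample values.
#' @param strategies subset of `c("contiguous", "discontiguous")`.
#' @param depth rarefaction depth per simulated sample.
#' @param iterations replicate sample sets per combination.
#' @param seed master seed.
#' @param n_perm_per_curve orderings averaged per SAR curve.
#' @param merge_sides merge side pairs first (default TRUE).
#' @return data frame with one row per (strategy, k, iteration, law):
#'   `c`, `z`, `b`, `rmse`, `converged`, `n_samples`,
#'   `mean_area_fraction`.
#' @export
turnover_vs_samplesize <- function(counts, meta, k_values,
                                   strategies = c("contiguous", "discontiguous"),
                                   depth, iterations = 5L, seed = 1L,
                                   n_perm_per_curve = 10L, merge_sides = TRUE) {
  rows <- list()
  for (strat in strategies) for (k in k_values) {
    plan <- sampling_plan(strategy = strat, k = k, merge_sides = merge_sides,
                          rarefaction_depth = depth, iterations = iterations,
                          seed = derive_seed(seed, "turnover", strat, k))
    sets <- apply_plan(counts, meta, plan)
    for (set in sets) {
      if (ncol(set$counts) < 4L) next
      pa <- presence_absence(set$counts)
      curve <- sar_random(pa, set$sample_area_fraction,
                          n_perm = n_perm_per_curve,
                          seed = derive_seed(seed, "turnover-sar", strat, k,
                                             set$iteration))
      for (law in c("PL", "LPL")) {
        f <- fit_scaling_law(curve, law)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strat, k = k, iteration = set$iteration, law = law,
          c = f$c, z = f$z, b = f$b, rmse = f$rmse, converged = f$converged,
          n_samples = ncol(set$counts),
          mean_area_fraction = mean(set$sample_area_fraction),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Minimal observed area needed to extrapolate total richness
#'
#' Refits the scaling law on growing prefixes of the SAR curve and reports
#' the smallest observed area fraction from which the extrapolation to the
#' full environment predicts the true total richness within `tolerance`
#' (relative error).
#'
#' @param curve a `sar_curve` over area fractions (last point = whole
#'   environment).
#' @param law `"PL"` or `"LPL"`.
#' @param tolerance relative richness error allowed (default 0.1).
#' @return list with `area_fraction` (NA if never satisfied), `reached`,
#'   `relative_error` at the returned prefix, `n_points_used`.
#' @export
area_for_richness_error <- function(curve, law = c("PL", "LPL"),
                                    tolerance = 0.1) {
  law <- match.arg(law)
  min_pts <- if (law == "PL") 3L else 4L
  n <- nrow(curve)
  if (n <= min_pts) stop("curve too short")
  total_area <- curve$area[n]
  total_rich <- curve$expected_richness[n]
  for (j in min_pts:n) {
    f <- tryCatch(fit_scaling_law(curve[seq_len(j), ], law),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    pred <- predict(f, total_area)
    err <- abs(pred - total_rich) / total_rich
    if (is.finite(err) && err <= tolerance)
      return(list(area_fraction = curve$area[j] / total_area, reached = TRUE,
                  relative_error = err, n_points_used = j))
  }
  list(area_fraction = NA_real_, reached = FALSE, relative_error = NA_real_,
       n_points_used = NA_integer_)
}
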