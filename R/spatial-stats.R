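# all permutations of a vector, rows = permutations (used for exact
# Spearman p-values; only called for small n)
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) cbind(v[i], all_permutations(v[-i]))))
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank correlation of abundance against position
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks on
#' ties). The two-sided p-value is exact for n <= 8, obtained by enumerating
#' all permutations of the abundance ranks against the fixed positions; for
#' larger n the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom is used.
#'
#' @param abundance numeric vector (e.g. a taxon's relative abundance per
#'   section).
#' @param position numeric vector of the same length (section positions,
#'   cm); >= 4 pairs required.
#' @return list with `rho`, `p` and `degenerate` (TRUE when either vector is
#'   constant, in which case rho = 0 and p = 1).
#' @export
spearman_trend <- function(abundance, position) {
  n <- length(abundance)
  if (length(position) != n) stop("length mismatch")
  if (n < 4L) stop("need >= 4 paired observations")
  rho <- spearman_rho(position, abundance)
  if (is.na(rho)) return(list(rho = 0, p = 1, degenerate = TRUE))
  if (n <= 8L) {
    ry <- rank(abundance)
    rx <- rank(position)
    perms <- all_permutations(ry)
    sx <- stats::sd(rx); mx <- mean(rx)
    rhos <- as.vector((perms %*% (rx - mx)) / ((n - 1) * sx * apply(perms, 1L, stats::sd)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), degenerate = FALSE)
}

# exact distribution of the number of runs given n1 and n2 symbols:
# P(R = 2k)   = 2 C(n1-1,k-1) C(n2-1,k-1) / C(n, n1)
# P(R = 2k+1) = [C(n1-1,k) C(n2-1,k-1) + C(n1-1,k-1) C(n2-1,k)] / C(n, n1)
runs_distribution <- function(n1, n2) {
  n <- n1 + n2
  rmax <- 2L * min(n1, n2) + (n1 != n2)
  r <- 2:rmax
  lden <- lchoose(n, n1)
  pr <- vapply(r, function(rr) {
    if (rr %% 2L == 0L) {
      k <- rr %/% 2L
      2 * exp(lchoose(n1 - 1, k - 1) + lchoose(n2 - 1, k - 1) - lden)
    } else {
      k <- (rr - 1L) %/% 2L
      exp(lchoose(n1 - 1, k) + lchoose(n2 - 1, k - 1) - lden) +
        exp(lchoose(n1 - 1, k - 1) + lchoose(n2 - 1, k) - lden)
    }
  }, numeric(1))
  data.frame(runs = r, prob = pr)
}

#' Wald-Wolfowitz runs test for nonrandom ordering
#'
#' Dichotomises the series around its median (values equal to the median are
#' dropped, the classical convention) and tests whether the number of runs
#' of above/below-median values is compatible with a random arrangement. The
#' two-sided p-value is exact (from the runs distribution) when the
#' dichotomised length is <= 20, and uses the normal approximation with
#' continuity correction otherwise. Too few runs indicate clustering
#' (e.g. a spatial trend); too many indicate alternation.
#'
#' @param series numeric vector in spatial order, >= 6 observations.
#' @return list with `p`, `runs` (observed), `n1`, `n2`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
#' @examples
#' runs_test(c(1, 1, 1, 5, 5, 5, 1, 2, 6, 7))
runs_test <- function(series) {
  if (length(series) < 6L) stop("need >= 6 observations")
  med <- stats::median(series)
  s <- series[series != med]
  if (length(s) == 0L) stop("degenerate series: all observations equal the median")
  above <- s > med
  n1 <- sum(above); n2 <- sum(!above)
  if (n1 == 0L || n2 == 0L)
    stop("degenerate series: all retained observations on one side of the median")
  runs <- 1L + sum(above[-1L] != above[-length(above)])
  if (n1 + n2 <= 20L) {
    dist <- runs_distribution(n1, n2)
    lower <- sum(dist$prob[dist$runs <= runs])
    upper <- sum(dist$prob[dist$runs >= runs])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- 2 * n1 * n2 / n + 1
    sigma <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
    z_lo <- (runs - mu + 0.5) / sigma
    z_hi <- (runs - mu - 0.5) / sigma
    p <- min(1, 2 * min(stats::pnorm(z_lo), stats::pnorm(z_hi, lower.tail = FALSE)))
    method <- "normal"
  }
  list(p = p, runs = runs, n1 = n1, n2 = n2, method = method)
}

#' Detect per-taxon spatial trends along the environment
#'
#' For each taxon, its relative abundance series in axial order is tested
#' with a Spearman correlation against position (monotonic trends) and a
#' Wald-Wolfowitz runs test (nonrandom, e.g. peaked, arrangements). P-values
#' are Benjamini-Hochberg adjusted across taxa, separately per test family.
#' A taxon is classified `monotonic` if its adjusted Spearman p is below
#' `alpha_level`; otherwise `nonrandom` if its adjusted runs p is; otherwise
#' `none`. Degenerate series (constant, or absent taxa) are classified
#' `none` and flagged.
#'
#' @param counts count matrix (taxa x sections).
#' @param meta section metadata; sections are ordered by `position_cm`
#'   (ties broken by section id, so the two sides of one axial position are
#'   adjacent).
#' @param alpha_level significance level on adjusted p-values (default
#'   0.05).
#' @return data frame with one row per taxon: `taxon_id`, `spearman_rho`,
#'   `spearman_p`, `runs_p`, `rho_p_adj`, `runs_p_adj`, `classification`,
#'   `degenerate`.
#' @export
classify_trends <- function(counts, meta, alpha_level = 0.05) {
  counts <- validate_count_table(counts)
  meta <- validate_section_metadata(meta, counts)
  secs <- meta$section_id[order(meta$position_cm, meta$section_id)]
  if (length(secs) < 6L) stop("need >= 6 sections")
  sub <- counts[, secs, drop = FALSE]
  rel <- sweep(sub, 2L, pmax(colSums(sub), 1L), "/")
  pos <- meta$position_cm[match(secs, meta$section_id)]
  res <- lapply(rownames(rel), function(tx) {
    y <- rel[tx, ]
    sp <- spearman_trend(y, pos)
    rt <- tryCatch(runs_test(y), error = function(e) NULL)
    data.frame(taxon_id = tx, spearman_rho = sp$rho, spearman_p = sp$p,
               runs_p = if (is.null(rt)) 1 else rt$p,
               spearman_degenerate = sp$degenerate,
               runs_degenerate = is.null(rt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$rho_p_adj <- stats::p.adjust(out$spearman_p, method = "BH")
  out$runs_p_adj <- stats::p.adjust(out$runs_p, method = "BH")
  # a degenerate test never supports a classification, but one degenerate
  # family does not veto the other (sparse taxa often break only the runs
  # test, whose median is zero)
  out$classification <- ifelse(
    !out$spearman_degenerate & out$rho_p_adj <= alpha_level, "monotonic",
    ifelse(!out$runs_degenerate & out$runs_p_adj <= alpha_level, "nonrandom",
           "none"))
  out$degenerate <- out$spearman_degenerate & out$runs_degenerate
  out[, c("taxon_id", "spearman_rho", "spearman_p", "runs_p", "rho_p_adj",
          "runs_p_adj", "classification", "degenerate",
          "spearman_degenerate", "runs_degenerate")]
}

# SSE of the continuous two-segment fit with the break at psi
segmented_sse <- function(psi, x, y) {
  X <- cbind(1, x, pmax(x - psi, 0))
  sum(stats::lm.fit(X, y)$residuals^2)
}

fit_breakpoint_once <- function(x, y, n_grid = 80L) {
  ux <- sort(unique(x))
  if (length(ux) < 8L) stop("need more distinct distances to place a breakpoint")
  cand <- ux[4:(length(ux) - 3L)]                 # exclude 3 points per edge
  if (length(cand) > n_grid)
    cand <- unique(stats::quantile(cand, probs = seq(0, 1, length.out = n_grid),
                                   names = FALSE, type = 1))
  sse <- vapply(cand, segmented_sse, numeric(1), x = x, y = y)
  best <- which.min(sse)
  lo <- cand[max(1L, best - 1L)]; hi <- cand[min(length(cand), best + 1L)]
  opt <- stats::optimize(segmented_sse, interval = c(lo, hi), x = x, y = y)
  if (opt$objective <= sse[best]) {
    psi <- opt$minimum; best_sse <- opt$objective
  } else {
    psi <- cand[best]; best_sse <- sse[best]
  }
  coefs <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)$coefficients
  list(breakpoint = psi, intercept = coefs[1L], slope_left = coefs[2L],
       slope_right = coefs[2L] + coefs[3L], sse = best_sse)
}

#' Fit a single slope change to a distance-decay relationship
#'
#' Fits a continuous two-segment piecewise-linear function of distance to
#' dissimilarities by least squares. The breakpoint is located by a grid
#' search over the observed distances (excluding 3 distinct values at each
#' edge; large grids are thinned to `n_grid` quantile-spaced candidates),
#' refined by golden-section search between the neighbouring grid points.
#' The breakpoint standard error is estimated by case-resampling bootstrap.
#' When the two-segment fit improves the single-line SSE by less than 1%,
#' `supported` is FALSE (no evidence for a slope change).
#'
#' @param distance distances (cm), >= 10 points spanning a positive range.
#' @param dissimilarity dissimilarities, same length.
#' @param n_boot bootstrap replicates for the standard error (default 100;
#'   0 skips the bootstrap, `breakpoint_se_cm` is then NA).
#' @param seed integer seed for the bootstrap, or NULL.
#' @param n_grid maximal number of breakpoint candidates in the grid.
#' @return list of class `breakpoint_fit`: `breakpoint_cm`,
#'   `breakpoint_se_cm`, `slope_left`, `slope_right`, `intercept`, `sse`,
#'   `sse_single_line`, `supported`.
#' @export
#' @examples
#' dd <- generate_distance_decay(n = 200, breakpoint_cm = 30, noise_sd = 0,
#'                               seed = 1)
#' breakpoint_fit(dd$distance_cm, dd$dissimilarity, n_boot = 0)$breakpoint_cm
breakpoint_fit <- function(distance, dissimilarity, n_boot = 100L, seed = NULL,
                           n_grid = 80L) {
  if (length(distance) != length(dissimilarity)) stop("length mismatch")
  if (length(distance) < 10L) stop("need >= 10 points")
  if (diff(range(distance)) <= 0) stop("distances must span a positive range")
  fit <- fit_breakpoint_once(distance, dissimilarity, n_grid)
  sse1 <- sum(stats::lm.fit(cbind(1, distance), dissimilarity)$residuals^2)
  supported <- (sse1 - fit$sse) / max(sse1, .Machine$double.eps) >= 0.01
  se <- NA_real_
  if (n_boot > 0L) {
    set_seed_if(seed)
    n <- length(distance)
    bps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_breakpoint_once(distance[idx], dissimilarity[idx],
                                   n_grid = min(n_grid, 40L))$breakpoint,
               error = function(e) NA_real_)
    }, numeric(1))
    se <- stats::sd(bps, na.rm = TRUE)
  }
  structure(list(breakpoint_cm = unname(fit$breakpoint),
                 breakpoint_se_cm = se,
                 slope_left = unname(fit$slope_left),
                 slope_right = unname(fit$slope_right),
                 intercept = unname(fit$intercept),
                 sse = fit$sse, sse_single_line = sse1,
                 supported = supported),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("breakpoint_fit: %.2f +/- %.2f cm (slopes %.4g -> %.4g)%s\n",
              x$breakpoint_cm, x$breakpoint_se_cm, x$slope_left, x$slope_right,
              if (x$supported) "" else " [no supported breakpoint]"))
  invisible(x)
}
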