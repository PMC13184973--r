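#' Presence/absence matrix from counts
#'
#' @param counts count matrix (taxa x samples).
#' @param min_count minimal read count for a taxon to be called present
#'   (default 1).
#' @return logical matrix of the same shape.
#' @export
presence_absence <- function(counts, min_count = 1L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  counts >= min_count
}

#' Exact hypergeometric co-occurrence p-value for one taxon pair
#'
#' Tests positive association of two taxa across `N` samples from their
#' presence/absence pattern: given marginals `mA` and `mB` (samples
#' containing each taxon) and `X` samples containing both, the one-sided
#' p-value is `P(X' >= X)` under the central hypergeometric null in which
#' taxon A's presences are placed uniformly at random among the samples.
#' `alternative = "two.sided"` doubles the smaller tail (capped at 1).
#'
#' @param X observed co-occurrence count.
#' @param mA,mB marginal presence counts, `0 <= mA, mB <= N`.
#' @param N number of samples.
#' @param alternative `"greater"` (positive association, default) or
#'   `"two.sided"`.
#' @return exact p-value in `(0, 1]`.
#' @export
#' @examples
#' pair_pvalue(2, 2, 2, 4) # 1/6
pair_pvalue <- function(X, mA, mB, N, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (mA < 0 || mB < 0 || mA > N || mB > N) stop("marginals must lie in [0, N]")
  lo <- max(0, mA + mB - N); hi <- min(mA, mB)
  if (X < lo || X > hi) stop("infeasible co-occurrence count X = ", X,
                             " (support [", lo, ", ", hi, "])")
  upper <- stats::phyper(X - 1, mA, N - mA, mB, lower.tail = FALSE)
  if (alternative == "greater") return(min(upper, 1))
  lower <- stats::phyper(X, mA, N - mA, mB)
  min(1, 2 * min(upper, lower))
}

#' Count significantly co-occurring taxon pairs in a sample set
#'
#' Taxa present in every sample (ubiquitous) carry no co-occurrence signal
#' under the hypergeometric null and are excluded from pair testing and
#' counted separately; taxa present in no sample are dropped. Every
#' remaining pair is tested with [pair_pvalue()]; p-values are
#' Benjamini-Hochberg adjusted across pairs when `bh = TRUE` (default).
#'
#' @param pa logical presence/absence matrix (taxa x samples), >= 2 samples.
#' @param alpha_level significance threshold on the (adjusted) p-value.
#' @param bh apply Benjamini-Hochberg correction across pairs.
#' @param alternative passed to [pair_pvalue()].
#' @return list of class `cooccurrence_summary` with `n_samples`,
#'   `n_taxa_tested`, `n_ubiquitous`, `n_dropped`, `n_significant_pairs` and
#'   `pair_records` (data frame: ids, X, mA, mB, p, p_adjusted,
#'   significant).
#' @export
count_significant <- function(pa, alpha_level = 0.05, bh = TRUE,
                              alternative = "greater") {
  if (!is.logical(pa)) pa <- pa > 0
  N <- ncol(pa)
  if (N < 2L) stop("need >= 2 samples")
  occ <- rowSums(pa)
  ubiquitous <- occ == N
  dropped <- occ == 0
  tested <- which(!ubiquitous & !dropped)
  n_t <- length(tested)
  records <- NULL
  n_sig <- 0L
  if (n_t >= 2L) {
    sub <- pa[tested, , drop = FALSE]
    co <- tcrossprod(sub * 1L)              # pairwise co-occurrence counts
    ij <- which(upper.tri(co), arr.ind = TRUE)
    mA <- occ[tested][ij[, 1L]]
    mB <- occ[tested][ij[, 2L]]
    X <- co[ij]
    p <- if (alternative == "greater") {
      stats::phyper(X - 1, mA, N - mA, mB, lower.tail = FALSE)
    } else {
      upper <- stats::phyper(X - 1, mA, N - mA, mB, lower.tail = FALSE)
      lower <- stats::phyper(X, mA, N - mA, mB)
      pmin(1, 2 * pmin(upper, lower))
    }
    p_adj <- if (bh) stats::p.adjust(p, method = "BH") else p
    # tolerance absorbs floating-point slop in boundary cases such as
    # p = 1/choose(6, 3) against alpha = 0.05
    sig <- p_adj <= alpha_level + 1e-12
    n_sig <- sum(sig)
    records <- data.frame(taxon_a = rownames(pa)[tested][ij[, 1L]],
                          taxon_b = rownames(pa)[tested][ij[, 2L]],
                          X = X, mA = mA, mB = mB, p = p, p_adjusted = p_adj,
                          significant = sig, stringsAsFactors = FALSE)
  }
  structure(list(n_samples = N, n_taxa_tested = n_t,
                 n_ubiquitous = sum(ubiquitous), n_dropped = sum(dropped),
                 n_significant_pairs = n_sig, pair_records = records),
            class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat(sprintf(paste0("cooccurrence_summary: %d samples, %d taxa tested, ",
                     "%d ubiquitous, %d significant pairs\n"),
              x$n_samples, x$n_taxa_tested, x$n_ubiquitous,
              x$n_significant_pairs))
  invisible(x)
}

#' Co-occurrence sweep at an equalised number of samples
#'
#' Comparing co-occurrence counts across sampling strategies is confounded
#' by the different number of samples each strategy yields; this sweep
#' controls for it by repeatedly drawing the same number of samples from
#' every condition before testing.
#'
#' @param sample_sets named list of conditions; each condition is a list of
#'   simulated sample sets as returned by [apply_plan()] (elements carrying a
#'   `counts` matrix), or a single such list element.
#' @param n_select number of samples drawn per test (must not exceed any
#'   condition's sample count).
#' @param iterations random subsets per condition (default 100).
#' @param seed master seed.
#' @param alpha_level,bh,min_count passed to [count_significant()] /
#'   [presence_absence()].
#' @return data frame with one row per (condition, iteration):
#'   `n_significant_pairs`, `n_ubiquitous`, `n_taxa_tested`.
#' @export
equalized_sweep <- function(sample_sets, n_select, iterations = 100L, seed = 1L,
                            alpha_level = 0.05, bh = TRUE, min_count = 1L) {
  rows <- list()
  for (cond in names(sample_sets)) {
    sets <- sample_sets[[cond]]
    if (!is.null(sets$counts)) sets <- list(sets)
    n_avail <- min(vapply(sets, function(s) ncol(s$counts), integer(1)))
    if (n_select > n_avail)
      stop("n_select ", n_select, " exceeds available samples (", n_avail,
           ") in condition '", cond, "'")
    for (it in seq_len(iterations)) {
      set.seed(derive_seed(seed, "equalized", cond, it))
      s <- sets[[sample(length(sets), 1L)]]
      cols <- sample(ncol(s$counts), n_select)
      pa <- presence_absence(s$counts[, cols, drop = FALSE], min_count)
      cs <- count_significant(pa, alpha_level = alpha_level, bh = bh)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, iteration = it,
        n_significant_pairs = cs$n_significant_pairs,
        n_ubiquitous = cs$n_ubiquitous,
        n_taxa_tested = cs$n_taxa_tested, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
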