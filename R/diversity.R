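#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric) so the
#' result sums exactly to `depth` and never exceeds the input elementwise.
#'
#' @param counts non-negative integer vector.
#' @param depth target number of reads, `0 <= depth <= sum(counts)`.
#' @param seed integer seed or NULL (use the current RNG stream).
#' @return integer vector of the same length and names as `counts`.
#' @export
#' @examples
#' rarefy_counts(c(a = 8000, b = 2000), 1000, seed = 1)
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (depth > total) stop("insufficient reads: depth ", depth, " > total ", total)
  set_seed_if(seed)
  out <- integer(length(counts))
  names(out) <- names(counts)
  if (depth == 0) return(out)
  if (depth == total) return(stats::setNames(as.integer(counts), names(counts)))
  idx <- sample.int(total, depth)
  out[] <- tabulate(findInterval(idx - 0.5, c(0, cumsum(counts))),
                    nbins = length(counts))
  out
}

#' Rarefy every section of a count table
#'
#' Applies [rarefy_counts()] column-wise, deriving one sub-seed per section
#' from the master seed and the section id so the draw for one section does
#' not depend on which others are present.
#'
#' @param counts count matrix (taxa x sections).
#' @param depth target depth per section.
#' @param seed master seed or NULL.
#' @param iteration integer folded into the per-section sub-seeds so that
#'   replicate rarefactions differ.
#' @return integer matrix of the same shape.
#' @export
rarefy_table <- function(counts, depth, seed = NULL, iteration = 1L) {
  counts <- validate_count_table(counts)
  out <- counts
  for (s in colnames(counts)) {
    sub <- if (is.null(seed)) NULL else derive_seed(seed, "rarefy", s, iteration)
    out[, s] <- rarefy_counts(counts[, s], depth, seed = sub)
  }
  out
}

#' Alpha diversity metrics of one sample
#'
#' Observed richness, Shannon entropy (nats), Gini-Simpson index
#' (`1 - sum p_i^2`) and Pielou evenness (`H / log(richness)`, defined as 0
#' for a single-taxon sample).
#'
#' @param counts non-negative count (or abundance) vector with at least one
#'   positive entry.
#' @return one-row data frame with `richness`, `shannon`, `simpson`,
#'   `pielou`.
#' @export
#' @examples
#' alpha_metrics(c(2, 1, 1, 0))
alpha_metrics <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  rich <- length(p)
  h <- -sum(p * log(p))
  data.frame(richness = rich,
             shannon = h,
             simpson = 1 - sum(p^2),
             pielou = if (rich > 1) h / log(rich) else 0)
}

#' Alpha diversity of every section of a count table
#'
#' @param counts count matrix (taxa x sections).
#' @return data frame with one row per section (`section_id` plus the
#'   columns of [alpha_metrics()]).
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_count_table(counts)
  recs <- lapply(colnames(counts), function(s)
    cbind(data.frame(section_id = s, stringsAsFactors = FALSE),
          alpha_metrics(counts[, s])))
  do.call(rbind, recs)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`; 0 iff the vectors are
#' identical, 1 for disjoint supports.
#'
#' @param x,y non-negative vectors of equal length, each with at least one
#'   positive entry.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("negative entries")
  if (sum(x) == 0 || sum(y) == 0) stop("empty sample")
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Pairwise Bray-Curtis dissimilarities among sections
#'
#' Computed on per-section relative abundances (so unequal depths do not
#' masquerade as composition differences) via [vegan::vegdist()].
#'
#' @param counts count matrix (taxa x sections); all column sums must be
#'   positive.
#' @param normalize divide each column by its sum first (default TRUE).
#' @return a `dist` object over sections.
#' @export
bray_curtis_matrix <- function(counts, normalize = TRUE) {
  counts <- validate_count_table(counts)
  if (any(colSums(counts) == 0)) stop("empty section(s)")
  m <- t(counts)
  if (normalize) m <- m / rowSums(m)
  vegan::vegdist(m, method = "bray")
}

#' Distance-decay table of community dissimilarity
#'
#' Lists every unordered pair of sections with its axial distance (absolute
#' difference of `position_cm`; two sides at the same axial position are at
#' distance 0) and Bray-Curtis dissimilarity, optionally restricted to a
#' taxon subset. With `renormalize = TRUE` (default) subset counts are
#' re-normalised before computing the dissimilarity; pairs in which a member
#' has no reads left after subsetting are dropped with a warning.
#'
#' @param counts count matrix (taxa x sections).
#' @param meta section metadata (positions, sides).
#' @param subset_taxa optional character vector of taxon ids.
#' @param renormalize re-normalise subset abundances (default TRUE); FALSE
#'   compares raw subset counts.
#' @return data frame with `section_a`, `section_b`, `distance_cm`,
#'   `dissimilarity`, `same_side`.
#' @export
distance_decay <- function(counts, meta, subset_taxa = NULL, renormalize = TRUE) {
  counts <- validate_count_table(counts)
  meta <- validate_section_metadata(meta, counts)
  secs <- intersect(colnames(counts), meta$section_id)
  if (length(secs) < 2L) stop("need >= 2 sections with metadata")
  meta <- meta[match(secs, meta$section_id), ]
  sub <- counts[, secs, drop = FALSE]
  if (!is.null(subset_taxa)) {
    unknown <- setdiff(subset_taxa, rownames(counts))
    if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
    sub <- sub[subset_taxa, , drop = FALSE]
  }
  tot <- colSums(sub)
  keep <- tot > 0
  if (any(!keep)) {
    warning("dropping sections with no reads in subset: ",
            paste(secs[!keep], collapse = ", "))
    sub <- sub[, keep, drop = FALSE]
    meta <- meta[keep, ]
    secs <- secs[keep]
    if (length(secs) < 2L) stop("fewer than 2 sections left after subsetting")
  }
  m <- t(sub)
  if (renormalize) m <- m / rowSums(m)
  bc <- as.matrix(vegan::vegdist(m, method = "bray"))
  ij <- which(upper.tri(bc), arr.ind = TRUE)
  data.frame(section_a = secs[ij[, 1L]],
             section_b = secs[ij[, 2L]],
             distance_cm = abs(meta$position_cm[ij[, 1L]] - meta$position_cm[ij[, 2L]]),
             dissimilarity = bc[ij],
             same_side = meta$side[ij[, 1L]] == meta$side[ij[, 2L]],
             stringsAsFactors = FALSE)
}

#' Core/satellite partition from abundance-occupancy ranking
#'
#' Taxa are ranked by the mean of their occupancy rank and their mean
#' relative abundance rank (both descending). Taxa are then added to the
#' candidate core in rank order; after each addition the contribution of the
#' cumulative core set to the community's Bray-Curtis structure is computed
#' as `1 - mean_s BC(core-only profile of section s, full profile of s)`
#' (which reduces to `mean_s 2*c_s/(1 + c_s)` where `c_s` is the core's
#' summed relative abundance in section s). The elbow is the last rank whose
#' addition improves this contribution by at least `elbow_threshold`
#' (relative increase, default 2%); taxa up to the elbow are the core, the
#' rest are satellites. Ties in the ranking are broken by taxon id.
#'
#' @param counts count matrix (taxa x sections), >= 2 sections.
#' @param elbow_threshold minimal relative gain in explained similarity for
#'   a taxon to extend the core (default 0.02).
#' @return list of class `core_partition`: `core_taxa`, `satellite_taxa`,
#'   `rank_scores` (data frame in rank order with occupancy, mean relative
#'   abundance and cumulative contribution) and `elbow_index`.
#' @export
core_satellite_partition <- function(counts, elbow_threshold = 0.02) {
  counts <- validate_count_table(counts)
  if (ncol(counts) < 2L) stop("occupancy undefined with a single section")
  if (any(colSums(counts) == 0)) stop("empty section(s)")
  rel <- sweep(counts, 2L, colSums(counts), "/")
  occupancy <- rowMeans(counts > 0)
  mean_rel <- rowMeans(rel)
  # descending ranks; average ties, then break remaining ties by taxon id
  score <- (rank(-occupancy, ties.method = "average") +
            rank(-mean_rel, ties.method = "average")) / 2
  ord <- order(score, rownames(counts))
  rel_ord <- rel[ord, , drop = FALSE]
  cum_share <- apply(rel_ord, 2L, cumsum)            # ranks x sections
  contribution <- rowMeans(2 * cum_share / (1 + cum_share))
  gain <- c(Inf, diff(contribution) / pmax(contribution[-length(contribution)], .Machine$double.eps))
  qualifying <- which(gain >= elbow_threshold)
  elbow <- max(qualifying)   # rank 1 always qualifies
  taxa_ord <- rownames(counts)[ord]
  structure(list(
    core_taxa = taxa_ord[seq_len(elbow)],
    satellite_taxa = taxa_ord[-seq_len(elbow)],
    rank_scores = data.frame(taxon_id = taxa_ord,
                             occupancy = occupancy[ord],
                             mean_rel_abundance = mean_rel[ord],
                             contribution = contribution,
                             stringsAsFactors = FALSE),
    elbow_index = elbow), class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("core_partition: %d core / %d satellite taxa (elbow at rank %d)\n",
              length(x$core_taxa), length(x$satellite_taxa), x$elbow_index))
  invisible(x)
}
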