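#' Expected number of cells in a planar biofilm neighbourhood
#'
#' Converts an areal cell density to the expected number of cells within a
#' small planar patch. One cm^2 equals 1e8 um^2.
#'
#' @param density areal cell density, cells/cm^2.
#' @param area_um2 patch area, um^2.
#' @return expected number of cells (may be fractional).
#' @export
#' @examples
#' cells_in_area(1e7, 10)  # 1 cell in 10 um^2
cells_in_area <- function(density, area_um2) {
  if (any(density <= 0)) stop("density must be > 0")
  if (any(area_um2 <= 0)) stop("area must be > 0")
  density * area_um2 / 1e8
}

#' Expected number of cells in a spherical biofilm neighbourhood
#'
#' Cells are assumed uniformly distributed through the biofilm thickness, so
#' the volumetric density is `density / (1e8 * thickness_um)` cells/um^3.
#' The neighbourhood is a sphere of radius `radius_um` centred mid-thickness;
#' with `clip = TRUE` (default) the sphere is intersected with the biofilm
#' slab, giving volume `2*pi*(r^2*a - a^3/3)` with
#' `a = min(r, thickness_um/2)`; with `clip = FALSE` the full sphere
#' `4/3*pi*r^3` is used regardless of thickness.
#'
#' Because the density is a section-level average that ignores microcolony
#' clustering, the result is a theoretical expectation for a randomly placed
#' focal cell; the focal cell itself is not counted.
#'
#' @param density areal cell density, cells/cm^2.
#' @param thickness_um biofilm thickness, um.
#' @param radius_um neighbourhood radius, um.
#' @param clip clip the sphere to the biofilm slab (default TRUE).
#' @return expected number of cells.
#' @export
#' @examples
#' cells_in_volume(1e7, thickness_um = 100, radius_um = 5)
cells_in_volume <- function(density, thickness_um, radius_um, clip = TRUE) {
  if (any(density <= 0) || any(thickness_um <= 0) || any(radius_um <= 0))
    stop("density, thickness and radius must be > 0")
  rho <- density / (1e8 * thickness_um)           # cells per um^3
  a <- if (clip) pmin(radius_um, thickness_um / 2) else radius_um
  vol <- 2 * pi * (radius_um^2 * a - a^3 / 3)
  rho * vol
}

#' Heaps'-law expected richness of a local neighbourhood
#'
#' Expected number of distinct taxa among `n` cells drawn at random from a
#' community with relative abundances `p`:
#' `E[R_m(n)] = m - sum_i (1 - p_i)^n`, where `m` is the number of taxa with
#' positive abundance. `n` may be fractional (the expected cell count of a
#' small neighbourhood usually is); the expression is evaluated at real `n`
#' via `exp(n * log(1 - p))`, which smoothly interpolates the integer-`n`
#' expectation.
#'
#' @param p vector of relative abundances (non-negative, summing to 1 within
#'   1e-6; zero entries are ignored).
#' @param n expected number of cells in the neighbourhood, >= 0.
#' @return expected richness, in `[0, m]`.
#' @export
#' @examples
#' heaps_expected_richness(c(0.5, 0.3, 0.2), 5)
heaps_expected_richness <- function(p, n) {
  if (any(p < 0)) stop("negative abundance")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  if (length(n) != 1L || n < 0) stop("n must be a single value >= 0")
  p <- p[p > 0]
  m <- length(p)
  if (n == 0) return(0)
  m - sum(exp(n * log1p(-p[p < 1])))
}

#' Monte-Carlo estimate of neighbourhood richness
#'
#' Brute-force companion to [heaps_expected_richness()]: draws `reps`
#' independent multinomial samples of `n` cells from `p` and reports the mean
#' and s.d. of the number of distinct taxa drawn.
#'
#' @param p relative abundance vector.
#' @param n integer number of cells per draw, >= 1.
#' @param reps number of replicate draws, >= 1.
#' @param seed integer seed or NULL.
#' @return list with `mean`, `sd` and `se` of the distinct-taxon count.
#' @export
mc_neighborhood_richness <- function(p, n, reps = 10000L, seed = NULL) {
  if (any(p < 0)) stop("negative abundance")
  if (n < 1 || reps < 1) stop("n and reps must be >= 1")
  set_seed_if(seed)
  draws <- stats::rmultinom(reps, round(n), p)
  distinct <- colSums(draws > 0)
  list(mean = mean(distinct), sd = stats::sd(distinct),
       se = stats::sd(distinct) / sqrt(reps))
}

#' Per-section neighbourhood richness profile
#'
#' For every section with physical measurements, computes the expected cell
#' count of each requested neighbourhood (planar patches by area, spherical
#' neighbourhoods by radius) from that section's areal cell density and
#' thickness, and the expected taxonomic richness of that neighbourhood from
#' the section's relative abundances via [heaps_expected_richness()].
#'
#' Sections without a physical record are skipped with a warning.
#'
#' @param counts count matrix (taxa x sections).
#' @param physical data frame as from [read_section_physical()].
#' @param areas_um2 numeric vector of planar areas, um^2 (may be empty).
#' @param radii_um numeric vector of spherical radii, um (may be empty).
#' @param clip clip spheres to the biofilm slab (see [cells_in_volume()]).
#' @return data frame with one row per (section, query): `section_id`,
#'   `query` (e.g. `"area_10"`, `"radius_5"`), `kind`, `size`,
#'   `expected_cells`, `expected_richness`, `section_richness`.
#' @export
neighborhood_richness_profile <- function(counts, physical,
                                          areas_um2 = c(10, 1e6),
                                          radii_um = c(5, 20),
                                          clip = TRUE) {
  counts <- validate_count_table(counts)
  if (length(areas_um2) == 0 && length(radii_um) == 0)
    stop("no neighbourhood queries given")
  secs <- colnames(counts)
  missing_phys <- setdiff(secs, physical$section_id)
  if (length(missing_phys)) {
    warning("skipping sections without physical data: ",
            paste(missing_phys, collapse = ", "))
    secs <- setdiff(secs, missing_phys)
  }
  rows <- list()
  for (s in secs) {
    ph <- physical[physical$section_id == s, ][1L, ]
    p <- relative_abundances(counts, s)
    m <- sum(p > 0)
    for (a in areas_um2) {
      n <- cells_in_area(ph$cell_density_areal, a)
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = s, query = paste0("area_", format(a, scientific = FALSE)),
        kind = "area", size = a, expected_cells = n,
        expected_richness = heaps_expected_richness(p, n),
        section_richness = m, stringsAsFactors = FALSE)
    }
    for (r in radii_um) {
      n <- cells_in_volume(ph$cell_density_areal, ph$thickness_um, r, clip)
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = s, query = paste0("radius_", format(r, scientific = FALSE)),
        kind = "volume", size = r, expected_cells = n,
        expected_richness = heaps_expected_richness(p, n),
        section_richness = m, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
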