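#' Spatially indexed taxa-by-section count tables
#'
#' The central data structure of the package is an integer matrix of read
#' counts with taxa as rows and biofilm sections as columns, accompanied by a
#' section metadata table giving each section's 1-D position along the
#' environment, its side, its length and its surface area. Counts are plain
#' base matrices with dimnames; metadata are plain data frames, so all the
#' usual subsetting idioms apply.
#'
#' @name count-table
NULL

#' Validate a taxa-by-section count matrix
#'
#' Checks the invariants every downstream function relies on: a non-empty
#' integer-valued matrix, non-negative counts, and unique non-missing row
#' (taxon) and column (section) names.
#'
#' @param counts matrix of read counts, taxa x sections.
#' @return the validated matrix (in integer storage mode), invisibly usable.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table must be a matrix with at least 1 taxon and 1 section")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have taxon rownames and section colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate section ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts))) stop("count table contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at taxon '%s', section '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at taxon '%s', section '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a taxa-by-section count table from TSV
#'
#' Expects a UTF-8 tab-delimited file with taxa as rows and sections as
#' columns: the first column holds taxon ids and the header row holds section
#' ids. All cells must be non-negative integers.
#'
#' @param path path to the TSV file.
#' @return validated integer matrix, taxa x sections.
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("count table needs a taxon id column plus at least one section column")
  taxa <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat), dimnames = dimnames(mat)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at taxon '%s', section '%s'",
                 taxa[bad[1L]], colnames(mat)[bad[2L]]))
  }
  rownames(num) <- taxa
  validate_count_table(num)
}

#' Write a count table as TSV
#'
#' Writes the taxa-rows-by-section-columns orientation used by
#' [read_count_table()]; the taxon id column is named `taxon_id`.
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate section metadata
#'
#' Section metadata carry the spatial index of the count table: the centre
#' position of each section along the environment (cm, 0 at the upstream
#' end), its side (`side1`, `side2` or `merged`), its length (cm) and its
#' biofilm surface area (cm^2). Sections missing from the metadata are simply
#' absent; downstream distance computations use the recorded positions and
#' never assume contiguity.
#'
#' @param meta data frame with columns `section_id`, `position_cm`, `side`,
#'   `length_cm`, `area_cm2` and optionally `environment`.
#' @param counts optional companion count matrix; when given, every metadata
#'   section must exist in the matrix.
#' @return the validated data frame.
#' @export
validate_section_metadata <- function(meta, counts = NULL) {
  need <- c("section_id", "position_cm", "side", "length_cm", "area_cm2")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$section_id)) stop("duplicate section ids in metadata")
  if (any(meta$position_cm < 0)) stop("position_cm must be >= 0")
  if (any(meta$length_cm <= 0)) stop("length_cm must be > 0")
  if (any(meta$area_cm2 <= 0)) stop("area_cm2 must be > 0")
  if (!all(meta$side %in% c("side1", "side2", "merged")))
    stop("side must be one of side1, side2, merged")
  if (!is.null(counts)) {
    unknown <- setdiff(meta$section_id, colnames(counts))
    if (length(unknown)) stop("metadata sections absent from count table: ",
                              paste(unknown, collapse = ", "))
  }
  meta
}

#' Read or write section metadata / physical measurements TSVs
#'
#' Metadata files are tab-delimited with a header naming the columns
#' documented in [validate_section_metadata()]. Physical measurement files
#' carry `section_id`, `cell_density_areal` (cells/cm^2) and `thickness_um`
#' (micrometres).
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_section_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  validate_section_metadata(meta)
}

#' @rdname read_section_metadata
#' @param meta metadata data frame.
#' @export
write_section_metadata <- function(meta, path) {
  validate_section_metadata(meta)
  write_tsv_fixed(meta, path)
}

#' @rdname read_section_metadata
#' @export
read_section_physical <- function(path) {
  phys <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("section_id", "cell_density_areal", "thickness_um")
  miss <- setdiff(need, names(phys))
  if (length(miss)) stop("physical table missing columns: ", paste(miss, collapse = ", "))
  if (any(phys$cell_density_areal <= 0)) stop("cell_density_areal must be > 0")
  if (any(phys$thickness_um <= 0)) stop("thickness_um must be > 0")
  phys
}

#' @rdname read_section_metadata
#' @param phys physical measurements data frame.
#' @export
write_section_physical <- function(phys, path) {
  write_tsv_fixed(phys, path)
}

#' Default biofilm area of a bisected pipe section
#'
#' For a cylindrical pipe bisected lengthwise, each half-section exposes a
#' biofilm strip of area `length_cm * pi * inner_diameter_cm / 2`.
#'
#' @param length_cm section length, cm.
#' @param inner_diameter_cm pipe inner diameter, cm (default 0.8).
#' @param bisected logical; `FALSE` returns the full circumference area.
#' @return area in cm^2.
#' @export
#' @examples
#' section_area(1.2) # one half of a 1.2 cm section of 0.8 cm pipe
section_area <- function(length_cm, inner_diameter_cm = 0.8, bisected = TRUE) {
  stopifnot(length_cm > 0, inner_diameter_cm > 0)
  full <- length_cm * pi * inner_diameter_cm
  if (bisected) full / 2 else full
}

#' Relative abundances of one section
#'
#' Converts one section's counts into the probability vector used by the
#' neighbourhood richness expectation: each taxon's share of the section's
#' reads.
#'
#' @param counts count matrix (taxa x sections).
#' @param section section id (column name).
#' @return named numeric vector summing to 1; zero-count taxa have p = 0.
#' @export
relative_abundances <- function(counts, section) {
  counts <- validate_count_table(counts)
  if (!section %in% colnames(counts)) stop("unknown section: ", section)
  x <- counts[, section]
  tot <- sum(x)
  if (tot == 0) stop("empty section: ", section)
  x / tot
}

#' Merge sections of a count table by group
#'
#' Sums counts elementwise over disjoint groups of sections, e.g. to combine
#' the two halves of a bisected pipe section or to pool adjacent sections
#' into a larger simulated sample. Total reads over the grouped sections are
#' conserved.
#'
#' @param counts count matrix (taxa x sections).
#' @param groups named list of character vectors of section ids; names become
#'   the merged section ids (unnamed lists get `grp1`, `grp2`, ...).
#' @return count matrix with one column per group, same taxa.
#' @export
merge_counts <- function(counts, groups) {
  counts <- validate_count_table(counts)
  if (!length(groups)) stop("no groups given")
  all_ids <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(all_ids, colnames(counts))
  if (length(unknown)) stop("unknown section ids: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(all_ids)) stop("overlapping groups: section(s) ",
                                   paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (any(lengths(groups) == 0L)) stop("empty group")
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("grp", seq_along(groups))
  out <- vapply(groups, function(g) {
    as.integer(rowSums(counts[, g, drop = FALSE]))
  }, integer(nrow(counts)))
  dimnames(out) <- list(rownames(counts), nm)
  out
}
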