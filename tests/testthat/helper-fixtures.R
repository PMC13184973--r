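# shared fixtures built in code

# small valid count table with taxa rows / section columns
tiny_table <- function() {
  m <- matrix(c(3L, 0L, 1L, 2L), nrow = 2, byrow = TRUE,
              dimnames = list(c("tA", "tB"), c("s1", "s2")))
  m
}

random_table <- function(n_taxa = 8, n_sections = 5, lambda = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_sections, lambda), n_taxa, n_sections,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_sections))))
  storage.mode(m) <- "integer"
  m
}

# metadata for a single-sided run of n sections of 1.2 cm
linear_metadata <- function(section_ids, length_cm = 1.2) {
  n <- length(section_ids)
  data.frame(section_id = section_ids,
             position_cm = (seq_len(n) - 0.5) * length_cm,
             side = "merged", length_cm = length_cm,
             area_cm2 = section_area(length_cm, bisected = FALSE),
             environment = "test", stringsAsFactors = FALSE)
}

# a small, fast synthetic community used across tests
small_sim <- function(seed = 42, ...) {
  generate_biofilm(synthetic_config(n_taxa = 120, n_sections = 40, n_sides = 2,
                                    depth = 2000, seed = seed, ...))
}
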