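# Shared fixtures: all built in code, no files on disk.

# minimal 3-locus loci set (cycle order == report order)
toy_loci <- function() {
  loci_set(
    name = c("L1", "L2", "L3"),
    rsid = c("rs1", "rs2", "rs3"),
    major = c("A", "C", "G"),
    minor = c("G", "T", "A"),
    cycle_position = 0:2,
    report_position = 0:2
  )
}

# one-row genotype tibble from per-locus allele pairs (cycle order)
make_record <- function(loci, pairs, sample_id = "S1", cohort = "case",
                        survival_days = NA_real_, event = NA_integer_) {
  stopifnot(length(pairs) == nrow(loci))
  row <- tibble::tibble(sample_id = sample_id, cohort = cohort,
                        survival_days = survival_days, event = event)
  for (i in seq_len(nrow(loci))) row[[loci$name[i]]] <- pairs[i]
  validate_genotypes(row, loci)
}

# cohort of homozygous carriers of given haplotypes (report-order strings)
hom_cohort <- function(loci, haplotypes, counts, cohort = "control") {
  pairs <- purrr::map(rep(haplotypes, counts), ~ c(.x, .x))
  diplotypes_to_genotypes(pairs, loci,
                          ids = paste0("H", seq_along(pairs)), cohort = cohort)
}

# genotype "X/X" strings for a homozygous carrier of a state vector,
# in cycle order; states "a"/"b" map to major/minor
hom_pairs_for_states <- function(loci, states) {
  al <- ifelse(states == "a", loci$major, loci$minor)
  paste(al, al, sep = "/")
}

# study graph assembled from explicit two-state state-vector cycles
graph_from_states <- function(loci, state_rows, counts,
                              coding = "two_state") {
  recs <- purrr::imap(rep(seq_along(state_rows), counts), function(ridx, i) {
    make_record(loci, hom_pairs_for_states(loci, state_rows[[ridx]]),
                sample_id = paste0("G", i))
  })
  tab <- dplyr::bind_rows(recs)
  build_study_graph(personal_cycles(tab, loci, coding))
}

expect_balanced <- function(graph, tol = 1e-9) {
  bal <- snpcycle:::vertex_balance(graph)
  expect_lt(max(abs(bal)), tol + 1e-12)
}
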