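test_that("edge-mismatch distance reproduces hand-counted examples", {
  loci <- ctla4_loci()
  a6 <- stats::setNames(rep("a", 6), loci$name)
  expect_equal(cycle_distance(a6, a6), 0)

  # AACCAT vs GGCTGG: the two cycles share no vertex, so all 6 slots differ
  h1 <- snpcycle:::haplotype_to_states("AACCAT", loci)
  h2 <- snpcycle:::haplotype_to_states("GGCTGG", loci)
  expect_equal(cycle_distance(h1, h2), 6)

  # AACCAT vs AGCCAT differ only at CT60: both edges incident to CT60 mismatch
  h5 <- snpcycle:::haplotype_to_states("AGCCAT", loci)
  expect_equal(cycle_distance(h1, h5), 2)

  expect_error(cycle_distance(rep("a", 6), rep("a", 3)), "different numbers")
  expect_error(cycle_distance(rep("a", 6), c(rep("ab", 5), "b")), "two-state")
})

test_that("the distance is a metric on the full two-state cycle space", {
  loci <- ctla4_loci()
  g <- graph_from_states(loci, list(rep("a", 6)), 1)
  cand <- enumerate_cycles(g)  # all 64 two-state cycles
  n <- nrow(cand)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- cycle_distance(cand[i, ], cand[j, ])
  }
  expect_true(all(D >= 0 & D <= 6))
  expect_equal(diag(D), rep(0L, n))
  expect_true(all((D == 0) == diag(TRUE, n)))     # identity of indiscernibles
  expect_identical(D, t(D))                       # symmetry
  for (k in seq_len(n)) {                         # triangle inequality
    expect_true(all(D <= outer(D[, k], D[k, ], `+`)))
  }
  # complement: L minus the number of shared edge slots
  for (i in c(1, 17, 64)) for (j in c(2, 33)) {
    p <- cand[i, ]; r <- cand[j, ]
    nxt <- c(2:6, 1)
    shared <- sum((p == r) & (p[nxt] == r[nxt]))
    expect_equal(D[i, j], 6 - shared)
  }
})

test_that("distance vectors have one column per reference rank", {
  loci <- ctla4_loci()
  tab <- simulate_cohorts(loci, n_case = 30, n_control = 30, seed = 2)
  cyc <- personal_cycles(tab, loci, "two_state")
  refs8 <- as_reference_set(
    apply(enumerate_cycles(graph_from_states(loci, list(rep("a", 6)), 1))[1:8, ],
          1, paste, collapse = "-"),
    loci = loci)
  dv <- distance_vectors(cyc, refs8)
  expect_equal(sum(grepl("^d[0-9]+$", names(dv))), 8)
  expect_true(all(as.matrix(dv[, paste0("d", 1:8)]) %in% 0:6))

  # subject identical to a reference scores 0 there
  first_ref <- refs8$cycle[[1]]
  hom <- make_record(loci, hom_pairs_for_states(loci, first_ref), "Z1")
  dv1 <- distance_vectors(personal_cycles(hom, loci, "two_state"), refs8)
  expect_equal(dv1$d1, 0L)

  # sign-flip presentation convention
  dvf <- distance_vectors(cyc, refs8, sign_flip = TRUE)
  expect_equal(as.matrix(dvf[, paste0("d", 1:8)]),
               -as.matrix(dv[, paste0("d", 1:8)]))

  expect_error(distance_vectors(cyc, as_reference_set("a-ab-a-a-a-a", loci = loci)),
               "does not match")
})

test_that("delta tables have K(K-1)/2 antisymmetric, bounded columns", {
  loci <- ctla4_loci()
  tab <- simulate_cohorts(loci, n_case = 40, n_control = 40, seed = 8)
  cyc <- personal_cycles(tab, loci, "three_state")
  dec <- greedy_decompose(build_study_graph(cyc))
  dv <- distance_vectors(cyc, dec)
  dd <- delta_differences(dv)
  K <- nrow(dec)
  expect_equal(length(delta_columns(dd)), K * (K - 1) / 2)
  pairs <- attr(dd, "pairs")
  for (p in sample(nrow(pairs), 5)) {
    i <- pairs$i[p]; j <- pairs$j[p]
    expect_equal(dd[[pairs$name[p]]],
                 dv[[paste0("d", i)]] - dv[[paste0("d", j)]])
    expect_true(all(abs(dd[[pairs$name[p]]]) <= 6))
  }
  # 8 references give 28 pairs; 20 give 190
  refs20 <- as_reference_set(
    apply(enumerate_cycles(build_study_graph(cyc))[1:20, ], 1,
          paste, collapse = "-"), loci = loci)
  dv20 <- distance_vectors(cyc, refs20)
  expect_equal(length(delta_columns(delta_differences(dv20))), 190)

  dv1 <- dv[, c("sample_id", "cohort", "d1")]
  attr(dv1, "ranks") <- 1L
  expect_error(delta_differences(dv1), "at least 2")
})

test_that("cohort delta means land on the diagonal iff cohorts are exchangeable", {
  loci <- ctla4_loci()
  tab <- simulate_cohorts(loci, n_case = 50, n_control = 50, seed = 13)
  cyc <- personal_cycles(tab, loci, "two_state")
  dec <- greedy_decompose(build_study_graph(cyc))
  dd <- delta_differences(distance_vectors(cyc, dec))

  # identical delta distributions in both cohorts: all points on y = x
  both <- dplyr::bind_rows(
    dplyr::mutate(dd, cohort = "case", sample_id = paste0(sample_id, "_a")),
    dplyr::mutate(dd, cohort = "control", sample_id = paste0(sample_id, "_b"))
  )
  attr(both, "pairs") <- attr(dd, "pairs")
  m <- cohort_mean_deltas(both)
  expect_equal(m$case_mean, m$control_mean)
  expect_true(all(m$diag_distance < 1e-12))

  # single-subject cohorts: means equal those subjects' deltas
  solo <- dd[1:2, ]
  solo$cohort <- c("case", "control")
  ms <- cohort_mean_deltas(solo)
  expect_equal(ms$case_mean,
               unname(unlist(solo[1, attr(dd, "pairs")$name])))

  expect_error(cohort_mean_deltas(dplyr::mutate(dd, cohort = "case")),
               "nonempty")
})

test_that("discriminating pairs respect the 0.5 band before ranking", {
  means <- structure(tibble::tibble(
    pair = c("d1-d2", "d1-d3", "d2-d3"),
    i = c(1, 1, 2), j = c(2, 3, 3),
    case_mean = c(2, 0.3, 1), control_mean = c(-2, -0.3, 1)
  ), class = c("nps_delta_means", class(tibble::tibble())))
  means$diag_distance <- abs(means$case_mean - means$control_mean) / sqrt(2)
  sel <- select_discriminating_pairs(means, min_abs = 0.5)
  # (0.3, -0.3) excluded despite being off-diagonal; on-diagonal excluded
  expect_equal(sel$pair, "d1-d2")
  expect_equal(sel$selection_rank, 1L)
  # everything on the diagonal: empty selection
  diag_means <- dplyr::mutate(means, case_mean = control_mean,
                              diag_distance = 0)
  expect_equal(nrow(select_discriminating_pairs(diag_means)), 0)
})

test_that("the absence marker finds subjects at maximal distance", {
  loci <- ctla4_loci()
  ref <- stats::setNames(rep("b", 6), loci$name)
  # carrier of the reference: excluded; vertex-disjoint subject: included
  tab <- dplyr::bind_rows(
    make_record(loci, hom_pairs_for_states(loci, ref), "carrier"),
    make_record(loci, hom_pairs_for_states(loci, rep("a", 6)), "avoider")
  )
  cyc <- personal_cycles(tab, loci, "two_state")
  res <- max_distance_subset(cyc, ref)
  expect_equal(res$sample_ids, "avoider")
  expect_equal(res$patterns$pattern, "a-a-a-a-a-a")

  # generator planted at 77%: measured fraction close among cases
  sim <- simulate_cohorts(loci, n_case = 300, n_control = 100,
                          absence_fraction = 0.77,
                          absence_reference = "GGTTGG", seed = 5)
  scyc <- personal_cycles(sim, loci, "two_state")
  frac <- max_distance_subset(scyc, "GGTTGG")$fraction_by_cohort[["case"]]
  expect_lt(abs(frac - 0.77), 0.05)
})

test_that("2D delta histograms count every subject once per cohort", {
  loci <- ctla4_loci()
  tab <- simulate_cohorts(loci, n_case = 40, n_control = 35, seed = 17)
  cyc <- personal_cycles(tab, loci, "two_state")
  dec <- greedy_decompose(build_study_graph(cyc))
  dd <- delta_differences(distance_vectors(cyc, dec))
  cols <- delta_columns(dd)
  h <- delta_histogram(dd, cols[1], cols[2])
  sums <- tapply(h$n, h$cohort, sum)
  expect_equal(unname(sums[["case"]]), 40)
  expect_equal(unname(sums[["control"]]), 35)
  expect_error(delta_histogram(dd, "d98-d99", cols[1]), "unknown")

  # degenerate: single shared cell
  dd0 <- dd
  for (cl in cols) dd0[[cl]] <- 0L
  h0 <- delta_histogram(dd0, cols[1], cols[2])
  expect_equal(nrow(h0), 2)
  expect_true(all(h0$dx == 0 & h0$dy == 0))
})

test_that("delta results are invariant to subject order and id relabeling", {
  loci <- ctla4_loci()
  tab <- simulate_cohorts(loci, n_case = 30, n_control = 30, seed = 23)
  cyc <- personal_cycles(tab, loci, "two_state")
  dec <- greedy_decompose(build_study_graph(cyc))
  dd1 <- delta_differences(distance_vectors(cyc, dec))
  m1 <- cohort_mean_deltas(dd1)

  perm <- withr::with_seed(1, sample(nrow(tab)))
  tab2 <- tab[perm, ]
  tab2$sample_id <- paste0("renamed_", seq_len(nrow(tab2)))
  cyc2 <- personal_cycles(tab2, loci, "two_state")
  dd2 <- delta_differences(distance_vectors(cyc2, dec))
  m2 <- cohort_mean_deltas(dd2)
  expect_equal(m1, m2)
})
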