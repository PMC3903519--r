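test_that("personal cycles follow the coding rules", {
  loci <- ctla4_loci()
  # all-homozygous-major subject: all-a cycle in either coding
  hom_major <- make_record(loci, hom_pairs_for_states(loci, rep("a", 6)))
  for (coding in c("two_state", "three_state")) {
    pc <- build_personal_cycle(hom_major, loci, coding)
    expect_equal(unname(pc$states), rep("a", 6))
    expect_equal(nrow(pc$edges), 6)
    expect_equal(pc$edges$to_locus[6], pc$edges$from_locus[1])  # closed
  }

  # homozygous carrier of the G G C T G G haplotype: minor everywhere
  # except CT318 (whose major is C)
  hap2 <- make_record(
    ctla4_loci(),
    hom_pairs_for_states(loci, c(CT318 = "a", AG49 = "b", CT60 = "b",
                                 JO30 = "b", JO27 = "b", JO31 = "b")),
    "S2")
  pc <- build_personal_cycle(hap2, loci, "two_state")
  expect_equal(pc$states,
               c(CT318 = "a", AG49 = "b", CT60 = "b",
                 JO30 = "b", JO27 = "b", JO31 = "b"))

  # heterozygous at all six loci: all ab in three-state, all b in two-state
  het <- make_record(loci, paste(loci$major, loci$minor, sep = "/"), "S3")
  expect_equal(unname(build_personal_cycle(het, loci, "three_state")$states),
               rep("ab", 6))
  expect_equal(unname(build_personal_cycle(het, loci, "two_state")$states),
               rep("b", 6))
})

test_that("study graph accumulates +1 per subject per edge", {
  loci <- toy_loci()
  # N copies of one cycle
  g1 <- graph_from_states(loci, list(c("a", "b", "a")), 7)
  td <- tidy(g1)
  expect_equal(sum(td$weight), 3 * 7)
  expect_equal(td$weight[td$from_state == "a" & td$to_state == "b" &
                           td$slot == 1], 7)

  # one all-a + one all-b cycle: per-pair sums = 2
  g2 <- graph_from_states(loci, list(rep("a", 3), rep("b", 3)), c(1, 1))
  expect_true(all(vapply(g2$weights, sum, 0) == 2))
  expect_true(all(vapply(g2$weights, function(w) w["a", "a"], 0) == 1))

  # 60 all-a + 40 all-b
  g3 <- graph_from_states(loci, list(rep("a", 3), rep("b", 3)), c(60, 40))
  for (w in g3$weights) {
    expect_equal(w["a", "a"], 60)
    expect_equal(w["b", "b"], 40)
    expect_equal(w["a", "b"] + w["b", "a"], 0)
  }
  expect_error(build_study_graph(personal_cycles(
    tibble::tibble(sample_id = character(), cohort = character(),
                   L1 = character(), L2 = character(), L3 = character()),
    loci, "two_state")), "zero cycles")
})

test_that("per-pair conservation, vertex balance and additivity hold on random cohorts", {
  loci <- ctla4_loci()
  for (seed in 1:5) {
    tab <- simulate_cohorts(loci, n_case = 40, n_control = 40, seed = seed)
    for (coding in c("two_state", "three_state")) {
      cyc <- personal_cycles(tab, loci, coding)
      g <- build_study_graph(cyc)
      expect_true(all(vapply(g$weights, sum, 0) == g$n_subjects))
      expect_balanced(g)
      # additivity over a cohort split
      ga <- build_study_graph(cyc[tab$cohort == "case", ])
      gb <- build_study_graph(cyc[tab$cohort == "control", ])
      gsum <- ga + gb
      expect_equal(gsum$weights, g$weights)
      expect_equal(gsum$n_subjects, g$n_subjects)
    }
  }
})

test_that("dosage graph deposits allele-dose products, 2 per subject per pair", {
  loci <- toy_loci()
  # homozygous major at both loci of every pair: everything on (a,a)
  hom <- make_record(loci, c("A/A", "C/C", "G/G"))
  gd <- build_dosage_graph(hom, loci)
  expect_true(all(vapply(gd$weights, function(w) w["a", "a"], 0) == 2))

  # heterozygous at both loci of a pair: 0.5 on each of the four edges
  het <- make_record(loci, c("A/G", "C/T", "G/A"))
  gd2 <- build_dosage_graph(het, loci)
  for (w in gd2$weights) expect_true(all(w == 0.5))

  # homozygous-diplotype cohort: dosage = 2 x subject-level graph exactly
  chx <- hom_cohort(ctla4_loci(), c("AACCAT", "GGCTGG", "AGTTGG"),
                    c(11, 6, 3))
  gdh <- build_dosage_graph(chx, ctla4_loci())
  gsh <- build_study_graph(personal_cycles(chx, ctla4_loci(), "two_state"))
  expect_equal(gdh$weights, lapply(gsh$weights, `*`, 2))
})

test_that("edge weights expose conditional probabilities and marginals", {
  loci <- toy_loci()
  # N identical all-a cycles
  g1 <- graph_from_states(loci, list(rep("a", 3)), 9)
  p <- edge_conditional_probabilities(g1, 1)
  expect_equal(p$conditional[p$from_state == "a" & p$to_state == "a"], 1)
  expect_equal(p$marginal[p$from_state == "a"][1], 1)

  # perfect LD: 60 all-a + 40 all-b
  g2 <- graph_from_states(loci, list(rep("a", 3), rep("b", 3)), c(60, 40))
  p2 <- edge_conditional_probabilities(g2, 1)
  expect_equal(p2$conditional[p2$from_state == "b" & p2$to_state == "b"], 1)
  expect_equal(p2$marginal[p2$from_state == "b"][1], 0.4)

  # shared first vertex, split second: P(b|a) = 0.5
  g3 <- graph_from_states(loci, list(c("a", "a", "a"), c("a", "b", "b")),
                          c(1, 1))
  p3 <- edge_conditional_probabilities(g3, 1)
  expect_equal(p3$conditional[p3$from_state == "a" & p3$to_state == "b"], 0.5)
  # rows with positive marginal sum to 1
  sums <- tapply(p3$conditional, p3$from_state, sum)
  expect_equal(unname(sums[["a"]]), 1)

  g_zero <- g3
  g_zero$weights[[1]][] <- 0
  expect_error(edge_conditional_probabilities(g_zero, 1), "zero-weight")
})

test_that("study graphs serialize to JSON bit-exactly in subject mode", {
  loci <- ctla4_loci()
  tab <- simulate_cohorts(loci, n_case = 25, n_control = 25, seed = 3)
  g <- build_study_graph(personal_cycles(tab, loci, "three_state"))
  path <- withr::local_tempfile(fileext = ".json")
  write_study_graph(g, path)
  back <- read_study_graph(path)
  expect_identical(back$weights, g$weights)
  expect_equal(back$n_subjects, g$n_subjects)
  expect_equal(tibble::as_tibble(back$loci), tibble::as_tibble(g$loci))
})
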