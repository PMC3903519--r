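# exhaustive extraction-order search minimizing the number of components;
# independent oracle for small graphs (used only at tiny sizes)
oracle_min_components <- function(graph, cap = 20000L) {
  candidates <- enumerate_cycles(graph)
  states <- graph$states
  L <- length(graph$weights)
  nxt <- c(2:L, 1L)
  idx_mat <- matrix(match(candidates, states), nrow = nrow(candidates))
  best <- Inf
  nodes <- 0L
  rec <- function(w, depth) {
    if (all(unlist(w) == 0)) { best <<- min(best, depth); return() }
    if (depth + 1 >= best) return()
    nodes <<- nodes + 1L
    if (nodes > cap) stop("oracle cap exceeded")
    bn <- rep(Inf, nrow(candidates))
    for (k in seq_len(L)) {
      bn <- pmin(bn, w[[k]][cbind(idx_mat[, k], idx_mat[, nxt[k]])])
    }
    for (cand in which(bn > 0)) {
      w2 <- w
      for (k in seq_len(L)) {
        i <- idx_mat[cand, k]; j <- idx_mat[cand, nxt[k]]
        w2[[k]][i, j] <- w2[[k]][i, j] - bn[cand]
      }
      rec(w2, depth + 1L)
    }
  }
  rec(graph$weights, 0L)
  best
}

test_that("candidate enumeration covers the full cycle space in fixed order", {
  loci6 <- ctla4_loci()
  g2 <- graph_from_states(loci6, list(rep("a", 6)), 1)
  cand2 <- enumerate_cycles(g2)
  expect_equal(nrow(cand2), 64)
  expect_equal(unname(cand2[1, ]), rep("a", 6))
  expect_equal(unname(cand2[64, ]), rep("b", 6))
  expect_false(anyDuplicated(apply(cand2, 1, paste, collapse = "")) > 0)

  g3 <- build_study_graph(personal_cycles(
    make_record(loci6, hom_pairs_for_states(loci6, rep("a", 6))),
    loci6, "three_state"))
  expect_equal(nrow(enumerate_cycles(g3)), 729)

  toy <- graph_from_states(toy_loci(), list(rep("a", 3)), 1)
  expect_equal(nrow(enumerate_cycles(toy)), 8)
})

test_that("the widest cycle maximizes the bottleneck with deterministic tie-breaks", {
  loci <- ctla4_loci()
  X <- rep("a", 6); Y <- rep("b", 6)  # vertex-disjoint
  g <- graph_from_states(loci, list(X, Y), c(70, 30))
  pick <- max_bottleneck_cycle(g)
  expect_equal(unname(pick$states), X)
  expect_equal(pick$bottleneck, 70)

  gN <- graph_from_states(loci, list(c("a", "b", "a", "b", "a", "b")), 13)
  pickN <- max_bottleneck_cycle(gN)
  expect_equal(unname(pickN$states), c("a", "b", "a", "b", "a", "b"))
  expect_equal(pickN$bottleneck, 13)

  # equal multiplicities, disjoint supports: fewer minor states wins
  g5050 <- graph_from_states(loci, list(X, Y), c(50, 50))
  expect_equal(unname(max_bottleneck_cycle(g5050)$states), X)

  g_zero <- g
  for (k in seq_along(g_zero$weights)) g_zero$weights[[k]][] <- 0
  g_zero$n_subjects <- 0
  expect_error(max_bottleneck_cycle(g_zero), "no cycle")
})

test_that("greedy decomposition reconstructs disjoint mixtures exactly", {
  loci <- ctla4_loci()
  g <- graph_from_states(loci, list(rep("a", 6), rep("b", 6)), c(60, 40))
  dec <- greedy_decompose(g)
  expect_equal(nrow(dec), 2)
  expect_equal(dec$multiplicity, c(60, 40))
  expect_equal(dec$frequency, c(0.6, 0.4))
  expect_equal(max(unlist(attr(dec, "residual"))), 0)

  g1 <- graph_from_states(loci, list(c("a", "b", "b", "a", "a", "b")), 17)
  dec1 <- greedy_decompose(g1)
  expect_equal(nrow(dec1), 1)
  expect_equal(dec1$multiplicity, 17)

  # shared vertex at the first locus does not merge the bottlenecks;
  # the all-a cycle is extracted first by the tie-break
  g2 <- graph_from_states(loci, list(rep("a", 6), c("a", rep("b", 5))),
                          c(50, 50))
  dec2 <- greedy_decompose(g2)
  expect_equal(nrow(dec2), 2)
  expect_equal(dec2$multiplicity, c(50, 50))
  expect_equal(dec2$pattern[1], "a-a-a-a-a-a")
})

test_that("reference cycles translate to haplotype strings in report order", {
  loci <- ctla4_loci()
  all_a <- stats::setNames(rep("a", 6), loci$name)
  expect_equal(rrp_to_haplotype(all_a, loci), "AACCAT")
  all_b <- stats::setNames(rep("b", 6), loci$name)
  expect_equal(rrp_to_haplotype(all_b, loci), "GGTTGG")
  b_at_ct318 <- all_a
  b_at_ct318["CT318"] <- "b"
  expect_equal(rrp_to_haplotype(b_at_ct318, loci), "AATCAT")
  with_het <- all_a
  with_het["CT60"] <- "ab"
  expect_error(rrp_to_haplotype(with_het, loci), "three-state")
})

test_that("decomposition conserves every edge weight and stays balanced stepwise", {
  loci <- ctla4_loci()
  for (seed in 1:6) {
    tab <- simulate_cohorts(loci, n_case = 50, n_control = 50, seed = seed)
    coding <- if (seed %% 2 == 0) "three_state" else "two_state"
    g <- build_study_graph(personal_cycles(tab, loci, coding))
    dec <- greedy_decompose(g)
    # exact conservation at tol 0
    expect_equal(max(abs(unlist(attr(dec, "residual")))), 0)
    expect_equal(sum(dec$multiplicity), g$n_subjects)
    expect_equal(sum(dec$frequency), 1)
    # termination bound
    expect_lte(nrow(dec), length(g$weights) * length(g$states)^2)
    # replay the subtraction cycle by cycle: balance after every step
    work <- g
    L <- length(work$weights)
    nxt <- c(2:L, 1L)
    for (r in seq_len(nrow(dec))) {
      idx <- match(dec$cycle[[r]], g$states)
      for (k in seq_len(L)) {
        work$weights[[k]][idx[k], idx[nxt[k]]] <-
          work$weights[[k]][idx[k], idx[nxt[k]]] - dec$multiplicity[r]
      }
      expect_balanced(work)
      expect_true(all(unlist(work$weights) >= 0))
    }
  }
})

test_that("greedy matches the exhaustive minimum-component oracle on edge-disjoint mixtures", {
  loci <- ctla4_loci()
  # pairwise edge-disjoint family: any two members agree only at
  # non-adjacent cycle positions, so no edge slot is shared
  supports <- list(
    rep("a", 6),
    rep("b", 6),
    c("a", "b", "a", "b", "a", "b"),
    c("b", "a", "b", "a", "b", "a")
  )
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cycle_distance(supports[[i]], supports[[j]]), 6)
  }
  withr::with_seed(42, {
    for (rep_i in 1:4) {
      k <- sample(2:4, 1)
      use <- sample(4, k)
      mult <- sample(3:40, k)  # distinct with high probability
      g <- graph_from_states(loci, supports[use], mult)
      dec <- greedy_decompose(g)
      expect_equal(nrow(dec), oracle_min_components(g))
      got <- dec[order(dec$pattern), ]
      want <- tibble::tibble(
        pattern = vapply(supports[use], paste, "", collapse = "-"),
        multiplicity = mult
      )
      want <- want[order(want$pattern), ]
      expect_equal(got$pattern, want$pattern)
      expect_equal(got$multiplicity, want$multiplicity)
    }
  })
})

test_that("greedy frequencies equal empirical haplotype frequencies on homozygous cohorts", {
  loci <- ctla4_loci()
  pool <- default_haplotype_pool()
  counts <- round(pool$frequency * 200)
  tab <- hom_cohort(loci, pool$haplotype, counts)
  dec <- greedy_decompose(build_study_graph(personal_cycles(tab, loci, "two_state")))
  emp <- counts / sum(counts)
  got <- dec$frequency[match(pool$haplotype, dec$haplotype)]
  expect_equal(got, emp)
})

test_that("reference sets build from decompositions, patterns and haplotype strings", {
  loci <- ctla4_loci()
  refs <- as_reference_set(c("AACCAT", "a-b-b-b-b-b"), loci = loci)
  expect_equal(nrow(refs), 2)
  expect_equal(attr(refs, "coding"), "two_state")
  expect_equal(unname(refs$cycle[[1]]), rep("a", 6))
  expect_equal(refs$multiplicity, c(0, 0))
  refs3 <- as_reference_set("a-ab-b-ab-a-b", loci = loci)
  expect_equal(attr(refs3, "coding"), "three_state")
  expect_error(as_reference_set("a-b", loci = loci), "wrong length")
})
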