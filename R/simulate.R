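#' Default haplotype pool for the six CTLA-4 loci
#'
#' The five major CTLA-4 haplotypes and their published population
#' frequencies (46.99, 29.34, 9.77, 6.49 and 2.81 percent, which sum to
#' 95.4), renormalized to 1 rather than padded with an invented residual
#' haplotype. Strings are in report order (AG49, CT60, CT318, JO27, JO30,
#' JO31).
#'
#' @return A tibble `haplotype`, `frequency` (summing to 1).
#' @export
default_haplotype_pool <- function() {
  raw <- c(AACCAT = 46.99, GGCTGG = 29.34, AGTTGG = 9.77,
           AGCTGG = 6.49, AGCCAT = 2.81)
  tibble::tibble(haplotype = names(raw), frequency = unname(raw) / sum(raw))
}

validate_pool <- function(pool, loci = NULL) {
  stopifnot(all(c("haplotype", "frequency") %in% names(pool)))
  if (abs(sum(pool$frequency) - 1) > 1e-9) {
    stop("pool frequencies must sum to 1 (got ", sum(pool$frequency), ")")
  }
  if (any(pool$frequency < 0)) stop("negative pool frequency")
  if (!is.null(loci)) {
    for (h in pool$haplotype) haplotype_to_states(h, loci)  # errors if invalid
  }
  pool
}

#' Draw diplotypes from a haplotype pool under HWE
#'
#' Hardy-Weinberg equilibrium is random pairing: each subject is two
#' independent haplotype draws from the pool.
#'
#' @param pool tibble `haplotype`, `frequency`.
#' @param n number of subjects.
#' @param seed integer seed (draws never touch global RNG state).
#' @return A list of length `n` of character pairs `c(h1, h2)`.
#' @export
sample_diplotypes <- function(pool, n, seed = 1L) {
  validate_pool(pool)
  if (nrow(pool) == 0L) stop("empty haplotype pool")
  withr::with_seed(as.integer(seed), {
    h1 <- sample(pool$haplotype, n, replace = TRUE, prob = pool$frequency)
    h2 <- sample(pool$haplotype, n, replace = TRUE, prob = pool$frequency)
    purrr::map2(h1, h2, c)
  })
}

#' Convert diplotypes to unphased genotype records
#'
#' Locus-wise union of the two haplotypes' alleles; phase is discarded
#' (alleles within a pair are written in sorted order).
#'
#' @param pairs list of haplotype pairs ([sample_diplotypes()]).
#' @param loci an `nps_loci` tibble.
#' @param ids sample ids (default `S1..Sn`).
#' @param cohort cohort label(s), recycled.
#' @return A validated genotype tibble.
#' @export
diplotypes_to_genotypes <- function(pairs, loci, ids = NULL, cohort = "unknown") {
  n <- length(pairs)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  rep_names <- report_order(loci)
  h1 <- do.call(rbind, lapply(pairs, function(p) strsplit(p[1], "")[[1]]))
  h2 <- do.call(rbind, lapply(pairs, function(p) strsplit(p[2], "")[[1]]))
  if (ncol(h1) != nrow(loci)) stop("haplotype length does not match loci")
  out <- tibble::tibble(sample_id = ids, cohort = rep_len(cohort, n))
  for (i in seq_along(rep_names)) {
    a <- h1[, i]; b <- h2[, i]
    out[[rep_names[i]]] <- paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  validate_genotypes(out, loci)
}

# diplotype pairs (i <= j) over a pool with their HWE probabilities
pool_diplotype_grid <- function(pool) {
  K <- nrow(pool)
  grid <- tidyr::expand_grid(i = seq_len(K), j = seq_len(K)) |>
    dplyr::filter(.data$i <= .data$j)
  grid$prob <- ifelse(grid$i == grid$j,
                      pool$frequency[grid$i]^2,
                      2 * pool$frequency[grid$i] * pool$frequency[grid$j])
  grid$h1 <- pool$haplotype[grid$i]
  grid$h2 <- pool$haplotype[grid$j]
  grid
}

# does the two-state cycle of diplotype (h1, h2) avoid every vertex of ref?
diplotype_avoids_reference <- function(h1, h2, ref_states, loci) {
  s1 <- haplotype_to_states(h1, loci)
  s2 <- haplotype_to_states(h2, loci)
  state <- ifelse(s1 == "b" | s2 == "b", "b", "a")  # dominant coding
  all(state != ref_states[loci$name])
}

#' Simulate case/control genotype cohorts
#'
#' Draws both cohorts as HWE diplotypes from haplotype pools with the
#' strong linkage disequilibrium the pool structure encodes. Cases may use
#' a biased pool (`case_pool`), and a fraction of cases may be constrained
#' to diplotypes whose two-state cycle shares no vertex with a designated
#' reference cycle (the absence-marker construction); the remaining cases
#' are drawn from the complementary diplotype set, so the constrained
#' fraction is Bernoulli with the requested rate.
#'
#' @param loci an `nps_loci` tibble.
#' @param n_case,n_control cohort sizes (defaults 286 / 288, the melanoma
#'   study design).
#' @param pool haplotype pool for controls (and cases unless overridden).
#' @param case_pool optional alternative pool for cases.
#' @param absence_fraction optional fraction of cases forced to maximal
#'   distance from `absence_reference`.
#' @param absence_reference reference cycle (pattern string, haplotype
#'   string, or named state vector) for the absence constraint.
#' @param seed integer seed.
#' @return A validated genotype tibble of `n_case + n_control` rows with
#'   cohort labels `"case"` / `"control"`.
#' @export
simulate_cohorts <- function(loci = ctla4_loci(), n_case = 286, n_control = 288,
                             pool = default_haplotype_pool(), case_pool = NULL,
                             absence_fraction = NULL, absence_reference = NULL,
                             seed = 1L) {
  validate_pool(pool, loci)
  cp <- if (is.null(case_pool)) pool else validate_pool(case_pool, loci)
  seed <- as.integer(seed)

  case_pairs <- if (!is.null(absence_fraction)) {
    if (is.null(absence_reference)) {
      stop("absence_fraction requires an absence_reference cycle")
    }
    ref <- if (is.character(absence_reference)) {
      as_reference_set(absence_reference, loci = loci,
                       coding = "two_state")$cycle[[1]]
    } else {
      absence_reference
    }
    grid <- pool_diplotype_grid(cp)
    grid$avoids <- purrr::map2_lgl(grid$h1, grid$h2,
                                   diplotype_avoids_reference,
                                   ref_states = ref, loci = loci)
    if (!any(grid$avoids)) {
      stop("infeasible absence constraint: no diplotype in the pool avoids the reference")
    }
    if (all(grid$avoids) && absence_fraction < 1) {
      stop("infeasible absence constraint: every diplotype avoids the reference")
    }
    withr::with_seed(seed, {
      forced <- stats::runif(n_case) < absence_fraction
      draw_from <- function(sub, k) {
        idx <- sample(nrow(sub), k, replace = TRUE,
                      prob = sub$prob / sum(sub$prob))
        purrr::map(idx, function(r) c(sub$h1[r], sub$h2[r]))
      }
      pairs <- vector("list", n_case)
      pairs[forced] <- draw_from(grid[grid$avoids, ], sum(forced))
      pairs[!forced] <- draw_from(grid[!grid$avoids, ], sum(!forced))
      pairs
    })
  } else {
    sample_diplotypes(cp, n_case, seed = seed)
  }
  control_pairs <- sample_diplotypes(pool, n_control, seed = seed + 1L)

  dplyr::bind_rows(
    diplotypes_to_genotypes(case_pairs, loci,
                            ids = sprintf("case_%03d", seq_len(n_case)),
                            cohort = "case"),
    diplotypes_to_genotypes(control_pairs, loci,
                            ids = sprintf("ctrl_%03d", seq_len(n_control)),
                            cohort = "control")
  )
}

#' Simulate group-dependent survival times
#'
#' Assigns each subject a short/long survival group through a logistic
#' dependence on one designated delta feature, then draws survival days
#' uniformly below (short) or above (long) the threshold. The group split
#' is exact: the `n_short = round(short_fraction * n)` subjects with the
#' largest latent score `effect * z + noise * logistic noise` (z = the
#' standardized delta feature) are short survivors. `effect = 0` makes the
#' groups independent of the genotype features (a null generator); large
#' `noise` converges to the same null.
#'
#' @param deltas an `nps_deltas` tibble for the subjects to label.
#' @param pair delta feature column driving survival (default the first).
#' @param threshold_days the true change point (default 1820).
#' @param short_fraction target fraction of short survivors (default
#'   145/282, the balanced split of the melanoma cohort).
#' @param effect latent effect size of the delta feature.
#' @param noise latent noise scale.
#' @param min_days,max_days support of the survival times.
#' @param gap_days dead zone just above the threshold that no long-survivor
#'   time falls into, so the planted change point is identifiable by a
#'   threshold scan to within its own resolution (default 30 days).
#' @param seed integer seed.
#' @return A tibble `sample_id`, `survival_days`, `event` (all 1),
#'   `group` (`"short"`/`"long"`).
#' @export
simulate_survival <- function(deltas, pair = delta_columns(deltas)[1],
                              threshold_days = 1820,
                              short_fraction = 145 / 282,
                              effect = 3, noise = 1,
                              min_days = 30, max_days = 2 * threshold_days,
                              gap_days = 30, seed = 1L) {
  if (!pair %in% names(deltas)) stop("missing delta feature: ", pair)
  n <- nrow(deltas)
  z <- deltas[[pair]]
  z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
  withr::with_seed(as.integer(seed), {
    latent <- effect * z + noise * stats::rlogis(n)
    n_short <- round(short_fraction * n)
    short <- rep(FALSE, n)
    short[order(-latent)[seq_len(n_short)]] <- TRUE
    days <- numeric(n)
    days[short] <- stats::runif(sum(short), min_days, threshold_days)
    days[!short] <- stats::runif(sum(!short), threshold_days + gap_days, max_days)
    tibble::tibble(sample_id = deltas$sample_id,
                   survival_days = days, event = 1L,
                   group = ifelse(short, "short", "long"))
  })
}
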