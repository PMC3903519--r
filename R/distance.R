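#' Edge-mismatch distance between two cycles
#'
#' Counts the adjacent-locus edge slots at which the two cycles differ. The
#' edge in slot `k` joins the states at cycle positions `k` and `k+1 (mod
#' L)`, so two cycles agree in a slot iff they agree at both endpoints. The
#' count ranges 0..L, is 0 iff the cycles are identical, and is a metric on
#' cycles (a Hamming distance on the edge sequence).
#'
#' @param p,r state vectors of equal length (cycle order), or objects with a
#'   `states` field as from [build_personal_cycle()].
#' @return Integer mismatch count in `0..L`.
#' @export
cycle_distance <- function(p, r) {
  if (is.list(p) && !is.null(p$states)) p <- p$states
  if (is.list(r) && !is.null(r$states)) r <- r$states
  p <- unlist(p); r <- unlist(r)
  if (length(p) != length(r)) stop("cycles have different numbers of loci")
  two_state <- c("a", "b")
  if (xor(all(p %in% two_state), all(r %in% two_state))) {
    stop("cannot compare a two-state cycle to a three-state cycle")
  }
  L <- length(p)
  nxt <- c(2:L, 1L)
  same_vertex <- p == r
  sum(!(same_vertex & same_vertex[nxt]))
}

#' Distance vectors of a cohort from a reference set
#'
#' For each subject, the vector of edge-mismatch distances of their personal
#' cycle from every reference cycle, indexed by reference rank.
#'
#' @param cycles an `nps_cycles` tibble ([personal_cycles()]).
#' @param references an `nps_decomposition`, `nps_references`, or character
#'   patterns accepted by [as_reference_set()].
#' @param sign_flip negate distances so that identity (0 mismatches) is
#'   numerically largest; a presentation convention, off by default.
#' @return A tibble of class `nps_distances`: `sample_id`, `cohort`, then
#'   one integer column `d1..dK` per reference rank.
#' @export
distance_vectors <- function(cycles, references, sign_flip = FALSE) {
  loci <- attr(cycles, "loci")
  refs <- as_reference_set(references, loci = loci,
                          coding = attr(cycles, "coding"))
  if (nrow(refs) == 0L) stop("empty reference set")
  if (!identical(attr(refs, "coding"), attr(cycles, "coding"))) {
    stop("reference coding (", attr(refs, "coding"),
         ") does not match cycle coding (", attr(cycles, "coding"), ")")
  }
  m <- cycle_states_matrix(cycles)
  L <- ncol(m)
  nxt <- c(2:L, 1L)
  out <- tibble::tibble(sample_id = cycles$sample_id, cohort = cycles$cohort)
  for (j in seq_len(nrow(refs))) {
    ref <- refs$cycle[[j]][colnames(m)]
    same <- sweep(m, 2, ref, `==`)
    match_slot <- same & same[, nxt, drop = FALSE]
    d <- L - rowSums(match_slot)
    out[[paste0("d", refs$rank[j])]] <- as.integer(if (sign_flip) -d else d)
  }
  structure(out, loci = loci, coding = attr(cycles, "coding"),
            ranks = refs$rank, references = refs,
            class = c("nps_distances", class(tibble::tibble())))
}

#' Pairwise distance differences (the delta feature space)
#'
#' For every reference pair `(i, j)` with `i < j` by rank, computes
#' `delta_ij = d_i - d_j` per subject: positive means the subject's cycle is
#' closer to reference `j`, negative closer to reference `i`, zero
#' equidistant. With K references there are `K(K-1)/2` columns (190 for
#' K = 20).
#'
#' @param vectors an `nps_distances` tibble ([distance_vectors()]).
#' @return A tibble of class `nps_deltas`: `sample_id`, `cohort`, then one
#'   column per pair named `"d<i>-d<j>"`. Attribute `pairs` tabulates the
#'   pair index.
#' @export
delta_differences <- function(vectors) {
  ranks <- attr(vectors, "ranks")
  K <- length(ranks)
  if (K < 2L) stop("need at least 2 reference profiles to form differences")
  pairs <- utils::combn(sort(ranks), 2)
  out <- tibble::tibble(sample_id = vectors$sample_id, cohort = vectors$cohort)
  nm <- character(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    nm[p] <- paste0("d", i, "-d", j)
    out[[nm[p]]] <- vectors[[paste0("d", i)]] - vectors[[paste0("d", j)]]
  }
  structure(out,
            pairs = tibble::tibble(i = pairs[1, ], j = pairs[2, ], name = nm),
            loci = attr(vectors, "loci"),
            class = c("nps_deltas", class(tibble::tibble())))
}

delta_columns <- function(deltas) {
  attr(deltas, "pairs")$name
}

#' Cohort means of the delta features
#'
#' Averages each pairwise distance difference separately over cases and
#' controls. Plotting case mean against control mean puts non-discriminating
#' pairs on the diagonal `y = x`; discriminating pairs sit far from it.
#'
#' @param deltas an `nps_deltas` tibble ([delta_differences()]).
#' @param labels cohort label per subject; defaults to the `cohort` column.
#' @return A tibble of class `nps_delta_means`: `pair`, `i`, `j`,
#'   `case_mean`, `control_mean`, `diag_distance` (perpendicular distance
#'   from the diagonal, `|case - control| / sqrt(2)`).
#' @export
cohort_mean_deltas <- function(deltas, labels = deltas$cohort) {
  stopifnot(length(labels) == nrow(deltas))
  is_case <- labels == "case"
  is_control <- labels == "control"
  if (!any(is_case) || !any(is_control)) {
    stop("both cohorts must be nonempty to compute cohort means")
  }
  pairs <- attr(deltas, "pairs")
  vals <- as.matrix(deltas[, pairs$name, drop = FALSE])
  out <- tibble::tibble(
    pair = pairs$name, i = pairs$i, j = pairs$j,
    case_mean = unname(colMeans(vals[is_case, , drop = FALSE])),
    control_mean = unname(colMeans(vals[is_control, , drop = FALSE]))
  )
  out$diag_distance <- abs(out$case_mean - out$control_mean) / sqrt(2)
  structure(out, class = c("nps_delta_means", class(tibble::tibble())))
}

#' Select maximally discriminating reference pairs
#'
#' Drops pairs whose cohort means both sit inside the `min_abs` band around
#' zero (subjects there are on average equally distant from both
#' references), then ranks the rest by perpendicular distance from the
#' diagonal.
#'
#' @param means an `nps_delta_means` tibble ([cohort_mean_deltas()]).
#' @param min_abs band half-width; a pair is kept if either cohort mean has
#'   absolute value at least this (default 0.5).
#' @param top_k keep at most this many pairs (default all).
#' @return The filtered, ranked tibble with a `selection_rank` column.
#' @export
select_discriminating_pairs <- function(means, min_abs = 0.5, top_k = Inf) {
  kept <- means |>
    dplyr::filter(pmax(abs(.data$case_mean), abs(.data$control_mean)) >= min_abs,
                  .data$diag_distance > 0) |>
    dplyr::arrange(dplyr::desc(.data$diag_distance))
  kept <- utils::head(kept, n = if (is.finite(top_k)) top_k else nrow(kept))
  dplyr::mutate(kept, selection_rank = dplyr::row_number())
}

#' Subjects at maximal distance from one reference
#'
#' The absence marker: subjects whose personal cycle shares no edge with the
#' given reference cycle (distance exactly L). Returns their ids and a
#' census of the distinct cycle patterns in that subset.
#'
#' @param cycles an `nps_cycles` tibble.
#' @param reference a single reference: one row of a reference set, a named
#'   state vector, or a pattern/haplotype string.
#' @return A list with `sample_ids`, `fraction` (of all subjects),
#'   `fraction_by_cohort`, and `patterns` (tibble `pattern`, `n`).
#' @export
max_distance_subset <- function(cycles, reference) {
  loci <- attr(cycles, "loci")
  if (is.character(reference) && length(reference) == 1L && is.null(names(reference))) {
    reference <- as_reference_set(reference, loci = loci,
                                  coding = attr(cycles, "coding"))$cycle[[1]]
  } else if (inherits(reference, "nps_references") ||
             inherits(reference, "nps_decomposition")) {
    stopifnot(nrow(reference) == 1L)
    reference <- reference$cycle[[1]]
  }
  m <- cycle_states_matrix(cycles)
  L <- ncol(m)
  nxt <- c(2:L, 1L)
  same <- sweep(m, 2, reference[colnames(m)], `==`)
  d <- L - rowSums(same & same[, nxt, drop = FALSE])
  at_max <- d == L
  pat <- apply(m[at_max, , drop = FALSE], 1, paste, collapse = "-")
  census <- tibble::tibble(pattern = names(table(pat)),
                           n = as.integer(table(pat))) |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(
    sample_ids = cycles$sample_id[at_max],
    fraction = mean(at_max),
    fraction_by_cohort = tapply(at_max, cycles$cohort, mean),
    patterns = census
  )
}

#' Two-dimensional delta histogram
#'
#' Per-cohort counts of subjects over the integer grid of two delta
#' features; the multimodal structure of these histograms exposes cohort
#' heterogeneity (subgroups closer to one reference than the other).
#'
#' @param deltas an `nps_deltas` tibble.
#' @param pair_x,pair_y column names like `"d1-d2"`.
#' @param labels cohort label per subject; defaults to the `cohort` column.
#' @return A tibble `cohort`, `dx`, `dy`, `n`; counts per cohort sum to the
#'   cohort size.
#' @export
delta_histogram <- function(deltas, pair_x, pair_y, labels = deltas$cohort) {
  for (p in c(pair_x, pair_y)) {
    if (!p %in% names(deltas)) stop("unknown delta pair: ", p)
  }
  tibble::tibble(cohort = labels,
                 dx = deltas[[pair_x]], dy = deltas[[pair_y]]) |>
    dplyr::count(.data$cohort, .data$dx, .data$dy, name = "n")
}

#' Export a delta table to CSV
#'
#' @param deltas an `nps_deltas` (or `nps_distances`) tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_delta_table <- function(deltas, path) {
  readr::write_csv(tibble::as_tibble(deltas), path, progress = FALSE)
  invisible(path)
}
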