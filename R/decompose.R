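#' Enumerate all candidate reference cycles
#'
#' A candidate cycle visits exactly one state vertex per locus partition, so
#' there are `S^L` candidates for `S` states per locus over `L` loci (64 for
#' two-state six-locus graphs, 729 for three-state). Rows are in
#' lexicographic order of the state sequence (cycle order, `a < ab < b`),
#' which downstream tie-breaking relies on.
#'
#' @param graph a `study_graph`, or anything with `states`/`loci` fields.
#' @return A character matrix, one row per candidate, one column per locus
#'   in cycle order.
#' @export
enumerate_cycles <- function(graph) {
  states <- graph$states
  L <- nrow(graph$loci)
  grid <- do.call(expand.grid,
                  c(rev(rep(list(states), L)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  m <- as.matrix(grid[, rev(seq_len(L)), drop = FALSE])
  dimnames(m) <- list(NULL, graph$loci$name)
  m
}

# bottleneck (min edge weight) of each candidate row under the graph weights
candidate_bottlenecks <- function(weights, candidates, states) {
  L <- length(weights)
  nxt <- c(2:L, 1L)
  n <- nrow(candidates)
  idx <- matrix(match(candidates, states), nrow = n)
  S <- length(states)
  bn <- rep(Inf, n)
  for (k in seq_len(L)) {
    wk <- weights[[k]]
    ek <- wk[cbind(idx[, k], idx[, nxt[k]])]
    bn <- pmin(bn, ek)
  }
  bn
}

#' Widest cycle of a study graph
#'
#' Finds the candidate cycle maximizing the bottleneck (the minimum edge
#' weight along the cycle). Ties are broken first by fewer non-`a` states,
#' then by lexicographic state order (`a < ab < b`), making the extraction
#' deterministic.
#'
#' @param graph a `study_graph` with at least one positive-bottleneck cycle.
#' @param candidates optional precomputed [enumerate_cycles()] matrix.
#' @return A list with `states` (named character vector, cycle order) and
#'   `bottleneck` (its minimum edge weight, > 0).
#' @export
max_bottleneck_cycle <- function(graph, candidates = NULL) {
  if (is.null(candidates)) candidates <- enumerate_cycles(graph)
  bn <- candidate_bottlenecks(graph$weights, candidates, graph$states)
  if (all(bn <= 0)) stop("no cycle with positive bottleneck (graph exhausted)")
  best <- max(bn)
  hit <- which(bn == best)
  if (length(hit) > 1L) {
    burden <- rowSums(candidates[hit, , drop = FALSE] != "a")
    hit <- hit[burden == min(burden)]
    # candidates are in lexicographic order; first hit is the lexicographic min
    hit <- hit[1L]
  }
  states <- candidates[hit, ]
  names(states) <- graph$loci$name
  list(states = states, bottleneck = best)
}

#' Greedy decomposition of a study graph into reference cycles
#'
#' Repeatedly extracts the widest cycle ([max_bottleneck_cycle()]) and
#' subtracts its bottleneck from its L edges, recording the cycle and the
#' removed weight (its multiplicity), until every edge weight is `<= tol`.
#' Each iteration zeroes at least one edge, so the loop runs at most
#' `L * S^2` times. Because per-pair totals and vertex balance are conserved
#' at every subtraction, the extracted cycles reconstruct the original edge
#' weights exactly (to `tol`). On two-state graphs the reference cycles play
#' the role of haplotypes and `frequency` estimates the haplotype frequency.
#'
#' @param graph a `study_graph` satisfying vertex balance.
#' @param tol residual weight tolerance; `0` (exact) for integer-weight
#'   graphs, defaults to `1e-9 * total weight` otherwise.
#' @return A tibble of class `nps_decomposition`, one row per reference
#'   cycle: `rank`, `pattern` (hyphen-joined states in cycle order),
#'   `haplotype` (allele string in report order; two-state graphs only),
#'   `multiplicity`, `frequency`, and list-column `cycle` (the named state
#'   vector). Sorted by decreasing multiplicity. Attributes carry the loci,
#'   coding and residual weights.
#' @export
greedy_decompose <- function(graph, tol = NULL) {
  weights <- graph$weights
  allw <- unlist(weights)
  if (is.null(tol)) {
    tol <- if (all(allw == round(allw))) 0 else 1e-9 * sum(allw)
  }
  bal <- vertex_balance(graph)
  if (max(abs(bal)) > max(tol, 1e-9)) {
    stop("vertex balance violated; greedy decomposition is not guaranteed to terminate cleanly")
  }
  candidates <- enumerate_cycles(graph)
  L <- length(weights)
  nxt <- c(2:L, 1L)
  states <- graph$states
  search <- decompose_search(weights, candidates, states, nxt, tol,
                             budget = 20000L)
  if (is.null(search)) {
    stop("decomposition search budget exhausted before reaching an exact decomposition")
  }
  out_states <- lapply(search$picks, function(p) {
    stats::setNames(candidates[p, ], graph$loci$name)
  })
  out_mult <- search$mults
  work <- list(weights = search$residual)
  ord <- order(-out_mult)
  out_states <- out_states[ord]
  out_mult <- out_mult[ord]
  total <- graph$n_subjects * graph$weight_unit
  res <- tibble::tibble(
    rank = seq_along(out_mult),
    pattern = vapply(out_states, paste, "", collapse = "-"),
    haplotype = if (graph$coding == "two_state") {
      vapply(out_states, rrp_to_haplotype, "", loci = graph$loci)
    } else {
      NA_character_
    },
    multiplicity = out_mult,
    frequency = out_mult / total,
    cycle = out_states
  )
  structure(res,
            loci = graph$loci, coding = graph$coding,
            n_subjects = graph$n_subjects, weight_unit = graph$weight_unit,
            residual = work$weights,
            class = c("nps_decomposition", class(tibble::tibble())))
}

#' Haplotype string of a two-state reference cycle
#'
#' Maps state `a` to the locus's major allele and `b` to its minor allele
#' and concatenates the alleles in report order.
#'
#' @param states named character state vector (names = locus names) or a
#'   one-row of an `nps_decomposition` via its `cycle` list-column.
#' @param loci an `nps_loci` tibble.
#' @return A single allele string, e.g. `"AACCAT"`.
#' @export
rrp_to_haplotype <- function(states, loci) {
  if (any(states == "ab")) {
    stop("three-state cycles have no nucleotide haplotype string; states a/ab/b label them instead")
  }
  s <- states[loci$name]
  allele <- ifelse(s == "a", loci$major, loci$minor)
  paste(allele[order(loci$report_position)], collapse = "")
}

# Depth-first widest-cycle extraction with backtracking.
#
# Pure greedy (always subtract the current widest cycle) can strand weight:
# the residual circulation stays balanced yet admits only closed walks that
# wrap the partitions more than once. Because every study graph is a sum of
# single-wrap personal cycles an exact decomposition always exists, so when
# a branch dead-ends we back up and try the next candidate in the greedy
# preference order (bottleneck desc, fewer non-a states, lexicographic).
# Each extraction zeroes at least one edge, bounding the depth by the
# number of positive edges (<= L*S^2); `budget` caps total node expansions.
decompose_search <- function(weights, candidates, states, nxt, tol, budget) {
  L <- length(weights)
  S <- length(states)
  idx_mat <- matrix(match(candidates, states), nrow = nrow(candidates))
  # flat edge index of candidate r in slot k, for fast coverage checks
  edge_idx <- vapply(seq_len(L), function(k) {
    (k - 1L) * S * S + (idx_mat[, nxt[k]] - 1L) * S + idx_mat[, k]
  }, integer(nrow(candidates)))
  burden_all <- rowSums(candidates != "a")
  budget_left <- budget
  failed <- new.env(hash = TRUE, parent = emptyenv())

  recurse <- function(w) {
    if (all(unlist(w) <= tol)) {
      return(list(picks = integer(0), mults = numeric(0), residual = w))
    }
    key <- paste(signif(unlist(w), 12), collapse = ",")
    if (!is.null(failed[[key]])) return(NULL)
    if (budget_left <= 0L) return(NULL)
    bn <- candidate_bottlenecks(w, candidates, states)
    viable <- which(bn > tol)
    fail <- function() { failed[[key]] <- TRUE; NULL }
    if (!length(viable)) return(fail())  # stranded weight: backtrack
    # every positive edge must lie on some viable cycle, else dead end
    flat <- unlist(w)
    pos <- which(flat > tol)
    covered <- unique(as.vector(edge_idx[viable, , drop = FALSE]))
    if (!all(pos %in% covered)) return(fail())
    ord <- viable[order(-bn[viable], burden_all[viable], viable)]
    for (cand in ord) {
      budget_left <<- budget_left - 1L
      if (budget_left < 0L) return(NULL)
      w2 <- w
      m <- bn[cand]
      for (k in seq_len(L)) {
        i <- idx_mat[cand, k]; j <- idx_mat[cand, nxt[k]]
        w2[[k]][i, j] <- w2[[k]][i, j] - m
      }
      rest <- recurse(w2)
      if (!is.null(rest)) {
        return(list(picks = c(cand, rest$picks),
                    mults = c(m, rest$mults),
                    residual = rest$residual))
      }
    }
    fail()
  }
  res <- recurse(weights)
  if (is.null(res)) return(NULL)
  # merge repeated extractions of the same cycle
  if (anyDuplicated(res$picks)) {
    agg <- rowsum(res$mults, res$picks)
    picks <- as.integer(rownames(agg))
    first_seen <- match(picks, res$picks)
    keep <- order(first_seen)
    res$picks <- picks[keep]
    res$mults <- agg[keep, 1]
  }
  res
}

# inverse: haplotype string in report order -> state vector in cycle order
haplotype_to_states <- function(haplotype, loci) {
  alleles <- strsplit(haplotype, "")[[1]]
  if (length(alleles) != nrow(loci)) {
    stop("haplotype string length ", length(alleles), " != ", nrow(loci), " loci")
  }
  rep_names <- report_order(loci)
  st <- character(nrow(loci))
  names(st) <- rep_names
  for (i in seq_along(rep_names)) {
    row <- loci[loci$name == rep_names[i], ]
    st[i] <- if (alleles[i] == row$major) "a"
      else if (alleles[i] == row$minor) "b"
      else stop("allele ", alleles[i], " invalid at locus ", rep_names[i])
  }
  st[loci$name]
}

#' Assemble a reference cycle set
#'
#' Reference sets for distance work can come from a decomposition, from
#' explicit state patterns (hyphen-joined states in cycle order, e.g.
#' `"a-b-b-a-b-b"`), or from haplotype strings in report order. Injected
#' cycles get multiplicity 0: the identity of a reference is its edge set,
#' not its frequency, so a reference set derived from one cohort can be
#' applied to another.
#'
#' @param x an `nps_decomposition`, or a character vector of patterns or
#'   haplotype strings.
#' @param loci required when `x` is a character vector.
#' @param coding coding of character-built sets (default `"two_state"`,
#'   or `"three_state"` when any pattern contains `ab`).
#' @return A tibble of class `nps_references`: `rank`, `pattern`, `cycle`
#'   (list-column of named state vectors), `multiplicity`.
#' @export
as_reference_set <- function(x, loci = NULL, coding = NULL) {
  if (inherits(x, "nps_references")) return(x)
  if (inherits(x, "nps_decomposition")) {
    out <- tibble::tibble(rank = x$rank, pattern = x$pattern,
                          cycle = x$cycle, multiplicity = x$multiplicity)
    return(structure(out, loci = attr(x, "loci"), coding = attr(x, "coding"),
                     class = c("nps_references", class(tibble::tibble()))))
  }
  if (!is.character(x)) stop("cannot build a reference set from ", class(x)[1])
  if (is.null(loci)) stop("loci required to build references from strings")
  cycles <- lapply(x, function(s) {
    if (grepl("-", s, fixed = TRUE)) {
      st <- strsplit(s, "-", fixed = TRUE)[[1]]
      if (length(st) != nrow(loci)) stop("pattern has wrong length: ", s)
      ok <- st %in% c("a", "ab", "b")
      if (!all(ok)) stop("invalid state in pattern: ", s)
      stats::setNames(st, loci$name)
    } else {
      haplotype_to_states(s, loci)
    }
  })
  if (is.null(coding)) {
    coding <- if (any(vapply(cycles, function(cc) any(cc == "ab"), TRUE)))
      "three_state" else "two_state"
  }
  out <- tibble::tibble(
    rank = seq_along(cycles),
    pattern = vapply(cycles, paste, "", collapse = "-"),
    cycle = cycles,
    multiplicity = 0
  )
  structure(out, loci = loci, coding = coding,
            class = c("nps_references", class(tibble::tibble())))
}

#' @export
tidy.nps_decomposition <- function(x, ...) {
  tibble::as_tibble(x[, c("rank", "pattern", "haplotype", "multiplicity", "frequency")])
}

#' @export
glance.nps_decomposition <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x),
    coding = attr(x, "coding"),
    n_subjects = attr(x, "n_subjects"),
    weight_unit = attr(x, "weight_unit"),
    total_multiplicity = sum(x$multiplicity),
    max_residual = max(unlist(attr(x, "residual")))
  )
}

#' Write a decomposition report
#'
#' CSV with rank, state pattern (cycle order), haplotype string (report
#' order; two-state only), multiplicity and frequency, plus a JSON sidecar
#' with the residual weights.
#'
#' @param decomposition an `nps_decomposition`.
#' @param path output CSV path; the residual JSON gets suffix
#'   `".residual.json"`.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(decomposition, path) {
  readr::write_csv(tidy(decomposition), path, progress = FALSE)
  resid <- lapply(attr(decomposition, "residual"), function(w) {
    list(rows = rownames(w), cols = colnames(w),
         values = unname(as.list(as.data.frame(w))))
  })
  jsonlite::write_json(resid, paste0(path, ".residual.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
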