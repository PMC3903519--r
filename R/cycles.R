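coding_states <- function(coding) {
  switch(coding,
    two_state = c("a", "b"),
    three_state = c("a", "ab", "b"),
    stop("coding must be 'two_state' or 'three_state', got: ", coding)
  )
}

#' Encode genotypes as personal relationship cycles
#'
#' Each subject's multilocus genotype becomes a closed path through a
#' k-partite graph: one allele-state vertex per locus, visited in cycle
#' order, with the last locus joined back to the first. Under `two_state`
#' coding states follow the dominant model ([dominant_state()]); under
#' `three_state` coding they carry full zygosity ([zygosity_state()]).
#'
#' @param genotypes validated genotype tibble ([read_genotype_table()]).
#' @param loci an `nps_loci` tibble.
#' @param coding `"two_state"` or `"three_state"`.
#' @return A tibble of class `nps_cycles`: `sample_id`, `cohort`, then one
#'   state column per locus in cycle order. Attributes `coding` and `loci`
#'   carry the encoding.
#' @export
personal_cycles <- function(genotypes, loci, coding = c("two_state", "three_state")) {
  coding <- match.arg(coding)
  state_fun <- if (coding == "two_state") dominant_state else zygosity_state
  out <- tibble::tibble(sample_id = genotypes$sample_id,
                        cohort = genotypes$cohort)
  for (i in seq_len(nrow(loci))) {
    out[[loci$name[i]]] <-
      state_fun(genotypes[[loci$name[i]]], loci$major[i], loci$minor[i])
  }
  structure(out,
            coding = coding, loci = loci,
            class = c("nps_cycles", class(tibble::tibble())))
}

#' Build one personal cycle
#'
#' Single-subject convenience around [personal_cycles()]: returns the state
#' sequence and the derived edge list of one subject's cycle.
#'
#' @param record one-row genotype tibble.
#' @inheritParams personal_cycles
#' @return A list with `sample_id`, `coding`, `states` (named character
#'   vector in cycle order) and `edges` (tibble `slot`, `from_locus`,
#'   `to_locus`, `from_state`, `to_state`; slot `L` closes the cycle).
#' @export
build_personal_cycle <- function(record, loci, coding = c("two_state", "three_state")) {
  coding <- match.arg(coding)
  stopifnot(nrow(record) == 1L)
  cyc <- personal_cycles(record, loci, coding)
  states <- cycle_states_matrix(cyc)[1L, ]
  L <- nrow(loci)
  nxt <- c(2:L, 1L)
  list(
    sample_id = record$sample_id,
    coding = coding,
    states = states,
    edges = tibble::tibble(
      slot = seq_len(L),
      from_locus = loci$name,
      to_locus = loci$name[nxt],
      from_state = unname(states),
      to_state = unname(states[nxt])
    )
  )
}

# n x L character matrix of states in cycle order, rownames = sample_id
cycle_states_matrix <- function(cycles) {
  loci <- attr(cycles, "loci")
  m <- as.matrix(as.data.frame(cycles[, loci$name, drop = FALSE]))
  rownames(m) <- cycles$sample_id
  m
}

#' Accumulate personal cycles into a weighted study graph
#'
#' Every subject's cycle adds `weight_unit` (default 1) to each of its L
#' edges, so for each adjacent locus pair the edge-weight matrix counts
#' state co-occurrences across the cohort. The weight on edge
#' `(x at locus k, y at locus k+1)` divided by the pair total estimates the
#' co-occurrence probability of those allele states; row-normalizing gives
#' conditional probabilities (see [edge_conditional_probabilities()]).
#'
#' @param cycles an `nps_cycles` tibble ([personal_cycles()]).
#' @param weight_unit weight added per subject per edge.
#' @return An object of class `study_graph`: the loci, coding, per-pair
#'   weight matrices, `n_subjects` and `weight_unit`.
#' @export
build_study_graph <- function(cycles, weight_unit = 1) {
  if (nrow(cycles) == 0L) stop("cannot build a study graph from zero cycles")
  loci <- attr(cycles, "loci")
  coding <- attr(cycles, "coding")
  states <- coding_states(coding)
  m <- cycle_states_matrix(cycles)
  L <- nrow(loci)
  nxt <- c(2:L, 1L)
  weights <- vector("list", L)
  for (k in seq_len(L)) {
    tab <- table(factor(m[, k], levels = states),
                 factor(m[, nxt[k]], levels = states))
    weights[[k]] <- matrix(as.numeric(tab), length(states), length(states),
                           dimnames = list(states, states)) * weight_unit
  }
  names(weights) <- paste0(loci$name, "->", loci$name[nxt])
  new_study_graph(loci, coding, weights, nrow(m), weight_unit)
}

new_study_graph <- function(loci, coding, weights, n_subjects, weight_unit) {
  g <- structure(
    list(loci = loci, coding = coding, states = coding_states(coding),
         weights = weights, n_subjects = n_subjects,
         weight_unit = weight_unit),
    class = "study_graph"
  )
  check_graph_invariants(g)
  g
}

check_graph_invariants <- function(graph, tol = 1e-9) {
  tot <- graph$n_subjects * graph$weight_unit
  for (k in seq_along(graph$weights)) {
    w <- graph$weights[[k]]
    if (any(w < -tol)) stop("negative edge weight in pair ", k)
    if (abs(sum(w) - tot) > tol * max(1, tot)) {
      stop("per-pair conservation violated at pair ", k, ": sum ", sum(w),
           " != ", tot)
    }
  }
  bal <- vertex_balance(graph)
  if (max(abs(bal)) > tol * max(1, tot)) {
    stop("vertex balance violated (max imbalance ", max(abs(bal)), ")")
  }
  invisible(graph)
}

# matrix (L x S) of out-minus-in weight per vertex (locus, state)
vertex_balance <- function(graph) {
  L <- length(graph$weights)
  prv <- c(L, seq_len(L - 1L))
  out <- t(vapply(seq_len(L), function(k) {
    rowSums(graph$weights[[k]]) - colSums(graph$weights[[prv[k]]])
  }, numeric(length(graph$states))))
  rownames(out) <- graph$loci$name
  out
}

#' Build a study graph from allele dosages
#'
#' Chromosome-level alternative to the subject-level [build_study_graph()]:
#' for each adjacent locus pair, a subject with minor-allele doses
#' `d_x, d_y in {0,1,2}` at the two loci contributes `d_x * d_y / 2` to edge
#' `(b,b)`, `(2-d_x) * d_y / 2` to `(a,b)`, and so on — i.e. the outer
#' product of the dose vectors over the two states, halved so each subject
#' deposits 2 chromosome-equivalents per pair. On cohorts of homozygous
#' diplotypes this is exactly twice the subject-level two-state graph, which
#' makes decomposition multiplicities commensurate with allele-level
#' haplotype frequencies.
#'
#' @param genotypes validated genotype tibble.
#' @param loci an `nps_loci` tibble.
#' @return A `study_graph` with `coding = "two_state"` and `weight_unit = 2`.
#' @export
build_dosage_graph <- function(genotypes, loci) {
  if (nrow(genotypes) == 0L) stop("cannot build a dosage graph from zero records")
  L <- nrow(loci)
  nxt <- c(2:L, 1L)
  # minor-allele dose per subject per locus
  dose <- vapply(seq_len(L), function(i) {
    z <- zygosity_state(genotypes[[loci$name[i]]], loci$major[i], loci$minor[i])
    c(a = 0, ab = 1, b = 2)[z]
  }, numeric(nrow(genotypes)))
  dose <- matrix(dose, nrow = nrow(genotypes))
  weights <- vector("list", L)
  for (k in seq_len(L)) {
    dx <- dose[, k]; dy <- dose[, nxt[k]]
    w <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    w["a", "a"] <- sum((2 - dx) * (2 - dy)) / 2
    w["a", "b"] <- sum((2 - dx) * dy) / 2
    w["b", "a"] <- sum(dx * (2 - dy)) / 2
    w["b", "b"] <- sum(dx * dy) / 2
    weights[[k]] <- w
  }
  names(weights) <- paste0(loci$name, "->", loci$name[nxt])
  new_study_graph(loci, "two_state", weights, nrow(genotypes), 2)
}

#' Conditional state probabilities along one edge slot
#'
#' Converts the weight matrix of one adjacent locus pair into the estimated
#' conditional probabilities `P(state at second locus | state at first)`
#' together with the marginal state distribution at the first locus.
#'
#' @param graph a `study_graph`.
#' @param pair edge-slot index `1..L` (slot k joins the k-th and (k+1 mod L)-th
#'   locus in cycle order), or a slot name like `"AG49->CT60"`.
#' @return A tibble with `from_state`, `to_state`, `weight`, `marginal` (of
#'   `from_state`) and `conditional` = P(to | from).
#' @export
edge_conditional_probabilities <- function(graph, pair) {
  if (is.character(pair)) pair <- match(pair, names(graph$weights))
  w <- graph$weights[[pair]]
  if (is.null(w)) stop("unknown edge slot")
  tot <- sum(w)
  if (tot <= 0) stop("zero-weight pair: no probabilities defined")
  marg <- rowSums(w) / tot
  cond <- w / ifelse(rowSums(w) > 0, rowSums(w), 1)
  tidyr::expand_grid(from_state = rownames(w), to_state = colnames(w)) |>
    dplyr::mutate(
      weight = purrr::map2_dbl(.data$from_state, .data$to_state, ~ w[.x, .y]),
      marginal = unname(marg[.data$from_state]),
      conditional = purrr::map2_dbl(.data$from_state, .data$to_state,
                                    ~ cond[.x, .y])
    )
}

#' @export
print.study_graph <- function(x, ...) {
  cat("<study_graph> ", x$coding, ", ", nrow(x$loci), " loci, ",
      x$n_subjects, " subjects (weight unit ", x$weight_unit, ")\n", sep = "")
  cat("cycle order:", paste(x$loci$name, collapse = " -> "), "\n")
  invisible(x)
}

#' Tidy a study graph into an edge table
#'
#' @param x a `study_graph`.
#' @param ... unused.
#' @return A tibble with one row per edge: `slot`, `from_locus`, `to_locus`,
#'   `from_state`, `to_state`, `weight`.
#' @export
tidy.study_graph <- function(x, ...) {
  L <- length(x$weights)
  nxt <- c(2:L, 1L)
  purrr::map_dfr(seq_len(L), function(k) {
    w <- x$weights[[k]]
    tidyr::expand_grid(from_state = rownames(w), to_state = colnames(w)) |>
      dplyr::mutate(
        slot = k,
        from_locus = x$loci$name[k],
        to_locus = x$loci$name[nxt[k]],
        weight = purrr::map2_dbl(.data$from_state, .data$to_state,
                                 ~ w[.x, .y])
      ) |>
      dplyr::select("slot", "from_locus", "to_locus",
                    "from_state", "to_state", "weight")
  })
}

#' @export
glance.study_graph <- function(x, ...) {
  tibble::tibble(
    coding = x$coding,
    n_loci = nrow(x$loci),
    n_subjects = x$n_subjects,
    weight_unit = x$weight_unit,
    total_weight = sum(vapply(x$weights, sum, 0))
  )
}

#' Add two study graphs
#'
#' Graphs over the same loci and coding add edgewise; building a graph from
#' a union of cohorts equals the sum of the cohort graphs.
#'
#' @param e1,e2 `study_graph` objects with identical loci, coding and
#'   weight unit.
#' @return Their edgewise sum.
#' @export
`+.study_graph` <- function(e1, e2) {
  stopifnot(identical(e1$coding, e2$coding),
            identical(e1$loci$name, e2$loci$name),
            identical(e1$weight_unit, e2$weight_unit))
  weights <- purrr::map2(e1$weights, e2$weights, `+`)
  new_study_graph(e1$loci, e1$coding, weights,
                  e1$n_subjects + e2$n_subjects, e1$weight_unit)
}

#' Serialize a study graph to JSON
#'
#' Subject-mode graphs round-trip bit-exactly (integer weights).
#'
#' @param graph a `study_graph`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_graph <- function(graph, path) {
  payload <- list(
    coding = graph$coding,
    n_subjects = graph$n_subjects,
    weight_unit = graph$weight_unit,
    loci = as.list(tibble::as_tibble(graph$loci)),
    states = graph$states,
    weights = lapply(graph$weights, function(w) {
      list(rows = rownames(w), cols = colnames(w), values = unname(as.list(as.data.frame(w))))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study graph from JSON
#'
#' @param path path written by [write_study_graph()].
#' @return A `study_graph`.
#' @export
read_study_graph <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  loci <- validate_loci(tibble::as_tibble(p$loci))
  weights <- lapply(p$weights, function(w) {
    # values are serialized column by column; jsonlite simplifies the list
    # of columns into a row-per-column matrix, so transpose in that case
    m <- if (is.list(w$values)) do.call(cbind, w$values) else t(as.matrix(w$values))
    storage.mode(m) <- "double"
    dimnames(m) <- list(w$rows, w$cols)
    m
  })
  L <- nrow(loci)
  nxt <- c(2:L, 1L)
  names(weights) <- paste0(loci$name, "->", loci$name[nxt])
  new_study_graph(loci, p$coding, weights, p$n_subjects, p$weight_unit)
}
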