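#' Enumerate diplotypes compatible with an unphased genotype
#'
#' A subject heterozygous at `h` loci admits `2^(h-1)` unordered haplotype
#' pairs (phase configurations); a fully homozygous subject has exactly one.
#' Haplotype strings use report order.
#'
#' @param record one-row genotype tibble.
#' @param loci an `nps_loci` tibble.
#' @return A list of unordered pairs, each a character vector `c(h1, h2)`.
#' @export
compatible_diplotypes <- function(record, loci) {
  stopifnot(nrow(record) == 1L)
  rep_names <- report_order(loci)
  per_locus <- lapply(rep_names, function(nm) {
    row <- loci[loci$name == nm, ]
    sort(allele_pair(record[[nm]]))  # canonical order within pair
  })
  het <- vapply(per_locus, function(p) p[1] != p[2], TRUE)
  h <- sum(het)
  L <- length(per_locus)
  base1 <- vapply(per_locus, `[`, "", 1L)
  base2 <- vapply(per_locus, `[`, "", 2L)
  if (h == 0L) {
    return(list(c(paste(base1, collapse = ""), paste(base2, collapse = ""))))
  }
  het_idx <- which(het)
  # fix the phase at the first heterozygous locus to enumerate unordered pairs
  free <- het_idx[-1L]
  n_free <- length(free)
  combos <- if (n_free == 0L) matrix(FALSE, 1, 0) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_free)))
  lapply(seq_len(nrow(combos)), function(i) {
    flip <- rep(FALSE, L)
    flip[free] <- as.logical(combos[i, ])
    h1 <- ifelse(flip, base2, base1)
    h2 <- ifelse(flip, base1, base2)
    c(paste(h1, collapse = ""), paste(h2, collapse = ""))
  })
}

#' EM haplotype frequency estimation under Hardy-Weinberg equilibrium
#'
#' Maximum-likelihood haplotype frequencies from unphased multilocus
#' genotypes. The E-step assigns each subject posterior weights over its
#' compatible diplotypes proportional to `2^[h1 != h2] * f(h1) * f(h2)`
#' (HWE random pairing); the M-step sets frequencies to expected haplotype
#' counts over `2n` chromosomes. The observed-data log likelihood is
#' non-decreasing across iterations and convergence is declared when the
#' largest absolute frequency change drops below `tol`.
#'
#' @param genotypes validated genotype tibble.
#' @param loci an `nps_loci` tibble.
#' @param tol convergence tolerance on the max frequency change.
#' @param max_iter iteration cap.
#' @param drop_below final frequencies below this are dropped and the table
#'   renormalized.
#' @return An object of class `nps_em`: tibble columns `haplotype`,
#'   `frequency`, `se` (binomial approximation `sqrt(f(1-f)/2n)`), with
#'   attributes `log_likelihood`, `n_iterations`, `converged`, `trace`
#'   (per-iteration log likelihood).
#' @export
em_fit <- function(genotypes, loci, tol = 1e-8, max_iter = 1000,
                   drop_below = 1e-6) {
  if (nrow(genotypes) == 0L) stop("em_fit needs at least one record")
  # collapse identical genotype patterns for speed
  key <- do.call(paste, c(lapply(loci$name, function(nm) genotypes[[nm]]),
                          list(sep = "|")))
  counts <- table(key)
  reps <- genotypes[match(names(counts), key), , drop = FALSE]
  pair_sets <- lapply(seq_len(nrow(reps)), function(i) {
    compatible_diplotypes(reps[i, ], loci)
  })
  n_pat <- length(pair_sets)
  w_pat <- as.numeric(counts)
  n <- sum(w_pat)

  haps <- sort(unique(unlist(pair_sets)))
  H <- length(haps)
  # per pattern: index matrices into haps and the heterozygosity multiplier
  i1 <- lapply(pair_sets, function(ps) match(vapply(ps, `[`, "", 1L), haps))
  i2 <- lapply(pair_sets, function(ps) match(vapply(ps, `[`, "", 2L), haps))
  mult <- lapply(pair_sets, function(ps)
    ifelse(vapply(ps, function(p) p[1] != p[2], TRUE), 2, 1))

  f <- rep(1 / H, H)
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    expected <- numeric(H)
    ll <- 0
    for (p in seq_len(n_pat)) {
      lik <- mult[[p]] * f[i1[[p]]] * f[i2[[p]]]
      tot <- sum(lik)
      ll <- ll + w_pat[p] * log(tot)
      post <- lik / tot
      contrib <- w_pat[p] * post
      expected <- expected +
        tabulate2(i1[[p]], contrib, H) + tabulate2(i2[[p]], contrib, H)
    }
    f_new <- expected / (2 * n)
    ll_trace <- c(ll_trace, ll)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  keep <- f >= drop_below
  f_keep <- f[keep] / sum(f[keep])
  ord <- order(-f_keep)
  out <- tibble::tibble(
    haplotype = haps[keep][ord],
    frequency = f_keep[ord],
    se = sqrt(f_keep[ord] * (1 - f_keep[ord]) / (2 * n))
  )
  structure(out,
            log_likelihood = ll_trace[length(ll_trace)],
            n_iterations = iter, converged = converged,
            trace = ll_trace, n_subjects = n,
            class = c("nps_em", class(tibble::tibble())))
}

# weighted tabulate: sum w over idx into bins 1..nbins
tabulate2 <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
tidy.nps_em <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.nps_em <- function(x, ...) {
  tibble::tibble(
    n_haplotypes = nrow(x),
    log_likelihood = attr(x, "log_likelihood"),
    n_iterations = attr(x, "n_iterations"),
    converged = attr(x, "converged"),
    n_subjects = attr(x, "n_subjects")
  )
}

#' Hardy-Weinberg chi-square test at one locus
#'
#' One-degree-of-freedom goodness-of-fit of the observed homozygous-major /
#' heterozygous / homozygous-minor counts against expectations from the
#' estimated allele frequency. A monomorphic locus returns statistic 0 and
#' p-value 1 by convention.
#'
#' @param genotypes validated genotype tibble.
#' @param loci an `nps_loci` tibble.
#' @param locus locus name; default tests all loci.
#' @return A tibble with `locus`, `n_aa`, `n_ab`, `n_bb`, `minor_freq`,
#'   `statistic`, `p_value`.
#' @export
hwe_chisq <- function(genotypes, loci, locus = loci$name) {
  purrr::map_dfr(locus, function(nm) {
    row <- loci[loci$name == nm, ]
    z <- zygosity_state(genotypes[[nm]], row$major, row$minor)
    n_aa <- sum(z == "a"); n_ab <- sum(z == "ab"); n_bb <- sum(z == "b")
    n <- n_aa + n_ab + n_bb
    q <- (2 * n_bb + n_ab) / (2 * n)
    if (q == 0 || q == 1) {
      stat <- 0; p <- 1
    } else {
      expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
      stat <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
    tibble::tibble(locus = nm, n_aa = n_aa, n_ab = n_ab, n_bb = n_bb,
                   minor_freq = q, statistic = stat, p_value = p)
  })
}

#' Write a haplotype frequency table
#'
#' @param fit an `nps_em` fit (or any tibble with haplotype/frequency/se).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(fit, path) {
  readr::write_csv(tibble::as_tibble(fit), path, progress = FALSE)
  invisible(path)
}
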