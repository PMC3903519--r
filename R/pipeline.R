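#' Run the full genotype-network analysis pipeline
#'
#' End-to-end orchestration: read loci and genotypes, encode personal
#' cycles, build the study graph, decompose it into reference cycles,
#' compute distance vectors and pairwise distance differences, score cohort
#' discrimination, and (when survival data are present) run the survival
#' threshold scan and logistic model. All reports are written as CSV/JSON
#' into `out_dir` together with a JSON run manifest.
#'
#' @param loci an `nps_loci` tibble or path to a loci config file.
#' @param genotypes a validated genotype tibble or path to a genotype table.
#' @param coding `"two_state"` or `"three_state"`.
#' @param graph_mode `"subject"` (+1 per subject per edge) or `"dosage"`
#'   (allele-dose products, 2 chromosome-equivalents per subject; forces
#'   two-state references).
#' @param references `"combined"`, `"case"` or `"control"` to decompose
#'   that cohort's graph, or a character vector / file of injected
#'   reference patterns.
#' @param out_dir output directory (created if absent).
#' @param alpha significance level for the survival tests.
#' @param scan numeric `c(lo, hi, step)` for the survival threshold scan.
#' @param run_survival run the survival stage; default auto (runs iff any
#'   survival data present). Requesting it without survival columns errors.
#' @param seed integer seed (classifier folds).
#' @return Invisibly, a list with the main in-memory results: `graph`,
#'   `decomposition`, `distances`, `deltas`, `delta_means`,
#'   `classification`, and optionally `scan`, `survival_model`.
#' @export
run_pipeline <- function(loci, genotypes, coding = c("two_state", "three_state"),
                         graph_mode = c("subject", "dosage"),
                         references = "combined",
                         out_dir = ".", alpha = 0.05,
                         scan = c(800, 1900, 10),
                         run_survival = NULL, seed = 1L) {
  coding <- match.arg(coding)
  graph_mode <- match.arg(graph_mode)
  if (is.character(loci) && length(loci) == 1L) loci <- read_loci_config(loci)
  if (is.character(genotypes) && length(genotypes) == 1L) {
    genotypes <- read_genotype_table(genotypes, loci)
  } else {
    genotypes <- validate_genotypes(genotypes, loci)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  cycles <- stage("encode", personal_cycles(genotypes, loci, coding))

  graph <- stage("build", {
    if (graph_mode == "dosage") {
      if (coding != "two_state") {
        stop("dosage mode defines a two-state graph; set coding = 'two_state'")
      }
      build_dosage_graph(genotypes, loci)
    } else {
      build_study_graph(cycles)
    }
  })
  write_study_graph(graph, file.path(out_dir, "study_graph.json"))

  refs <- stage("decompose", {
    if (length(references) == 1L && references %in% c("combined", "case", "control")) {
      sub <- if (references == "combined") cycles else
        cycles[cycles$cohort == references, , drop = FALSE]
      if (nrow(sub) == 0L) stop("no subjects in reference cohort '", references, "'")
      g <- if (graph_mode == "dosage") {
        gt <- genotypes[genotypes$sample_id %in% sub$sample_id, , drop = FALSE]
        build_dosage_graph(gt, loci)
      } else {
        build_study_graph(sub)
      }
      dec <- greedy_decompose(g)
      write_decomposition(dec, file.path(out_dir, "decomposition.csv"))
      as_reference_set(dec)
    } else {
      pats <- if (length(references) == 1L && file.exists(references)) {
        readLines(references)
      } else {
        references
      }
      as_reference_set(pats[nzchar(pats)], loci = loci, coding = coding)
    }
  })

  distances <- stage("distances", distance_vectors(cycles, refs))
  write_delta_table(distances, file.path(out_dir, "distances.csv"))
  deltas <- stage("deltas", delta_differences(distances))
  write_delta_table(deltas, file.path(out_dir, "deltas.csv"))

  has_both <- all(c("case", "control") %in% genotypes$cohort)
  delta_means <- NULL
  classification <- NULL
  if (has_both) {
    delta_means <- stage("discriminate", cohort_mean_deltas(deltas))
    selected <- select_discriminating_pairs(delta_means)
    report <- dplyr::mutate(delta_means,
                            selected = .data$pair %in% selected$pair)
    readr::write_csv(report, file.path(out_dir, "discrimination.csv"),
                     progress = FALSE)
    classification <- stage("classify",
                            classify_cohort(distances, folds = 10, seed = seed))
  }

  has_survival <- any(!is.na(genotypes$survival_days))
  if (is.null(run_survival)) run_survival <- has_survival
  scan_result <- NULL
  survival_model <- NULL
  if (run_survival) {
    if (!has_survival) {
      stop("[stage survival] survival requested but the genotype table has no ",
           "survival_days values", call. = FALSE)
    }
    cases <- !is.na(genotypes$survival_days)
    scan_result <- stage("survival", threshold_scan(
      deltas[cases, , drop = FALSE], genotypes$survival_days[cases],
      lo = scan[1], hi = scan[2], step = scan[3], alpha = alpha))
    readr::write_csv(scan_result$scan, file.path(out_dir, "threshold_scan.csv"),
                     progress = FALSE)
    readr::write_csv(tibble::as_tibble(scan_result$best_tests),
                     file.path(out_dir, "survival_tests.csv"), progress = FALSE)
    sig <- scan_result$best_tests$pair[scan_result$best_tests$significant]
    if (length(sig)) {
      survival_model <- stage("odds", survival_logistic(
        deltas[cases, , drop = FALSE], sig, scan_result$best_groups))
      write_survival_model(survival_model,
                           file.path(out_dir, "survival_model.json"))
    }
  }

  manifest <- list(
    package = "snpcycle",
    version = as.character(utils::packageVersion("snpcycle")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    coding = coding, graph_mode = graph_mode,
    references = paste(references, collapse = ","),
    n_subjects = nrow(genotypes),
    n_references = nrow(refs),
    n_delta_pairs = nrow(attr(deltas, "pairs")),
    alpha = alpha,
    scan = as.numeric(scan),
    survival_stage = run_survival
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(graph = graph,
                 references = refs,
                 decomposition = if (inherits(refs, "nps_references")) refs,
                 distances = distances, deltas = deltas,
                 delta_means = delta_means, classification = classification,
                 scan = scan_result, survival_model = survival_model,
                 manifest = manifest))
}
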