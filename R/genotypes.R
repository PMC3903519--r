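#' Read a genotype table
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line) with one row per subject. Required columns: `sample_id`, `cohort`;
#' optional `survival_days` and `event` (0/1); then one column per locus,
#' named as in `loci`, holding unordered allele pairs like `"A/G"`.
#'
#' Every allele is validated against the locus's major/minor pair; a
#' violation, a missing locus column or a duplicate `sample_id` is an error.
#' Missing genotype values are an error by default; set
#' `drop_incomplete = TRUE` to silently drop incomplete rows instead.
#'
#' @param path path to the delimited genotype table.
#' @param loci an `nps_loci` tibble ([loci_set()]).
#' @param drop_incomplete drop rows with missing genotypes instead of erroring.
#' @return A tibble with columns `sample_id`, `cohort`, `survival_days`,
#'   `event`, then one `"X/Y"` column per locus (cycle order); row order of
#'   the file is preserved.
#' @export
read_genotype_table <- function(path, loci, drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  validate_genotypes(tab, loci, drop_incomplete = drop_incomplete)
}

#' Validate a genotype data frame against a loci set
#'
#' @param genotypes data frame shaped as in [read_genotype_table()].
#' @inheritParams read_genotype_table
#' @return The validated, type-normalized tibble.
#' @export
validate_genotypes <- function(genotypes, loci, drop_incomplete = FALSE) {
  tab <- tibble::as_tibble(genotypes)
  for (col in c("sample_id", "cohort")) {
    if (!col %in% names(tab)) stop("genotype table missing column: ", col)
  }
  missing_loci <- setdiff(loci$name, names(tab))
  if (length(missing_loci)) {
    stop("genotype table missing locus columns: ",
         paste(missing_loci, collapse = ", "))
  }
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  tab$cohort <- as.character(tab$cohort)
  bad_cohort <- !tab$cohort %in% c("case", "control", "unknown")
  if (any(bad_cohort)) {
    stop("cohort labels must be case/control/unknown; offending rows: ",
         paste(utils::head(tab$sample_id[bad_cohort], 5), collapse = ", "))
  }
  tab$survival_days <- if ("survival_days" %in% names(tab)) {
    suppressWarnings(as.numeric(tab$survival_days))
  } else {
    NA_real_
  }
  if (any(!is.na(tab$survival_days) & tab$survival_days < 0)) {
    stop("negative survival_days")
  }
  tab$event <- if ("event" %in% names(tab)) {
    suppressWarnings(as.integer(tab$event))
  } else {
    NA_integer_
  }

  incomplete <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(loci))) {
    nm <- loci$name[i]
    g <- tab[[nm]]
    miss <- is.na(g) | g == "" | g == "./."
    incomplete <- incomplete | miss
    pair <- strsplit(ifelse(miss, "N/N", g), "/", fixed = TRUE)
    lens <- lengths(pair)
    if (any(lens != 2L & !miss)) {
      stop("malformed genotype at ", nm, " (expected 'X/Y'): ",
           paste(utils::head(g[lens != 2L & !miss], 3), collapse = ", "))
    }
    ok <- c(loci$major[i], loci$minor[i])
    a1 <- vapply(pair, `[`, "", 1L)
    a2 <- vapply(pair, `[`, "", 2L)
    bad <- !miss & (!(a1 %in% ok) | !(a2 %in% ok))
    if (any(bad)) {
      stop("allele not in {", ok[1], ",", ok[2], "} at locus ", nm,
           " for sample(s): ",
           paste(utils::head(tab$sample_id[bad], 5), collapse = ", "))
    }
  }
  if (any(incomplete)) {
    if (drop_incomplete) {
      tab <- tab[!incomplete, , drop = FALSE]
    } else {
      stop("missing genotypes for sample(s): ",
           paste(utils::head(tab$sample_id[incomplete], 5), collapse = ", "),
           " (set drop_incomplete = TRUE to drop them)")
    }
  }
  dplyr::select(tab, "sample_id", "cohort", "survival_days", "event",
                dplyr::all_of(loci$name))
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; round-trips valid tables exactly.
#'
#' @param genotypes validated genotype tibble.
#' @param path output path; `.tsv` extension selects tab, anything else comma.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  out <- genotypes
  if (all(is.na(out$survival_days))) out$survival_days <- NULL
  if (all(is.na(out$event))) out$event <- NULL
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read genotypes for a loci set from a VCF file
#'
#' Matches VCF records to loci by rsid in the ID column; takes GT per sample,
#' accepting both `/` and `|` separators (phase is discarded). Requires the
#' `vcfR` package.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param loci an `nps_loci` tibble; every rsid must appear in the VCF.
#' @param cohort cohort label(s) for the samples (recycled).
#' @return A genotype tibble as from [read_genotype_table()].
#' @export
read_genotype_vcf <- function(path, loci, cohort = "unknown") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotype_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  samples <- colnames(gt)
  out <- tibble::tibble(
    sample_id = samples,
    cohort = rep_len(cohort, length(samples))
  )
  for (i in seq_len(nrow(loci))) {
    j <- match(loci$rsid[i], ids)
    if (is.na(j)) stop("rsid not found in VCF: ", loci$rsid[i])
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    codes <- strsplit(gsub("|", "/", gt[j, ], fixed = TRUE), "/", fixed = TRUE)
    alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
    out[[loci$name[i]]] <- unname(vapply(codes, function(cd) {
      if (length(cd) != 2L || anyNA(cd) || any(cd == ".")) return(NA_character_)
      paste(alleles[as.integer(cd) + 1L], collapse = "/")
    }, ""))
  }
  validate_genotypes(out, loci)
}

allele_pair <- function(genotype) {
  strsplit(genotype, "/", fixed = TRUE)[[1]]
}

#' Zygosity state of one genotype at one locus
#'
#' Three-state coding: `"a"` homozygous major, `"ab"` heterozygous, `"b"`
#' homozygous minor. Symmetric in the order of the allele pair.
#'
#' @param genotype an `"X/Y"` allele-pair string (or vector of them).
#' @param major,minor the locus's alleles.
#' @return Character vector of states in `{"a","ab","b"}`.
#' @export
zygosity_state <- function(genotype, major, minor) {
  pair <- strsplit(genotype, "/", fixed = TRUE)
  vapply(pair, function(p) {
    n_minor <- sum(p == minor)
    c("a", "ab", "b")[n_minor + 1L]
  }, "")
}

#' Dominant-model state of one genotype at one locus
#'
#' Two-state coding under the dominant model: any copy of the minor allele
#' gives state `"b"`, otherwise `"a"`. Equivalently, collapses the
#' heterozygous state of [zygosity_state()] onto the minor vertex.
#'
#' @inheritParams zygosity_state
#' @return Character vector of states in `{"a","b"}`.
#' @export
dominant_state <- function(genotype, major, minor) {
  z <- zygosity_state(genotype, major, minor)
  ifelse(z == "a", "a", "b")
}
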