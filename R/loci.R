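#' Define a set of biallelic SNP loci
#'
#' A loci set is a tibble with one row per SNP and two independent locus
#' orders: `cycle_position` fixes where the locus sits in the closed genotype
#' cycle, `report_position` fixes the column order used for haplotype strings.
#' Both are 0-based permutations of `0..L-1`.
#'
#' @param name character, short locus labels (e.g. `"AG49"`).
#' @param rsid character, dbSNP identifiers.
#' @param major,minor single-character major/minor alleles per locus.
#' @param cycle_position,report_position integer 0-based positions; each must
#'   be a permutation of `0..L-1`.
#' @return A tibble of class `nps_loci`, sorted by `cycle_position`.
#' @examples
#' loci_set(
#'   name = c("L1", "L2", "L3"),
#'   rsid = c("rs1", "rs2", "rs3"),
#'   major = c("A", "C", "G"), minor = c("G", "T", "A"),
#'   cycle_position = 0:2, report_position = 0:2
#' )
#' @export
loci_set <- function(name, rsid, major, minor, cycle_position, report_position) {
  loci <- tibble::tibble(
    name = as.character(name),
    rsid = as.character(rsid),
    major = as.character(major),
    minor = as.character(minor),
    cycle_position = as.integer(cycle_position),
    report_position = as.integer(report_position)
  )
  validate_loci(loci)
}

validate_loci <- function(loci) {
  L <- nrow(loci)
  if (L < 3L) {
    stop("a loci set needs at least 3 loci to form a cycle, got ", L)
  }
  if (anyDuplicated(loci$name)) {
    stop("duplicate locus names: ",
         paste(unique(loci$name[duplicated(loci$name)]), collapse = ", "))
  }
  bad <- loci$major == loci$minor
  if (any(bad)) {
    stop("identical major and minor alleles at: ",
         paste(loci$name[bad], collapse = ", "))
  }
  if (!all(nchar(loci$major) == 1L) || !all(nchar(loci$minor) == 1L)) {
    stop("alleles must be single characters")
  }
  for (col in c("cycle_position", "report_position")) {
    pos <- loci[[col]]
    if (!setequal(pos, 0:(L - 1L))) {
      stop(col, " values must be a permutation of 0..", L - 1L)
    }
  }
  loci <- dplyr::arrange(loci, .data$cycle_position)
  class(loci) <- c("nps_loci", class(tibble::tibble()))
  loci
}

#' Read a loci configuration file
#'
#' Accepts YAML or JSON: a list of records with fields `name`, `rsid`,
#' `major`, `minor`, `cycle_position`, `report_position` (0-based).
#'
#' @param path path to a YAML or JSON loci configuration.
#' @return An `nps_loci` tibble (see [loci_set()]), in cycle order.
#' @export
read_loci_config <- function(path) {
  if (!file.exists(path)) stop("loci config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.data.frame(raw)) {
    recs <- raw
  } else {
    recs <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  }
  needed <- c("name", "rsid", "major", "minor", "cycle_position", "report_position")
  missing <- setdiff(needed, names(recs))
  if (length(missing)) {
    stop("loci config missing fields: ", paste(missing, collapse = ", "))
  }
  loci_set(recs$name, recs$rsid, recs$major, recs$minor,
           recs$cycle_position, recs$report_position)
}

#' Write a loci configuration file
#'
#' @param loci an `nps_loci` tibble.
#' @param path output path; format chosen by extension (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_loci_config <- function(loci, path) {
  recs <- purrr::transpose(as.list(dplyr::ungroup(tibble::as_tibble(loci))))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' The six CTLA-4 SNP loci
#'
#' The canonical six-locus set for the CTLA-4 gene region: CT60 (rs3087243),
#' AG49 (rs231775), CT318 (rs5742909), JO27 (rs11571297), JO30 (rs7565213)
#' and JO31 (rs11571302). The cycle order runs
#' CT318-AG49-CT60-JO30-JO27-JO31 (JO31 closes the hexagon); the reporting
#' order for haplotype strings is AG49, CT60, CT318, JO27, JO30, JO31.
#'
#' @return An `nps_loci` tibble with six rows.
#' @export
ctla4_loci <- function() {
  loci_set(
    name  = c("AG49", "CT60", "CT318", "JO27", "JO30", "JO31"),
    rsid  = c("rs231775", "rs3087243", "rs5742909", "rs11571297",
              "rs7565213", "rs11571302"),
    major = c("A", "A", "C", "C", "A", "T"),
    minor = c("G", "G", "T", "T", "G", "G"),
    cycle_position  = c(1L, 2L, 0L, 4L, 3L, 5L),
    report_position = c(0L, 1L, 2L, 3L, 4L, 5L)
  )
}

# loci names in report order (haplotype string column order)
report_order <- function(loci) {
  loci$name[order(loci$report_position)]
}

# loci names in cycle order (loci are stored sorted by cycle_position)
cycle_order <- function(loci) {
  loci$name
}
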