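#' Assemble a genotype-lifestyle survival cohort
#'
#' Bundles the three tables the analysis operates on: a genotype dosage
#' matrix (minor-allele counts 0/1/2, `NA` for missing calls), a covariate
#' table of lifestyle and anthropometric variables, and a right-censored
#' breast-cancer outcome (follow-up time in years and an event indicator).
#' All components must describe the same subjects in the same order.
#'
#' @param subjects Tibble with columns `subject_id`, `time_years` (> 0) and
#'   `event` (0/1), one row per subject.
#' @param genotypes Integer matrix, subjects x SNPs, entries in
#'   \{0, 1, 2, NA\}; column names are SNP identifiers.
#' @param covariates Tibble of covariate columns (continuous or categorical),
#'   one row per subject.
#' @param snp_info Optional tibble with `snp_id`, `gene` and `maf` columns;
#'   generated from the genotype matrix when omitted.
#'
#' @return An object of class `cohort`: a list with elements `data` (tibble
#'   combining subjects and covariates), `genotypes` and `snp_info`.
#' @export
cohort <- function(subjects, genotypes, covariates = NULL, snp_info = NULL) {
  subjects <- tibble::as_tibble(subjects)
  need <- c("subject_id", "time_years", "event")
  if (!all(need %in% names(subjects)))
    abort("subjects must have subject_id, time_years and event columns",
          class = "riskforest_format_error")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(subjects)
  if (nrow(genotypes) != n)
    abort("genotype and outcome tables have different subject counts",
          class = "riskforest_alignment_error")
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != n)
      abort("covariate and outcome tables have different subject counts",
            class = "riskforest_alignment_error")
  } else {
    covariates <- tibble::tibble(.rows = n)
  }
  if (anyDuplicated(subjects$subject_id))
    abort("subject ids must be unique", class = "riskforest_format_error")
  if (any(!is.finite(subjects$time_years)) || any(subjects$time_years <= 0))
    abort("follow-up time must be strictly positive",
          class = "riskforest_validation_error")
  if (!all(subjects$event %in% c(0L, 1L)))
    abort("event indicator must be 0/1",
          class = "riskforest_validation_error")
  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad))
    abort("genotype dosages must be 0, 1, 2 or missing",
          class = "riskforest_format_error")
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("SNP_", seq_len(ncol(genotypes)))
  if (is.null(snp_info)) {
    snp_info <- tibble::tibble(
      snp_id = colnames(genotypes),
      gene = NA_character_,
      maf = colMeans(genotypes, na.rm = TRUE) / 2
    )
  } else {
    snp_info <- tibble::as_tibble(snp_info)
    if (!all(colnames(genotypes) %in% snp_info$snp_id))
      abort("snp_info must describe every genotype column",
            class = "riskforest_format_error")
    snp_info <- snp_info[match(colnames(genotypes), snp_info$snp_id), ]
  }
  structure(
    list(
      data = dplyr::bind_cols(subjects[need], covariates),
      genotypes = genotypes,
      snp_info = snp_info
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", n_subjects(x), " subjects, ", sum(x$data$event),
      " events, ", ncol(x$genotypes), " SNPs, ",
      ncol(x$data) - 3L, " covariates\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A [cohort()] object.
#' @return Integer subject count.
#' @export
n_subjects <- function(x) nrow(x$data)

#' @export
dim.cohort <- function(x) c(nrow(x$data), ncol(x$genotypes))

#' Read a cohort from delimited files
#'
#' Reads the three tab-delimited cohort tables and joins them on subject id.
#' The genotype file has a header of SNP ids with the subject id in the first
#' column; missing genotype calls are coded `NA`. An optional JSON sidecar
#' schema declares covariate types (`"continuous"`/`"categorical"`), units,
#' and stratification specs.
#'
#' @param genotype_path,covariate_path,outcome_path Paths to the three
#'   tab-delimited tables. The outcome table must contain `subject_id`,
#'   `time_years` and `event` columns.
#' @param schema Optional path to a JSON schema, or an equivalent list.
#'
#' @return A validated [cohort()].
#' @export
read_cohort <- function(genotype_path, covariate_path = NULL, outcome_path,
                        schema = NULL) {
  geno <- readr::read_tsv(genotype_path, show_col_types = FALSE,
                          na = c("NA", ""))
  out <- readr::read_tsv(outcome_path, show_col_types = FALSE)
  cov <- if (!is.null(covariate_path))
    readr::read_tsv(covariate_path, show_col_types = FALSE) else NULL
  if (is.character(schema)) schema <- jsonlite::read_json(schema)

  id_col <- names(geno)[1]
  ids <- out$subject_id
  if (!setequal(geno[[id_col]], ids) ||
      (!is.null(cov) && !setequal(cov$subject_id, ids)))
    abort("subject ids differ across cohort files",
          class = "riskforest_alignment_error")
  geno <- geno[match(ids, geno[[id_col]]), , drop = FALSE]
  gmat <- as.matrix(geno[, -1, drop = FALSE])
  if (!is.null(cov)) {
    cov <- cov[match(ids, cov$subject_id), , drop = FALSE]
    cov$subject_id <- NULL
    if (!is.null(schema$covariates)) {
      for (nm in names(schema$covariates)) {
        type <- schema$covariates[[nm]]$type %||% "continuous"
        if (identical(type, "categorical") && nm %in% names(cov))
          cov[[nm]] <- factor(cov[[nm]])
      }
    }
  }
  cohort(out[c("subject_id", "time_years", "event")], gmat, cov)
}

#' Write a cohort to delimited files
#'
#' Writes the genotype, covariate and outcome tables in the dialect
#' [read_cohort()] expects, plus a JSON sidecar with SNP metadata.
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("genotypes.tsv", "covariates.tsv", "outcome.tsv",
                            "snp_info.json"))
  gt <- tibble::as_tibble(x$genotypes)
  gt <- dplyr::bind_cols(tibble::tibble(subject_id = x$data$subject_id), gt)
  readr::write_tsv(gt, paths[1])
  readr::write_tsv(dplyr::select(x$data, -"time_years", -"event"), paths[2])
  readr::write_tsv(
    dplyr::select(x$data, "subject_id", "time_years", "event"), paths[3])
  jsonlite::write_json(x$snp_info, paths[4], digits = NA)
  invisible(paths)
}

#' Extract subjects by row index
#' @noRd
subset_cohort <- function(x, idx) {
  cohort(x$data[idx, c("subject_id", "time_years", "event")],
         x$genotypes[idx, , drop = FALSE],
         x$data[idx, setdiff(names(x$data),
                             c("subject_id", "time_years", "event")),
                drop = FALSE],
         x$snp_info)
}

#' Flatten a cohort into a modelling frame
#'
#' Returns a single tibble with follow-up time, event indicator, covariates
#' and genotype dosages (missing calls imputed to the per-SNP mode, which
#' preserves the marginal genotype distribution), ready for the forest and
#' regression functions.
#'
#' @param x A [cohort()].
#' @param snps,covariates Optional character vectors restricting which SNP
#'   and covariate columns are included (default: all).
#' @return A tibble with `time_years`, `event` and one column per variable.
#' @export
as_analysis_frame <- function(x, snps = NULL, covariates = NULL) {
  stopifnot(inherits(x, "cohort"))
  snps <- snps %||% colnames(x$genotypes)
  covariates <- covariates %||%
    setdiff(names(x$data), c("subject_id", "time_years", "event"))
  g <- impute_genotypes_mode(x$genotypes[, snps, drop = FALSE])
  dplyr::bind_cols(
    x$data[c("subject_id", "time_years", "event")],
    x$data[covariates],
    tibble::as_tibble(g)
  )
}
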