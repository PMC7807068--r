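test_that("cohort round-trips through the delimited file dialect", {
  dir <- write_tiny_cohort_files()
  coh <- read_cohort(file.path(dir, "genotypes.tsv"),
                     file.path(dir, "covariates.tsv"),
                     file.path(dir, "outcome.tsv"))
  expect_s3_class(coh, "cohort")
  expect_equal(n_subjects(coh), 3)
  expect_equal(unname(coh$genotypes[, "rs1"]), c(0L, 1L, 2L))
  expect_true(is.na(coh$genotypes[1, "rs2"]))
  expect_equal(coh$data$time_years, c(4.2, 10.0, 16.5))

  out <- write_cohort(coh, tempfile("rt"))
  coh2 <- read_cohort(out[1], out[2], out[3])
  expect_equal(coh2$data, coh$data)
  expect_equal(coh2$genotypes, coh$genotypes)
})

test_that("misaligned and malformed inputs raise classed errors", {
  dir <- write_tiny_cohort_files()
  out <- readr::read_tsv(file.path(dir, "outcome.tsv"),
                         show_col_types = FALSE)
  readr::write_tsv(out[-2, ], file.path(dir, "outcome.tsv"))
  expect_error(
    read_cohort(file.path(dir, "genotypes.tsv"),
                file.path(dir, "covariates.tsv"),
                file.path(dir, "outcome.tsv")),
    class = "riskforest_alignment_error")

  subj <- tibble::tibble(subject_id = c("a", "b"), time_years = c(1, 2),
                         event = c(0L, 1L))
  expect_error(cohort(subj, matrix(c(0L, 3L), ncol = 1)),
               class = "riskforest_format_error")
  subj$time_years[1] <- 0
  expect_error(cohort(subj, matrix(c(0L, 1L), ncol = 1)),
               class = "riskforest_validation_error")
})

test_that("QC filter removes SNPs by missingness and HWE and is idempotent", {
  set.seed(1)
  n <- 400
  g_ok <- simulate_genotypes(n, setNames(rep(0.3, 3), paste0("ok", 1:3)),
                             seed = 2)
  g_miss <- g_ok[, 1]
  g_miss[sample(n, ceiling(0.03 * n))] <- NA  # 3% missing
  g_hwe1 <- c(rep(0L, 200), rep(2L, 200))     # no heterozygotes at all
  g_hwe2 <- rep(1L, n)                        # all heterozygotes
  g <- cbind(g_ok, bad_miss = g_miss, bad_hwe1 = g_hwe1, bad_hwe2 = g_hwe2)
  coh <- cohort(tibble::tibble(subject_id = paste0("s", 1:n),
                               time_years = runif(n, 1, 20),
                               event = rbinom(n, 1, 0.1)), g)
  filt <- qc_filter(coh)
  rep_tab <- qc_report(filt)
  expect_equal(sum(rep_tab$removed), 3)
  expect_setequal(rep_tab$snp_id[rep_tab$removed],
                  c("bad_miss", "bad_hwe1", "bad_hwe2"))
  expect_setequal(colnames(filt$genotypes), paste0("ok", 1:3))

  # compliant input passes unchanged; filtering twice equals filtering once
  again <- qc_filter(filt)
  expect_equal(again$genotypes, filt$genotypes)
  expect_false(any(qc_report(again)$removed))
})

test_that("stratification uses the printed boundary conventions", {
  n <- 7
  coh <- cohort(
    tibble::tibble(subject_id = paste0("s", 1:n),
                   time_years = 1:n, event = rep(c(0L, 1L), length.out = n)),
    matrix(0L, n, 1, dimnames = list(NULL, "rs1")),
    tibble::tibble(bmi = c(29.9, 30.0, 25, 31, 35, 28, 30.1),
                   whr = c(0.84, 0.85, 0.851, 0.7, 0.9, 0.85, 0.86),
                   met_h_wk = c(10, 9.9, 12, 0, 10.1, 5, 20))
  )
  st <- stratify(coh, stratum_spec("bmi", 30, "lt"))
  expect_true("s1" %in% st$low$data$subject_id)    # BMI 29.9 -> low
  expect_true("s2" %in% st$high$data$subject_id)   # BMI 30.0 -> high
  st <- stratify(coh, stratum_spec("whr", 0.85, "le"))
  expect_true("s2" %in% st$low$data$subject_id)    # WHR 0.85 -> low (<= rule)
  expect_true("s3" %in% st$high$data$subject_id)
  st <- stratify(coh, stratum_spec("met_h_wk", 10, "ge"))
  expect_true("s1" %in% st$low$data$subject_id)    # active >= 10 first group
  expect_true("s2" %in% st$high$data$subject_id)

  # partition completeness over random specs
  for (spec in default_strata()[c("bmi", "whr", "met")]) {
    st <- stratify(coh, spec)
    expect_equal(n_subjects(st$low) + n_subjects(st$high), n)
    expect_setequal(c(st$low$data$subject_id, st$high$data$subject_id),
                    coh$data$subject_id)
  }
  expect_error(stratify(coh, stratum_spec("nope", 1, "lt")),
               class = "riskforest_config_error")
})

test_that("mode imputation fills missing calls without changing the mode", {
  g <- matrix(c(0L, 0L, 1L, NA, 2L, NA, 2L, 2L), ncol = 2)
  imp <- impute_genotypes_mode(g)
  expect_false(anyNA(imp))
  expect_equal(imp[4, 1], 0L)  # mode of column 1
  expect_equal(imp[2, 2], 2L)  # mode of column 2
})
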