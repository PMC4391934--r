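# Cohort table I/O and the end-to-end pipeline.

cohort_numeric_cols <- c("ki67_sum", "ck_sum", "ki67_ck_ratio", "dfs_months",
                         "event", "age", "t_stage", "n_stage", "histo_grade")
cohort_domains <- list(
  menopausal = c("pre", "post"),
  er = c("positive", "negative"),
  her2 = c("amplified", "non-amplified"),
  t_stage = 1:3, n_stage = 0:3, histo_grade = 1:3, event = 0:1)

#' Write a cohort table
#'
#' Writes one row per patient as CSV (the canonical tabular dialect) or TSV,
#' selected by extension.
#'
#' @param cohort A cohort data frame (e.g. from [simulate_cohort()]).
#' @param path Output `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(cohort), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a per-patient CSV/TSV table, optionally renaming columns through
#' `column_map`, types and validates every row, and reports how many rows
#' were accepted and rejected. Mandatory columns are `patient_id`,
#' `ki67_sum` and `ck_sum`; a stored `ki67_ck_ratio` is cross-checked against
#' `ki67_sum / ck_sum` (1% tolerance) and recomputed. Rows failing any check
#' (non-numeric or negative sums, `ck_sum <= 0`, categorical values outside
#' their domain, inconsistent ratio) are rejected with a row-level log
#' message.
#'
#' @param path CSV or TSV file.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g.
#'   `c(ki67_sum = "Ki67 quantificational value")`.
#' @return An object of class `cohort_table`: list with `records` (validated
#'   cohort data frame), `n_read`, `n_rejected`, `log` (character vector of
#'   row-level messages) and `source`.
#' @export
read_cohort_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src))
      stop("schema error: mapped columns absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    idx <- match(unname(column_map), names(raw))
    names(raw)[idx] <- names(column_map)
  }
  mandatory <- c("patient_id", "ki67_sum", "ck_sum")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent))
    stop("schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  n_read <- nrow(raw)
  log <- character(0)
  keep <- rep(TRUE, n_read)
  out <- raw
  for (col in intersect(cohort_numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !(is.na(raw[[col]]) | raw[[col]] == "")
    if (any(bad)) {
      log <- c(log, sprintf("row %d: non-numeric %s ('%s')",
                            which(bad), col, raw[[col]][bad]))
      keep[bad] <- FALSE
    }
    out[[col]] <- v
  }
  chk <- function(bad, what) {
    bad <- which(bad & keep)
    if (length(bad)) {
      log <<- c(log, sprintf("row %d: %s", bad, what))
      keep[bad] <<- FALSE
    }
  }
  chk(!is.na(out$ki67_sum) & out$ki67_sum < 0, "negative ki67_sum")
  chk(is.na(out$ki67_sum), "missing ki67_sum")
  chk(is.na(out$ck_sum) | out$ck_sum <= 0, "missing or non-positive ck_sum")
  for (col in intersect(names(cohort_domains), names(out)))
    chk(!is.na(out[[col]]) & !(out[[col]] %in% cohort_domains[[col]]),
        paste("value outside domain of", col))
  if ("dfs_months" %in% names(out))
    chk(!is.na(out$dfs_months) & out$dfs_months <= 0, "non-positive dfs_months")
  if ("ki67_ck_ratio" %in% names(out)) {
    stored <- out$ki67_ck_ratio
    recomputed <- out$ki67_sum / out$ck_sum
    chk(!is.na(stored) & is.finite(recomputed) &
          abs(stored - recomputed) > 0.01 * pmax(recomputed, .Machine$double.eps),
        "stored ratio inconsistent with ki67_sum / ck_sum (> 1%)")
    out$ki67_ck_ratio <- recomputed
  } else {
    out$ki67_ck_ratio <- out$ki67_sum / out$ck_sum
  }
  records <- out[keep, , drop = FALSE]
  if (anyDuplicated(records$patient_id))
    stop("schema error: duplicate patient ids", call. = FALSE)
  rownames(records) <- NULL
  class(records) <- c("cohort", "data.frame")
  for (msg in log) message(msg)
  structure(list(records = records, n_read = n_read,
                 n_rejected = n_read - nrow(records), log = log, source = path),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort table: %d rows read from %s, %d accepted, %d rejected\n",
              x$n_read, x$source, nrow(x$records), x$n_rejected))
  invisible(x)
}

default_config <- function() {
  list(
    seed = 1,
    scene = list(enabled = TRUE, height = 128, width = 128, n_nests = 3,
                 nest_axes = c(12, 24), proliferation_fraction = 0.25,
                 noise_sd = 1, n_fields = 6),
    cohort = list(source = "simulate", n_patients = 240, log_hr = log(2)),
    grading = list(min_group_frac = 0.10,
                   biomarkers = c("ki67_sum", "ki67_ck_ratio")),
    survival = list(covariates = c("t_stage", "n_stage", "histo_grade",
                                   "er_positive", "her2_amplified")),
    roc = list(horizon = 60))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

# numeric covariate coding for the multivariate model: ordered stages as
# integer scores, binary factors as 0/1 indicators
code_covariates <- function(cohort) {
  data.frame(t_stage = cohort$t_stage,
             n_stage = cohort$n_stage,
             histo_grade = cohort$histo_grade,
             er_positive = as.integer(cohort$er == "positive"),
             her2_amplified = as.integer(cohort$her2 == "amplified"))
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end chain: simulate (or ingest) a cohort and an
#' optional demonstration imaging scene, unmix and quantify the scene,
#' dichotomise each biomarker at its best-P log-rank cut-point, and evaluate
#' the grades with Kaplan-Meier/log-rank, a multivariate Cox model and ROC
#' analysis. The run is fully deterministic for a fixed config and seed.
#'
#' @param config Either a YAML file path or a nested list overriding the
#'   defaults; see `ki67ck:::default_config()` for the sections (`seed`,
#'   `scene`, `cohort`, `grading`, `survival`, `roc`).
#' @param output_dir Optional directory; when given, result tables (cohort
#'   with grades, cut-point scans, Cox and ROC tables, KM curves) are written
#'   as CSV plus a JSON run manifest (config hash, seed, package version).
#' @param seed Optional integer overriding `config$seed`.
#' @return A report list with elements `cohort`, `cutpoints`, `imaging`
#'   (NULL when the scene stage is disabled), `km`, `logrank`, `cox`, `roc`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  if (!is.null(seed)) config$seed <- seed
  config$seed <- as.integer(config$seed)

  # --- imaging branch: simulate -> unmix -> quantify one demo core ---
  imaging <- NULL
  if (isTRUE(config$scene$enabled)) {
    sp_args <- config$scene[setdiff(names(config$scene), c("enabled", "n_fields"))]
    sp_args$seed <- config$seed * 1000L
    sp <- do.call(scene_params, sp_args)
    lib <- build_default_library()
    core <- simulate_core(sp, lib, n_fields = config$scene$n_fields)
    fq <- lapply(core$cubes, function(cb)
      quantify_field(drop_autofluorescence(unmix_cube(cb, lib))))
    cq <- aggregate_core(fq, expected_fields = config$scene$n_fields)
    imaging <- list(core_quant = cq, truth = core$truth,
                    ratio_recovery_error = abs(cq$ratio - core$truth$true_ratio) /
                      core$truth$true_ratio)
  }

  # --- cohort ---
  if (identical(config$cohort$source, "simulate")) {
    cp_args <- config$cohort[setdiff(names(config$cohort), c("source", "path", "column_map"))]
    cp_args$seed <- config$seed
    cohort <- simulate_cohort(do.call(cohort_params, cp_args))
    parse_log <- character(0)
  } else {
    tab <- read_cohort_table(config$cohort$path, config$cohort$column_map)
    cohort <- tab$records
    parse_log <- tab$log
  }
  if (is.null(cohort$dfs_months) || is.null(cohort$event))
    stop("stage cohort: follow-up columns (dfs_months, event) are required for survival analysis",
         call. = FALSE)

  # --- grading: best-P cut-point per biomarker ---
  cutpoints <- list()
  for (bm in config$grading$biomarkers) {
    cutpoints[[bm]] <- optimal_cutpoint(cohort[[bm]], cohort$dfs_months,
                                        cohort$event, config$grading$min_group_frac)
    cohort[[paste0(bm, "_grade")]] <- assign_grade(cohort[[bm]], cutpoints[[bm]]$cutoff)
  }

  # --- survival evaluation per grade ---
  km <- list(); lr <- list(); cox <- list()
  base_cov <- code_covariates(cohort)[, config$survival$covariates, drop = FALSE]
  for (bm in config$grading$biomarkers) {
    g <- cohort[[paste0(bm, "_grade")]]
    km[[bm]] <- lapply(split(seq_len(nrow(cohort)), g), function(i)
      km_fit(cohort$dfs_months[i], cohort$event[i]))
    lr[[bm]] <- logrank_test(cohort$dfs_months, cohort$event, g)
    cov <- cbind(base_cov, grade_ii = as.integer(g == "II"))
    names(cov)[ncol(cov)] <- paste0(bm, "_grade_ii")
    cox[[bm]] <- cox_fit(cohort$dfs_months, cohort$event, cov)
  }

  # --- ROC on recurrence within the horizon ---
  ro <- roc_outcome(cohort$dfs_months, cohort$event, config$roc$horizon)
  roc_factors <- c(stats::setNames(
    lapply(config$grading$biomarkers,
           function(bm) as.integer(cohort[[paste0(bm, "_grade")]] == "II")),
    paste0(config$grading$biomarkers, "_grade")),
    list(n_stage = cohort$n_stage, histo_grade = cohort$histo_grade,
         her2_amplified = as.integer(cohort$her2 == "amplified")))
  roc <- lapply(roc_factors, function(v) roc_auc(v[ro$keep], ro$outcome))

  manifest <- list(package = "ki67ck",
                   version = as.character(utils::packageVersion("ki67ck")),
                   seed = config$seed, config_md5 = config_hash(config),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   n_patients = nrow(cohort), parse_log = parse_log)

  report <- list(cohort = cohort, cutpoints = cutpoints, imaging = imaging,
                 km = km, logrank = lr, cox = cox, roc = roc,
                 manifest = manifest, config = config)
  if (!is.null(output_dir)) write_report(report, output_dir)
  invisible(report)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_table(report$cohort, file.path(output_dir, "cohort_with_grades.csv"))
  for (bm in names(report$cutpoints))
    utils::write.csv(report$cutpoints[[bm]]$scanned,
                     file.path(output_dir, sprintf("cutpoint_scan_%s.csv", bm)),
                     row.names = FALSE)
  for (bm in names(report$cox))
    utils::write.csv(as.data.frame(report$cox[[bm]]),
                     file.path(output_dir, sprintf("cox_%s.csv", bm)),
                     row.names = FALSE)
  for (bm in names(report$km))
    for (g in names(report$km[[bm]]))
      utils::write.csv(as.data.frame(report$km[[bm]][[g]]),
                       file.path(output_dir, sprintf("km_%s_grade_%s.csv", bm, g)),
                       row.names = FALSE)
  roc_tab <- data.frame(factor = names(report$roc),
                        auc = vapply(report$roc, `[[`, numeric(1), "auc"),
                        ci_low = vapply(report$roc, function(x) x$ci[1], numeric(1)),
                        ci_high = vapply(report$roc, function(x) x$ci[2], numeric(1)),
                        p = vapply(report$roc, `[[`, numeric(1), "p"))
  utils::write.csv(roc_tab, file.path(output_dir, "roc.csv"), row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
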