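ASSAY_COLUMNS <- c("compound", "drying_temp_C", "condition", "time_weeks",
                   "replicate", "concentration_ug_per_ml", "ph")

REPORT_SCHEMA_VERSION <- "1.0"

#' Read replicate-level assay samples from CSV
#'
#' Expects the assay schema
#' `compound,drying_temp_C,condition,time_weeks,replicate,concentration_ug_per_ml,ph`
#' (UTF-8, "." decimal separator). Malformed rows — non-numeric or negative
#' concentration, negative time, missing compound/condition — are rejected
#' with a warning naming the row and field; a missing column is an error.
#'
#' @param path CSV file path.
#' @return tibble of valid samples; rejected row messages in the
#'   `rejected` attribute.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(ASSAY_COLUMNS, "ph"), names(raw))
  if (length(missing_cols) > 0) {
    stop("assay CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"ph" %in% names(raw)) raw$ph <- NA_real_
  if (nrow(raw) == 0) {
    warning("assay CSV contains a header but no data rows", call. = FALSE)
    out <- tibble::as_tibble(raw[, ASSAY_COLUMNS])
    attr(out, "rejected") <- character(0)
    return(out)
  }

  num <- function(v) suppressWarnings(as.numeric(v))
  conc <- num(raw$concentration_ug_per_ml)
  tw <- num(raw$time_weeks)
  temp <- num(raw$drying_temp_C)
  rep_id <- num(raw$replicate)
  ph <- num(raw$ph)

  problems <- character(0)
  flag <- function(bad, field) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf("row %d: invalid %s", rows, field))
    }
    bad & !is.na(bad)
  }
  bad <- flag(is.na(conc), "concentration_ug_per_ml (non-numeric)")
  bad <- bad | flag(!is.na(conc) & conc < 0, "concentration_ug_per_ml (negative)")
  bad <- bad | flag(is.na(tw), "time_weeks (non-numeric)")
  bad <- bad | flag(!is.na(tw) & tw < 0, "time_weeks (negative)")
  bad <- bad | flag(is.na(temp), "drying_temp_C (non-numeric)")
  bad <- bad | flag(is.na(rep_id), "replicate (non-numeric)")
  bad <- bad | flag(!nzchar(trimws(raw$compound)), "compound (empty)")
  bad <- bad | flag(!nzchar(trimws(raw$condition)), "condition (empty)")

  if (length(problems) > 0) {
    warning(length(problems), " malformed row value(s) rejected:\n  ",
            paste(head(problems, 10), collapse = "\n  "),
            if (length(problems) > 10) "\n  ..." else "", call. = FALSE)
  }
  keep <- !bad
  out <- tibble::tibble(
    compound = trimws(raw$compound[keep]),
    drying_temp_C = temp[keep],
    condition = trimws(raw$condition[keep]),
    time_weeks = tw[keep],
    replicate = as.integer(rep_id[keep]),
    concentration_ug_per_ml = conc[keep],
    ph = ph[keep]
  )
  attr(out, "rejected") <- problems
  out
}

#' Read a flat key-value configuration file
#'
#' Minimal flat `key = value` format (a TOML subset): one assignment per
#' line, `#` comments, numeric and comma-separated list values coerced,
#' quoted strings unquoted. Keys mirror [study_design()] fields
#' (`time_frames_weeks`, `n_replicates`, `compounds`, `drying_temps_C`,
#' `conditions`, `noise_sd`, `seed`) plus pipeline options (`aggregation`,
#' `input`).
#'
#' @param path config file path.
#' @return named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config parse error, expected 'key = value': ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parts <- gsub('^"|"$', "", parts)
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(nums))) nums else parts
  }
  out
}

analyze_cell <- function(samples, compound, drying_temp_C, condition,
                         aggregation = "per_time_means",
                         control = classify_control(),
                         conformity_r2 = 0.8) {
  record <- list(compound = compound, drying_temp_C = drying_temp_C,
                 condition = condition)
  tryCatch({
    ser <- to_series(samples, compound, drying_temp_C, condition,
                     aggregation = aggregation)
    rel <- classify_relation(ser, control)
    est <- estimate_shelf_life(rel)

    keep <- samples$compound == compound &
      samples$drying_temp_C == drying_temp_C &
      samples$condition == condition
    cell <- samples[keep, , drop = FALSE]
    mean_by_time <- tapply(cell$concentration_ug_per_ml, cell$time_weeks, mean)
    conf <- tryCatch(
      conformity_test(as.numeric(names(mean_by_time)),
                      as.numeric(mean_by_time), r2_threshold = conformity_r2),
      error = function(e) NULL)
    aov_tab <- tryCatch(
      one_way_anova(cell$concentration_ug_per_ml, cell$time_weeks),
      error = function(e) NULL)
    ph_mean <- if (all(is.na(cell$ph))) NA_real_ else mean(cell$ph, na.rm = TRUE)

    record$relation <- rel$label
    record$model <- serialize_model(rel)
    record$shelf_life <- serialize_estimate(est)
    record$conformity <- if (is.null(conf)) NULL else
      list(conforms = conf$conforms, reason = conf$reason,
           best_order_n = if (is.null(conf$best_order)) NULL else conf$best_order$order_n)
    record$anova <- if (is.null(aov_tab)) NULL else list(
      ss_treatment = aov_tab$ss_treatment, ss_error = aov_tab$ss_error,
      ss_total = aov_tab$ss_total, df_treatment = aov_tab$df_treatment,
      df_error = aov_tab$df_error, f_stat = aov_tab$f_stat,
      p_value = aov_tab$p_value, ttv_percent = aov_tab$ttv_percent,
      significance = significance_label(aov_tab$p_value)
    )
    record$ph_mean <- ph_mean
    record
  }, error = function(e) {
    record$error <- conditionMessage(e)
    record
  })
}

serialize_model <- function(rel) {
  q <- rel$quadratic
  l <- rel$linear
  list(
    quadratic = if (is.null(q)) NULL else list(
      a = q$a, b = q$b, c = q$c, r_squared = q$r_squared,
      r_squared_display = round(q$r_squared, 2), n_points = q$n_points),
    linear = if (is.null(l)) NULL else list(
      slope = l$slope, intercept = l$intercept, r_squared = l$r_squared,
      r_squared_display = round(l$r_squared, 2), n_points = l$n_points)
  )
}

serialize_estimate <- function(est) {
  if (!est$predictable) {
    return(list(predictable = FALSE, reason = est$reason))
  }
  list(predictable = TRUE,
       extremum_x = est$extremum_x,
       root_neg = est$root_neg, root_pos = est$root_pos,
       x3 = est$x3,
       shelf_life_weeks = est$shelf_life_weeks,
       shelf_life_weeks_display = est$shelf_life_weeks_rounded,
       extrapolated = est$extrapolated,
       reason = est$reason)
}

#' Run the full storage-stability analysis pipeline
#'
#' For each treatment cell present in the data: aggregate and log3-encode
#' the series, fit and classify the trajectory, derive the shelf-life where
#' the positive-quadratic construction applies, test Arrhenius conformity on
#' per-time mean concentrations in real weeks, and run the one-way
#' time-frame ANOVA on replicate-level data. Failures in one cell are
#' contained in that cell's record.
#'
#' @param samples assay tibble ([generate_assay()] / [read_samples()]); if
#'   `NULL`, data are generated from `design` and `trajectories`.
#' @param design a [study_design()] used when `samples` is `NULL`.
#' @param trajectories trajectory list used when `samples` is `NULL`.
#' @param aggregation series aggregation for trajectory fits.
#' @param control classification thresholds ([classify_control()]).
#' @param conformity_r2 R-squared threshold for [conformity_test()].
#' @return a `study_report` list.
#' @export
run_pipeline <- function(samples = NULL, design = study_design(),
                         trajectories = default_trajectories(),
                         aggregation = c("per_time_means", "replicate_level"),
                         control = classify_control(),
                         conformity_r2 = 0.8) {
  aggregation <- match.arg(aggregation)
  generated <- is.null(samples)
  if (generated) samples <- generate_assay(design, trajectories)
  if (nrow(samples) == 0) {
    warning("no samples to analyze; report has zero cells", call. = FALSE)
    cells <- data.frame(compound = character(0), drying_temp_C = numeric(0),
                        condition = character(0))
  } else {
    cells <- unique(samples[, c("compound", "drying_temp_C", "condition")])
    cells <- cells[order(cells$compound, cells$drying_temp_C, cells$condition), ]
  }
  records <- lapply(seq_len(nrow(cells)), function(i) {
    analyze_cell(samples, cells$compound[i], cells$drying_temp_C[i],
                 cells$condition[i], aggregation = aggregation,
                 control = control, conformity_r2 = conformity_r2)
  })
  names(records) <- vapply(seq_len(nrow(cells)), function(i) {
    cell_key(cells$compound[i], cells$drying_temp_C[i], cells$condition[i])
  }, character(1))
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    software = list(package = "phytoshelf",
                    version = as.character(utils::packageVersion("phytoshelf"))),
    generation = list(generated = generated,
                      seed = if (generated) design$seed else NULL,
                      noise_sd = if (generated) design$noise_sd else NULL,
                      aggregation = aggregation),
    n_samples = nrow(samples),
    cells = records
  ), class = "study_report")
}

#' Write a study report as JSON
#'
#' Numbers are serialized at full precision; display-rounded companions
#' (whole weeks, two-decimal R-squared) are embedded per cell.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a study report back from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return a `study_report` list.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(rep, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> schema", x$schema_version, "-", length(x$cells),
      "cell(s),", x$n_samples, "samples\n")
  for (key in names(x$cells)) {
    rec <- x$cells[[key]]
    if (!is.null(rec$error)) {
      cat(sprintf("  %-18s ERROR: %s\n", key, rec$error))
      next
    }
    sl <- rec$shelf_life
    cat(sprintf("  %-18s %-19s %s\n", key, rec$relation,
                if (isTRUE(sl$predictable))
                  sprintf("shelf-life ~ %s weeks%s",
                          format(sl$shelf_life_weeks_display),
                          if (isTRUE(sl$extrapolated)) " (extrapolated)" else "")
                else "shelf-life not predictable"))
  }
  invisible(x)
}
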