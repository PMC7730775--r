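#' Reproduce the county-level HPV vaccination analysis end-to-end
#'
#' Runs the full configurational workflow on a table holding the school
#' delivery factor, four binary information channels and the dichotomized
#' uptake outcome: screens factors for variation, computes diversity indices,
#' builds the six analytic samples induced by pairing the four channels into a
#' meta-factor, fits [cna()] in every sample for the outcome present
#' (`HI_UPTAKE=1`) *and* absent (`HI_UPTAKE=0`, same settings — conditions
#' preventing an outcome may differ from those producing it), pools the
#' distinct models per outcome, extracts common cores, tabulates potentially
#' backfiring channels, and runs a fit-robustness scan.
#'
#' @param x a [config_table()] containing `outcome` and all factors in
#'   `c(schools, channels)` — e.g. [hpv_fixture()] — or a raw data.frame plus
#'   a [calibration_spec()] via `calibration`.
#' @param con,cov,maxstep search settings, see [cna()]; both outcome analyses
#'   use the same settings.
#' @param channels the four binary information-channel factors.
#' @param schools the multi-value school-delivery factor.
#' @param outcome the binary outcome factor.
#' @param calibration optional [calibration_spec()] applied to `x` first.
#' @param robustness_grid thresholds for the fit-robustness scan on the
#'   unpaired table (default `c(0.8, 0.9, 1)`); `NULL` skips the scan.
#' @param checklist named list of free-text entries for the reporting
#'   recommendations that are substantive rather than computational
#'   (`rationale_method`, `rationale_factors`, `rationale_final_model`);
#'   anything not supplied is marked "user-supplied".
#' @return an object of class `"hpv_study"`; see [render_report()].
#' @examples
#' \donttest{
#' rep <- run_hpv_study(hpv_fixture())
#' rep
#' }
#' @export
run_hpv_study <- function(x, con = 1, cov = 1, maxstep = c(3L, 4L, 10L),
                          channels = c("SBI", "MC", "SM", "CCY"),
                          schools = "SCHOOLS", outcome = "HI_UPTAKE",
                          calibration = NULL, robustness_grid = c(0.8, 0.9, 1),
                          checklist = list()) {
  if (!is.null(calibration)) x <- apply_calibration(x, calibration, outcome = outcome)
  if (!is_config_table(x)) x <- config_table(x, outcome = outcome)
  required <- c(schools, channels, outcome)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("required factor missing from table: ", missing[1], call. = FALSE)
  }

  screening <- screen_factors(x)
  explanatory <- c(schools, sort(channels))
  diversity <- list(
    selected_factors = diversity_index(x, explanatory),
    selected_space = space_size(x, explanatory))

  samples <- make_analytic_samples(x, channels)
  pos_lit <- paste0(outcome, "=1")
  neg_lit <- paste0(outcome, "=0")
  fits <- lapply(samples, function(s) {
    list(positive = cna(s, pos_lit, con = con, cov = cov, maxstep = maxstep),
         negative = cna(s, neg_lit, con = con, cov = cov, maxstep = maxstep))
  })

  pool <- function(side) {
    models <- unlist(lapply(fits, function(f) asf(f[[side]])), recursive = FALSE)
    if (length(models) == 0L) return(list())
    keys <- vapply(models, model_key, "")
    models <- models[!duplicated(keys)]
    models[order(vapply(models, model_key, ""))]
  }
  pooled_pos <- pool("positive")
  pooled_neg <- pool("negative")

  core_pos <- if (length(pooled_pos)) common_core(pooled_pos) else NULL
  core_neg <- if (length(pooled_neg)) common_core(pooled_neg) else NULL
  core_checks <- list(
    positive = if (length(pooled_pos)) {
      vapply(pooled_pos, function(m) is_submodel(core_pos, m$condition), TRUE)
    } else logical(),
    negative = if (length(pooled_neg)) {
      vapply(pooled_neg, function(m) is_submodel(core_neg, m$condition), TRUE)
    } else logical())

  backfire <- summarize_backfire(x, pooled_pos, outcome = pos_lit)

  robustness <- if (!is.null(robustness_grid)) {
    robustness_scan(x, pos_lit, con_grid = robustness_grid, maxstep = maxstep)
  }

  n_models <- function(side) {
    vapply(fits, function(f) length(asf(f[[side]])), 1L)
  }
  supplied <- function(key) checklist[[key]] %||% "user-supplied"
  checklist_items <- list(
    `1_rationale_method` = supplied("rationale_method"),
    `2_rationale_factors` = supplied("rationale_factors"),
    `3_calibration_process` = if (is.null(calibration)) {
      "table supplied pre-calibrated (see calibration echo)"
    } else "calibration spec applied (see calibration echo)",
    `4_software_version` = paste0("coinca ", software_version()),
    `5_iterations` = paste0("six analytic samples from channel pairings: ",
                            paste(names(samples), collapse = ", ")),
    `6_model_counts` = sprintf(
      "models per sample (%s=1): %s; (%s=0): %s; pooled distinct: %d positive, %d negative",
      outcome, paste(n_models("positive"), collapse = "/"),
      outcome, paste(n_models("negative"), collapse = "/"),
      length(pooled_pos), length(pooled_neg)),
    `7_thresholds` = threshold_ranges_text(con, cov, pooled_pos, pooled_neg, robustness),
    `8_rationale_final_model` = supplied("rationale_final_model"))

  structure(list(
    calibration = calibration,
    settings = list(con = con, cov = cov, maxstep = as.integer(maxstep),
                    channels = channels, schools = schools, outcome = outcome),
    screening = screening,
    diversity = diversity,
    samples = samples,
    fits = fits,
    pooled = list(positive = pooled_pos, negative = pooled_neg),
    cores = list(positive = core_pos, negative = core_neg),
    core_checks = core_checks,
    backfire = backfire,
    robustness = robustness,
    checklist = checklist_items),
    class = "hpv_study")
}

software_version <- function() {
  as.character(utils::packageVersion("coinca"))
}

threshold_ranges_text <- function(con, cov, pooled_pos, pooled_neg, robustness) {
  base <- sprintf("final-model thresholds: con >= %s, cov >= %s", con, cov)
  if (!is.null(robustness) && nrow(robustness) > 0L) {
    grid <- attr(robustness, "grid")
    base <- paste0(base, sprintf(
      "; scanned ranges for non-final models: con in [%s, %s], cov in [%s, %s]",
      min(grid$con), max(grid$con), min(grid$cov), max(grid$cov)))
  }
  base
}

#' Cross-tabulate potentially backfiring channels
#'
#' For every channel that appears negated (at level 0) in any of the pooled
#' models, counts the cases where the channel was actually present (level 1)
#' against the outcome, and lists the exception cases — channel present *and*
#' outcome present. A channel that is present mostly in outcome-absent cases
#' is a candidate backfiring strategy. Meta-factor names of the form `A_or_B`
#' are resolved through their source columns when not in the table.
#'
#' @param x the base [config_table()].
#' @param models list of pooled `"cna_model"`s sharing one outcome.
#' @param outcome outcome literal text (defaults to the models' outcome).
#' @return a data.frame with one row per negated channel: `channel`,
#'   `n_present`, `n_without_outcome`, `exceptions` (comma-separated ids).
#' @export
summarize_backfire <- function(x, models, outcome = NULL) {
  stopifnot(is_config_table(x))
  empty <- data.frame(channel = character(), n_present = integer(),
                      n_without_outcome = integer(), exceptions = character(),
                      stringsAsFactors = FALSE)
  if (length(models) == 0L) return(empty)
  if (is.null(outcome)) {
    outcome <- models[[1]]$outcome
  }
  out <- outcome_indicator(outcome, x)
  negated <- sort(unique(unlist(lapply(models, function(m) {
    unlist(lapply(unclass(as_condition(m)), function(conj) {
      names(conj)[conj == 0L]
    }))
  }))))
  rows <- list()
  for (ch in negated) {
    if (ch %in% names(x)) {
      present <- x[[ch]] == 1L
    } else if (grepl("_or_", ch, fixed = TRUE)) {
      parts <- strsplit(ch, "_or_", fixed = TRUE)[[1]]
      if (!all(parts %in% names(x))) next
      present <- Reduce(`|`, lapply(parts, function(p) x[[p]] == 1L))
    } else {
      next
    }
    if (!any(present)) {
      warning("channel ", ch, " is never present; tabulation row is all zero",
              call. = FALSE)
    }
    exceptions <- case_ids(x)[present & out]
    rows[[ch]] <- data.frame(
      channel = ch,
      n_present = sum(present),
      n_without_outcome = sum(present & !out),
      exceptions = paste(exceptions, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out_df <- do.call(rbind, rows)
  row.names(out_df) <- NULL
  out_df
}

#' @export
print.hpv_study <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

#' Render a study report
#'
#' Emits the full study report — calibration echo, screening, diversity,
#' per-sample model counts, pooled model listings in the field's notation with
#' exact-fraction and 2 d.p. fit scores, common cores, backfire tabulation,
#' robustness scan, and the eight-item reporting checklist — as human-readable
#' text or as JSON (which parses back to the same content).
#'
#' @param report an `"hpv_study"` object from [run_hpv_study()].
#' @param format `"text"` or `"json"`.
#' @return a character scalar.
#' @export
render_report <- function(report, format = c("text", "json")) {
  stopifnot(inherits(report, "hpv_study"))
  format <- match.arg(format)
  if (format == "json") return(report_json(report))
  report_text(report)
}

report_text <- function(r) {
  model_lines <- function(models, indent = "    ") {
    if (length(models) == 0L) return(paste0(indent, "(none)"))
    vapply(models, function(m) {
      sprintf("%s%s  [con %s, cov %s]", indent, format(m),
              format(m$consistency), format(m$coverage))
    }, "")
  }
  lines <- c(
    "Configurational study report (coincidence analysis)",
    sprintf("software: coinca %s", software_version()),
    "",
    sprintf("settings: con >= %s, cov >= %s, maxstep = (%s)",
            r$settings$con, r$settings$cov,
            paste(r$settings$maxstep, collapse = ", ")),
    sprintf("factors: %s (multi-value), channels %s, outcome %s",
            r$settings$schools, paste(r$settings$channels, collapse = "/"),
            r$settings$outcome),
    "",
    "factor screen:",
    sprintf("  constant: %s", if (length(r$screening$constant))
      paste(r$screening$constant, collapse = ", ") else "none"),
    sprintf("  limited variation: %s", if (length(r$screening$limited_variation))
      paste(r$screening$limited_variation, collapse = ", ") else "none"),
    sprintf("diversity index over selected factors: %s of %d configurations",
            format(r$diversity$selected_factors), r$diversity$selected_space),
    "",
    sprintf("analytic samples (%d):", length(r$samples)))
  for (nm in names(r$samples)) {
    f <- r$fits[[nm]]
    lines <- c(lines, sprintf("  %s: %d positive / %d negative models",
                              nm, length(asf(f$positive)), length(asf(f$negative))))
  }
  lines <- c(lines, "",
             sprintf("pooled models, %s=1 (%d):", r$settings$outcome,
                     length(r$pooled$positive)),
             model_lines(r$pooled$positive),
             sprintf("pooled models, %s=0 (%d):", r$settings$outcome,
                     length(r$pooled$negative)),
             model_lines(r$pooled$negative),
             "",
             sprintf("common core (%s=1): %s", r$settings$outcome,
                     if (is.null(r$cores$positive)) "none"
                     else format(r$cores$positive)),
             sprintf("common core (%s=0): %s", r$settings$outcome,
                     if (is.null(r$cores$negative)) "none"
                     else format(r$cores$negative)))
  if (nrow(r$backfire) > 0L) {
    lines <- c(lines, "", "negated-channel tabulation:")
    for (i in seq_len(nrow(r$backfire))) {
      b <- r$backfire[i, ]
      lines <- c(lines, sprintf(
        "  %s: present in %d cases, %d without the outcome%s",
        b$channel, b$n_present, b$n_without_outcome,
        if (nzchar(b$exceptions)) paste0(" (exceptions: ", b$exceptions, ")") else ""))
    }
  }
  if (!is.null(r$robustness)) {
    lines <- c(lines, "", "fit-robustness (recurrence across threshold grid):")
    if (nrow(r$robustness) == 0L) {
      lines <- c(lines, "  (no models on the grid)")
    } else {
      lines <- c(lines, sprintf("  %.2f  %s", r$robustness$score,
                                r$robustness$model))
    }
  }
  lines <- c(lines, "", "reporting checklist:")
  for (key in names(r$checklist)) {
    lines <- c(lines, sprintf("  (%s) %s", sub("_.*", "", key),
                              paste0(sub("^[0-9]+_", "", key), ": ",
                                     r$checklist[[key]])))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

report_json <- function(r) {
  frac_rec <- function(f) {
    if (is.null(f)) NULL
    else list(num = f$num, den = f$den, decimal = round_half_up(f))
  }
  payload <- list(
    software = paste0("coinca ", software_version()),
    settings = r$settings,
    calibration = if (is.null(r$calibration)) NULL else unclass(r$calibration),
    screening = list(constant = as.list(r$screening$constant),
                     limited_variation = as.list(r$screening$limited_variation),
                     min_minority_count = r$screening$min_minority_count),
    diversity = list(selected_factors = frac_rec(r$diversity$selected_factors),
                     selected_space = r$diversity$selected_space),
    samples = lapply(names(r$samples), function(nm) {
      f <- r$fits[[nm]]
      list(name = nm,
           positive_models = lapply(asf(f$positive), model_record),
           negative_models = lapply(asf(f$negative), model_record))
    }),
    pooled = list(positive = lapply(r$pooled$positive, model_record),
                  negative = lapply(r$pooled$negative, model_record)),
    cores = list(
      positive = if (is.null(r$cores$positive)) NULL else format(r$cores$positive),
      negative = if (is.null(r$cores$negative)) NULL else format(r$cores$negative),
      checks = r$core_checks),
    backfire = r$backfire,
    robustness = if (is.null(r$robustness)) NULL else {
      list(grid = attr(r$robustness, "grid"),
           scores = as.data.frame(r$robustness))
    },
    checklist = r$checklist)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   dataframe = "rows", null = "null")
}

#' Write all study outputs to a directory
#'
#' Writes `report.json`, `report.txt`, `models_pos.txt` and `models_neg.txt`.
#'
#' @param report an `"hpv_study"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hpv_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(render_report(report, "text"), file.path(dir, "report.txt"))
  writeLines(render_report(report, "json"), file.path(dir, "report.json"))
  model_listing <- function(models) {
    if (length(models) == 0L) return(character())
    vapply(models, function(m) {
      sprintf("%s  [con %s, cov %s]", format(m), format(m$consistency),
              format(m$coverage))
    }, "")
  }
  writeLines(model_listing(report$pooled$positive), file.path(dir, "models_pos.txt"))
  writeLines(model_listing(report$pooled$negative), file.path(dir, "models_neg.txt"))
  invisible(dir)
}
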