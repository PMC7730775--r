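#' Dichotomize a raw numeric measurement at a cut value
#'
#' Turns a per-case numeric measurement (e.g. a vaccination uptake percentage
#' on a 0-100 scale) into a crisp binary factor. With
#' `direction = "at_or_above"` (the default) a case is coded 1 exactly when its
#' value is greater than or equal to `cut` — the cut itself counts as present,
#' so a county at exactly the 65% uptake threshold is coded high-uptake.
#'
#' @param raw numeric vector of raw values; missing values are an error, not
#'   imputed (names, if present, are used in error messages).
#' @param cut numeric threshold.
#' @param direction `"at_or_above"` codes `raw >= cut` as 1;
#'   `"below"` codes `raw < cut` as 1.
#' @return an integer vector of 0/1 levels.
#' @examples
#' dichotomize(c(84, 65, 64.999, 49), cut = 65)
#' @export
dichotomize <- function(raw, cut, direction = c("at_or_above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(raw), length(raw) >= 1L,
            is.numeric(cut), length(cut) == 1L, is.finite(cut))
  if (any(!is.finite(raw))) {
    bad <- which(!is.finite(raw))[1]
    lab <- if (!is.null(names(raw))) names(raw)[bad] else paste("case", bad)
    stop("missing or non-finite raw value for ", lab, call. = FALSE)
  }
  if (direction == "at_or_above") as.integer(raw >= cut) else as.integer(raw < cut)
}

#' Recode two binary school-delivery factors into one ordinal factor
#'
#' Collapses "vaccine offered in all schools" (`as_col`) and "vaccine offered
#' in some schools" (`ss_col`) into a single trivalent ordinal factor:
#' 0 = no school delivery, 1 = some schools only, 2 = all schools. All-schools
#' delivery dominates: level 2 is assigned whenever `as_col` is 1, regardless
#' of `ss_col`.
#'
#' @param as_col,ss_col binary integer vectors of equal length, in the same
#'   case order.
#' @return an integer vector with levels in \{0, 1, 2\}.
#' @examples
#' recode_schools(as_col = c(0, 0, 1, 1), ss_col = c(0, 1, 0, 1))
#' @export
recode_schools <- function(as_col, ss_col) {
  check_binary(as_col, "as_col")
  check_binary(ss_col, "ss_col")
  stopifnot(length(as_col) == length(ss_col))
  ifelse(as_col == 1L, 2L, ifelse(ss_col == 1L, 1L, 0L))
}

check_binary <- function(v, what) {
  if (!is.numeric(v) || any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop(what, " must be binary (0/1) with no missing values", call. = FALSE)
  }
  invisible(as.integer(v))
}

#' Aggregate two binary factors into a meta-factor (logical OR)
#'
#' A meta-factor is present in a case if, and only if, at least one of the two
#' aggregated source factors is present — the standard configurational device
#' for reducing the factor count without dropping either property from the
#' analysis.
#'
#' `aggregate_meta_factor()` works on bare columns; `add_meta_factor()` appends
#' the aggregated column to a [config_table()], dropping the two sources, under
#' the collision-free name `A_or_B` (sources in the order given).
#'
#' @param a,b binary integer vectors (same case order).
#' @return integer 0/1 vector.
#' @examples
#' aggregate_meta_factor(c(1, 0, 0), c(0, 0, 1))
#' @export
aggregate_meta_factor <- function(a, b) {
  check_binary(a, "first factor")
  check_binary(b, "second factor")
  stopifnot(length(a) == length(b))
  as.integer(a | b)
}

#' @rdname aggregate_meta_factor
#' @param x a [config_table()].
#' @param f1,f2 names of the binary source factors.
#' @param name name for the meta-factor; default `paste0(f1, "_or_", f2)`.
#' @export
add_meta_factor <- function(x, f1, f2, name = paste0(f1, "_or_", f2)) {
  stopifnot(is_config_table(x))
  for (f in c(f1, f2)) {
    if (!f %in% names(x)) stop("factor ", f, " not in table", call. = FALSE)
  }
  check_factor_name(name)
  if (name %in% setdiff(names(x), c(f1, f2))) {
    stop("meta-factor name ", name, " collides with an existing factor",
         call. = FALSE)
  }
  df <- as.data.frame(x)
  meta <- aggregate_meta_factor(df[[f1]], df[[f2]])
  df <- df[setdiff(names(df), c(f1, f2))]
  df[[name]] <- meta
  config_table(df, case_ids = case_ids(x), outcome = outcome_factor(x))
}

#' Screen factors for constant or limited variation
#'
#' A factor observed at a single level across all cases cannot make a
#' difference to any outcome and can be excluded a priori; a factor whose
#' minority levels occur in fewer than `min_minority_count` cases carries very
#' limited variation. The screen only reports — it never mutates the table, so
#' exclusions remain an explicit, auditable user decision.
#'
#' @param x a [config_table()].
#' @param min_minority_count minimum number of cases required outside the
#'   modal level for a factor to count as varying (default 2).
#' @return an object of class `"factor_screen"`: a list with character vectors
#'   `constant` and `limited_variation`, plus the per-factor level counts.
#' @export
screen_factors <- function(x, min_minority_count = 2L) {
  stopifnot(is_config_table(x), min_minority_count >= 1L)
  counts <- lapply(as.data.frame(x), function(v) table(v))
  constant <- names(counts)[vapply(counts, length, 1L) == 1L]
  minority <- vapply(counts, function(tb) {
    if (length(tb) == 1L) return(NA_integer_)
    as.integer(sum(tb) - max(tb))
  }, 1L)
  limited <- names(counts)[!is.na(minority) & minority < min_minority_count]
  structure(list(constant = constant,
                 limited_variation = limited,
                 min_minority_count = as.integer(min_minority_count),
                 level_counts = counts),
            class = "factor_screen")
}

#' @export
print.factor_screen <- function(x, ...) {
  cat("Factor variation screen (min minority count:", x$min_minority_count, ")\n")
  cat("  constant:          ",
      if (length(x$constant)) paste(x$constant, collapse = ", ") else "none", "\n")
  cat("  limited variation: ",
      if (length(x$limited_variation)) paste(x$limited_variation, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Size of the logically possible configuration space
#'
#' The number of logically possible configurations of a set of factors is the
#' product of their domain sizes: 11 binary factors and one trivalent factor
#' span `2^11 * 3 = 6144` configurations; 4 binary plus one trivalent span 48.
#'
#' @param x a [config_table()], a named list of domain vectors, or an integer
#'   vector of domain sizes.
#' @param factors optional subset of factor names.
#' @return a numeric count (exact for all realistic sizes).
#' @examples
#' space_size(c(rep(2, 11), 3))
#' @export
space_size <- function(x, factors = NULL) {
  sizes <- domain_sizes(x, factors)
  prod(sizes)
}

domain_sizes <- function(x, factors = NULL) {
  if (is_config_table(x)) x <- factor_domains(x)
  if (is.list(x)) {
    if (!is.null(factors)) {
      missing <- setdiff(factors, names(x))
      if (length(missing)) stop("unknown factor: ", missing[1], call. = FALSE)
      x <- x[factors]
    }
    sizes <- vapply(x, function(d) length(unique(d)), 1L)
  } else {
    sizes <- as.integer(x)
  }
  if (length(sizes) < 1L) stop("need at least one factor", call. = FALSE)
  if (any(sizes < 2L)) stop("every factor domain needs >= 2 levels", call. = FALSE)
  sizes
}

#' Diversity index of a configuration table
#'
#' The ratio of observed distinct configurations to all logically possible
#' configurations over a factor subset, as an exact rational. Small diversity
#' (badly fragmented data) limits how informative configurational conclusions
#' can be; the index is 1 exactly when the observed cases saturate the space.
#'
#' @param x a [config_table()].
#' @param factors factor names to project onto (default: all factors).
#' @return a [cna_fraction()] in (0, 1].
#' @export
diversity_index <- function(x, factors = NULL) {
  stopifnot(is_config_table(x))
  if (is.null(factors)) factors <- names(x)
  if (length(factors) < 1L) stop("factor subset must be non-empty", call. = FALSE)
  missing <- setdiff(factors, names(x))
  if (length(missing)) stop("unknown factor: ", missing[1], call. = FALSE)
  df <- as.data.frame(x)[factors]
  observed <- nrow(unique(df))
  total <- space_size(x, factors)
  cna_fraction(observed, total)
}

#' Build the analytic samples induced by pairing information channels
#'
#' Every unordered pair of the given binary channel factors defines one
#' analytic sample: the two paired channels are replaced by their OR
#' meta-factor while all remaining factors (including the outcome) are kept
#' unchanged. Four channels yield six samples; `k` channels yield
#' `choose(k, 2)`.
#'
#' @param x a [config_table()].
#' @param channels character vector of (exactly) four binary factor names, or
#'   more generally at least two.
#' @param n_channels required number of channels (default 4, the study
#'   design); set to `NULL` to accept any `length(channels) >= 2`.
#' @return a named list of [config_table()]s, one per pair, in lexicographic
#'   pair order; names are the meta-factor names.
#' @export
make_analytic_samples <- function(x, channels, n_channels = 4L) {
  stopifnot(is_config_table(x))
  if (!is.null(n_channels) && length(channels) != n_channels) {
    stop("expected ", n_channels, " channel factors, got ", length(channels),
         call. = FALSE)
  }
  if (length(channels) < 2L) stop("need at least two channels", call. = FALSE)
  doms <- factor_domains(x)
  for (ch in channels) {
    if (!ch %in% names(x)) stop("channel ", ch, " not in table", call. = FALSE)
    if (!identical(doms[[ch]], c(0L, 1L))) {
      stop("channel ", ch, " is not binary", call. = FALSE)
    }
  }
  channels <- sort(channels)
  pairs <- utils::combn(channels, 2L, simplify = FALSE)
  samples <- lapply(pairs, function(p) add_meta_factor(x, p[1], p[2]))
  names(samples) <- vapply(pairs, function(p) paste0(p[1], "_or_", p[2]), "")
  samples
}

#' Declarative calibration specifications
#'
#' A `calibration_spec` bundles the data-preparation rules that turn a raw
#' study table into an analysis-ready [config_table()]: dichotomization
#' thresholds, ordinal recodes of school-delivery factors, meta-factor
#' aggregations, and variation-screening parameters. Rules are applied in the
#' order threshold -> recode -> aggregation -> screening; rules touching
#' disjoint columns commute, and re-applying a spec to its own output is an
#' error by construction (each produced name must be new).
#'
#' @param threshold_rules list of lists with fields `source`, `name`, `cut`,
#'   and optional `direction`.
#' @param recode_rules list of lists with fields `as_col`, `ss_col`, `name`
#'   (ordinal school recode).
#' @param aggregation_rules list of lists with fields `a`, `b` and optional
#'   `name`.
#' @param exclusion_rules list with optional fields `min_minority_count` and
#'   `drop` (character vector of factors to drop after screening).
#' @return an object of class `"calibration_spec"`.
#' @seealso [apply_calibration()], [read_calibration_spec()]
#' @export
calibration_spec <- function(threshold_rules = list(), recode_rules = list(),
                             aggregation_rules = list(), exclusion_rules = list()) {
  spec <- structure(list(threshold_rules = threshold_rules,
                         recode_rules = recode_rules,
                         aggregation_rules = aggregation_rules,
                         exclusion_rules = exclusion_rules),
                    class = "calibration_spec")
  produced <- c(vapply(threshold_rules, function(r) r$name, ""),
                vapply(recode_rules, function(r) r$name, ""))
  if (anyDuplicated(produced)) {
    stop("calibration rules produce duplicate factor names", call. = FALSE)
  }
  spec
}

#' Read a calibration spec from YAML or JSON
#'
#' @param path a YAML (`.yml`/`.yaml`) or JSON file with keys
#'   `threshold_rules`, `recode_rules`, `aggregation_rules`, `exclusion_rules`.
#' @return a [calibration_spec()].
#' @export
read_calibration_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML specs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  calibration_spec(threshold_rules = doc$threshold_rules %||% list(),
                   recode_rules = doc$recode_rules %||% list(),
                   aggregation_rules = doc$aggregation_rules %||% list(),
                   exclusion_rules = doc$exclusion_rules %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a calibration spec to a raw study table
#'
#' @param raw a data.frame of raw columns (numeric measurements and binary
#'   indicators) with case ids as row names, or a [config_table()].
#' @param spec a [calibration_spec()].
#' @param outcome optional designated outcome factor of the result.
#' @return a [config_table()] holding the produced and retained factors.
#' @export
apply_calibration <- function(raw, spec, outcome = NULL) {
  stopifnot(inherits(spec, "calibration_spec"))
  df <- as.data.frame(raw)
  ids <- if (is_config_table(raw)) case_ids(raw) else rownames(df)
  consumed <- character()
  for (r in spec$threshold_rules) {
    if (r$name %in% names(df)) {
      stop("produced factor ", r$name, " already present in raw data", call. = FALSE)
    }
    vals <- stats::setNames(df[[r$source]], ids)
    df[[r$name]] <- dichotomize(vals, r$cut, r$direction %||% "at_or_above")
    consumed <- c(consumed, r$source)
  }
  for (r in spec$recode_rules) {
    if (r$name %in% names(df)) {
      stop("produced factor ", r$name, " already present in raw data", call. = FALSE)
    }
    df[[r$name]] <- recode_schools(df[[r$as_col]], df[[r$ss_col]])
    consumed <- c(consumed, r$as_col, r$ss_col)
  }
  for (r in spec$aggregation_rules) {
    nm <- r$name %||% paste0(r$a, "_or_", r$b)
    if (nm %in% names(df)) {
      stop("produced factor ", nm, " already present in raw data", call. = FALSE)
    }
    df[[nm]] <- aggregate_meta_factor(df[[r$a]], df[[r$b]])
    consumed <- c(consumed, r$a, r$b)
  }
  df <- df[setdiff(names(df), consumed)]
  ct <- config_table(df, case_ids = ids, outcome = outcome)
  drop <- spec$exclusion_rules$drop %||% character()
  if (length(drop)) {
    keep <- setdiff(names(ct), drop)
    ct <- config_table(as.data.frame(ct)[keep], case_ids = ids, outcome = outcome)
  }
  ct
}
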