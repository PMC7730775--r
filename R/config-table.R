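#' Case-by-factor configuration tables
#'
#' The universal input of coincidence analysis: rows are cases (counties,
#' sites, organisations), columns are crisp factors with small non-negative
#' integer levels. A `config_table` is a `data.frame` carrying three
#' attributes: the case identifiers (row names), the factor domains (named
#' list of sorted integer level vectors), and an optional designated outcome
#' factor.
#'
#' Domains are inferred as the sorted distinct observed levels of each column;
#' a column observed at a single level in \{0, 1\} is treated as binary with
#' domain \{0, 1\} (a constant factor is still a factor). Explicit `domains`
#' override inference, e.g. to declare an unobserved level of an ordinal
#' factor.
#'
#' @param data a data.frame of integer factor levels, or a named list/matrix
#'   coercible to one.
#' @param case_ids character vector of unique case labels; defaults to
#'   existing row names or `"c1"`, `"c2"`, ...
#' @param outcome optional name of the designated outcome factor.
#' @param domains optional named list of integer vectors declaring factor
#'   domains (each with at least 2 distinct non-negative levels).
#' @return an object of classes `"config_table"` and `"data.frame"`.
#' @examples
#' ct <- config_table(data.frame(A = c(1, 1, 0, 0), Y = c(1, 0, 1, 0)),
#'                    outcome = "Y")
#' factor_domains(ct)
#' @export
config_table <- function(data, case_ids = NULL, outcome = NULL, domains = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) < 1L) stop("a configuration table needs at least one case", call. = FALSE)
  if (ncol(data) < 1L) stop("a configuration table needs at least one factor", call. = FALSE)
  if (is.null(case_ids)) {
    rn <- attr(data, "row.names")
    case_ids <- if (is.character(rn)) rn else paste0("c", seq_len(nrow(data)))
  }
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) {
    stop("duplicate case ids: ",
         paste(unique(case_ids[duplicated(case_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(case_ids) != nrow(data)) stop("case_ids length mismatch", call. = FALSE)

  for (nm in names(data)) {
    check_factor_name(nm)
    v <- data[[nm]]
    if (any(is.na(v))) {
      stop("missing value in factor ", nm, " (case ",
           case_ids[which(is.na(v))[1]], ")", call. = FALSE)
    }
    if (!is.numeric(v) || any(v != as.integer(v)) || any(v < 0)) {
      stop("factor ", nm, " must hold non-negative integer levels", call. = FALSE)
    }
    data[[nm]] <- as.integer(v)
  }

  inferred <- lapply(data, function(v) {
    lev <- sort(unique(v))
    if (length(lev) == 1L && lev %in% c(0L, 1L)) lev <- c(0L, 1L)
    lev
  })
  if (!is.null(domains)) {
    if (is.null(names(domains)) || !all(names(domains) %in% names(data))) {
      stop("domains must be named after table factors", call. = FALSE)
    }
    for (nm in names(domains)) {
      dom <- sort(unique(as.integer(domains[[nm]])))
      if (length(dom) < 2L || any(dom < 0L)) {
        stop("domain of ", nm, " must have >= 2 distinct non-negative levels",
             call. = FALSE)
      }
      bad <- setdiff(data[[nm]], dom)
      if (length(bad)) {
        stop("factor ", nm, ": observed level ", bad[1],
             " outside declared domain", call. = FALSE)
      }
      inferred[[nm]] <- dom
    }
  }

  if (!is.null(outcome)) {
    if (!outcome %in% names(data)) {
      stop("outcome factor ", outcome, " not in table", call. = FALSE)
    }
    if (ncol(data) < 2L) {
      stop("a table with a designated outcome needs >= 2 factors", call. = FALSE)
    }
  }

  rownames(data) <- case_ids
  structure(data,
            domains = inferred,
            outcome_factor = outcome,
            class = c("config_table", "data.frame"))
}

check_factor_name <- function(nm) {
  if (!nzchar(nm) || grepl("[=*+<>[:space:]-]", nm)) {
    stop("invalid factor name '", nm,
         "' (must be non-empty, without =, *, +, <, >, - or whitespace)",
         call. = FALSE)
  }
  invisible(nm)
}

#' @rdname config_table
#' @param x an object.
#' @export
is_config_table <- function(x) inherits(x, "config_table")

#' @rdname config_table
#' @export
case_ids <- function(x) {
  stopifnot(is_config_table(x))
  rownames(x)
}

#' @rdname config_table
#' @export
factor_domains <- function(x) {
  stopifnot(is_config_table(x))
  attr(x, "domains")
}

#' @rdname config_table
#' @export
outcome_factor <- function(x) {
  stopifnot(is_config_table(x))
  attr(x, "outcome_factor")
}

#' @export
print.config_table <- function(x, ...) {
  out <- outcome_factor(x)
  cat(sprintf("Configuration table: %d cases x %d factors%s\n",
              nrow(x), ncol(x),
              if (is.null(out)) "" else paste0(" (outcome: ", out, ")")))
  doms <- factor_domains(x)
  kinds <- vapply(doms, function(d) {
    if (identical(d, c(0L, 1L))) "binary" else paste0("mv{", paste(d, collapse = ","), "}")
  }, character(1))
  cat("Factors:", paste0(names(doms), " [", kinds, "]", collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 25L))
  if (nrow(x) > 25L) cat("... and", nrow(x) - 25L, "more cases\n")
  invisible(x)
}

#' Read and write configuration tables as CSV
#'
#' The tabular interchange format is plain CSV (comma separated, UTF-8, header
#' row mandatory): one identifier column (default `case_id`) followed by
#' integer-levelled factor columns. `write_config_csv()` emits the same layout,
#' so a read/write round trip is byte-stable for canonical files.
#'
#' @param path file path.
#' @param id_col name of the case-identifier column (default `"case_id"`).
#' @param outcome,domains passed on to [config_table()].
#' @return `read_config_csv()` returns a [config_table()];
#'   `write_config_csv()` returns `path` invisibly.
#' @export
read_config_csv <- function(path, id_col = "case_id", outcome = NULL, domains = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (!id_col %in% names(raw)) {
    stop("id column '", id_col, "' not found in ", path, call. = FALSE)
  }
  ids <- raw[[id_col]]
  raw <- raw[setdiff(names(raw), id_col)]
  for (nm in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      stop("non-integer value '", raw[[nm]][bad[1]], "' at row ", bad[1],
           ", column ", nm, call. = FALSE)
    }
    raw[[nm]] <- as.integer(v)
  }
  config_table(raw, case_ids = ids, outcome = outcome, domains = domains)
}

#' @rdname read_config_csv
#' @param x a [config_table()].
#' @export
write_config_csv <- function(x, path, id_col = "case_id") {
  stopifnot(is_config_table(x))
  out <- cbind(stats::setNames(data.frame(case_ids(x), stringsAsFactors = FALSE), id_col),
               as.data.frame(x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
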