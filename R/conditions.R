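# Expression algebra over factor-value literals.
#
# Internal representation:
#   literal     — one factor fixed at one level
#   conjunction — named integer vector (names = factors, sorted), at most one
#                 literal per factor, so contradictions are unrepresentable
#   condition   — class "cna_condition": a DNF, i.e. a list of conjunctions,
#                 canonical (no disjunct subsumed by another, deterministic
#                 order: by size, then by text)
#   model       — class "cna_model": condition <-> outcome literal, with
#                 optional consistency/coverage fit scores

new_condition <- function(disjuncts) {
  structure(canonicalize_disjuncts(disjuncts), class = "cna_condition")
}

conj_text <- function(conj) paste0(names(conj), "=", unname(conj), collapse = "*")

canonicalize_disjuncts <- function(disjuncts) {
  if (length(disjuncts) == 0L) return(list())
  disjuncts <- lapply(disjuncts, function(conj) {
    conj <- conj[order(names(conj))]
    storage.mode(conj) <- "integer"
    conj
  })
  # drop duplicates and subsumed disjuncts: if literals(a) is a subset of
  # literals(b), then b implies a and is redundant under OR
  keys <- vapply(disjuncts, conj_text, "")
  disjuncts <- disjuncts[!duplicated(keys)]
  n <- length(disjuncts)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[i] && keep[j] && conj_subset(disjuncts[[j]], disjuncts[[i]])) {
        keep[i] <- FALSE  # disjunct j is a proper subset of i; i is redundant
      }
    }
  }
  disjuncts <- disjuncts[keep]
  keys <- vapply(disjuncts, conj_text, "")
  disjuncts[order(lengths(disjuncts), keys)]
}

# TRUE iff every literal of a occurs in b
conj_subset <- function(a, b) {
  if (length(a) > length(b)) return(FALSE)
  idx <- match(names(a), names(b))
  !anyNA(idx) && all(unname(b)[idx] == unname(a))
}

#' Parse and print conditions and models
#'
#' Conditions are disjunctive normal forms over factor-value literals, written
#' in the field's notation: `FACTOR=level` atoms combined with `*` (AND) and
#' `+` (OR), e.g. `"SCHOOLS=2 + SCHOOLS=1*MC=1"`. A model links a condition
#' biconditionally (`<->`, sufficiency and necessity; the Unicode arrow
#' \ifelse{latex}{\out{$\leftrightarrow$}}{↔} is accepted on input) to a single
#' outcome literal. Factor names are normalised to upper case; printing is
#' canonical (literals sorted by factor, disjuncts by size then text), so
#' `parse_model(format(m))` is structurally identical to `m`.
#'
#' @param text a character scalar in model notation.
#' @return `parse_condition()` returns a `"cna_condition"`; `parse_model()`
#'   returns a `"cna_model"` with fit scores unset.
#' @examples
#' m <- parse_model("SCHOOLS=2 + SCHOOLS=1*MC=1 <-> HI_UPTAKE=1")
#' format(m)
#' @export
parse_condition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("↔", "<->", text)
  if (grepl("<->", text, fixed = TRUE)) {
    stop("'", text, "' contains '<->'; use parse_model() for full models",
         call. = FALSE)
  }
  disjunct_texts <- strsplit(text, "+", fixed = TRUE)[[1]]
  if (length(disjunct_texts) == 0L || all(!nzchar(trimws(disjunct_texts)))) {
    stop("empty condition", call. = FALSE)
  }
  disjuncts <- lapply(seq_along(disjunct_texts), function(i) {
    lits <- strsplit(disjunct_texts[i], "*", fixed = TRUE)[[1]]
    parsed <- lapply(lits, parse_literal)
    facs <- vapply(parsed, `[[`, "", "factor")
    levs <- vapply(parsed, `[[`, 1L, "level")
    dup <- duplicated(facs)
    if (any(dup)) {
      clash <- facs[dup][1]
      if (length(unique(levs[facs == clash])) > 1L) {
        stop("contradictory literals for factor ", clash, " in disjunct ", i,
             call. = FALSE)
      }
      levs <- levs[!dup]
      facs <- facs[!dup]
    }
    stats::setNames(levs, facs)
  })
  new_condition(disjuncts)
}

parse_literal <- function(text) {
  text <- trimws(text)
  if (!grepl("^[A-Za-z][A-Za-z0-9_.]*[[:space:]]*=[[:space:]]*[0-9]+$", text)) {
    stop("malformed literal '", text, "' (expected FACTOR=level)", call. = FALSE)
  }
  parts <- strsplit(text, "=", fixed = TRUE)[[1]]
  list(factor = toupper(trimws(parts[1])), level = as.integer(trimws(parts[2])))
}

#' @rdname parse_condition
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("↔", "<->", text)
  parts <- strsplit(text, "<->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("a model needs exactly one '<->' (got '", text, "')", call. = FALSE)
  }
  condition <- parse_condition(parts[1])
  outcome <- parse_literal(parts[2])
  if (outcome$factor %in% condition_factors(condition)) {
    stop("outcome factor ", outcome$factor, " appears in the condition",
         call. = FALSE)
  }
  new_model(condition, outcome)
}

new_model <- function(condition, outcome, consistency = NULL, coverage = NULL) {
  structure(list(condition = condition, outcome = outcome,
                 consistency = consistency, coverage = coverage),
            class = "cna_model")
}

condition_factors <- function(cond) {
  unique(unlist(lapply(unclass(cond), names), use.names = FALSE))
}

#' @export
format.cna_condition <- function(x, ...) {
  if (length(unclass(x)) == 0L) return("<empty>")
  paste(vapply(unclass(x), conj_text, ""), collapse = " + ")
}

#' @export
print.cna_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.cna_model <- function(x, ...) {
  paste0(format(x$condition), " <-> ", x$outcome$factor, "=", x$outcome$level)
}

#' @export
print.cna_model <- function(x, ...) {
  cat(format(x))
  if (!is.null(x$consistency)) {
    cat(sprintf("  [con: %s, cov: %s]",
                format(x$consistency), format(x$coverage)))
  }
  cat("\n")
  invisible(x)
}

as_condition <- function(x) {
  if (inherits(x, "cna_condition")) return(x)
  if (inherits(x, "cna_model")) return(x$condition)
  if (is.character(x)) return(parse_condition(x))
  stop("cannot interpret object as a condition", call. = FALSE)
}

as_outcome <- function(x) {
  if (is.list(x) && all(c("factor", "level") %in% names(x))) {
    return(list(factor = x$factor, level = as.integer(x$level)))
  }
  if (is.character(x)) return(parse_literal(x))
  stop("cannot interpret object as an outcome literal", call. = FALSE)
}

#' Evaluate a condition on the cases of a configuration table
#'
#' Standard Boolean semantics over factor levels: a literal holds in a case
#' iff the case's level equals the literal's level, a conjunction holds iff
#' all its literals hold, and a DNF holds iff any disjunct holds.
#'
#' @param cond a `"cna_condition"`, a `"cna_model"` (its condition is used), or
#'   condition text such as `"A=1*B=0 + C=2"`.
#' @param x a [config_table()].
#' @return a logical vector along the cases of `x`.
#' @export
evaluate_condition <- function(cond, x) {
  stopifnot(is_config_table(x))
  cond <- as_condition(cond)
  doms <- factor_domains(x)
  for (conj in unclass(cond)) {
    for (f in names(conj)) {
      if (!f %in% names(x)) stop("unknown factor ", f, call. = FALSE)
      if (!conj[[f]] %in% doms[[f]]) {
        stop("level ", conj[[f]], " outside the domain of ", f, call. = FALSE)
      }
    }
  }
  hit <- rep(FALSE, nrow(x))
  for (conj in unclass(cond)) {
    ok <- rep(TRUE, nrow(x))
    for (f in names(conj)) ok <- ok & (x[[f]] == conj[[f]])
    hit <- hit | ok
  }
  hit
}

outcome_indicator <- function(outcome, x) {
  outcome <- as_outcome(outcome)
  if (!outcome$factor %in% names(x)) {
    stop("unknown outcome factor ", outcome$factor, call. = FALSE)
  }
  if (!outcome$level %in% factor_domains(x)[[outcome$factor]]) {
    stop("level ", outcome$level, " outside the domain of ", outcome$factor,
         call. = FALSE)
  }
  x[[outcome$factor]] == outcome$level
}

#' Consistency and coverage of a condition for an outcome
#'
#' Consistency is the fraction of condition-instantiating cases that also
#' exhibit the outcome (sufficiency fit); coverage is the fraction of
#' outcome cases that instantiate the condition (necessity / empirical
#' importance). Both are exact rationals; a condition with no instantiating
#' case (or an outcome with no case) yields the designated undefined score,
#' see [is_undefined()].
#'
#' @param cond condition (object or text), see [evaluate_condition()].
#' @param outcome outcome literal (object or text such as `"HI_UPTAKE=1"`).
#' @param x a [config_table()].
#' @return a [cna_fraction()].
#' @examples
#' ct <- hpv_fixture()
#' consistency("SCHOOLS=2 + SCHOOLS=1*MC=1", "HI_UPTAKE=1", ct)  # 7/8
#' @export
consistency <- function(cond, outcome, x) {
  inst <- evaluate_condition(cond, x)
  out <- outcome_indicator(outcome, x)
  cna_fraction(sum(inst & out), sum(inst))
}

#' @rdname consistency
#' @export
coverage <- function(cond, outcome, x) {
  inst <- evaluate_condition(cond, x)
  out <- outcome_indicator(outcome, x)
  cna_fraction(sum(inst & out), sum(out))
}

#' Submodel relation between two conditions
#'
#' `core` is a submodel of `model` iff there is an injective mapping from the
#' disjuncts of `core` to the disjuncts of `model` such that each core
#' disjunct's literal set is contained in its image's literal set. This is the
#' sense in which an incomplete common core "is part of" every complete model
#' of an ambiguous solution set. The relation is reflexive and transitive; it
#' is decided by exhaustive injection search (model sets in scope are small).
#'
#' @param core,model conditions, models, or condition text; for two models the
#'   outcome literals must also match.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_submodel("SCHOOLS=2 + SCHOOLS=1*MC=1",
#'             "SCHOOLS=2 + SCHOOLS=1*MC=1*CCY=0")
#' @export
is_submodel <- function(core, model) {
  if (inherits(core, "cna_model") && inherits(model, "cna_model")) {
    if (!identical(core$outcome, model$outcome)) return(FALSE)
  }
  a <- unclass(as_condition(core))
  b <- unclass(as_condition(model))
  if (length(a) == 0L) return(TRUE)  # the empty core is part of everything
  find_injection(a, b, used = rep(FALSE, length(b)))
}

find_injection <- function(a, b, used) {
  if (length(a) == 0L) return(TRUE)
  head <- a[[1]]
  for (j in seq_along(b)) {
    if (!used[j] && conj_subset(head, b[[j]])) {
      used[j] <- TRUE
      if (find_injection(a[-1], b, used)) return(TRUE)
      used[j] <- FALSE
    }
  }
  FALSE
}

model_key <- function(m) {
  paste0(format(m$condition), " <-> ", m$outcome$factor, "=", m$outcome$level)
}

# structured JSON-ready record of a model (condition as list of [factor,level]
# pairs, fits as numerator/denominator plus rounded decimal)
model_record <- function(m) {
  fit <- function(f) {
    if (is.null(f)) NULL
    else list(num = f$num, den = f$den, decimal = round_half_up(f))
  }
  list(text = model_key(m),
       condition = lapply(unclass(m$condition), function(conj) {
         lapply(names(conj), function(f) list(factor = f, level = conj[[f]]))
       }),
       outcome = list(factor = m$outcome$factor, level = m$outcome$level),
       consistency = fit(m$consistency),
       coverage = fit(m$coverage))
}
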