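#' Coincidence analysis: bottom-up discovery of Boolean causal models
#'
#' Fits configurational models to a case-by-factor table by bottom-up search:
#' single factor values are tested for sufficiency first, then conjunctions of
#' two, three, ... (up to `maxstep[1]`) — every conjunction kept is a
#' *minimal sufficient condition* (msc): it meets the consistency threshold
#' while none of its proper sub-conjunctions does. Disjunctions of msc are then
#' tested for necessity the same way, yielding *atomic solution formulas*
#' (asf): disjunctions meeting both thresholds none of whose proper
#' sub-disjunctions does. With several outcomes, asfs are combined into
#' *complex solution formulas* (csf) representing chains or common-cause
#' structures, after filtering cyclic and structurally redundant combinations.
#'
#' All minimality checks are exhaustive within `maxstep`, so returned models
#' are automatically redundancy-free, and *all* models surviving the
#' thresholds are reported — model ambiguity is surfaced, never resolved
#' silently. The search is deterministic; identical inputs give byte-identical
#' solution listings.
#'
#' @param x a [config_table()] or data.frame of integer factor levels.
#' @param outcome one or more outcome literals as text (e.g. `"HI_UPTAKE=1"`;
#'   the negated outcome is simply `"HI_UPTAKE=0"`). Defaults to the table's
#'   designated outcome factor at level 1.
#' @param con,cov consistency and coverage thresholds in (0, 1], given as a
#'   number or an exact string such as `"1"`, `"0.95"` or `"13/14"`.
#' @param maxstep integer triple: maximum conjuncts per msc, maximum disjuncts
#'   per asf, maximum total literals per asf. Default `c(3, 4, 10)`.
#' @param candidate_factors optional restriction of the factors admitted into
#'   conditions (default: all factors except the outcome factor under test).
#' @return an object of class `"cna"` with components `solutions` (per-outcome
#'   msc and asf lists), `csf`, `settings` and `diagnostics`. See [msc()],
#'   [asf()], [csf()], [common_core()], and the `print`, `summary`, `coef`,
#'   `predict` and `residuals` methods.
#' @examples
#' tt <- expand.grid(A = 0:1, B = 0:1, C = 0:1)
#' tt$Y <- as.integer(tt$A == 1 | (tt$B == 1 & tt$C == 1))
#' fit <- cna(config_table(tt), outcome = "Y=1")
#' fit
#' @export
cna <- function(x, outcome = NULL, con = 1, cov = 1, maxstep = c(3L, 4L, 10L),
                candidate_factors = NULL) {
  if (!is_config_table(x)) x <- config_table(x)
  if (is.null(outcome)) {
    of <- outcome_factor(x)
    if (is.null(of)) stop("no outcome given and none designated in the table",
                          call. = FALSE)
    lev <- if (1L %in% factor_domains(x)[[of]]) 1L else max(factor_domains(x)[[of]])
    outcome <- paste0(of, "=", lev)
  }
  outcomes <- lapply(outcome, as_outcome)
  ofacs <- vapply(outcomes, `[[`, "", "factor")
  if (anyDuplicated(ofacs)) {
    stop("outcome factors must be pairwise distinct", call. = FALSE)
  }
  settings <- make_settings(con, cov, maxstep, candidate_factors)

  solutions <- list()
  diagnostics <- list(tested = list(), csf_cyclic = 0L, csf_redundant = 0L)
  for (o in outcomes) {
    key <- paste0(o$factor, "=", o$level)
    m <- find_msc_internal(x, o, settings)
    a <- build_asf_internal(m, x, o, settings)
    solutions[[key]] <- list(outcome = o, msc = m$msc, asf = a$asf)
    diagnostics$tested[[key]] <- list(msc_tested = m$tested, asf_tested = a$tested)
  }
  cs <- build_csf_internal(solutions, x)
  diagnostics$csf_cyclic <- cs$cyclic
  diagnostics$csf_redundant <- cs$redundant

  structure(list(call = match.call(), table = x, settings = settings,
                 solutions = solutions, csf = cs$csf,
                 diagnostics = diagnostics),
            class = "cna")
}

make_settings <- function(con, cov, maxstep, candidate_factors = NULL) {
  maxstep <- as.integer(maxstep)
  if (length(maxstep) != 3L || any(is.na(maxstep)) || any(maxstep < 1L)) {
    stop("maxstep must be three positive integers", call. = FALSE)
  }
  if (maxstep[3] < max(maxstep[1], maxstep[2])) {
    stop("maxstep total literals must be >= max(conjuncts, disjuncts)",
         call. = FALSE)
  }
  con_r <- parse_rational(con)
  cov_r <- parse_rational(cov)
  for (thr in list(con_r, cov_r)) {
    if (thr[1] <= 0 || thr[1] > thr[2]) {
      stop("thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  list(con = con_r, cov = cov_r, maxstep = maxstep,
       candidate_factors = candidate_factors)
}

# ---- minimal sufficient conditions -----------------------------------------

find_msc_internal <- function(x, outcome, settings) {
  doms <- factor_domains(x)
  candidates <- settings$candidate_factors %||% names(x)
  candidates <- sort(setdiff(candidates, outcome$factor))
  if (length(candidates) == 0L) {
    stop("no candidate factors besides the outcome", call. = FALSE)
  }
  out <- outcome_indicator(outcome, x)
  if (!any(out)) {
    stop("no case instantiates the outcome ", outcome$factor, "=",
         outcome$level, call. = FALSE)
  }
  df <- as.data.frame(x)
  msc <- list()
  tested <- integer()
  for (k in seq_len(min(settings$maxstep[1], length(candidates)))) {
    found_k <- list()
    for (facs in utils::combn(candidates, k, simplify = FALSE)) {
      grid <- expand.grid(lapply(doms[facs], identity), KEEP.OUT.ATTRS = FALSE)
      for (ri in seq_len(nrow(grid))) {
        conj <- stats::setNames(as.integer(unlist(grid[ri, ], use.names = FALSE)), facs)
        conj <- conj[order(names(conj))]
        tested[k] <- (if (k <= length(tested)) tested[k] else 0L) + 1L
        if (any(vapply(msc, function(m) conj_subset(m$conj, conj), TRUE))) next
        inst <- rep(TRUE, nrow(df))
        for (f in names(conj)) inst <- inst & (df[[f]] == conj[[f]])
        n_inst <- sum(inst)
        if (n_inst == 0L) next  # undefined consistency: excluded
        cons <- cna_fraction(sum(inst & out), n_inst)
        if (isTRUE(frac_ge(cons, settings$con))) {
          found_k[[length(found_k) + 1L]] <-
            list(conj = conj, inst = inst,
                 consistency = cons,
                 coverage = cna_fraction(sum(inst & out), sum(out)))
        }
      }
    }
    if (length(found_k)) {
      found_k <- found_k[order(vapply(found_k, function(m) conj_text(m$conj), ""))]
      msc <- c(msc, found_k)
    }
  }
  list(msc = msc, tested = tested)
}

#' Minimal sufficient conditions for an outcome
#'
#' Runs only the first stage of the bottom-up search (or extracts it from a
#' fitted `"cna"` object): all conjunctions within the size bound that meet
#' the consistency threshold while none of their proper sub-conjunctions does.
#'
#' @param x a [config_table()], data.frame, or fitted `"cna"` object.
#' @param outcome outcome literal text (required unless `x` is a `"cna"`
#'   object; then the msc of that outcome, or of all outcomes, are returned).
#' @param con consistency threshold.
#' @param maxstep as in [cna()] (only the first component matters here).
#' @param candidate_factors optional factor restriction.
#' @return a data.frame with one row per msc: `condition`, `consistency`,
#'   `coverage` (decimal, half-up 2 d.p.) and the exact numerator/denominator
#'   columns.
#' @export
msc <- function(x, outcome = NULL, con = 1, maxstep = c(3L, 4L, 10L),
                candidate_factors = NULL) {
  if (inherits(x, "cna")) {
    sols <- select_solutions(x, outcome)
    return(do.call(rbind, lapply(sols, function(s) msc_frame(s$msc, s$outcome))))
  }
  if (!is_config_table(x)) x <- config_table(x)
  o <- as_outcome(outcome)
  settings <- make_settings(con, 1, maxstep, candidate_factors)
  m <- find_msc_internal(x, o, settings)
  msc_frame(m$msc, o)
}

msc_frame <- function(msc, outcome) {
  if (length(msc) == 0L) {
    return(data.frame(outcome = character(), condition = character(),
                      consistency = numeric(), coverage = numeric(),
                      con_num = integer(), con_den = integer(),
                      cov_num = integer(), cov_den = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    outcome = paste0(outcome$factor, "=", outcome$level),
    condition = vapply(msc, function(m) conj_text(m$conj), ""),
    consistency = vapply(msc, function(m) round_half_up(m$consistency), 1),
    coverage = vapply(msc, function(m) round_half_up(m$coverage), 1),
    con_num = vapply(msc, function(m) m$consistency$num, 1L),
    con_den = vapply(msc, function(m) m$consistency$den, 1L),
    cov_num = vapply(msc, function(m) m$coverage$num, 1L),
    cov_den = vapply(msc, function(m) m$coverage$den, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
}

# ---- atomic solution formulas ----------------------------------------------

build_asf_internal <- function(m, x, outcome, settings) {
  msc <- m$msc
  out <- outcome_indicator(outcome, x)
  n_out <- sum(out)
  asf <- list()
  tested <- 0L
  if (length(msc) == 0L) return(list(asf = asf, tested = tested))
  inst_mat <- vapply(msc, `[[`, rep(TRUE, nrow(x)), "inst")
  if (is.null(dim(inst_mat))) inst_mat <- matrix(inst_mat, nrow = nrow(x))
  sizes <- lengths(lapply(msc, `[[`, "conj"))
  accepted_idx <- list()
  for (k in seq_len(min(settings$maxstep[2], length(msc)))) {
    for (idx in utils::combn(seq_along(msc), k, simplify = FALSE)) {
      if (sum(sizes[idx]) > settings$maxstep[3]) next
      tested <- tested + 1L
      if (any(vapply(accepted_idx, function(a) all(a %in% idx), TRUE))) next
      inst <- rowSums(inst_mat[, idx, drop = FALSE]) > 0
      n_inst <- sum(inst)
      if (n_inst == 0L || n_out == 0L) next
      cons <- cna_fraction(sum(inst & out), n_inst)
      covg <- cna_fraction(sum(inst & out), n_out)
      if (isTRUE(frac_ge(cons, settings$con)) && isTRUE(frac_ge(covg, settings$cov))) {
        accepted_idx[[length(accepted_idx) + 1L]] <- idx
        cond <- new_condition(lapply(msc[idx], `[[`, "conj"))
        asf[[length(asf) + 1L]] <- new_model(cond, outcome, cons, covg)
      }
    }
  }
  if (length(asf)) {
    keys <- vapply(asf, model_key, "")
    asf <- asf[order(lengths(lapply(asf, function(a) unclass(a$condition))), keys)]
  }
  list(asf = asf, tested = tested)
}

#' Atomic solution formulas of a fitted coincidence analysis
#'
#' @param x a fitted `"cna"` object.
#' @param outcome optional outcome literal text to select one outcome.
#' @return a list of `"cna_model"` objects in canonical order.
#' @export
asf <- function(x, outcome = NULL) {
  stopifnot(inherits(x, "cna"))
  sols <- select_solutions(x, outcome)
  models <- unlist(lapply(sols, `[[`, "asf"), recursive = FALSE)
  names(models) <- NULL
  models
}

select_solutions <- function(x, outcome = NULL) {
  if (is.null(outcome)) return(x$solutions)
  o <- as_outcome(outcome)
  key <- paste0(o$factor, "=", o$level)
  if (!key %in% names(x$solutions)) {
    stop("outcome ", key, " was not analysed", call. = FALSE)
  }
  x$solutions[key]
}

# ---- complex solution formulas ---------------------------------------------

build_csf_internal <- function(solutions, x) {
  with_asf <- Filter(function(s) length(s$asf) > 0L, solutions)
  partial <- length(with_asf) < length(solutions)
  cyclic <- 0L
  redundant <- 0L
  csf <- list()
  if (length(with_asf) >= 1L) {
    idx_grid <- expand.grid(lapply(with_asf, function(s) seq_along(s$asf)),
                            KEEP.OUT.ATTRS = FALSE)
    for (ri in seq_len(nrow(idx_grid))) {
      atoms <- mapply(function(s, i) s$asf[[i]], with_asf,
                      as.integer(idx_grid[ri, ]), SIMPLIFY = FALSE)
      names(atoms) <- NULL
      if (has_cycle(atoms)) {
        cyclic <- cyclic + 1L
        next
      }
      if (length(atoms) > 1L && has_redundant_atom(atoms, x)) {
        redundant <- redundant + 1L
        next
      }
      csf[[length(csf) + 1L]] <-
        structure(list(atoms = atoms, partial = partial), class = "cna_csf")
    }
  }
  if (length(csf)) {
    keys <- vapply(csf, function(cs) {
      paste(vapply(cs$atoms, model_key, ""), collapse = " & ")
    }, "")
    csf <- csf[order(keys)]
  }
  list(csf = csf, cyclic = cyclic, redundant = redundant)
}

# directed factor graph: condition factors -> outcome factor; DFS cycle check
has_cycle <- function(atoms) {
  edges <- do.call(rbind, lapply(atoms, function(a) {
    cbind(from = condition_factors(a$condition), to = a$outcome$factor)
  }))
  nodes <- unique(c(edges[, 1], edges[, 2]))
  adj <- lapply(stats::setNames(nodes, nodes),
                function(n) unique(edges[edges[, 1] == n, 2]))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(n) {
    if (state[[n]] == 1L) return(TRUE)
    if (state[[n]] == 2L) return(FALSE)
    state[[n]] <<- 1L
    for (nx in adj[[n]]) if (visit(nx)) return(TRUE)
    state[[n]] <<- 2L
    FALSE
  }
  for (n in nodes) if (visit(n)) return(TRUE)
  FALSE
}

# basic structural-redundancy filter: an atom is redundant in a combination if
# deleting it leaves the satisfying set of configurations (over the factors
# involved) unchanged, i.e. the remaining atoms already enforce it
has_redundant_atom <- function(atoms, x) {
  facs <- sort(unique(unlist(lapply(atoms, function(a) {
    c(condition_factors(a$condition), a$outcome$factor)
  }))))
  doms <- factor_domains(x)[facs]
  if (prod(lengths(doms)) > 250000) return(FALSE)  # guard; spaces in scope are tiny
  space <- config_table(expand.grid(doms, KEEP.OUT.ATTRS = FALSE))
  sat <- lapply(atoms, function(a) {
    evaluate_condition(a$condition, space) == outcome_indicator(a$outcome, space)
  })
  all_sat <- Reduce(`&`, sat)
  for (i in seq_along(atoms)) {
    rest <- Reduce(`&`, sat[-i])
    if (identical(rest, all_sat)) return(TRUE)
  }
  FALSE
}

#' Complex solution formulas of a fitted coincidence analysis
#'
#' With a single outcome the csf list mirrors the asf list; with several
#' outcomes it holds the acyclic, non-redundant combinations of one asf per
#' outcome. Combinations in which some outcome has no asf are reported with
#' `partial = TRUE` rather than suppressed.
#'
#' @param x a fitted `"cna"` object.
#' @return a list of `"cna_csf"` objects.
#' @export
csf <- function(x) {
  stopifnot(inherits(x, "cna"))
  x$csf
}

#' @export
format.cna_csf <- function(x, ...) {
  txt <- paste(vapply(x$atoms, function(a) paste0("(", format(a), ")")),
               collapse = " * ")
  if (isTRUE(x$partial)) txt <- paste(txt, "[partial]")
  txt
}

#' @export
print.cna_csf <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.cna <- function(x, ...) {
  cat("Coincidence analysis\n")
  cat(sprintf("  thresholds: con >= %s, cov >= %s; maxstep = (%s)\n",
              thr_text(x$settings$con), thr_text(x$settings$cov),
              paste(x$settings$maxstep, collapse = ", ")))
  for (key in names(x$solutions)) {
    s <- x$solutions[[key]]
    cat(sprintf("  outcome %s: %d msc, %d asf\n",
                key, length(s$msc), length(s$asf)))
    for (a in s$asf) {
      cat("    ", format(a), sprintf("  [con %s, cov %s]",
                                     format(a$consistency), format(a$coverage)), "\n",
          sep = "")
    }
  }
  if (length(x$solutions) > 1L) {
    cat(sprintf("  csf: %d (cyclic filtered: %d, redundant filtered: %d)\n",
                length(x$csf), x$diagnostics$csf_cyclic,
                x$diagnostics$csf_redundant))
  }
  invisible(x)
}

thr_text <- function(thr) {
  if (thr[2] == 1) as.character(thr[1]) else paste0(thr[1], "/", thr[2])
}

#' @export
summary.cna <- function(object, ...) {
  structure(list(fit = object, coef = coef.cna(object),
                 core = lapply(object$solutions, function(s) {
                   if (length(s$asf)) common_core(s$asf) else NULL
                 })),
            class = "summary.cna")
}

#' @export
print.summary.cna <- function(x, ...) {
  print(x$fit)
  for (key in names(x$core)) {
    if (!is.null(x$core[[key]]) && length(x$fit$solutions[[key]]$asf) > 1L) {
      cat("  common core (", key, "): ", format(x$core[[key]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
coef.cna <- function(object, ...) {
  rows <- lapply(names(object$solutions), function(key) {
    s <- object$solutions[[key]]
    if (length(s$asf) == 0L) return(NULL)
    data.frame(outcome = key,
               condition = vapply(s$asf, function(a) format(a$condition), ""),
               consistency = vapply(s$asf, function(a) round_half_up(a$consistency), 1),
               coverage = vapply(s$asf, function(a) round_half_up(a$coverage), 1),
               n_disjuncts = vapply(s$asf, function(a) length(unclass(a$condition)), 1L),
               n_literals = vapply(s$asf, function(a) {
                 sum(lengths(unclass(a$condition)))
               }, 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(outcome = character(), condition = character(),
                      consistency = numeric(), coverage = numeric(),
                      n_disjuncts = integer(), n_literals = integer())
  }
  row.names(out) <- NULL
  out
}

#' @export
predict.cna <- function(object, newdata = NULL, ...) {
  tab <- if (is.null(newdata)) object$table
         else if (is_config_table(newdata)) newdata
         else config_table(newdata)
  lapply(object$solutions, function(s) {
    if (length(s$asf) == 0L) {
      return(matrix(logical(0), nrow = nrow(tab), ncol = 0L,
                    dimnames = list(case_ids(tab), NULL)))
    }
    m <- vapply(s$asf, function(a) evaluate_condition(a$condition, tab),
                logical(nrow(tab)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(tab))
    dimnames(m) <- list(case_ids(tab), vapply(s$asf, function(a) format(a$condition), ""))
    m
  })
}

#' @export
residuals.cna <- function(object, ...) {
  tab <- object$table
  lapply(object$solutions, function(s) {
    out <- as.integer(outcome_indicator(s$outcome, tab))
    if (length(s$asf) == 0L) {
      return(matrix(integer(0), nrow = nrow(tab), ncol = 0L,
                    dimnames = list(case_ids(tab), NULL)))
    }
    m <- vapply(s$asf, function(a) {
      out - as.integer(evaluate_condition(a$condition, tab))
    }, integer(nrow(tab)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(tab))
    # +1: outcome case not covered (coverage gap); -1: counterexample to
    # sufficiency (consistency gap); 0: correctly classified
    dimnames(m) <- list(case_ids(tab), vapply(s$asf, function(a) format(a$condition), ""))
    m
  })
}

# ---- common core ------------------------------------------------------------

#' Common core of a set of models for the same outcome
#'
#' The maximal condition (by total literal count; ties broken by canonical
#' text) that is a [is_submodel()] of every model in the set. When an analysis
#' is ambiguous — several models fit equally well — the common core is the
#' part of the solution that is determinately supported by the data.
#'
#' @param models a non-empty list of `"cna_model"` or `"cna_condition"`
#'   objects (or condition text) for one outcome.
#' @return a `"cna_condition"`; empty when the models share nothing.
#' @export
common_core <- function(models) {
  stopifnot(length(models) >= 1L)
  conds <- lapply(models, as_condition)
  if (length(conds) > 1L) {
    ofacs <- unique(vapply(models, function(m) {
      if (inherits(m, "cna_model")) m$outcome$factor else NA_character_
    }, ""))
    ofacs <- ofacs[!is.na(ofacs)]
    if (length(ofacs) > 1L) {
      stop("common_core() expects models for a single outcome", call. = FALSE)
    }
  }
  if (length(conds) == 1L) return(conds[[1]])
  sizes <- vapply(conds, function(cd) sum(lengths(unclass(cd))), 1)
  base <- unclass(conds[[which.min(sizes)]])
  others <- conds[-which.min(sizes)]

  best <- NULL
  best_size <- -1L
  best_text <- ""
  for (dset in all_subsets(seq_along(base))) {
    literal_choices <- lapply(base[dset], function(conj) {
      lapply(all_subsets(seq_along(conj)), function(i) conj[i])
    })
    for (combo in cartesian_lists(literal_choices)) {
      cand <- new_condition(combo)
      size <- sum(lengths(unclass(cand)))
      text <- format(cand)
      if (size < best_size || (size == best_size && text >= best_text)) next
      if (all(vapply(others, function(m) is_submodel(cand, m), TRUE))) {
        best <- cand
        best_size <- size
        best_text <- text
      }
    }
  }
  if (is.null(best)) new_condition(list()) else best
}

all_subsets <- function(idx) {
  unlist(lapply(seq_along(idx), function(k) {
    utils::combn(idx, k, simplify = FALSE)
  }), recursive = FALSE)
}

cartesian_lists <- function(choices) {
  if (length(choices) == 0L) return(list())
  out <- lapply(choices[[1]], list)
  for (ch in choices[-1]) {
    out <- unlist(lapply(out, function(acc) {
      lapply(ch, function(el) c(acc, list(el)))
    }), recursive = FALSE)
  }
  out
}

# ---- robustness scan --------------------------------------------------------

#' Fit-robustness scan over a grid of consistency/coverage thresholds
#'
#' Refits the analysis at every grid point and scores each distinct model by
#' the fraction of grid points whose solution set contains it or a supermodel
#' of it (per [is_submodel()]). Models that recur across thresholds are robust
#' to the exact choice of fit cut-offs; models appearing only at isolated
#' thresholds are likely overfitted.
#'
#' @param x a [config_table()] or data.frame.
#' @param outcome outcome literal text.
#' @param con_grid,cov_grid numeric vectors of thresholds (the grid is their
#'   Cartesian product; `cov_grid` defaults to `con_grid`).
#' @param maxstep,candidate_factors as in [cna()].
#' @return an object of class `"cna_robustness"`: a data.frame with columns
#'   `model` and `score`, plus the grid as an attribute.
#' @export
robustness_scan <- function(x, outcome, con_grid, cov_grid = con_grid,
                            maxstep = c(3L, 4L, 10L), candidate_factors = NULL) {
  if (!is_config_table(x)) x <- config_table(x)
  stopifnot(length(con_grid) >= 1L, length(cov_grid) >= 1L)
  grid <- expand.grid(con = con_grid, cov = cov_grid, KEEP.OUT.ATTRS = FALSE)
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- cna(x, outcome, con = grid$con[i], cov = grid$cov[i],
               maxstep = maxstep, candidate_factors = candidate_factors)
    asf(fit)
  })
  all_models <- unlist(runs, recursive = FALSE)
  if (length(all_models) == 0L) {
    res <- data.frame(model = character(), score = numeric())
  } else {
    keys <- vapply(all_models, model_key, "")
    distinct <- all_models[!duplicated(keys)]
    score <- vapply(distinct, function(m) {
      hits <- vapply(runs, function(run) {
        any(vapply(run, function(cand) {
          identical(cand$outcome, m$outcome) &&
            is_submodel(m$condition, cand$condition)
        }, TRUE))
      }, TRUE)
      mean(hits)
    }, 1)
    res <- data.frame(model = vapply(distinct, model_key, ""), score = score,
                      stringsAsFactors = FALSE)
    res <- res[order(-res$score, res$model), , drop = FALSE]
    row.names(res) <- NULL
  }
  structure(res, grid = grid, class = c("cna_robustness", "data.frame"))
}

#' @export
print.cna_robustness <- function(x, ...) {
  grid <- attr(x, "grid")
  cat(sprintf("Fit-robustness scan over %d threshold grid points\n", nrow(grid)))
  print.data.frame(x)
  invisible(x)
}

#' @export
plot.cna_robustness <- function(x, ...) {
  if (nrow(x) == 0L) {
    graphics::plot.new()
    graphics::title("Fit-robustness: no models found")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 16, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(x$score), names.arg = rev(x$model), horiz = TRUE,
                    las = 1, xlim = c(0, 1), cex.names = 0.6,
                    xlab = "recurrence across threshold grid", ...)
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a fitted coincidence analysis
#'
#' `solution_text()` renders the solution set as a plain-text listing in the
#' field's model notation with fit scores as exact fractions and 2 d.p.
#' decimals; `solution_json()` renders the same content as deterministic JSON
#' (byte-identical across repeated runs on identical input).
#'
#' @param x a fitted `"cna"` object.
#' @return a character scalar.
#' @export
solution_text <- function(x) {
  stopifnot(inherits(x, "cna"))
  lines <- c("Coincidence analysis solution set",
             sprintf("thresholds: con >= %s, cov >= %s; maxstep = (%s)",
                     thr_text(x$settings$con), thr_text(x$settings$cov),
                     paste(x$settings$maxstep, collapse = ", ")))
  for (key in names(x$solutions)) {
    s <- x$solutions[[key]]
    lines <- c(lines, sprintf("outcome %s:", key),
               sprintf("  msc (%d):", length(s$msc)))
    for (m in s$msc) {
      lines <- c(lines, sprintf("    %s  [con %s, cov %s]", conj_text(m$conj),
                                format(m$consistency), format(m$coverage)))
    }
    lines <- c(lines, sprintf("  asf (%d):", length(s$asf)))
    for (a in s$asf) {
      lines <- c(lines, sprintf("    %s  [con %s, cov %s]", format(a),
                                format(a$consistency), format(a$coverage)))
    }
  }
  if (length(x$solutions) > 1L || length(x$csf) != length(asf(x))) {
    lines <- c(lines, sprintf("csf (%d):", length(x$csf)),
               vapply(x$csf, function(cs) paste0("  ", format(cs)), ""))
  }
  paste(lines, collapse = "\n")
}

#' @rdname solution_text
#' @export
solution_json <- function(x) {
  stopifnot(inherits(x, "cna"))
  payload <- list(
    settings = list(con = paste0(x$settings$con[1], "/", x$settings$con[2]),
                    cov = paste0(x$settings$cov[1], "/", x$settings$cov[2]),
                    maxstep = x$settings$maxstep),
    solutions = lapply(x$solutions, function(s) {
      list(outcome = paste0(s$outcome$factor, "=", s$outcome$level),
           msc = lapply(s$msc, function(m) {
             list(condition = conj_text(m$conj),
                  consistency = list(num = m$consistency$num,
                                     den = m$consistency$den,
                                     decimal = round_half_up(m$consistency)),
                  coverage = list(num = m$coverage$num, den = m$coverage$den,
                                  decimal = round_half_up(m$coverage)))
           }),
           asf = lapply(s$asf, model_record))
    }),
    csf = lapply(x$csf, function(cs) {
      list(atoms = lapply(cs$atoms, model_record), partial = cs$partial)
    }),
    diagnostics = x$diagnostics)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
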