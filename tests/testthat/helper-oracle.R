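# Independent brute-force oracle for the search definitions, deliberately
# written against the *definitions* (literal case-by-case counting, exhaustive
# sub-conjunction / sub-disjunction enumeration), not against the package's
# search path. Thresholds used with the oracle are dyadic rationals (1, 0.875,
# 0.75, 0.5), for which count * threshold comparisons are exact in doubles.

# all conjunctions over `factors` (named list of level vectors) up to size k,
# as named integer vectors
oracle_all_conjunctions <- function(factors, max_size) {
  out <- list()
  nms <- sort(names(factors))
  for (k in seq_len(min(max_size, length(nms)))) {
    for (fs in utils::combn(nms, k, simplify = FALSE)) {
      grid <- expand.grid(factors[fs], KEEP.OUT.ATTRS = FALSE)
      for (i in seq_len(nrow(grid))) {
        out[[length(out) + 1L]] <-
          stats::setNames(as.integer(unlist(grid[i, ], use.names = FALSE)), fs)
      }
    }
  }
  out
}

# literal per-case recount of instantiation
oracle_instantiates <- function(conj, df) {
  vapply(seq_len(nrow(df)), function(i) {
    all(vapply(names(conj), function(f) df[i, f] == conj[[f]], TRUE))
  }, TRUE)
}

oracle_consistency <- function(conj_or_list, outcome, df) {
  inst <- oracle_dnf_instantiates(conj_or_list, df)
  out <- df[[outcome$factor]] == outcome$level
  if (sum(inst) == 0) return(NA_real_)
  sum(inst & out) / sum(inst)
}

oracle_coverage <- function(conj_or_list, outcome, df) {
  inst <- oracle_dnf_instantiates(conj_or_list, df)
  out <- df[[outcome$factor]] == outcome$level
  if (sum(out) == 0) return(NA_real_)
  sum(inst & out) / sum(out)
}

oracle_dnf_instantiates <- function(x, df) {
  if (!is.list(x)) x <- list(x)
  Reduce(`|`, lapply(x, oracle_instantiates, df = df))
}

# proper sub-conjunctions of a conjunction (all non-empty strict literal subsets)
oracle_subconjunctions <- function(conj) {
  n <- length(conj)
  if (n == 1L) return(list())
  unlist(lapply(seq_len(n - 1L), function(k) {
    utils::combn(seq_len(n), k, simplify = FALSE)
  }), recursive = FALSE) |> lapply(function(idx) conj[idx])
}

# minimal sufficient conditions by literal application of the definition
oracle_msc <- function(df, outcome, con, factors, max_conj) {
  cands <- oracle_all_conjunctions(factors[setdiff(names(factors), outcome$factor)],
                                   max_conj)
  keep <- Filter(function(conj) {
    cs <- oracle_consistency(conj, outcome, df)
    if (is.na(cs) || cs < con) return(FALSE)
    for (sub in oracle_subconjunctions(conj)) {
      cs_sub <- oracle_consistency(sub, outcome, df)
      if (!is.na(cs_sub) && cs_sub >= con) return(FALSE)
    }
    TRUE
  }, cands)
  keep
}

conj_key_oracle <- function(conj) {
  conj <- conj[order(names(conj))]
  paste0(names(conj), "=", unname(conj), collapse = "*")
}

# atomic solution formulas by literal application of the definition:
# disjunction key = sorted conj keys joined by " | "
oracle_asf <- function(df, outcome, con, cov, factors, maxstep) {
  mscs <- oracle_msc(df, outcome, con, factors, maxstep[1])
  if (length(mscs) == 0L) return(character())
  meets <- function(idx) {
    d <- mscs[idx]
    cs <- oracle_consistency(d, outcome, df)
    cv <- oracle_coverage(d, outcome, df)
    !is.na(cs) && !is.na(cv) && cs >= con && cv >= cov
  }
  found <- character()
  for (k in seq_len(min(maxstep[2], length(mscs)))) {
    for (idx in utils::combn(seq_along(mscs), k, simplify = FALSE)) {
      if (sum(lengths(mscs[idx])) > maxstep[3]) next
      if (!meets(idx)) next
      minimal <- TRUE
      if (k > 1L) {
        for (kk in seq_len(k - 1L)) {
          for (sub in utils::combn(idx, kk, simplify = FALSE)) {
            if (meets(sub)) {
              minimal <- FALSE
              break
            }
          }
          if (!minimal) break
        }
      }
      if (minimal) {
        found <- c(found,
                   paste(sort(vapply(mscs[idx], conj_key_oracle, "")),
                         collapse = " | "))
      }
    }
  }
  sort(found)
}

# package asf rendered in the oracle's set notation for comparison
asf_keys <- function(models) {
  sort(vapply(models, function(m) {
    paste(sort(vapply(unclass(m$condition), conj_key_oracle, "")),
          collapse = " | ")
  }, ""))
}

msc_keys <- function(msc_frame) sort(msc_frame$condition)

oracle_msc_keys <- function(...) sort(vapply(oracle_msc(...), conj_key_oracle, ""))

# random binary table with a designated outcome column Y
random_binary_table <- function(n_factors, n_cases) {
  nms <- c(LETTERS[seq_len(n_factors)], "Y")
  df <- as.data.frame(matrix(sample(0:1, (n_factors + 1L) * n_cases, replace = TRUE),
                             nrow = n_cases, dimnames = list(NULL, nms)))
  doms <- stats::setNames(rep(list(c(0L, 1L)), n_factors + 1L), nms)
  config_table(df, outcome = "Y", domains = doms)
}

# random ground-truth condition over a random subset of binary factors
random_truth_condition <- function(factor_names, max_disjuncts = 2L,
                                   max_conjuncts = 3L) {
  n_dis <- sample(seq_len(max_disjuncts), 1L)
  disjuncts <- lapply(seq_len(n_dis), function(i) {
    k <- sample(seq_len(max_conjuncts), 1L)
    fs <- sample(factor_names, min(k, length(factor_names)))
    paste0(fs, "=", sample(0:1, length(fs), replace = TRUE), collapse = "*")
  })
  paste(unlist(disjuncts), collapse = " + ")
}
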