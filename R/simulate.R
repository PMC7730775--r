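#' Ground-truth structures for method validation
#'
#' Bundles a generating Boolean structure (one or more atomic models with
#' pairwise distinct outcome factors, acyclic) with a noise rate and a
#' fragmentation rate, for use with [simulate()]. Noise-free, non-fragmented
#' data generated from a truth satisfies every atom biconditionally on all
#' cases, so a search at `con = cov = 1` must recover a logically equivalent
#' model — the basis of the package's parameter-recovery validation.
#'
#' @param model a `"cna_model"`, model text (`"A=1 + B=1*C=1 <-> Y=1"`), or a
#'   list of these (a causal chain / common-cause structure).
#' @param noise probability in [0, 1) of independently flipping each generated
#'   outcome value (measurement error).
#' @param fragmentation share in [0, 1) of the *distinct* exogenous
#'   configurations removed from the sampling space before cases are drawn
#'   (limited diversity).
#' @return an object of class `"cna_truth"`.
#' @seealso [simulate.cna_truth()]
#' @export
ground_truth <- function(model, noise = 0, fragmentation = 0) {
  if (!is.list(model) || inherits(model, "cna_model")) model <- list(model)
  atoms <- lapply(model, function(m) {
    if (is.character(m)) parse_model(m)
    else if (inherits(m, "cna_model")) m
    else stop("model must be a cna_model or model text", call. = FALSE)
  })
  ofacs <- vapply(atoms, function(a) a$outcome$factor, "")
  if (anyDuplicated(ofacs)) stop("outcome factors must be distinct", call. = FALSE)
  if (has_cycle(atoms)) stop("ground truth structure is cyclic", call. = FALSE)
  stopifnot(noise >= 0, noise < 1, fragmentation >= 0, fragmentation < 1)
  structure(list(atoms = atoms, noise = noise, fragmentation = fragmentation),
            class = "cna_truth")
}

#' @export
print.cna_truth <- function(x, ...) {
  cat("Ground truth structure:\n")
  for (a in x$atoms) cat("  ", format(a), "\n", sep = "")
  cat(sprintf("  noise: %g, fragmentation: %g\n", x$noise, x$fragmentation))
  invisible(x)
}

#' Simulate configurational data from a ground truth
#'
#' Draws exogenous configurations uniformly over their logically possible
#' space (after removing a `fragmentation` share of distinct configurations),
#' sets each endogenous factor by evaluating its atom's condition in causal
#' order (condition true: the outcome literal's level; false: the lowest other
#' domain level), then flips each outcome value independently with probability
#' `noise`. Fully reproducible from `seed`.
#'
#' @param object a [ground_truth()].
#' @param nsim number of tables to generate (a list is returned when
#'   `nsim > 1`).
#' @param seed integer seed; the caller's random-number state is restored on
#'   exit, as for other `simulate()` methods.
#' @param n_cases number of cases per table.
#' @param factors optional named list of factor domains; defaults to binary
#'   \{0, 1\} for every factor mentioned in the truth.
#' @param ... unused.
#' @return a [config_table()] (or list of them) whose designated outcome is
#'   the truth's first outcome factor, with the truth attached as attribute
#'   `"truth"`.
#' @examples
#' tr <- ground_truth("A=1 + B=1*C=1 <-> Y=1")
#' ct <- simulate(tr, seed = 7, n_cases = 50)
#' consistency("A=1 + B=1*C=1", "Y=1", ct)  # 1 (noise-free)
#' @export
simulate.cna_truth <- function(object, nsim = 1, seed = NULL, n_cases = 100,
                               factors = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  out <- lapply(seq_len(nsim), function(i) {
    simulate_one(object, n_cases, factors)
  })
  if (nsim == 1L) out[[1]] else out
}

simulate_one <- function(truth, n_cases, factors) {
  stopifnot(n_cases >= 1L)
  atoms <- truth$atoms
  ofacs <- vapply(atoms, function(a) a$outcome$factor, "")
  used <- unique(unlist(lapply(atoms, function(a) {
    c(condition_factors(a$condition), a$outcome$factor)
  })))
  if (is.null(factors)) {
    factors <- stats::setNames(rep(list(c(0L, 1L)), length(used)), sort(used))
  }
  missing <- setdiff(used, names(factors))
  if (length(missing)) {
    stop("truth references unknown factor ", missing[1], call. = FALSE)
  }
  factors <- lapply(factors, function(d) sort(unique(as.integer(d))))
  exo <- setdiff(names(factors), ofacs)
  if (length(exo) == 0L) stop("truth leaves no exogenous factors", call. = FALSE)

  space <- expand.grid(factors[exo], KEEP.OUT.ATTRS = FALSE)
  if (truth$fragmentation > 0) {
    n_drop <- floor(truth$fragmentation * nrow(space))
    if (n_drop >= nrow(space)) n_drop <- nrow(space) - 1L
    if (n_drop > 0L) {
      space <- space[-sample.int(nrow(space), n_drop), , drop = FALSE]
    }
  }
  df <- space[sample.int(nrow(space), n_cases, replace = TRUE), , drop = FALSE]
  rownames(df) <- NULL

  # endogenous factors in causal order: an atom fires once none of the factors
  # in its condition is a still-unset outcome
  remaining <- atoms
  while (length(remaining)) {
    pending <- vapply(remaining, function(a) a$outcome$factor, "")
    ready <- which(vapply(remaining, function(a) {
      !any(condition_factors(a$condition) %in% pending)
    }, TRUE))
    if (length(ready) == 0L) stop("cannot order truth atoms", call. = FALSE)
    a <- remaining[[ready[1]]]
    tmp <- config_table(df, domains = factors[names(df)])
    hit <- evaluate_condition(a$condition, tmp)
    dom <- factors[[a$outcome$factor]]
    alt <- dom[dom != a$outcome$level][1]
    df[[a$outcome$factor]] <- ifelse(hit, a$outcome$level, alt)
    remaining <- remaining[-ready[1]]
  }

  if (truth$noise > 0) {
    for (of in ofacs) {
      flip <- stats::runif(n_cases) < truth$noise
      if (any(flip)) {
        dom <- factors[[of]]
        df[[of]][flip] <- vapply(df[[of]][flip], function(v) {
          others <- dom[dom != v]
          if (length(others) == 1L) others else sample(others, 1L)
        }, 1L)
      }
    }
  }

  ct <- config_table(df[sort(names(df))], outcome = ofacs[1],
                     domains = factors[sort(names(df))])
  attr(ct, "truth") <- truth
  ct
}
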