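#' The 21-county HPV catch-up vaccination fixture (synthetic reconstruction)
#'
#' A deterministic 21-case table over the five analysis factors of the
#' published Swedish county-level HPV catch-up vaccination study —
#' `SCHOOLS` (school delivery: 0 none, 1 some, 2 all), `SBI` (school-based
#' information), `MC` (media coverage), `SM` (social media), `CCY`
#' (cinema commercial / YouTube) — plus the dichotomized outcome `HI_UPTAKE`
#' (catch-up uptake of at least 65%).
#'
#' This is *not* the study's published analytic dataset: it is a synthetic,
#' constraint-equivalent reconstruction built only from the facts the study
#' narrative reports (case and outcome counts, the Jönköping and Skåne
#' configurations, the cinema/YouTube cross-tabulation, and the fit scores of
#' the reported models). Every such constraint, and the deterministic fill
#' rule for the unconstrained cells, is recorded in the machine-readable
#' manifest returned by [hpv_fixture_constraints()]; the constraints are
#' re-verified in the package's test suite. Only the `Jonkoping` and `Skane`
#' case labels are meaningful; the remaining county names are assigned
#' alphabetically and carry no information.
#'
#' @return a [config_table()] with 21 cases, outcome `HI_UPTAKE`.
#' @examples
#' ct <- hpv_fixture()
#' consistency("SCHOOLS=2 + SCHOOLS=1*MC=1", "HI_UPTAKE=1", ct)  # 7/8
#' @export
hpv_fixture <- function() {
  cols <- c("SCHOOLS", "SBI", "MC", "SM", "CCY", "HI_UPTAKE")
  rows <- list(
    # --- high-uptake counties (7) -------------------------------------------
    # three counties sharing the configuration SCHOOLS=1 * MC=1 * CCY=0
    Blekinge        = c(1, 0, 1, 0, 0, 1),
    Dalarna         = c(1, 0, 1, 0, 0, 1),
    Gavleborg       = c(1, 0, 1, 0, 0, 1),
    # all-schools counties; Jönköping is the one that also used CCY and SM
    Gotland         = c(2, 0, 0, 0, 0, 1),
    Halland         = c(2, 0, 1, 0, 0, 1),
    Jamtland        = c(2, 1, 0, 0, 0, 1),
    Jonkoping       = c(2, 0, 0, 1, 1, 1),
    # --- low-uptake counties (14) -------------------------------------------
    # Skåne: some schools + media coverage, yet no high uptake (CCY present)
    Skane           = c(1, 0, 1, 0, 1, 0),
    Kalmar          = c(1, 0, 0, 0, 1, 0),
    Kronoberg       = c(1, 1, 0, 1, 0, 0),
    Norrbotten      = c(1, 0, 0, 0, 0, 0),
    Orebro          = c(0, 0, 1, 0, 0, 0),
    Ostergotland    = c(0, 1, 1, 0, 1, 0),
    Sodermanland    = c(0, 0, 0, 1, 1, 0),
    Stockholm       = c(0, 1, 0, 0, 1, 0),
    Uppsala         = c(0, 0, 0, 0, 1, 0),
    Varmland        = c(0, 0, 1, 1, 0, 0),
    Vasterbotten    = c(0, 1, 0, 1, 0, 0),
    Vasternorrland  = c(0, 0, 0, 0, 0, 0),
    Vastmanland     = c(0, 1, 1, 1, 1, 0),
    Vastra_Gotaland = c(0, 0, 0, 0, 0, 0)
  )
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- cols
  config_table(df, case_ids = names(rows), outcome = "HI_UPTAKE",
               domains = list(SCHOOLS = 0:2))
}

#' @rdname hpv_fixture
#' @export
hpv_fixture_constraints <- function() {
  path <- system.file("extdata", "hpv_fixture_constraints.json", package = "coinca")
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' @rdname hpv_fixture
#' @export
hpv_fixture_path <- function() {
  system.file("extdata", "hpv_fixture_synthetic.csv", package = "coinca")
}
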