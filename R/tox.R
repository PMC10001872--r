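#' Default toxicological reference table
#'
#' Oral reference doses (RfD), cancer slope factors (SF) and FAO/WHO maximum
#' allowable concentrations (MAC) for the four contaminants the package models
#' by default: cadmium, arsenic, lead and copper in polished rice.
#'
#' Units: `rfd_ug_per_kg_day` in ug/kg bw/day; `sf_per_mg_kg_day` in
#' (mg/kg bw/day)^-1 (the USEPA oral slope-factor convention -- note the mg
#' scale, reconciled inside [carcinogenic_risk()]); `mac_ug_per_kg` in ug/kg.
#' Copper is not treated as a carcinogen and carries no slope factor.
#'
#' @return A `data.frame` with columns `element`, `rfd_ug_per_kg_day`,
#'   `sf_per_mg_kg_day`, `mac_ug_per_kg`, `cr_acceptable_low`,
#'   `cr_acceptable_high`, validated by [validate_tox_table()].
#' @examples
#' tox_defaults()
#' @export
tox_defaults <- function() {
  tab <- data.frame(
    element = c("Cd", "As", "Pb", "Cu"),
    rfd_ug_per_kg_day = c(1, 0.3, 3.5, 40),
    # Oral slope factors in (mg/kg/day)^-1: As 1.5, Cd 6.1, Pb 8.5e-3.
    # Some secondary sources typeset all three with a 1e-3 factor; the
    # published mean CRs are only consistent with these magnitudes.
    sf_per_mg_kg_day = c(6.1, 1.5, 8.5e-3, NA_real_),
    mac_ug_per_kg = c(100, 200, 200, 10000),
    cr_acceptable_low = 1e-6,
    cr_acceptable_high = 1e-4,
    stringsAsFactors = FALSE
  )
  validate_tox_table(tab)
}

#' Load a toxicological reference table from CSV
#'
#' Reads a table with one row per element and the columns described in
#' [tox_defaults()] (`cr_acceptable_low`/`high` are optional and default to
#' the conventional 1e-6 / 1e-4 band). An element with no slope factor (empty
#' or NA `sf_per_mg_kg_day`) is kept but excluded from carcinogenic-risk
#' computations; a message notes the exclusion.
#'
#' @param path Path to a CSV file.
#' @return Validated reference `data.frame` (possibly zero rows).
#' @export
load_tox_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    return(empty_tox_table())
  }
  need <- c("element", "rfd_ug_per_kg_day", "sf_per_mg_kg_day", "mac_ug_per_kg")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("toxicological table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$cr_acceptable_low)) tab$cr_acceptable_low <- 1e-6
  if (is.null(tab$cr_acceptable_high)) tab$cr_acceptable_high <- 1e-4
  tab$sf_per_mg_kg_day <- as.numeric(tab$sf_per_mg_kg_day)
  validate_tox_table(tab)
}

empty_tox_table <- function() {
  data.frame(
    element = character(0), rfd_ug_per_kg_day = numeric(0),
    sf_per_mg_kg_day = numeric(0), mac_ug_per_kg = numeric(0),
    cr_acceptable_low = numeric(0), cr_acceptable_high = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a toxicological reference table
#'
#' Enforces the table's invariants: unique element symbols, strictly positive
#' RfD and MAC, nonnegative slope factors where present, and a proper
#' acceptability band (`cr_acceptable_low < cr_acceptable_high`).
#'
#' @param tab A reference `data.frame`.
#' @return The table, invisibly unchanged, on success; errors otherwise.
#' @export
validate_tox_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (nrow(tab) == 0) return(tab)
  if (anyDuplicated(tab$element)) {
    stop("duplicate element symbol(s) in toxicological table: ",
         paste(unique(tab$element[duplicated(tab$element)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(tab$rfd_ug_per_kg_day) | tab$rfd_ug_per_kg_day <= 0)) {
    stop("RfD must be a positive number for every element", call. = FALSE)
  }
  if (any(!is.finite(tab$mac_ug_per_kg) | tab$mac_ug_per_kg <= 0)) {
    stop("MAC must be a positive number for every element", call. = FALSE)
  }
  sf <- tab$sf_per_mg_kg_day
  if (any(!is.na(sf) & sf < 0)) {
    stop("slope factors must be >= 0 where present", call. = FALSE)
  }
  if (any(is.na(sf))) {
    message("no slope factor for ", paste(tab$element[is.na(sf)], collapse = ", "),
            "; excluded from carcinogenic risk")
  }
  if (any(tab$cr_acceptable_low >= tab$cr_acceptable_high)) {
    stop("cr_acceptable_low must be < cr_acceptable_high", call. = FALSE)
  }
  tab
}

# Look up the single ToxRef row for an element; hard error when absent so a
# risk computation can never silently drop or mismatch an element.
tox_lookup <- function(tox, element) {
  i <- which(tox$element == element)
  if (length(i) != 1L) {
    stop("element '", element, "' does not resolve to exactly one row of the ",
         "toxicological table", call. = FALSE)
  }
  tox[i, , drop = FALSE]
}
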