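#' Hazard quotient
#'
#' Ratio of the estimated daily intake to the oral reference dose, HQ =
#' EDI/RfD, both in ug/kg bw/day. Values above 1 indicate a potential
#' non-carcinogenic risk. Vectorised over draw vectors.
#'
#' @param edi EDI, ug/kg bw/day (scalar or draw vector).
#' @param rfd Oral reference dose, ug/kg bw/day (> 0).
#' @return Dimensionless HQ, same shape as `edi`.
#' @examples
#' hazard_quotient(6.35, 40)  # copper at the national mean intake
#' @export
hazard_quotient <- function(edi, rfd) {
  if (any(!is.finite(rfd) | rfd <= 0)) stop("rfd must be > 0", call. = FALSE)
  edi / rfd
}

#' Hazard index
#'
#' Cumulative non-carcinogenic risk: the sum of hazard quotients over
#' co-occurring contaminants. Over Monte Carlo draws the sum is taken
#' draw-wise (columns are elements), so HI percentiles describe the
#' distribution of the summed hazard, not a sum of percentiles.
#'
#' @param hqs Numeric vector of per-element HQs, or a matrix/data.frame of
#'   HQ draws with one column per element.
#' @return Scalar HI, or a vector of draw-wise HIs.
#' @examples
#' hazard_index(c(Cd = 0.108, As = 0.834, Pb = 0.0282, Cu = 0.159))
#' @export
hazard_index <- function(hqs) {
  if (is.matrix(hqs) || is.data.frame(hqs)) {
    if (ncol(hqs) == 0) stop("at least one HQ is required", call. = FALSE)
    return(rowSums(as.matrix(hqs)))
  }
  if (length(hqs) == 0) stop("at least one HQ is required", call. = FALSE)
  sum(hqs)
}

#' Carcinogenic risk
#'
#' Lifetime excess cancer probability CR = EDI x SF. Slope factors follow
#' the USEPA convention of risk per (mg/kg bw/day), while the package keeps
#' EDI in ug/kg bw/day, so the intake is converted to mg inside this
#' function (factor 1e-3) -- the only place the unit changes.
#'
#' @param edi EDI, ug/kg bw/day (scalar or draw vector).
#' @param sf Slope factor, (mg/kg bw/day)^-1 (>= 0).
#' @return Dimensionless risk, same shape as `edi`.
#' @examples
#' carcinogenic_risk(0.250, 1.5)  # 3.75e-4, arsenic at the national mean
#' @export
carcinogenic_risk <- function(edi, sf) {
  if (any(!is.finite(sf) | sf < 0)) {
    stop("sf must be >= 0 (elements without a slope factor are excluded ",
         "from carcinogenic risk upstream)", call. = FALSE)
  }
  (edi * 1e-3) * sf
}

#' Total carcinogenic risk
#'
#' Sum of per-carcinogen risks; draw-wise over matrices of CR draws, like
#' [hazard_index()].
#'
#' @param crs Numeric vector of per-carcinogen CRs, or a matrix/data.frame
#'   of CR draws (one column per carcinogen).
#' @return Scalar TCR, or a vector of draw-wise TCRs.
#' @export
total_carcinogenic_risk <- function(crs) {
  hazard_index(crs)
}

#' Classify risk values against regulatory thresholds
#'
#' Non-carcinogenic metrics (HQ, HI) are binary at 1; carcinogenic metrics
#' (CR, TCR) are three-way against the conventional acceptability band:
#' negligible below `low`, acceptable within `[low, high]`, unacceptable
#' above `high`. All comparisons are strict, so boundary values are
#' compliant/acceptable.
#'
#' @param value Numeric value(s) of the metric.
#' @param metric `"hq"`, `"hi"`, `"cr"` or `"tcr"`.
#' @param low,high Carcinogenic acceptability band (defaults 1e-6, 1e-4).
#' @return Character vector: `"ok"`/`"potential risk"` for HQ/HI;
#'   `"negligible"`/`"acceptable"`/`"unacceptable"` for CR/TCR.
#' @examples
#' classify_risk(1.04e-3, "tcr")   # unacceptable
#' classify_risk(8.54e-7, "cr")    # negligible
#' @export
classify_risk <- function(value, metric = c("hq", "hi", "cr", "tcr"),
                          low = 1e-6, high = 1e-4) {
  metric <- match.arg(metric)
  if (metric %in% c("hq", "hi")) {
    return(ifelse(value > 1, "potential risk", "ok"))
  }
  ifelse(value > high, "unacceptable",
         ifelse(value < low, "negligible", "acceptable"))
}

#' Contribution shares of risk components
#'
#' Fraction of a summed metric (HI or TCR) attributable to each component:
#' x_i / sum(x). Components must be nonnegative with a positive total.
#'
#' @param x Named nonnegative numeric vector (e.g. per-element mean HQs).
#' @return Fractions summing to 1, same names.
#' @examples
#' contribution_shares(c(As = 3.75e-4, Cd = 6.62e-4, Pb = 8.54e-7))
#' @export
contribution_shares <- function(x) {
  if (any(!is.finite(x) | x < 0)) {
    stop("components must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(x)
  if (total <= 0) stop("zero total: shares undefined", call. = FALSE)
  x / total
}
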