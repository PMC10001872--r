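#' Summarise concentration samples by stratum
#'
#' Per stratum and element: sample count, geometric mean (exp of the mean of
#' logs), arithmetic standard deviation, minimum and maximum -- the
#' sufficient statistics of the lognormal concentration model. A singleton
#' stratum has SD 0. A zero or negative concentration is a hard error (the
#' geometric mean is undefined) naming the offending sample.
#'
#' @param samples Sample `data.frame` ([read_samples()]/[generate_samples()]).
#' @param by Name of the stratum column, or `NULL` to pool everything into a
#'   single `"all"` stratum.
#' @return A `data.frame` in the layout of [nepal_table1()].
#' @export
summarize_conc <- function(samples, by = "province") {
  samples <- validate_samples(samples)
  nonpos <- samples$concentration_ug_per_kg <= 0
  if (any(nonpos)) {
    stop("geometric mean undefined: nonpositive concentration for sample(s) ",
         paste(utils::head(samples$sample_id[nonpos], 5), collapse = ", "),
         call. = FALSE)
  }
  strat <- if (is.null(by)) rep("all", nrow(samples)) else {
    if (is.null(samples[[by]])) {
      stop("no stratum column '", by, "' in samples", call. = FALSE)
    }
    samples[[by]]
  }
  key <- interaction(strat, samples$element, drop = TRUE, lex.order = TRUE)
  parts <- split(seq_len(nrow(samples)), key)
  rows <- lapply(parts, function(i) {
    x <- samples$concentration_ug_per_kg[i]
    data.frame(
      stratum = strat[i[1]],
      element = samples$element[i[1]],
      n = length(x),
      gm_ug_per_kg = exp(mean(log(x))),
      sd_ug_per_kg = if (length(x) > 1) stats::sd(x) else 0,
      min_ug_per_kg = min(x),
      max_ug_per_kg = max(x),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen samples against maximum allowable concentrations
#'
#' Flags every sample whose concentration strictly exceeds its element's MAC
#' (a value exactly at the limit is compliant, matching the regulatory
#' "below the maximum allowable concentration" reading). Every element in
#' the data must have a MAC in `tox`.
#'
#' @param samples Sample `data.frame`.
#' @param tox Toxicological reference table ([tox_defaults()]).
#' @return List with `exceedances` (the offending sample rows, with a
#'   `mac_ug_per_kg` column) and `counts` (per-element exceedance counts,
#'   including zeros).
#' @examples
#' s <- data.frame(sample_id = c("a", "b"), element = "Cu",
#'                 concentration_ug_per_kg = c(9999, 10059))
#' screen_mac(s, tox_defaults())$counts
#' @export
screen_mac <- function(samples, tox) {
  samples <- validate_samples(samples)
  if (nrow(samples) == 0) {
    return(list(exceedances = samples,
                counts = data.frame(element = character(0),
                                    n = integer(0), n_exceed = integer(0))))
  }
  els <- unique(samples$element)
  mac <- vapply(els, function(e) tox_lookup(tox, e)$mac_ug_per_kg, 0)
  if (any(!is.finite(mac))) {
    stop("missing MAC for element(s): ",
         paste(els[!is.finite(mac)], collapse = ", "), call. = FALSE)
  }
  samples$mac_ug_per_kg <- mac[match(samples$element, els)]
  over <- samples$concentration_ug_per_kg > samples$mac_ug_per_kg
  counts <- data.frame(
    element = els,
    n = as.integer(table(factor(samples$element, els))),
    n_exceed = as.integer(tapply(over, factor(samples$element, els), sum)),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- NULL
  list(exceedances = samples[over, , drop = FALSE], counts = counts)
}
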