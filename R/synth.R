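#' Bundled survey summary table (Nepal rice, seven provinces)
#'
#' Published geometric mean, arithmetic SD and observed range of Cd, As, Pb
#' and Cu (ug/kg) in 170 commercial rice samples stratified over the seven
#' provinces of Nepal, plus the national total. These sufficient statistics
#' are the targets the synthetic generator reproduces; the underlying raw
#' per-sample data were never published.
#'
#' @param include_total Keep the `"Total Nepal"` row (a national summary, not
#'   a generating stratum) in the result.
#' @return A `data.frame` with columns `stratum`, `element`, `n`,
#'   `gm_ug_per_kg`, `sd_ug_per_kg`, `min_ug_per_kg`, `max_ug_per_kg`.
#' @export
nepal_table1 <- function(include_total = TRUE) {
  path <- system.file("extdata", "nepal_table1_summary.csv",
                      package = "dietrisk", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!include_total) tab <- tab[tab$stratum != "Total Nepal", , drop = FALSE]
  tab
}

# 32-bit FNV-1a hash of a string, done in 16-bit halves so products stay
# exactly representable in doubles.
fnv1a32 <- function(s) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(s)) {
    # xor the byte into the low bits, then multiply mod 2^32 in halves
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), bitwAnd(b, 255L))
    lo <- h %% 2^16
    hi <- (h - lo) / 2^16
    h <- (lo * prime + ((hi * prime) %% 2^16) * 2^16) %% 2^32
  }
  h
}

#' Derive a stream-specific seed
#'
#' One user-facing integer seed governs every random stream in a run; each
#' (stratum, element, purpose) stream gets its own sub-seed by hashing the
#' labels together with the master seed. Adding strata or elements therefore
#' never reshuffles the draws of existing ones.
#'
#' @param seed Master integer seed.
#' @param ... Character/numeric labels identifying the stream.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
stream_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "|")
  as.integer(fnv1a32(key) %% (2^31 - 1))
}

#' Generate synthetic concentration samples from summary targets
#'
#' For each stratum x element row of `summary`, fits a lognormal by
#' GM/arithmetic-SD moment matching ([fit_lognormal()]) and draws `n`
#' concentrations. Deterministic given `seed`, with an independent stream
#' per stratum x element (see [stream_seed()]).
#'
#' Truncation to the observed `[min, max]` range is available but off by
#' default: it guarantees range containment at the cost of perturbing the
#' matched GM/SD, and the documented contract of the generator is the moment
#' match.
#'
#' @param summary Summary `data.frame` in the layout of [nepal_table1()]
#'   (columns `stratum`, `element`, `n`, `gm_ug_per_kg`, `sd_ug_per_kg`, and,
#'   if `truncate = TRUE`, `min_ug_per_kg`/`max_ug_per_kg`).
#' @param seed Master integer seed.
#' @param n_override Optional single count overriding every row's `n`.
#' @param truncate Truncate draws to the row's observed range.
#' @return A sample `data.frame` (columns `sample_id`, `province`, `element`,
#'   `concentration_ug_per_kg`) passing [validate_samples()].
#' @examples
#' head(generate_samples(nepal_table1(include_total = FALSE), seed = 1))
#' @export
generate_samples <- function(summary, seed, n_override = NULL,
                             truncate = FALSE) {
  stopifnot(is.data.frame(summary), nrow(summary) >= 1)
  need <- c("stratum", "element", "n", "gm_ug_per_kg", "sd_ug_per_kg")
  missing_cols <- setdiff(need, names(summary))
  if (length(missing_cols) > 0) {
    stop("summary table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(summary))
  for (i in seq_len(nrow(summary))) {
    row <- summary[i, ]
    n <- if (is.null(n_override)) row$n else n_override
    spec <- fit_lognormal(
      row$gm_ug_per_kg, row$sd_ug_per_kg,
      lower = if (truncate) row$min_ug_per_kg else NULL,
      upper = if (truncate) row$max_ug_per_kg else NULL
    )
    set.seed(stream_seed(seed, row$stratum, row$element, "conc"))
    x <- dist_draw(spec, n, positive = TRUE)
    out[[i]] <- data.frame(
      sample_id = sprintf("%s-%03d", gsub("\\s+", "_", row$stratum),
                          seq_len(n)),
      province = row$stratum,
      element = row$element,
      concentration_ug_per_kg = x,
      stringsAsFactors = FALSE
    )
  }
  validate_samples(do.call(rbind, out), what = "synthetic samples")
}

#' Define a population (consumer) group
#'
#' Exposure-factor bundle for one consumer stratum: rice intake rate (IR),
#' body weight (BW), exposure frequency (EF), exposure duration (ED) and
#' averaging time (AT). IR and BW may be fixed values or [dist_spec()]
#' models; IR and BW draws are independent. By default EF = 365 days/yr and
#' AT = ED x 365 days, so the chronic-exposure factor EF*ED/AT equals 1.
#'
#' @param name Group label (free text: a province, region, or vulnerable
#'   group such as "toddlers").
#' @param ir Intake rate, kg rice/day (number or `dist_spec`).
#' @param bw Body weight, kg (number or `dist_spec`).
#' @param ef Exposure frequency, days/year (<= 366).
#' @param ed Exposure duration, years.
#' @param at Averaging time, days.
#' @return An object of class `population_group`.
#' @examples
#' population_group("national", ir = 0.32, bw = 60)
#' @export
population_group <- function(name, ir, bw, ef = 365, ed = 30, at = ed * 365) {
  as_model <- function(x, what) {
    if (inherits(x, "dist_spec")) return(x)
    if (is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0) {
      return(dist_spec("point", value = x))
    }
    stop(what, " must be a positive number or a dist_spec", call. = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(ef) || ef <= 0 || ef > 366) {
    stop("ef must be in (0, 366] days/year", call. = FALSE)
  }
  if (!is.finite(ed) || ed <= 0) stop("ed must be > 0 years", call. = FALSE)
  if (!is.finite(at) || at <= 0) stop("at must be > 0 days", call. = FALSE)
  structure(list(name = name, ir = as_model(ir, "ir"), bw = as_model(bw, "bw"),
                 ef = ef, ed = ed, at = at),
            class = "population_group")
}

#' @export
print.population_group <- function(x, ...) {
  fmt <- function(m) {
    if (m$family == "point") format(m$params$value)
    else paste0(m$family, "(", paste(signif(unlist(m$params), 4),
                                     collapse = ", "), ")")
  }
  cat("<population_group> ", x$name,
      ": IR ", fmt(x$ir), " kg/day, BW ", fmt(x$bw), " kg, EF ", x$ef,
      " d/yr, ED ", x$ed, " yr, AT ", x$at, " d\n", sep = "")
  invisible(x)
}

#' Draw paired intake-rate and body-weight values for a group
#'
#' IR and BW are drawn independently from the group's models; point values
#' are replicated. Nonpositive draws (possible for a normal BW model) are
#' resampled, i.e. the models are implicitly truncated below at zero.
#'
#' @param group A [population_group()].
#' @param n_draws Number of paired draws.
#' @param seed Master integer seed.
#' @return A `data.frame` with columns `ir` and `bw`, `n_draws` rows.
#' @export
generate_population <- function(group, n_draws, seed) {
  stopifnot(inherits(group, "population_group"), n_draws >= 1)
  set.seed(stream_seed(seed, group$name, "ir"))
  ir <- dist_draw(group$ir, n_draws, positive = TRUE)
  set.seed(stream_seed(seed, group$name, "bw"))
  bw <- dist_draw(group$bw, n_draws, positive = TRUE)
  data.frame(ir = ir, bw = bw)
}

#' Bundled Nepalese consumer groups
#'
#' The national adult group plus the vulnerable age/sex strata (women,
#' children, preschoolers, toddlers) used for stratified reporting. The
#' intake rates and body weights are documented package assumptions chosen
#' to be realistic for Nepal (the national pair is consistent with annual
#' rice consumption of ~3.65 Mt and reproduces the published national mean
#' exposures); they are not values from any single survey, which published
#' only stratified exposure results, not its exposure factors.
#'
#' @return Named list of [population_group()] objects.
#' @export
nepal_groups <- function() {
  defs <- list(
    national = c(0.32, 60),
    women = c(0.36, 52),
    children = c(0.26, 27),
    preschoolers = c(0.21, 16),
    toddlers = c(0.13, 11)
  )
  out <- lapply(names(defs), function(nm) {
    population_group(nm, ir = defs[[nm]][1], bw = defs[[nm]][2])
  })
  names(out) <- names(defs)
  out
}
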