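#' Probabilistic dietary risk assessment
#'
#' The package's central fit: propagates concentration, intake-rate and
#' body-weight variability through the EDI equation for every population
#' group, characterises non-carcinogenic risk (HQ per element, HI summed
#' draw-wise) and carcinogenic risk (CR per carcinogen, TCR summed
#' draw-wise), and attaches threshold classifications and contribution
#' shares. A single national concentration model is shared by all groups,
#' so between-group differences reflect intake-to-bodyweight ratios only --
#' the usual design when samples cannot be assigned to consumers.
#'
#' @param conc Concentration input: a per-sample `data.frame`
#'   ([read_samples()] / [generate_samples()]) or a summary `data.frame`
#'   ([nepal_table1()] / [summarize_conc()]).
#' @param groups A [population_group()] or list of them.
#' @param tox Toxicological reference table ([tox_defaults()]).
#' @param iterations Monte Carlo iterations per group x element.
#' @param seed Master integer seed; every random stream derives from it.
#' @param levels Percentile reporting levels.
#' @param mode `"fitted"`: draw concentrations from lognormal models fitted
#'   to GM/SD summaries; `"resample"`: bootstrap observed concentrations
#'   (requires per-sample input).
#' @param conc_stratum When `conc` is a summary table with several strata,
#'   the stratum supplying the shared concentration model.
#' @return An object of class `hm_risk` with components `exposure` (per
#'   group: matrix of EDI draws, iterations x elements), `hq`, `hi`, `cr`,
#'   `tcr` (draw-wise), `conc_models`, and the call parameters. See
#'   [summary.hm_risk()] for the tabular view.
#' @examples
#' \donttest{
#' fit <- assess_risk(nepal_table1(), iterations = 2000, seed = 7)
#' fit
#' head(summary(fit))
#' }
#' @export
assess_risk <- function(conc, groups = nepal_groups()["national"],
                        tox = tox_defaults(), iterations = 10000, seed = 1,
                        levels = default_levels(),
                        mode = c("fitted", "resample"),
                        conc_stratum = "Total Nepal") {
  mode <- match.arg(mode)
  if (inherits(groups, "population_group")) groups <- list(groups)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- vapply(groups, function(g) g$name, "")
  }
  is_summary <- !is.null(conc$gm_ug_per_kg)
  if (is_summary) {
    if (mode == "resample") {
      stop("resample mode needs per-sample data, not a summary table",
           call. = FALSE)
    }
    summ <- conc
    if (!is.null(summ$stratum) && conc_stratum %in% summ$stratum) {
      summ <- summ[summ$stratum == conc_stratum, , drop = FALSE]
    }
  } else {
    samples <- validate_samples(conc)
    summ <- summarize_conc(samples, by = NULL)
  }
  elements <- unique(summ$element)
  # one shared national concentration model (or pool) per element
  conc_models <- lapply(elements, function(e) {
    if (mode == "resample") {
      samples$concentration_ug_per_kg[samples$element == e]
    } else {
      row <- summ[summ$element == e, ][1, ]
      fit_lognormal(row$gm_ug_per_kg, row$sd_ug_per_kg)
    }
  })
  names(conc_models) <- elements

  carcinogens <- elements[vapply(elements, function(e) {
    !is.na(tox_lookup(tox, e)$sf_per_mg_kg_day)
  }, TRUE)]

  per_group <- lapply(groups, function(g) {
    edi <- sapply(elements, function(e) {
      edi_mcs(conc_models[[e]], g, iterations = iterations, seed = seed,
              levels = levels, element = e)$draws
    })
    edi <- matrix(edi, nrow = iterations, ncol = length(elements),
                  dimnames = list(NULL, elements))
    rfd <- vapply(elements, function(e) tox_lookup(tox, e)$rfd_ug_per_kg_day, 0)
    hq <- sweep(edi, 2, rfd, "/")
    hi <- hazard_index(hq)
    if (length(carcinogens) > 0) {
      sf <- vapply(carcinogens, function(e) tox_lookup(tox, e)$sf_per_mg_kg_day, 0)
      cr <- carcinogenic_risk(edi[, carcinogens, drop = FALSE],
                              rep(sf, each = iterations))
      tcr <- total_carcinogenic_risk(cr)
    } else {
      cr <- matrix(numeric(0), nrow = iterations, ncol = 0)
      tcr <- rep(0, iterations)  # empty sum: no carcinogens, no cancer risk
    }
    list(edi = edi, hq = hq, hi = hi, cr = cr, tcr = tcr)
  })

  structure(list(
    elements = elements, carcinogens = carcinogens,
    groups = groups, tox = tox, conc_models = conc_models,
    exposure = per_group, iterations = iterations, seed = seed,
    levels = levels, mode = mode
  ), class = "hm_risk")
}

#' Summarise a risk assessment as a percentile table
#'
#' One row per group x element x metric (EDI, HQ, CR) plus HI and TCR rows
#' per group, with the arithmetic mean and the requested percentiles --
#' the layout of a standard probabilistic exposure table.
#'
#' @param object An `hm_risk` fit.
#' @param ... Unused.
#' @return A `data.frame` with columns `group`, `element`, `metric`,
#'   `average`, one `P*` column per level, `classification`.
#' @export
summary.hm_risk <- function(object, ...) {
  lev <- object$levels
  row_of <- function(group, element, metric, draws) {
    cls <- switch(metric,
      EDI = NA_character_,
      HQ = classify_risk(mean(draws), "hq"),
      HI = classify_risk(mean(draws), "hi"),
      CR = classify_risk(mean(draws), "cr"),
      TCR = classify_risk(mean(draws), "tcr"))
    cbind(data.frame(group = group, element = element, metric = metric,
                     average = mean(draws), stringsAsFactors = FALSE),
          as.data.frame(as.list(percentile(draws, lev))),
          data.frame(classification = cls, stringsAsFactors = FALSE))
  }
  out <- list()
  for (g in names(object$exposure)) {
    ex <- object$exposure[[g]]
    for (e in object$elements) {
      out[[length(out) + 1]] <- row_of(g, e, "EDI", ex$edi[, e])
      out[[length(out) + 1]] <- row_of(g, e, "HQ", ex$hq[, e])
      if (e %in% object$carcinogens) {
        out[[length(out) + 1]] <- row_of(g, e, "CR", ex$cr[, e])
      }
    }
    out[[length(out) + 1]] <- row_of(g, "all", "HI", ex$hi)
    out[[length(out) + 1]] <- row_of(g, "all", "TCR", ex$tcr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contribution shares within a fitted assessment
#'
#' Per-element fractions of the mean HI and of the mean TCR for one group,
#' computed from mean HQ and mean CR draws.
#'
#' @param fit An `hm_risk` fit.
#' @param group Group name (default: first group).
#' @return List with `hi_shares` and `tcr_shares`, each summing to 1.
#' @export
risk_shares <- function(fit, group = names(fit$exposure)[1]) {
  ex <- fit$exposure[[group]]
  if (is.null(ex)) stop("unknown group '", group, "'", call. = FALSE)
  list(hi_shares = contribution_shares(colMeans(ex$hq)),
       tcr_shares = contribution_shares(colMeans(ex$cr)))
}

#' @export
print.hm_risk <- function(x, ...) {
  cat("Probabilistic dietary heavy-metal risk assessment\n")
  cat("  elements:   ", paste(x$elements, collapse = ", "),
      "  (carcinogens: ", paste(x$carcinogens, collapse = ", "), ")\n",
      sep = "")
  cat("  iterations: ", x$iterations, "  seed: ", x$seed,
      "  concentration mode: ", x$mode, "\n", sep = "")
  for (g in names(x$exposure)) {
    ex <- x$exposure[[g]]
    mhi <- mean(ex$hi); mtcr <- mean(ex$tcr)
    cat(sprintf("  %-14s mean HI %.3f (%s), mean TCR %.3g (%s)\n",
                g, mhi, classify_risk(mhi, "hi"),
                mtcr, classify_risk(mtcr, "tcr")))
  }
  invisible(x)
}

#' Plot a risk assessment
#'
#' Base-graphics density of the draw-wise hazard index (and, optionally,
#' total carcinogenic risk on a log axis) per group, with the regulatory
#' thresholds marked.
#'
#' @param x An `hm_risk` fit.
#' @param which `"hi"` or `"tcr"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hm_risk <- function(x, which = c("hi", "tcr"), ...) {
  which <- match.arg(which)
  grp <- names(x$exposure)
  vals <- lapply(x$exposure, function(ex) ex[[which]])
  if (which == "tcr") vals <- lapply(vals, log10)
  dens <- lapply(vals, stats::density)
  xlim <- range(unlist(lapply(dens, `[[`, "x")))
  ylim <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
  lab <- if (which == "hi") "Hazard index" else "log10(total carcinogenic risk)"
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = lab, ylab = "density",
                 main = "Dietary heavy-metal risk", ...)
  for (i in seq_along(dens)) graphics::lines(dens[[i]], col = i)
  thr <- if (which == "hi") 1 else log10(c(1e-6, 1e-4))
  graphics::abline(v = thr, lty = 2, col = "grey40")
  graphics::legend("topright", legend = grp, col = seq_along(grp), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Deterministic risk characterisation from mean intakes
#'
#' The arithmetic layer of the framework without simulation: given mean
#' EDIs per element, returns HQ, HI, CR, TCR, contribution shares and
#' threshold classifications. Useful for reproducing published summary
#' tables from their printed mean intakes.
#'
#' @param edi Named numeric vector of mean EDIs, ug/kg bw/day (names are
#'   element symbols present in `tox`).
#' @param tox Toxicological reference table.
#' @return List with `hq`, `hi`, `cr`, `tcr`, `hi_shares`, `tcr_shares`,
#'   `flags`.
#' @examples
#' risk_from_edi(c(Cd = 0.108, As = 0.250, Pb = 0.100, Cu = 6.35))
#' @export
risk_from_edi <- function(edi, tox = tox_defaults()) {
  stopifnot(is.numeric(edi), !is.null(names(edi)))
  rfd <- vapply(names(edi), function(e) tox_lookup(tox, e)$rfd_ug_per_kg_day, 0)
  hq <- hazard_quotient(edi, rfd)
  hi <- hazard_index(hq)
  sf <- vapply(names(edi), function(e) tox_lookup(tox, e)$sf_per_mg_kg_day, 0)
  carc <- names(edi)[!is.na(sf)]
  cr <- carcinogenic_risk(edi[carc], sf[carc])
  tcr <- total_carcinogenic_risk(cr)
  list(
    hq = hq, hi = hi, cr = cr, tcr = tcr,
    hi_shares = contribution_shares(hq),
    tcr_shares = contribution_shares(cr),
    flags = c(hi = classify_risk(hi, "hi"), tcr = classify_risk(tcr, "tcr"))
  )
}
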