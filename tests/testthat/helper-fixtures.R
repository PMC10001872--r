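# Shared fixtures, all built in code.

# tiny valid sample table
toy_samples <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3"),
    province = c("A", "A", "B"),
    element = c("Cd", "Cd", "Cd"),
    concentration_ug_per_kg = c(1, 100, 10),
    stringsAsFactors = FALSE
  )
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# published national mean EDIs (ug/kg bw/day) used as deterministic inputs
national_mean_edi <- function() c(Cd = 0.108, As = 0.250, Pb = 0.100, Cu = 6.35)

quiet_tox <- function() suppressMessages(tox_defaults())

# independent oracle for the lognormal moment match: bisection on the
# moment equation, written without reference to fit_lognormal()
sigma_by_bisection <- function(gm, sd, lo = 1e-12, hi = 20, iter = 200) {
  mu <- log(gm)
  f <- function(s) (exp(s^2) - 1) * exp(2 * mu + s^2) - sd^2
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
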