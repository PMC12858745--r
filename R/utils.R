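#' @keywords internal
"_PACKAGE"

# Round half away from zero (spreadsheet-style), used for shift/TTS counts.
# base::round() rounds half to even, which is kept for the side-imputation
# quota where the spec of the procedure calls for banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

# Draw from a normal truncated to [lo, hi] by inverse-CDF sampling.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Draw from a lognormal truncated above at `hi`.
rlnorm_trunc <- function(n, meanlog, sdlog, hi = Inf) {
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, phi), meanlog, sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("earnoise_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# p-value formatter used by print methods
fmt_p <- function(p) ifelse(p < 1e-5, "< .00001", sprintf("= %.4g", p))
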