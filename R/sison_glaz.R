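# Simultaneous confidence intervals for multinomial proportions,
# Sison & Glaz (1995, JASA 90:366-369): the coverage of the box
# {p_i - c/N <= p_i-hat <= p_i + c/N} is approximated by truncated-Poisson
# probabilities with an Edgeworth-corrected conditioning on the total, and
# c is tuned (with a fractional adjustment 2*gamma/N on the upper limits)
# so that simultaneous coverage equals the nominal level.

# P(b <= Z <= a), Z ~ Poisson(lambda)
pois_interval <- function(b, a, lambda) {
  stats::ppois(a, lambda) - stats::ppois(b - 1, lambda)
}

# r-th factorial moment of a Poisson(lambda) truncated to [b, a]
trunc_pois_fmoment <- function(b, a, r, lambda) {
  lambda^r * (1 - (pois_interval(a - r + 1, a, lambda) -
                   pois_interval(b - r, b - 1, lambda)) /
                pois_interval(b, a, lambda))
}

# Approximate P(all |X_i - n_i| <= c) for the multinomial, via independent
# truncated Poissons conditioned on the total with an Edgeworth correction.
sg_nu <- function(c, counts, n) {
  b <- pmax(counts - c, 0)
  a <- pmin(counts + c, n)
  mu1 <- mapply(trunc_pois_fmoment, b, a, 1, counts)
  mu_r2 <- mapply(trunc_pois_fmoment, b, a, 2, counts)
  mu_r3 <- mapply(trunc_pois_fmoment, b, a, 3, counts)
  mu_r4 <- mapply(trunc_pois_fmoment, b, a, 4, counts)
  mu2 <- mu_r2 + mu1 - mu1^2
  mu3 <- mu_r3 + mu_r2 * (3 - 3 * mu1) + mu1 - 3 * mu1^2 + 2 * mu1^3
  mu4 <- mu_r4 + mu_r3 * (6 - 4 * mu1) + mu_r2 * (7 - 12 * mu1 + 6 * mu1^2) +
    mu1 - 4 * mu1^2 + 6 * mu1^3 - 3 * mu1^4
  s2 <- sum(mu2)
  g1 <- sum(mu3) / s2^1.5
  g2 <- (sum(mu4) - 3 * sum(mu2^2)) / s2^2
  x <- (n - sum(mu1)) / sqrt(s2)
  phi <- exp(-x^2 / 2) / sqrt(2 * pi)
  f <- phi * (1 + g1 * (x^3 - 3 * x) / 6 +
                g2 * (x^4 - 6 * x^2 + 3) / 24 +
                g1^2 * (x^6 - 15 * x^4 + 45 * x^2 - 15) / 72)
  exp(sum(log(pois_interval(b, a, counts))) + log(f / sqrt(s2)) -
        stats::dpois(n, n, log = TRUE))
}

#' Sison-Glaz simultaneous confidence intervals
#'
#' Simultaneous confidence intervals for all categories of a multinomial
#' distribution, controlling the overall (familywise) coverage at
#' `1 - alpha`. The half-width `c/N` is chosen so that the approximated
#' simultaneous coverage brackets the nominal level
#' (`nu(c) <= 1 - alpha < nu(c + 1)`), with a fractional widening
#' `2 * gamma / N` of the upper limits. Intervals are clipped to \[0, 1\]
#' and always contain the observed proportions.
#'
#' @param counts Non-negative integer vector of category counts, total > 0.
#' @param alpha Familywise error rate (default 0.05).
#' @return Data frame with columns `estimate`, `lower`, `upper`, one row
#'   per category.
#' @export
#' @examples
#' sison_glaz_ci(c(1279, 929, 40, 70, 16))
sison_glaz_ci <- function(counts, alpha = 0.05) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop_domain("counts must be >= 0")
  n <- sum(counts)
  if (n <= 0) stop_domain("total count must be > 0")
  p <- counts / n
  k <- length(counts)
  if (k == 1L)
    return(data.frame(estimate = 1, lower = 1, upper = 1))
  c0 <- 1
  nuc <- sg_nu(c0, counts, n)
  nucp1 <- sg_nu(c0 + 1, counts, n)
  while (!(nuc <= (1 - alpha) && (1 - alpha) < nucp1)) {
    if (c0 > n) stop_domain("no c solves nu(c) <= 1 - alpha < nu(c + 1)")
    c0 <- c0 + 1
    nuc <- nucp1
    nucp1 <- sg_nu(c0 + 1, counts, n)
  }
  g <- (1 - alpha - nuc) / (nucp1 - nuc)
  data.frame(
    estimate = p,
    lower = pmax(p - c0 / n, 0),
    upper = pmin(p + (c0 + 2 * g) / n, 1)
  )
}
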