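#' Informativeness-corrected inclusion probability
#'
#' Maps the percent-spliced-in value of an event to the probability that a
#' randomly sampled informative read supports the inclusion isoform. Each
#' isoform contributes read positions in proportion to its informativeness
#' constant (`c_inclusion`, `c_exclusion`); with equal constants the map is
#' the identity, recovering the uncorrected two-isoform binomial model.
#'
#' @param psi PSI value(s) in `[0, 1]`.
#' @param c_inclusion,c_exclusion Positive informativeness constants
#'   (effective read-position counts per isoform). Default 1 (no correction).
#' @return Inclusion-read probability, same length as `psi`.
#' @examples
#' inclusion_probability(0.5, c_inclusion = 2, c_exclusion = 1) # 2/3
#' @export
inclusion_probability <- function(psi, c_inclusion = 1, c_exclusion = 1) {
  stopifnot(all(psi >= 0 & psi <= 1), all(c_inclusion > 0), all(c_exclusion > 0))
  psi * c_inclusion / (psi * c_inclusion + (1 - psi) * c_exclusion)
}

#' Invert the informativeness correction
#'
#' Converts an observed inclusion-read fraction back to the PSI scale; the
#' inverse of [inclusion_probability()].
#'
#' @param q Inclusion-read fraction(s) in `[0, 1]`.
#' @inheritParams inclusion_probability
#' @return PSI value(s).
#' @export
psi_from_inclusion <- function(q, c_inclusion = 1, c_exclusion = 1) {
  stopifnot(all(q >= 0 & q <= 1), all(c_inclusion > 0), all(c_exclusion > 0))
  q * c_exclusion / (q * c_exclusion + (1 - q) * c_inclusion)
}

# Composite-Simpson weights on [0, 1] for an odd grid size.
simpson_weights <- function(grid_n) {
  stopifnot(grid_n %% 2 == 1)
  w <- rep(c(2, 4), length.out = grid_n)
  w[c(1, grid_n)] <- 1
  w / (3 * (grid_n - 1))
}

# Log marginal likelihood log integral_0^1 q(psi)^k (1-q(psi))^l dpsi on a
# fixed Simpson grid. Used for unequal informativeness constants and as
# the quadrature cross-check of the closed form.
log_marginal_quadrature <- function(k, l, c_inc, c_exc, grid_n = 2001) {
  psi <- seq(0, 1, length.out = grid_n)
  q <- inclusion_probability(psi, c_inc, c_exc)
  lf <- (if (k == 0) 0 else k * log(q)) + (if (l == 0) 0 else l * log1p(-q))
  logsumexp(lf + log(simpson_weights(grid_n)))
}

# Posterior over PSI by grid quadrature (uniform prior); returns the same
# summary as the closed-form Beta path.
psi_posterior_quadrature <- function(k, l, c_inc, c_exc, conf = 0.95, grid_n = 2001) {
  psi <- seq(0, 1, length.out = grid_n)
  q <- inclusion_probability(psi, c_inc, c_exc)
  lf <- (if (k == 0) 0 else k * log(q)) + (if (l == 0) 0 else l * log1p(-q))
  f <- exp(lf - max(lf))
  w <- simpson_weights(grid_n)
  z <- sum(w * f)
  m1 <- sum(w * f * psi) / z
  m2 <- sum(w * f * psi^2) / z
  cdf <- cumsum(w * f) / z
  alpha <- (1 - conf) / 2
  ci <- stats::approx(cdf, psi, xout = c(alpha, 1 - alpha), ties = "ordered", rule = 2)$y
  list(mean = m1, var = max(m2 - m1^2, 0), ci_low = ci[1], ci_high = ci[2])
}

#' Posterior PSI estimates from inclusion/exclusion counts
#'
#' Bayesian PSI estimation for two-isoform events: a Uniform(0, 1) prior on
#' PSI and a Binomial likelihood on the inclusion count with success
#' probability [inclusion_probability()]. With equal informativeness
#' constants the posterior is `Beta(n_inclusion + 1, n_exclusion + 1)` in
#' closed form; otherwise it is computed by fixed-grid quadrature.
#' A record with zero total reads returns the prior (mean 0.5, central 95%
#' interval `[0.025, 0.975]`).
#'
#' @param counts Data frame with columns `n_inclusion` and `n_exclusion`
#'   (non-negative integer read counts); any other columns (`event_id`,
#'   `sample`, `replicate`, `allele`, ...) are carried through. If an
#'   `event_id` column is present and `events` is supplied, per-event
#'   informativeness constants are taken from the catalog.
#' @param events Optional event catalog with columns `event_id`,
#'   `c_inclusion`, `c_exclusion`. Default `NULL`: constants 1 (uncorrected).
#' @param conf Credible level for the equal-tailed interval. Default 0.95.
#' @param grid_n Quadrature grid size for unequal constants. Default 2001.
#' @return The input tibble with columns `psi_mean`, `psi_var`, `ci_low`,
#'   `ci_high`, `n_total` appended.
#' @examples
#' psi_posterior(tibble::tibble(n_inclusion = 30, n_exclusion = 10))
#' @export
psi_posterior <- function(counts, events = NULL, conf = 0.95, grid_n = 2001) {
  counts <- as_tibble(counts)
  check_counts(counts$n_inclusion, counts$n_exclusion)
  k <- counts$n_inclusion
  l <- counts$n_exclusion
  if (!is.null(events) && "event_id" %in% names(counts)) {
    idx <- match(counts$event_id, events$event_id)
    c_inc <- events$c_inclusion[idx]
    c_exc <- events$c_exclusion[idx]
    c_inc[is.na(c_inc)] <- 1
    c_exc[is.na(c_exc)] <- 1
  } else {
    c_inc <- rep(1, length(k))
    c_exc <- rep(1, length(k))
  }
  a <- k + 1
  b <- l + 1
  alpha <- (1 - conf) / 2
  out <- tibble(
    psi_mean = a / (a + b),
    psi_var = a * b / ((a + b)^2 * (a + b + 1)),
    ci_low = stats::qbeta(alpha, a, b),
    ci_high = stats::qbeta(1 - alpha, a, b)
  )
  uneq <- which(c_inc != c_exc)
  for (i in uneq) {
    p <- psi_posterior_quadrature(k[i], l[i], c_inc[i], c_exc[i], conf, grid_n)
    out$psi_mean[i] <- p$mean
    out$psi_var[i] <- p$var
    out$ci_low[i] <- p$ci_low
    out$ci_high[i] <- p$ci_high
  }
  dplyr::bind_cols(counts, out, tibble(n_total = k + l))
}

#' Signed PSI difference
#'
#' Difference of two PSI estimates, first minus second. By convention the
#' first argument is the reference strain or allele, so a positive value
#' means higher inclusion there.
#'
#' @param psi1,psi2 PSI values (vectors recycle as usual).
#' @return `psi1 - psi2`.
#' @export
delta_psi <- function(psi1, psi2) {
  psi1 - psi2
}

#' Isoform-ratio PSI
#'
#' Plain long-isoform read fraction, `n_long / (n_long + n_short)`, as used
#' for validation-style count vectors (e.g. RT-PCR or long-read isoform
#' counts).
#'
#' @param n_long,n_short Reads supporting the long and short isoform.
#' @return PSI value(s) in `[0, 1]`.
#' @export
isoform_ratio_psi <- function(n_long, n_short) {
  check_counts(n_long, n_short)
  if (any(n_long + n_short < 1)) {
    abort("isoform_ratio_psi() needs at least one supporting read")
  }
  n_long / (n_long + n_short)
}

#' Fisher's exact test for splicing divergence
#'
#' Two-sided exact test on the 2x2 table (inclusion/exclusion x sample),
#' the test-independence check alternative to the Bayes factor. Two-sided
#' p sums all hypergeometric outcomes with probability at most that of the
#' observed table.
#'
#' @param n_inc1,n_exc1,n_inc2,n_exc2 Inclusion/exclusion read counts for
#'   the two records (vectorised).
#' @return Two-sided p-value(s). A table with an all-zero margin returns 1
#'   with a warning.
#' @export
fisher_divergence_test <- function(n_inc1, n_exc1, n_inc2, n_exc2) {
  check_counts(c(n_inc1, n_inc2), c(n_exc1, n_exc2))
  mapply(function(a, b, c, d) {
    if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
      warn("degenerate 2x2 table (all-zero margin); p = 1")
      return(1)
    }
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  }, n_inc1, n_exc1, n_inc2, n_exc2)
}
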