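#' Tail probability of a positively weighted chi-squared mixture
#'
#' Upper-tail probability of \eqn{Q = \sum_k \lambda_k \chi^2_1} at `q`.
#' The default `"liu"` method is the moment-matching approximation of Liu,
#' Tang and Zhang (2009): the mixture is matched in mean, variance and
#' skewness (kurtosis where attainable) to a shifted, possibly noncentral
#' chi-squared variable. `"satterthwaite"` matches mean and variance only
#' (a scaled central chi-squared).
#'
#' @param q observed statistic.
#' @param lambda nonnegative mixture weights (eigenvalues); zeros are
#'   dropped.
#' @param method `"liu"` (default) or `"satterthwaite"`.
#' @return The upper-tail probability in \[0, 1\].
#' @export
pchisq_mixture <- function(q, lambda, method = c("liu", "satterthwaite")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L) stop("all mixture weights are zero")
  if (method == "satterthwaite") {
    c1 <- sum(lambda); c2 <- sum(lambda^2)
    nu <- c1^2 / c2
    return(stats::pchisq(q * nu / c1, df = nu, lower.tail = FALSE))
  }
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- 1 / s1^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  t <- (q - mu_q) / sigma_q * sigma_x + mu_x
  stats::pchisq(t, df = l, ncp = delta, lower.tail = FALSE)
}
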