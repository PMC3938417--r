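# Mismatch distributions and the sudden-expansion model: observed
# pairwise-difference spectra, model-expected spectra, least-squares
# fitting, and parametric-bootstrap goodness-of-fit (SSD and
# Harpending's raggedness index).

#' Observed mismatch distribution of a population
#'
#' Relative frequencies of pairwise difference classes `0..d` over all
#' n(n-1)/2 sequence pairs, differences counted over mutually observed
#' (non-missing, non-gap) sites. Unimodal spectra are the classic
#' signature of recent demographic expansion; multimodal spectra of
#' stationarity or structure.
#'
#' @param aln a [alignment()] object.
#' @param population optional population to subset to.
#' @return object of class `"mismatch"`: list with `freqs` (named vector
#'   over classes 0..d), `n_pairs`, `n`.
#' @export
mismatch_observed <- function(aln, population = NULL) {
  aln <- aln_subset(aln, population)
  n <- length(aln$sample_id)
  if (n < 2) stop("mismatch distribution needs n >= 2")
  pd <- pairwise_differences(aln)
  k <- pd$diff[upper.tri(pd$diff)]
  d <- max(k)
  freqs <- tabulate(k + 1L, nbins = d + 1L) / length(k)
  names(freqs) <- 0:d
  structure(list(freqs = freqs, n_pairs = length(k), n = n),
            class = "mismatch")
}

#' @export
print.mismatch <- function(x, ...) {
  cat(sprintf("Mismatch distribution over %d pairs (classes 0..%d)\n",
              x$n_pairs, length(x$freqs) - 1L))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' For a population at mutational time `tau` after an instantaneous
#' change of the scaled mutation rate from `theta0` to `theta1`, the
#' probability that a random pair differs at j sites is
#' \deqn{F_j = \frac{1}{\theta_1} a_1^{-(j+1)} P(\Gamma(j+1, a_1) \le \tau)
#'   + e^{-\tau a_1} \frac{1}{\theta_0} \sum_{i=0}^{j}
#'     \frac{\tau^{j-i}}{(j-i)!} a_0^{-(i+1)}}
#' with \eqn{a_m = 1 + 1/\theta_m}. At `tau = 0` this is the equilibrium
#' geometric law with `theta0`; as `tau` grows it converges to the
#' equilibrium law with `theta1`.
#'
#' @param tau mutational time since the expansion (>= 0).
#' @param theta0,theta1 scaled mutation rates before/after expansion.
#' @param d_max largest difference class reported individually; classes
#'   beyond it are aggregated into a final `"tail"` bucket so that the
#'   returned vector sums to 1.
#' @return named numeric vector over classes `0..d_max` plus `"tail"`.
#' @export
mismatch_expected <- function(tau, theta0, theta1, d_max) {
  if (tau < 0 || theta0 < 0 || theta1 <= 0)
    stop("parameters must satisfy tau >= 0, theta0 >= 0, theta1 > 0")
  j <- 0:d_max
  a1 <- 1 + 1 / theta1
  p1 <- (1 / theta1) * a1^(-(j + 1)) * stats::pgamma(tau, shape = j + 1, rate = a1)
  ltau <- log(max(tau, .Machine$double.xmin))
  if (theta0 > 0) {
    a0 <- 1 + 1 / theta0
    p2 <- vapply(j, function(jj) {
      i <- 0:jj
      lterms <- -tau * a1 + (jj - i) * ltau - lgamma(jj - i + 1) -
        (i + 1) * log(a0) - log(theta0)
      if (tau == 0) lterms <- c(rep(-Inf, jj),
                                -(jj + 1) * log(a0) - log(theta0))
      exp(logsumexp(lterms))
    }, numeric(1))
  } else {
    # theta0 = 0: the pre-expansion population is monomorphic, all
    # residual probability mass collapses onto coalescence at tau
    p2 <- exp(-tau * a1 + j * ltau - lgamma(j + 1))
    if (tau == 0) p2 <- c(1, rep(0, d_max))
  }
  p <- p1 + p2
  out <- c(p, max(0, 1 - sum(p)))
  names(out) <- c(j, "tail")
  out
}

#' Equilibrium (stable-population) mismatch law
#'
#' The geometric law \eqn{\hat{F}_j(\theta) = \theta^j/(\theta+1)^{j+1}}
#' for a stationary population, with a tail bucket as in
#' [mismatch_expected()].
#'
#' @param theta scaled mutation rate.
#' @param d_max largest class reported individually.
#' @return named numeric vector over `0..d_max` plus `"tail"`.
#' @export
mismatch_stable <- function(theta, d_max) {
  j <- 0:d_max
  p <- if (theta > 0)
    exp(j * log(theta) - (j + 1) * log(theta + 1)) else c(1, rep(0, d_max))
  out <- c(p, max(0, 1 - sum(p)))
  names(out) <- c(j, "tail")
  out
}

#' Align an observed spectrum with a model spectrum (internal)
#' Observed frequencies are extended with an explicit zero tail bucket.
#' @noRd
obs_with_tail <- function(obs_freqs, d_max) {
  x <- numeric(d_max + 2L)
  x[seq_along(obs_freqs)] <- obs_freqs
  names(x) <- c(0:d_max, "tail")
  x
}

#' Sum of squared deviations between two spectra
#' @param x,e numeric vectors of equal length (observed, expected).
#' @return \eqn{\sum_j (x_j - e_j)^2}.
#' @export
ssd_stat <- function(x, e) sum((x - e)^2)

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{j=1}^{d+1} (x_j - x_{j-1})^2} over difference classes
#' `0..d` with one appended zero class (`x_{d+1} = 0`). Smooth unimodal
#' spectra give small values; ragged multimodal spectra large ones. The
#' appended-zero convention is fixed here once; variants exist across
#' programs.
#'
#' @param freqs relative frequencies over classes `0..d`.
#' @return the raggedness index.
#' @export
raggedness <- function(freqs) {
  x <- c(freqs, 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimises the sum of squared deviations between the observed
#' difference-class frequencies (with an explicit zero tail bucket) and
#' the model-expected spectrum, by bounded quasi-Newton least squares
#' from multiple fixed starting points (a moment-based start,
#' \eqn{\tau \approx \bar{k}}, plus a deterministic grid).
#'
#' @param obs a [mismatch_observed()] object.
#' @param n_starts number of starting points (>= 5 recommended).
#' @return object of class `"expansion_fit"` with elements `tau`,
#'   `theta0`, `theta1`, `ssd`, `obs`, `convergence`. Methods: `coef`,
#'   `print`, `predict`, `fitted`, `plot`.
#' @export
fit_expansion <- function(obs, n_starts = 8) {
  stopifnot(inherits(obs, "mismatch"))
  if (obs$n_pairs < 3) stop("need at least 3 pairs to fit the model")
  if (sum(obs$freqs) <= 0) stop("degenerate (all-zero) observed spectrum")
  d_max <- length(obs$freqs) - 1L
  x <- obs_with_tail(obs$freqs, d_max)
  kbar <- sum(as.numeric(names(obs$freqs)) * obs$freqs)
  objective <- function(par) {
    e <- mismatch_expected(par[1], par[2], par[3], d_max)
    sum((x - e)^2)
  }
  # bounds scale with the observed mean pairwise difference: an
  # unconstrained theta1 runs to degenerate star-tree fits whose
  # segregating-site content far exceeds the data's
  lower <- c(0, 0, 1e-4)
  upper <- c(max(10 * kbar + 10, 50), max(2 * kbar, 5), max(25 * kbar, 50))
  starts <- list(c(max(kbar, 0.5), 0.1, max(10 * kbar, 10)),
                 c(max(kbar / 2, 0.2), 0.5, 50),
                 c(1, 0.01, 100),
                 c(5, 1, 20),
                 c(0.5, 0.01, 1000),
                 c(2, 0.2, 5),
                 c(max(kbar * 2, 1), 0.05, 500),
                 c(0.1, 2, 10))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  best <- NULL
  conv <- integer(0)
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(st, lower), upper), objective,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("expansion-model fit failed to converge from all starting points")
  structure(list(tau = best$par[1], theta0 = best$par[2],
                 theta1 = best$par[3], ssd = best$value,
                 obs = obs, d_max = d_max, convergence = conv),
            class = "expansion_fit")
}

#' @export
coef.expansion_fit <- function(object, ...)
  c(tau = object$tau, theta0 = object$theta0, theta1 = object$theta1)

#' @export
print.expansion_fit <- function(x, ...) {
  cat("Sudden-expansion model fit\n")
  cat(sprintf("  tau = %.4f, theta0 = %.4f, theta1 = %.4f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.6g over classes 0..%d (+tail)\n", x$ssd, x$d_max))
  invisible(x)
}

#' @export
fitted.expansion_fit <- function(object, ...)
  mismatch_expected(object$tau, object$theta0, object$theta1, object$d_max)

#' @export
#' @param object an `expansion_fit`.
#' @param d_max difference classes to predict over (default: as fitted).
#' @rdname fit_expansion
predict.expansion_fit <- function(object, d_max = object$d_max, ...)
  mismatch_expected(object$tau, object$theta0, object$theta1, d_max)

#' @export
plot.expansion_fit <- function(x, ...) {
  obs <- obs_with_tail(x$obs$freqs, x$d_max)
  e <- fitted(x)
  bp <- graphics::barplot(obs[seq_len(x$d_max + 1L)],
                          names.arg = 0:x$d_max, col = "grey85",
                          xlab = "pairwise differences",
                          ylab = "relative frequency", ...)
  graphics::lines(bp, e[seq_len(x$d_max + 1L)], lwd = 2)
  graphics::points(bp, e[seq_len(x$d_max + 1L)], pch = 16)
  invisible(x)
}

#' Parametric-bootstrap goodness-of-fit for the expansion model
#'
#' Computes the SSD and raggedness index of the observed spectrum
#' against the fitted expectation, then their p-values as the fraction
#' of parametric-bootstrap replicates with a statistic at least as
#' large: each replicate simulates a coalescent sample of the same size
#' under the fitted (tau, theta0, theta1), refits the model, and
#' evaluates the statistic against its own refitted expectation.
#'
#' @param obs a [mismatch_observed()] object.
#' @param fit the [fit_expansion()] result for `obs`.
#' @param n_boot bootstrap replicates (>= 1; 1000 in typical use).
#' @param seed optional RNG seed.
#' @return list with `SSD`, `RI`, `p_SSD`, `p_RI`, `n_boot`.
#' @export
ssd_raggedness_test <- function(obs, fit, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(obs, "mismatch"), inherits(fit, "expansion_fit"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d_max <- fit$d_max
  x <- obs_with_tail(obs$freqs, d_max)
  e <- fitted(fit)
  SSD <- ssd_stat(x, e)
  RI <- raggedness(obs$freqs)
  ssd_b <- ri_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    mat <- sim_expansion_sample(obs$n, fit$tau, fit$theta0, fit$theta1)
    k <- pairdiff_from_binary(mat)
    d <- max(k)
    fr <- tabulate(k + 1L, nbins = d + 1L) / length(k)
    names(fr) <- 0:d
    ob <- structure(list(freqs = fr, n_pairs = length(k), n = obs$n),
                    class = "mismatch")
    fb <- tryCatch(fit_expansion(ob, n_starts = 4), error = function(e) NULL)
    if (is.null(fb)) {
      ssd_b[b] <- NA
      ri_b[b] <- NA
      next
    }
    ssd_b[b] <- ssd_stat(obs_with_tail(fr, fb$d_max), fitted(fb))
    ri_b[b] <- raggedness(fr)
  }
  list(SSD = SSD, RI = RI,
       p_SSD = mean(ssd_b >= SSD, na.rm = TRUE),
       p_RI = mean(ri_b >= RI, na.rm = TRUE),
       n_boot = n_boot)
}

#' Pairwise difference counts from a 0/1 site matrix (internal)
#' @noRd
pairdiff_from_binary <- function(mat) {
  n <- nrow(mat)
  if (ncol(mat) == 0L) return(rep(0L, n * (n - 1) / 2))
  d <- as.matrix(stats::dist(mat, method = "manhattan"))
  as.integer(d[upper.tri(d)])
}
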