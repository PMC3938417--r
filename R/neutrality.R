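# Neutrality-test statistics: Tajima's D, Fu's Fs and Ramos-Onsins &
# Rozas's R2, computed either from an alignment or from the raw
# ingredients (S, mean pairwise differences, singleton counts), with
# significance from fixed-S coalescent nulls.

#' Tajima's D from its ingredients (internal)
#' @noRd
tajima_d_from_stats <- function(n, S, kbar) {
  if (S < 1 || n < 2) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (kbar - S / a1) / sqrt(v)
}

# cache of log unsigned Stirling numbers of the first kind, per n
.stirling_env <- new.env(parent = emptyenv())

#' log |s(n, k)| for k = 1..n (internal)
#'
#' Built by the recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| carried in
#' log space, cached per sample size.
#' @noRd
log_stirling1 <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_env[[key]])) return(.stirling_env[[key]])
  lg <- log(1)                       # n = 1: |s(1,1)| = 1
  for (m in 2:n) {
    prev <- c(-Inf, lg, -Inf)        # pad for k-1 and k = m
    lg_new <- numeric(m)
    for (k in seq_len(m)) {
      a <- log(m - 1) + prev[k + 1]  # (m-1)|s(m-1,k)|
      b <- prev[k]                   # |s(m-1,k-1)|
      lg_new[k] <- logsumexp(c(a, b))
    }
    lg <- lg_new
  }
  .stirling_env[[key]] <- lg
  lg
}

#' Ewens sampling distribution of the number of haplotypes
#'
#' \eqn{P(K=k) = |s(n,k)|\,\theta^k / \theta_{(n)}} with
#' \eqn{\theta_{(n)}} the rising factorial; computed in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation rate (> 0).
#' @return numeric vector of probabilities for `k = 1..n`.
#' @export
ewens_distribution <- function(n, theta) {
  if (theta <= 0) stop("theta must be positive")
  lg <- log_stirling1(n)
  lp <- lg + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(lp)
}

#' Fu's Fs from its ingredients (internal)
#'
#' S' = P(K >= k_obs | theta = kbar) under the Ewens sampling formula;
#' Fs = ln(S'/(1-S')), evaluated in log space for stability.
#' @noRd
fs_from_stats <- function(n, kbar, k_obs) {
  if (n < 2 || kbar <= 0 || k_obs < 2) return(NA_real_)
  lg <- log_stirling1(n)
  lp <- lg + seq_len(n) * log(kbar) - sum(log(kbar + 0:(n - 1)))
  lp <- lp - logsumexp(lp)            # guard against rounding drift
  ls_hi <- logsumexp(lp[k_obs:n])
  ls_lo <- logsumexp(lp[seq_len(k_obs - 1)])
  ls_hi - ls_lo
}

#' R2 from its ingredients (internal)
#' @noRd
r2_from_stats <- function(n, S, kbar, U) {
  if (S < 1) return(NA_real_)
  sqrt(mean((U - kbar / 2)^2)) / S
}

#' Alignment ingredients for the neutrality tests (internal)
#'
#' S counts sites with at least two base states among non-missing,
#' non-gap characters; kbar is the mean pairwise difference (pairwise
#' deletion); U_i is the folded singleton count of sequence i (sites at
#' which it alone differs from all the others); k_obs the number of
#' haplotypes by exact identity over non-missing sites.
#' @noRd
aln_neutrality_stats <- function(aln, population = NULL) {
  aln <- aln_subset(aln, population)
  m <- aln$seq
  n <- nrow(m)
  usable <- !(is_missing_char(m) | m == "-")
  S <- 0L
  U <- numeric(n)
  for (s in seq_len(ncol(m))) {
    obs <- usable[, s]
    states <- m[obs, s]
    tab <- table(states)
    if (length(tab) >= 2L) {
      S <- S + 1L
      if (length(tab) == 2L && min(tab) == 1L) {
        minority <- names(tab)[which.min(tab)]
        idx <- which(obs)[states == minority]
        U[idx] <- U[idx] + 1
      }
    }
  }
  pd <- pairwise_differences(aln)
  kbar <- mean(pd$diff[upper.tri(pd$diff)])
  k_obs <- nrow(collapse_haplotypes(aln)$table$counts)
  list(n = n, S = S, kbar = kbar, U = U, k_obs = k_obs)
}

#' @noRd
get_null <- function(null, n, S, reps, seed) {
  if (!is.null(null)) return(null)
  if (reps < 1) return(NULL)
  coalescent_null(n, S, reps = reps, seed = seed)
}

#' Tajima's D with a coalescent p-value
#'
#' \eqn{D = (\bar{k} - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the
#' classical constants. The p-value is the two-tailed empirical fraction
#' from a fixed-S coalescent null (negative D signals an excess of rare
#' variants, as after demographic expansion).
#'
#' @param aln a [alignment()] object.
#' @param population optional population to subset to.
#' @param reps coalescent replicates for the p-value (0 to skip).
#' @param seed optional RNG seed.
#' @param null optional precomputed [coalescent_null()] data.frame, to
#'   share one null across tests.
#' @return list with `D`, `p`, `S`, `kbar`; `D` is `NA` when `S = 0`.
#' @export
tajimas_d <- function(aln, population = NULL, reps = 1000, seed = NULL,
                      null = NULL) {
  st <- aln_neutrality_stats(aln, population)
  D <- tajima_d_from_stats(st$n, st$S, st$kbar)
  p <- NA_real_
  if (!is.na(D)) {
    null <- get_null(null, st$n, st$S, reps, seed)
    if (!is.null(null)) {
      nd <- null$D[!is.na(null$D)]
      p <- min(1, 2 * min(mean(nd <= D), mean(nd >= D)))
    }
  }
  list(D = D, p = p, S = st$S, kbar = st$kbar)
}

#' Fu's Fs with a coalescent p-value
#'
#' Fs compares the observed number of haplotypes with the number
#' expected under the Ewens sampling formula at \eqn{\theta = \bar{k}}:
#' \eqn{F_s = \ln(S'/(1-S'))} with \eqn{S' = P(K \ge k_{obs})}. Large
#' negative values signal an excess of haplotypes, as after expansion.
#' The p-value is the low-tail fraction of the coalescent null.
#'
#' @inheritParams tajimas_d
#' @return list with `Fs`, `p`, `k_obs`, `kbar`; `Fs` is `NA` when all
#'   sequences are identical or `k_obs < 2`.
#' @export
fus_fs <- function(aln, population = NULL, reps = 1000, seed = NULL,
                   null = NULL) {
  st <- aln_neutrality_stats(aln, population)
  Fs <- fs_from_stats(st$n, st$kbar, st$k_obs)
  p <- NA_real_
  if (!is.na(Fs)) {
    null <- get_null(null, st$n, max(st$S, 1L), reps, seed)
    if (!is.null(null)) {
      nf <- null$Fs[!is.na(null$Fs)]
      p <- mean(nf <= Fs)
    }
  }
  list(Fs = Fs, p = p, k_obs = st$k_obs, kbar = st$kbar)
}

#' Ramos-Onsins & Rozas's R2 with a coalescent p-value
#'
#' \eqn{R_2 = \sqrt{\frac{1}{n}\sum_i (U_i - \bar{k}/2)^2} / S}, where
#' \eqn{U_i} is the number of folded singletons carried by sequence i.
#' Small values signal expansion; the p-value is the low-tail fraction
#' of the coalescent null.
#'
#' @inheritParams tajimas_d
#' @return list with `R2`, `p`, `S`; `R2` is `NA` when `S = 0`.
#' @export
r2_statistic <- function(aln, population = NULL, reps = 1000, seed = NULL,
                         null = NULL) {
  st <- aln_neutrality_stats(aln, population)
  R2 <- r2_from_stats(st$n, st$S, st$kbar, st$U)
  p <- NA_real_
  if (!is.na(R2)) {
    null <- get_null(null, st$n, st$S, reps, seed)
    if (!is.null(null)) {
      nr <- null$R2[!is.na(null$R2)]
      p <- mean(nr <= R2)
    }
  }
  list(R2 = R2, p = p, S = st$S)
}

#' All neutrality tests for one population, sharing one coalescent null
#'
#' @inheritParams tajimas_d
#' @return an object of class `"neutrality_test"` carrying `S`, `kbar`,
#'   `D`, `Fs`, `R2` and their p-values.
#' @export
neutrality_test <- function(aln, population = NULL, reps = 1000,
                            seed = NULL) {
  st <- aln_neutrality_stats(aln, population)
  null <- if (st$S >= 1 && reps >= 1)
    coalescent_null(st$n, st$S, reps = reps, seed = seed) else NULL
  d <- tajimas_d(aln, population, null = null, reps = reps)
  f <- fus_fs(aln, population, null = null, reps = reps)
  r <- r2_statistic(aln, population, null = null, reps = reps)
  structure(list(population = population %||% "(all)", n = st$n,
                 S = st$S, kbar = st$kbar,
                 D = d$D, p_D = d$p, Fs = f$Fs, p_Fs = f$p,
                 R2 = r$R2, p_R2 = r$p, reps = reps),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf("Neutrality tests - population %s (n = %d)\n",
              x$population, x$n))
  cat(sprintf("  S = %d, mean pairwise differences = %.3f\n", x$S, x$kbar))
  fmt <- function(v, p, tail) {
    if (is.na(v)) return("n.a.")
    sprintf("%8.3f  (p = %s, %s)", v,
            if (is.na(p)) "n.a." else format.pval(p, digits = 3), tail)
  }
  cat("  Tajima's D :", fmt(x$D, x$p_D, "two-tailed"), "\n")
  cat("  Fu's Fs    :", fmt(x$Fs, x$p_Fs, "low tail"), "\n")
  cat("  R2         :", fmt(x$R2, x$p_R2, "low tail"), "\n")
  invisible(x)
}
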