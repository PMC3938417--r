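# Standard neutral (Kingman) coalescent engine used for null
# distributions of the neutrality tests, and a variable-size variant for
# parametric bootstraps of the sudden-expansion model.

#' Simulate one Kingman genealogy (internal)
#'
#' Time is in coalescent units of 2N generations. Returns, per coalescent
#' interval, the lineages present (as leaf index sets) and the interval
#' duration, which is all that mutation placement needs.
#' @noRd
sim_genealogy <- function(n) {
  lin <- as.list(seq_len(n))
  k <- n
  intervals <- vector("list", n - 1L)
  dur <- numeric(n - 1L)
  i <- 0L
  while (k > 1L) {
    i <- i + 1L
    dur[i] <- stats::rexp(1, rate = k * (k - 1) / 2)
    intervals[[i]] <- lin
    pick <- sample.int(k, 2L)
    merged <- c(lin[[pick[1]]], lin[[pick[2]]])
    lin[[pick[1]]] <- merged
    lin[pick[2]] <- NULL
    k <- k - 1L
  }
  list(intervals = intervals, dur = dur, tmrca = sum(dur))
}

#' Place a fixed number of mutations uniformly on a genealogy (internal)
#'
#' Fixed-S conditioning: exactly `S` mutations, each on a branch chosen
#' with probability proportional to its length, under infinite sites
#' (every mutation a new column). Returns an n x S 0/1 matrix.
#' @noRd
drop_mutations_fixed_s <- function(gen, n, S) {
  if (S == 0L) return(matrix(0L, n, 0L))
  k <- lengths(gen$intervals)
  w <- k * gen$dur
  iv <- sample.int(length(w), S, replace = TRUE, prob = w)
  mat <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    lins <- gen$intervals[[iv[s]]]
    carrier <- lins[[sample.int(length(lins), 1L)]]
    mat[carrier, s] <- 1L
  }
  mat
}

#' Summary statistics from a 0/1 site matrix (internal)
#'
#' Computes the segregating-site count, mean pairwise differences,
#' per-sequence folded singleton counts and the number of distinct
#' haplotypes, the raw ingredients of Tajima's D, Fu's Fs and R2.
#' @noRd
binary_site_stats <- function(mat) {
  n <- nrow(mat)
  cs <- colSums(mat)
  seg <- cs > 0L & cs < n
  mat <- mat[, seg, drop = FALSE]
  cs <- cs[seg]
  S <- length(cs)
  npairs <- n * (n - 1) / 2
  kbar <- if (S) sum(cs * (n - cs)) / npairs else 0
  U <- numeric(n)
  for (s in seq_len(S)) {
    if (cs[s] == 1L) {
      U[which(mat[, s] == 1L)] <- U[which(mat[, s] == 1L)] + 1
    } else if (cs[s] == n - 1L) {
      U[which(mat[, s] == 0L)] <- U[which(mat[, s] == 0L)] + 1
    }
  }
  k_obs <- length(unique(apply(mat, 1, paste, collapse = "")))
  list(n = n, S = S, kbar = kbar, U = U, k_obs = k_obs)
}

#' Coalescent null distributions for the neutrality tests
#'
#' Simulates standard neutral Kingman genealogies and, per replicate,
#' places exactly `S_obs` mutations uniformly on the branches (fixed-S
#' conditioning, the convention of common sequence-analysis software),
#' then evaluates Tajima's D, Fu's Fs and R2 on the simulated sample.
#'
#' @param n sample size (>= 2).
#' @param S_obs observed number of segregating sites (>= 1).
#' @param reps number of replicates (default 1000).
#' @param seed optional RNG seed.
#' @return data.frame with columns `D`, `Fs`, `R2`, `tmrca` (coalescent
#'   units of 2N generations); statistics are `NA` where undefined in a
#'   replicate.
#' @export
coalescent_null <- function(n, S_obs, reps = 1000, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (S_obs < 1) stop("S_obs must be >= 1")
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("D", "Fs", "R2", "tmrca")))
  for (r in seq_len(reps)) {
    gen <- sim_genealogy(n)
    mat <- drop_mutations_fixed_s(gen, n, S_obs)
    st <- binary_site_stats(mat)
    out[r, "D"] <- tajima_d_from_stats(st$n, st$S, st$kbar)
    out[r, "Fs"] <- fs_from_stats(st$n, st$kbar, st$k_obs)
    out[r, "R2"] <- r2_from_stats(st$n, st$S, st$kbar, st$U)
    out[r, "tmrca"] <- gen$tmrca
  }
  as.data.frame(out)
}

#' Simulate sequences under the sudden-expansion coalescent (internal)
#'
#' Genealogy in mutational time: with k lineages the coalescence rate is
#' k(k-1)/2 / theta(x), where theta(x) = theta1 more recently than the
#' expansion time tau and theta0 beyond it. Each branch mutates at rate
#' 1/2 per unit mutational time, so a pair coalescing at time x carries
#' Poisson(x) differences; at equilibrium this yields the geometric
#' pairwise-difference law. Returns a 0/1 site matrix.
#' @noRd
sim_expansion_sample <- function(n, tau, theta0, theta1) {
  lin <- as.list(seq_len(n))
  k <- n
  x <- 0
  blen <- numeric(0)       # branch lengths, aligned with carriers
  carriers <- list()
  birth <- rep(0, n)       # time each current lineage started
  ids <- seq_len(n)        # current lineage -> index into birth
  nlin <- n
  while (k > 1L) {
    repeat {
      th <- if (x < tau) theta1 else max(theta0, 1e-9)
      rate <- k * (k - 1) / 2 / th
      w <- stats::rexp(1, rate)
      if (x < tau && x + w > tau) {
        # epoch boundary: redraw in the older epoch from tau
        x <- tau
        next
      }
      x <- x + w
      break
    }
    pick <- sample.int(k, 2L)
    for (p in pick) {
      blen <- c(blen, x - birth[ids[p]])
      carriers <- c(carriers, list(lin[[p]]))
    }
    merged <- c(lin[[pick[1]]], lin[[pick[2]]])
    lin[[pick[1]]] <- merged
    nlin <- nlin + 1L
    birth <- c(birth, x)
    ids[pick[1]] <- nlin
    lin[pick[2]] <- NULL
    ids <- ids[-pick[2]]
    k <- k - 1L
  }
  nmut <- stats::rpois(length(blen), blen / 2)
  tot <- sum(nmut)
  if (tot == 0L) return(matrix(0L, n, 0L))
  mat <- matrix(0L, n, tot)
  col <- 0L
  for (b in seq_along(blen)) {
    if (nmut[b] > 0L) {
      for (j in seq_len(nmut[b])) {
        col <- col + 1L
        mat[carriers[[b]], col] <- 1L
      }
    }
  }
  mat
}
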