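# Independent brute-force oracles, coded separately from the package
# internals: double loops and exact polynomial arithmetic only.

# probability that two draws without replacement differ, by enumeration
# of all ordered pairs
oracle_hap_div <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  n <- length(labels)
  if (n < 2) return(NA_real_)
  diff <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && labels[i] != labels[j]) diff <- diff + 1L
  }
  diff / (n * (n - 1))
}

# per-site nucleotide diversity by exhaustive pair comparison,
# pairwise deletion
oracle_pi <- function(seqmat) {
  n <- nrow(seqmat)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- seqmat[i, ]; b <- seqmat[j, ]
    ok <- !(a %in% c("N", "?", "-")) & !(b %in% c("N", "?", "-"))
    vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
  }
  mean(vals)
}

# raw ingredients from a gap-free character matrix, by scanning
oracle_ingredients <- function(seqmat) {
  n <- nrow(seqmat); L <- ncol(seqmat)
  S <- 0L
  U <- numeric(n)
  for (s in seq_len(L)) {
    col <- seqmat[, s]
    if (length(unique(col)) >= 2) S <- S + 1L
    for (i in seq_len(n)) {
      if (all(col[-i] == col[-i][1]) && col[i] != col[-i][1])
        U[i] <- U[i] + 1
    }
  }
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(seqmat[i, ] != seqmat[j, ])
  kbar <- tot / (n * (n - 1) / 2)
  k_obs <- length(unique(apply(seqmat, 1, paste, collapse = "")))
  list(n = n, S = S, kbar = kbar, U = U, k_obs = k_obs)
}

oracle_tajima_d <- function(seqmat) {
  g <- oracle_ingredients(seqmat)
  n <- g$n; S <- g$S
  if (S < 1) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (g$kbar - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# exact unsigned Stirling numbers of the first kind from the rising
# factorial polynomial x(x+1)...(x+n-1): an independent route to the
# Ewens probabilities (exact in doubles for small n)
oracle_stirling1 <- function(n) {
  coefs <- c(0, 1)                       # polynomial x
  if (n >= 2) for (m in 1:(n - 1)) {
    shifted <- c(0, coefs)               # x * p(x)
    coefs <- m * c(coefs, 0) + shifted   # (x + m) p(x)
  }
  coefs[2:(n + 1)]                       # |s(n, k)|, k = 1..n
}

oracle_fs <- function(seqmat) {
  g <- oracle_ingredients(seqmat)
  if (g$kbar <= 0 || g$k_obs < 2) return(NA_real_)
  st <- oracle_stirling1(g$n)
  theta <- g$kbar
  pk <- st * theta^seq_len(g$n) / prod(theta + 0:(g$n - 1))
  sp <- sum(pk[g$k_obs:g$n])
  log(sp / (1 - sp))
}

oracle_r2 <- function(seqmat) {
  g <- oracle_ingredients(seqmat)
  if (g$S < 1) return(NA_real_)
  sqrt(sum((g$U - g$kbar / 2)^2) / g$n) / g$S
}

# random gap-free toy alignment: mutations scattered over random
# subsets of sequences so that realistic S, singleton and haplotype
# structure all arise
random_toy_alignment <- function(n = NULL, L = NULL) {
  n <- n %||% sample(4:8, 1)
  L <- L %||% sample(12:30, 1)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(base, each = n), n, L)
  nmut <- sample(1:8, 1)
  for (k in seq_len(nmut)) {
    site <- sample.int(L, 1)
    who <- sample.int(n, sample.int(n - 1, 1))
    m[who, site] <- sample(setdiff(c("A", "C", "G", "T"), base[site]), 1)
  }
  m
}

aln_from_matrix <- function(m, population = "pop") {
  alignment(paste0("s", seq_len(nrow(m))), rep(population, nrow(m)),
            apply(m, 1, paste, collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
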