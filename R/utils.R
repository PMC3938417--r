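# Internal helpers shared across modules.

MISSING_CHARS <- c("N", "?")
ALLOWED_CHARS <- c("A", "C", "G", "T", "-", "N", "?")

#' @noRd
is_missing_char <- function(x) x == "N" | x == "?"

#' Row-wise multinomial sampling via a chain of binomials.
#'
#' Draws one multinomial vector per row of `prob`, with per-row sizes.
#' Equivalent in law to calling `rmultinom()` once per row, but vectorised
#' across rows so that thousands of simulation replicates advance together.
#'
#' @param size integer vector (recycled) of total counts per row.
#' @param prob numeric matrix, rows summing to 1 (rows are renormalised).
#' @return integer matrix of the same dimension as `prob`, rows summing to
#'   `size`.
#' @noRd
rmultinom_rows <- function(size, prob) {
  n <- nrow(prob)
  k <- ncol(prob)
  size <- rep_len(as.integer(size), n)
  rs <- rowSums(prob)
  bad <- !is.finite(rs) | rs <= 0
  if (any(bad)) stop("invalid probability rows in multinomial sampling")
  prob <- prob / rs
  out <- matrix(0L, n, k)
  if (k == 1L) {
    out[, 1L] <- size
    return(out)
  }
  remaining <- size
  prem <- rep(1, n)
  for (j in seq_len(k - 1L)) {
    pj <- prob[, j] / prem
    pj[!is.finite(pj)] <- 0
    pj <- pmin(pmax(pj, 0), 1)
    x <- stats::rbinom(n, remaining, pj)
    # rbinom returns NA only for invalid input; sizes of 0 give 0
    out[, j] <- x
    remaining <- remaining - x
    prem <- prem - prob[, j]
  }
  out[, k] <- remaining
  out
}

#' Largest-remainder apportionment of n among target frequencies.
#' Ties in the fractional remainders are broken by index order.
#' @noRd
largest_remainder <- function(freqs, n) {
  raw <- freqs * n
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' log(sum(exp(x))) without overflow.
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
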