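#' Nei's unbiased haplotype (gene) diversity
#'
#' \eqn{H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}, the probability
#' that two individuals drawn without replacement carry different
#' haplotypes.
#'
#' @param counts vector of positive haplotype counts for one population.
#' @return diversity in `[0, 1]`, or `NA` when `n < 2` (printed as "-"
#'   in survey tables).
#' @examples
#' haplotype_diversity(c(34, 1, 1))  # ~0.11
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Comparison populations for private-haplotype counts (internal)
#'
#' With population metadata: other wild populations at the same grouping
#' level (country vs country, continent vs continent); laboratory-strain
#' and grand-total columns never enter the comparison set of wild
#' populations, while the strains themselves are compared against all
#' wild country-level columns. Without metadata every other population is
#' the comparison set.
#' @noRd
private_comparison_set <- function(table, population) {
  meta <- table$pop_meta
  pops <- table$populations
  if (is.null(meta)) return(setdiff(pops, population))
  lvl <- meta$level[match(population, meta$population)]
  if (is.na(lvl)) stop("population missing from metadata: ", population)
  if (lvl == "total")
    stop("private haplotypes are undefined for the grand-total column")
  if (lvl == "strain") {
    cmp <- meta$population[meta$level == "country"]
  } else {
    cmp <- meta$population[meta$level == lvl]
    cmp <- setdiff(cmp, population)
    if (lvl == "country") {
      # a country is not compared against its own continent
      parent <- meta$parent[match(population, meta$population)]
      cmp <- setdiff(cmp, parent)
    }
  }
  intersect(cmp, pops)
}

#' Haplotype number and private haplotypes of a population
#'
#' `h` is the number of haplotypes observed in the population;
#' `private_h` the number of those absent from every other wild
#' population at the same grouping level (see
#' [load_printed_table()] for the metadata that defines levels).
#'
#' @param table a [haplotype_table()].
#' @param population a population (column) name.
#' @return list with `h` and `private_h`.
#' @export
haplotype_summary <- function(table, population) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!population %in% table$populations)
    stop("unknown population: ", population)
  own <- table$counts[, population] > 0
  cmp <- private_comparison_set(table, population)
  if (length(cmp) == 0L) {
    priv <- sum(own)
  } else {
    elsewhere <- rowSums(table$counts[, cmp, drop = FALSE]) > 0
    priv <- sum(own & !elsewhere)
  }
  list(h = sum(own), private_h = priv)
}

#' Nucleotide diversity per site
#'
#' \eqn{\pi = \frac{2}{n(n-1)} \sum_{i<j} k_{ij} / L_{ij}}, with pairwise
#' differences \eqn{k_{ij}} counted over sites where both sequences carry
#' a base (gaps and missing excluded) and \eqn{L_{ij}} the number of such
#' sites. With `deletion = "pairwise"` (default) each pair uses its own
#' \eqn{L_{ij}}, accommodating partial sequences of heterogeneous length;
#' `"complete"` restricts all pairs to sites observed in every sequence.
#'
#' @param aln a [alignment()] object.
#' @param population optional population to subset to.
#' @param deletion `"pairwise"` or `"complete"` site policy.
#' @return per-site diversity (multiply by 1000 for the conventional
#'   reporting scale), or `NA` when fewer than 2 sequences.
#' @export
nucleotide_diversity <- function(aln, population = NULL,
                                 deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  aln <- aln_subset(aln, population)
  n <- length(aln$sample_id)
  if (n < 2) return(NA_real_)
  if (deletion == "complete") {
    usable <- !(is_missing_char(aln$seq) | aln$seq == "-")
    keep <- colSums(usable) == n
    if (!any(keep)) return(NA_real_)
    aln$seq <- aln$seq[, keep, drop = FALSE]
    aln$L <- sum(keep)
  }
  pd <- pairwise_differences(aln)
  ut <- upper.tri(pd$diff)
  ok <- pd$sites[ut] > 0
  mean((pd$diff[ut] / pd$sites[ut])[ok])
}

#' Table-3-style diversity summary across populations
#'
#' Computes, for each requested population, the sample size, haplotype
#' number `h`, private haplotype count `P_h`, haplotype diversity `hd`
#' and (when an alignment is supplied) nucleotide diversity `pi_1000`
#' on the conventional x1000 scale. Frequency-based columns are rounded
#' only at this reporting layer (2 decimals, as printed in survey
#' tables); use the underlying functions for full precision.
#'
#' @param table a [haplotype_table()].
#' @param populations populations to report; default all columns.
#' @param aln optional matching [alignment()] for nucleotide diversity.
#' @param digits rounding for the reporting columns (default 2; `NA`
#'   for no rounding).
#' @return a data.frame with one row per population.
#' @export
diversity_summary <- function(table, populations = NULL, aln = NULL,
                              digits = 2) {
  stopifnot(inherits(table, "haplotype_table"))
  populations <- populations %||% table$populations
  rows <- lapply(populations, function(p) {
    ct <- pop_counts(table, p)
    hs <- tryCatch(haplotype_summary(table, p),
                   error = function(e) list(h = sum(ct > 0), private_h = NA))
    hd <- haplotype_diversity(ct)
    pi <- if (is.null(aln)) NA_real_ else
      nucleotide_diversity(aln, population = p)
    data.frame(population = p, n = sum(ct), h = hs$h,
               private_h = hs$private_h,
               hap_diversity = hd, pi_1000 = pi * 1000)
  })
  out <- do.call(rbind, rows)
  if (!is.na(digits)) {
    out$hap_diversity <- round(out$hap_diversity, digits)
    out$pi_1000 <- round(out$pi_1000, digits)
  }
  out
}

#' Haplotype-frequency Fst between two populations
#'
#' \eqn{F_{ST} = (H_T - H_S)/H_T} on haplotype frequencies, where
#' \eqn{H_T} is the unbiased gene diversity of the pooled sample and
#' \eqn{H_S} the sample-size-weighted mean within-population diversity.
#' Significance comes from permuting individuals between the two
#' populations. No molecular distance between haplotypes enters this
#' estimator.
#'
#' @param table a [haplotype_table()].
#' @param popA,popB population (column) names.
#' @param permutations number of label permutations for the p-value
#'   (0 to skip).
#' @param seed optional RNG seed.
#' @return list with `fst` (clipped to `[0, 1]`) and `p` (`NA` when
#'   `permutations = 0`). Two populations fixed for the same haplotype
#'   give `fst = 0, p = 1`.
#' @export
fst_haplotype <- function(table, popA, popB, permutations = 1000,
                          seed = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  a <- table$counts[, popA]
  b <- table$counts[, popB]
  if (sum(a) < 2 || sum(b) < 2)
    stop("both populations need n >= 2")
  obs <- fst_from_counts(a, b)
  if (is.na(obs)) return(list(fst = 0, p = 1))
  p <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    pool <- c(rep(seq_along(a), a), rep(seq_along(b), b))
    nA <- sum(a)
    nhap <- length(a)
    null <- replicate(permutations, {
      idx <- sample.int(length(pool), nA)
      pa <- tabulate(pool[idx], nbins = nhap)
      pb <- tabulate(pool[-idx], nbins = nhap)
      f <- fst_from_counts(pa, pb)
      if (is.na(f)) 0 else f
    })
    p <- (sum(null >= obs) + 1) / (permutations + 1)
  }
  list(fst = min(max(obs, 0), 1), p = p)
}

#' @noRd
fst_from_counts <- function(a, b) {
  ht <- haplotype_diversity(a + b)
  if (is.na(ht) || ht == 0) return(NA_real_)
  hs <- (sum(a) * haplotype_diversity(a) + sum(b) * haplotype_diversity(b)) /
    (sum(a) + sum(b))
  (ht - hs) / ht
}
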