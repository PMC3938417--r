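# Synthetic alignments and haplotype tables with prescribed frequency
# spectra and segregating-site structure, so that every statistical
# stage of the package is testable without sequence downloads.

#' Generate a haplotype table with one dominant haplotype
#'
#' Builds a single-population count table with a focal haplotype at
#' frequency approximately `i0` and the remaining `1 - i0` shared
#' equally by the other haplotypes, realised exactly over `n_samples`
#' individuals by largest-remainder rounding (remainder ties broken by
#' haplotype order). This is the founding spectrum of the forward
#' simulations: one most common haplotype against an equal-frequency
#' background.
#'
#' @param n_haplotypes number of haplotypes (>= 1).
#' @param n_samples number of individuals.
#' @param i0 focal-haplotype frequency in (0, 1].
#' @param prefix haplotype name prefix (default `"H"`).
#' @param population population (column) name.
#' @return a [haplotype_table()] with one column.
#' @export
generate_table <- function(n_haplotypes, n_samples, i0 = 1,
                           prefix = "H", population = "pop1") {
  if (n_haplotypes < 1) stop("n_haplotypes must be >= 1")
  if (i0 <= 0 || i0 > 1) stop("i0 must be in (0, 1]")
  freqs <- if (n_haplotypes == 1) 1 else
    c(i0, rep((1 - i0) / (n_haplotypes - 1), n_haplotypes - 1))
  counts <- largest_remainder(freqs, n_samples)
  if (n_haplotypes > 1 && counts[1] == 0)
    stop("i0 too small: focal haplotype rounds to zero samples")
  if (any(counts == 0))
    stop("n_samples too small to realise all haplotypes")
  m <- matrix(counts, ncol = 1,
              dimnames = list(paste0(prefix, seq_len(n_haplotypes)),
                              population))
  haplotype_table(m)
}

#' Generate a synthetic alignment realising a haplotype table
#'
#' Creates one reference sequence per haplotype by placing exactly `S`
#' mutations at distinct sites (infinite sites on a finite length) on a
#' genealogy over the haplotypes - either a Kingman coalescent tree
#' (mutations shared along clades) or a star tree (independent
#' branches) - then emits each sample as a copy of its haplotype's
#' sequence. Optionally a fraction of samples is truncated to a random
#' contiguous prefix or suffix (marked `?`), mimicking partial published
#' sequences. Identical seeds give byte-identical output.
#'
#' @param table a [haplotype_table()]; every haplotype with positive
#'   total count is emitted at its count, per population.
#' @param L alignment length in sites (defaults: 664 for a control-
#'   region-like locus; use 549 for a cytochrome-b-like locus).
#' @param S number of segregating sites; must satisfy
#'   `n_haplotypes - 1 <= S <= L` so that all haplotypes are
#'   distinguishable.
#' @param genealogy `"coalescent"` or `"star"`.
#' @param missing_fraction fraction of samples truncated (default 0).
#' @param seed optional RNG seed.
#' @return a [alignment()] object; haplotype reference sequences are
#'   attached as attribute `"haplotype_seq"`.
#' @export
generate_alignment <- function(table, L = 664, S = 30,
                               genealogy = c("coalescent", "star"),
                               missing_fraction = 0, seed = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  genealogy <- match.arg(genealogy)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  if (S > L) stop("S must not exceed the alignment length L")
  H <- nrow(table$counts)
  if (H > 1 && S < H - 1)
    stop("need S >= n_haplotypes - 1 to distinguish all haplotypes")
  if (H == 1 && S > 0)
    stop("a single haplotype cannot carry segregating sites")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  sites <- sample.int(L, S)
  # carriers[[s]]: haplotype indices carrying the derived state at site s
  carriers <- place_mutations(H, S, genealogy)
  hap_seqs <- matrix(rep(anc, each = H), H, L)
  for (s in seq_len(S)) {
    derived <- sample(setdiff(bases, anc[sites[s]]), 1)
    hap_seqs[carriers[[s]], sites[s]] <- derived
  }
  hap_str <- apply(hap_seqs, 1, paste, collapse = "")
  counts <- table$counts
  idx <- rep(rep(seq_len(H), ncol(counts)), as.vector(counts))
  popl <- rep(rep(table$populations, each = H), as.vector(counts))
  n <- length(idx)
  ids <- sprintf("s%03d", seq_len(n))
  seqs <- hap_str[idx]
  if (missing_fraction > 0) {
    n_miss <- round(missing_fraction * n)
    who <- sample.int(n, n_miss)
    for (i in who) {
      keep <- sample(seq(floor(0.4 * L), floor(0.9 * L)), 1)
      sv <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      if (stats::runif(1) < 0.5) {
        sv[(keep + 1):L] <- "?"       # keep prefix
      } else {
        sv[seq_len(L - keep)] <- "?"  # keep suffix
      }
      seqs[i] <- paste(sv, collapse = "")
    }
  }
  aln <- alignment(ids, popl, seqs, L = L)
  attr(aln, "haplotype_seq") <- stats::setNames(hap_str, table$haplotypes)
  aln
}

#' Assign S mutations to clades of a genealogy over H haplotypes
#' (internal)
#'
#' Coalescent mode simulates a Kingman tree over the haplotype lineages
#' and drops mutations on branches proportionally to length (below the
#' root, so every mutation is a proper subset); star mode assigns each
#' mutation to a single random haplotype. Afterwards any haplotypes
#' left indistinguishable are separated by re-assigning the most
#' recently placed mutations as singletons, preserving the total S.
#' @noRd
place_mutations <- function(H, S, genealogy) {
  if (S == 0L) return(list())
  if (H == 1L) stop("cannot place segregating mutations on one haplotype")
  if (genealogy == "star") {
    carriers <- lapply(sample.int(H, S, replace = TRUE), identity)
  } else {
    gen <- sim_genealogy(H)
    k <- lengths(gen$intervals)
    w <- k * gen$dur
    iv <- sample.int(length(w), S, replace = TRUE, prob = w)
    carriers <- lapply(seq_len(S), function(s) {
      lins <- gen$intervals[[iv[s]]]
      lins[[sample.int(length(lins), 1L)]]
    })
  }
  # guarantee pairwise-distinct haplotypes: peel duplicate members off
  # identity groups with singleton mutations taken from the end
  reassign <- S
  repeat {
    sig <- vapply(seq_len(H), function(h)
      paste(vapply(carriers, function(cr) h %in% cr, logical(1)),
            collapse = ""), character(1))
    dup <- which(duplicated(sig))
    if (length(dup) == 0L) break
    if (reassign < 1L)
      stop("could not separate all haplotypes with the requested S")
    carriers[[reassign]] <- dup[1L]
    reassign <- reassign - 1L
  }
  carriers
}
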