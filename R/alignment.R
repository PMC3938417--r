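#' Construct an aligned set of mtDNA sequences with population labels
#'
#' An alignment is the raw substrate for all sequence-based statistics in
#' the package: nucleotide diversity, mismatch distributions and the
#' neutrality tests. All sequences share one length `L`; shorter (partial)
#' sequences are represented padded with `?` at the unobserved sites.
#' `N` and `?` are missing data; `-` is an alignment gap, kept as a fifth
#' character state for haplotype identity but excluded from pairwise
#' difference counts.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param population character vector of population labels, same length.
#' @param sequence character vector of aligned sequences over
#'   `A,C,G,T,-,N,?` (case-insensitive). Sequences shorter than `L` are
#'   padded with `?` on the right (use `offset` for a different anchor).
#' @param L alignment length in sites. Defaults to the longest sequence.
#' @param offset integer vector of 1-based start positions of each
#'   sequence within the `L`-site frame (default 1).
#' @return an object of class `"hap_alignment"`: a list with elements
#'   `sample_id`, `population`, `seq` (an `n x L` character matrix) and
#'   `L`.
#' @export
alignment <- function(sample_id, population, sequence, L = NULL, offset = 1L) {
  n <- length(sample_id)
  if (n == 0L) stop("alignment is empty")
  if (length(population) != n || length(sequence) != n)
    stop("sample_id, population and sequence must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  sequence <- toupper(sequence)
  offset <- rep_len(as.integer(offset), n)
  lens <- nchar(sequence)
  if (is.null(L)) L <- max(lens + offset - 1L)
  L <- as.integer(L)
  if (any(lens + offset - 1L > L))
    stop("sequence exceeds declared alignment length L = ", L)
  mat <- matrix("?", n, L)
  for (i in seq_len(n)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% ALLOWED_CHARS))
    if (length(bad))
      stop(sprintf("illegal character '%s' at site %d of record '%s'",
                   chars[bad[1]], bad[1] + offset[i] - 1L, sample_id[i]))
    if (length(chars)) mat[i, seq_along(chars) + offset[i] - 1L] <- chars
  }
  rownames(mat) <- sample_id
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 seq = mat, L = L),
            class = "hap_alignment")
}

#' Read an alignment from FASTA plus a sample label table
#'
#' The label table is a CSV with a header and columns `sample_id`,
#' `population`, and optionally `offset` (1-based start of each record in
#' the alignment frame, for partial sequences anchored away from site 1).
#' Every FASTA record must have a label row. Records shorter than `L`
#' (e.g. partial control-region sequences of 278-664 bp against a 664 bp
#' frame) are padded with `?`.
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param labels_path path to the label CSV.
#' @param L declared alignment length; default: longest record.
#' @return a [alignment()] object.
#' @export
read_alignment <- function(fasta_path, labels_path, L = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (file.size(fasta_path) == 0) stop("empty FASTA file: ", fasta_path)
  recs <- seqinr::read.fasta(fasta_path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE, forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("empty FASTA file: ", fasta_path)
  ids <- names(recs)
  seqs <- toupper(unlist(recs, use.names = FALSE))
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(labels)))
    stop("label table must have columns 'sample_id' and 'population'")
  idx <- match(ids, labels$sample_id)
  if (anyNA(idx))
    stop("no label row for record(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  offset <- if ("offset" %in% names(labels)) labels$offset[idx] else 1L
  alignment(ids, labels$population[idx], seqs, L = L, offset = offset)
}

#' Write an alignment to FASTA and a label CSV
#'
#' @param aln a [alignment()] object.
#' @param fasta_path output FASTA path.
#' @param labels_path optional output CSV path for the sample labels.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, labels_path = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = aln$sample_id,
                      file.out = fasta_path, nbchar = 70)
  if (!is.null(labels_path))
    utils::write.csv(data.frame(sample_id = aln$sample_id,
                                population = aln$population),
                     labels_path, row.names = FALSE, quote = FALSE)
  invisible(fasta_path)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n",
              length(x$sample_id), x$L))
  tab <- table(x$population)
  cat("Populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is_missing_char(x$seq))
  if (miss > 0) cat(sprintf("Missing data: %.1f%% of sites\n", 100 * miss))
  invisible(x)
}

#' Subset an alignment to one population (internal).
#' @noRd
aln_subset <- function(aln, population = NULL) {
  if (is.null(population)) return(aln)
  keep <- aln$population %in% population
  if (!any(keep)) stop("unknown population: ", paste(population, collapse = ", "))
  structure(list(sample_id = aln$sample_id[keep],
                 population = aln$population[keep],
                 seq = aln$seq[keep, , drop = FALSE], L = aln$L),
            class = "hap_alignment")
}

#' Pairwise difference count between two site vectors.
#' Gaps and missing characters are excluded from the comparison.
#' @noRd
pair_diff <- function(a, b) {
  ok <- !(is_missing_char(a) | is_missing_char(b) | a == "-" | b == "-")
  c(diff = sum(a[ok] != b[ok]), sites = sum(ok))
}

#' All pairwise difference counts for an alignment (internal).
#' @return list(diff = matrix, sites = matrix) over sequence pairs.
#' @noRd
pairwise_differences <- function(aln) {
  m <- aln$seq
  n <- nrow(m)
  D <- matrix(0, n, n)
  Lm <- matrix(0, n, n)
  usable <- !(is_missing_char(m) | m == "-")
  for (i in seq_len(n)) {
    if (i < n) {
      for (j in (i + 1L):n) {
        ok <- usable[i, ] & usable[j, ]
        d <- sum(m[i, ok] != m[j, ok])
        D[i, j] <- D[j, i] <- d
        Lm[i, j] <- Lm[j, i] <- sum(ok)
      }
    }
  }
  list(diff = D, sites = Lm)
}

#' Collapse aligned sequences into haplotypes
#'
#' Full-length sequences (no missing sites) partition into haplotypes by
#' exact identity; the gap character `-` counts as a fifth state. A
#' sequence with missing data is assigned to the existing haplotype with
#' the smallest Hamming distance over its observed sites (the minimal
#' distance rule used for partial published sequences); if that minimal
#' distance is positive a new haplotype is founded. Distance ties are
#' broken by the highest current haplotype count, then by first-seen
#' order; the number of tied assignments is recorded.
#'
#' @param aln a [alignment()] object.
#' @param prefix haplotype name prefix (default `"H"`).
#' @return a list with components
#'   \describe{
#'     \item{table}{a [haplotype_table()] of counts, haplotype x population.}
#'     \item{assignment}{data.frame with `sample_id`, `haplotype`,
#'       `used_missing_rule`, `min_distance`.}
#'     \item{ties}{number of assignments decided by a tie-break.}
#'     \item{haplotype_seq}{named character vector of representative
#'       sequences.}
#'   }
#' @export
collapse_haplotypes <- function(aln, prefix = "H") {
  stopifnot(inherits(aln, "hap_alignment"))
  m <- aln$seq
  n <- nrow(m)
  missing <- is_missing_char(m)
  if (any(rowSums(missing) == ncol(m)))
    stop("alignment contains an all-missing sequence: ",
         aln$sample_id[which(rowSums(missing) == ncol(m))[1]])
  complete <- rowSums(missing) == 0
  hap_seqs <- character(0)     # representative full sequences
  hap_of <- character(n)
  ties <- 0L
  min_dist <- numeric(n)

  key <- apply(m, 1, paste, collapse = "")
  # pass 1: complete sequences, exact identity in input order
  for (i in which(complete)) {
    hit <- match(key[i], hap_seqs)
    if (is.na(hit)) {
      hap_seqs <- c(hap_seqs, key[i])
      hit <- length(hap_seqs)
    }
    hap_of[i] <- as.character(hit)
  }
  counts <- tabulate(as.integer(hap_of[complete]), nbins = length(hap_seqs))
  # pass 2: partial sequences by minimal distance, input order
  for (i in which(!complete)) {
    obs <- !missing[i, ]
    if (length(hap_seqs)) {
      d <- vapply(hap_seqs, function(h) {
        hv <- strsplit(h, "", fixed = TRUE)[[1]]
        ok <- obs & !is_missing_char(hv)
        sum(hv[ok] != m[i, ok])
      }, numeric(1), USE.NAMES = FALSE)
      best <- min(d)
    } else {
      best <- Inf
    }
    if (is.finite(best) && best == 0) {
      cand <- which(d == best)
      if (length(cand) > 1L) {
        cand <- cand[counts[cand] == max(counts[cand])]
        if (length(cand) > 1L) cand <- cand[1L]  # earliest-named
        ties <- ties + 1L
      }
      hap_of[i] <- as.character(cand)
      counts[cand] <- counts[cand] + 1L
      min_dist[i] <- 0
    } else {
      # found a new haplotype; unobserved sites stay missing in its
      # representative, treated as wildcard in later comparisons
      hap_seqs <- c(hap_seqs, key[i])
      counts <- c(counts, 1L)
      hap_of[i] <- as.character(length(hap_seqs))
      min_dist[i] <- if (is.finite(best)) best else NA_real_
    }
  }
  hid <- paste0(prefix, seq_along(hap_seqs))
  hap_idx <- as.integer(hap_of)
  pops <- unique(aln$population)
  cmat <- matrix(0L, length(hap_seqs), length(pops),
                 dimnames = list(hid, pops))
  for (i in seq_len(n))
    cmat[hap_idx[i], aln$population[i]] <- cmat[hap_idx[i], aln$population[i]] + 1L
  tab <- haplotype_table(cmat)
  assignment <- data.frame(sample_id = aln$sample_id,
                           haplotype = hid[hap_idx],
                           used_missing_rule = !complete,
                           min_distance = ifelse(complete, 0, min_dist),
                           stringsAsFactors = FALSE)
  names(hap_seqs) <- hid
  list(table = tab, assignment = assignment, ties = ties,
       haplotype_seq = hap_seqs)
}
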