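#' Haplotype count tables
#'
#' A haplotype table holds non-negative integer counts of haplotypes
#' (rows) across populations (columns). It is the unit of all
#' frequency-based statistics: haplotype diversity, private haplotype
#' counts and haplotype-frequency Fst. Column sums are the per-population
#' sample sizes. Every haplotype must be observed at least once overall.
#'
#' @param counts integer matrix, haplotypes x populations, with dimnames.
#' @param pop_meta optional data.frame describing the populations
#'   (columns `population`, `level`, `parent`), used to pick the
#'   comparison set for private-haplotype counts when a table mixes
#'   grouping levels (countries, continents, strains, totals).
#' @return an object of class `"haplotype_table"`.
#' @export
haplotype_table <- function(counts, pop_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("H", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("pop", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) < 1))
    stop("every haplotype must have total count >= 1: ",
         paste(rownames(counts)[rowSums(counts) < 1], collapse = ", "))
  structure(list(counts = counts,
                 haplotypes = rownames(counts),
                 populations = colnames(counts),
                 pop_meta = pop_meta),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table: %d haplotypes x %d populations (n = %d)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(utils::head(x$counts, 10))
  if (nrow(x$counts) > 10) cat("... (", nrow(x$counts) - 10, " more rows)\n")
  invisible(x)
}

#' @export
summary.haplotype_table <- function(object, ...) {
  n <- colSums(object$counts)
  h <- colSums(object$counts > 0)
  hd <- apply(object$counts, 2, function(ct) haplotype_diversity(ct[ct > 0]))
  out <- data.frame(population = object$populations, n = n, h = h,
                    hap_diversity = hd, row.names = NULL)
  class(out) <- c("summary.haplotype_table", "data.frame")
  out
}

#' Extract one population's positive counts (internal).
#' @noRd
pop_counts <- function(table, population) {
  if (!population %in% table$populations)
    stop("unknown population: ", population)
  ct <- table$counts[, population]
  ct[ct > 0]
}

#' Read / write haplotype tables as CSV
#'
#' The CSV layout has the haplotype identifier in the first column and
#' one integer column per population.
#'
#' @param path CSV file path.
#' @return for `read_haplotype_table`, a [haplotype_table()].
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  haplotype_table(m)
}

#' @rdname read_haplotype_table
#' @param table a [haplotype_table()].
#' @export
write_haplotype_table <- function(table, path) {
  stopifnot(inherits(table, "haplotype_table"))
  df <- data.frame(haplotype = table$haplotypes, table$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged haplotype count tables of the global Norway rat survey
#'
#' The package ships, as plain-CSV fixtures, the printed geographic
#' occurrence tables of cytochrome-b haplotypes (C1-C39; 161 samples) and
#' D-loop haplotypes (D1-D25; 239 samples) from a worldwide Norway rat
#' collection, including continent rows, country rows and the
#' inbred-strains and grand-total columns. Population metadata (grouping
#' level and continent membership) is attached so that private-haplotype
#' counts compare populations at the same level and exclude laboratory
#' strains.
#'
#' @param name `"cytb"` or `"dloop"`.
#' @return a [haplotype_table()] with `pop_meta` attached.
#' @export
load_printed_table <- function(name = c("cytb", "dloop")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_haplotype_counts.csv"),
                      package = "mtpopgen", mustWork = TRUE)
  meta_path <- system.file("extdata", "populations.csv",
                           package = "mtpopgen", mustWork = TRUE)
  tab <- read_haplotype_table(path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  meta <- meta[meta$locus == name, c("population", "level", "parent")]
  stopifnot(setequal(meta$population, tab$populations))
  tab$pop_meta <- meta
  tab
}
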