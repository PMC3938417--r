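test_that("read_alignment parses FASTA with labels, pads partial records", {
  fa <- tempfile(fileext = ".fasta")
  lb <- tempfile(fileext = ".csv")
  writeLines(c(">r1", "ACGTACGTAC", ">r2", "ACGTACGTAC", ">r3", "ACGT"), fa)
  writeLines(c("sample_id,population,offset",
               "r1,Germany,1", "r2,Germany,1", "r3,France,3"), lb)
  aln <- read_alignment(fa, lb)
  expect_s3_class(aln, "hap_alignment")
  expect_equal(length(aln$sample_id), 3)
  expect_equal(aln$L, 10)
  # r3 occupies sites 3..6, the rest is '?'
  expect_equal(unname(aln$seq["r3", ]),
               c("?", "?", "A", "C", "G", "T", "?", "?", "?", "?"))
  # partial record against a longer declared frame
  aln2 <- read_alignment(fa, lb, L = 664)
  expect_equal(sum(aln2$seq["r3", ] == "?"), 664 - 4)
})

test_that("read_alignment rejects malformed input", {
  fa <- tempfile(fileext = ".fasta")
  lb <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,population", "r1,A"), lb)
  file.create(fa)
  expect_error(read_alignment(fa, lb), "empty")
  writeLines(c(">r1", "ACGT", ">r1", "ACGT"), fa)
  writeLines(c("sample_id,population", "r1,A"), lb)
  expect_error(read_alignment(fa, lb), "[Dd]uplicate")
  writeLines(c(">r1", "ACXT"), fa)
  expect_error(read_alignment(fa, lb), "illegal character 'X' at site 3.*r1")
  writeLines(c(">r1", "ACGT", ">r2", "ACGT"), fa)
  expect_error(read_alignment(fa, lb), "no label")
})

test_that("collapse groups identical sequences and separates variants", {
  a <- alignment(paste0("s", 1:5), rep("p", 5), rep("ACGTACGT", 5))
  res <- collapse_haplotypes(a)
  expect_equal(nrow(res$table$counts), 1)
  expect_equal(sum(res$table$counts), 5)
  b <- alignment(c("x", "y"), c("p", "p"), c("ACGTACGT", "ACGTACGA"))
  expect_equal(nrow(collapse_haplotypes(b)$table$counts), 2)
  # gap is a fifth state for identity
  g <- alignment(c("x", "y"), c("p", "p"), c("ACGT-CGT", "ACGTACGT"))
  expect_equal(nrow(collapse_haplotypes(g)$table$counts), 2)
})

test_that("minimal distance rule assigns partials; count breaks ties", {
  # two haplotypes with counts 10 and 2; the partial observes only the
  # sites where the two agree, so it is distance 0 from both
  h1 <- "AAAAAAAAAA"
  h2 <- "AAAAAAAATT"
  seqs <- c(rep(h1, 10), rep(h2, 2), "??AAAAAA??")
  a <- alignment(paste0("s", 1:13), rep("p", 13), seqs)
  res <- collapse_haplotypes(a)
  expect_equal(res$assignment$haplotype[13], res$assignment$haplotype[1])
  expect_equal(res$ties, 1L)
  expect_true(res$assignment$used_missing_rule[13])
  # brute-force distance scan confirms the tie over observed sites
  obs <- 3:8
  d1 <- sum(strsplit(h1, "")[[1]][obs] != strsplit(seqs[13], "")[[1]][obs])
  d2 <- sum(strsplit(h2, "")[[1]][obs] != strsplit(seqs[13], "")[[1]][obs])
  expect_equal(c(d1, d2), c(0, 0))
  # positive minimal distance founds a new haplotype
  far <- alignment(c("a", "b"), c("p", "p"), c("AAAAAAAAAA", "??TTTTTT??"))
  expect_equal(nrow(collapse_haplotypes(far)$table$counts), 2)
  # all-missing sequences are rejected
  bad <- alignment(c("a", "b"), c("p", "p"), c("AAAA", "????"))
  expect_error(collapse_haplotypes(bad), "all-missing")
})

test_that("collapse is permutation-invariant for full-length sequences", {
  set.seed(7)
  m <- random_toy_alignment(n = 8, L = 20)
  a1 <- aln_from_matrix(m)
  perm <- sample(8)
  a2 <- alignment(paste0("s", 1:8), rep("pop", 8),
                  apply(m[perm, ], 1, paste, collapse = ""))
  t1 <- sort(as.vector(collapse_haplotypes(a1)$table$counts))
  t2 <- sort(as.vector(collapse_haplotypes(a2)$table$counts))
  expect_equal(t1, t2)
})

test_that("printed fixtures match the published sample sizes and rows", {
  tc <- load_printed_table("cytb")
  td <- load_printed_table("dloop")
  expect_equal(sum(tc$counts[, "All"]), 161)
  expect_equal(sum(td$counts[, "All"]), 239)
  expect_equal(sum(tc$counts[, "All"] > 0), 39)
  expect_equal(sum(td$counts[, "All"] > 0), 25)
  # Germany rows as printed
  expect_equal(unname(tc$counts[c("C1", "C2", "C3"), "Germany"]), c(34, 1, 1))
  expect_equal(sum(tc$counts[, "Germany"]), 36)
  expect_equal(unname(td$counts["D1", "Germany"]), 112)
  expect_equal(sum(td$counts[, "Germany"]), 155)
  # every continent column is the sum of its country columns
  meta <- tc$pop_meta
  for (cont in meta$population[meta$level == "continent"]) {
    kids <- meta$population[!is.na(meta$parent) & meta$parent == cont]
    expect_equal(unname(tc$counts[, cont]),
                 unname(rowSums(tc$counts[, kids, drop = FALSE])),
                 label = cont)
  }
  expect_error(load_printed_table("nuclear"), "arg")
})

test_that("haplotype table round-trips through CSV and validates", {
  tab <- generate_table(5, 40, i0 = 0.4)
  f <- tempfile(fileext = ".csv")
  write_haplotype_table(tab, f)
  back <- read_haplotype_table(f)
  expect_equal(back$counts, tab$counts)
  expect_error(haplotype_table(matrix(c(-1, 2), 2, 1)), "non-negative")
  expect_error(haplotype_table(matrix(c(0, 2), 2, 1,
                                      dimnames = list(c("a", "b"), "p"))),
               "count >= 1")
})
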