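test_that("haplotype diversity matches printed survey values", {
  expect_equal(round(haplotype_diversity(c(34, 1, 1)), 2), 0.11)
  expect_equal(round(haplotype_diversity(c(9, 4, 1, 1)), 2), 0.60)
  expect_equal(haplotype_diversity(c(50)), 0)
  expect_true(is.na(haplotype_diversity(c(1))))
})

test_that("haplotype diversity equals the pair-sampling probability", {
  set.seed(11)
  for (rep in 1:30) {
    k <- sample(1:6, 1)
    counts <- sample(1:12, k, replace = TRUE)
    expect_equal(haplotype_diversity(counts), oracle_hap_div(counts),
                 tolerance = 1e-12)
  }
})

test_that("haplotype and private-haplotype counts reproduce the survey", {
  tc <- load_printed_table("cytb")
  td <- load_printed_table("dloop")
  expect_equal(haplotype_summary(tc, "Asia")$h, 32)
  expect_equal(haplotype_summary(tc, "Germany")$private_h, 0)
  expect_equal(haplotype_summary(tc, "France")$private_h, 2)
  expect_equal(haplotype_summary(tc, "Europe")$private_h, 3)
  expect_equal(haplotype_summary(tc, "China")$private_h, 23)
  expect_equal(haplotype_summary(tc, "Vietnam")$private_h, 2)
  expect_equal(haplotype_summary(td, "Germany"), list(h = 9, private_h = 6))
  expect_equal(haplotype_summary(td, "Asia"), list(h = 11, private_h = 10))
  expect_equal(haplotype_summary(td, "China")$private_h, 9)
  # laboratory strains compared against all wild countries
  expect_equal(haplotype_summary(tc, "Inbred strains")$private_h, 1)
  expect_error(haplotype_summary(tc, "Atlantis"), "unknown population")
  # with a single population every haplotype is private
  solo <- generate_table(6, 30, i0 = 0.5)
  expect_equal(haplotype_summary(solo, "pop1"),
               list(h = 6, private_h = 6))
})

test_that("diversity summary mirrors the printed table layout", {
  tc <- load_printed_table("cytb")
  df <- diversity_summary(tc, c("Germany", "France", "Europe", "All"))
  expect_equal(df$hap_diversity, c(0.11, 0.60, 0.33, 0.86))
  expect_equal(df$n, c(36, 15, 53, 161))
  expect_equal(df$h, c(3, 4, 6, 39))
})

test_that("nucleotide diversity matches exhaustive pair comparison", {
  a <- alignment(c("x", "y"), c("p", "p"),
                 c(strrep("A", 100),
                   paste0(strrep("A", 97), "TTT")))
  expect_equal(nucleotide_diversity(a), 0.03)
  same <- alignment(c("x", "y", "z"), rep("p", 3), rep("ACGTACGT", 3))
  expect_equal(nucleotide_diversity(same), 0)
  expect_error(nucleotide_diversity(same, population = "missingpop"),
               "unknown population")
  set.seed(3)
  for (rep in 1:10) {
    m <- random_toy_alignment(n = 4)
    expect_equal(nucleotide_diversity(aln_from_matrix(m)), oracle_pi(m),
                 tolerance = 1e-12)
  }
})

test_that("deletion policies differ only in the presence of missing data", {
  seqs <- c("ACGTACGTAC", "ACGAACGTAC", "??GTACGAAC")
  a <- alignment(paste0("s", 1:3), rep("p", 3), seqs)
  pw <- nucleotide_diversity(a, deletion = "pairwise")
  cd <- nucleotide_diversity(a, deletion = "complete")
  # complete deletion drops the first two sites for every pair
  expect_equal(cd, mean(c(1 / 8, 1 / 8, 2 / 8)))
  expect_equal(pw, mean(c(1 / 10, 1 / 8, 2 / 8)))
})

test_that("haplotype-frequency Fst behaves at its boundary cases", {
  m <- matrix(c(10, 10, 10, 10), 2, 2,
              dimnames = list(c("h1", "h2"), c("A", "B")))
  expect_equal(fst_haplotype(haplotype_table(m), "A", "B",
                             permutations = 0)$fst, 0)
  fixed <- matrix(c(20, 0, 0, 20), 2, 2,
                  dimnames = list(c("h1", "h2"), c("A", "B")))
  expect_equal(fst_haplotype(haplotype_table(fixed), "A", "B",
                             permutations = 0)$fst, 1)
  # both populations fixed for the same haplotype: H_T = 0
  same <- matrix(c(20, 20), 1, 2, dimnames = list("h1", c("A", "B")))
  res <- fst_haplotype(haplotype_table(same), "A", "B", permutations = 10)
  expect_equal(res$fst, 0)
  expect_equal(res$p, 1)
})

test_that("Fst on the Germany/France counts equals the direct formula", {
  tc <- load_printed_table("cytb")
  res <- fst_haplotype(tc, "Germany", "France", permutations = 0)
  # independent hand evaluation of (H_T - H_S)/H_T on the printed counts
  a <- tc$counts[, "Germany"]; b <- tc$counts[, "France"]
  pool <- a + b
  n <- sum(pool)
  ht <- n / (n - 1) * (1 - sum((pool / n)^2))
  hA <- 36 / 35 * (1 - sum((a / 36)^2))
  hB <- 15 / 14 * (1 - sum((b / 15)^2))
  hs <- (36 * hA + 15 * hB) / 51
  expect_equal(res$fst, (ht - hs) / ht, tolerance = 1e-12)
  expect_gt(res$fst, 0)
})

test_that("Fst permutation p-values are well calibrated under the null", {
  set.seed(21)
  pool_freq <- c(0.5, 0.3, 0.2)
  ps <- replicate(100, {
    counts <- cbind(A = rmultinom(1, 25, pool_freq)[, 1],
                    B = rmultinom(1, 25, pool_freq)[, 1])
    keep <- rowSums(counts) > 0
    tab <- haplotype_table(counts[keep, , drop = FALSE])
    fst_haplotype(tab, "A", "B", permutations = 99)$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.7)
  expect_lte(mean(ps <= 0.05), 0.12)
})
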