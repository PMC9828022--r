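test_that("individual missingness filter is strict at the boundary", {
  geno <- matrix(0L, 3, 10)
  geno[1, 1:6] <- NA_integer_  # 0.6 missing -> removed
  geno[2, 1:5] <- NA_integer_  # exactly 0.5 -> retained
  g <- genotype_matrix(geno, paste0("c", 1:10), rep(1L, 10),
                       rep("A", 3))
  f <- filter_individuals_by_missingness(g)
  expect_equal(nrow(f$geno), 2L)
  expect_false("ind001" %in% rownames(f$geno))
  expect_error(filter_individuals_by_missingness(g, threshold = -1),
               "all individuals removed")
})

test_that("locus presence filter keeps loci typed in >= 95% of individuals", {
  set.seed(2)
  n <- 100
  geno <- matrix(sample(0:2, n * 3, TRUE), n, 3)
  geno[1:6, 1] <- NA_integer_   # 94% presence -> removed
  geno[1:5, 2] <- NA_integer_   # 95% presence -> kept
  g <- genotype_matrix(geno, c("a", "b", "c"), rep(1L, 3), rep("A", n))
  f <- filter_loci_by_presence(g)
  expect_equal(f$contig, c("b", "c"))
  # planted 10 x 10 matrix: survivors match a hand tally
  m <- matrix(0L, 10, 10)
  miss <- cbind(sample(1:10, 5, TRUE), sample(1:10, 5, TRUE))
  m[miss] <- NA_integer_
  g2 <- genotype_matrix(m, paste0("c", 1:10), rep(1L, 10), rep("A", 10))
  f2 <- filter_loci_by_presence(g2, presence = 0.95)
  keep_hand <- colSums(!is.na(m)) / 10 >= 0.95
  expect_equal(f2$contig, paste0("c", 1:10)[keep_hand])
})

test_that("first SNP per contig is kept regardless of input order", {
  g <- tiny_genotypes()  # c1 has SNPs at 10 and 70
  f <- first_snp_per_contig(g)
  expect_equal(sort(f$contig), c("c1", "c2", "c3"))
  expect_equal(f$pos[f$contig == "c1"], 10L)
  # shuffled locus order gives the same surviving set
  shuf <- subset_loci <- c(2L, 4L, 1L, 3L)
  gs <- genotype_matrix(g$geno[, shuf], g$contig[shuf], g$pos[shuf], g$cohort)
  fs <- first_snp_per_contig(gs)
  expect_setequal(colnames(fs$geno), colnames(f$geno))
  # already one SNP per contig: unchanged
  expect_equal(ncol(first_snp_per_contig(f)$geno), ncol(f$geno))
})

test_that("heterozygosity outliers above mean + 3 SD are removed", {
  # 19 individuals at het 0.1, one at 0.9: threshold ~ 0.68 (sample SD)
  geno <- matrix(0L, 20, 10)
  geno[, 1] <- 1L                      # every individual het at locus 1
  geno[20, 1:9] <- 1L                  # outlier het at 9 of 10 loci
  g <- genotype_matrix(geno, paste0("c", 1:10), rep(1L, 10), rep("A", 20))
  het <- rowMeans(geno == 1L)
  thr <- mean(het) + 3 * sd(het)
  expect_equal(thr, 0.6766563, tolerance = 1e-6)
  f <- remove_het_outlier_individuals(g)
  expect_equal(nrow(f$geno), 19L)
  # all equal proportions: nobody removed
  g2 <- genotype_matrix(matrix(1L, 5, 4), paste0("c", 1:4), rep(1L, 4),
                        rep("A", 5))
  expect_equal(nrow(remove_het_outlier_individuals(g2)$geno), 5L)
  # single individual: SD convention keeps it
  g3 <- genotype_matrix(matrix(c(0L, 1L), 1, 2), c("a", "b"), c(1L, 1L), "A")
  expect_equal(nrow(remove_het_outlier_individuals(g3)$geno), 1L)
})

test_that("exact Hardy-Weinberg test matches enumeration and filters loci", {
  # perfect proportions: retained
  perfect <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  # all homozygotes at intermediate frequency: removed
  awful <- rep(c(0L, 2L), 50)
  mono <- rep(0L, 100)
  geno <- cbind(perfect, awful, mono)
  g <- genotype_matrix(geno, c("a", "b", "c"), rep(1L, 3), rep("A", 100))
  f <- hwp_filter(g, alpha = 0.001)
  expect_setequal(f$contig, c("a", "c"))
  # oracle: independent enumeration of the conditional distribution
  hw_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- 2 * nAA + nAa
    minor <- min(na, 2 * n - na)
    hs <- seq(minor %% 2, minor, by = 2)
    pr <- sapply(hs, function(h) {
      a1 <- (minor - h) / 2; a2 <- n - h - a1
      exp(lfactorial(n) - lfactorial(a1) - lfactorial(h) - lfactorial(a2) +
            h * log(2) + lfactorial(minor) + lfactorial(2 * n - minor) -
            lfactorial(2 * n))
    })
    sum(pr[pr <= pr[hs == nAa] + 1e-12])
  }
  for (cfg in list(c(25, 50, 25), c(50, 0, 50), c(10, 20, 5), c(3, 1, 7))) {
    expect_equal(serialSFS:::hwe_exact_p(cfg[1], cfg[2], cfg[3]),
                 hw_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-9)
  }
  expect_lt(serialSFS:::hwe_exact_p(50, 0, 50), 1e-3)
  expect_equal(serialSFS:::hwe_exact_p(100, 0, 0), 1)  # monomorphic
  # chi-square alternative agrees qualitatively
  f2 <- hwp_filter(g, alpha = 0.001, method = "chisq")
  expect_setequal(f2$contig, c("a", "c"))
})

test_that("heterozygosity statistics match closed forms", {
  # all-heterozygote locus, n = 10: H_obs 1, H_exp 0.5, F_IS -1
  g1 <- genotype_matrix(matrix(1L, 10, 1), "c1", 1L, rep("A", 10))
  h1 <- heterozygosity_stats(g1)$per_locus
  expect_equal(h1$H_obs, 1)
  expect_equal(h1$H_exp, 0.5)
  expect_equal(h1$F_IS, -1)
  # AA = 6, aa = 4: H_obs 0, H_exp 0.5333, F_IS 1
  g2 <- genotype_matrix(matrix(c(rep(0L, 6), rep(2L, 4)), 10, 1), "c1", 1L,
                        rep("A", 10))
  h2 <- heterozygosity_stats(g2)$per_locus
  expect_equal(h2$H_obs, 0)
  expect_equal(h2$H_exp, 16 / 30, tolerance = 1e-9)
  expect_equal(h2$F_IS, 1)
  # monomorphic locus: H_obs = H_exp = 0, F_IS undefined
  g3 <- genotype_matrix(matrix(0L, 10, 1), "c1", 1L, rep("A", 10))
  h3 <- heterozygosity_stats(g3)$per_locus
  expect_equal(h3$H_obs, 0)
  expect_equal(h3$H_exp, 0)
  expect_true(is.na(h3$F_IS))
  # brute-force enumeration oracle on a random matrix, per cohort
  set.seed(14)
  geno <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(.4, .3, .2, .1)),
                 10, 6)
  keep <- colSums(!is.na(geno)) >= 2
  geno <- geno[, keep, drop = FALSE]
  g4 <- genotype_matrix(geno, paste0("c", seq_len(ncol(geno))),
                        rep(1L, ncol(geno)), rep("A", 10))
  h4 <- heterozygosity_stats(g4, by_cohort = FALSE)$per_locus
  for (j in seq_len(ncol(geno))) {
    x <- geno[, j][!is.na(geno[, j])]
    n <- length(x)
    hob <- mean(x == 1)
    p <- sum(x) / (2 * n)
    hex <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - hob / (2 * n))
    expect_equal(h4$H_obs[j], hob, tolerance = 1e-12)
    expect_equal(h4$H_exp[j], hex, tolerance = 1e-12)
  }
})

test_that("windowed pi matches the average-pairwise-difference oracle", {
  # one SNP, 4 chromosomes, counts 1/3: site pi = 0.5 (3 of 6 pairs differ)
  g <- genotype_matrix(matrix(c(1L, 0L), 2, 1), "c1", 1L, rep("A", 2))
  w <- windowed_pi(g)
  expect_equal(w$per_window$pi, 0.5 / 140, tolerance = 1e-12)
  # two identical SNPs in one window double the window pi
  g2 <- genotype_matrix(matrix(c(1L, 0L, 1L, 0L), 2, 2), c("c1", "c1"),
                        c(1L, 50L), rep("A", 2))
  expect_equal(windowed_pi(g2)$per_window$pi, 2 * 0.5 / 140,
               tolerance = 1e-12)
  # SNPs 141 bp apart fall in different windows
  g3 <- genotype_matrix(matrix(c(1L, 0L, 1L, 0L), 2, 2), c("c1", "c1"),
                        c(1L, 150L), rep("A", 2))
  expect_equal(nrow(windowed_pi(g3)$per_window), 2L)
  # brute-force pairwise oracle with missingness, per cohort
  set.seed(15)
  geno <- matrix(sample(c(0:2, NA), 80, TRUE, prob = c(.5, .2, .2, .1)),
                 8, 10)
  g4 <- genotype_matrix(geno, rep("c1", 10), seq(10L, 100L, 10L),
                        rep("A", 8))
  w4 <- windowed_pi(g4, by_cohort = FALSE)$per_window
  site_or <- function(x) {
    x <- x[!is.na(x)]
    # expand genotypes to chromosomes: gg alt copies -> gg ones
    chroms <- unlist(lapply(x, function(gg) c(rep(1, gg), rep(0, 2 - gg))))
    cc <- length(chroms)
    diffs <- 0; pairs <- 0
    for (i in seq_len(cc - 1)) for (j in (i + 1):cc) {
      diffs <- diffs + (chroms[i] != chroms[j]); pairs <- pairs + 1
    }
    diffs / pairs
  }
  expected <- sum(apply(geno, 2, site_or)) / 140
  expect_equal(sum(w4$pi), expected, tolerance = 1e-12)
})

test_that("pi and H_exp are invariant to allele relabelling", {
  set.seed(16)
  geno <- matrix(sample(c(0:2, NA), 60, TRUE), 6, 10)
  ok <- colSums(!is.na(geno)) >= 2
  geno <- geno[, ok, drop = FALSE]
  g <- genotype_matrix(geno, paste0("c", seq_len(ncol(geno))),
                       rep(1L, ncol(geno)), rep("A", 6))
  gr <- g
  gr$geno <- 2L - g$geno
  expect_equal(windowed_pi(g, by_cohort = FALSE)$summary$pi,
               windowed_pi(gr, by_cohort = FALSE)$summary$pi,
               tolerance = 1e-12)
  expect_equal(heterozygosity_stats(g, by_cohort = FALSE)$per_locus$H_exp,
               heterozygosity_stats(gr, by_cohort = FALSE)$per_locus$H_exp,
               tolerance = 1e-12)
})

test_that("pi bootstrap interval is seed-stable and degenerates correctly", {
  # degenerate one-genotype matrix: zero-width interval at the point value
  g0 <- genotype_matrix(matrix(1L, 4, 2), c("a", "b"), c(1L, 1L),
                        rep("A", 4))
  ci0 <- pi_bootstrap_ci(g0, reps = 50, seed = 1)
  expect_equal(ci0$lower, ci0$point)
  expect_equal(ci0$upper, ci0$point)
  set.seed(17)
  geno <- matrix(sample(0:2, 80, TRUE), 8, 10)
  g <- genotype_matrix(geno, rep("c1", 10), seq(10L, 100L, 10L),
                       rep("A", 8))
  a <- pi_bootstrap_ci(g, reps = 100, seed = 9)
  b <- pi_bootstrap_ci(g, reps = 100, seed = 9)
  expect_equal(a, b)
  expect_lte(a$lower, a$upper)
})

test_that("filters only ever drop rows and columns", {
  set.seed(18)
  x <- generate_filter_testset(seed = 4)
  g <- x$genotypes
  for (f in list(filter_individuals_by_missingness, filter_loci_by_presence,
                 first_snp_per_contig, remove_het_outlier_individuals,
                 hwp_filter)) {
    out <- f(g)
    expect_true(all(rownames(out$geno) %in% rownames(g$geno)))
    expect_true(all(colnames(out$geno) %in% colnames(g$geno)))
  }
})
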