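test_that("single-cohort folding pairs complements and is idempotent", {
  # n = 4 haploids, unfolded segregating counts (s1, s2, s3)
  s <- multisfs(matrix(1:3, ncol = 1), c(5, 7, 2), n_haploid = 4,
                kind = "observed")
  f <- sfs_fold(s)
  ent <- sfs_entries(f)
  expect_equal(ent[, 1], c(1, 2))
  expect_equal(f$value, c(5 + 2, 7))     # s1+s3, s2
  expect_equal(sfs_total(f), sfs_total(s))
  expect_error(sfs_fold(f), "already folded")
})

test_that("3-D folding matches the exhaustive complement oracle", {
  set.seed(7)
  n_hap <- c(4L, 6L, 2L)
  dims <- n_hap + 1L
  grid <- as.matrix(expand.grid(0:n_hap[1], 0:n_hap[2], 0:n_hap[3]))
  vals <- runif(nrow(grid))
  s <- multisfs(grid, vals, n_hap, kind = "observed")
  f <- sfs_fold(s)
  # oracle: dense complement pairing
  tot <- sum(n_hap)
  dense <- array(0, dims)
  for (r in seq_len(nrow(grid))) {
    e <- grid[r, ]
    if (sum(e) > tot / 2) e <- n_hap - e
    dense[e[1] + 1, e[2] + 1, e[3] + 1] <-
      dense[e[1] + 1, e[2] + 1, e[3] + 1] + vals[r]
  }
  got <- array(0, dims)
  fe <- sfs_entries(f)
  for (r in seq_along(f$value))
    got[fe[r, 1] + 1, fe[r, 2] + 1, fe[r, 3] + 1] <- f$value[r]
  expect_equal(got, dense, tolerance = 1e-12)
  # mass conserved exactly and no mass beyond the pooled half
  expect_equal(sfs_total(f), sum(vals))
  expect_true(all(rowSums(fe) <= tot / 2))
})

test_that("sfs_from_genotypes drops incomplete loci and matches a tally", {
  g <- tiny_genotypes()
  s <- sfs_from_genotypes(g)
  # locus 4 has a missing call -> 3 complete loci
  expect_equal(sfs_total(s), 3)
  oracle <- brute_force_sfs(g$geno, g$cohort, sort(unique(g$cohort)))
  ent <- sfs_entries(s)
  for (r in seq_along(s$value)) {
    key <- paste(ent[r, ], collapse = ",")
    expect_equal(s$value[r], oracle[[key]])
  }
  # one diploid per cohort, genotypes (1, 0, 0): folded count 1 at (1, 0, 0)
  g1 <- genotype_matrix(matrix(c(1L, 0L, 0L), 3, 1), "c1", 1L,
                        c("A", "B", "C"))
  s1 <- sfs_from_genotypes(g1)
  expect_equal(unname(sfs_entries(s1)[1, ]), c(1, 0, 0))
  expect_equal(s1$value, 1)
  expect_error(sfs_from_genotypes(
    genotype_matrix(matrix(c(1L, NA), 2, 1), "c1", 1L, c("A", "B"))),
    "no loci with complete data")
})

test_that("remove_monomorphic zeroes the invariant entries and renormalizes", {
  # expected spectrum with half its mass monomorphic, rest uniform
  n_hap <- c(2L, 2L)
  ent <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  s <- multisfs(ent, c(0.5, 0.2, 0.2, 0.1), n_hap, kind = "expected",
                folded = TRUE, n_sims = 1000)
  r <- remove_monomorphic(s)
  expect_equal(sum(r$value), 1, tolerance = 1e-12)
  expect_equal(r$value, c(0.2, 0.2, 0.1) / 0.5)
  # observed spectrum without monomorphic mass is unchanged
  so <- multisfs(rbind(c(1, 0), c(1, 1)), c(3, 4), n_hap, kind = "observed")
  expect_equal(remove_monomorphic(so)$value, so$value)
  sm <- multisfs(rbind(c(0, 0)), 5, n_hap, kind = "observed")
  expect_error(remove_monomorphic(sm), "all mass is monomorphic")
})

test_that("marginals sum the full spectrum and match brute force", {
  set.seed(11)
  n_hap <- c(6L, 4L, 8L)
  grid <- as.matrix(expand.grid(0:6, 0:4, 0:8))
  keep <- sample(nrow(grid), 40)
  vals <- rpois(40, 3) + 1
  s <- multisfs(grid[keep, ], vals, n_hap, kind = "observed",
                labels = c("a", "b", "c"))
  for (co in 1:3) {
    m <- sfs_marginalize(s, co)
    expect_equal(sum(m), sfs_total(s))
    # brute-force: per-cohort counts folded by that cohort's minor allele
    marg <- rep(0, n_hap[co] + 1)
    for (r in seq_along(vals)) {
      i <- grid[keep[r], co]
      marg[i + 1] <- marg[i + 1] + vals[r]
    }
    half <- floor(n_hap[co] / 2)
    oracle <- vapply(0:half, function(j) {
      if (n_hap[co] - j == j) marg[j + 1]
      else marg[j + 1] + marg[n_hap[co] - j + 1]
    }, numeric(1))
    expect_equal(unname(m), oracle)
  }
  # concentrated spectrum: cohort-1 marginal concentrates at count 1
  s1 <- multisfs(rbind(c(1, 0, 0)), 7, n_hap, kind = "observed")
  expect_equal(unname(sfs_marginalize(s1, 1)), c(0, 7, 0, 0))
  expect_error(sfs_marginalize(s, "nope"), "unknown cohort")
})

test_that("bootstrap resampling preserves totals and is seed-reproducible", {
  set.seed(3)
  ent <- cbind(sample(0:10, 30, TRUE), sample(0:15, 30, TRUE))
  s <- multisfs(ent, rpois(30, 5) + 1, c(20L, 24L), kind = "observed")
  b1 <- sfs_bootstrap_resample(s, seed = 99)
  b2 <- sfs_bootstrap_resample(s, seed = 99)
  expect_equal(sfs_total(b1), sfs_total(s))
  expect_identical(b1$index, b2$index)
  expect_identical(b1$value, b2$value)
  expect_error(sfs_bootstrap_resample(sfs_as_expected(s)), "observed")
  # multinomial expectation: mean over resamples approximates O_e
  L <- sfs_total(s)
  acc <- setNames(rep(0, length(s$index)), s$index)
  set.seed(5)
  R <- 2000
  for (i in seq_len(R)) {
    b <- sfs_bootstrap_resample(s)
    m <- match(b$index, s$index)
    acc[m] <- acc[m] + b$value
  }
  means <- acc / R
  se <- sqrt(s$value * (1 - s$value / L))  # binomial SE of one draw
  expect_true(all(abs(means - s$value) <= 3 * se / sqrt(R) + 1e-9))
})

test_that(".obs round-trip is exact and tolerates whitespace", {
  set.seed(13)
  ent <- unique(cbind(sample(0:4, 8, TRUE), sample(0:6, 8, TRUE)))[1:5, ]
  s <- multisfs(ent, c(3, 1, 4, 1, 5), c(4L, 6L),
                kind = "observed", folded = FALSE)
  s <- sfs_fold(s)
  path <- tempfile(fileext = ".obs")
  write_obs(s, path)
  r <- read_obs(path)
  expect_identical(r$index, s$index)
  expect_identical(r$value, s$value)
  expect_equal(r$n_haploid, s$n_haploid)
  # whitespace-mangled dialect
  lines <- readLines(path)
  lines[3] <- gsub("\t", "   ", lines[3])
  mangled <- tempfile(fileext = ".obs")
  writeLines(c(lines[1:2], "", lines[3]), mangled)
  r2 <- read_obs(mangled)
  expect_identical(r2$value, s$value)
  expect_error(read_obs(tempfile()), "not found")
})
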