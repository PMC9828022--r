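#' Remove individuals with excess missing data
#'
#' Individuals whose fraction of missing genotype calls exceeds `threshold`
#' (strictly) are discarded; an individual at exactly the threshold is
#' retained.
#'
#' @param g A [genotype_matrix()].
#' @param threshold Maximum tolerated missing fraction (default 0.5).
#' @return The filtered `genotype_matrix`.
#' @export
filter_individuals_by_missingness <- function(g, threshold = 0.5) {
  miss <- rowMeans(is.na(g$geno))
  keep <- miss <= threshold
  if (!any(keep)) stop("all individuals removed by missingness filter")
  subset_gm(g, individuals = keep)
}

#' Keep loci genotyped in a minimum fraction of individuals
#'
#' A locus is kept iff its non-missing fraction is at least `presence`.
#'
#' @param g A [genotype_matrix()].
#' @param presence Minimum required non-missing fraction (default 0.95).
#' @return The filtered `genotype_matrix`.
#' @export
filter_loci_by_presence <- function(g, presence = 0.95) {
  ok <- colMeans(!is.na(g$geno)) >= presence
  if (!any(ok)) stop("all loci removed by presence filter")
  subset_gm(g, loci = ok)
}

#' Keep only the first SNP on each contig
#'
#' Per contig, the SNP with the smallest position is retained, producing a
#' putatively unlinked one-SNP-per-contig data set. The result is
#' invariant to the input locus order.
#'
#' @param g A [genotype_matrix()].
#' @return The filtered `genotype_matrix`.
#' @export
first_snp_per_contig <- function(g) {
  o <- order(g$contig, g$pos)
  first <- o[!duplicated(g$contig[o])]
  subset_gm(g, loci = sort(first))
}

#' Remove individuals with outlying heterozygosity
#'
#' Computes each individual's proportion of heterozygous calls over its
#' non-missing loci and removes individuals more than `k_sd` standard
#' deviations above the mean. Mean and SD come from the pre-removal
#' distribution (single pass). With a single individual (SD undefined) the
#' threshold degenerates to the mean and nobody is removed.
#'
#' @param g A [genotype_matrix()] with at least one individual.
#' @param k_sd Number of standard deviations (default 3).
#' @return The filtered `genotype_matrix`.
#' @export
remove_het_outlier_individuals <- function(g, k_sd = 3) {
  het <- rowMeans(g$geno == 1L, na.rm = TRUE)
  s <- if (nrow(g$geno) > 1) stats::sd(het) else 0
  if (is.na(s)) s <- 0
  thr <- mean(het) + k_sd * s
  subset_gm(g, individuals = het <= thr)
}

# Exact test of Hardy-Weinberg proportions for one biallelic locus:
# full enumeration of heterozygote counts conditional on the minor allele
# count; the p-value sums the probabilities of all configurations no more
# probable than the observed one.
hwe_exact_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  na <- 2 * nAA + nAa           # allele A count
  minor <- min(na, 2 * n - na)  # minor allele count
  if (minor == 0) return(1)     # monomorphic
  hs <- seq(minor %% 2, minor, by = 2)
  logp <- vapply(hs, function(h) {
    a1 <- (minor - h) / 2       # homozygotes for the minor allele
    a2 <- n - h - a1            # homozygotes for the major allele
    lgamma(n + 1) - lgamma(a1 + 1) - lgamma(h + 1) - lgamma(a2 + 1) +
      h * log(2) + lgamma(minor + 1) + lgamma(2 * n - minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(nAa, hs)
  if (is.na(obs)) return(0)     # impossible configuration
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# chi-square test of HWP (no continuity correction), for comparison
hwe_chisq_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  p <- (2 * nAA + nAa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stats::pchisq(sum((c(nAA, nAa, naa) - e)^2 / e), df = 1, lower.tail = FALSE)
}

#' Remove loci out of Hardy-Weinberg proportions
#'
#' Tests each locus over all individuals pooled with an exact test (full
#' enumeration of heterozygote counts given the allele counts); loci with
#' `p < alpha` are removed. Monomorphic loci are retained untested. A
#' chi-square alternative is available for comparison.
#'
#' @param g A [genotype_matrix()].
#' @param alpha Removal threshold (default 0.001).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return The filtered `genotype_matrix`.
#' @export
hwp_filter <- function(g, alpha = 0.001, method = c("exact", "chisq")) {
  method <- match.arg(method)
  test <- if (method == "exact") hwe_exact_p else hwe_chisq_p
  pvals <- apply(g$geno, 2, function(x) {
    x <- x[!is.na(x)]
    test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  })
  subset_gm(g, loci = pvals >= alpha)
}

#' Per-locus and per-cohort heterozygosity statistics
#'
#' For each locus with `n` typed diploids and alternate-allele frequency
#' `p`: observed heterozygosity `H_obs` = heterozygote fraction; expected
#' heterozygosity (gene diversity with small-sample correction)
#' `H_exp = n/(n-1) * (1 - p^2 - q^2 - H_obs/(2n))`; inbreeding
#' coefficient `F_IS = 1 - H_obs/H_exp`. Cohort values are across-locus
#' means; loci with `H_exp = 0` are excluded from the `F_IS` mean.
#'
#' @param g A [genotype_matrix()].
#' @param by_cohort Compute statistics within each cohort (default) or
#'   over all individuals pooled.
#' @return A list with `per_locus` (data frame: cohort, locus, n, H_obs,
#'   H_exp, F_IS) and `summary` (data frame of cohort means).
#' @export
heterozygosity_stats <- function(g, by_cohort = TRUE) {
  groups <- if (by_cohort) split(seq_len(nrow(g$geno)), g$cohort)
            else list(all = seq_len(nrow(g$geno)))
  per <- do.call(rbind, lapply(names(groups), function(cl) {
    sub <- g$geno[groups[[cl]], , drop = FALSE]
    n <- colSums(!is.na(sub))
    if (any(n < 2)) stop("need >= 2 typed individuals per locus (cohort ", cl, ")")
    hobs <- colSums(sub == 1L, na.rm = TRUE) / n
    p <- colSums(sub, na.rm = TRUE) / (2 * n)
    hexp <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - hobs / (2 * n))
    fis <- ifelse(hexp > 0, 1 - hobs / hexp, NA_real_)
    data.frame(cohort = cl, locus = colnames(g$geno), n = n,
               H_obs = hobs, H_exp = hexp, F_IS = fis, row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(split(per, per$cohort), function(d) {
    data.frame(cohort = d$cohort[1],
               H_obs = mean(d$H_obs), H_exp = mean(d$H_exp),
               F_IS = mean(d$F_IS, na.rm = TRUE), row.names = NULL)
  }))
  list(per_locus = per, summary = summ)
}

# site-wise average pairwise difference: a alternate copies among c
# non-missing chromosomes
site_pi <- function(a, c) ifelse(c < 2, 0, 2 * a * (c - a) / (c * (c - 1)))

#' Windowed nucleotide diversity
#'
#' Per contig window of `window` bp, `pi` = sum over SNPs in the window of
#' `2 a (c - a) / (c (c - 1))` divided by the window length, where `a` is
#' the alternate-allele count and `c` the number of non-missing chromosomes
#' at the site. Windows with no SNP are not reported.
#'
#' @param g A [genotype_matrix()].
#' @param window Window length in bp (default 140).
#' @param by_cohort Compute within cohorts (default) or pooled.
#' @return A list with `per_window` (data frame: cohort, contig,
#'   window_start, pi) and `summary` (data frame of cohort mean pi across
#'   windows).
#' @export
windowed_pi <- function(g, window = 140L, by_cohort = TRUE) {
  if (window <= 0) stop("window must be positive")
  groups <- if (by_cohort) split(seq_len(nrow(g$geno)), g$cohort)
            else list(all = seq_len(nrow(g$geno)))
  per <- do.call(rbind, lapply(names(groups), function(cl) {
    sub <- g$geno[groups[[cl]], , drop = FALSE]
    a <- colSums(sub, na.rm = TRUE)
    cc <- 2 * colSums(!is.na(sub))
    sp <- site_pi(a, cc)
    win <- (g$pos - 1L) %/% window
    key <- paste(g$contig, win, sep = "\r")
    agg <- rowsum(sp, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    data.frame(cohort = cl,
               contig = vapply(parts, `[`, "", 1),
               window_start = as.integer(vapply(parts, `[`, "", 2)) * window + 1L,
               pi = agg[, 1] / window, row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(split(per, per$cohort), function(d) {
    data.frame(cohort = d$cohort[1], pi = mean(d$pi), row.names = NULL)
  }))
  list(per_window = per, summary = summ)
}

#' Bootstrap confidence interval for mean windowed nucleotide diversity
#'
#' Resamples individuals with replacement, recomputes the mean windowed
#' `pi`, and reports the 2.5/97.5 percentile interval.
#'
#' @param g A [genotype_matrix()] (subset to one cohort for cohort-level
#'   intervals).
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param window Window length in bp.
#' @return List with `point` (plug-in mean pi), `lower`, `upper`.
#' @export
pi_bootstrap_ci <- function(g, reps = 1000L, seed = 1L, window = 140L) {
  if (nrow(g$geno) < 2) stop("need >= 2 individuals")
  point <- windowed_pi(g, window = window, by_cohort = FALSE)$summary$pi
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(nrow(g$geno), replace = TRUE)
    gb <- g
    gb$geno <- g$geno[idx, , drop = FALSE]
    gb$cohort <- g$cohort[idx]
    windowed_pi(gb, window = window, by_cohort = FALSE)$summary$pi
  }, numeric(1))
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(point = point, lower = ci[1], upper = ci[2])
}

#' Apply the full post-VCF filter chain
#'
#' Convenience wrapper applying, in order: individual missingness (> 0.5
#' removed), locus presence (>= 0.95 required), first SNP per contig,
#' heterozygosity-outlier individuals (> mean + 3 SD removed), and the
#' Hardy-Weinberg proportion filter (exact test, p < 0.001 removed).
#'
#' @param g A [genotype_matrix()].
#' @param missing_threshold,presence,k_sd,hwp_alpha Stage parameters.
#' @return The filtered `genotype_matrix`.
#' @export
filter_chain <- function(g, missing_threshold = 0.5, presence = 0.95,
                         k_sd = 3, hwp_alpha = 0.001) {
  g <- filter_individuals_by_missingness(g, missing_threshold)
  g <- filter_loci_by_presence(g, presence)
  g <- first_snp_per_contig(g)
  g <- remove_het_outlier_individuals(g, k_sd)
  hwp_filter(g, hwp_alpha)
}
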