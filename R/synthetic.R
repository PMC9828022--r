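#' Generate cohort genotypes under a known demography
#'
#' Simulates `L` single-SNP loci under the demographic model: for each
#' locus an unfolded SFS entry is drawn with the coalescent engine, the
#' derived alleles are assigned to uniformly chosen haplotypes within each
#' cohort, haplotypes are paired consecutively into diploids, and i.i.d.
#' missingness is applied to genotype calls. One SNP per contig, matching
#' the one-SNP-per-contig analysis design. A per-individual missingness
#' multiplier can skew missingness toward chosen individuals.
#'
#' @param params A [param_vector()] (the generating truth).
#' @param samples A [sample_spec()]; haploid sizes must be even so that
#'   haplotypes pair into diploids.
#' @param L Number of loci (>= 1).
#' @param missing_rate I.i.d. probability a genotype call is missing
#'   (in `[0, 1)`).
#' @param cfg A [sim_config()] controlling the expected-spectrum estimate
#'   the per-locus entries are drawn from.
#' @param seed Integer seed; the output is a pure function of arguments
#'   and seed.
#' @param ind_missing_multiplier Optional per-individual multiplier on
#'   `missing_rate` (recycled; capped at 0.99).
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (generating parameters, sample design, drawn entries, seed).
#' @export
generate_cohort_genotypes <- function(params, samples = sample_spec(), L,
                                      missing_rate = 0, cfg = sim_config(),
                                      seed = 1L, ind_missing_multiplier = 1) {
  if (L < 1) stop("L must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (any(samples$n_haploid %% 2L != 0L)) {
    stop("haploid sample sizes must be even to form diploids")
  }
  set.seed(seed)
  tl <- build_timeline(params)
  ent <- simulate_entries(tl, samples, n = L, cfg = cfg, seed = NULL)
  n_dip <- samples$n_haploid %/% 2L
  ntot <- sum(n_dip)
  geno <- matrix(0L, ntot, L)
  offsets <- c(0L, cumsum(n_dip))
  for (loc in seq_len(L)) {
    for (c in seq_along(n_dip)) {
      k <- ent[loc, c]
      if (k == 0) next
      hap <- integer(samples$n_haploid[c])
      hap[sample.int(samples$n_haploid[c], k)] <- 1L
      gc <- hap[seq(1, length(hap), by = 2)] + hap[seq(2, length(hap), by = 2)]
      geno[(offsets[c] + 1):offsets[c + 1], loc] <- gc
    }
  }
  cohort <- rep(samples$labels, n_dip)
  rownames(geno) <- sprintf("%s_ind%03d", cohort,
                            unlist(lapply(n_dip, seq_len)))
  if (missing_rate > 0) {
    rate <- pmin(missing_rate * rep_len(ind_missing_multiplier, ntot), 0.99)
    mask <- matrix(stats::runif(ntot * L) < rate, ntot, L)
    geno[mask] <- NA_integer_
  }
  g <- genotype_matrix(geno,
                       contig = sprintf("contig%05d", seq_len(L)),
                       pos = rep(25L, L),
                       cohort = cohort)
  truth <- list(params = params, samples = samples, L = L,
                missing_rate = missing_rate, entries = ent, seed = seed)
  list(genotypes = g, truth = truth)
}

#' Generate a genotype matrix with planted filter violations
#'
#' Builds a small matrix in which specific individuals and loci violate
#' each post-VCF filter rule: individuals above/below the 50% missingness
#' boundary, loci above/below the 95% presence requirement, multi-SNP
#' contigs, heterozygosity-outlier individuals and a locus far out of
#' Hardy-Weinberg proportions. The intended survivor sets of the full
#' filter chain are recorded in the truth record.
#'
#' @param seed Integer seed.
#' @return List with `genotypes` and `truth` (element `survivors`: the
#'   individual ids and locus names expected to pass [filter_chain()]).
#' @export
generate_filter_testset <- function(seed = 1L) {
  set.seed(seed)
  n_base <- 20L   # well-behaved individuals
  L_base <- 40L   # well-behaved loci (one per contig)
  n <- n_base + 3L  # + high-missing, boundary-missing, het-outlier
  geno <- matrix(0L, n, L_base)
  # moderate-frequency genotypes in HWP for the well-behaved block
  for (j in seq_len(L_base)) {
    p <- stats::runif(1, 0.2, 0.5)
    geno[seq_len(n), j] <- stats::rbinom(n, 2, p)
  }
  ids <- c(sprintf("good%02d", seq_len(n_base)),
           "too_missing", "boundary_missing", "het_outlier")
  # heterozygosity outlier: heterozygous at every well-behaved locus
  geno[n_base + 3L, ] <- 1L
  contig <- sprintf("c%03d", seq_len(L_base))
  pos <- rep(10L, L_base)
  # extra loci (4 of them; 44 total so the 50% boundary is exact):
  # keeper: complete, in HWP, own contig -> survives the whole chain
  keeper <- matrix(stats::rbinom(n, 2, 0.3), n, 1)
  # low presence: missing in 3 of the 22 individuals left after the
  # missingness filter (19/22 < 95%)
  low_presence <- matrix(stats::rbinom(n, 2, 0.3), n, 1)
  low_presence[1:3, 1] <- NA_integer_
  # second SNP on contig c001 at a later position (first-SNP rule)
  dup_snp <- matrix(stats::rbinom(n, 2, 0.3), n, 1)
  # HWP violator: all homozygotes, half ref half alt (exact p << 1e-3)
  hwp_bad <- matrix(rep(c(0L, 2L), length.out = n), n, 1)
  geno <- cbind(geno, keeper, low_presence, dup_snp, hwp_bad)
  contig <- c(contig, "c800", "c900", "c001", "c901")
  pos <- c(pos, 10L, 10L, 50L, 10L)
  L_tot <- ncol(geno)  # 44
  # individual with > 50% missing (removed): 24/44
  geno[n_base + 1L, seq_len(24L)] <- NA_integer_
  # individual with exactly 50% missing (boundary; retained): 22/44
  geno[n_base + 2L, seq_len(22L)] <- NA_integer_
  colnames(geno) <- paste0(contig, "_", pos)
  rownames(geno) <- ids
  g <- genotype_matrix(geno, contig, pos, cohort = rep("A", n))
  survivors <- list(
    individuals = setdiff(ids, c("too_missing", "het_outlier")),
    loci = c(colnames(geno)[seq_len(L_base)], "c800_10")
  )
  list(genotypes = g,
       truth = list(survivors = survivors, seed = seed))
}

#' Generate an age-structured table with known answers
#'
#' Random but reproducible abundance/mortality/maturity/fecundity
#' schedules, with the closed-form peak-spawning abundance and generation
#' lengths stored in the truth record.
#'
#' @param A Oldest age class (>= 1).
#' @param years Calendar years to cover.
#' @param seed Integer seed.
#' @param p Fraction of year elapsed at peak spawning.
#' @return List with `table` (an [age_table()]) and `truth` (per-year
#'   peak-spawning abundance and the female/male/average generation
#'   lengths computed in closed form from the schedules).
#' @export
generate_age_table <- function(A = 7L, years = 1982:2008, seed = 1L,
                               p = 10 / 12) {
  if (A < 1) stop("A must be >= 1")
  set.seed(seed)
  grid <- expand.grid(age = 0:A, year = years)[, c("year", "age")]
  grid$N <- stats::runif(nrow(grid), 1e4, 1e7)
  grid$Z <- stats::runif(nrow(grid), 0.1, 1.2)
  grid$maturity <- pmin(1, pmax(0, (grid$age - 0.5) / 3))
  grid$fecundity <- ifelse(grid$age == 0, 0, grid$age^1.5)
  tbl <- age_table(grid, p = p)
  nps <- vapply(years, function(y) {
    d <- grid[grid$year == y, ]
    sum(d$N * d$maturity * exp(-p * d$Z))
  }, numeric(1))
  gl <- vapply(years, function(y) {
    d <- grid[grid$year == y, ]
    wf <- d$N * d$maturity * d$fecundity
    wm <- d$N * d$maturity
    c(sum(d$age * wf) / sum(wf), sum(d$age * wm) / sum(wm))
  }, numeric(2))
  truth <- list(
    peak_spawning = stats::setNames(nps, years),
    female = mean(gl[1, ]), male = mean(gl[2, ]),
    average = (mean(gl[1, ]) + mean(gl[2, ])) / 2,
    seed = seed
  )
  list(table = tbl, truth = truth)
}
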