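# shared fixtures for the test suite (all built in code)

# small three-cohort design used where the full study design would be slow
small_design <- function() {
  sample_spec(n_haploid = c(10L, 20L, 30L), times = c(7, 5.5, 0),
              labels = c("t7", "t5.5", "t0"))
}

# reported ML point estimates (diploid units) used in worked examples
table2_ml <- function() {
  list(NANC = 1052, NPREBOT = 32209, NBOT = 910, NPOP08 = 10212,
       TLEN = 2, TBOT = 12)
}

# tiny deterministic genotype matrix: 5 individuals x 4 loci, two cohorts
tiny_genotypes <- function() {
  geno <- rbind(
    c(0L, 1L, 2L, 0L),
    c(1L, 1L, 0L, 0L),
    c(0L, 0L, 1L, NA),
    c(2L, 0L, 0L, 0L),
    c(0L, 2L, 1L, 0L)
  )
  rownames(geno) <- paste0("ind", 1:5)
  genotype_matrix(geno,
                  contig = c("c1", "c1", "c2", "c3"),
                  pos = c(10L, 70L, 5L, 30L),
                  cohort = c("A", "A", "B", "B", "B"))
}

# brute-force multiSFS tally used as the independent oracle
brute_force_sfs <- function(geno, cohort, cohort_levels) {
  complete <- colSums(is.na(geno)) == 0
  geno <- geno[, complete, drop = FALSE]
  n_hap <- vapply(cohort_levels, function(cl) 2L * sum(cohort == cl),
                  integer(1))
  tot <- sum(n_hap)
  counts <- list()
  for (j in seq_len(ncol(geno))) {
    e <- vapply(cohort_levels, function(cl)
      sum(geno[cohort == cl, j]), numeric(1))
    if (sum(e) > tot / 2) e <- n_hap - e
    key <- paste(e, collapse = ",")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
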