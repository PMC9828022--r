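#' Multidimensional site frequency spectrum (multiSFS)
#'
#' Sparse container for a (possibly folded) multidimensional SFS over one or
#' more cohorts. Entry `(i1, ..., ik)` holds the number of loci (kind
#' `"observed"`) or the probability (kind `"expected"`) with `ic` copies of
#' the derived/minor allele in cohort `c`.
#'
#' @param entries Integer matrix (n x n_cohorts) of per-cohort allele
#'   counts, or `NULL` for an empty spectrum.
#' @param values Numeric vector of counts or probabilities per entry row.
#' @param n_haploid Integer vector of per-cohort haploid sample sizes.
#' @param kind `"observed"` (counts) or `"expected"` (probabilities).
#' @param folded Logical; whether the spectrum is folded by the pooled
#'   minor allele.
#' @param labels,times Cohort metadata.
#' @param n_sims For expected spectra, the Monte Carlo sample size used to
#'   estimate it (drives the zero-probability floor in
#'   [composite_loglik()]).
#' @return An object of class `multisfs` with fields `dims` (per-cohort
#'   `n+1` where `n` is the haploid size), `index` (1-based linear
#'   indices, first cohort fastest),
#'   `value`, and the metadata above.
#' @export
multisfs <- function(entries, values, n_haploid, kind = c("observed", "expected"),
                     folded = FALSE, labels = NULL, times = NULL,
                     n_sims = NULL) {
  kind <- match.arg(kind)
  n_haploid <- as.integer(n_haploid)
  dims <- n_haploid + 1L
  if (is.null(entries)) {
    idx <- integer(0); values <- numeric(0)
  } else {
    entries <- as.matrix(entries)
    if (ncol(entries) != length(n_haploid)) stop("entry arity mismatch")
    if (any(entries < 0) || any(t(entries) > dims - 1L))
      stop("entry out of range for sample sizes")
    idx <- entries_to_index(entries, dims)
  }
  if (any(values < 0)) stop("counts/probabilities must be >= 0")
  # aggregate duplicate entries, drop zeros, sort by index
  keep <- values > 0
  idx <- idx[keep]; values <- values[keep]
  if (anyDuplicated(idx)) {
    agg <- rowsum(values, idx)
    idx <- as.numeric(rownames(agg)); values <- agg[, 1]
  }
  o <- order(idx)
  structure(list(dims = dims, n_haploid = n_haploid,
                 index = idx[o], value = unname(values[o]),
                 kind = kind, folded = folded,
                 labels = labels %||% as.character(seq_along(dims)),
                 times = times %||% rep(0, length(dims)),
                 n_sims = n_sims),
            class = "multisfs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear index (1-based, first cohort varying fastest) from entry rows
entries_to_index <- function(entries, dims) {
  strides <- cumprod(c(1, dims[-length(dims)]))
  as.numeric(entries %*% strides) + 1
}

# entry rows from linear index
index_to_entries <- function(index, dims) {
  k <- length(dims)
  out <- matrix(0L, length(index), k)
  rem <- index - 1
  for (c in seq_len(k)) {
    out[, c] <- as.integer(rem %% dims[c])
    rem <- rem %/% dims[c]
  }
  out
}

#' @export
print.multisfs <- function(x, ...) {
  cat(sprintf("multisfs (%s%s): cohorts n_haploid = %s; %d non-zero entries; total %.6g\n",
              x$kind, if (x$folded) ", folded" else "",
              paste(x$n_haploid, collapse = "/"),
              length(x$index), sum(x$value)))
  invisible(x)
}

#' Total mass of a spectrum
#' @param s A `multisfs`.
#' @return Sum of all entry values (locus count or total probability).
#' @export
sfs_total <- function(s) sum(s$value)

#' Entry rows of a spectrum
#' @param s A `multisfs`.
#' @return Integer matrix of per-cohort allele counts, one row per stored
#'   entry (aligned with `s$value`).
#' @export
sfs_entries <- function(s) index_to_entries(s$index, s$dims)

#' Fold a spectrum by the pooled minor allele
#'
#' Each entry `e` is pooled with its complement `n - e` (per-cohort haploid
#' sizes `n`); mass is moved to the member whose pooled allele count is at
#' most half the pooled total.
#' Entries at exactly half the pooled total are kept where they fall with
#' full weight. Total mass is conserved exactly.
#'
#' @param s An unfolded `multisfs`.
#' @return The folded spectrum.
#' @export
sfs_fold <- function(s) {
  if (s$folded) stop("spectrum is already folded")
  ent <- sfs_entries(s)
  pooled <- rowSums(ent)
  tot <- sum(s$n_haploid)
  flip <- pooled > tot / 2
  if (any(flip))
    ent[flip, ] <- rep(s$n_haploid, each = sum(flip)) - ent[flip, , drop = FALSE]
  multisfs(ent, s$value, s$n_haploid, kind = s$kind, folded = TRUE,
           labels = s$labels, times = s$times, n_sims = s$n_sims)
}

#' Remove monomorphic entries
#'
#' Zeroes the all-reference and all-alternate entries; expected spectra are
#' renormalized over the remaining (polymorphic) entries.
#'
#' @param s A `multisfs`.
#' @return The spectrum without monomorphic mass.
#' @export
remove_monomorphic <- function(s) {
  mono <- c(1, prod(s$dims))
  keep <- !(s$index %in% mono)
  if (!any(keep) && length(s$index) > 0) stop("all mass is monomorphic")
  val <- s$value[keep]
  if (s$kind == "expected" && sum(val) > 0) val <- val / sum(val)
  out <- s
  out$index <- s$index[keep]
  out$value <- val
  out
}

#' Build an observed multiSFS from genotypes
#'
#' Uses only loci with zero missing genotypes (complete-data rule), tallies
#' one entry per locus at its per-cohort alternate-allele counts, then folds
#' by the pooled minor allele.
#'
#' @param g A [genotype_matrix()].
#' @param cohort_levels Cohort label order defining the spectrum's
#'   dimensions (default: sorted unique labels).
#' @param times Sampling times per cohort (metadata only).
#' @return A folded observed `multisfs`; its total equals the number of
#'   complete loci.
#' @export
sfs_from_genotypes <- function(g, cohort_levels = sort(unique(g$cohort)),
                               times = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(g$cohort %in% cohort_levels))
    stop("cohort label absent from cohort_levels")
  complete <- colSums(is.na(g$geno)) == 0
  if (!any(complete)) stop("no loci with complete data")
  geno <- g$geno[, complete, drop = FALSE]
  counts <- vapply(cohort_levels, function(cl) {
    colSums(geno[g$cohort == cl, , drop = FALSE])
  }, numeric(ncol(geno)))
  if (ncol(geno) == 1) counts <- matrix(counts, nrow = 1)
  n_hap <- vapply(cohort_levels, function(cl) 2L * sum(g$cohort == cl), integer(1))
  s <- multisfs(counts, rep(1, nrow(counts)), n_haploid = n_hap,
                kind = "observed", folded = FALSE, labels = cohort_levels,
                times = times %||% rep(0, length(cohort_levels)))
  sfs_fold(s)
}

#' Marginal one-dimensional folded SFS for one cohort
#'
#' Sums the spectrum over all other cohorts' indices, then folds the
#' marginal by that cohort's own minor allele.
#'
#' @param s A `multisfs`.
#' @param cohort Cohort label or index.
#' @return Named numeric vector over minor-allele counts `0..n`.
#' @export
sfs_marginalize <- function(s, cohort) {
  if (is.character(cohort)) cohort <- match(cohort, s$labels)
  if (is.na(cohort) || cohort < 1 || cohort > length(s$dims))
    stop("unknown cohort")
  ent <- sfs_entries(s)
  i <- ent[, cohort]
  n2 <- s$dims[cohort] - 1L  # = cohort haploid size
  marg <- rep(0, n2 + 1)
  for (r in seq_along(i)) marg[i[r] + 1] <- marg[i[r] + 1] + s$value[r]
  # per-cohort fold of the marginal
  half <- floor(n2 / 2)
  folded <- numeric(half + 1)
  for (j in 0:half) {
    comp <- n2 - j
    folded[j + 1] <- if (comp == j) marg[j + 1] else marg[j + 1] + marg[comp + 1]
  }
  names(folded) <- 0:half
  folded
}

#' Bootstrap-resample an observed spectrum over loci
#'
#' Draws `L` loci (the observed total) from the spectrum's empirical entry
#' distribution by a multinomial draw; totals are preserved.
#'
#' @param s An observed `multisfs` with total `L >= 1`.
#' @param seed Integer seed for reproducibility.
#' @return A resampled observed `multisfs`.
#' @export
sfs_bootstrap_resample <- function(s, seed = NULL) {
  if (s$kind != "observed") stop("bootstrap resampling needs an observed spectrum")
  L <- sum(s$value)
  if (L < 1) stop("empty spectrum")
  if (!is.null(seed)) set.seed(seed)
  draw <- as.numeric(stats::rmultinom(1, size = L, prob = s$value / L))
  out <- s
  keep <- draw > 0
  out$index <- s$index[keep]
  out$value <- draw[keep]
  out
}

#' Convert an observed spectrum to its empirical probability spectrum
#'
#' @param s An observed `multisfs`.
#' @return An expected-kind `multisfs` with entry probabilities `O_e / L`.
#' @export
sfs_as_expected <- function(s) {
  if (s$kind != "observed") stop("input must be observed counts")
  out <- s
  out$kind <- "expected"
  out$value <- s$value / sum(s$value)
  out$n_sims <- sum(s$value)
  out
}

#' Write a multiSFS in .obs text format
#'
#' One canonical dialect: a header line `"1 observations ..."`, a second
#' line with the number of demes and per-cohort haploid sample sizes, then
#' the flattened value vector with the LAST cohort's index varying fastest.
#'
#' @param s A `multisfs`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obs <- function(s, path) {
  k <- length(s$dims)
  dense <- rep(0, prod(s$dims))
  ent <- sfs_entries(s)
  # file order: last cohort fastest
  rev_strides <- rev(cumprod(c(1, rev(s$dims)[-k])))
  fpos <- as.numeric(ent %*% rev_strides) + 1
  dense[fpos] <- s$value
  lines <- c(
    sprintf("1 observations. Flattened multiSFS (%s%s), last cohort fastest.",
            s$kind, if (s$folded) ", folded" else ""),
    paste(c(k, s$n_haploid), collapse = "\t"),
    paste(format(dense, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a multiSFS from .obs text format
#'
#' Tolerates arbitrary whitespace between values and values split over
#' multiple lines.
#'
#' @param path Path to an .obs file written by [write_obs()] (or in the
#'   compatible dialect).
#' @param kind `"observed"` or `"expected"`.
#' @param folded Whether the stored spectrum is folded.
#' @return A `multisfs`.
#' @export
read_obs <- function(path, kind = "observed", folded = TRUE) {
  if (!file.exists(path)) stop(".obs file not found: ", path)
  lines <- readLines(path)
  hdr <- scan(text = lines[2], quiet = TRUE)
  k <- as.integer(hdr[1])
  n_hap <- as.integer(hdr[-1])
  dims <- n_hap + 1L
  vals <- scan(text = paste(lines[-(1:2)], collapse = " "), quiet = TRUE)
  if (length(vals) != prod(dims)) stop("value count does not match dimensions")
  nz <- which(vals != 0)
  # decode file order (last cohort fastest)
  ent <- matrix(0L, length(nz), k)
  rem <- nz - 1
  for (c in k:1) {
    ent[, c] <- as.integer(rem %% dims[c])
    rem <- rem %/% dims[c]
  }
  multisfs(ent, vals[nz], n_hap, kind = kind, folded = folded)
}
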