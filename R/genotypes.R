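#' Biallelic genotype matrix with locus metadata and cohort labels
#'
#' Container for individuals x loci biallelic genotypes coded as copies of
#' the alternate allele (0/1/2, `NA` = missing), with per-locus contig and
#' 1-based position and a per-individual cohort label.
#'
#' @param geno Integer matrix (individuals x loci) with values in
#'   `{0, 1, 2, NA}`. Row names are individual ids.
#' @param contig Character vector, one contig id per locus.
#' @param pos Integer vector of 1-based positions, unique within contig.
#' @param cohort Character vector, one cohort label per individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, contig, pos, cohort) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
    stop("genotypes must be 0, 1, 2 or NA")
  if (length(contig) != ncol(geno) || length(pos) != ncol(geno))
    stop("contig/pos length must equal number of loci")
  if (length(cohort) != nrow(geno))
    stop("one cohort label per individual required")
  if (anyDuplicated(paste(contig, pos)))
    stop("positions must be unique within contig")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("%s_%d", contig, pos)
  structure(list(geno = geno, contig = as.character(contig),
                 pos = as.integer(pos), cohort = as.character(cohort)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "loci;", length(unique(x$cohort)), "cohort(s);",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# internal: subset rows (individuals) / cols (loci) keeping metadata in sync
subset_gm <- function(g, individuals = NULL, loci = NULL) {
  geno <- g$geno
  cohort <- g$cohort
  contig <- g$contig
  pos <- g$pos
  if (!is.null(individuals)) {
    geno <- geno[individuals, , drop = FALSE]
    cohort <- cohort[individuals]
  }
  if (!is.null(loci)) {
    geno <- geno[, loci, drop = FALSE]
    contig <- contig[loci]
    pos <- pos[loci]
  }
  genotype_matrix(geno, contig, pos, cohort)
}

#' Read genotypes from a VCF plus a sample-to-cohort table
#'
#' Reads biallelic SNP records (GT field) from a VCF file via
#' \pkg{vcfR} and attaches cohort labels from a two-column tab-separated
#' table (`sample`, `cohort`). Multiallelic records and indels are dropped.
#'
#' @param vcf_path Path to a VCF file (plain or gzipped).
#' @param cohort_path Path to a TSV with columns `sample` and `cohort`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(vcf_path, cohort_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (!file.exists(cohort_path)) stop("cohort table not found: ", cohort_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    x <- gsub("\\|", "/", x)
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  geno <- t(matrix(code(c(gt)), nrow = nrow(gt)))  # individuals x loci
  rownames(geno) <- colnames(gt)
  colnames(geno) <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  tab <- utils::read.table(cohort_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "cohort") %in% names(tab)))
    stop("cohort table needs columns 'sample' and 'cohort'")
  m <- match(rownames(geno), tab$sample)
  if (anyNA(m)) stop("cohort label absent for individual(s): ",
                     paste(rownames(geno)[is.na(m)], collapse = ", "))
  genotype_matrix(geno, fix[, "CHROM"], as.integer(fix[, "POS"]),
                  tab$cohort[m])
}

#' Write a genotype matrix as VCF plus a cohort table
#'
#' Emits a minimal VCF 4.2 text file (GT-only, REF=A, ALT=T) and a
#' two-column `sample`/`cohort` TSV so that synthetic data round-trip
#' through the standard formats.
#'
#' @param g A [genotype_matrix()].
#' @param vcf_path,cohort_path Output paths.
#' @return Invisibly, the VCF path.
#' @export
write_genotypes_vcf <- function(g, vcf_path, cohort_path) {
  geno <- g$geno
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(geno)), function(j) {
    gts <- ifelse(is.na(geno[, j]), "./.", gt_code[as.character(geno[, j])])
    paste(c(g$contig[j], g$pos[j], ".", "A", "T", ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  utils::write.table(data.frame(sample = rownames(geno), cohort = g$cohort),
                     cohort_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}
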