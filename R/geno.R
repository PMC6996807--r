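# Genotype ingestion, QC and genomic relationship matrix.

#' Construct a genotype matrix
#'
#' Wraps an accessions x markers matrix of biallelic SNP dosages coded
#' 0/1/2 (minor-allele copy counts), with `NA` as the missing sentinel.
#'
#' @param dosages numeric matrix, accessions in rows, markers in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param accession_ids,marker_ids identifiers; default to the dimnames of
#'   `dosages`.
#' @return an object of class `genotype_matrix` (an integer matrix with
#'   dimnames).
#' @export
genotype_matrix <- function(dosages,
                            accession_ids = rownames(dosages),
                            marker_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(accession_ids)) {
    accession_ids <- sprintf("ACC%04d", seq_len(nrow(dosages)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- sprintf("M%05d", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(accession_ids)) stop("duplicate accession identifiers")
  if (anyDuplicated(marker_ids)) stop("duplicate marker identifiers")
  if (length(accession_ids) != nrow(dosages) ||
      length(marker_ids) != ncol(dosages)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(accession_ids, marker_ids)
  class(dosages) <- c("genotype_matrix", class(dosages))
  dosages
}

.geno_unclass <- function(geno) {
  m <- unclass(geno)
  class(m) <- NULL
  m
}

#' Minor allele frequency and call rate per marker
#'
#' MAF is computed from non-missing calls only.
#'
#' @param geno a [genotype_matrix()].
#' @return data.frame with columns `marker`, `maf`, `callrate`.
#' @export
marker_stats <- function(geno) {
  d <- .geno_unclass(geno)
  callrate <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  data.frame(marker = colnames(d), maf = maf, callrate = callrate,
             row.names = NULL)
}

#' Quality-control filter for SNP markers
#'
#' Removes markers with call rate less than or equal to `callrate_min` or
#' minor allele frequency less than or equal to `maf_min`; markers strictly
#' above both thresholds are kept. Accessions and marker order are preserved.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minor allele frequency threshold in `[0, 1]` (default 0.05).
#' @param callrate_min call-rate threshold in `[0, 1]` (default 0.95).
#' @return the filtered `genotype_matrix`.
#' @export
filter_snps <- function(geno, maf_min = 0.05, callrate_min = 0.95) {
  stopifnot(maf_min >= 0, maf_min <= 1, callrate_min >= 0, callrate_min <= 1)
  st <- marker_stats(geno)
  keep <- !is.na(st$maf) & st$maf > maf_min & st$callrate > callrate_min
  if (!any(keep)) {
    stop(errorCondition("no markers survive QC",
                        class = c("rrgp_no_markers", "error")))
  }
  d <- .geno_unclass(geno)[, keep, drop = FALSE]
  genotype_matrix(d)
}

#' Genomic relationship matrix from SNP dosages
#'
#' Builds `G = W W' / m` from the centered (and, with `scaling = "unit"`,
#' column-standardized) dosage matrix `W` with `m` markers. With unit scaling
#' each column is divided by its population standard deviation (divisor `n`),
#' which makes `mean(diag(G)) = 1` an exact identity on complete data. The
#' alternative `scaling = "vanraden"` divides the centered cross-product by
#' `2 * sum(p * (1 - p))` instead of standardizing columns.
#'
#' @param geno a [genotype_matrix()]; must be complete unless
#'   `impute_mean = TRUE`.
#' @param scaling `"unit"` (column-standardized, default) or `"vanraden"`.
#' @param ridge value added to the diagonal (default 0). Models that invert
#'   `G` should add a small ridge once, up front; see [add_ridge()].
#' @param impute_mean replace missing calls by the marker mean (testing
#'   convenience only; imputation proper is out of scope).
#' @return symmetric accessions x accessions matrix with dimnames.
#' @export
compute_grm <- function(geno, scaling = c("unit", "vanraden"), ridge = 0,
                        impute_mean = FALSE) {
  scaling <- match.arg(scaling)
  d <- .geno_unclass(geno)
  storage.mode(d) <- "double"
  if (nrow(d) < 2) stop("need at least 2 accessions")
  if (anyNA(d)) {
    if (!impute_mean) {
      stop("missing genotypes present; impute first or set impute_mean = TRUE")
    }
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  n <- nrow(d)
  m <- ncol(d)
  cm <- colMeans(d)
  v <- colMeans(d^2) - cm^2  # population variance
  if (any(v <= 0)) {
    stop("monomorphic markers present (zero variance); run filter_snps() first")
  }
  W <- sweep(d, 2, cm)
  if (scaling == "unit") {
    W <- sweep(W, 2, sqrt(v), "/")
    G <- tcrossprod(W) / m
  } else {
    p <- cm / 2
    G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  if (ridge != 0) G <- add_ridge(G, ridge)
  G
}

#' Add a diagonal ridge to a relationship matrix
#'
#' `G` built from finitely many markers is singular whenever accessions
#' outnumber markers' effective rank; a small ridge makes every inversion in
#' the package well defined. Apply it once, when the matrix enters a model.
#'
#' @param G symmetric matrix.
#' @param ridge value added to the diagonal (default `1e-6`).
#' @return the stabilized matrix.
#' @export
add_ridge <- function(G, ridge = 1e-6) {
  G + diag(ridge, nrow(G))
}

#' Blend a genomic relationship matrix with the identity
#'
#' `G* = (1 - weight) G + weight I` (VanRaden blending). A centered GRM is
#' always singular — the ones vector lies in its null space — and a merely
#' ridged inverse makes Gibbs location updates nearly reducible along that
#' direction. Blending bounds the smallest eigenvalue by `weight`, which is
#' what pedigree-package practice does before inverting a genomic matrix.
#'
#' @param G relationship matrix.
#' @param weight identity weight in `(0, 1)` (default 0.05).
#' @return the blended matrix.
#' @export
blend_grm <- function(G, weight = 0.05) {
  stopifnot(weight > 0, weight < 1)
  (1 - weight) * G + diag(weight, nrow(G))
}

#' Read a dosage table
#'
#' Reads a whitespace- or comma-delimited table whose header row holds marker
#' ids and whose first column holds accession ids; remaining entries are
#' dosages 0/1/2 with `NA` (or the string in `na_strings`) for missing.
#'
#' @param file path.
#' @param na_strings strings read as missing (default `c("NA", ".")`).
#' @return a [genotype_matrix()].
#' @export
read_dosage <- function(file, na_strings = c("NA", ".")) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                    na.strings = na_strings, stringsAsFactors = FALSE)
  acc <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  genotype_matrix(d, accession_ids = acc, marker_ids = colnames(tab)[-1])
}

#' Write a dosage table
#'
#' @param geno a [genotype_matrix()].
#' @param file path.
#' @param sep field separator (default tab).
#' @export
write_dosage <- function(geno, file, sep = "\t") {
  d <- .geno_unclass(geno)
  out <- data.frame(accession = rownames(d), d, check.names = FALSE)
  write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read genotypes from PLINK-style .ped/.map text files
#'
#' Thin adapter for the classic text PLINK pair: `.map` supplies marker ids
#' (column 2), `.ped` supplies two allele columns per marker after the six
#' leading pedigree columns. Dosages count copies of the minor allele
#' determined from the file itself; `0` alleles are missing calls. The binary
#' `.bed` format is not supported (text formats only).
#'
#' @param ped,map paths to the `.ped` and `.map` files.
#' @return a [genotype_matrix()].
#' @export
read_ped <- function(ped, map) {
  mp <- read.table(map, header = FALSE, stringsAsFactors = FALSE)
  marker_ids <- as.character(mp[[2]])
  pd <- read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(pd) != 6 + 2 * length(marker_ids)) {
    stop(".ped column count does not match .map marker count")
  }
  acc <- pd[[2]]
  m <- length(marker_ids)
  d <- matrix(NA_integer_, nrow(pd), m)
  for (j in seq_len(m)) {
    a1 <- pd[[6 + 2 * j - 1]]
    a2 <- pd[[6 + 2 * j]]
    alleles <- c(a1, a2)
    obs <- alleles[alleles != "0"]
    lev <- names(sort(table(obs)))  # rarest first
    if (length(lev) == 0) next
    minor <- lev[1]
    miss <- a1 == "0" | a2 == "0"
    d[, j] <- (a1 == minor) + (a2 == minor)
    d[miss, j] <- NA_integer_
  }
  genotype_matrix(d, accession_ids = acc, marker_ids = marker_ids)
}

#' Write / read a relationship matrix as a delimited square table
#'
#' @param G symmetric matrix with accession dimnames.
#' @param file path.
#' @rdname grm_io
#' @export
write_grm <- function(G, file) {
  out <- data.frame(accession = rownames(G), G, check.names = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname grm_io
#' @export
read_grm <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  G <- as.matrix(tab[, -1, drop = FALSE])
  rownames(G) <- as.character(tab[[1]])
  G
}
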