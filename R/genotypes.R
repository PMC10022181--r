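#' Genotype container
#'
#' Construct a genotype set: allele dosages (0/1/2, `NA` missing) for a set
#' of individuals with breed labels, a marker map, and optionally the two
#' phased haplotypes per individual. Where both haplotypes are present their
#' sum must equal the dosage.
#'
#' @param dosage Individuals x markers integer matrix with rownames (ids)
#'   and colnames (marker ids).
#' @param map Data frame with columns `marker`, `chr`, `pos`; positions must
#'   be strictly increasing within chromosome.
#' @param breed Named character vector (`B`, `H` or `BH`) covering all ids,
#'   or a data frame with columns `id`, `breed`.
#' @param hap1,hap2 Optional haplotype matrices (0/1) with the same
#'   dimnames as `dosage`; rows may be all-`NA` for unphased individuals.
#' @return An object of class `cb_genotypes`.
#' @export
genotype_set <- function(dosage, map, breed, hap1 = NULL, hap2 = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  map <- tibble::as_tibble(as.data.frame(map))
  stopifnot(all(c("marker", "chr", "pos") %in% names(map)))
  map$marker <- as.character(map$marker)
  map$chr <- as.character(map$chr)
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in map")
  if (!identical(colnames(dosage), map$marker)) {
    stop("dosage columns must match map$marker in order")
  }
  bad_pos <- unlist(lapply(split(map$pos, map$chr), function(p) any(diff(p) <= 0)))
  if (any(bad_pos)) stop("positions not strictly increasing within chromosome")
  if (is.data.frame(breed)) breed <- stats::setNames(breed$breed, breed$id)
  breed <- breed[rownames(dosage)]
  if (anyNA(breed)) stop("breed label missing for some individuals")
  if (!all(breed %in% c("B", "H", "BH"))) stop("breed labels must be B, H or BH")
  if (!is.null(hap1) != !is.null(hap2)) stop("supply both haplotypes or neither")
  if (!is.null(hap1)) {
    stopifnot(identical(dim(hap1), dim(dosage)),
              identical(dim(hap2), dim(dosage)))
    both <- !is.na(hap1) & !is.na(hap2) & !is.na(dosage)
    if (any((hap1 + hap2)[both] != dosage[both])) {
      stop("haplotypes do not sum to dosage")
    }
  }
  structure(list(dosage = dosage, map = map,
                 breed = stats::setNames(as.character(breed), rownames(dosage)),
                 hap1 = hap1, hap2 = hap2),
            class = "cb_genotypes")
}

#' @export
print.cb_genotypes <- function(x, ...) {
  cat("Genotype set:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers on", length(unique(x$map$chr)),
      "chromosome(s)\n")
  cat("  breeds:", paste(names(table(x$breed)), table(x$breed),
                         sep = "=", collapse = ", "), "\n")
  ph <- phased_ids(x)
  cat("  phased individuals:", length(ph), "\n")
  invisible(x)
}

#' Ids with complete phased haplotypes
#' @param gs A `cb_genotypes`.
#' @return Character vector of ids.
#' @export
phased_ids <- function(gs) {
  if (is.null(gs$hap1)) return(character(0))
  rownames(gs$dosage)[rowSums(is.na(gs$hap1)) == 0 &
                      rowSums(is.na(gs$hap2)) == 0]
}

#' Read phased genotypes from a VCF file
#'
#' Parses GT fields with `vcfR`. Dosages are kept for every sample;
#' haplotypes are retained only for samples whose every genotype is phased
#' (`|` separator). Multi-allelic sites are rejected.
#'
#' @param path VCF path (optionally gzipped).
#' @param breeds Named character vector or `id`/`breed` data frame giving
#'   each sample's breed.
#' @return A [genotype_set()].
#' @export
read_phased_vcf <- function(path, breeds) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {          # single-variant files drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (any(nchar(fix[, "ALT"]) > 1 | grepl(",", fix[, "ALT"]))) {
    stop("multi-allelic or non-SNP ALT alleles are not supported")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  marker <- fix[, "ID"]
  marker[is.na(marker) | marker == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(marker) | marker == "."]
  samples <- colnames(gt)

  as_mk_mat <- function(x) matrix(x, nrow = nrow(gt), ncol = ncol(gt))
  a1 <- as_mk_mat(suppressWarnings(as.integer(substr(gt, 1, 1))))
  a2 <- as_mk_mat(suppressWarnings(as.integer(substr(gt, 3, 3))))
  sepc <- as_mk_mat(substr(gt, 2, 2))

  h1 <- t(a1); h2 <- t(a2)
  dimnames(h1) <- dimnames(h2) <- list(samples, marker)
  dos <- h1 + h2
  phased_obs <- t(sepc == "|") & !is.na(h1) & !is.na(h2)
  all_phased <- rowSums(phased_obs) == ncol(h1)
  h1[!all_phased, ] <- NA_integer_
  h2[!all_phased, ] <- NA_integer_

  map <- tibble::tibble(marker = marker, chr = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]))
  genotype_set(dos, map, breeds, hap1 = h1, hap2 = h2)
}

#' Allele frequencies in a group
#'
#' Frequency of the reference (counted) allele per marker: mean dosage over
#' non-missing entries divided by 2.
#'
#' @param gs A [genotype_set()].
#' @param group Ids to use; defaults to all individuals.
#' @return Named numeric vector of frequencies per marker; markers with no
#'   observed genotype in the group are `NaN` and carry the attribute
#'   `all_missing` listing them.
#' @export
allele_freq <- function(gs, group = rownames(gs$dosage)) {
  if (!length(group)) stop("empty group")
  miss <- setdiff(group, rownames(gs$dosage))
  if (length(miss)) stop("ids not in genotype set: ", paste(miss, collapse = ", "))
  m <- gs$dosage[group, , drop = FALSE]
  p <- colMeans(m, na.rm = TRUE) / 2
  bad <- colSums(!is.na(m)) == 0
  if (any(bad)) attr(p, "all_missing") <- colnames(m)[bad]
  p
}

#' Quality control of genotype data
#'
#' Applies, in order: individual call-rate, SNP call-rate, minor allele
#' frequency (computed over retained individuals), and a within-breed 1-df
#' chi-square Hardy-Weinberg test restricted to purebreds (a marker failing
#' in any pure breed is removed). Each removed marker is attributed to the
#' first rule it fails.
#'
#' @param gs A [genotype_set()].
#' @param ind_callrate,snp_callrate Minimum call-rate fractions (default 0.90).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_p_min Hardy-Weinberg p-value threshold (default 1e-7).
#' @return A list with the filtered `genotypes` and a `report` of class
#'   `cb_qc_report`.
#' @export
qc_filter <- function(gs, ind_callrate = 0.90, snp_callrate = 0.90,
                      maf_min = 0.01, hwe_p_min = 1e-7) {
  dos <- gs$dosage
  cr_ind <- rowMeans(!is.na(dos))
  drop_ind <- rownames(dos)[cr_ind < ind_callrate]
  keep_ind <- setdiff(rownames(dos), drop_ind)
  dos <- dos[keep_ind, , drop = FALSE]

  cr_snp <- colMeans(!is.na(dos))
  fail_cr <- cr_snp < snp_callrate

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- !fail_cr & (is.nan(maf) | maf < maf_min)

  fail_hwe <- rep(FALSE, ncol(dos))
  for (b in c("B", "H")) {
    ids <- keep_ind[gs$breed[keep_ind] == b]
    if (length(ids) < 2L) next
    sub <- dos[ids, , drop = FALSE]
    pv <- hwe_chisq_p(sub)
    fail_hwe <- fail_hwe | (!is.na(pv) & pv < hwe_p_min)
  }
  fail_hwe <- fail_hwe & !fail_cr & !fail_maf

  drop_snp <- fail_cr | fail_maf | fail_hwe
  if (all(drop_snp)) stop("all markers removed by QC; review thresholds")
  keep_mk <- colnames(dos)[!drop_snp]

  sub_idx <- function(m) if (is.null(m)) NULL else m[keep_ind, keep_mk, drop = FALSE]
  out <- genotype_set(dos[, keep_mk, drop = FALSE],
                      gs$map[!drop_snp, , drop = FALSE],
                      gs$breed[keep_ind],
                      hap1 = sub_idx(gs$hap1), hap2 = sub_idx(gs$hap2))
  report <- structure(list(
    removed_individuals = drop_ind,
    removed_markers = colnames(dos)[drop_snp],
    tally = tibble::tibble(
      rule = c("ind_callrate", "snp_callrate", "maf", "hwe"),
      removed = c(length(drop_ind), sum(fail_cr), sum(fail_maf), sum(fail_hwe))),
    thresholds = c(ind_callrate = ind_callrate, snp_callrate = snp_callrate,
                   maf_min = maf_min, hwe_p_min = hwe_p_min)),
    class = "cb_qc_report")
  list(genotypes = out, report = report)
}

# 1-df chi-square HWE test per marker (no continuity correction),
# columns of a dosage matrix.
hwe_chisq_p <- function(dos) {
  nAA <- colSums(dos == 2, na.rm = TRUE)
  nAa <- colSums(dos == 1, na.rm = TRUE)
  naa <- colSums(dos == 0, na.rm = TRUE)
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAa <- 2 * n * p * q; eaa <- n * q^2
  stat <- (nAA - eAA)^2 / eAA + (nAa - eAa)^2 / eAa + (naa - eaa)^2 / eaa
  pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pv[n == 0 | p == 0 | q == 0] <- NA_real_
  pv
}

#' @export
print.cb_qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat("  individuals removed:", length(x$removed_individuals), "\n")
  cat("  markers removed:", length(x$removed_markers), "\n")
  print(as.data.frame(x$tally), row.names = FALSE)
  invisible(x)
}

#' @rdname qc_filter
#' @param x A `cb_qc_report`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.cb_qc_report <- function(x, ...) x$tally

#' Read a two-column breed label file
#'
#' `id<TAB>breed`, no header required (a header line `id` is skipped).
#'
#' @param path File path.
#' @return Named character vector of breed labels.
#' @export
read_breeds <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (identical(tolower(df[1, 1]), "id")) df <- df[-1, , drop = FALSE]
  stats::setNames(df[[2]], df[[1]])
}
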