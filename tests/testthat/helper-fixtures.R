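# shared fixtures and independent oracles, built in code at test time

trio_ped <- function() {
  as_pedigree(data.frame(id = c("s1", "d1", "x1"),
                         sire = c(NA, NA, "s1"),
                         dam = c(NA, NA, "d1"),
                         breed = c("B", "H", "BH")))
}

# recursive-kinship oracle for the numerator relationship matrix,
# independent of the tabular construction used by build_A()
kinship_oracle <- function(ped) {
  id <- ped$id
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  memo <- new.env()
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      a <- max(i, j); b <- min(i, j)  # a is the later-born (sorted pedigree)
      0.5 * (phi(si[a], b) + phi(di[a], b))
    }
    memo[[key]] <- val
    val
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# random valid pedigree with n animals (parents always earlier)
random_ped <- function(n, p_known = 0.7, two_breeds = FALSE) {
  id <- sprintf("a%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  breed <- rep("B", n)
  if (two_breeds) breed <- sample(c("B", "H"), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_known) {
      cand <- seq_len(i - 1L)
      if (two_breeds) cand <- cand[breed[cand] == breed[i]]
      if (length(cand) >= 2) {
        pick <- sample(cand, 2)
        sire[i] <- id[pick[1]]; dam[i] <- id[pick[2]]
      }
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, breed = breed))
}

# small genotype set built by hand
toy_genotypes <- function(dosage, chr = NULL, breed = NULL,
                          hap1 = NULL, hap2 = NULL) {
  m <- ncol(dosage)
  if (is.null(chr)) chr <- rep("1", m)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("m%03d", seq_len(m))
  }
  map <- tibble::tibble(marker = colnames(dosage), chr = chr,
                        pos = as.integer(stats::ave(seq_len(m), chr,
                                                    FUN = seq_along) * 100L))
  if (is.null(breed)) {
    breed <- stats::setNames(rep("B", nrow(dosage)), rownames(dosage))
  }
  genotype_set(dosage, map, breed, hap1 = hap1, hap2 = hap2)
}

# one small simulated dataset shared across test files (built lazily once)
.sim_env <- new.env()
small_sim <- function() {
  if (is.null(.sim_env$sim)) {
    cfg <- sim_config(seed = 31L, n_chromosomes = 3L, markers_per_chr = 120L,
                      n_sires_B = 8L, n_dams_H = 90L, progeny_per_sire = 12,
                      purebred_generations = 2L, n_founders_B = 24L,
                      n_founders_H = 50L, n_pens = 3L, n_hys = 3L,
                      prop_genotyped_sires = 0.75, prop_genotyped_dams = 0.3)
    sim <- simulate_crossbred_data(cfg)
    sim$gs <- qc_filter(sim$genotypes)$genotypes
    .sim_env$sim <- sim
  }
  .sim_env$sim
}

# phenotype table for a plain single-trait design over given animals
one_trait_phenos <- function(ids, y) {
  data.frame(id = ids, mu = "c", y1 = y, y2 = NA_real_)
}

write_tmp_ped <- function(df, sep = ",") {
  f <- tempfile(fileext = ".csv")
  utils::write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

write_tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
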