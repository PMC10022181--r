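#' Configuration for the two-way crossbred simulator
#'
#' Defaults emulate the structure of a dairy x beef two-way crossbreeding
#' scheme: two purebred populations with allele-frequency divergence
#' `fst`, a sire breed (`B`) contributing ~38 progeny per sire to F1
#' crossbreds out of dam-breed (`H`) females, two low-heritability traits
#' with a moderate negative genetic correlation, breed-origin-specific
#' marker effects with correlation `breed_corr` between origins, and
#' partial genotyping of the parent generations (all crossbreds genotyped).
#'
#' @param seed Integer seed driving all random draws; every derived stream
#'   uses fixed offsets from it.
#' @param n_chromosomes,markers_per_chr Genome layout; one chromosome is
#'   one Morgan.
#' @param fst Allele-frequency divergence between the breeds.
#' @param n_sires_B Sires of the crossbred generation.
#' @param n_dams_H Dams available for crossbred matings.
#' @param progeny_per_sire Mean paternal half-sib family size (Poisson).
#' @param purebred_generations Random-mating generations behind the parents.
#' @param n_founders_B,n_founders_H Per-generation sizes of the purebred
#'   breeding populations.
#' @param h2 Length-2 heritabilities of the crossbred traits.
#' @param rg Genetic correlation between the traits.
#' @param res_corr Residual correlation between the traits.
#' @param breed_corr Correlation between B-origin and H-origin marker
#'   effects (purebred-crossbred genetic correlation < 1 when below 1).
#' @param prop_genotyped_sires,prop_genotyped_dams Genotyped fractions of
#'   the crossbreds' sires and dams.
#' @param prop_fcr_missing Fraction of crossbreds missing the second trait.
#' @param n_pens,n_hys Fixed-effect level counts (sex always has 2).
#' @param birth_window Character length-2, first and last birth dates.
#' @return A list of class `cb_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L, markers_per_chr = 500L,
                       fst = 0.15,
                       n_sires_B = 50L, n_dams_H = 2000L,
                       progeny_per_sire = 38,
                       purebred_generations = 3L,
                       n_founders_B = 100L, n_founders_H = 400L,
                       h2 = c(0.08, 0.08), rg = -0.5, res_corr = -0.3,
                       breed_corr = 0.7,
                       prop_genotyped_sires = 0.7,
                       prop_genotyped_dams = 0.13,
                       prop_fcr_missing = 0.11,
                       n_pens = 10L, n_hys = 8L,
                       birth_window = c("2019-06-01", "2021-12-01")) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$h2 > 0 & cfg$h2 < 1), abs(cfg$rg) <= 1,
            cfg$fst > 0, cfg$fst < 1,
            cfg$n_sires_B >= 1, cfg$n_dams_H >= 1,
            cfg$seed < 2^31)
  class(cfg) <- "cb_sim_config"
  cfg
}

#' Simulate diverged base-breed allele frequencies
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each breed's
#' frequency is Beta-distributed around the ancestral value with variance
#' `fst * p (1 - p)`, then clamped to [0.05, 0.95] so the default panel
#' stays segregating.
#'
#' @param cfg A [sim_config()].
#' @return A list `map` (marker map tibble), `p_anc`, `p_B`, `p_H`.
#' @export
simulate_base_breeds <- function(cfg) {
  set.seed(cfg$seed)
  m <- cfg$n_chromosomes * cfg$markers_per_chr
  map <- tibble::tibble(
    marker = sprintf("snp%05d", seq_len(m)),
    chr = as.character(rep(seq_len(cfg$n_chromosomes),
                           each = cfg$markers_per_chr)),
    pos = rep(seq_len(cfg$markers_per_chr) * 1000L, cfg$n_chromosomes))
  p_anc <- stats::runif(m, 0.05, 0.95)
  draw <- function() {
    if (cfg$fst < 1e-6) return(p_anc)
    shape_sum <- 1 / cfg$fst - 1
    p <- stats::rbeta(m, p_anc * shape_sum, (1 - p_anc) * shape_sum)
    pmin(pmax(p, 0.05), 0.95)
  }
  list(map = map, p_anc = p_anc, p_B = draw(), p_H = draw())
}

# one gamete from a parent's two haplotypes: Poisson(1) crossovers per
# chromosome (one Morgan), uniform positions, no interference
meiose <- function(h1, h2, chr_index) {
  out <- integer(length(h1))
  for (ci in chr_index) {
    m <- length(ci)
    k <- stats::rpois(1L, 1)
    cur <- sample(1:2, 1L)
    if (k == 0L) {
      out[ci] <- if (cur == 1L) h1[ci] else h2[ci]
    } else {
      bp <- sort(sample.int(m - 1L, size = min(k, m - 1L)))
      seg_start <- c(1L, bp + 1L)
      seg_end <- c(bp, m)
      for (s in seq_along(seg_start)) {
        idx <- ci[seg_start[s]:seg_end[s]]
        out[idx] <- if (cur == 1L) h1[idx] else h2[idx]
        cur <- 3L - cur
      }
    }
  }
  out
}

#' Simulate the two-way crossbred population
#'
#' Gene-drops phased haplotypes through `purebred_generations` of random
#' mating within each breed, then crosses the final-generation sire-breed
#' males with dam-breed females to produce F1 crossbreds (paternal
#' haplotype of breed B, maternal of breed H, recombined within breed).
#' Genotyping status: all crossbreds, plus the configured fractions of
#' their sires and dams.
#'
#' @param cfg A [sim_config()].
#' @param base Output of [simulate_base_breeds()]; generated when `NULL`.
#' @return A list of class `cb_sim_pop`: `ped` (a `cb_pedigree`),
#'   `genotypes` (a phased [genotype_set()] of the genotyped animals),
#'   `hap1`, `hap2` (all animals, for truth computations), `truth_boa`
#'   (true breed of origin per crossbred chromosome haplotype), `base`,
#'   and id bookkeeping (`crossbreds`, `sires`, `dams`, `genotyped`).
#' @export
simulate_population <- function(cfg, base = NULL) {
  if (is.null(base)) base <- simulate_base_breeds(cfg)
  set.seed(cfg$seed + 1L)
  map <- base$map
  m <- nrow(map)
  chr_index <- split(seq_len(m), map$chr)[unique(map$chr)]

  ids <- character(0); sire <- character(0); dam <- character(0)
  breed <- character(0); sex <- character(0)
  H1 <- NULL; H2 <- NULL
  add <- function(id, s, d, b, sx, h1, h2) {
    ids <<- c(ids, id); sire <<- c(sire, s); dam <<- c(dam, d)
    breed <<- c(breed, b); sex <<- c(sex, sx)
    H1 <<- rbind(H1, h1); H2 <<- rbind(H2, h2)
  }

  grow_breed <- function(b, p, n_gen_size, n_final, final_sex_needed) {
    prefix <- b
    # founders
    n0 <- n_gen_size
    founders <- sprintf("%s_G0_%03d", prefix, seq_len(n0))
    sx <- rep(c("M", "F"), length.out = n0)
    for (i in seq_len(n0)) {
      add(founders[i], NA, NA, b, sx[i],
          stats::rbinom(m, 1L, p), stats::rbinom(m, 1L, p))
    }
    prev <- founders; prev_sex <- sx
    for (g in seq_len(cfg$purebred_generations)) {
      last <- g == cfg$purebred_generations
      n_g <- if (last) n_final else n_gen_size
      cur <- sprintf("%s_G%d_%04d", prefix, g, seq_len(n_g))
      cur_sex <- if (last) rep(final_sex_needed, n_g)
                 else rep(c("M", "F"), length.out = n_g)
      males <- prev[prev_sex == "M"]; females <- prev[prev_sex == "F"]
      for (i in seq_len(n_g)) {
        s <- sample(males, 1L); d <- sample(females, 1L)
        si <- match(s, ids); di <- match(d, ids)
        add(cur[i], s, d, b, cur_sex[i],
            meiose(H1[si, ], H2[si, ], chr_index),
            meiose(H1[di, ], H2[di, ], chr_index))
      }
      prev <- cur; prev_sex <- cur_sex
    }
    prev
  }

  sires <- grow_breed("B", base$p_B, cfg$n_founders_B, cfg$n_sires_B, "M")
  dams <- grow_breed("H", base$p_H, cfg$n_founders_H, cfg$n_dams_H, "F")

  # F1 crossbreds: Poisson family sizes, dams drawn with minimal reuse
  fam <- stats::rpois(length(sires), cfg$progeny_per_sire)
  fam[fam == 0L] <- 1L
  n_x <- sum(fam)
  dam_draw <- if (n_x <= length(dams)) sample(dams, n_x)
              else sample(dams, n_x, replace = TRUE)
  xid <- sprintf("X_%05d", seq_len(n_x))
  k <- 0L
  for (si_i in seq_along(sires)) {
    s <- sires[si_i]
    smi <- match(s, ids)
    for (j in seq_len(fam[si_i])) {
      k <- k + 1L
      d <- dam_draw[k]
      dmi <- match(d, ids)
      add(xid[k], s, d, "BH", sample(c("M", "F"), 1L),
          meiose(H1[smi, ], H2[smi, ], chr_index),   # paternal = B origin
          meiose(H1[dmi, ], H2[dmi, ], chr_index))   # maternal = H origin
    }
  }
  rownames(H1) <- rownames(H2) <- ids
  colnames(H1) <- colnames(H2) <- map$marker

  ped <- as_pedigree(data.frame(id = ids, sire = sire, dam = dam,
                                breed = breed))
  gen_sires <- sample(sires, round(cfg$prop_genotyped_sires * length(sires)))
  gen_dams_pool <- unique(dam_draw)
  gen_dams <- sample(gen_dams_pool,
                     round(cfg$prop_genotyped_dams * length(gen_dams_pool)))
  genotyped <- c(gen_sires, gen_dams, xid)

  gs <- genotype_set(
    dosage = (H1 + H2)[genotyped, , drop = FALSE],
    map = map,
    breed = stats::setNames(breed, ids)[genotyped],
    hap1 = H1[genotyped, , drop = FALSE],
    hap2 = H2[genotyped, , drop = FALSE])

  truth_boa <- tidyr::expand_grid(id = xid, chr = unique(map$chr), hap = 1:2)
  truth_boa$breed <- ifelse(truth_boa$hap == 1L, "B", "H")

  structure(list(ped = ped, genotypes = gs, hap1 = H1, hap2 = H2,
                 truth_boa = truth_boa, base = base,
                 sex = stats::setNames(sex, ids),
                 crossbreds = xid, sires = sires, dams = dams,
                 genotyped = genotyped, cfg = cfg),
            class = "cb_sim_pop")
}

#' Simulate phenotypes on the crossbred cohort
#'
#' Marker substitution effects are drawn per breed of origin and trait from
#' a normal with correlation `breed_corr` across origins and `rg` across
#' traits; each animal's true breeding value sums the origin-matched
#' effects over its two haplotypes, so the crossbred TBV decomposes exactly
#' into B-origin and H-origin parts. Residual variances are solved from the
#' realized TBV variance among crossbreds so the target heritabilities hold
#' in expectation; sex, pen and herd-year-season effects and a start-weight
#' covariate are added, and the second trait is set missing for a random
#' fraction.
#'
#' @param cfg A [sim_config()].
#' @param pop A `cb_sim_pop` from [simulate_population()].
#' @param traits Names of the two traits (default `c("adg", "fcr")`).
#' @return A list: `phenos` (tibble: `id`, `sex`, `pen`, `hys`,
#'   `start_weight`, `birth_date`, the two traits), `truth` (tibble of TBV
#'   per animal per trait with B/H origin parts), `params` (effect sizes
#'   and realized variance components).
#' @export
simulate_phenotypes <- function(cfg, pop, traits = c("adg", "fcr")) {
  set.seed(cfg$seed + 2L)
  m <- ncol(pop$hap1)
  To <- matrix(c(1, cfg$breed_corr, cfg$breed_corr, 1), 2)
  Tt <- matrix(c(1, cfg$rg, cfg$rg, 1), 2)
  Sig <- kronecker(Tt, To)          # order: (t1 B, t1 H, t2 B, t2 H)
  # symmetric square root: tolerant of the rank-deficient boundary cases
  # breed_corr = 1 and |rg| = 1
  es <- eigen(Sig, symmetric = TRUE)
  Shalf <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  eff <- matrix(stats::rnorm(m * 4L), m, 4L) %*% Shalf / sqrt(m)
  alpha <- list(
    B = eff[, c(1, 3)],             # markers x traits, B-origin effects
    H = eff[, c(2, 4)])

  ids <- rownames(pop$hap1)
  breed <- stats::setNames(pop$ped$breed[match(ids, pop$ped$id)], ids)
  xb <- pop$crossbreds
  tbv_part <- function(hap, origin) hap %*% alpha[[origin]]
  tbv_B <- matrix(0, length(ids), 2, dimnames = list(ids, traits))
  tbv_H <- tbv_B
  pure_b <- ids[breed == "B"]; pure_h <- ids[breed == "H"]
  tbv_B[pure_b, ] <- tbv_part(pop$hap1[pure_b, , drop = FALSE] +
                              pop$hap2[pure_b, , drop = FALSE], "B")
  tbv_H[pure_h, ] <- tbv_part(pop$hap1[pure_h, , drop = FALSE] +
                              pop$hap2[pure_h, , drop = FALSE], "H")
  tbv_B[xb, ] <- tbv_part(pop$hap1[xb, , drop = FALSE], "B")   # paternal
  tbv_H[xb, ] <- tbv_part(pop$hap2[xb, , drop = FALSE], "H")   # maternal
  tbv <- tbv_B + tbv_H

  Vg <- apply(tbv[xb, , drop = FALSE], 2, stats::var)
  Ve <- Vg * (1 - cfg$h2) / cfg$h2
  Re <- diag(sqrt(Ve)) %*% matrix(c(1, cfg$res_corr, cfg$res_corr, 1), 2) %*%
    diag(sqrt(Ve))
  resid <- matrix(stats::rnorm(length(xb) * 2L), ncol = 2L) %*% chol(Re)

  Vp <- Vg + Ve
  n_x <- length(xb)
  sex <- pop$sex[xb]
  pen <- sample(sprintf("pen%02d", seq_len(cfg$n_pens)), n_x, replace = TRUE)
  window <- as.Date(cfg$birth_window)
  birth <- window[1] + sort(sample.int(as.integer(diff(window)) + 1L, n_x,
                                       replace = TRUE)) - 1L
  hys <- sprintf("hys%02d", as.integer(cut(as.integer(birth), cfg$n_hys)))
  start_weight <- stats::rnorm(n_x, 230, 25)

  eff_sex <- stats::setNames(stats::rnorm(2L, 0, 0.5), c("M", "F"))
  eff_pen <- stats::setNames(stats::rnorm(cfg$n_pens, 0, 0.3),
                             sprintf("pen%02d", seq_len(cfg$n_pens)))
  eff_hys <- stats::setNames(stats::rnorm(cfg$n_hys, 0, 0.3),
                             sprintf("hys%02d", seq_len(cfg$n_hys)))
  slope <- 0.3 * sqrt(Vp) / 25

  # fixed effects: shared level effects scaled by each trait's phenotypic SD
  y <- matrix(NA_real_, n_x, 2, dimnames = list(xb, traits))
  for (t in 1:2) {
    y[, t] <- tbv[xb, t] + resid[, t] +
      (eff_sex[sex] + eff_pen[pen] + eff_hys[hys]) * sqrt(Vp[t]) +
      slope[t] * (start_weight - 230)
  }
  miss <- sample(n_x, round(cfg$prop_fcr_missing * n_x))
  y[miss, 2] <- NA_real_

  phenos <- tibble::tibble(
    id = xb, sex = unname(sex), pen = pen, hys = hys,
    start_weight = start_weight, birth_date = birth)
  phenos[[traits[1]]] <- unname(y[, 1])
  phenos[[traits[2]]] <- unname(y[, 2])

  truth <- tibble::tibble(
    id = rep(ids, 2L),
    trait = rep(traits, each = length(ids)),
    tbv = c(tbv[, 1], tbv[, 2]),
    tbv_B = c(tbv_B[, 1], tbv_B[, 2]),
    tbv_H = c(tbv_H[, 1], tbv_H[, 2]))

  fixed_part <- (eff_sex[sex] + eff_pen[pen] + eff_hys[hys]) %o% sqrt(Vp) +
    outer(start_weight - 230, slope)
  list(phenos = phenos, truth = truth,
       params = list(Vg = Vg, Ve = Ve, Re = Re, h2 = cfg$h2, rg = cfg$rg,
                     alpha = alpha, fixed_part = fixed_part,
                     eff_sex = eff_sex, eff_pen = eff_pen, eff_hys = eff_hys,
                     slope = slope))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete crossbred dataset
#'
#' Convenience wrapper: base breeds, population, phenotypes.
#'
#' @param cfg A [sim_config()].
#' @return A list `ped`, `genotypes`, `phenos`, `truth` (TBV table),
#'   `truth_boa`, `pop` (the full population object).
#' @export
simulate_crossbred_data <- function(cfg = sim_config()) {
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes(cfg, pop)
  list(ped = pop$ped, genotypes = pop$genotypes, phenos = ph$phenos,
       truth = ph$truth, truth_boa = pop$truth_boa, params = ph$params,
       pop = pop)
}

#' Write a simulated dataset to standard file formats
#'
#' Emits a phased VCF (GT with `|` separators) for the genotyped animals,
#' the pedigree as CSV, breed labels as TSV, the phenotype table as CSV and
#' the truth tables as TSV, all consumable by the package's readers.
#'
#' @param sim Output of [simulate_crossbred_data()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             ped = file.path(dir, "pedigree.csv"),
             breeds = file.path(dir, "breeds.tsv"),
             phenos = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth_tbv.tsv"),
             truth_boa = file.path(dir, "truth_boa.tsv"))

  gs <- sim$genotypes
  con <- file(paths["vcf"], "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=crossblup-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gs$dosage)),
                     collapse = "\t")), con)
  gt <- matrix(paste0(t(gs$hap1), "|", t(gs$hap2)),
               nrow = ncol(gs$dosage))
  body <- paste(gs$map$chr, gs$map$pos, gs$map$marker, "A", "G", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  close(con)

  ped_df <- as.data.frame(sim$ped)
  ped_df$sire[is.na(ped_df$sire)] <- "0"
  ped_df$dam[is.na(ped_df$dam)] <- "0"
  utils::write.csv(ped_df, paths["ped"], row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(id = rownames(gs$dosage),
                                breed = unname(gs$breed)),
                     paths["breeds"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(as.data.frame(sim$phenos), paths["phenos"],
                   row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(sim$truth), paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$truth_boa), paths["truth_boa"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
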