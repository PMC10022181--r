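test_that("single-record BLUP with identity relationships shrinks residuals", {
  set.seed(21)
  n <- 30L
  ids <- sprintf("i%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  su <- 2; se <- 6
  y <- rnorm(n, 5, sqrt(su + se))
  spec <- model_spec(c("y1", "y2"), ~ 1, list(u = K), method = "ss")
  vc <- varcomp(list(u = diag(c(su, 1))), diag(c(se, 1)),
                traits = c("y1", "y2"))
  fit <- build_and_solve(spec, one_trait_phenos(ids, y), vc)
  ebv <- fit$ebv$ebv[fit$ebv$trait == "y1"][match(ids, fit$ebv$id[fit$ebv$trait == "y1"])]
  b0 <- fit$fixed$estimate[1]
  lambda <- su / (su + se)
  expect_equal(ebv, lambda * (y - b0), tolerance = 1e-8)

  # zero genetic variance: all EBV are zero
  vc0 <- varcomp(list(u = matrix(0, 2, 2)), diag(c(se, 1)),
                 traits = c("y1", "y2"))
  fit0 <- build_and_solve(spec, one_trait_phenos(ids, y), vc0)
  expect_true(all(fit0$ebv$ebv == 0))

  # exactly duplicated phenotype rows are merged, not double-counted
  ph <- one_trait_phenos(ids, y)
  fit2 <- build_and_solve(spec, rbind(ph, ph[1:5, ]), vc)
  expect_equal(fit2$ebv, fit$ebv)
})

test_that("with everyone genotyped, single-step solutions equal GBLUP", {
  sim <- small_sim()
  ids <- phased_ids(sim$gs)[1:40]
  # founder-style pedigree: parents treated as unknown
  ped <- as_pedigree(data.frame(id = ids, sire = NA, dam = NA,
                                breed = sim$ped$breed[match(ids, sim$ped$id)]))
  A <- build_A(ped)
  G <- build_G(sim$gs, ids = ids)
  Gb <- bend_psd(blend(adjust_G(G, A), A, 0.05))
  H <- build_H(A, Gb, ids)
  expect_equal(H, Gb[rownames(H), colnames(H)], ignore_attr = TRUE)

  set.seed(2)
  y <- rnorm(length(ids))
  spec_h <- model_spec(c("y1", "y2"), ~ 1, list(u = H), method = "ss")
  spec_g <- model_spec(c("y1", "y2"), ~ 1,
                       list(u = Gb[rownames(H), colnames(H)]), method = "ss")
  vc <- varcomp(list(u = diag(c(1, 1))), diag(c(3, 3)),
                traits = c("y1", "y2"))
  ph <- one_trait_phenos(ids, y)
  expect_equal(build_and_solve(spec_h, ph, vc)$ebv,
               build_and_solve(spec_g, ph, vc)$ebv, tolerance = 1e-8)
})

test_that("REML matches the balanced half-sib ANOVA estimator", {
  set.seed(7)
  ns <- 40L; np <- 20L; su <- 3; se <- 7
  sire_eff <- rnorm(ns, 0, sqrt(su / 4))
  prog <- sprintf("p%04d", 1:(ns * np))
  sire <- rep(sprintf("s%02d", 1:ns), each = np)
  ped <- as_pedigree(data.frame(id = c(sprintf("s%02d", 1:ns), prog),
                                sire = c(rep(NA, ns), sire),
                                dam = NA, breed = "B"))
  A <- build_A(ped)
  y <- rep(sire_eff, each = np) + rnorm(ns * np, 0, sqrt(se + 0.75 * su))
  spec <- model_spec(c("y1", "y2"), ~ 1, list(u = A), method = "ss")
  vc <- reml(spec, one_trait_phenos(prog, y), tol = 1e-8)
  th <- tidy(vc)

  ybar <- tapply(y, sire, mean)
  MSB <- np * sum((ybar - mean(y))^2) / (ns - 1)
  MSW <- sum((y - ybar[sire])^2) / (ns * (np - 1))
  su_hat <- 4 * (MSB - MSW) / np
  se_hat <- MSW - 0.75 * su_hat
  expect_equal(th$estimate[th$term == "u" & th$parameter == "var1"], su_hat,
               tolerance = 1e-6)
  expect_equal(th$estimate[th$term == "e" & th$parameter == "var1"], se_hat,
               tolerance = 1e-6)

  # asymptotic SEs exist for the identified parameters
  expect_true(all(is.finite(th$se[th$parameter == "var1"])))
})

test_that("REML drives the genetic variance to the boundary without signal", {
  set.seed(8)
  n <- 120L
  ids <- sprintf("i%03d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  y <- rnorm(n)  # no genetic structure and K = I: variance not separable,
                 # but a half-sib K with no signal must hit the boundary
  ped <- as_pedigree(data.frame(
    id = c(sprintf("s%02d", 1:10), ids),
    sire = c(rep(NA, 10), rep(sprintf("s%02d", 1:10), each = 12)),
    dam = NA, breed = "B"))
  A <- build_A(ped)
  spec <- model_spec(c("y1", "y2"), ~ 1, list(u = A), method = "ss")
  vc <- reml(spec, one_trait_phenos(ids, y), tol = 1e-7, on_nonconv = "warn")
  expect_lt(vc$G$u[1, 1], 0.05)
})

test_that("EM iterations never decrease the restricted likelihood", {
  set.seed(9)
  ns <- 15L; np <- 8L
  prog <- sprintf("p%03d", 1:(ns * np))
  ped <- as_pedigree(data.frame(
    id = c(sprintf("s%02d", 1:ns), prog),
    sire = c(rep(NA, ns), rep(sprintf("s%02d", 1:ns), each = np)),
    dam = NA, breed = "B"))
  A <- build_A(ped)
  y <- rnorm(ns * np) + rep(rnorm(ns, 0, 0.7), each = np)
  spec <- model_spec(c("y1", "y2"), ~ 1, list(u = A), method = "ss")
  vc <- reml(spec, one_trait_phenos(prog, y), method = "em", tol = 1e-4,
             max_iter = 80, on_nonconv = "warn")
  expect_true(all(diff(vc$details$trajectory) > -1e-8))
})

test_that("non-convergence raises an error carrying the trajectory", {
  set.seed(10)
  ids <- sprintf("i%02d", 1:40)
  ped <- as_pedigree(data.frame(
    id = c("s1", "s2", ids),
    sire = c(NA, NA, rep(c("s1", "s2"), each = 20)),
    dam = NA, breed = "B"))
  A <- build_A(ped)
  spec <- model_spec(c("y1", "y2"), ~ 1, list(u = A), method = "ss")
  err <- tryCatch(
    reml(spec, one_trait_phenos(ids, rnorm(40)), method = "em",
         tol = 1e-12, max_iter = 3L),
    cb_reml_nonconvergence = function(e) e)
  expect_s3_class(err, "cb_reml_nonconvergence")
  expect_true(length(err$trajectory) >= 2)
})

test_that("derived parameters reproduce the two-trait arithmetic", {
  mk_vc <- function(su1, se1, su2 = 1, se2 = 1, cov_u = 0) {
    varcomp(list(u = matrix(c(su1, cov_u, cov_u, su2), 2)),
            matrix(c(se1, 0, 0, se2), 2), traits = c("adg", "fcr"))
  }
  # single-term heritabilities
  dp <- derived_parameters(mk_vc(0.008, 0.090, 0.189, 2.191), "ss")
  expect_equal(round(dp$estimate[1], 3), 0.082)
  expect_equal(round(dp$estimate[2], 3), 0.079)

  # equal components with zero covariances: rg = 0
  dp0 <- derived_parameters(mk_vc(1, 1, 1, 1, 0), "ss")
  expect_equal(dp0$estimate[3], 0)

  # breed-specific aggregate, hand-checked rg
  vc_bs <- varcomp(list(uB = matrix(c(0.4, 0.1, 0.1, 0.6), 2),
                        uH = matrix(c(0.2, 0.3, 0.3, 0.8), 2)),
                   diag(c(1, 1)), traits = c("adg", "fcr"))
  dp_bs <- derived_parameters(vc_bs, "bs")
  g1 <- 0.5 * (0.4 + 0.2); g2 <- 0.5 * (0.6 + 0.8)
  expect_equal(dp_bs$estimate[1], g1 / (g1 + 1))
  expect_equal(dp_bs$estimate[3], 0.5 * (0.1 + 0.3) / sqrt(g1 * g2))
})

test_that("metafounder variance rescaling preserves genetic correlations", {
  g <- gamma_matrix(0.702, 0.570, 0.672)
  vc <- varcomp(list(u = matrix(c(0.010, -0.02, -0.02, 0.27), 2)),
                diag(c(0.085, 2.2)), traits = c("adg", "fcr"),
                asymp_cov = diag(6))
  sc <- scale_mf_varcomp(vc, g)
  k <- mf_scale_factor(g)
  expect_equal(sc$G$u, k * vc$G$u)
  expect_equal(sc$R, vc$R)
  rg <- function(v) v$G$u[1, 2] / sqrt(v$G$u[1, 1] * v$G$u[2, 2])
  expect_equal(rg(sc), rg(vc))
  # Gamma = 0: no change
  expect_equal(scale_mf_varcomp(vc, gamma_matrix(0, 0, 0))$G$u, vc$G$u)
  # asymptotic covariance scales by k^2 on the genetic block
  expect_equal(diag(sc$asymp_cov)[1:3], rep(k^2, 3))
  expect_equal(diag(sc$asymp_cov)[4:6], rep(1, 3))
})

test_that("reliabilities hit the stated fixed points", {
  # synthetic fit with controlled PEV
  ids <- c("a", "b")
  H <- diag(2) * 1.2; dimnames(H) <- list(ids, ids)
  su <- matrix(c(0.5, 0, 0, 0.5), 2)
  index <- tidyr::expand_grid(term = "u", trait = c("t1", "t2"), id = ids)
  index$pos <- seq_len(nrow(index))
  # PEV = 0 for 'a', PEV = H_ii * su for 'b' (no information)
  pev_diag <- c(0, 1.2 * 0.5, 0, 1.2 * 0.5)
  fit <- structure(list(
    spec = list(traits = c("t1", "t2"), terms = list(u = H), method = "ss"),
    animals = ids,
    pev = list(C_uu = diag(pev_diag), index = index)), class = "cb_fit")
  bundle <- structure(list(method = "ss", H = H), class = "cb_hbundle")
  vc <- varcomp(list(u = su), diag(2), traits = c("t1", "t2"))
  rel <- reliability(fit, bundle, vc, ids = ids)
  expect_equal(rel$reliability[rel$id == "a"], c(1, 1))
  expect_equal(rel$reliability[rel$id == "b"], c(0, 0))
})

test_that("metafounder contrast reliabilities match a dense-inverse oracle", {
  # small system solved end to end, then the printed contrast evaluated
  # directly from an independently assembled inverse
  sim <- small_sim()
  keep <- c(sim$pop$sires[1:3],
            sim$pop$crossbreds[1:12])
  ped <- as_pedigree(as.data.frame(sim$ped)[sim$ped$id %in% keep, ] |>
    transform(sire = ifelse(sire %in% keep, sire, NA),
              dam = ifelse(dam %in% keep, dam, NA)))
  g <- gamma_matrix(0.6, 0.3, 0.5)
  Ag <- build_A_gamma(ped, g, keep_metafounders = TRUE)
  spec <- model_spec(c("y1", "y2"), ~ 1, list(u = Ag), method = "mf")
  set.seed(33)
  ph <- one_trait_phenos(sim$pop$crossbreds[1:12], rnorm(12))
  su <- matrix(c(0.5, 0.1, 0.1, 0.4), 2); se <- diag(c(1, 1))
  vc <- varcomp(list(u = su), se, traits = c("y1", "y2"))
  fit <- build_and_solve(spec, ph, vc, pev = "full")
  bundle <- structure(list(method = "mf", H = Ag, gamma = g),
                      class = "cb_hbundle")
  rel <- reliability(fit, bundle, vc, ids = keep)

  # oracle: rebuild the coefficient matrix from first principles
  obs_ids <- ph$id
  n <- nrow(Ag)
  X <- matrix(0, 12, 2); X[, 1] <- 1  # intercept for trait 1 only block
  Z <- matrix(0, 12, 2 * n)
  Z[cbind(1:12, match(obs_ids, rownames(Ag)))] <- 1
  Rin <- diag(1 / se[1, 1], 12)
  Xb <- matrix(1, 12, 1)
  C <- rbind(
    cbind(crossprod(Xb, Rin %*% Xb), crossprod(Xb, Rin %*% Z)),
    cbind(crossprod(Z, Rin %*% Xb),
          crossprod(Z, Rin %*% Z) + kronecker(solve(su), solve(Ag))))
  Ci <- solve(C)
  Cuu <- Ci[-1, -1]
  i <- keep[5]; t <- 1
  pos_of <- function(id) (t - 1L) * n + match(id, rownames(Ag))
  for (mf in c("MF_B", "MF_H")) {
    num <- Cuu[pos_of(i), pos_of(i)] + Cuu[pos_of(mf), pos_of(mf)] -
      2 * Cuu[pos_of(i), pos_of(mf)]
    den <- (Ag[i, i] + Ag[mf, mf] - 2 * Ag[i, mf]) * su[t, t]
    want <- 1 - num / den
    got <- rel$reliability[rel$id == i & rel$trait == "y1" &
                             rel$measure == paste0("mf_", sub("MF_", "", mf))]
    expect_equal(got, max(min(want, 1), 0), tolerance = 1e-6)
  }
})

test_that("contrast reliabilities exceed naive metafounder reliabilities", {
  sim <- small_sim()
  bundle <- build_h_bundle("mf", sim$ped, sim$gs)
  spec <- model_spec(c("adg", "fcr"), ~ sex + pen + hys + start_weight,
                     list(u = bundle$H), method = "mf")
  vc <- reml(spec, sim$phenos, tol = 1e-6, on_nonconv = "warn")
  fit <- build_and_solve(spec, sim$phenos, vc, pev = "full")
  sires <- intersect(sim$pop$sires, rownames(bundle$H))
  rel <- reliability(fit, bundle, vc, ids = sires, ped = sim$ped)

  # naive definition 1 - PEV / (H_ii sigma2)
  idx <- fit$pev$index
  naive <- sapply(sires, function(i) {
    p <- idx$pos[idx$term == "u" & idx$trait == "adg" & idx$id == i]
    1 - diag(fit$pev$C_uu)[p] / (bundle$H[i, i] * vc$G$u[1, 1])
  })
  contrast <- rel$reliability[rel$trait == "adg" & rel$measure == "mf_B"]
  expect_true(mean(contrast) >= mean(pmax(pmin(naive, 1), 0)))
})

test_that("group summaries of reliabilities behave at the edges", {
  rel <- tibble::tibble(id = c("a", "b", "c"), trait = "t1", measure = "ss",
                        reliability = c(0.2, 0.4, 0.3))
  out <- summarize_reliability(rel, list(g1 = c("a", "b"), g2 = "c",
                                         empty = character(0)))
  expect_equal(out$mean_reliability[out$group == "g1"], 0.3)
  expect_equal(out$mean_reliability[out$group == "g2"], 0.3)
  expect_true(is.na(out$mean_reliability[out$group == "empty"]))
})

test_that("genotyping the sires raises their model-based reliability", {
  # paired design: the same cohort evaluated with and without the sires'
  # genotypes, everything else identical (an uncontrolled grouping of
  # genotyped vs non-genotyped sires would be confounded with family size
  # at this scale); metafounder relationships, true variance components
  cfg <- sim_config(seed = 31L, n_chromosomes = 3L, markers_per_chr = 400L,
                    n_sires_B = 10L, n_dams_H = 120L, progeny_per_sire = 12,
                    purebred_generations = 2L, n_founders_B = 30L,
                    n_founders_H = 60L, n_pens = 3L, n_hys = 3L,
                    prop_genotyped_sires = 1, prop_genotyped_dams = 0.3)
  sim <- simulate_crossbred_data(cfg)
  gs <- qc_filter(sim$genotypes)$genotypes
  sires <- intersect(sim$pop$sires, rownames(gs$dosage))
  keep <- setdiff(rownames(gs$dosage), sires)
  gs_no <- genotype_set(gs$dosage[keep, ], gs$map, gs$breed[keep],
                        hap1 = gs$hap1[keep, ], hap2 = gs$hap2[keep, ])
  Vg <- sim$params$Vg
  Su <- diag(sqrt(Vg)) %*% matrix(c(1, -0.5, -0.5, 1), 2) %*% diag(sqrt(Vg))
  vc <- varcomp(list(u = Su), sim$params$Re, traits = c("adg", "fcr"))
  gamma <- estimate_gamma(gs, sim$ped)
  mean_rel <- function(g) {
    b <- build_h_bundle("mf", sim$ped, g, gamma = gamma)
    spec <- model_spec(c("adg", "fcr"), ~ sex + pen + hys + start_weight,
                       list(u = b$H), method = "mf")
    fit <- build_and_solve(spec, sim$phenos, vc, pev = "full")
    rel <- suppressWarnings(reliability(fit, b, vc, ids = sires))
    sub <- rel[rel$measure == "mf_B", ]
    tapply(sub$reliability, sub$trait, mean)
  }
  with_g <- mean_rel(gs)
  without_g <- mean_rel(gs_no)
  expect_gte(with_g[["adg"]], without_g[["adg"]])
  expect_gte(with_g[["fcr"]], without_g[["fcr"]])
})
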