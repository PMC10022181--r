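test_that("VanRaden G matches closed forms and a naive double loop", {
  m <- 10L
  d_AA <- matrix(2, 1, m, dimnames = list("i1", sprintf("m%02d", 1:m)))
  gs <- toy_genotypes(d_AA)
  p <- rep(0.5, m)
  expect_equal(unname(build_G(gs, p)["i1", "i1"]), 2)

  d_het <- matrix(1, 1, m, dimnames = dimnames(d_AA))
  expect_equal(unname(build_G(toy_genotypes(d_het), p)["i1", "i1"]), 0)

  # duplicate rows give identical relationships
  d2 <- rbind(i1 = rbinom(m, 2, 0.4), i2 = 0)
  d2["i2", ] <- d2["i1", ]
  colnames(d2) <- sprintf("m%02d", 1:m)
  G2 <- build_G(toy_genotypes(d2), p = rep(0.4, m))
  expect_equal(G2["i1", "i2"], G2["i1", "i1"])

  # naive elementwise oracle on a random instance
  set.seed(9)
  d3 <- matrix(rbinom(10 * 20, 2, runif(20, 0.2, 0.8)), 10, 20, byrow = TRUE,
               dimnames = list(sprintf("i%02d", 1:10), sprintf("m%02d", 1:20)))
  gs3 <- toy_genotypes(d3)
  p3 <- allele_freq(gs3)
  G3 <- build_G(gs3, p3)
  oracle <- matrix(0, 10, 10)
  denom <- sum(2 * p3 * (1 - p3))
  for (i in 1:10) for (k in 1:10) {
    oracle[i, k] <- sum((d3[i, ] - 2 * p3) * (d3[k, ] - 2 * p3)) / denom
  }
  expect_equal(unname(G3), oracle, tolerance = 1e-12)
})

test_that("the 0.5-referenced G matches its closed forms", {
  m <- 8L
  nm <- list("i1", sprintf("m%02d", 1:m))
  expect_equal(unname(build_G_half(toy_genotypes(matrix(2, 1, m, dimnames = nm)))[1, 1]), 2)
  expect_equal(unname(build_G_half(toy_genotypes(matrix(1, 1, m, dimnames = nm)))[1, 1]), 0)
  opp <- rbind(i1 = rep(2, m), i2 = rep(0, m))
  colnames(opp) <- nm[[2]]
  expect_equal(unname(build_G_half(toy_genotypes(opp))["i1", "i2"]), -2)
})

test_that("breed-specific G blocks follow the printed centering", {
  # purebreds: 4 B individuals; crossbreds: 2 with Q rows
  m <- 6L
  M_B <- matrix(c(2, 0, 1, 1), 4, m, dimnames = list(sprintf("b%d", 1:4),
                                                     sprintf("m%d", 1:m)))
  # p_B = 0.5 at every marker
  Q <- rbind(x1 = rep(0.5, m), x2 = rep(1, m))
  Q["x1", ] <- c(1, 0, 1, 0, 1, 0)
  Q["x2", ] <- 0
  content <- structure(list(M_B = M_B, Q_B = Q, M_H = M_B[0, , drop = FALSE],
                            Q_H = 1 - Q), class = "cb_allele_content")
  G <- build_G_breed(content, "B")
  # purebred all-AA row with p = 0.5: diagonal 2
  expect_equal(unname(G["b1", "b1"]), sum((2 - 1)^2) / (2 * sum(0.25)))
  # crossbred whose Q row equals p exactly gets partial diagonal 0
  content2 <- content
  content2$Q_B["x1", ] <- 0.5
  expect_warning(G2 <- build_G_breed(content2, "B"), NA)
  expect_equal(unname(G2["x1", "x1"]), 0)

  # on simulated data, the two partial genomic matrices reproduce the
  # direct matrix products of the printed formulas
  sim <- small_sim()
  boa <- trace_all(sim$gs, sim$ped)
  ct <- build_allele_content(sim$gs, boa)
  GB <- suppressWarnings(build_G_breed(ct, "B"))
  pB <- colMeans(ct$M_B, na.rm = TRUE) / 2
  keep <- pB > 0 & pB < 1 & !is.na(pB)
  Zm <- sweep(ct$M_B[, keep], 2, 2 * pB[keep])
  Zq <- sweep(ct$Q_B[, keep], 2, pB[keep])
  den <- sum(2 * pB[keep] * (1 - pB[keep]))
  expect_equal(GB[rownames(Zm), rownames(Zq)],
               (Zm %*% t(Zq)) / den, tolerance = 1e-10)
  expect_equal(GB[rownames(Zq), rownames(Zq)],
               tcrossprod(Zq) / den, tolerance = 1e-10)
})

test_that("compatibility adjustment solves the two-moment system", {
  # already compatible: identity transformation
  set.seed(3)
  A22 <- build_A(random_ped(6))
  expect_equal(adjust_G(A22, A22), A22, ignore_attr = TRUE)

  # G = I, A_ref = 2 I over 2 ids: solve by hand
  G <- diag(2); dimnames(G) <- list(c("a", "b"), c("a", "b"))
  A2 <- 2 * G
  Ga <- adjust_G(G, A2)
  # mean(G*) = a + b/2 = 1 and mean(diag G*) = a + b = 2 -> b = 2, a = 0
  expect_equal(attr(Ga, "a"), 0)
  expect_equal(attr(Ga, "b"), 2)
  expect_equal(Ga, A2, ignore_attr = TRUE)

  # idempotence after one pass
  Gr <- matrix(rnorm(36), 6, 6); Gr <- tcrossprod(Gr) / 6
  dimnames(Gr) <- dimnames(A22)
  once <- adjust_G(Gr, A22)
  twice <- adjust_G(once, A22)
  expect_equal(unclass(once), unclass(twice), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("blending is a convex combination with the stated fixed points", {
  set.seed(4)
  A22 <- build_A(random_ped(5))
  G <- A22 + diag(0.1, 5); dimnames(G) <- dimnames(A22)
  expect_equal(blend(G, A22, 0), G)
  expect_equal(blend(G, A22, 1), A22)
  expect_equal(blend(A22, A22, 0.05), A22)
  expect_error(blend(G, A22, 1.2), "omega")
})

test_that("the single-step H block formula matches a dense oracle", {
  sim <- small_sim()
  A <- build_A(sim$ped)

  # no genotyped animals: H = A
  expect_equal(build_H(A, A[0, 0, drop = FALSE], character(0)), A)

  # all genotyped: H = blended G
  ids <- rownames(A)[1:8]
  As <- A[ids, ids]
  Gb <- As + diag(0.05, 8); dimnames(Gb) <- dimnames(As)
  expect_equal(build_H(As, Gb, ids), Gb)

  # 3-animal pedigree, 1 genotyped: brute-force block expression
  trio <- trio_ped()
  At <- build_A(trio)
  g <- matrix(1.08, 1, 1, dimnames = list("x1", "x1"))
  H <- build_H(At, g, "x1")
  ng <- c("s1", "d1")
  A11 <- At[ng, ng]; A12 <- At[ng, "x1", drop = FALSE]
  A22i <- solve(At["x1", "x1", drop = FALSE])
  expect_equal(H[ng, ng],
               A11 - A12 %*% A22i %*% t(A12) +
                 A12 %*% A22i %*% g %*% A22i %*% t(A12))
  expect_equal(H[ng, "x1", drop = FALSE], A12 %*% A22i %*% g)
  expect_equal(H["x1", "x1"], g[1, 1])

  # projection identity: G_blend = A22 leaves every block of A unchanged
  gen <- sample(rownames(A), 10)
  H_id <- build_H(A, A[gen, gen], gen)
  expect_equal(H_id, A, tolerance = 1e-10)

  # PSD of the assembled H variants at omega = 0.05
  for (b in list(build_h_bundle("ss", sim$ped, sim$gs),
                 build_h_bundle("mf", sim$ped, sim$gs))) {
    ev <- eigen(b$H, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("breed-specific H matrices sum to A when nothing is genotyped", {
  ped <- small_sim()$ped
  pa <- build_partial_A(ped)
  HB <- build_H(pa$B, pa$B[0, 0, drop = FALSE], character(0))
  HH <- build_H(pa$H, pa$H[0, 0, drop = FALSE], character(0))
  expect_equal(HB + HH, build_A(ped), tolerance = 1e-12)
})

test_that("Gamma estimation is zero at the 0.5 reference and matches a GLS oracle", {
  # every dosage = 1 -> every GLS base frequency = 0.5 -> Gamma = 0
  ped <- as_pedigree(data.frame(id = sprintf("%s%d", rep(c("b", "h"), each = 3),
                                             rep(1:3, 2)),
                                sire = NA, dam = NA,
                                breed = rep(c("B", "H"), each = 3)))
  d <- matrix(1, 6, 10, dimnames = list(ped$id, sprintf("m%02d", 1:10)))
  gs <- toy_genotypes(d, breed = stats::setNames(ped$breed, ped$id))
  g0 <- estimate_gamma(gs, ped)
  expect_equal(c(g0$gamma_B, g0$gamma_BH, g0$gamma_H), c(0, 0, 0))

  # simulated data: whitened-regression oracle for the GLS base frequency
  sim <- small_sim()
  g <- estimate_gamma(sim$gs, sim$ped)
  A <- build_A(sim$ped)
  p_oracle <- matrix(NA_real_, 2, ncol(sim$gs$dosage),
                     dimnames = list(c("B", "H"), NULL))
  for (b in c("B", "H")) {
    ids <- intersect(sim$ped$id[sim$ped$breed == b], rownames(sim$gs$dosage))
    L <- t(chol(A[ids, ids]))
    for (j in seq_len(ncol(sim$gs$dosage))) {
      yw <- forwardsolve(L, sim$gs$dosage[ids, j] / 2)
      xw <- forwardsolve(L, rep(1, length(ids)))
      p_oracle[b, j] <- sum(xw * yw) / sum(xw * xw)
    }
  }
  S <- tcrossprod(p_oracle - 0.5) / ncol(p_oracle)
  expect_equal(g$gamma_B, 8 * S["B", "B"], tolerance = 1e-8)
  expect_equal(g$gamma_BH, 8 * S["B", "H"], tolerance = 1e-8)
  expect_equal(g$gamma_H, 8 * S["H", "H"], tolerance = 1e-8)

  # plausible magnitude for a drifted pair of breeds
  expect_true(g$gamma_B > 0.3 && g$gamma_B < 1.5)
  expect_true(g$gamma_BH < min(g$gamma_B, g$gamma_H))
})

test_that("the metafounder scale factor follows its closed form", {
  expect_equal(mf_scale_factor(gamma_matrix(0, 0, 0)), 1)
  # reported two-breed estimates: k = 1 + 0.687/2 - 0.6285
  k <- mf_scale_factor(gamma_matrix(0.702, 0.570, 0.672))
  expect_equal(round(k, 3), 0.715)
  # constant Gamma = c: k = 1 - c/2
  expect_equal(mf_scale_factor(gamma_matrix(0.4, 0.4, 0.4)), 1 - 0.2)
})

test_that("bending restores positive semi-definiteness minimally", {
  M <- diag(c(2, 1, -0.05))
  dimnames(M) <- list(letters[1:3], letters[1:3])
  Mb <- bend_psd(M)
  ev <- eigen(Mb, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(Mb[1, 1], 2, tolerance = 1e-8)
  # PSD input untouched
  expect_identical(bend_psd(diag(2)), diag(2))
})
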