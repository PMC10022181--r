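#' VanRaden genomic relationship matrix
#'
#' `G = ZZ' / sum(2 p q)` with `Z` coded `2 - 2p`, `1 - 2p`, `-2p` for the
#' three genotypes; missing dosages are mean-imputed to `2p` (contributing
#' zero to `Z`).
#'
#' @param gs A [genotype_set()].
#' @param p Allele frequency vector used for centering; defaults to the
#'   observed frequencies over all individuals in `gs` (see [allele_freq()]).
#' @param ids Individuals to include; defaults to all.
#' @return A symmetric matrix over `ids`.
#' @export
build_G <- function(gs, p = allele_freq(gs), ids = rownames(gs$dosage)) {
  M <- gs$dosage[ids, , drop = FALSE]
  stopifnot(length(p) == ncol(M))
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("sum(2pq) is zero; no polymorphic markers")
  Z <- sweep(M, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(ids, ids)
  G
}

#' Genomic relationship matrix referenced to allele frequency 0.5
#'
#' `G^0.5 = ZZ' / (m/2)` with `Z` coded 1, 0, -1 for the three genotypes;
#' missing dosages contribute 0. This is the genomic matrix paired with
#' metafounder pedigree relationships.
#'
#' @inheritParams build_G
#' @return A symmetric matrix over `ids`.
#' @export
build_G_half <- function(gs, ids = rownames(gs$dosage)) {
  M <- gs$dosage[ids, , drop = FALSE]
  m <- ncol(M)
  if (m == 0L) stop("no markers")
  Z <- M - 1
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (m / 2)
  dimnames(G) <- list(ids, ids)
  G
}

#' Breed-specific genomic relationship matrix
#'
#' Builds `G^(b)` over genotyped purebreds of breed `b` and the traced
#' crossbreds, from breed-specific allele contents: the purebred block
#' centres dosages at `2 p_b`, the crossbred block centres the single-copy
#' allele contents `Q_b` at `p_b`, and all blocks share the denominator
#' `2 p_b'(1 - p_b)` with `p_b` the breed-specific allele frequencies
#' computed from the genotyped purebreds of that breed. Markers monomorphic
#' within the breed are excluded (with a warning) from both numerator and
#' denominator.
#'
#' @param content A `cb_allele_content` from [build_allele_content()].
#' @param breed `"B"` or `"H"`.
#' @return A symmetric matrix over purebred-then-crossbred ids.
#' @export
build_G_breed <- function(content, breed = c("B", "H")) {
  breed <- match.arg(breed)
  M <- content[[paste0("M_", breed)]]
  Q <- content[[paste0("Q_", breed)]]
  if (is.null(M) || nrow(M) == 0L) stop("no genotyped purebreds of breed ", breed)
  p <- colMeans(M, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " marker(s) monomorphic in breed ", breed,
            " excluded from G^(", breed, ")")
  }
  keep <- which(!mono)
  p <- p[keep]
  denom <- sum(2 * p * (1 - p))
  Zm <- sweep(M[, keep, drop = FALSE], 2, 2 * p, "-")
  Zq <- sweep(Q[, keep, drop = FALSE], 2, p, "-")
  Zm[is.na(Zm)] <- 0
  Zq[is.na(Zq)] <- 0
  Z <- rbind(Zm, Zq)
  G <- tcrossprod(Z) / denom
  ids <- c(rownames(M), rownames(Q))
  dimnames(G) <- list(ids, ids)
  G
}

#' Adjust G for compatibility with a pedigree reference
#'
#' Finds scalars `(a, b)` such that `G* = a + b G` matches the reference
#' matrix in overall mean and diagonal mean, and returns `G*`. This is the
#' standard compatibility adjustment between genomic and pedigree
#' relationships over the genotyped subset.
#'
#' @param G Genomic relationship matrix.
#' @param A_ref Pedigree relationship matrix over the same ids (any order;
#'   matched by labels when present).
#' @return The adjusted matrix, with attributes `a` and `b`.
#' @export
adjust_G <- function(G, A_ref) {
  if (!is.null(rownames(G)) && !is.null(rownames(A_ref))) {
    stopifnot(setequal(rownames(G), rownames(A_ref)))
    A_ref <- A_ref[rownames(G), colnames(G), drop = FALSE]
  }
  mg <- mean(G); mdg <- mean(diag(G))
  ma <- mean(A_ref); mda <- mean(diag(A_ref))
  if (abs(mdg - mg) < 1e-12) stop("degenerate G: diagonal mean equals overall mean")
  b <- (mda - ma) / (mdg - mg)
  a <- ma - b * mg
  out <- a + b * G
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Blend genomic and pedigree relationships
#'
#' `(1 - omega) G + omega A22`, with `omega` the relative weight on the
#' polygenic (pedigree) component.
#'
#' @param G,A22 Relationship matrices over the same ids.
#' @param omega Blending weight in `[0, 1]` (default 0.05).
#' @return The blended matrix.
#' @export
blend <- function(G, A22, omega = 0.05) {
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]")
  if (!is.null(rownames(G)) && !is.null(rownames(A22))) {
    stopifnot(setequal(rownames(G), rownames(A22)))
    A22 <- A22[rownames(G), colnames(G), drop = FALSE]
  }
  (1 - omega) * G + omega * A22
}

#' Combined pedigree-genomic relationship matrix (single-step H)
#'
#' Evaluates the single-step block formula
#' \deqn{H = \begin{bmatrix}
#'   A_{11} - A_{12}A_{22}^{-1}A_{21} + A_{12}A_{22}^{-1} G A_{22}^{-1}A_{21}
#'     & A_{12}A_{22}^{-1} G \\
#'   G A_{22}^{-1} A_{21} & G \end{bmatrix}}
#' where subscripts 1 and 2 index non-genotyped and genotyped animals and
#' `G` is the (already blended/adjusted) genomic matrix. The same formula
#' serves the standard matrix (A with blended G), the metafounder matrix
#' (A^Gamma with blended G^0.5), and each breed-specific partial matrix
#' (A^(b) with its adjusted blended G^(b)).
#'
#' @param A Pedigree relationship matrix over all animals.
#' @param G_blend Genomic matrix over the genotyped subset (bottom-right
#'   block of the result).
#' @param genotyped Ids of genotyped animals (must label rows of `G_blend`).
#' @return A symmetric matrix over the ids of `A`, in `A`'s order.
#' @export
build_H <- function(A, G_blend, genotyped = rownames(G_blend)) {
  ids <- rownames(A)
  stopifnot(all(genotyped %in% ids))
  if (length(genotyped) == 0L) return(A)
  G_blend <- G_blend[genotyped, genotyped, drop = FALSE]
  ng <- setdiff(ids, genotyped)
  A22 <- A[genotyped, genotyped, drop = FALSE]
  A22i <- tryCatch(solve(A22), error = function(e)
    stop("A22 is singular; check pedigree depth for genotyped animals"))
  if (length(ng) == 0L) {
    return(G_blend[ids, ids, drop = FALSE])
  }
  A11 <- A[ng, ng, drop = FALSE]
  A12 <- A[ng, genotyped, drop = FALSE]
  P <- A12 %*% A22i               # projection of genotyped onto non-genotyped
  H11 <- A11 - P %*% t(A12) + P %*% G_blend %*% t(P)
  H12 <- P %*% G_blend
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  H[ng, ng] <- H11
  H[ng, genotyped] <- H12
  H[genotyped, ng] <- t(H12)
  H[genotyped, genotyped] <- G_blend
  (H + t(H)) / 2
}

#' Estimate the metafounder relationship matrix Gamma by GLS
#'
#' For each marker and each pure breed, the base-population allele frequency
#' is estimated by generalised least squares over that breed's genotyped
#' animals, `p_hat = (1' A_b^-1 1)^-1 1' A_b^-1 (m_j / 2)`, with `A_b` the
#' pedigree relationships among them. Gamma is then `8 S`, where `S` is the
#' across-marker second-moment matrix of the deviations of the estimated
#' base frequencies from 0.5 (the reference frequency of the metafounder
#' genomic matrix).
#'
#' Crossbred genotypes are not used: the estimator targets the purebred base
#' populations.
#'
#' @param gs A [genotype_set()].
#' @param ped A `cb_pedigree` containing the genotyped purebreds.
#' @return A [gamma_matrix()] with attribute `p_base` (2 x markers matrix of
#'   estimated base frequencies).
#' @export
estimate_gamma <- function(gs, ped) {
  stopifnot(inherits(ped, "cb_pedigree"))
  A <- build_A(ped)
  p_base <- matrix(NA_real_, 2, ncol(gs$dosage),
                   dimnames = list(c("B", "H"), colnames(gs$dosage)))
  for (b in c("B", "H")) {
    ids <- intersect(ped$id[ped$breed == b], rownames(gs$dosage))
    if (length(ids) < 2L) stop("fewer than 2 genotyped purebreds of breed ", b)
    Ab <- A[ids, ids]
    Ai1 <- solve(Ab, rep(1, length(ids)))
    w <- Ai1 / sum(Ai1)                       # GLS weights
    M <- gs$dosage[ids, , drop = FALSE]
    M[is.na(M)] <- NA
    # weighted mean of m_j/2 with GLS weights, skipping missing entries
    num <- colSums(w * M / 2, na.rm = TRUE)
    den <- colSums(w * (!is.na(M)))
    p_base[b, ] <- num / den
  }
  dev <- p_base - 0.5
  S <- tcrossprod(dev) / ncol(p_base)
  g <- gamma_matrix(8 * S["B", "B"], 8 * S["B", "H"], 8 * S["H", "H"])
  attr(g, "p_base") <- p_base
  g
}

#' Metafounder variance rescaling factor
#'
#' `k = 1 + mean(diag(Gamma))/2 - mean(Gamma)`, the factor that converts
#' genetic (co)variances estimated under related metafounders to the
#' unrelated-founders scale used by the other models.
#'
#' @param gamma A [gamma_matrix()].
#' @return Scalar `k`.
#' @export
mf_scale_factor <- function(gamma) {
  G <- as.matrix(as_gamma(gamma))
  1 + mean(diag(G)) / 2 - mean(G)
}

#' Bend a symmetric matrix to positive semi-definiteness
#'
#' Clips eigenvalues below `eps * max(eigenvalue)` up to that floor and
#' reconstructs. Genomic matrices adjusted for pedigree compatibility on a
#' small reference panel can pick up slightly negative eigenvalues (the
#' intercept of the adjustment shifts a rank-deficient matrix); bending
#' restores a valid covariance with minimal distortion. A no-op for
#' matrices already PSD.
#'
#' @param M Symmetric matrix.
#' @param eps Relative eigenvalue floor (default 1e-6).
#' @return The bent matrix, dimnames preserved.
#' @export
bend_psd <- function(M, eps = 1e-6) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  floor_ev <- eps * max(e$values, 0)
  if (all(e$values >= floor_ev)) return(M)
  out <- e$vectors %*% (pmax(e$values, floor_ev) * t(e$vectors))
  dimnames(out) <- dimnames(M)
  out
}

#' Assemble the single-step relationship bundle for one method
#'
#' Convenience wrapper producing everything the mixed-model module needs:
#' for `"ss"` the standard H (VanRaden G adjusted to A22 and blended); for
#' `"mf"` the metafounder H (G^0.5 blended with A^Gamma_22; metafounder rows
#' retained when `keep_metafounders`); for `"bs"` the pair of partial H
#' matrices (each breed's adjusted, blended G^(b) with its partial A^(b)).
#'
#' @param method `"ss"`, `"mf"` or `"bs"`.
#' @param ped A `cb_pedigree`.
#' @param gs A [genotype_set()] (QC'd). Genotyped animals are the ids shared
#'   between `gs` and the pedigree.
#' @param omega Polygenic blending weight (default 0.05).
#' @param gamma Gamma for `"mf"`; estimated via [estimate_gamma()] when
#'   `NULL`.
#' @param content Allele contents for `"bs"` (from [build_allele_content()]);
#'   required for that method.
#' @param keep_metafounders For `"mf"`: carry the metafounder rows through H
#'   (needed for contrast reliabilities).
#' @return A list of class `cb_hbundle`: `method`, `H` (matrix, or named
#'   list `B`/`H` of partial matrices for `"bs"`), `A` (pedigree counterpart,
#'   same shape), `omega`, `genotyped`, and `gamma` (mf only).
#' @export
build_h_bundle <- function(method = c("ss", "mf", "bs"), ped, gs,
                           omega = 0.05, gamma = NULL, content = NULL,
                           keep_metafounders = TRUE) {
  method <- match.arg(method)
  genotyped <- intersect(ped$id, rownames(gs$dosage))
  out <- list(method = method, omega = omega, genotyped = genotyped)
  if (method == "ss") {
    A <- build_A(ped)
    G <- build_G(gs, ids = genotyped)
    G <- adjust_G(G, A[genotyped, genotyped])
    out$H <- build_H(A, bend_psd(blend(G, A[genotyped, genotyped], omega)),
                     genotyped)
    out$A <- A
  } else if (method == "mf") {
    if (is.null(gamma)) gamma <- estimate_gamma(gs, ped)
    Ag <- build_A_gamma(ped, gamma, keep_metafounders = keep_metafounders)
    G <- build_G_half(gs, ids = genotyped)
    out$H <- build_H(Ag, bend_psd(blend(G, Ag[genotyped, genotyped], omega)),
                     genotyped)
    out$A <- Ag
    out$gamma <- gamma
  } else {
    if (is.null(content)) stop("method 'bs' requires allele contents")
    pa <- build_partial_A(ped)
    fr <- breed_fractions(ped)
    out$H <- list(); out$A <- list()
    for (b in c("B", "H")) {
      # the partial matrices are singular beyond the animals carrying
      # genome from breed b; each term covers only those animals
      f_b <- if (b == "B") fr$fB else 1 - fr$fB
      sub <- ped$id[f_b > 1e-12]
      ids_b <- intersect(rownames(content[[paste0("M_", b)]]), sub)
      ids_x <- intersect(rownames(content$Q_B), sub)
      gids <- c(ids_b, ids_x)
      Ab <- pa[[b]][sub, sub]
      Gb <- build_G_breed(content, b)[gids, gids]
      Ab22 <- Ab[gids, gids]
      Gb <- adjust_G(Gb, Ab22)
      out$H[[b]] <- build_H(Ab, bend_psd(blend(Gb, Ab22, omega)), gids)
      out$A[[b]] <- Ab
    }
    out$genotyped <- intersect(c(rownames(content$M_B), rownames(content$M_H),
                                 rownames(content$Q_B)), ped$id)
  }
  class(out) <- "cb_hbundle"
  out
}
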