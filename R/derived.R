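#' Heritabilities and genetic correlation with delta-method SEs
#'
#' For single-term models (standard and metafounder ssGBLUP),
#' `h2 = s2_u / (s2_u + s2_e)` per trait and
#' `r_g = cov_u / sqrt(s2_u1 s2_u2)`. For the breed-specific model the
#' crossbred genetic variance aggregates the two breed terms,
#' `s2_u = 0.5 (s2_B + s2_H)` per trait, giving
#' `h2 = 0.5(s2_B + s2_H) / (0.5(s2_B + s2_H) + s2_e)` and
#' `r_g = 0.5(cov_B + cov_H) / sqrt(s2_u1 s2_u2)`.
#' Standard errors use the first-order delta method on the asymptotic
#' covariance of the variance components (when available).
#'
#' @param vc A [varcomp()].
#' @param method `"ss"`, `"mf"` or `"bs"`; defaults to `"bs"` when `vc` has
#'   two genetic terms, `"ss"` otherwise.
#' @return A tibble with columns `parameter` (`h2`, `rg`), `trait`,
#'   `estimate`, `se`. Zero denominators yield `NA` estimates.
#' @export
derived_parameters <- function(vc, method = NULL) {
  stopifnot(inherits(vc, "cb_varcomp"))
  if (is.null(method)) method <- if (length(vc$G) == 2L) "bs" else "ss"
  theta <- vc_to_theta(vc)
  nterm <- length(vc$G)

  fns <- if (method == "bs") {
    stopifnot(nterm == 2L)
    list(
      h2_1 = function(th) {
        g <- 0.5 * (th[1] + th[4]); d <- g + th[7]
        if (d <= 0) return(NA_real_); g / d
      },
      h2_2 = function(th) {
        g <- 0.5 * (th[3] + th[6]); d <- g + th[9]
        if (d <= 0) return(NA_real_); g / d
      },
      rg = function(th) {
        g1 <- 0.5 * (th[1] + th[4]); g2 <- 0.5 * (th[3] + th[6])
        if (g1 <= 0 || g2 <= 0) return(NA_real_)
        0.5 * (th[2] + th[5]) / sqrt(g1 * g2)
      })
  } else {
    stopifnot(nterm == 1L)
    list(
      h2_1 = function(th) if (th[1] + th[4] <= 0) NA_real_ else th[1] / (th[1] + th[4]),
      h2_2 = function(th) if (th[3] + th[6] <= 0) NA_real_ else th[3] / (th[3] + th[6]),
      rg = function(th) if (th[1] <= 0 || th[3] <= 0) NA_real_ else
        th[2] / sqrt(th[1] * th[3]))
  }

  se_of <- function(f) {
    if (is.null(vc$asymp_cov)) return(NA_real_)
    V <- vc$asymp_cov
    V[is.na(V)] <- 0
    h <- pmax(abs(theta), 1e-6) * 1e-5
    g <- vapply(seq_along(theta), function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h[k]; tm[k] <- tm[k] - h[k]
      (f(tp) - f(tm)) / (2 * h[k])
    }, numeric(1))
    if (anyNA(g)) return(NA_real_)
    sqrt(max(drop(t(g) %*% V %*% g), 0))
  }

  tibble::tibble(
    parameter = c("h2", "h2", "rg"),
    trait = c(vc$traits, NA_character_),
    estimate = c(fns$h2_1(theta), fns$h2_2(theta), fns$rg(theta)),
    se = c(se_of(fns$h2_1), se_of(fns$h2_2), se_of(fns$rg)))
}

#' Model-based reliabilities from a fitted evaluation
#'
#' Computes per-animal, per-trait reliabilities from the prediction error
#' (co)variances of a fit solved with `pev = "full"`:
#'
#' * standard ssGBLUP: `Rel_i = 1 - PEV_ii / (H_ii s2_u)`;
#' * metafounder ssGBLUP: the contrast form against each metafounder
#'   `mf`, `Rel_i = 1 - [PEV(u_i) + PEV(u_mf) - 2 PEV(u_i, u_mf)] /
#'   [(H_ii + H_mf,mf - 2 H_i,mf) s2_u]`, one value per reference
#'   metafounder (requires the metafounder rows kept in H and hence in the
#'   fit), plus a breed-fraction-weighted combination when a pedigree is
#'   supplied;
#' * breed-specific ssGBLUP: per-breed values
#'   `1 - PEV_b,ii / (H_b,ii s2_b)` and a combined value
#'   `1 - PEV(u_B,i + u_H,i) / (H_B,ii s2_B + H_H,ii s2_H)`.
#'
#' Values outside `[0, 1]` (near-zero denominators) are clipped with a
#' warning.
#'
#' @param fit A `cb_fit` from [build_and_solve()] with `pev = "full"`.
#' @param bundle The [build_h_bundle()] the fit used.
#' @param vc The [varcomp()] used in the fit.
#' @param ids Animals to report (default: all in the fit, metafounders
#'   excluded).
#' @param ped Optional `cb_pedigree` for breed-fraction weighting of
#'   metafounder references.
#' @return A tibble `id`, `trait`, `measure`, `reliability`.
#' @export
reliability <- function(fit, bundle, vc, ids = NULL, ped = NULL) {
  stopifnot(inherits(fit, "cb_fit"), !is.null(fit$pev))
  C <- fit$pev$C_uu
  index <- fit$pev$index
  traits <- fit$spec$traits
  mf_labels <- c("MF_B", "MF_H")
  if (is.null(ids)) ids <- setdiff(fit$animals, mf_labels)
  pos <- function(term, trait, id) {
    sel <- index[index$term == term & index$trait == trait, , drop = FALSE]
    sel$pos[match(id, sel$id)]
  }
  rows <- list()
  clip_n <- 0L
  add <- function(id, trait, measure, rel) {
    out_lo <- rel < -1e-8; out_hi <- rel > 1 + 1e-8
    clip_n <<- clip_n + sum(out_lo | out_hi, na.rm = TRUE)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = id, trait = trait, measure = measure,
      reliability = unname(pmin(pmax(rel, 0), 1)))
  }

  if (bundle$method %in% c("ss", "mf")) {
    H <- bundle$H
    su <- vc$G[[1]]
    for (t in 1:2) {
      p_i <- pos("u", traits[t], ids)
      pev_ii <- diag(C)[p_i]
      if (bundle$method == "ss") {
        add(ids, traits[t], "ss", 1 - pev_ii / (diag(H)[match(ids, rownames(H))] * su[t, t]))
      } else {
        have_mf <- all(mf_labels %in% rownames(H))
        if (!have_mf) stop("metafounder rows absent from H; rebuild the ",
                           "bundle with keep_metafounders = TRUE")
        per_mf <- list()
        for (mf in mf_labels) {
          p_mf <- pos("u", traits[t], mf)
          num <- pev_ii + diag(C)[p_mf] - 2 * C[cbind(p_i, rep(p_mf, length(p_i)))]
          den <- (diag(H)[match(ids, rownames(H))] + H[mf, mf] -
                    2 * H[match(ids, rownames(H)), mf]) * su[t, t]
          r <- 1 - num / den
          per_mf[[mf]] <- r
          add(ids, traits[t], paste0("mf_", sub("MF_", "", mf)), r)
        }
        if (!is.null(ped)) {
          fr <- breed_fractions(ped)
          wB <- fr$fB[match(ids, fr$id)]
          add(ids, traits[t], "mf_combined",
              wB * per_mf[["MF_B"]] + (1 - wB) * per_mf[["MF_H"]])
        }
      }
    }
  } else {
    HB <- bundle$H$B; HH <- bundle$H$H
    sB <- vc$G[["uB"]]; sH <- vc$G[["uH"]]
    for (t in 1:2) {
      # ids absent from a breed term carry no genetic effect of that
      # origin: PEV and H entries are identically zero there
      pB <- pos("uB", traits[t], ids)
      pH <- pos("uH", traits[t], ids)
      z <- function(v) ifelse(is.na(v), 0, v)
      pevB <- z(diag(C)[pB]); pevH <- z(diag(C)[pH])
      pec <- ifelse(is.na(pB) | is.na(pH), 0, C[cbind(pB, pH)])
      hB <- z(diag(HB)[match(ids, rownames(HB))])
      hH <- z(diag(HH)[match(ids, rownames(HH))])
      relB <- ifelse(is.na(pB), NA_real_, 1 - pevB / (hB * sB[t, t]))
      relH <- ifelse(is.na(pH), NA_real_, 1 - pevH / (hH * sH[t, t]))
      add(ids[!is.na(pB)], traits[t], "B", relB[!is.na(pB)])
      add(ids[!is.na(pH)], traits[t], "H", relH[!is.na(pH)])
      add(ids, traits[t], "combined",
          1 - (pevB + pevH + 2 * pec) / (hB * sB[t, t] + hH * sH[t, t]))
    }
  }
  if (clip_n > 0L) {
    warning(clip_n, " reliabilit(ies) outside [0, 1] clipped ",
            "(near-zero denominators)")
  }
  dplyr::bind_rows(rows)
}

# expected breed-B genome fractions, reusing the partial-matrix recursion
breed_fractions <- function(ped) {
  id <- ped$id
  si <- match(ped$sire, id); di <- match(ped$dam, id)
  fB <- numeric(length(id))
  for (i in seq_along(id)) {
    if (is.na(si[i]) && is.na(di[i])) {
      fB[i] <- switch(ped$breed[i], B = 1, H = 0, BH = 0.5)
    } else if (is.na(si[i]) || is.na(di[i])) {
      known <- if (is.na(si[i])) fB[di[i]] else fB[si[i]]
      fB[i] <- switch(ped$breed[i], B = 1, H = 0,
                      BH = (known + (if (known >= 0.5) 0 else 1)) / 2)
    } else {
      fB[i] <- (fB[si[i]] + fB[di[i]]) / 2
    }
  }
  tibble::tibble(id = id, fB = fB)
}

#' Group means of model-based reliabilities
#'
#' Mirrors the usual reporting layout: mean reliability for all animals in
#' each group (e.g. all sires / genotyped sires / non-genotyped sires).
#'
#' @param rel Tibble from [reliability()].
#' @param groups Named list of id vectors.
#' @return A tibble `group`, `trait`, `measure`, `mean_reliability`, `n`;
#'   empty groups yield `NA`.
#' @export
summarize_reliability <- function(rel, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- lapply(names(groups), function(g) {
    sub <- rel[rel$id %in% groups[[g]], , drop = FALSE]
    if (!nrow(sub)) {
      return(tibble::tibble(group = g, trait = NA_character_,
                            measure = NA_character_,
                            mean_reliability = NA_real_, n = 0L))
    }
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$trait, .data$measure),
      mean_reliability = mean(.data$reliability), n = dplyr::n(),
      .groups = "drop")
    agg$group <- g
    agg[c("group", "trait", "measure", "mean_reliability", "n")]
  })
  dplyr::bind_rows(out)
}
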