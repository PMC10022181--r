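#' Split phenotypes at a cut-off birth date
#'
#' The partial dataset keeps animals born strictly before the cut-off date;
#' focal animals are those born on or after it.
#'
#' @param phenos Phenotype table with columns `id` and `birth_date`
#'   (`Date` or parseable character).
#' @param cutoff Cut-off date.
#' @return A list with `partial` (phenotype tibble) and `focal` (id vector).
#' @export
split_by_cutoff <- function(phenos, cutoff) {
  stopifnot("birth_date" %in% names(phenos))
  bd <- as.Date(phenos$birth_date)
  cutoff <- as.Date(cutoff)
  if (anyNA(bd)) stop("missing or unparseable birth dates")
  focal <- phenos$id[bd >= cutoff]
  if (!length(focal)) stop("no focal animals: all born before ", cutoff)
  list(partial = tibble::as_tibble(phenos[bd < cutoff, , drop = FALSE]),
       focal = focal)
}

#' LR-method estimators from partial and whole EBV
#'
#' The four linear-regression (LR) validation estimators for a set of focal
#' animals, comparing their EBV from a partial (early) evaluation `u_p` with
#' those from the whole-data evaluation `u_w`:
#'
#' * bias `Delta = mean(u_p) - mean(u_w)` (trait units; 0 when unbiased);
#' * dispersion `b = cov(u_w, u_p) / var(u_p)` (1 when correctly dispersed);
#' * population accuracy
#'   `acc = sqrt(cov(u_w, u_p) / ((1 + F_bar - 2 f_bar) sigma2_u))`, with
#'   `F_bar` the focal animals' mean inbreeding, `2 f_bar` their mean
#'   pairwise relationship, and `sigma2_u` the genetic variance from the
#'   partial fit;
#' * accuracy ratio `rho = cor(u_w, u_p)`, estimating the partial-to-whole
#'   accuracy ratio.
#'
#' Sample (n-1) covariances are used throughout. A negative covariance
#' leaves the accuracy undefined (`NA`, flagged).
#'
#' @param u_p,u_w Aligned EBV vectors for the focal animals.
#' @param F_bar Mean inbreeding coefficient of the focal animals.
#' @param f_bar Half the mean pairwise (off-diagonal) relationship.
#' @param sigma2_u Genetic variance from the partial evaluation.
#' @return A one-row tibble `bias`, `dispersion`, `accuracy`, `ratio`,
#'   `n_focal`.
#' @export
lr_estimators <- function(u_p, u_w, F_bar = 0, f_bar = 0, sigma2_u = NA_real_) {
  stopifnot(length(u_p) == length(u_w), length(u_p) >= 2L)
  vp <- stats::var(u_p)
  cv <- stats::cov(u_w, u_p)
  bias <- mean(u_p) - mean(u_w)
  if (vp <= 0) {
    b <- NA_real_; rho <- NA_real_
  } else {
    b <- cv / vp
    rho <- stats::cor(u_w, u_p)
  }
  acc <- NA_real_
  if (!is.na(sigma2_u) && sigma2_u > 0) {
    den <- (1 + F_bar - 2 * f_bar) * sigma2_u
    if (cv >= 0 && den > 0) acc <- sqrt(cv / den)
  }
  tibble::tibble(bias = bias, dispersion = b, accuracy = acc, ratio = rho,
                 n_focal = length(u_p))
}

#' Relative accuracy gain implied by an accuracy ratio
#'
#' `(1 / ratio - 1) * 100`: the percentage increase in population accuracy
#' from the partial to the whole evaluation implied by the LR accuracy
#' ratio.
#'
#' @param ratio Accuracy ratio (`rho` from [lr_estimators()]), must be > 0.
#' @return Percentage gain.
#' @export
relative_accuracy_gain <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) stop("ratio must be positive")
  (1 / ratio - 1) * 100
}

#' Run the LR validation for one method
#'
#' Fits the whole and the partial evaluations (variance components
#' re-estimated on the partial data by default, as when each evaluation is
#' run from scratch), aligns the focal animals' EBV (summed over terms for
#' the breed-specific model), and computes the four LR estimators per
#' trait. The accuracy denominator uses the partial fit's genetic variance
#' (for the metafounder model the rescaled variance; for the breed-specific
#' model the aggregate `0.5 (s2_B + s2_H)`), the focal animals' mean
#' pedigree inbreeding, and their mean pairwise pedigree relationship.
#'
#' @param spec A [model_spec()].
#' @param phenos Phenotype table incl. `birth_date`.
#' @param ped The `cb_pedigree` (for inbreeding and mean relationship of
#'   focal animals).
#' @param cutoff Cut-off date.
#' @param gamma [gamma_matrix()] of the metafounder fit (required for
#'   `method = "mf"` rescaling).
#' @param focal Optional explicit focal id vector. With `cutoff = NULL`
#'   this gives a no-holdout control: the partial dataset equals the whole
#'   dataset and the estimators are exactly (0, 1, ., 1).
#' @param reuse_varcomp Reuse the whole-data variance components for the
#'   partial evaluation instead of re-estimating (default `FALSE`).
#' @param reml_args List of extra arguments passed to [reml()].
#' @return A tibble with one row per trait: the four estimators plus
#'   `n_focal`, `cutoff`, `method`, and attribute `fits` carrying both
#'   fitted variance components.
#' @export
run_lr <- function(spec, phenos, ped, cutoff, gamma = NULL, focal = NULL,
                   reuse_varcomp = FALSE, reml_args = list()) {
  stopifnot(inherits(spec, "cb_model_spec"), inherits(ped, "cb_pedigree"))
  if (is.null(cutoff)) {
    if (is.null(focal)) stop("supply a cutoff date or an explicit focal set")
    sp <- list(partial = tibble::as_tibble(phenos), focal = focal)
  } else {
    sp <- split_by_cutoff(phenos, cutoff)
    if (!is.null(focal)) sp$focal <- focal
  }
  focal <- sp$focal

  vc_w <- do.call(reml, c(list(spec = spec, phenos = phenos), reml_args))
  fit_w <- build_and_solve(spec, phenos, vc_w)
  vc_p <- if (reuse_varcomp) vc_w else
    do.call(reml, c(list(spec = spec, phenos = sp$partial), reml_args))
  fit_p <- build_and_solve(spec, sp$partial, vc_p)

  total_term <- if (length(spec$terms) > 1L) "total" else names(spec$terms)[1]
  ebv_of <- function(fit, trait) {
    sub <- fit$ebv[fit$ebv$term == total_term & fit$ebv$trait == trait, ]
    sub$ebv[match(focal, sub$id)]
  }

  A <- build_A(ped)
  fa <- intersect(focal, ped$id)
  Af <- A[fa, fa, drop = FALSE]
  F_bar <- mean(diag(Af) - 1)
  two_f_bar <- if (length(fa) > 1L)
    mean(Af[upper.tri(Af)]) else 0

  sigma2_partial <- function(vc, trait_i) {
    if (spec$method == "bs") {
      0.5 * (vc$G[["uB"]][trait_i, trait_i] + vc$G[["uH"]][trait_i, trait_i])
    } else if (spec$method == "mf") {
      if (is.null(gamma)) stop("gamma required to rescale metafounder variance")
      mf_scale_factor(gamma) * vc$G[[1]][trait_i, trait_i]
    } else {
      vc$G[[1]][trait_i, trait_i]
    }
  }

  out <- lapply(1:2, function(t) {
    est <- lr_estimators(ebv_of(fit_p, spec$traits[t]),
                         ebv_of(fit_w, spec$traits[t]),
                         F_bar = F_bar, f_bar = two_f_bar / 2,
                         sigma2_u = sigma2_partial(vc_p, t))
    est$trait <- spec$traits[t]
    est
  })
  rep <- dplyr::bind_rows(out)
  rep$method <- spec$method
  rep$cutoff <- if (is.null(cutoff)) as.Date(NA) else as.Date(cutoff)
  rep <- rep[c("method", "trait", "bias", "dispersion", "accuracy",
               "ratio", "n_focal", "cutoff")]
  attr(rep, "fits") <- list(varcomp_whole = vc_w, varcomp_partial = vc_p,
                            F_bar = F_bar, two_f_bar = two_f_bar)
  class(rep) <- c("cb_lr", class(rep))
  rep
}

#' Write an LR validation report as TSV
#'
#' Columns `method`, `trait`, `bias`, `dispersion`, `accuracy`, `ratio`.
#'
#' @param rep Tibble from [run_lr()] (rows from several methods may be
#'   bound together first).
#' @param path Output path.
#' @export
write_lr_report <- function(rep, path) {
  utils::write.table(
    as.data.frame(rep)[c("method", "trait", "bias", "dispersion",
                         "accuracy", "ratio")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
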