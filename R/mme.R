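#' Specify a bivariate crossbred evaluation model
#'
#' Defines the trait pair, the fixed effects, and the genetic term(s) of the
#' evaluation: one combined-relationship term for standard or metafounder
#' ssGBLUP, or two breed-specific partial terms for BS-ssGBLUP. Each genetic
#' term is a labeled relationship matrix covering every animal to be
#' evaluated (phenotyped or not).
#'
#' @param traits Character vector of length 2 naming the trait columns in
#'   the phenotype table (e.g. `c("adg", "fcr")`).
#' @param fixed One-sided formula of fixed effects, evaluated per trait
#'   (e.g. `~ sex + pen + hys + start_weight`).
#' @param terms Named list of relationship matrices; one entry (`u`) for
#'   standard/metafounder models, two (`uB`, `uH`) for breed-specific.
#' @param method `"ss"`, `"mf"` or `"bs"` (bookkeeping for reliabilities
#'   and derived parameters).
#' @return An object of class `cb_model_spec`.
#' @export
model_spec <- function(traits, fixed, terms, method = c("ss", "mf", "bs")) {
  method <- match.arg(method)
  stopifnot(length(traits) == 2L, inherits(fixed, "formula"),
            is.list(terms), length(terms) >= 1L)
  if (is.null(names(terms)) || any(names(terms) == "")) {
    names(terms) <- paste0("u", seq_along(terms))
  }
  # each term carries its own animal set: the breed-specific partial
  # matrices only cover animals with a nonzero genome fraction from that
  # breed (the matrices are structurally singular beyond that set)
  for (K in terms) {
    stopifnot(is.matrix(K), !is.null(rownames(K)))
  }
  structure(list(traits = traits, fixed = fixed, terms = terms,
                 method = method), class = "cb_model_spec")
}

# Observation-level bookkeeping shared by the MME solver and REML.
# Stacks the two traits' non-missing records, builds the block-diagonal
# fixed design (rank-reduced by QR) and records each observation's trait
# and animal.
assemble_obs <- function(spec, phenos) {
  phenos <- as.data.frame(phenos)
  stopifnot("id" %in% names(phenos), all(spec$traits %in% names(phenos)))
  for (nm in names(spec$terms)) {
    unknown <- setdiff(phenos$id, rownames(spec$terms[[nm]]))
    if (length(unknown)) {
      stop("phenotyped animals missing from relationship matrix '", nm,
           "': ", paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  dup <- duplicated(phenos)
  if (any(dup)) phenos <- phenos[!dup, , drop = FALSE]  # merge exact repeats
  if (anyDuplicated(phenos$id)) {
    stop("repeated records per animal are not supported: ",
         paste(utils::head(unique(phenos$id[duplicated(phenos$id)]), 5),
               collapse = ", "))
  }
  y <- numeric(0); t_idx <- integer(0); a_id <- character(0)
  Xs <- list()
  for (t in 1:2) {
    tr <- spec$traits[t]
    rows <- which(!is.na(phenos[[tr]]))
    if (!length(rows)) next
    dat <- droplevels(as.data.frame(lapply(phenos[rows, , drop = FALSE],
      function(col) if (is.character(col)) factor(col) else col)))
    Xt <- stats::model.matrix(spec$fixed, data = dat)
    y <- c(y, phenos[[tr]][rows])
    t_idx <- c(t_idx, rep(t, length(rows)))
    a_id <- c(a_id, phenos$id[rows])
    Xs[[t]] <- Xt
  }
  if (!length(y)) stop("no phenotype records")
  X <- bdiag_dense(Xs)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  list(y = y, t_idx = t_idx, a_id = a_id, X = X, n_obs = length(y))
}

bdiag_dense <- function(mats) {
  mats <- mats[!vapply(mats, is.null, TRUE)]
  nr <- vapply(mats, nrow, 1L); nc <- vapply(mats, ncol, 1L)
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c(0L, cumsum(nr)); c0 <- c(0L, cumsum(nc))
  cn <- character(0)
  for (k in seq_along(mats)) {
    out[(r0[k] + 1L):r0[k + 1L], (c0[k] + 1L):c0[k + 1L]] <- mats[[k]]
    cn <- c(cn, paste0("t", k, ":", colnames(mats[[k]])))
  }
  colnames(out) <- cn
  out
}

# Symmetric solve with a diagonal jitter fallback for numerically
# semi-definite relationship matrices.
sym_inv <- function(M, label = "matrix") {
  out <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(chol2inv(chol(M + diag(1e-8, nrow(M)))),
                    error = function(e) stop(label, " is singular"))
  }
  dimnames(out) <- dimnames(M)
  out
}

#' Solve Henderson's mixed model equations
#'
#' Assembles and solves the bivariate MME for the given variance components:
#' fixed effects per trait, one vector of breeding values per genetic term
#' and trait, residual (co)variance with trait-specific missing-record
#' patterns. Prediction error (co)variances come from the inverse
#' coefficient matrix when requested.
#'
#' @param spec A [model_spec()].
#' @param phenos Phenotype table with columns `id`, the two traits (NA =
#'   missing) and every fixed-effect column.
#' @param varcomp A [varcomp()] with one genetic 2x2 block per term plus the
#'   residual block.
#' @param pev `"none"` (default) or `"full"`: invert the coefficient matrix
#'   and keep the breeding-value PEV blocks.
#' @return An object of class `cb_fit` with elements `fixed` (tibble),
#'   `ebv` (tibble: `id`, `term`, `trait`, `ebv`; for multi-term models the
#'   term `"total"` holds the summed EBV), `varcomp`, and when requested
#'   `pev` (list with the full breeding-value covariance block and its
#'   index).
#' @export
build_and_solve <- function(spec, phenos, varcomp, pev = c("none", "full")) {
  pev <- match.arg(pev)
  stopifnot(inherits(spec, "cb_model_spec"), inherits(varcomp, "cb_varcomp"))
  obs <- assemble_obs(spec, phenos)
  n_obs <- obs$n_obs

  # a term with (numerically) zero genetic variance contributes nothing:
  # its EBV are identically zero and it is dropped from the equations
  zero_terms <- character(0)
  for (nm in names(spec$terms)) {
    ev <- eigen(varcomp$G[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10)) stop("genetic (co)variance block '", nm, "' is not PSD")
    if (max(abs(varcomp$G[[nm]])) < 1e-12) zero_terms <- c(zero_terms, nm)
  }
  zero_ids <- lapply(spec$terms[zero_terms], rownames)
  spec_active <- spec
  spec_active$terms <- spec$terms[setdiff(names(spec$terms), zero_terms)]
  all_zero <- !length(spec_active$terms)
  if (!all_zero) spec <- spec_active
  nt <- if (all_zero) 0L else length(spec$terms)
  term_ids <- if (all_zero) list() else lapply(spec$terms, rownames)

  # residual R^-1 as a dense n_obs x n_obs matrix built from per-animal
  # 2x2 (or scalar) blocks
  Se <- varcomp$R
  Rinv <- matrix(0, n_obs, n_obs)
  for (a in unique(obs$a_id)) {
    o <- which(obs$a_id == a)
    tt <- obs$t_idx[o]
    Ri <- solve(Se[tt, tt, drop = FALSE])
    Rinv[o, o] <- Ri
  }

  # design: W = [X | Z_term1 | Z_term2 ...]; within each term, u is
  # ordered (trait1 over that term's animals, then trait2)
  p_fix <- ncol(obs$X)
  Zs <- list()
  index <- list()
  off <- p_fix
  for (k in seq_len(nt)) {
    ids_k <- term_ids[[k]]
    n_k <- length(ids_k)
    a_idx <- match(obs$a_id, ids_k)
    Z1 <- matrix(0, n_obs, n_k)
    Z1[cbind(seq_len(n_obs), a_idx)] <- 1
    Zs[[k]] <- cbind(Z1 * (obs$t_idx == 1), Z1 * (obs$t_idx == 2))
    index[[k]] <- tibble::tibble(
      pos = off - p_fix + seq_len(2L * n_k),
      term = names(spec$terms)[k],
      trait = rep(spec$traits, each = n_k),
      id = rep(ids_k, 2L))
    off <- off + 2L * n_k
  }
  W <- cbind(obs$X, do.call(cbind, Zs))

  C <- crossprod(W, Rinv %*% W)
  for (k in seq_len(nt)) {
    nm <- names(spec$terms)[k]
    Ki <- sym_inv(spec$terms[[k]], paste0("relationship matrix '", nm, "'"))
    Sui <- solve(varcomp$G[[nm]])
    block <- p_fix + min(index[[k]]$pos):max(index[[k]]$pos)
    C[block, block] <- C[block, block] + kronecker(Sui, Ki)
  }
  rhs <- crossprod(W, Rinv %*% obs$y)
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed model equations are singular: ", conditionMessage(e)))

  fixed <- tibble::tibble(coef = colnames(obs$X), estimate = sol[seq_len(p_fix)])
  if (length(index)) {
    index <- dplyr::bind_rows(index)
    ebv <- index
    ebv$ebv <- sol[p_fix + index$pos]
    ebv <- ebv[c("id", "term", "trait", "ebv")]
  } else {
    index <- NULL
    ebv <- tibble::tibble(id = character(0), term = character(0),
                          trait = character(0), ebv = numeric(0))
  }
  for (nm in zero_terms) {
    ebv <- dplyr::bind_rows(ebv, tidyr::expand_grid(
      id = zero_ids[[nm]], term = nm, trait = spec$traits) |>
        dplyr::mutate(ebv = 0))
  }
  nt <- nt + length(zero_terms)
  if (nt > 1L) {
    # total EBV: sum over terms, animals absent from a term contribute 0
    tot <- dplyr::summarise(dplyr::group_by(ebv, .data$id, .data$trait),
                            ebv = sum(.data$ebv), .groups = "drop")
    tot$term <- "total"
    ebv <- dplyr::bind_rows(ebv, tot[c("id", "term", "trait", "ebv")])
  }

  out <- list(spec = spec, fixed = fixed, ebv = ebv, varcomp = varcomp,
              animals = unique(c(unlist(term_ids), unlist(zero_ids))),
              n_obs = n_obs, p_fix = p_fix)
  if (pev == "full") {
    Ci <- solve(C)
    u_cols <- (p_fix + 1L):ncol(C)
    out$pev <- list(C_uu = Ci[u_cols, u_cols, drop = FALSE], index = index)
  }
  class(out) <- "cb_fit"
  out
}

#' @export
print.cb_fit <- function(x, ...) {
  cat("Crossbred evaluation fit (", x$spec$method, "): ",
      length(x$animals), " animals, ", x$n_obs, " records\n", sep = "")
  cat("  genetic terms:", paste(names(x$spec$terms), collapse = ", "), "\n")
  invisible(x)
}

#' Variance component container
#'
#' @param G Named list of 2x2 genetic (co)variance matrices, one per
#'   genetic term.
#' @param R 2x2 residual (co)variance matrix.
#' @param traits Trait names (length 2).
#' @param asymp_cov Optional asymptotic covariance of the distinct
#'   parameters (order: per term `var1, cov, var2`, then residual).
#' @param details Optional list of fitting diagnostics.
#' @return An object of class `cb_varcomp`.
#' @export
varcomp <- function(G, R, traits = c("trait1", "trait2"), asymp_cov = NULL,
                    details = list()) {
  if (is.matrix(G)) G <- list(u = G)
  for (M in c(G, list(R))) stopifnot(is.matrix(M), all(dim(M) == 2L),
                                     isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
  structure(list(G = G, R = R, traits = traits, asymp_cov = asymp_cov,
                 details = details), class = "cb_varcomp")
}

#' @export
print.cb_varcomp <- function(x, ...) {
  cat("Variance components (traits:", paste(x$traits, collapse = ", "), ")\n")
  for (nm in names(x$G)) {
    cat(" genetic [", nm, "]\n", sep = "")
    print(round(x$G[[nm]], 5))
  }
  cat(" residual\n")
  print(round(x$R, 5))
  invisible(x)
}

# Parameter vector <-> varcomp: per term (v11, cov, v22), then residual.
vc_to_theta <- function(vc) {
  th <- unlist(lapply(vc$G, function(M) c(M[1, 1], M[1, 2], M[2, 2])))
  unname(c(th, vc$R[1, 1], vc$R[1, 2], vc$R[2, 2]))
}

theta_to_vc <- function(theta, template) {
  G <- template$G
  k <- 0L
  for (nm in names(G)) {
    G[[nm]] <- matrix(theta[k + c(1, 2, 2, 3)], 2, 2)
    k <- k + 3L
  }
  R <- matrix(theta[k + c(1, 2, 2, 3)], 2, 2)
  varcomp(G, R, traits = template$traits, asymp_cov = template$asymp_cov,
          details = template$details)
}

theta_names <- function(vc) {
  c(unlist(lapply(names(vc$G), function(nm)
    paste0(nm, c("_var1", "_cov", "_var2")))),
    c("e_var1", "e_cov", "e_var2"))
}
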