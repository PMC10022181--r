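#' REML estimation of bivariate variance components
#'
#' Estimates the genetic and residual (co)variance matrices of a
#' [model_spec()] by restricted maximum likelihood on the marginal
#' covariance of the phenotyped animals (relationship matrices are collapsed
#' to the phenotyped subset, which leaves the likelihood unchanged). Two
#' algorithms are available: average-information (AI) scoring with
#' step-halving and an expectation-maximisation fallback whenever an AI step
#' leaves the parameter space, or pure EM. The EM updates never decrease
#' the restricted log-likelihood.
#'
#' The asymptotic covariance of the estimates is the inverse
#' average-information matrix at convergence. Parameters that carry no
#' information (e.g. the second trait's components when only one trait has
#' records) are pinned at their starting values; variances shrinking to the
#' zero boundary are clamped at a small floor and reported in the details.
#'
#' @param spec A [model_spec()].
#' @param phenos Phenotype table (see [build_and_solve()]).
#' @param init Optional starting [varcomp()]; defaults to an even split of
#'   the phenotypic (co)variance across the genetic term(s) and residual.
#' @param method `"ai"` (default) or `"em"`.
#' @param tol Relative parameter-change convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @param on_nonconv `"error"` (default; the error carries the likelihood
#'   trajectory) or `"warn"`.
#' @return A [varcomp()] with `asymp_cov` and fitting `details`
#'   (`loglik`, `trajectory`, `iterations`, `converged`, `boundary`).
#' @export
reml <- function(spec, phenos, init = NULL, method = c("ai", "em"),
                 tol = 1e-8, max_iter = 200L,
                 on_nonconv = c("error", "warn")) {
  method <- match.arg(method)
  on_nonconv <- match.arg(on_nonconv)
  stopifnot(inherits(spec, "cb_model_spec"))
  obs <- assemble_obs(spec, phenos)
  y <- obs$y; X <- obs$X; n_obs <- obs$n_obs
  p_ids <- unique(obs$a_id)
  n_p <- length(p_ids)
  a2 <- match(obs$a_id, p_ids)
  t_idx <- obs$t_idx
  nt <- length(spec$terms)
  term_names <- names(spec$terms)

  K_pp <- lapply(spec$terms, function(K) K[p_ids, p_ids, drop = FALSE])
  K_obs <- lapply(K_pp, function(K) K[a2, a2, drop = FALSE])
  same <- outer(a2, a2, "==") * 1
  pat <- list(
    v11 = outer(t_idx == 1, t_idx == 1) * 1,
    cov = (outer(t_idx == 1, t_idx == 2) | outer(t_idx == 2, t_idx == 1)) * 1,
    v22 = outer(t_idx == 2, t_idx == 2) * 1)

  # one (base, pattern) pair per parameter, order: per term v11, cov, v22;
  # then residual
  bases <- c(rep(K_obs, each = 3L), rep(list(same), 3L))
  pats <- rep(pat, nt + 1L)
  npar <- length(bases)

  # starting values
  obs_traits <- sort(unique(t_idx))
  Sp <- diag(0, 2)
  for (t in obs_traits) Sp[t, t] <- stats::var(y[t_idx == t])
  if (length(obs_traits) == 2L) {
    both <- intersect(obs$a_id[t_idx == 1], obs$a_id[t_idx == 2])
    if (length(both) > 2L) {
      Sp[1, 2] <- Sp[2, 1] <- stats::cov(
        y[t_idx == 1][match(both, obs$a_id[t_idx == 1])],
        y[t_idx == 2][match(both, obs$a_id[t_idx == 2])])
    }
  }
  if (is.null(init)) {
    # modest genetic share: variance ratios in this domain are usually low,
    # and starting small keeps early AI steps inside the parameter space
    Gi <- lapply(term_names, function(nm) 0.3 * Sp / nt)
    names(Gi) <- term_names
    init <- varcomp(Gi, 0.7 * Sp, traits = spec$traits)
  }
  theta <- vc_to_theta(init)
  floor_v <- 1e-8 * max(diag(Sp), 1e-12)

  build_V <- function(th) {
    V <- matrix(0, n_obs, n_obs)
    for (k in seq_len(npar)) V <- V + th[k] * (pats[[k]] * bases[[k]])
    V
  }
  # restricted log-likelihood and projection quantities
  eval_theta <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vi - t(XtVi) %*% chol2inv(chx) %*% XtVi
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  drop(crossprod(y, Py)))
    list(ll = ll, P = P, Py = Py)
  }
  valid_theta <- function(th) {
    k <- 0L
    for (j in seq_len(nt + 1L)) {
      M <- matrix(th[k + c(1, 2, 2, 3)], 2, 2)
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (ev[2] < -1e-12 || any(diag(M) < 0)) return(FALSE)
      k <- k + 3L
    }
    TRUE
  }
  clamp_theta <- function(th) {
    k <- 0L
    for (j in seq_len(nt + 1L)) {
      v1 <- max(th[k + 1L], floor_v); v2 <- max(th[k + 3L], floor_v)
      cv <- th[k + 2L]
      lim <- 0.999 * sqrt(v1 * v2)
      th[k + 1L] <- v1; th[k + 3L] <- v2
      th[k + 2L] <- max(min(cv, lim), -lim)
      k <- k + 3L
    }
    th
  }

  # parameters that can carry information: both traits present for v22/cov
  active <- rep(TRUE, npar)
  if (!(1 %in% obs_traits)) active[seq_len(npar) %% 3L == 1L] <- FALSE
  if (!(2 %in% obs_traits)) active[seq_len(npar) %% 3L == 0L] <- FALSE
  if (length(obs_traits) == 1L) active[seq_len(npar) %% 3L == 2L] <- FALSE

  em_step <- function(th, st) {
    vc <- theta_to_vc(th, init)
    th_new <- th
    k <- 0L
    for (j in seq_len(nt)) {
      Su <- vc$G[[j]]
      Kp <- K_pp[[j]]
      Cu <- rbind(Kp[, a2, drop = FALSE] * rep(Su[1, t_idx], each = n_p),
                  Kp[, a2, drop = FALSE] * rep(Su[2, t_idx], each = n_p))
      uhat <- Cu %*% st$Py
      Vcond <- kronecker(Su, Kp) - Cu %*% st$P %*% t(Cu)
      Ki <- sym_inv(Kp, "collapsed relationship matrix")
      iu <- function(t) (t - 1L) * n_p + seq_len(n_p)
      Eij <- function(i, j2) {
        drop(crossprod(uhat[iu(i)], Ki %*% uhat[iu(j2)])) +
          sum(Ki * Vcond[iu(i), iu(j2)])
      }
      th_new[k + 1L] <- Eij(1, 1) / n_p
      th_new[k + 2L] <- Eij(1, 2) / n_p
      th_new[k + 3L] <- Eij(2, 2) / n_p
      k <- k + 3L
    }
    Se <- vc$R
    ind <- outer(seq_len(n_p), a2, "==") * 1
    Ce <- rbind(ind * rep(Se[1, t_idx], each = n_p),
                ind * rep(Se[2, t_idx], each = n_p))
    ehat <- Ce %*% st$Py
    Vce <- kronecker(Se, diag(n_p)) - Ce %*% st$P %*% t(Ce)
    ie <- function(t) (t - 1L) * n_p + seq_len(n_p)
    Rij <- function(i, j2) {
      (sum(ehat[ie(i)] * ehat[ie(j2)]) +
         sum(diag(Vce[ie(i), ie(j2)]))) / n_p
    }
    th_new[k + 1L] <- Rij(1, 1)
    th_new[k + 2L] <- Rij(1, 2)
    th_new[k + 3L] <- Rij(2, 2)
    th_new[!active] <- th[!active]
    clamp_theta(th_new)
  }

  grad_ai <- function(th, st) {
    Fmat <- matrix(0, n_obs, npar)
    g <- numeric(npar)
    for (k in seq_len(npar)) {
      D <- pats[[k]] * bases[[k]]
      f <- D %*% st$Py
      Fmat[, k] <- f
      g[k] <- -0.5 * (sum(st$P * D) - drop(crossprod(st$Py, f)))
    }
    AI <- 0.5 * crossprod(Fmat, st$P %*% Fmat)
    list(g = g, AI = AI)
  }

  st <- eval_theta(theta)
  if (is.null(st)) {
    theta <- clamp_theta(theta)
    st <- eval_theta(theta)
    if (is.null(st)) stop("starting values give a singular covariance")
  }
  traj <- st$ll
  converged <- FALSE
  stagnant <- 0L
  n_em <- 0L
  ga <- NULL
  for (it in seq_len(max_iter)) {
    if (method == "ai") {
      ga <- grad_ai(theta, st)
      act <- active & diag(ga$AI) > 1e-12 * max(diag(ga$AI), 1e-300)
      # active set: drop parameters pinned at a boundary whose gradient
      # points outward (variance floors, correlation clamps) -- leaving
      # them in corrupts the scoring direction for the free parameters
      k <- 0L
      for (j in seq_len(nt + 1L)) {
        v1 <- theta[k + 1L]; cv <- theta[k + 2L]; v2 <- theta[k + 3L]
        if (v1 <= floor_v * 1.0001 && ga$g[k + 1L] < 0) act[k + 1L] <- FALSE
        if (v2 <= floor_v * 1.0001 && ga$g[k + 3L] < 0) act[k + 3L] <- FALSE
        lim <- 0.999 * sqrt(v1 * v2)
        if (abs(cv) >= lim * (1 - 1e-9) && sign(cv) * ga$g[k + 2L] > 0) {
          act[k + 2L] <- FALSE
        }
        if (v1 <= floor_v * 1.0001 || v2 <= floor_v * 1.0001) {
          act[k + 2L] <- FALSE  # covariance meaningless at a zero variance
        }
        k <- k + 3L
      }
      step <- numeric(npar)
      Asub <- ga$AI[act, act, drop = FALSE]
      step[act] <- if (!sum(act)) 0 else tryCatch(
        solve(Asub + diag(1e-8 * mean(diag(Asub)), sum(act)), ga$g[act]),
        error = function(e) rep(0, sum(act)))
      alpha <- 1
      accepted <- FALSE
      for (h in 1:8) {
        # project the candidate onto the parameter space (variance floors,
        # |correlation| <= 0.999) before evaluating, so boundary optima are
        # reached in one step rather than crawled to
        cand <- clamp_theta(theta + alpha * step)
        if (valid_theta(cand)) {
          stc <- eval_theta(cand)
          if (!is.null(stc) && stc$ll >= st$ll - 1e-10) {
            theta_new <- cand; st_new <- stc
            accepted <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (!accepted) {
        n_em <- n_em + 1L
        theta_new <- em_step(theta, st)
        st_new <- eval_theta(theta_new)
        if (is.null(st_new)) stop("EM fallback produced a singular covariance")
      }
    } else {
      theta_new <- em_step(theta, st)
      st_new <- eval_theta(theta_new)
      if (is.null(st_new)) stop("EM step produced a singular covariance")
    }
    delta <- max(abs(theta_new - theta) / (abs(theta) + 1))
    at_floor <- theta_new <= floor_v * 1.0001
    delta_free <- max(c(0, (abs(theta_new - theta) /
                              (abs(theta) + 1))[active & !at_floor]))
    ll_gain <- st_new$ll - st$ll
    stagnant <- if (abs(ll_gain) < 1e-8 * (abs(st_new$ll) + 1))
      stagnant + 1L else 0L
    traj <- c(traj, st_new$ll)
    theta <- theta_new; st <- st_new
    if (delta_free < tol || delta < tol || (it > 3L && stagnant >= 3L)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    msg <- sprintf("REML did not converge in %d iterations (last rel. change %.2e)",
                   max_iter, delta)
    if (on_nonconv == "error") {
      cond <- structure(class = c("cb_reml_nonconvergence", "error", "condition"),
                        list(message = msg, call = sys.call(-1),
                             trajectory = traj, theta = theta))
      stop(cond)
    }
    warning(msg)
  }
  ga <- grad_ai(theta, st)
  acov <- matrix(NA_real_, npar, npar,
                 dimnames = list(theta_names(init), theta_names(init)))
  act <- active & diag(ga$AI) > 0
  acov[act, act] <- tryCatch(
    solve(ga$AI[act, act, drop = FALSE]),
    error = function(e) MASS_ginv(ga$AI[act, act, drop = FALSE]))
  out <- theta_to_vc(theta, init)
  out$asymp_cov <- acov
  out$details <- list(loglik = st$ll, trajectory = traj, iterations = it,
                      converged = converged, method = method, n_em = n_em,
                      n_animals = n_p, n_obs = n_obs,
                      boundary = theta_names(init)[theta <= floor_v * 1.0001])
  out
}

# small pseudo-inverse helper (avoids importing MASS for one call)
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Rescale metafounder variance components to the unrelated-base scale
#'
#' Multiplies the genetic (co)variance block (and the corresponding rows and
#' columns of the asymptotic covariance) by `k = 1 + mean(diag(Gamma))/2 -
#' mean(Gamma)`, leaving the residual unchanged, so that metafounder
#' estimates are comparable with models assuming unrelated founders.
#' Heritabilities change under this scaling; genetic correlations do not.
#'
#' @param vc A [varcomp()] from a metafounder fit.
#' @param gamma The [gamma_matrix()] used in the fit.
#' @return The rescaled [varcomp()]; `details$mf_scale` records `k`.
#' @export
scale_mf_varcomp <- function(vc, gamma) {
  stopifnot(inherits(vc, "cb_varcomp"))
  k <- mf_scale_factor(gamma)
  vc$G <- lapply(vc$G, function(M) k * M)
  if (!is.null(vc$asymp_cov)) {
    ng <- 3L * length(vc$G)
    d <- c(rep(k, ng), rep(1, 3L))
    vc$asymp_cov <- vc$asymp_cov * tcrossprod(d)
  }
  vc$details$mf_scale <- k
  vc
}
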