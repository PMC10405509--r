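#' Control settings for REML estimation
#'
#' @param max_iter Maximum number of accepted iterations (default 200).
#' @param tol_par Convergence tolerance on the maximum relative parameter
#'   change between accepted iterates.
#' @param tol_ll Convergence tolerance on the decrease of `-2 logL`.
#' @param fd_rel Relative step for the central finite-difference scores.
#' @param max_halving Maximum number of step-halvings per iteration before
#'   the iteration is declared boundary-converged.
#' @param bend_eps Relative eigenvalue floor used when a proposal leaves
#'   the positive-definite cone ("bending").
#' @param verbose Print the iteration trace.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(max_iter = 200L, tol_par = 1e-7, tol_ll = 1e-6,
                         fd_rel = 1e-4, max_halving = 15L, bend_eps = 1e-8,
                         verbose = FALSE) {
  structure(
    list(
      max_iter = as.integer(max_iter), tol_par = tol_par, tol_ll = tol_ll,
      fd_rel = fd_rel, max_halving = as.integer(max_halving),
      bend_eps = bend_eps, verbose = isTRUE(verbose)
    ),
    class = "reml_control"
  )
}

## Build a variance_components object from a free-parameter vector,
## bending each structure matrix back into the PSD cone if needed.
## Returns NULL if the result is still unusable.
vc_project <- function(config, theta, sigma2_dummy, bend_eps = 1e-8) {
  map <- parameter_map(config)
  gf <- genetic_factors(config)
  ec <- env_components(config)
  G0 <- matrix(0, length(gf), length(gf), dimnames = list(gf, gf))
  E0 <- matrix(0, length(ec), length(ec), dimnames = list(ec, ec))
  for (k in seq_len(nrow(map))) {
    if (!map$free[k]) next
    v <- theta[[map$term[k]]]
    if (map$matrix[k] == "G0") {
      G0[map$row[k], map$col[k]] <- G0[map$col[k], map$row[k]] <- v
    } else if (map$matrix[k] == "E0") {
      E0[map$row[k], map$col[k]] <- E0[map$col[k], map$row[k]] <- v
    }
  }
  skel <- structure(list(config = config, G0 = G0, E0 = E0, map = map),
    class = "variance_components"
  )
  G0 <- bend_psd(G0, free_pattern_matrix(skel, "G0"), bend_eps)
  E0 <- bend_psd(E0, free_pattern_matrix(skel, "E0"), bend_eps)
  ## keep variances strictly positive: a bent-to-zero variance makes the
  ## precision singular
  floor_g <- 1e-6 * max(diag(G0), 1)
  diag(G0) <- pmax(diag(G0), floor_g)
  floor_e <- 1e-6 * max(diag(E0), 1)
  diag(E0) <- pmax(diag(E0), floor_e)
  out <- structure(
    list(config = config, G0 = G0, E0 = E0, sigma2_dummy = sigma2_dummy, map = map),
    class = "variance_components"
  )
  out
}

## Default starting values: 30% of the phenotypic variance to the direct
## genetic variance, 10% each to the maternal genetic and permanent
## environmental variances, 40% to the residual; covariances 0.
reml_start <- function(prep, config, sigma2_dummy) {
  map <- parameter_map(config)
  ## phenotypic variance corrected for the fixed effects (ordinary least
  ## squares), so that sex/hatch effects and the genetic trend across
  ## rounds do not inflate the starting values
  X <- prep$design$X
  b <- tryCatch(
    as.numeric(Matrix::solve(
      Matrix::crossprod(X) + Matrix::Diagonal(ncol(X), 1e-8),
      Matrix::crossprod(X, prep$y)
    )),
    error = function(e) NULL
  )
  resid <- if (is.null(b)) prep$y else prep$y - as.numeric(X %*% b)
  vp <- stats::setNames(numeric(config$traits), trait_names(config))
  for (t in seq_len(config$traits)) {
    rows <- prep$design$records$trait == t
    vp[t] <- stats::var(resid[rows])
  }
  trait_of <- function(f) {
    if (config$traits == 1L) {
      1L
    } else {
      match(sub(".*_", "", f), c("F", "M"))
    }
  }
  th <- numeric(0)
  for (k in which(map$free)) {
    term <- map$term[k]
    if (map$row[k] != map$col[k]) {
      th[term] <- 0
      next
    }
    v <- vp[trait_of(map$row[k])]
    th[term] <- switch(substr(map$row[k], 1, 1),
      a = 0.30 * v,
      m = 0.10 * v,
      e = 0.40 * v,
      p = 0.10 * v
    )
  }
  th
}

## scale used for relative convergence / finite-difference steps: the
## geometric mean of the two variances a parameter connects
theta_scales <- function(vc) {
  map <- vc$map
  out <- numeric(0)
  for (k in which(map$free)) {
    M <- vc[[map$matrix[k]]]
    s <- sqrt(M[map$row[k], map$row[k]] * M[map$col[k], map$col[k]])
    out[map$term[k]] <- max(abs(M[map$row[k], map$col[k]]), s, 1e-8)
  }
  out
}

## ---------------------------------------------------------------------
## Average information matrix, computed exactly through MME solves:
## AI_ij = 1/2 f_i' P f_j with f_i = dV/dtheta_i %*% P y.
ai_matrix <- function(prep, fit) {
  vc <- fit$vc
  config <- prep$config
  map <- vc$map
  free <- which(map$free)
  p <- prep$p
  N <- prep$N
  qg <- prep$qg
  rr <- mme_residuals(prep, fit$asm, fit$sol)
  v_all <- as.numeric(Matrix::crossprod(prep$M, rr$Py))
  u_tilde <- v_all
  u_tilde[seq_len(p)] <- 0 # X'Py = 0 at the solution; keep exact zeros
  nfree <- length(free)
  F_ <- matrix(0, length(prep$y), nfree)
  env_off <- p + qg * N
  e_comp_of_trait <- function(t) if (config$traits == 1L) "e" else c("e_F", "e_M")[t]
  for (ii in seq_along(free)) {
    k <- free[ii]
    w <- numeric(prep$dim)
    if (map$matrix[k] == "G0") {
      fr <- match(map$row[k], prep$gf)
      fc <- match(map$col[k], prep$gf)
      ur <- u_tilde[p + (fr - 1L) * N + seq_len(N)]
      uc <- u_tilde[p + (fc - 1L) * N + seq_len(N)]
      Auc <- as.numeric(a_mult_cpp(prep$ped_sire, prep$ped_dam, prep$f, as.matrix(uc)))
      w[p + (fr - 1L) * N + seq_len(N)] <- Auc
      if (fr != fc) {
        Aur <- as.numeric(a_mult_cpp(prep$ped_sire, prep$ped_dam, prep$f, as.matrix(ur)))
        w[p + (fc - 1L) * N + seq_len(N)] <- w[p + (fc - 1L) * N + seq_len(N)] + Aur
      }
    } else {
      cr <- map$row[k]
      cc <- map$col[k]
      ec_tab <- prep$env_cols
      if (nrow(ec_tab)) {
        rows_r <- ec_tab[ec_tab$comp == cr, ]
        rows_c <- ec_tab[ec_tab$comp == cc, ]
        common <- intersect(rows_r$.an, rows_c$.an)
        if (length(common)) {
          col_r <- rows_r$col[match(common, rows_r$.an)]
          col_c <- rows_c$col[match(common, rows_c$.an)]
          w[env_off + col_r] <- w[env_off + col_r] + u_tilde[env_off + col_c]
          if (cr != cc) {
            w[env_off + col_c] <- w[env_off + col_c] + u_tilde[env_off + col_r]
          }
        }
      }
    }
    f_i <- as.numeric(prep$M %*% w)
    ## absorbed residual rows: dV/dsigma2_e also carries an identity there
    if (map$matrix[k] == "E0" && map$row[k] == map$col[k] &&
      substr(map$row[k], 1, 1) == "e") {
      for (g in prep$groups) {
        if (identical(g$type, "explicit")) next
        if (e_comp_of_trait(g$type) == map$row[k]) {
          f_i[g$rows] <- f_i[g$rows] + rr$Py[g$rows]
        }
      }
    }
    F_[, ii] <- f_i
  }
  RHS <- as.matrix(Matrix::crossprod(prep$M, F_ / rr$rv_rec))
  TH <- as.matrix(Matrix::solve(fit$Ch, RHS, system = "A"))
  PF <- (F_ - as.matrix(prep$M %*% TH)) / rr$rv_rec
  AI <- 0.5 * crossprod(F_, PF)
  AI <- (AI + t(AI)) / 2
  dimnames(AI) <- list(map$term[free], map$term[free])
  AI
}

## Central finite-difference score of -2logL over the free parameters.
fd_gradient <- function(prep, vc, m2l_fun, fd_rel) {
  theta <- vc_free_values(vc)
  sc <- theta_scales(vc)[names(theta)]
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    h <- fd_rel * sc[i]
    up <- theta
    up[i] <- up[i] + h
    dn <- theta
    dn[i] <- dn[i] - h
    g[i] <- (m2l_fun(up) - m2l_fun(dn)) / (2 * h)
  }
  stats::setNames(g, names(theta))
}

## ---------------------------------------------------------------------

#' REML estimation of the maternal animal model
#'
#' Estimates the free (co)variance parameters by restricted maximum
#' likelihood, holding the dummy residual variance fixed.  Iterations are
#' Newton steps with the exact average-information matrix as curvature and
#' central finite-difference scores, guarded by step-halving and
#' eigenvalue bending so that accepted iterates never increase `-2 logL`
#' and never leave the positive-(semi)definite cone.  Approximate
#' standard errors come from the inverse average-information matrix at
#' convergence.
#'
#' @inheritParams blup
#' @param config A [model_config()] (or a model name string).
#' @param init Optional starting values: a [variance_components()] object
#'   or a named vector of free parameters.  Default: 30% of the
#'   phenotypic variance to `sigma2_a`, 10% each to `sigma2_m` and
#'   `sigma2_pe`, 40% to `sigma2_e`, covariances 0.
#' @param sigma2_dummy Fixed dummy residual variance (default 1).  A
#'   warning is emitted if it is not small relative to the initial
#'   residual variance, since the device requires a constant smaller than
#'   the true residual.
#' @param control A [reml_control()] list.
#' @return An object of class `reml_fit`; see [tidy.reml_fit()] and
#'   [glance.reml_fit()].
#' @examples
#' \donttest{
#' pop <- run_program(sim_config(
#'   n_sr = 4, n_males_selected = 2,
#'   n_females_selected = 20, offspring_per_sr = 80, random_until_sr = 4
#' ), seed = 1)
#' fit <- reml(pop$phenotypes, pop$pedigree, "modam")
#' tidy(fit)
#' }
#' @export
reml <- function(data, pedigree, config, init = NULL, sigma2_dummy = 1,
                 fixed = NULL, use_inbreeding = TRUE,
                 control = reml_control()) {
  if (is.character(config)) config <- model_config(config)
  pedigree <- check_pedigree(pedigree)
  design <- build_design(data, pedigree, config, fixed = fixed)
  prep <- mme_prep(design, pedigree, use_inbreeding = use_inbreeding)
  reml_on_prep(prep, config, init, sigma2_dummy, control)
}

reml_on_prep <- function(prep, config, init = NULL, sigma2_dummy = 1,
                         control = reml_control()) {
  map <- parameter_map(config)
  theta <- if (is.null(init)) {
    reml_start(prep, config, sigma2_dummy)
  } else if (inherits(init, "variance_components")) {
    vc_free_values(init)
  } else {
    unlist(init)[map$term[map$free]]
  }
  if (anyNA(theta)) stop("incomplete starting values", call. = FALSE)
  e_terms <- map$term[map$free & map$row == map$col &
    substr(map$row, 1, 1) == "e" & map$matrix == "E0"]
  if (any(sigma2_dummy >= theta[e_terms])) {
    warning(
      "sigma2_dummy (", sigma2_dummy, ") is not small relative to the ",
      "initial residual variance; the dummy residual must stay below the ",
      "true residual",
      call. = FALSE
    )
  }

  ## symbolic factorization on the union pattern (all free covariances
  ## nonzero), reused by every numeric update
  asm0 <- mme_assemble(prep, vc_reference(config, sigma2_dummy))
  Ch <- mme_factor(asm0$C)

  fit_cache <- NULL
  n_eval <- 0L
  eval_fit <- function(th, want_fit = FALSE) {
    vc <- vc_project(config, th, sigma2_dummy, control$bend_eps)
    f <- tryCatch(
      {
        asm <- mme_assemble(prep, vc)
        Ch <<- mme_factor(asm$C, Ch)
        sv <- mme_solve(prep, asm, Ch)
        n_eval <<- n_eval + 1L
        c(sv, list(asm = asm, Ch = Ch, vc = vc))
      },
      error = function(e) NULL
    )
    if (is.null(f)) {
      return(if (want_fit) NULL else Inf)
    }
    if (want_fit) f else f$minus2logL
  }

  fit <- eval_fit(theta, want_fit = TRUE)
  if (is.null(fit)) stop("starting values give a singular system", call. = FALSE)
  theta <- vc_free_values(fit$vc)
  m2l <- fit$minus2logL
  trace <- list(tibble::tibble(
    iter = 0L, minus2logL = m2l,
    max_rel_change = NA_real_, step = "init"
  ))
  status <- "max_iterations"
  AI <- NULL
  free_map <- map[map$free, ]
  var_of <- function(comp) {
    which(free_map$row == comp & free_map$col == comp)
  }
  for (it in seq_len(control$max_iter)) {
    g <- fd_gradient(prep, fit$vc, eval_fit, control$fd_rel)
    AI <- ai_matrix(prep, fit)
    ## active-set treatment of the positivity boundary: a variance that
    ## has decayed to (numerically) zero and whose score does not pull it
    ## back into the interior is frozen, together with any covariance
    ## touching it (pinned near zero by the cone anyway); the Newton
    ## system is solved on the active set, whose curvature is not
    ## poisoned by the near-singular component
    nfree <- length(theta)
    vt_ix <- which(free_map$row == free_map$col)
    maxvar <- max(theta[vt_ix])
    frozen <- rep(FALSE, nfree)
    for (i in vt_ix) {
      if (theta[i] <= 1e-4 * maxvar && g[i] >= 0) frozen[i] <- TRUE
    }
    for (i in setdiff(seq_len(nfree), vt_ix)) {
      rv <- var_of(free_map$row[i])
      cv <- var_of(free_map$col[i])
      if ((length(rv) && frozen[rv]) || (length(cv) && frozen[cv])) {
        frozen[i] <- TRUE
      }
    }
    active <- !frozen
    dir <- numeric(nfree)
    dir[active] <- tryCatch(
      -solve(2 * AI[active, active, drop = FALSE], g[active]),
      error = function(e) -g[active] / pmax(diag(2 * AI)[active], 1e-12)
    )
    new_fit <- NULL
    step_kind <- "ai"
    ## a variance may not shrink below 20% of its current value in one
    ## step.  The clamp is per coordinate (a boundary-bound variance
    ## decays geometrically without throttling progress on the other
    ## parameters), which is a simple active-set treatment of the
    ## positivity constraints.
    var_terms <- which(vapply(names(g), function(nm) {
      k <- match(nm, fit$vc$map$term)
      fit$vc$map$row[k] == fit$vc$map$col[k]
    }, logical(1)))
    step_to <- function(lam) {
      cand <- theta + lam * dir
      cand[var_terms] <- pmax(cand[var_terms], 0.2 * theta[var_terms])
      cand
    }
    ## expected decrease along the feasible (clamped) step; once it falls
    ## below the numerical resolution of the likelihood evaluation the
    ## surface is flat and the fit has converged
    pred_dec <- -sum(g * (step_to(1) - theta)) / 2
    noise_floor <- max(control$tol_ll, 1e-8 * abs(m2l))
    if (is.finite(pred_dec) && pred_dec >= 0 && pred_dec < noise_floor) {
      status <- "converged"
      break
    }
    lam <- 1
    ## accept any decrease, allowing for the numerical noise floor of the
    ## likelihood evaluation (relative ~1e-9)
    accept_tol <- max(1e-10, 1e-9 * abs(m2l))
    best_try <- Inf
    for (h in 0:control$max_halving) {
      cand <- step_to(lam)
      f_try <- eval_fit(cand, want_fit = TRUE)
      if (!is.null(f_try) && is.finite(f_try$minus2logL)) {
        best_try <- min(best_try, f_try$minus2logL)
        if (f_try$minus2logL <= m2l + accept_tol) {
          new_fit <- f_try
          if (h > 0) step_kind <- "ai_halved"
          break
        }
      }
      lam <- lam / 2
    }
    if (is.null(new_fit)) {
      ## no decrease found: converged if the Newton displacement or the
      ## expected gain is negligible, or if the best candidate differs
      ## from the current point by less than the evaluation noise (the
      ## surface is flat to numerical precision); otherwise a genuine
      ## boundary failure
      dir_rel <- max(abs(dir) / theta_scales(fit$vc)[names(g)])
      status <- if (dir_rel < 1e-4 || pred_dec < 10 * noise_floor ||
        best_try <= m2l + noise_floor) {
        "converged"
      } else {
        "boundary"
      }
      break
    }
    new_theta <- vc_free_values(new_fit$vc)
    sc <- theta_scales(new_fit$vc)[names(new_theta)]
    rel <- max(abs(new_theta - theta) / sc)
    dll <- m2l - new_fit$minus2logL
    trace[[length(trace) + 1L]] <- tibble::tibble(
      iter = it, minus2logL = new_fit$minus2logL,
      max_rel_change = rel, step = step_kind
    )
    if (control$verbose) {
      message(sprintf(
        "iter %3d  -2logL %.6f  d(-2logL) %.3g  max rel change %.3g",
        it, new_fit$minus2logL, dll, rel
      ))
    }
    ## a variance still decaying geometrically toward the boundary has
    ## not finished moving even when the deviance change per step looks
    ## small; hold off convergence until it is numerically negligible
    decaying <- any(
      new_theta[var_terms] <= 0.2001 * theta[var_terms] &
        new_theta[var_terms] > 1e-5 * max(new_theta[var_terms])
    )
    theta <- new_theta
    m2l <- new_fit$minus2logL
    fit <- new_fit
    if ((rel < control$tol_par || dll < control$tol_ll) && !decaying) {
      status <- "converged"
      break
    }
  }
  if (is.null(AI)) AI <- ai_matrix(prep, fit)
  vcov_par <- tryCatch(solve(AI), error = function(e) {
    matrix(NA_real_, nrow(AI), ncol(AI), dimnames = dimnames(AI))
  })
  se <- sqrt(pmax(diag(vcov_par), 0))
  sol <- solution_tibbles(prep, fit)
  structure(
    list(
      vc = fit$vc, theta = theta, se = se, vcov = vcov_par,
      minus2logL = m2l, converged = status == "converged", status = status,
      trace = dplyr::bind_rows(trace), config = config,
      n = length(prep$y), n_params = length(theta), n_evaluations = n_eval,
      fixed = sol$fixed, ebv = sol$ebv, env = sol$env,
      residuals = sol$residuals,
      sigma2_dummy = fit$vc$sigma2_dummy
    ),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(
    "<reml_fit> model ", x$config$model, " (", x$config$traits, " trait",
    if (x$config$traits > 1) "s", "), ", x$n, " records\n",
    "  -2logL = ", format(x$minus2logL, digits = 12),
    ", status: ", x$status, " (", nrow(x$trace) - 1L, " iterations)\n",
    sep = ""
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a REML fit
#'
#' One row per free (co)variance parameter with its estimate and the
#' approximate standard error from the inverse average-information
#' matrix.
#'
#' @param x A [reml()] fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = unname(x$se[names(x$theta)])
  )
}

#' One-line summary of a REML fit
#'
#' @param x A [reml()] fit.
#' @param ... Unused.
#' @return A one-row tibble: model, number of records, free parameters,
#'   `-2 logL`, heritability and the direct-maternal correlations of the
#'   first trait, convergence status.
#' @export
glance.reml_fit <- function(x, ...) {
  dr <- derived_ratios(x$vc)
  tibble::tibble(
    model = x$config$model,
    n = x$n,
    n_params = x$n_params,
    minus2logL = x$minus2logL,
    h2 = dr$h2[1],
    r_am = dr$r_am[1],
    r_epe = dr$r_epe[1],
    converged = x$converged,
    iterations = nrow(x$trace) - 1L
  )
}

#' Likelihood-ratio test between nested maternal models
#'
#' The statistic is the difference in `-2 logL` between the nested and the
#' full model; degrees of freedom are the difference in free-parameter
#' counts.  When a variance parameter lies on the boundary under the
#' nested model the naive chi-square reference is conservative; no
#' boundary mixture correction is applied.
#'
#' @param nested,full Two [reml()] fits on the same data, with the nested
#'   model's free parameters a subset of the full model's.
#' @param tol Tolerance for flagging a negative statistic (a symptom of
#'   non-convergence).
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
lrt <- function(nested, full, tol = 0.01) {
  if (!inherits(nested, "reml_fit") || !inherits(full, "reml_fit")) {
    stop("lrt() expects two reml_fit objects", call. = FALSE)
  }
  t_n <- names(nested$theta)
  t_f <- names(full$theta)
  if (!all(t_n %in% t_f)) {
    stop("models are not nested: ", paste(setdiff(t_n, t_f), collapse = ", "),
      " not in the full model",
      call. = FALSE
    )
  }
  if (nested$n != full$n) {
    stop("fits use different numbers of records", call. = FALSE)
  }
  stat <- nested$minus2logL - full$minus2logL
  if (stat < -tol) {
    warning("negative likelihood-ratio statistic (", format(stat),
      "): convergence failure in one of the fits",
      call. = FALSE
    )
  }
  stat <- max(stat, 0)
  df <- length(t_f) - length(t_n)
  tibble::tibble(
    statistic = stat, df = df,
    p.value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  )
}

## ---------------------------------------------------------------------
## Single iterations, exposed for diagnostics and small-scale study.

#' One average-information REML iteration
#'
#' Performs a single Newton step with the exact average-information
#' curvature and finite-difference score, with step-halving and bending.
#' Only free parameters change; the dummy variance and masked entries are
#' untouched.
#'
#' @inheritParams reml
#' @param vc Current [variance_components()].
#' @return A list with the updated `vc`, `minus2logL` before and after,
#'   the `gradient` and the `ai` matrix.
#' @export
ai_step <- function(data, pedigree, config, vc, fixed = NULL,
                    use_inbreeding = TRUE, control = reml_control()) {
  if (is.character(config)) config <- model_config(config)
  pedigree <- check_pedigree(pedigree)
  design <- build_design(data, pedigree, config, fixed = fixed)
  prep <- mme_prep(design, pedigree, use_inbreeding = use_inbreeding)
  asm0 <- mme_assemble(prep, vc_reference(config, vc$sigma2_dummy))
  Ch <- mme_factor(asm0$C)
  eval_m2l <- function(th) {
    v <- vc_project(config, th, vc$sigma2_dummy, control$bend_eps)
    asm <- mme_assemble(prep, v)
    Ch <<- mme_factor(asm$C, Ch)
    mme_solve(prep, asm, Ch)$minus2logL
  }
  fit <- mme_fit(prep, vc, Ch)
  Ch <- fit$Ch
  g <- fd_gradient(prep, vc, eval_m2l, control$fd_rel)
  AI <- ai_matrix(prep, fit)
  dir <- tryCatch(
    -solve(2 * AI, g),
    error = function(e) -g / pmax(diag(2 * AI), 1e-12)
  )
  theta <- vc_free_values(vc)
  lam <- 1
  out_vc <- vc
  m2l_new <- fit$minus2logL
  for (h in 0:control$max_halving) {
    cand <- vc_project(config, theta + lam * dir, vc$sigma2_dummy, control$bend_eps)
    m2l_try <- tryCatch(
      {
        asm <- mme_assemble(prep, cand)
        Ch <- mme_factor(asm$C, Ch)
        mme_solve(prep, asm, Ch)$minus2logL
      },
      error = function(e) Inf
    )
    if (is.finite(m2l_try) && m2l_try <= fit$minus2logL + 1e-10) {
      out_vc <- cand
      m2l_new <- m2l_try
      break
    }
    lam <- lam / 2
  }
  list(
    vc = out_vc, minus2logL = fit$minus2logL, minus2logL_new = m2l_new,
    gradient = g, ai = AI
  )
}

#' One expectation-maximization REML iteration
#'
#' Closed-form EM update for single-trait models, using the exact
#' conditional (co)variances of the random effects from a dense inverse
#' of the coefficient matrix; therefore limited to small and medium
#' systems (the production path is [reml()]).  When Cov(e, pe) is free,
#' individuals missing one of the two environmental components are
#' completed with their conditional moments (an exact
#' missing-data EM on the augmented model); with Cov(e, pe) masked the
#' variance updates decouple and are exact directly.  Only free
#' parameters change; masked entries stay zero and the dummy variance is
#' never updated.  Each EM step cannot increase `-2 logL`.
#'
#' @inheritParams ai_step
#' @param max_dim Guard on the coefficient-matrix dimension for the dense
#'   inverse.
#' @return A list with the updated `vc` and the input `minus2logL`.
#' @export
em_step <- function(data, pedigree, config, vc, fixed = NULL,
                    use_inbreeding = TRUE, max_dim = 4000L) {
  if (is.character(config)) config <- model_config(config)
  if (config$traits != 1L) {
    stop("em_step() is implemented for single-trait models; use ai_step()",
      call. = FALSE
    )
  }
  pedigree <- check_pedigree(pedigree)
  design <- build_design(data, pedigree, config, fixed = fixed)
  prep <- mme_prep(design, pedigree, use_inbreeding = use_inbreeding, absorb = FALSE)
  if (prep$dim > max_dim) {
    stop("system dimension ", prep$dim, " exceeds max_dim for the dense EM step",
      call. = FALSE
    )
  }
  fit <- mme_fit(prep, vc)
  Cinv <- solve(as.matrix(fit$asm$C))
  p <- prep$p
  N <- prep$N
  qg <- prep$qg
  map <- vc$map
  ## --- genetic matrix -------------------------------------------------
  Ainv <- prep$Ainv
  At <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")
  tr_ainv_block <- function(k, l) {
    rows <- p + (k - 1L) * N + (At@i + 1L)
    cols <- p + (l - 1L) * N + (At@j + 1L)
    sum(At@x * Cinv[cbind(rows, cols)])
  }
  u_g <- function(k) fit$sol[p + (k - 1L) * N + seq_len(N)]
  G0 <- vc$G0
  freeG <- free_pattern_matrix(vc, "G0")
  for (k in seq_len(qg)) {
    for (l in k:qg) {
      if (!freeG[k, l]) next
      uk <- u_g(k)
      ul <- u_g(l)
      quad <- sum(uk * as.numeric(Ainv %*% ul))
      G0[k, l] <- G0[l, k] <- (quad + tr_ainv_block(k, l)) / N
    }
  }
  ## --- environmental matrix -------------------------------------------
  env_off <- p + qg * N
  ec_tab <- prep$env_cols
  E0 <- vc$E0
  freeE <- free_pattern_matrix(vc, "E0")
  if (!vc$config$cor_epe) {
    for (comp in rownames(E0)) {
      rows <- ec_tab[ec_tab$comp == comp, ]
      if (!nrow(rows)) next
      ix <- env_off + rows$col
      E0[comp, comp] <- (sum(fit$sol[ix]^2) + sum(diag(Cinv)[ix])) / nrow(rows)
    }
  } else {
    ## complete each individual to the full (e, pe) pair
    ids <- unique(ec_tab$.an)
    S <- matrix(0, 2, 2, dimnames = list(c("e", "pe"), c("e", "pe")))
    for (id in ids) {
      rows <- ec_tab[ec_tab$.an == id, ]
      pres <- rows$comp
      ix <- env_off + rows$col
      u_p <- fit$sol[ix]
      C_pp <- Cinv[ix, ix, drop = FALSE]
      Euu <- matrix(0, 2, 2, dimnames = list(c("e", "pe"), c("e", "pe")))
      M1 <- tcrossprod(u_p) + C_pp
      Euu[pres, pres] <- M1
      miss <- setdiff(c("e", "pe"), pres)
      if (length(miss)) {
        B <- E0[miss, pres, drop = FALSE] %*% solve(E0[pres, pres, drop = FALSE])
        cond <- E0[miss, miss, drop = FALSE] -
          B %*% E0[pres, miss, drop = FALSE]
        Euu[miss, pres] <- B %*% M1
        Euu[pres, miss] <- t(Euu[miss, pres])
        Euu[miss, miss] <- B %*% M1 %*% t(B) + cond
      }
      S <- S + Euu
    }
    E0new <- S / length(ids)
    E0[freeE] <- E0new[freeE]
    E0[!freeE & row(E0) != col(E0)] <- 0
  }
  out <- structure(
    list(
      config = vc$config, G0 = G0, E0 = E0,
      sigma2_dummy = vc$sigma2_dummy, map = map
    ),
    class = "variance_components"
  )
  list(vc = out, minus2logL = fit$minus2logL)
}
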