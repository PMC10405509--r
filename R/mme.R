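## Sparse Henderson mixed-model equations for the maternal animal model
## with the dummy-residual reparameterization.
##
## The only least-squares residual in the equations is the fixed dummy
## variance; the usual residual e enters as a random effect per record so
## that it can covary with the dam's permanent environmental effect.
## An e level whose component cannot covary with anything (every record
## when Cov(e, pe) is masked; every non-dam record otherwise) is absorbed
## exactly into a record-level residual of variance sigma2_e +
## sigma2_dummy; its BLUP is recovered analytically afterwards.  This is
## plain marginalization, so likelihoods and solutions are identical to
## the fully explicit system (which the dense-oracle tests verify).

mme_prep <- function(design, pedigree, use_inbreeding = TRUE, absorb = TRUE) {
  config <- design$config
  rec <- design$records
  N <- design$n_animals
  gf <- genetic_factors(config)
  qg <- length(gf)
  p <- ncol(design$X)
  f <- inbreeding_vec(pedigree, use_inbreeding)
  Ainv <- a_inverse(pedigree, use_inbreeding)
  ldetA <- a_logdet(pedigree, f)

  ## ---- explicit environmental levels -------------------------------
  pe <- design$pe_levels
  dam_set <- unique(pe$.dam)
  has_record <- rec$.an[match(dam_set, rec$.an)]
  explicit_e_an <- if (!absorb) {
    unique(rec$.an)
  } else if (config$cor_epe) {
    dam_set[!is.na(has_record)]
  } else {
    integer(0)
  }

  e_comp <- function(t) if (config$traits == 1L) "e" else c("e_F", "e_M")[t]
  pe_comp <- function(g) if (config$traits == 1L) "pe" else c("pe_F", "pe_M")[g]
  env_ids <- sort(unique(c(explicit_e_an, pe$.dam)))
  env_cols <- purrr::map_dfr(env_ids, function(id) {
    comps <- character(0)
    if (id %in% explicit_e_an) {
      comps <- e_comp(rec$trait[match(id, rec$.an)])
    }
    gs <- sort(pe$group[pe$.dam == id])
    comps <- c(comps, pe_comp(gs))
    tibble::tibble(.an = id, comp = comps)
  })
  if (nrow(env_cols)) env_cols$col <- seq_len(nrow(env_cols))
  m_env <- nrow(env_cols)
  dim_c <- p + qg * N + m_env

  env_key <- paste(env_cols$.an, env_cols$comp)
  rec_explicit <- rec$.an %in% explicit_e_an

  ## ---- data part of the equations ----------------------------------
  a_fac <- function(t) if (config$traits == 1L) "a" else c("a_F", "a_M")[t]
  m_fac <- function(t) if (config$traits == 1L) "m" else c("m_F", "m_M")[t]
  Xt <- methods::as(design$X, "TsparseMatrix")
  ti <- Xt@i + 1L
  tj <- Xt@j + 1L
  tx <- Xt@x
  ## direct genetic effect
  ti <- c(ti, rec$row)
  tj <- c(tj, p + (match(a_fac(rec$trait), gf) - 1L) * N + rec$.an)
  tx <- c(tx, rep(1, nrow(rec)))
  ## maternal genetic effect
  if (config$include_maternal) {
    has_dam <- rec$.dam > 0L
    ti <- c(ti, rec$row[has_dam])
    tj <- c(tj, p + (match(m_fac(rec$trait[has_dam]), gf) - 1L) * N + rec$.dam[has_dam])
    tx <- c(tx, rep(1, sum(has_dam)))
  }
  ## permanent environmental effect of the dam
  has_dam <- rec$.dam > 0L
  pe_cols <- env_cols$col[match(
    paste(rec$.dam[has_dam], pe_comp(rec$trait[has_dam])), env_key
  )]
  ti <- c(ti, rec$row[has_dam])
  tj <- c(tj, p + qg * N + pe_cols)
  tx <- c(tx, rep(1, sum(has_dam)))
  ## explicit residual level (the dam's own e)
  if (any(rec_explicit)) {
    er <- which(rec_explicit)
    e_cols <- env_cols$col[match(paste(rec$.an[er], e_comp(rec$trait[er])), env_key)]
    ti <- c(ti, er)
    tj <- c(tj, p + qg * N + e_cols)
    tx <- c(tx, rep(1, length(er)))
  }
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nrow(rec), dim_c))

  ## residual groups: explicit rows see only the dummy variance; absorbed
  ## rows see sigma2_e(trait) + sigma2_dummy
  groups <- list()
  if (any(rec_explicit)) {
    groups <- c(groups, list(list(rows = which(rec_explicit), type = "explicit")))
  }
  for (t in seq_len(config$traits)) {
    rows <- which(!rec_explicit & rec$trait == t)
    if (length(rows)) groups <- c(groups, list(list(rows = rows, type = t)))
  }
  y <- rec$y
  for (g in seq_along(groups)) {
    rows <- groups[[g]]$rows
    Mg <- M[rows, , drop = FALSE]
    groups[[g]]$K <- Matrix::crossprod(Mg)
    groups[[g]]$r <- as.numeric(Matrix::crossprod(Mg, y[rows]))
    groups[[g]]$yy <- sum(y[rows]^2)
    groups[[g]]$n <- length(rows)
  }

  ## ---- genetic precision templates (one per factor pair) ------------
  At <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")
  ai <- At@i + 1L
  aj <- At@j + 1L
  ax <- At@x
  gpairs <- list()
  for (k in seq_len(qg)) {
    for (l in k:qg) {
      if (k == l) {
        T_ <- Matrix::sparseMatrix(
          i = p + (k - 1L) * N + ai, j = p + (k - 1L) * N + aj, x = ax,
          dims = c(dim_c, dim_c)
        )
      } else {
        T_ <- Matrix::sparseMatrix(
          i = c(p + (k - 1L) * N + ai, p + (l - 1L) * N + ai),
          j = c(p + (l - 1L) * N + aj, p + (k - 1L) * N + aj),
          x = c(ax, ax),
          dims = c(dim_c, dim_c)
        )
      }
      gpairs[[paste(k, l)]] <- T_
    }
  }

  ## ---- environmental precision template ----------------------------
  ## individuals grouped by component pattern; per group, positions of the
  ## full-symmetric inverse-block entries
  env_groups <- list()
  if (m_env) {
    sig <- vapply(split(env_cols$comp, env_cols$.an), paste, collapse = "|", FUN.VALUE = "")
    for (s in unique(sig)) {
      ids <- as.integer(names(sig)[sig == s])
      comps <- strsplit(s, "|", fixed = TRUE)[[1]]
      nc <- length(comps)
      cols <- matrix(
        env_cols$col[match(
          paste(rep(ids, each = nc), comps), env_key
        )],
        nrow = nc
      ) # nc x n_ids
      ii <- jj <- integer(0)
      ent <- integer(0) # which entry of the nc x nc inverse block
      for (r1 in seq_len(nc)) {
        for (r2 in seq_len(nc)) {
          ii <- c(ii, p + qg * N + cols[r1, ])
          jj <- c(jj, p + qg * N + cols[r2, ])
          ent <- c(ent, rep((r2 - 1L) * nc + r1, ncol(cols)))
        }
      }
      env_groups[[s]] <- list(comps = comps, n = length(ids), i = ii, j = jj, entry = ent)
    }
  }

  prep <- list(
    design = design, config = config, N = N, p = p, qg = qg, gf = gf,
    m_env = m_env, dim = dim_c, y = y, M = M,
    groups = groups, gpairs = gpairs, env_groups = env_groups,
    env_cols = env_cols, rec_explicit = rec_explicit,
    Ainv = Ainv, ldetA = ldetA, f = f,
    pedigree_animal = pedigree$animal,
    ped_sire = pedigree$.sire, ped_dam = pedigree$.dam
  )
  prep$fastmap <- build_fastmap(prep)
  prep
}

## Precomputed map from each component's nonzeros into the slots of the
## union-pattern coefficient matrix, so that assembly is a handful of
## vector scatter-adds instead of repeated sparse-matrix additions.
build_fastmap <- function(prep) {
  ref <- mme_assemble(prep, vc_reference(prep$config, 1))
  Ct <- methods::as(ref$C, "TsparseMatrix")
  dimn <- as.numeric(prep$dim)
  okey <- as.numeric(Ct@j) * dimn + as.numeric(Ct@i)
  upper_key <- function(M) {
    Tt <- methods::as(M, "TsparseMatrix")
    keep <- Tt@i <= Tt@j
    list(
      key = as.numeric(Tt@j[keep]) * dimn + as.numeric(Tt@i[keep]),
      x = Tt@x[keep]
    )
  }
  map_of <- function(uk) {
    idx <- match(uk$key, okey)
    if (anyNA(idx)) stop("internal error: component entry outside union pattern")
    list(idx = idx, x = uk$x)
  }
  groups <- lapply(prep$groups, function(g) map_of(upper_key(g$K)))
  gpairs <- lapply(prep$gpairs, function(T_) map_of(upper_key(T_)))
  env <- lapply(prep$env_groups, function(eg) {
    keep <- eg$i <= eg$j
    key <- as.numeric(eg$j[keep] - 1) * dimn + as.numeric(eg$i[keep] - 1)
    idx <- match(key, okey)
    if (anyNA(idx)) stop("internal error: env entry outside union pattern")
    list(idx = idx, entry = eg$entry[keep], comps = eg$comps, n = eg$n)
  })
  list(template = ref$C, nnz = length(Ct@x), groups = groups, gpairs = gpairs, env = env)
}

## Residual variance per record group under vc.
group_resvar <- function(prep, vc) {
  e_var <- function(t) {
    if (prep$config$traits == 1L) vc$E0["e", "e"] else vc$E0[c("e_F", "e_M")[t], c("e_F", "e_M")[t]]
  }
  vapply(prep$groups, function(g) {
    if (identical(g$type, "explicit")) vc$sigma2_dummy else e_var(g$type) + vc$sigma2_dummy
  }, numeric(1))
}

mme_assemble <- function(prep, vc) {
  qg <- prep$qg
  G0 <- vc$G0
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("G0 is not positive definite; assembly refused", call. = FALSE)
  G0inv <- solve(G0)
  rv <- group_resvar(prep, vc)
  if (any(rv <= 0)) stop("non-positive residual variance", call. = FALSE)
  if (!is.null(prep$fastmap)) {
    return(mme_assemble_fast(prep, vc, G0inv, rv))
  }

  C <- NULL
  rhs <- numeric(prep$dim)
  yRy <- 0
  ldet_R <- 0
  for (g in seq_along(prep$groups)) {
    gg <- prep$groups[[g]]
    term <- (1 / rv[g]) * gg$K
    C <- if (is.null(C)) term else C + term
    rhs <- rhs + gg$r / rv[g]
    yRy <- yRy + gg$yy / rv[g]
    ldet_R <- ldet_R + gg$n * log(rv[g])
  }
  for (k in seq_len(qg)) {
    for (l in k:qg) {
      C <- C + G0inv[k, l] * prep$gpairs[[paste(k, l)]]
    }
  }
  ldet_env <- 0
  if (prep$m_env) {
    ii <- jj <- xx <- NULL
    for (eg in prep$env_groups) {
      B <- vc$E0[eg$comps, eg$comps, drop = FALSE]
      evb <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
      if (min(evb) <= 0) {
        stop("environmental covariance block is singular; assembly refused", call. = FALSE)
      }
      Binv <- solve(B)
      ii <- c(ii, eg$i)
      jj <- c(jj, eg$j)
      xx <- c(xx, as.numeric(Binv)[eg$entry])
      ldet_env <- ldet_env + eg$n * as.numeric(determinant(B, logarithm = TRUE)$modulus)
    }
    C <- C + Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(prep$dim, prep$dim))
  }
  C <- Matrix::forceSymmetric(C)
  ldet_sigma <- prep$N * as.numeric(determinant(G0, logarithm = TRUE)$modulus) +
    qg * prep$ldetA + ldet_env
  list(
    C = C, rhs = rhs, yRy = yRy,
    ldet_R = ldet_R, ldet_sigma = ldet_sigma,
    rv = rv, G0inv = G0inv
  )
}

## Fast assembly through the precomputed slot map.
mme_assemble_fast <- function(prep, vc, G0inv, rv) {
  fm <- prep$fastmap
  xv <- numeric(fm$nnz)
  rhs <- numeric(prep$dim)
  yRy <- 0
  ldet_R <- 0
  for (g in seq_along(prep$groups)) {
    gm <- fm$groups[[g]]
    xv[gm$idx] <- xv[gm$idx] + gm$x / rv[g]
    gg <- prep$groups[[g]]
    rhs <- rhs + gg$r / rv[g]
    yRy <- yRy + gg$yy / rv[g]
    ldet_R <- ldet_R + gg$n * log(rv[g])
  }
  qg <- prep$qg
  for (k in seq_len(qg)) {
    for (l in k:qg) {
      gm <- fm$gpairs[[paste(k, l)]]
      xv[gm$idx] <- xv[gm$idx] + G0inv[k, l] * gm$x
    }
  }
  ldet_env <- 0
  for (eg in fm$env) {
    B <- vc$E0[eg$comps, eg$comps, drop = FALSE]
    evb <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    if (min(evb) <= 0) {
      stop("environmental covariance block is singular; assembly refused", call. = FALSE)
    }
    Binv <- solve(B)
    xv[eg$idx] <- xv[eg$idx] + as.numeric(Binv)[eg$entry]
    ldet_env <- ldet_env + eg$n * as.numeric(determinant(B, logarithm = TRUE)$modulus)
  }
  C <- fm$template
  C@x <- xv
  ldet_sigma <- prep$N * as.numeric(determinant(vc$G0, logarithm = TRUE)$modulus) +
    qg * prep$ldetA + ldet_env
  list(
    C = C, rhs = rhs, yRy = yRy,
    ldet_R = ldet_R, ldet_sigma = ldet_sigma,
    rv = rv, G0inv = G0inv
  )
}

## Reference components for the symbolic factorization: every free
## covariance set to a small nonzero correlation so the analyzed pattern
## is the union over the whole iteration path.
vc_reference <- function(config, sigma2_dummy = 1) {
  map <- parameter_map(config)
  vals <- numeric(0)
  for (k in which(map$free)) {
    vals[map$term[k]] <- if (map$row[k] == map$col[k]) 1 else 0.01
  }
  variance_components(config, vals, sigma2_dummy = sigma2_dummy)
}

mme_factor <- function(C, cache = NULL) {
  if (is.null(cache)) {
    Matrix::Cholesky(C, LDL = FALSE, super = NA, perm = TRUE)
  } else {
    Matrix::update(cache, C)
  }
}

## Solve the assembled system; returns solutions and the restricted
## deviance -2 logL = log|C| + log|Sigma| + log|R| + y'Py (the (n-p)log 2pi
## constant is omitted throughout, consistently with the dense oracle).
mme_solve <- function(prep, asm, Ch) {
  sol <- as.numeric(Matrix::solve(Ch, asm$rhs, system = "A"))
  logdetC <- as.numeric(Matrix::determinant(Ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  yPy <- asm$yRy - sum(asm$rhs * sol)
  m2l <- logdetC + asm$ldet_sigma + asm$ldet_R + yPy
  list(sol = sol, minus2logL = m2l, logdetC = logdetC, yPy = yPy)
}

## Record-space residual r = y - M sol and its scaled version Py = R^-1 r.
mme_residuals <- function(prep, asm, sol) {
  r <- prep$y - as.numeric(prep$M %*% sol)
  rv_rec <- numeric(length(r))
  for (g in seq_along(prep$groups)) rv_rec[prep$groups[[g]]$rows] <- asm$rv[g]
  list(resid = r, Py = r / rv_rec, rv_rec = rv_rec)
}

## Full fit at fixed variance components (assemble + factor + solve).
mme_fit <- function(prep, vc, cache = NULL) {
  asm <- mme_assemble(prep, vc)
  Ch <- mme_factor(asm$C, cache)
  sv <- mme_solve(prep, asm, Ch)
  c(sv, list(asm = asm, Ch = Ch, vc = vc))
}

## ---------------------------------------------------------------------
## User-facing solution extraction

solution_tibbles <- function(prep, fit) {
  config <- prep$config
  sol <- fit$sol
  p <- prep$p
  N <- prep$N
  qg <- prep$qg
  fixed <- tibble::tibble(term = prep$design$x_names, estimate = sol[seq_len(p)])
  gen <- purrr::map_dfr(seq_len(qg), function(k) {
    tibble::tibble(
      factor = prep$gf[k],
      animal = prep$pedigree_animal,
      value = sol[p + (k - 1L) * N + seq_len(N)]
    )
  })
  ebv <- tidyr::pivot_wider(gen, names_from = "factor", values_from = "value")
  env <- NULL
  if (prep$m_env) {
    env <- tibble::tibble(
      animal = prep$pedigree_animal[prep$env_cols$.an],
      component = prep$env_cols$comp,
      value = sol[p + qg * N + prep$env_cols$col]
    )
  }
  ## residual effects: explicit from their level, absorbed recovered
  rr <- mme_residuals(prep, fit$asm, sol)
  rec <- prep$design$records
  e_hat <- numeric(nrow(rec))
  if (any(prep$rec_explicit)) {
    er <- which(prep$rec_explicit)
    e_comp <- function(t) if (config$traits == 1L) "e" else c("e_F", "e_M")[t]
    key <- paste(prep$env_cols$.an, prep$env_cols$comp)
    cols <- prep$env_cols$col[match(paste(rec$.an[er], e_comp(rec$trait[er])), key)]
    e_hat[er] <- sol[p + qg * N + cols]
  }
  ab <- which(!prep$rec_explicit)
  if (length(ab)) {
    e_var <- function(t) {
      if (config$traits == 1L) fit$vc$E0["e", "e"] else fit$vc$E0[c("e_F", "e_M")[t], c("e_F", "e_M")[t]]
    }
    sev <- vapply(rec$trait[ab], e_var, numeric(1))
    e_hat[ab] <- sev / (sev + fit$vc$sigma2_dummy) * rr$resid[ab]
  }
  residuals <- tibble::tibble(
    animal = rec$animal, trait = rec$trait,
    y = rec$y,
    fixed_fitted = as.numeric(prep$design$X %*% sol[seq_len(p)]),
    e = e_hat, dummy = rr$resid - e_hat
  )
  list(fixed = fixed, ebv = ebv, env = env, residuals = residuals)
}

#' Solve the mixed-model equations at fixed variance components (BLUP)
#'
#' Assembles and solves the sparse Henderson equations for the chosen
#' model, returning fixed-effect solutions and BLUPs of the direct
#' genetic effect `a` (all pedigree animals), the maternal genetic effect
#' `m` (when modeled), the permanent environmental effect `pe` (linked
#' dams) and the residual-as-random-effect `e` (every record; the dummy
#' residual is the remainder).
#'
#' @inheritParams dense_mixed_model_oracle
#' @param use_inbreeding Use inbreeding-adjusted A-inverse (default TRUE).
#' @return An object of class `blup_solution`: a list with tibbles
#'   `fixed`, `ebv` (one row per animal, one column per genetic factor),
#'   `env` (explicit e/pe levels), `residuals`, plus `minus2logL`, `vc`,
#'   `config`.
#' @examples
#' \donttest{
#' pop <- run_program(sim_config(
#'   n_sr = 3, n_males_selected = 2,
#'   n_females_selected = 20, offspring_per_sr = 80, random_until_sr = 3
#' ), seed = 1)
#' cfg <- model_config("modam")
#' vc <- variance_components(cfg, c(
#'   sigma2_a = 8000, sigma2_m = 800,
#'   sigma2_e = 20000, sigma2_pe = 900
#' ))
#' sol <- blup(pop$phenotypes, pop$pedigree, cfg, vc)
#' head(sol$ebv)
#' }
#' @export
blup <- function(data, pedigree, config, vc, fixed = NULL, use_inbreeding = TRUE) {
  pedigree <- check_pedigree(pedigree)
  design <- build_design(data, pedigree, config, fixed = fixed)
  prep <- mme_prep(design, pedigree, use_inbreeding = use_inbreeding)
  fit <- mme_fit(prep, vc)
  out <- solution_tibbles(prep, fit)
  structure(
    c(out, list(
      minus2logL = fit$minus2logL, vc = vc, config = config,
      n = nrow(design$records)
    )),
    class = "blup_solution"
  )
}

#' @export
print.blup_solution <- function(x, ...) {
  cat(
    "<blup_solution> model ", x$config$model, ", ", x$n, " records, -2logL = ",
    format(x$minus2logL, digits = 10), "\n",
    sep = ""
  )
  invisible(x)
}

#' Restricted likelihood at given variance components
#'
#' Evaluates minus twice the restricted log-likelihood of the maternal
#' animal model via the sparse mixed-model equations:
#' `-2logL = log|C| + log|Sigma| + log|R| + y'Py`, where C is the
#' coefficient matrix, Sigma the random-effect covariance and R the fixed
#' dummy-residual covariance.  The additive constant `(n - p) log(2*pi)`
#' is omitted (the same convention as [dense_mixed_model_oracle()]).
#'
#' @inheritParams blup
#' @return Scalar `-2 logL` with attribute `pieces`.
#' @export
restricted_log_likelihood <- function(data, pedigree, config, vc, fixed = NULL,
                                      use_inbreeding = TRUE) {
  pedigree <- check_pedigree(pedigree)
  design <- build_design(data, pedigree, config, fixed = fixed)
  prep <- mme_prep(design, pedigree, use_inbreeding = use_inbreeding)
  fit <- mme_fit(prep, vc)
  structure(fit$minus2logL,
    pieces = c(
      logdetC = fit$logdetC, ldet_sigma = fit$asm$ldet_sigma,
      ldet_R = fit$asm$ldet_R, yPy = fit$yPy
    )
  )
}
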