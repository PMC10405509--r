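#' Tabular-method relationship matrix (reference implementation)
#'
#' Computes the full numerator relationship matrix A by the recursive
#' tabular method in plain R.  This is deliberately independent of the
#' sparse Henderson machinery in [a_inverse()] and is used as the test
#' oracle for it; it is only suitable for small pedigrees.
#'
#' @inheritParams inbreeding
#' @param max_animals Guard against accidental use at scale.
#' @return Dense symmetric matrix with animal ids as dimnames;
#'   diagonal equals 1 + F.
#' @export
tabular_relationship <- function(pedigree, max_animals = 1000L) {
  pedigree <- check_pedigree(pedigree)
  n <- nrow(pedigree)
  if (n > max_animals) {
    stop("tabular method is an oracle for small pedigrees (n <= ", max_animals, ")",
      call. = FALSE
    )
  }
  s <- pedigree$.sire
  d <- pedigree$.dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    above <- seq_len(i - 1L)
    row_s <- if (s[i] > 0L) A[s[i], above] else rep(0, i - 1L)
    row_d <- if (d[i] > 0L) A[d[i], above] else rep(0, i - 1L)
    if (i > 1L) {
      A[i, above] <- 0.5 * (row_s + row_d)
      A[above, i] <- A[i, above]
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(pedigree$animal, pedigree$animal)
  A
}

#' Dense mixed-model oracle
#'
#' Fits the maternal animal model by brute force: the full phenotypic
#' covariance matrix V is formed from the tabular A and the incidence
#' matrices, fixed effects are estimated by generalized least squares,
#' random effects by their posterior means, and the restricted likelihood
#' by the textbook dense formula.  Used to validate the sparse mixed-model
#' equations and the sparse restricted likelihood on small instances.
#'
#' @param data Phenotype data frame (see [build_design()]).
#' @param pedigree A [as_pedigree()] object.
#' @param config A [model_config()].
#' @param vc A [variance_components()] object for `config`.
#' @param fixed Optional fixed-effect formula, as in [build_design()].
#' @return List with elements `b` (fixed solutions), `u` (random-effect
#'   solutions named as in [blup()]), `minus2logL`, and `V`.
#' @export
dense_mixed_model_oracle <- function(data, pedigree, config, vc, fixed = NULL) {
  pedigree <- check_pedigree(pedigree)
  if (nrow(data) > 60) {
    stop("dense oracle is meant for small instances", call. = FALSE)
  }
  ds <- build_design(data, pedigree, config, fixed = fixed)
  A <- tabular_relationship(pedigree)
  inc <- design_incidence(ds, pedigree)
  X <- as.matrix(inc$X)
  y <- ds$records$y
  qg <- length(genetic_factors(config))
  G <- kronecker(vc$G0, A)
  U <- as.matrix(cbind(inc$Z, inc$B))
  Sig <- as.matrix(Matrix::bdiag(G, env_covariance_dense(ds, vc)))
  V <- U %*% Sig %*% t(U) + diag(vc$sigma2_dummy, nrow(X))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  XtViX <- XtVi %*% X
  b <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% b
  u <- Sig %*% t(U) %*% Vi %*% r
  m2l <- as.numeric(
    determinant(V, logarithm = TRUE)$modulus +
      determinant(XtViX, logarithm = TRUE)$modulus +
      t(r) %*% Vi %*% r
  )
  ## name the random-effect solutions
  N <- nrow(pedigree)
  gnames <- unlist(lapply(genetic_factors(config), function(f) {
    paste0(f, ".", pedigree$animal)
  }))
  list(
    b = stats::setNames(as.numeric(b), colnames(X)),
    u = stats::setNames(as.numeric(u), c(gnames, inc$env_names)),
    minus2logL = m2l,
    V = V
  )
}

#' Exhaustive-grid REML oracle
#'
#' Evaluates the restricted likelihood over an explicit grid of candidate
#' variance components (via the dense oracle machinery is not needed: the
#' sparse likelihood itself is evaluated, which the dense-equivalence
#' tests validate separately) and returns the grid optimum.  Intended for
#' problems with one or two free parameters.
#'
#' @inheritParams dense_mixed_model_oracle
#' @param grid A data frame; each row gives values for the parameters being
#'   searched (columns named like the free parameters of `config`), other
#'   parameters are taken from `vc`.
#' @return The `grid` tibble with a `minus2logL` column, sorted so the
#'   optimum is first; attribute `boundary` flags an optimum on the grid
#'   edge.
#' @export
grid_reml_oracle <- function(data, pedigree, config, vc, grid) {
  grid <- tibble::as_tibble(grid)
  m2l <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    vals <- vc_values(vc)
    vals[names(grid)] <- as.numeric(grid[i, ])
    vci <- variance_components(config, vals, sigma2_dummy = vc$sigma2_dummy)
    restricted_log_likelihood(data, pedigree, config, vci)
  })
  out <- dplyr::arrange(dplyr::mutate(grid, minus2logL = m2l), .data$minus2logL)
  edge <- vapply(names(grid), function(nm) {
    out[[nm]][1] %in% range(grid[[nm]])
  }, logical(1))
  attr(out, "boundary") <- any(edge)
  out
}
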