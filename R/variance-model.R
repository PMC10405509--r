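#' Model configuration for the maternal animal model family
#'
#' Five nested (co)variance structures are supported, all sharing the same
#' linear predictor `y = Xb + Za + Wm + Wpe + Be + dummy`:
#'
#' * `moda` - no maternal genetic effect; both direct-maternal covariances
#'   null (direct additive + permanent environmental dam effect only).
#' * `modam` - adds the maternal genetic effect `m`; covariances null.
#' * `coram` - additionally frees the direct-maternal genetic covariance
#'   Cov(a, m).
#' * `corepe` - maternal effect included; frees the direct-maternal
#'   environmental covariance Cov(e, pe) between the residual of the dam's
#'   own record and her permanent environmental effect; Cov(a, m) null.
#' * `coramepe` - both covariances free.
#'
#' With two traits the female and male body weights are treated as
#' distinct, genetically correlated traits measured on different animals;
#' each dam then carries one permanent environmental effect per offspring
#' sex, and only the female residual can covary with the maternal
#' environmental effects (males never contribute maternal effects, so the
#' corresponding covariances are structural zeros).
#'
#' @param model One of `"moda"`, `"modam"`, `"coram"`, `"corepe"`,
#'   `"coramepe"`.
#' @param traits 1 (single trait) or 2 (female/male body weight as
#'   separate traits).
#' @return An object of class `model_config`.
#' @examples
#' model_config("coramepe")
#' parameter_map(model_config("corepe", traits = 2))
#' @export
model_config <- function(model = c("moda", "modam", "coram", "corepe", "coramepe"),
                         traits = 1L) {
  model <- match.arg(tolower(model), c("moda", "modam", "coram", "corepe", "coramepe"))
  traits <- as.integer(traits)
  if (!traits %in% c(1L, 2L)) stop("traits must be 1 or 2", call. = FALSE)
  structure(
    list(
      model = model,
      traits = traits,
      include_maternal = model != "moda",
      cor_am = model %in% c("coram", "coramepe"),
      cor_epe = model %in% c("corepe", "coramepe")
    ),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(
    "<model_config> ", x$model, " (", x$traits, " trait",
    if (x$traits > 1) "s", ")\n",
    "  maternal genetic effect: ", x$include_maternal,
    "; Cov(a,m): ", x$cor_am, "; Cov(e,pe): ", x$cor_epe, "\n",
    sep = ""
  )
  invisible(x)
}

trait_names <- function(config) {
  if (config$traits == 1L) "t" else c("F", "M")
}

genetic_factors <- function(config) {
  if (config$traits == 1L) {
    if (config$include_maternal) c("a", "m") else "a"
  } else {
    f <- c("a_F", "a_M")
    if (config$include_maternal) f <- c(f, "m_F", "m_M")
    f
  }
}

env_components <- function(config) {
  if (config$traits == 1L) c("e", "pe") else c("e_F", "e_M", "pe_F", "pe_M")
}

cov_term_name <- function(f1, f2, traits) {
  n1 <- gsub("_", "", f1)
  n2 <- gsub("_", "", f2)
  if (traits == 1L) paste0("sigma_", n1, n2) else paste0("sigma_", n1, ".", n2)
}

var_term_name <- function(f) paste0("sigma2_", gsub("_", "", f))

#' Free-parameter structure of a model
#'
#' Lists every (co)variance parameter of the model's two structure
#' matrices (the genetic matrix G0 over the genetic factors and the
#' environmental matrix E0 over the residual and permanent environmental
#' components) plus the fixed dummy residual, with its address and
#' free/fixed status.  Structural zeros (masked entries) are exactly zero
#' and are never estimated; the dummy variance is a fixed constant.
#'
#' @param config A [model_config()].
#' @return A tibble with columns `term`, `matrix` (`"G0"`, `"E0"` or
#'   `"dummy"`), `row`, `col` (factor names) and `free`.
#' @export
parameter_map <- function(config) {
  gf <- genetic_factors(config)
  ec <- env_components(config)
  tr <- config$traits
  rows <- list()
  add <- function(mat, r, c, free, term) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      term = term, matrix = mat, row = r, col = c, free = free
    )
  }
  half_a <- function(f) substr(f, 1, 1) # "a"/"m"/"e"/"pe" part
  for (i in seq_along(gf)) {
    for (j in seq_len(i)) {
      f1 <- gf[j]
      f2 <- gf[i]
      if (i == j) {
        add("G0", f1, f2, TRUE, var_term_name(f1))
      } else {
        same_kind <- half_a(f1) == half_a(f2)
        free <- if (same_kind) TRUE else config$cor_am
        add("G0", f1, f2, free, cov_term_name(f1, f2, tr))
      }
    }
  }
  is_e <- function(f) f %in% c("e", "e_F", "e_M")
  for (i in seq_along(ec)) {
    for (j in seq_len(i)) {
      f1 <- ec[j]
      f2 <- ec[i]
      if (i == j) {
        add("E0", f1, f2, TRUE, var_term_name(f1))
        next
      }
      if (is_e(f1) && is_e(f2)) {
        free <- FALSE # residuals of different animals never covary
      } else if (!is_e(f1) && !is_e(f2)) {
        free <- TRUE # pe_F with pe_M (same dam)
      } else {
        ## e with pe: only the female residual can covary with maternal
        ## environmental effects, and only when the model frees Cov(e, pe)
        male_e <- (is_e(f1) && f1 == "e_M") || (is_e(f2) && f2 == "e_M")
        free <- config$cor_epe && !male_e
      }
      add("E0", f1, f2, free, cov_term_name(f1, f2, tr))
    }
  }
  add("dummy", "dummy", "dummy", FALSE, "sigma2_dummy")
  dplyr::bind_rows(rows)
}

#' (Co)variance components for a model
#'
#' Builds the dense per-factor-group covariance matrices `G0` and `E0`
#' from named parameter values, enforcing the model's structural zeros,
#' and attaches the fixed dummy residual variance.  Matrices must be
#' positive semi-definite after masking.
#'
#' @param config A [model_config()].
#' @param values Named numeric vector/list with one entry per free
#'   parameter (see [parameter_map()]); values supplied for masked terms
#'   must be zero.
#' @param sigma2_dummy Fixed dummy residual variance (trait-squared units,
#'   default 1).  It is never updated during estimation; the true residual
#'   variance of the trait is `sigma2_e + sigma2_dummy`.
#' @return An object of class `variance_components` with elements
#'   `config`, `G0`, `E0`, `sigma2_dummy` and the parameter `map`.
#' @examples
#' cfg <- model_config("coramepe")
#' vc <- variance_components(cfg, c(
#'   sigma2_a = 8046, sigma2_m = 829, sigma_am = -912,
#'   sigma2_e = 19860, sigma2_pe = 906, sigma_epe = 1272
#' ))
#' derived_ratios(vc)
#' @export
variance_components <- function(config, values, sigma2_dummy = 1) {
  map <- parameter_map(config)
  values <- unlist(values)
  free_terms <- map$term[map$free]
  missing <- setdiff(free_terms, names(values))
  if (length(missing)) {
    stop("missing value for free parameter(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  fixed_terms <- setdiff(map$term[!map$free], "sigma2_dummy")
  bad <- intersect(names(values), fixed_terms)
  bad <- bad[abs(values[bad]) > 0]
  if (length(bad)) {
    stop(
      "parameter ", bad[1], " is a structural zero under model '",
      config$model, "'",
      call. = FALSE
    )
  }
  if ("sigma2_dummy" %in% names(values)) sigma2_dummy <- unname(values[["sigma2_dummy"]])
  if (!is.numeric(sigma2_dummy) || sigma2_dummy <= 0) {
    stop("sigma2_dummy must be > 0", call. = FALSE)
  }
  gf <- genetic_factors(config)
  ec <- env_components(config)
  G0 <- matrix(0, length(gf), length(gf), dimnames = list(gf, gf))
  E0 <- matrix(0, length(ec), length(ec), dimnames = list(ec, ec))
  for (k in seq_len(nrow(map))) {
    if (map$matrix[k] == "dummy") next
    v <- if (map$free[k]) unname(values[[map$term[k]]]) else 0
    M <- if (map$matrix[k] == "G0") "G0" else "E0"
    tgt <- get(M)
    tgt[map$row[k], map$col[k]] <- v
    tgt[map$col[k], map$row[k]] <- v
    assign(M, tgt)
  }
  out <- structure(
    list(
      config = config, G0 = G0, E0 = E0,
      sigma2_dummy = sigma2_dummy, map = map
    ),
    class = "variance_components"
  )
  check_vc_psd(out)
  out
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat("<variance_components> model ", x$config$model, "\n", sep = "")
  cat("G0 (genetic):\n")
  print(round(x$G0, digits))
  cat("E0 (environmental):\n")
  print(round(x$E0, digits))
  cat("sigma2_dummy (fixed):", x$sigma2_dummy, "\n")
  invisible(x)
}

## Named vector of every mapped parameter value (free and masked).
vc_values <- function(vc) {
  map <- vc$map
  v <- numeric(nrow(map))
  for (k in seq_len(nrow(map))) {
    v[k] <- switch(map$matrix[k],
      G0 = vc$G0[map$row[k], map$col[k]],
      E0 = vc$E0[map$row[k], map$col[k]],
      dummy = vc$sigma2_dummy
    )
  }
  stats::setNames(v, map$term)
}

vc_free_values <- function(vc) {
  v <- vc_values(vc)
  v[vc$map$term[vc$map$free]]
}

vc_with_free <- function(vc, theta) {
  variance_components(vc$config, theta, sigma2_dummy = vc$sigma2_dummy)
}

## Connected components of the "possibly nonzero" pattern of a structure
## matrix: masked entries stay zero, so positive-definiteness (and bending)
## factorizes over these blocks.
mask_components <- function(M, free_pattern) {
  n <- nrow(M)
  adj <- free_pattern | M != 0
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      k <- stack[[1]]
      stack <- stack[-1]
      if (!is.na(comp[k])) next
      comp[k] <- cid
      stack <- c(stack, which(adj[k, ] & is.na(comp)))
    }
  }
  split(seq_len(n), comp)
}

free_pattern_matrix <- function(vc, which = c("G0", "E0")) {
  which <- match.arg(which)
  M <- vc[[which]]
  pat <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
  map <- vc$map[vc$map$matrix == which & vc$map$free, ]
  for (k in seq_len(nrow(map))) {
    pat[map$row[k], map$col[k]] <- TRUE
    pat[map$col[k], map$row[k]] <- TRUE
  }
  pat
}

check_vc_psd <- function(vc, tol = 1e-8) {
  for (w in c("G0", "E0")) {
    M <- vc[[w]]
    if (!nrow(M)) next
    comps <- mask_components(M, free_pattern_matrix(vc, w))
    for (ix in comps) {
      ev <- eigen(M[ix, ix, drop = FALSE], symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -tol * max(abs(ev), 1)) {
        stop(w, " is not positive semi-definite after masking", call. = FALSE)
      }
    }
  }
  invisible(vc)
}

## Eigenvalue clipping ("bending") applied per mask component, so masked
## zeros are never disturbed.  eps is relative to the largest eigenvalue.
bend_psd <- function(M, free_pattern, eps = 1e-8) {
  comps <- mask_components(M, free_pattern)
  for (ix in comps) {
    B <- M[ix, ix, drop = FALSE]
    ee <- eigen(B, symmetric = TRUE)
    lo <- eps * max(ee$values, eps)
    if (min(ee$values) < lo) {
      vals <- pmax(ee$values, lo)
      M[ix, ix] <- ee$vectors %*% diag(vals, length(vals)) %*% t(ee$vectors)
    }
  }
  M
}

#' Total residual variance per trait
#'
#' The model's true residual variance is the sum of the estimated residual
#' component `sigma2_e` and the fixed dummy residual.
#'
#' @param vc A [variance_components()] object.
#' @return Named numeric vector, one entry per trait.
#' @export
total_residual_variance <- function(vc) {
  if (vc$config$traits == 1L) {
    c(t = unname(vc$E0["e", "e"]) + vc$sigma2_dummy)
  } else {
    c(
      F = unname(vc$E0["e_F", "e_F"]) + vc$sigma2_dummy,
      M = unname(vc$E0["e_M", "e_M"]) + vc$sigma2_dummy
    )
  }
}

#' Heritability and direct-maternal correlations
#'
#' Computes, per trait, the heritability
#' `h2 = sigma2_a / (sigma2_a + sigma2_m + sigma2_pe + sigma2_e + sigma2_dummy)`
#' (maternal term omitted when the model excludes it; covariance terms are
#' not part of the phenotypic-variance denominator), the direct-maternal
#' genetic correlation `r_am` and the direct-maternal environmental
#' correlation `r_epe`.  In the two-trait model the dam's residual is
#' always the female one, so `r_epe` for males is
#' `Cov(e_F, pe_M) / sqrt(V(e_F) V(pe_M))`.
#'
#' @param vc A [variance_components()] object.
#' @return A tibble with columns `trait`, `h2`, `r_am`, `r_epe`
#'   (masked covariances give correlations of exactly 0).
#' @export
derived_ratios <- function(vc) {
  cfg <- vc$config
  safe_ratio <- function(cov, v1, v2) {
    if (cov == 0) {
      return(0)
    }
    if (v1 <= 0 || v2 <= 0) {
      stop("undefined ratio: zero variance in denominator", call. = FALSE)
    }
    cov / sqrt(v1 * v2)
  }
  if (cfg$traits == 1L) {
    va <- vc$G0["a", "a"]
    vm <- if (cfg$include_maternal) vc$G0["m", "m"] else 0
    vp <- va + vm + vc$E0["pe", "pe"] + vc$E0["e", "e"] + vc$sigma2_dummy
    if (vp <= 0) stop("undefined ratio: zero phenotypic variance", call. = FALSE)
    r_am <- if (cfg$include_maternal) {
      safe_ratio(vc$G0["a", "m"], va, vm)
    } else {
      0
    }
    r_epe <- safe_ratio(vc$E0["e", "pe"], vc$E0["e", "e"], vc$E0["pe", "pe"])
    return(tibble::tibble(trait = "t", h2 = unname(va / vp), r_am = r_am, r_epe = r_epe))
  }
  purrr::map_dfr(c("F", "M"), function(s) {
    a <- paste0("a_", s)
    m <- paste0("m_", s)
    pe <- paste0("pe_", s)
    e <- paste0("e_", s)
    va <- vc$G0[a, a]
    vm <- if (cfg$include_maternal) vc$G0[m, m] else 0
    vp <- va + vm + vc$E0[pe, pe] + vc$E0[e, e] + vc$sigma2_dummy
    tibble::tibble(
      trait = s,
      h2 = unname(va / vp),
      r_am = if (cfg$include_maternal) safe_ratio(vc$G0[a, m], va, vm) else 0,
      r_epe = safe_ratio(vc$E0["e_F", pe], vc$E0["e_F", "e_F"], vc$E0[pe, pe])
    )
  })
}
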