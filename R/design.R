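#' Build design structures for the maternal animal model
#'
#' Links phenotype records to the pedigree and builds the fixed-effect
#' matrix `X` plus the bookkeeping for the incidence of the direct genetic
#' effect (`Z`, keyed by the phenotyped animal), the maternal effects
#' (`W`, keyed by the dam, shared by the maternal genetic and permanent
#' environmental effects) and the residual-as-random-effect (`B`, keyed by
#' the phenotyped animal's own environmental level, the dummy-residual
#' device).  Records whose dam is unknown keep their direct effect but are
#' excluded from all maternal linkage (their `W` row is zero); the count is
#' recorded.
#'
#' @param data A data frame with columns `animal`, the response (default
#'   `bw`, grams) and the fixed-effect covariates.  With `traits = 2` a
#'   `sex` column (`"F"`/`"M"`) assigns each record to its trait.  Each
#'   animal has at most one record.
#' @param pedigree A [as_pedigree()] object containing every phenotyped
#'   animal.
#' @param config A [model_config()].
#' @param fixed Fixed-effect formula (right-hand side) evaluated in
#'   `data`.  Default: hatch-within-selection-round (`sr` x `hatch`), `sex`
#'   (single-trait models only) and `dam_age_class`, using whichever of
#'   those columns are present.
#' @param response Name of the response column, default `"bw"`.
#' @return An object of class `design_set`.
#' @export
build_design <- function(data, pedigree, config, fixed = NULL, response = "bw") {
  pedigree <- check_pedigree(pedigree)
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  an <- match(as.character(data$animal), pedigree$animal)
  if (anyNA(an)) {
    stop("record references animal absent from pedigree: ",
      data$animal[is.na(an)][1],
      call. = FALSE
    )
  }
  if (config$traits == 2L) {
    if (!"sex" %in% names(data)) {
      stop("two-trait models need a 'sex' column on the records", call. = FALSE)
    }
    trait <- match(toupper(as.character(data$sex)), c("F", "M"))
    if (anyNA(trait)) stop("sex must be F or M", call. = FALSE)
  } else {
    trait <- rep(1L, nrow(data))
  }
  if (anyDuplicated(cbind(an, trait))) {
    dup <- data$animal[duplicated(cbind(an, trait))][1]
    stop("duplicate record for animal ", dup, call. = FALSE)
  }
  dam <- pedigree$.dam[an]
  n_unknown_dam <- sum(dam == 0L)

  if (is.null(fixed)) {
    n_levels <- function(v) length(unique(v))
    terms <- character(0)
    if (all(c("sr", "hatch") %in% names(data)) &&
      n_levels(paste(data$sr, data$hatch)) > 1) {
      terms <- c(terms, "factor(sr):factor(hatch)")
    } else if ("sr" %in% names(data) && n_levels(data$sr) > 1) {
      terms <- c(terms, "factor(sr)")
    }
    if (config$traits == 1L && "sex" %in% names(data) && n_levels(data$sex) > 1) {
      terms <- c(terms, "sex")
    }
    if ("dam_age_class" %in% names(data) && n_levels(data$dam_age_class) > 1) {
      terms <- c(terms, "factor(dam_age_class)")
    }
    fixed <- if (length(terms)) {
      stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    } else {
      ~1
    }
  }

  ## X per trait (each trait has its own fixed-effect levels), assembled
  ## into record order; aliased columns dropped with the first-level
  ## (treatment-contrast) constraint applied per factor.
  tn <- trait_names(config)
  Xs <- vector("list", config$traits)
  x_names <- character(0)
  for (t in seq_len(config$traits)) {
    rows <- which(trait == t)
    mm <- Matrix::sparse.model.matrix(fixed, data = data[rows, , drop = FALSE])
    XtX <- as.matrix(Matrix::crossprod(mm))
    qr_x <- qr(XtX)
    keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
    if (length(keep) < ncol(mm)) {
      dropped <- colnames(mm)[-keep]
      message(
        "dropping ", length(dropped),
        " aliased fixed-effect column(s): ", paste(utils::head(dropped, 3), collapse = ", ")
      )
      mm <- mm[, keep, drop = FALSE]
    }
    Xs[[t]] <- list(rows = rows, X = mm)
    x_names <- c(x_names, if (config$traits == 1L) {
      colnames(mm)
    } else {
      paste0(tn[t], ":", colnames(mm))
    })
  }
  p <- sum(vapply(Xs, function(z) ncol(z$X), integer(1)))
  trip_i <- integer(0)
  trip_j <- integer(0)
  trip_x <- numeric(0)
  off <- 0L
  for (t in seq_len(config$traits)) {
    Xi <- as(Xs[[t]]$X, "TsparseMatrix")
    trip_i <- c(trip_i, Xs[[t]]$rows[Xi@i + 1L])
    trip_j <- c(trip_j, off + Xi@j + 1L)
    trip_x <- c(trip_x, Xi@x)
    off <- off + ncol(Xs[[t]]$X)
  }
  X <- Matrix::sparseMatrix(
    i = trip_i, j = trip_j, x = trip_x,
    dims = c(nrow(data), p), dimnames = list(NULL, x_names)
  )

  ## pe levels: one per dam per offspring-trait group with >= 1 linked record
  linked <- dam > 0L
  pe_key <- tibble::tibble(.dam = dam[linked], group = trait[linked])
  pe_levels <- dplyr::arrange(dplyr::distinct(pe_key), .data$.dam, .data$group)
  pe_levels$col <- seq_len(nrow(pe_levels))

  records <- tibble::tibble(
    row = seq_len(nrow(data)),
    animal = as.character(data$animal),
    .an = an, .dam = dam,
    trait = trait,
    y = as.numeric(data[[response]]),
    sr = if ("sr" %in% names(data)) as.integer(data$sr) else NA_integer_
  )
  records$pe_col <- NA_integer_
  m <- match(
    paste(records$.dam, records$trait),
    paste(pe_levels$.dam, pe_levels$group)
  )
  records$pe_col <- ifelse(records$.dam > 0L, m, NA_integer_)

  structure(
    list(
      records = records, X = X, x_names = x_names,
      pe_levels = pe_levels,
      n_unknown_dam = n_unknown_dam,
      config = config, fixed = fixed,
      n_animals = nrow(pedigree)
    ),
    class = "design_set"
  )
}

#' @export
print.design_set <- function(x, ...) {
  cat(
    "<design_set> ", nrow(x$records), " records, ",
    ncol(x$X), " fixed-effect columns, ",
    nrow(x$pe_levels), " permanent environmental levels",
    if (x$n_unknown_dam > 0) {
      paste0(" (", x$n_unknown_dam, " records with unknown dam, no maternal linkage)")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

## Per-individual environmental layout: every record's animal owns an `e`
## component, every dam owns her pe component(s).  Used by the dense
## oracle and by the sparse assembly (which absorbs e levels that cannot
## covary with anything else).
env_layout <- function(design) {
  config <- design$config
  rec <- design$records
  pe <- design$pe_levels
  ids <- sort(unique(c(rec$.an, pe$.dam)))
  ## map: for each individual, which env components (by E0 row name) it has
  e_name <- if (config$traits == 1L) {
    function(t) "e"
  } else {
    function(t) c("e_F", "e_M")[t]
  }
  pe_name <- if (config$traits == 1L) {
    function(g) "pe"
  } else {
    function(g) c("pe_F", "pe_M")[g]
  }
  rec_by_an <- split(rec$trait, rec$.an)
  pe_by_dam <- split(pe$group, pe$.dam)
  purrr::map_dfr(ids, function(id) {
    comps <- character(0)
    tr <- rec_by_an[[as.character(id)]]
    if (!is.null(tr)) comps <- c(comps, e_name(tr[1]))
    gs <- pe_by_dam[[as.character(id)]]
    if (!is.null(gs)) comps <- c(comps, pe_name(sort(gs)))
    tibble::tibble(.an = id, comp = comps)
  })
}

## Materialized incidence matrices for tests and the dense oracle:
## Z over genetic levels (factor-major, all pedigree animals) and B over
## the explicit per-individual environmental levels.
design_incidence <- function(design, pedigree) {
  config <- design$config
  rec <- design$records
  N <- nrow(pedigree)
  gf <- genetic_factors(config)
  nrec <- nrow(rec)
  gi <- integer(0)
  gj <- integer(0)
  a_of_trait <- function(t) if (config$traits == 1L) "a" else c("a_F", "a_M")[t]
  m_of_trait <- function(t) if (config$traits == 1L) "m" else c("m_F", "m_M")[t]
  for (r in seq_len(nrec)) {
    fa <- match(a_of_trait(rec$trait[r]), gf)
    gi <- c(gi, r)
    gj <- c(gj, (fa - 1L) * N + rec$.an[r])
    if (config$include_maternal && rec$.dam[r] > 0L) {
      fm <- match(m_of_trait(rec$trait[r]), gf)
      gi <- c(gi, r)
      gj <- c(gj, (fm - 1L) * N + rec$.dam[r])
    }
  }
  Z <- Matrix::sparseMatrix(i = gi, j = gj, x = 1, dims = c(nrec, length(gf) * N))

  lay <- env_layout(design)
  lay$col <- seq_len(nrow(lay))
  env_names <- paste0(lay$comp, ".", pedigree$animal[lay$.an])
  e_name <- function(t) if (config$traits == 1L) "e" else c("e_F", "e_M")[t]
  pe_name <- function(g) if (config$traits == 1L) "pe" else c("pe_F", "pe_M")[g]
  bi <- integer(0)
  bj <- integer(0)
  key <- paste(lay$.an, lay$comp)
  for (r in seq_len(nrec)) {
    bi <- c(bi, r)
    bj <- c(bj, lay$col[match(paste(rec$.an[r], e_name(rec$trait[r])), key)])
    if (rec$.dam[r] > 0L) {
      bi <- c(bi, r)
      bj <- c(bj, lay$col[match(paste(rec$.dam[r], pe_name(rec$trait[r])), key)])
    }
  }
  B <- Matrix::sparseMatrix(i = bi, j = bj, x = 1, dims = c(nrec, nrow(lay)))
  list(X = design$X, Z = Z, B = B, env_layout = lay, env_names = env_names)
}

## Dense environmental covariance over the explicit env layout (oracle).
env_covariance_dense <- function(design, vc) {
  lay <- env_layout(design)
  n <- nrow(lay)
  S <- matrix(0, n, n)
  for (id in unique(lay$.an)) {
    ix <- which(lay$.an == id)
    S[ix, ix] <- vc$E0[lay$comp[ix], lay$comp[ix]]
  }
  S
}
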