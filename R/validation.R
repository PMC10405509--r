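#' Forward-prediction split
#'
#' Training data are all selection rounds before the validation window;
#' validation birds are all birds in the last `n_validation_sr` rounds,
#' whose phenotypes are masked when predicting their breeding values.
#' Variance components are always estimated on the full data.
#'
#' @param data Phenotype tibble with columns `animal` and `sr`.
#' @param n_validation_sr Number of final selection rounds to validate on
#'   (default 5).
#' @return A list of class `split_plan` with elements `training` and
#'   `masked` (phenotype tibbles), `validation_animals`, and `mode`.
#' @export
forward_split <- function(data, n_validation_sr = 5L) {
  data <- tibble::as_tibble(data)
  if (!"sr" %in% names(data)) stop("data needs an 'sr' column", call. = FALSE)
  srs <- sort(unique(data$sr))
  if (length(srs) < n_validation_sr + 1L) {
    stop("need at least ", n_validation_sr + 1L, " selection rounds", call. = FALSE)
  }
  val_sr <- utils::tail(srs, n_validation_sr)
  if (!nrow(data[data$sr == max(srs), ])) stop("empty final selection round", call. = FALSE)
  val <- data$sr %in% val_sr
  structure(
    list(
      training = data[!val, , drop = FALSE],
      masked = data[!val, , drop = FALSE],
      validation = data[val, , drop = FALSE],
      validation_animals = as.character(data$animal[val]),
      validation_sr = val_sr,
      mode = "forward"
    ),
    class = "split_plan"
  )
}

#' Paternal half-sib split with random pairing
#'
#' Within the last `n_validation_sr` rounds, each paternal half-sib group
#' is split at random: half keep their phenotypes (training side), half
#' are masked (validation side; the odd animal goes to training).  Masked
#' half-sibs are then randomly paired, never pairing animals that share a
#' dam (full sibs share maternal effects); pairing is within sex when
#' `within_sex = TRUE`.  `n_resamples` independent pairings are drawn;
#' unpaired animals are ignored within a resample.
#'
#' @param data Phenotype tibble with `animal`, `sr` (and `sex` if pairing
#'   within sex).
#' @param pedigree A [as_pedigree()] object (supplies sire and dam).
#' @param n_validation_sr Validation window (default 5 rounds).
#' @param n_resamples Number of independent pairings (default 50).
#' @param within_sex Pair only animals of the same sex (used when female
#'   and male weights are distinct traits).
#' @param seed Seed for the split and the pairings.
#' @return A list of class `split_plan`: `masked` (training phenotypes
#'   for the reduced run), `validation_animals` (masked animals),
#'   `pairings` (list of `n_resamples` tibbles with columns `animal` and
#'   `halfsib`), and `mode = "halfsib"`.
#' @export
halfsib_split <- function(data, pedigree, n_validation_sr = 5L,
                          n_resamples = 50L, within_sex = FALSE, seed = 1L) {
  data <- tibble::as_tibble(data)
  pedigree <- check_pedigree(pedigree)
  set.seed(seed)
  srs <- sort(unique(data$sr))
  val_sr <- utils::tail(srs, n_validation_sr)
  ix <- match(as.character(data$animal), pedigree$animal)
  sire <- pedigree$.sire[ix]
  dam <- pedigree$.dam[ix]
  in_window <- data$sr %in% val_sr & sire > 0L
  masked_ids <- character(0)
  groups <- split(which(in_window), sire[in_window])
  val_rows <- integer(0)
  for (g in groups) {
    if (length(g) < 2L) next
    n_mask <- floor(length(g) / 2)
    val_rows <- c(val_rows, sample(g, n_mask))
  }
  masked_ids <- as.character(data$animal[val_rows])
  if (!length(masked_ids)) stop("no paternal half-sib groups to split", call. = FALSE)

  vdat <- tibble::tibble(
    animal = as.character(data$animal[val_rows]),
    sire = sire[val_rows], dam = dam[val_rows],
    sex = if (within_sex) as.character(data$sex[val_rows]) else ""
  )
  one_pairing <- function() {
    out <- list()
    for (key in unique(paste(vdat$sire, vdat$sex))) {
      sub <- vdat[paste(vdat$sire, vdat$sex) == key, ]
      if (nrow(sub) < 2L) next
      sub <- sub[sample(nrow(sub)), ]
      used <- rep(FALSE, nrow(sub))
      for (i in seq_len(nrow(sub))) {
        if (used[i]) next
        j <- which(!used & seq_len(nrow(sub)) > i & sub$dam != sub$dam[i])[1]
        if (is.na(j)) next
        used[i] <- used[j] <- TRUE
        out[[length(out) + 1L]] <- tibble::tibble(
          animal = sub$animal[i], halfsib = sub$animal[j]
        )
      }
    }
    if (!length(out)) {
      return(tibble::tibble(animal = character(0), halfsib = character(0)))
    }
    dplyr::bind_rows(out)
  }
  pairings <- replicate(n_resamples, one_pairing(), simplify = FALSE)
  if (all(vapply(pairings, nrow, integer(1)) == 0L)) {
    stop("no valid half-sib pairs (all groups are full sibs)", call. = FALSE)
  }
  structure(
    list(
      masked = data[!(as.character(data$animal) %in% masked_ids), , drop = FALSE],
      validation = data[as.character(data$animal) %in% masked_ids, , drop = FALSE],
      validation_animals = masked_ids,
      validation_sr = val_sr,
      pairings = pairings,
      mode = "halfsib"
    ),
    class = "split_plan"
  )
}

#' Correct values for the genetic trend
#'
#' Subtracts the within-selection-round mean from each value.  Both the
#' predictor and the response of every correlation/regression are
#' corrected this way before computing validation statistics, i.e. the
#' (co)variances used are those conditional on the round means.
#'
#' @param values Numeric vector.
#' @param sr Selection-round label per value.
#' @return Numeric vector of within-round deviations (round means 0).
#' @export
trend_correct <- function(values, sr) {
  values - stats::ave(values, sr)
}

#' Phenotypes corrected for fixed effects
#'
#' `y_c = y - X b_hat`, with the fixed part taken from the full-data fit
#' of the same model (the fit stores every record's fitted fixed part,
#' so a subset of its records can be corrected without rebuilding the
#' design - aliased-column constraints then agree with the fit by
#' construction).
#'
#' @param data Phenotype tibble: the records the fit used, or a subset.
#' @param pedigree A [as_pedigree()] object (kept for interface
#'   symmetry; the join is by animal).
#' @param fit A [reml()] or [blup()] result.
#' @return `data` with an added column `y_c`.
#' @export
corrected_phenotype <- function(data, pedigree, fit) {
  data <- tibble::as_tibble(data)
  res <- fit$residuals
  key_fit <- paste(res$animal, res$trait)
  trait <- if (fit$config$traits == 2L) {
    match(toupper(as.character(data$sex)), c("F", "M"))
  } else {
    rep(1L, nrow(data))
  }
  m <- match(paste(as.character(data$animal), trait), key_fit)
  if (anyNA(m)) {
    stop("record was not part of the fitted data (no fixed-effect solution): ",
      data$animal[is.na(m)][1],
      call. = FALSE
    )
  }
  dplyr::mutate(data, y_c = res$y[m] - res$fixed_fitted[m])
}

#' Accuracy and inflation of predictions
#'
#' Correlation and least-squares regression slope of a response on a
#' predictor, both trend-corrected within selection round first.  The
#' slope of the regression of the response on the predicted breeding
#' value measures inflation: 1 is ideal, below 1 means inflated
#' (over-dispersed) predictions.
#'
#' @param predictor,response Numeric vectors (e.g. reduced-data EBV and
#'   TBV).
#' @param sr Optional selection-round labels for trend correction.
#' @return A one-row tibble with `cor` and `slope`.
#' @export
accuracy_and_inflation <- function(predictor, response, sr = NULL) {
  if (!is.null(sr)) {
    predictor <- trend_correct(predictor, sr)
    response <- trend_correct(response, sr)
  }
  if (stats::sd(predictor) == 0) {
    warning("degenerate (zero-variance) predictor", call. = FALSE)
    return(tibble::tibble(cor = NA_real_, slope = NA_real_))
  }
  tibble::tibble(
    cor = stats::cor(predictor, response),
    slope = stats::cov(predictor, response) / stats::var(predictor)
  )
}

#' Cross-validate prediction models on a simulated population
#'
#' For each model: variance components are estimated by REML on the full
#' data; breeding values are then predicted with the phenotypes of the
#' validation birds masked (forward prediction over the last
#' `n_validation_sr` rounds, and optionally the paternal half-sib split).
#' Reported per model, all on trend-corrected values of validation birds:
#' accuracies `cor(TBV, EBV_reduced)`, `cor(y_c, EBV_reduced)`,
#' `cor(EBV_full, EBV_reduced)` (the Legarra-Reverter correlation) and
#' the half-sib accuracy `cor(y_c_i, EBV_reducedHS_j)` averaged over
#' pairings; inflation slopes of TBV, `y_c` and `EBV_full` on
#' `EBV_reduced`.
#'
#' @param pop A [run_program()] population (or a list with `phenotypes`,
#'   `pedigree`, optionally `truth`).
#' @param models Character vector of model names to compare.
#' @param n_validation_sr Validation window (default 5 rounds).
#' @param halfsib Also run the half-sib prediction (default TRUE).
#' @param n_resamples Pairings for the half-sib accuracy (default 50).
#' @param seed Seed for the half-sib split and pairings.
#' @param use_inbreeding Passed to the mixed-model machinery.
#' @param control [reml_control()] for the full-data fits.
#' @param fits Optional named list of pre-computed [reml()] fits to reuse.
#' @return An object of class `crossval_report`: tibble `stats` (one row
#'   per model and statistic), list `fits`, and the split plans.
#' @export
crossvalidate <- function(pop, models = c("moda", "modam", "coram", "corepe", "coramepe"),
                          n_validation_sr = 5L, halfsib = TRUE, n_resamples = 50L,
                          seed = 1L, use_inbreeding = TRUE,
                          control = reml_control(), fits = NULL) {
  phen <- tibble::as_tibble(pop$phenotypes)
  pedigree <- check_pedigree(pop$pedigree)
  truth <- pop$truth
  fw <- forward_split(phen, n_validation_sr)
  hs <- if (halfsib) {
    halfsib_split(phen, pedigree,
      n_validation_sr = n_validation_sr,
      n_resamples = n_resamples, seed = seed
    )
  } else {
    NULL
  }
  val_ids <- fw$validation_animals
  val_sr <- phen$sr[match(val_ids, phen$animal)]

  rows <- list()
  out_fits <- list()
  for (mdl in models) {
    config <- model_config(mdl)
    fit <- if (!is.null(fits) && mdl %in% names(fits)) {
      fits[[mdl]]
    } else {
      reml(phen, pedigree, config,
        use_inbreeding = use_inbreeding, control = control
      )
    }
    out_fits[[mdl]] <- fit
    red <- blup(fw$masked, pedigree, config, fit$vc, use_inbreeding = use_inbreeding)
    ebv_red <- stats::setNames(red$ebv$a, red$ebv$animal)[val_ids]
    ebv_full <- stats::setNames(fit$ebv$a, fit$ebv$animal)[val_ids]
    yc <- corrected_phenotype(fw$validation, pedigree, fit)
    yc <- stats::setNames(yc$y_c, as.character(yc$animal))[val_ids]

    st <- list(
      cor_yc = accuracy_and_inflation(ebv_red, yc, val_sr),
      cor_lr = accuracy_and_inflation(ebv_red, ebv_full, val_sr)
    )
    if (!is.null(truth)) {
      tbv <- stats::setNames(truth$a, truth$animal)[val_ids]
      st$cor_tbv <- accuracy_and_inflation(ebv_red, tbv, val_sr)
    }
    for (nm in names(st)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = mdl,
        statistic = c(
          cor_yc = "cor(y_c, EBV_reduced)",
          cor_lr = "cor(EBV_full, EBV_reduced)",
          cor_tbv = "cor(TBV, EBV_reduced)"
        )[[nm]],
        value = st[[nm]]$cor, sd = NA_real_
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = mdl,
        statistic = c(
          cor_yc = "slope y_c ~ EBV_reduced",
          cor_lr = "slope EBV_full ~ EBV_reduced",
          cor_tbv = "slope TBV ~ EBV_reduced"
        )[[nm]],
        value = st[[nm]]$slope, sd = NA_real_
      )
    }

    if (!is.null(hs)) {
      redhs <- blup(hs$masked, pedigree, config, fit$vc, use_inbreeding = use_inbreeding)
      ebv_hs <- stats::setNames(redhs$ebv$a, redhs$ebv$animal)
      ychs <- corrected_phenotype(hs$validation, pedigree, fit)
      yc_all <- stats::setNames(ychs$y_c, as.character(ychs$animal))
      sr_all <- stats::setNames(ychs$sr, as.character(ychs$animal))
      cors <- vapply(hs$pairings, function(pr) {
        if (!nrow(pr)) {
          return(NA_real_)
        }
        accuracy_and_inflation(
          trend_correct(ebv_hs[pr$halfsib], sr_all[pr$halfsib]),
          trend_correct(yc_all[pr$animal], sr_all[pr$animal])
        )$cor
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = mdl, statistic = "Halfsibs cor(y_c, EBV_reducedHS)",
        value = mean(cors, na.rm = TRUE), sd = stats::sd(cors, na.rm = TRUE)
      )
    }
  }
  structure(
    list(
      stats = dplyr::bind_rows(rows),
      fits = out_fits,
      forward = fw, halfsib = hs,
      n_validation = length(val_ids),
      n_pairs = if (!is.null(hs)) mean(vapply(hs$pairings, nrow, integer(1))) else NA_real_
    ),
    class = "crossval_report"
  )
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(
    "<crossval_report> ", length(x$fits), " models, ", x$n_validation,
    " validation birds",
    if (!is.na(x$n_pairs)) paste0(", ~", round(x$n_pairs), " half-sib pairs/resample"),
    "\n",
    sep = ""
  )
  wide <- tidyr::pivot_wider(x$stats[c("model", "statistic", "value")],
    names_from = "model", values_from = "value"
  )
  print(wide, n = Inf)
  invisible(x)
}

#' @export
tidy.crossval_report <- function(x, ...) x$stats
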