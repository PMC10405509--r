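#' Read a phenotype file
#'
#' Delimited text with header `animal,sr,hatch,sex,dam_age_class,bw`
#' (missing fields empty).  One record per animal and trait; duplicates
#' are rejected.
#'
#' @param path File path.
#' @param sep Field separator, default comma.
#' @return A typed tibble.
#' @export
read_phenotypes <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE)
  names(x) <- tolower(names(x))
  if (!all(c("animal", "bw") %in% names(x))) {
    stop("phenotype file needs at least 'animal' and 'bw' columns", call. = FALSE)
  }
  x$animal <- as.character(x$animal)
  bad <- which(is.na(x$bw))
  if (length(bad)) {
    stop("malformed record (missing bw) at line ", bad[1] + 1L, call. = FALSE)
  }
  key <- if ("sex" %in% names(x)) paste(x$animal, x$sex) else x$animal
  if (anyDuplicated(key)) {
    stop("duplicate phenotype record for animal ",
      x$animal[duplicated(key)][1],
      call. = FALSE
    )
  }
  for (cl in intersect(c("sr", "hatch", "dam_age_class"), names(x))) {
    x[[cl]] <- as.integer(x[[cl]])
  }
  tibble::as_tibble(x)
}

#' Write a simulated population as delimited text
#'
#' Writes `pedigree.csv`, `phenotypes.csv` and `truth.csv` (per-animal
#' true breeding values and environmental effects) to a directory.
#'
#' @param pop A [run_program()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    pop$pedigree[c("animal", "sire", "dam", "sex", "sr")],
    file.path(dir, "pedigree.csv"),
    row.names = FALSE, na = ""
  )
  utils::write.csv(pop$phenotypes, file.path(dir, "phenotypes.csv"),
    row.names = FALSE, na = ""
  )
  utils::write.csv(pop$truth, file.path(dir, "truth.csv"),
    row.names = FALSE, na = ""
  )
  invisible(dir)
}

#' Write an estimation / validation report
#'
#' Produces a variance-component table (parameters by model, with
#' standard errors and the likelihood-ratio test against the most
#' complex fitted model), and, when a [crossvalidate()] report is given,
#' accuracy and inflation tables; plus a lossless machine-readable
#' `summary.json` (requires the jsonlite package).
#'
#' @param dir Output directory.
#' @param fits Named list of [reml()] fits (or a [crossvalidate()] report,
#'   whose fits are used).
#' @param cv Optional [crossvalidate()] report.
#' @return `dir`, invisibly.
#' @export
write_report <- function(dir, fits, cv = NULL) {
  if (inherits(fits, "crossval_report")) {
    cv <- fits
    fits <- cv$fits
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vc_tab <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(tidy(f), model = nm, minus2logL = f$minus2logL)
  })
  if (length(fits) > 1) {
    full <- names(fits)[which.max(vapply(fits, function(f) f$n_params, numeric(1)))]
    vc_tab$lrt_vs_full <- vapply(vc_tab$model, function(nm) {
      if (nm == full) 0 else lrt(fits[[nm]], fits[[full]])$statistic
    }, numeric(1))
  }
  utils::write.csv(vc_tab, file.path(dir, "variance_components.csv"), row.names = FALSE)
  if (!is.null(cv)) {
    st <- cv$stats
    acc <- st[grepl("^cor|^Halfsibs", st$statistic), ]
    inf <- st[grepl("^slope", st$statistic), ]
    utils::write.csv(
      tidyr::pivot_wider(acc[c("model", "statistic", "value")],
        names_from = "model", values_from = "value"
      ),
      file.path(dir, "accuracy.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      tidyr::pivot_wider(inf[c("model", "statistic", "value")],
        names_from = "model", values_from = "value"
      ),
      file.path(dir, "inflation.csv"),
      row.names = FALSE
    )
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- list(
      models = purrr::imap(fits, function(f, nm) {
        list(
          model = nm, minus2logL = f$minus2logL, converged = f$converged,
          estimates = as.list(f$theta), std_errors = as.list(f$se)
        )
      }),
      validation = if (!is.null(cv)) {
        purrr::pmap(
          cv$stats[c("model", "statistic", "value", "sd")],
          function(model, statistic, value, sd) {
            list(model = model, statistic = statistic, value = value, sd = sd)
          }
        )
      }
    )
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(dir)
}

#' Read back a report summary
#'
#' @param dir Directory written by [write_report()].
#' @return The parsed `summary.json` list.
#' @export
read_report <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to read report summaries", call. = FALSE)
  }
  jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = FALSE)
}

#' Read a model / variance configuration file
#'
#' Structured text (YAML) describing an estimation run: the model name,
#' the trait count, optional initial values for the free parameters, the
#' fixed dummy variance and convergence settings, e.g.
#'
#' ```yaml
#' model: coramepe
#' traits: 1
#' sigma2_dummy: 1
#' init:
#'   sigma2_a: 8000
#'   sigma2_e: 20000
#' control:
#'   max_iter: 100
#' ```
#'
#' @param path File path.
#' @return A list with elements `config` ([model_config()]), `init`
#'   (named numeric or NULL), `sigma2_dummy` and `control`
#'   ([reml_control()]).
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read model configuration files",
      call. = FALSE
    )
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model)) stop("configuration needs a 'model' field", call. = FALSE)
  config <- model_config(raw$model, traits = raw$traits %||% 1L)
  control <- do.call(reml_control, as.list(raw$control %||% list()))
  list(
    config = config,
    init = if (!is.null(raw$init)) unlist(raw$init) else NULL,
    sigma2_dummy = raw$sigma2_dummy %||% 1,
    control = control
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
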