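## Shared fixtures and generators for the test suite.  Everything is
## built in code under fixed seeds; expensive simulated populations are
## cached for the duration of the test run.

## Random pedigree: n_founders unrelated animals, then each animal gets
## random earlier parents (a male sire and a female dam).
random_pedigree <- function(n, n_founders = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  sex <- c(
    rep(c("M", "F"), length.out = n_founders),
    sample(c("M", "F"), n - n_founders, replace = TRUE)
  )
  for (i in (n_founders + 1):n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    fems <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- paste0("A", sample(males, 1))
    dam[i] <- paste0("A", sample(fems, 1))
  }
  as_pedigree(data.frame(
    animal = paste0("A", seq_len(n)), sire = sire, dam = dam, sex = sex
  ))
}

## Small random phenotype set on the non-founders of a pedigree.
random_records <- function(pedigree, n_rec = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cand <- which(pedigree$.sire > 0L | pedigree$.dam > 0L)
  if (is.null(n_rec)) n_rec <- length(cand)
  rows <- sort(sample(cand, n_rec))
  data.frame(
    animal = pedigree$animal[rows],
    sr = sample(1:2, n_rec, replace = TRUE),
    sex = pedigree$sex[rows],
    bw = rnorm(n_rec, 2000, 170)
  )
}

## Filled-in variance components with plausible magnitudes for any model.
test_vc <- function(config, scale = 1) {
  pm <- parameter_map(config)
  vals <- numeric(0)
  for (term in pm$term[pm$free]) {
    vals[term] <-
      if (startsWith(term, "sigma2_a")) 8000 * scale
      else if (startsWith(term, "sigma2_m")) 900 * scale
      else if (startsWith(term, "sigma2_e")) 20000 * scale
      else if (startsWith(term, "sigma2_pe")) 950 * scale
      else if (grepl("^sigma_a", term)) -500 * scale
      else if (grepl("^sigma_m", term)) 400 * scale
      else if (grepl("^sigma_pe", term)) 300 * scale
      else 800 * scale
  }
  variance_components(config, vals)
}

## True components of the simulation study (single trait).
true_vc <- function() {
  variance_components(
    model_config("coramepe"),
    c(
      sigma2_a = 8046, sigma2_m = 829, sigma_am = -912,
      sigma2_e = 19860, sigma2_pe = 906, sigma_epe = 1272
    )
  )
}

## Cached small simulated population with a selection history, reused
## across test files.
.test_cache <- new.env(parent = emptyenv())

small_population <- function() {
  if (is.null(.test_cache$pop)) {
    cfg <- sim_config(
      n_sr = 8, offspring_per_sr = 600, n_males_selected = 2,
      n_females_selected = 20, service_life_sr = 2, random_until_sr = 3
    )
    .test_cache$pop <- suppressMessages(run_program(cfg, seed = 420))
  }
  .test_cache$pop
}

quiet <- function(expr) suppressMessages(expr)
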