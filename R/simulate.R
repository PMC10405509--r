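#' Configuration of the stochastic broiler breeding program
#'
#' Defaults describe the simulated program: 40 selection rounds (SR) of
#' 7800 phenotyped birds each, bred from 52 active sires and 520 active
#' dams under a hierarchical mating system (one sire serves 10 dams, a
#' dam is mated to a single sire).  Each SR the top 13 males and 130
#' females (ranked at random for SR 1-6, on pedigree-BLUP breeding values
#' from a single-trait `moda` evaluation afterwards) enter a parent pool
#' in which a cohort serves four overlapping SR (4 x 13 = 52 sires).
#' Offspring are hatched in 6 hatches per SR, with the per-dam-per-hatch
#' expectation declining linearly with dam age from 2.49 to 2.15 and
#' counts integerized by seeded largest remainder so each SR totals
#' exactly `offspring_per_sr` birds.
#'
#' The true (co)variance components default to the full maternal model
#' with both direct-maternal covariances (direct additive 8046, maternal
#' genetic 829, their covariance -912, permanent environmental 906,
#' residual 19860 with Cov(e, pe) = 1272, in g^2); phenotypes additionally
#' carry independent unit-variance dummy noise so that estimation with
#' the dummy residual fixed at 1 targets exactly these values.
#'
#' @param n_sr Number of selection rounds.
#' @param offspring_per_sr Birds hatched and phenotyped per SR.
#' @param n_males_selected,n_females_selected Parents selected per SR.
#' @param dams_per_sire Dams served by one sire (hierarchical mating).
#' @param service_life_sr SR a selected parent stays in the pool.
#' @param hatches_per_sr Hatches per SR.
#' @param random_until_sr Parents are selected at random up to and
#'   including this SR; afterwards truncation selection on BLUP EBV.
#' @param vc True [variance_components()] (single trait).
#' @param sigma2_dummy_noise Variance of the independent dummy noise added
#'   to each phenotype (default: the dummy variance in `vc`).
#' @param base_weight Intercept of the phenotype in g.
#' @param hatch_sd SD of the hatch-within-SR effects (g); default 10% of
#'   the phenotypic SD implied by `vc`.
#' @param sex_effect Additive fixed effect of being male (g).
#' @param dam_age_slope Fixed effect per weekly dam-age class (g).
#' @param offspring_decline Expected offspring per dam per hatch at the
#'   youngest and oldest dam age class.
#' @param estimate_vc Estimate the selection-index variance components
#'   once (after `random_until_sr`) by `moda` REML, as the program would;
#'   if `FALSE` the true components are used for selection.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sr = 40L,
                       offspring_per_sr = 7800L,
                       n_males_selected = 13L,
                       n_females_selected = 130L,
                       dams_per_sire = 10L,
                       service_life_sr = 4L,
                       hatches_per_sr = 6L,
                       random_until_sr = 6L,
                       vc = NULL,
                       sigma2_dummy_noise = NULL,
                       base_weight = 2000,
                       hatch_sd = NULL,
                       sex_effect = 207,
                       dam_age_slope = -2,
                       offspring_decline = c(2.49, 2.15),
                       estimate_vc = TRUE) {
  if (is.null(vc)) {
    vc <- variance_components(
      model_config("coramepe"),
      c(
        sigma2_a = 8046, sigma2_m = 829, sigma_am = -912,
        sigma2_e = 19860, sigma2_pe = 906, sigma_epe = 1272
      )
    )
  }
  if (vc$config$traits != 1L) {
    stop("the simulator uses a single-trait truth", call. = FALSE)
  }
  if (n_females_selected != n_males_selected * dams_per_sire) {
    stop("n_females_selected must equal n_males_selected * dams_per_sire",
      call. = FALSE
    )
  }
  vp <- vc$G0["a", "a"] +
    (if (vc$config$include_maternal) vc$G0["m", "m"] else 0) +
    vc$E0["pe", "pe"] + vc$E0["e", "e"] + vc$sigma2_dummy
  structure(
    list(
      n_sr = as.integer(n_sr),
      offspring_per_sr = as.integer(offspring_per_sr),
      n_males_selected = as.integer(n_males_selected),
      n_females_selected = as.integer(n_females_selected),
      dams_per_sire = as.integer(dams_per_sire),
      service_life_sr = as.integer(service_life_sr),
      hatches_per_sr = as.integer(hatches_per_sr),
      random_until_sr = as.integer(random_until_sr),
      vc = vc,
      sigma2_dummy_noise = if (is.null(sigma2_dummy_noise)) vc$sigma2_dummy else sigma2_dummy_noise,
      base_weight = base_weight,
      hatch_sd = if (is.null(hatch_sd)) 0.1 * sqrt(vp) else hatch_sd,
      sex_effect = sex_effect,
      dam_age_slope = dam_age_slope,
      offspring_decline = offspring_decline,
      estimate_vc = isTRUE(estimate_vc)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "<sim_config> ", x$n_sr, " SR x ", x$offspring_per_sr, " birds; ",
    x$service_life_sr * x$n_males_selected, " active sires, ",
    x$service_life_sr * x$n_females_selected, " active dams; ",
    "random selection through SR ", x$random_until_sr, "\n",
    sep = ""
  )
  invisible(x)
}

## PSD-tolerant multivariate normal draw (the simulator allows degenerate
## truths, e.g. all-zero components).
mvn_draw <- function(n, S) {
  ee <- eigen(S, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), nrow(S))
  Z <- matrix(stats::rnorm(n * nrow(S)), n, nrow(S))
  Z %*% t(L)
}

#' Draw unrelated founder animals
#'
#' Genetic values `(a, m)` are drawn from `MVN(0, G0)` and environmental
#' values `(e, pe)` from `MVN(0, E0)` independently across animals, per
#' the infinitesimal model.
#'
#' @param vc True [variance_components()] (single trait).
#' @param n Number of founders.
#' @return A tibble with columns `a`, `m`, `e`, `pe` (`m` is 0 when the
#'   truth excludes the maternal effect).
#' @export
draw_founders <- function(vc, n) {
  g <- mvn_draw(n, vc$G0)
  ev <- mvn_draw(n, vc$E0)
  tibble::tibble(
    a = g[, 1],
    m = if (ncol(g) > 1) g[, 2] else rep(0, n),
    e = ev[, 1], pe = ev[, 2]
  )
}

#' Mendelian sampling of offspring genetic values
#'
#' Offspring `(a, m)` equal the parent average plus a Mendelian deviation
#' drawn from `MVN(0, 0.5 * G0 * (1 - (F_s + F_d) / 2))`.
#'
#' @param vc True [variance_components()] (single trait).
#' @param a_sire,m_sire,a_dam,m_dam Parental genetic values (vectors).
#' @param f_sire,f_dam Parental inbreeding coefficients.
#' @return A tibble with columns `a` and `m`.
#' @export
mendelian_offspring <- function(vc, a_sire, m_sire, a_dam, m_dam,
                                f_sire = 0, f_dam = 0) {
  n <- length(a_sire)
  q <- nrow(vc$G0)
  ms <- mvn_draw(n, 0.5 * vc$G0) * sqrt(pmax(1 - (f_sire + f_dam) / 2, 0))
  tibble::tibble(
    a = 0.5 * (a_sire + a_dam) + ms[, 1],
    m = if (q > 1) 0.5 * (m_sire + m_dam) + ms[, 2] else rep(0, n)
  )
}

## Integerize expected counts preserving the total (largest remainder,
## random tie-breaking under the run's seed).
largest_remainder <- function(w, total) {
  x <- w / sum(w) * total
  out <- floor(x)
  need <- total - sum(out)
  if (need > 0) {
    rem <- x - out
    ord <- order(-rem, stats::runif(length(x)))
    out[ord[seq_len(need)]] <- out[ord[seq_len(need)]] + 1
  }
  out
}

## Minimal pedigree constructor for internally built (already sorted,
## integer-coded) pedigrees.
ped_from_internal <- function(sire, dam, sex, sr) {
  n <- length(sire)
  sire_ix <- as.integer(sire)
  dam_ix <- as.integer(dam)
  out <- tibble::tibble(
    animal = as.character(seq_len(n)),
    sire = ifelse(sire_ix > 0L, as.character(sire_ix), NA_character_),
    dam = ifelse(dam_ix > 0L, as.character(dam_ix), NA_character_),
    sex = sex,
    sr = pmax(as.integer(sr), 0L),
    .sire = sire_ix, .dam = dam_ix
  )
  class(out) <- c("pedigree", class(out))
  out
}

#' Run the stochastic breeding program
#'
#' Simulates the full breeding program under the infinitesimal model:
#' founder pools, hierarchical matings with seeded hatch allocation,
#' Mendelian inheritance with inbreeding-adjusted sampling variances,
#' phenotypes `BW = fixed + a + m_dam + pe_dam + e + dummy noise`, and
#' per-SR truncation selection (random through `random_until_sr`, then on
#' `moda` pedigree-BLUP breeding values whose variance components are
#' estimated once, after the random phase).  Every phenotype's components
#' are stored, so records decompose exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return An object of class `sim_population`: list with `pedigree`,
#'   `phenotypes` (animal, sr, hatch, sex, dam_age_class, dam, bw),
#'   `truth` (per-animal born SR, true `a`, `m`, `pe`, `e`, dummy noise
#'   and fixed part), `vc_selection`, `config`, `seed`.
#' @export
run_program <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  vc <- config$vc
  n_m <- config$n_males_selected
  n_f <- config$n_females_selected
  serv <- config$service_life_sr
  hatches <- config$hatches_per_sr
  n_found <- serv * (n_m + n_f)
  n_total <- n_found + config$n_sr * config$offspring_per_sr

  sire <- integer(n_total)
  dam <- integer(n_total)
  sex <- character(n_total)
  born <- integer(n_total)
  a <- numeric(n_total)
  m <- numeric(n_total)
  e <- numeric(n_total)
  pe <- numeric(n_total)

  ## founder cohorts, staggered so the starting pool has the full age
  ## structure of a running program
  fd <- draw_founders(vc, n_found)
  a[1:n_found] <- fd$a
  m[1:n_found] <- fd$m
  e[1:n_found] <- fd$e
  pe[1:n_found] <- fd$pe
  pool_m <- vector("list", serv)
  pool_f <- vector("list", serv)
  idx <- 0L
  for (c_ in seq_len(serv)) {
    ids_m <- idx + seq_len(n_m)
    ids_f <- idx + n_m + seq_len(n_f)
    idx <- idx + n_m + n_f
    sex[ids_m] <- "M"
    sex[ids_f] <- "F"
    born[c(ids_m, ids_f)] <- c_ - serv # oldest cohort born serv-1 SR ago
    pool_m[[c_]] <- ids_m
    pool_f[[c_]] <- ids_f
  }

  hatch_eff <- matrix(
    stats::rnorm(config$n_sr * hatches, 0, config$hatch_sd),
    config$n_sr, hatches
  )
  max_ac <- serv * hatches
  decl <- config$offspring_decline
  age_weight <- function(ac) {
    decl[1] + (decl[2] - decl[1]) * (ac - 1) / max(max_ac - 1, 1)
  }

  next_id <- n_found
  pheno <- vector("list", config$n_sr)
  vc_sel <- NULL
  moda_cfg <- model_config("moda")

  current_pedigree <- function(n) {
    ped_from_internal(sire[1:n], dam[1:n], sex[1:n], born[1:n])
  }
  accumulated_records <- function(upto_sr) {
    dplyr::bind_rows(pheno[seq_len(upto_sr)])
  }

  for (t in seq_len(config$n_sr)) {
    sires_t <- unlist(pool_m)
    dams_t <- unlist(pool_f)
    sire_of_dam <- stats::setNames(
      rep(sires_t, each = config$dams_per_sire),
      sample(dams_t)
    )
    ## hatch allocation by dam age
    grid <- expand.grid(dam = dams_t, hatch = seq_len(hatches))
    ac <- (t - born[grid$dam] - 1L) * hatches + grid$hatch
    counts <- largest_remainder(age_weight(ac), config$offspring_per_sr)
    off_dam <- rep(grid$dam, counts)
    off_hatch <- rep(grid$hatch, counts)
    off_ac <- rep(ac, counts)
    n_off <- length(off_dam)
    off_sire <- unname(sire_of_dam[as.character(off_dam)])
    ids <- next_id + seq_len(n_off)
    next_id <- next_id + n_off

    f_all <- ml_inbreeding_cpp(sire[1:(ids[1] - 1L)], dam[1:(ids[1] - 1L)])
    gen <- mendelian_offspring(
      vc, a[off_sire], m[off_sire], a[off_dam], m[off_dam],
      f_all[off_sire], f_all[off_dam]
    )
    env <- mvn_draw(n_off, vc$E0)
    sx <- sample(c("M", "F"), n_off, replace = TRUE)
    sire[ids] <- off_sire
    dam[ids] <- off_dam
    sex[ids] <- sx
    born[ids] <- t
    a[ids] <- gen$a
    m[ids] <- gen$m
    e[ids] <- env[, 1]
    pe[ids] <- env[, 2]

    fixed_part <- config$base_weight +
      hatch_eff[cbind(t, off_hatch)] +
      config$sex_effect * (sx == "M") +
      config$dam_age_slope * off_ac
    dn <- stats::rnorm(n_off, 0, sqrt(config$sigma2_dummy_noise))
    bw <- fixed_part + a[ids] + m[off_dam] + pe[off_dam] + e[ids] + dn
    pheno[[t]] <- tibble::tibble(
      animal = as.character(ids), sr = t, hatch = off_hatch, sex = sx,
      dam_age_class = off_ac, dam = as.character(off_dam), bw = bw,
      fixed_part = fixed_part, dummy = dn
    )

    ## select the next cohort (not needed after the final SR)
    if (t < config$n_sr) {
      males <- ids[sx == "M"]
      females <- ids[sx == "F"]
      if (t <= config$random_until_sr) {
        sel_m <- sample(males, n_m)
        sel_f <- sample(females, n_f)
      } else {
        recs <- accumulated_records(t)
        pedt <- current_pedigree(next_id)
        if (is.null(vc_sel)) {
          vc_sel <- if (config$estimate_vc) {
            ft <- reml_on_prep(
              mme_prep(
                build_design(
                  recs[c("animal", "sr", "hatch", "sex", "dam_age_class", "bw")],
                  pedt, moda_cfg
                ),
                pedt
              ),
              moda_cfg
            )
            ft$vc
          } else {
            variance_components(moda_cfg, c(
              sigma2_a = vc$G0["a", "a"],
              sigma2_pe = vc$E0["pe", "pe"],
              sigma2_e = vc$E0["e", "e"]
            ), sigma2_dummy = vc$sigma2_dummy)
          }
        }
        sol <- blup(
          recs[c("animal", "sr", "hatch", "sex", "dam_age_class", "bw")],
          pedt, moda_cfg, vc_sel
        )
        ebv <- stats::setNames(sol$ebv$a, sol$ebv$animal)
        sel_m <- males[order(ebv[as.character(males)], decreasing = TRUE)][seq_len(n_m)]
        sel_f <- females[order(ebv[as.character(females)], decreasing = TRUE)][seq_len(n_f)]
      }
      pool_m <- c(pool_m[-1], list(sel_m))
      pool_f <- c(pool_f[-1], list(sel_f))
    }
  }

  phenotypes <- dplyr::bind_rows(pheno)
  truth <- tibble::tibble(
    animal = as.character(seq_len(n_total)),
    born = born[1:n_total], sex = sex[1:n_total],
    a = a[1:n_total], m = m[1:n_total], pe = pe[1:n_total], e = e[1:n_total]
  )
  truth <- dplyr::left_join(
    truth,
    phenotypes[c("animal", "fixed_part", "dummy", "bw")],
    by = "animal"
  )
  structure(
    list(
      pedigree = ped_from_internal(sire, dam, sex, born),
      phenotypes = phenotypes[c(
        "animal", "sr", "hatch", "sex",
        "dam_age_class", "dam", "bw"
      )],
      truth = truth,
      vc_selection = vc_sel,
      config = config,
      seed = seed
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(
    "<sim_population> ", nrow(x$phenotypes), " phenotyped birds over ",
    x$config$n_sr, " SR (", nrow(x$pedigree), " animals in pedigree), seed ",
    x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
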