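test_that("founder draws match the configured truth", {
  set.seed(101)
  vc <- true_vc()
  fd <- draw_founders(vc, 10000)
  ## Monte Carlo tolerance: 3 SE of a variance/correlation at n = 10,000
  expect_equal(stats::var(fd$a), 8046, tolerance = 3 * sqrt(2 / 10000))
  expect_equal(stats::var(fd$m), 829, tolerance = 3 * sqrt(2 / 10000))
  expect_equal(stats::cor(fd$a, fd$m), -912 / sqrt(8046 * 829), tolerance = 0.02)
  expect_equal(stats::cor(fd$e, fd$pe), 1272 / sqrt(19860 * 906), tolerance = 0.03)
  ## no genetic covariance configured, none simulated
  vc0 <- variance_components(
    model_config("modam"),
    c(sigma2_a = 8046, sigma2_m = 829, sigma2_e = 19860, sigma2_pe = 906)
  )
  fd0 <- draw_founders(vc0, 10000)
  expect_lt(abs(stats::cor(fd0$a, fd0$m)), 0.03)
})

test_that("Mendelian sampling follows the infinitesimal rules", {
  set.seed(102)
  vc <- true_vc()
  n <- 10000
  off <- mendelian_offspring(
    vc, rep(100, n), rep(10, n), rep(-50, n), rep(-5, n)
  )
  expect_equal(mean(off$a), 25, tolerance = 3 * sqrt(0.5 * 8046 / n) / 25)
  expect_equal(stats::var(off$a - 25), 0.5 * 8046, tolerance = 3 * sqrt(2 / n))
  ## inbred parents shrink the sampling variance by 1 - (Fs + Fd)/2
  off_i <- mendelian_offspring(
    vc, rep(0, n), rep(0, n), rep(0, n), rep(0, n),
    f_sire = 0.25, f_dam = 0.25
  )
  expect_equal(stats::var(off_i$a), 0.5 * 8046 * 0.75, tolerance = 3 * sqrt(2 / n))
})

test_that("one full-scale round reproduces the program's design numbers", {
  cfg <- sim_config(n_sr = 1, random_until_sr = 1)
  pop <- suppressMessages(run_program(cfg, seed = 5))
  expect_equal(nrow(pop$phenotypes), 7800)
  fam <- table(pop$phenotypes$dam)
  expect_equal(length(fam), 520) # every active dam contributes
  expect_equal(mean(fam), 15)
  ## each dam mated to exactly one sire, each sire to 10 dams
  ds <- unique(pop$phenotypes[c("dam", "animal")])
  sire_of <- pop$pedigree$.sire[match(pop$phenotypes$animal, pop$pedigree$animal)]
  per_dam <- tapply(sire_of, pop$phenotypes$dam, function(s) length(unique(s)))
  expect_true(all(per_dam == 1))
  expect_equal(length(unique(sire_of)), 52)
  ## sex assignment within binomial 99% bounds of one half
  p_m <- mean(pop$phenotypes$sex == "M")
  expect_lt(abs(p_m - 0.5), 2.58 * sqrt(0.25 / 7800))
  ## per-dam-per-hatch counts decline with dam age
  young <- pop$phenotypes$dam_age_class <= 6
  n_young <- sum(young) / length(unique(paste(
    pop$phenotypes$dam[young], pop$phenotypes$hatch[young]
  )))
  old <- pop$phenotypes$dam_age_class > 18
  n_old <- sum(old) / length(unique(paste(
    pop$phenotypes$dam[old], pop$phenotypes$hatch[old]
  )))
  expect_gt(n_young, n_old)
})

test_that("every phenotype decomposes exactly into its stored components", {
  pop <- small_population()
  tr <- pop$truth
  ph <- pop$phenotypes
  i <- match(ph$animal, tr$animal)
  d <- match(ph$dam, tr$animal)
  rebuilt <- tr$fixed_part[i] + tr$a[i] + tr$m[d] + tr$pe[d] + tr$e[i] + tr$dummy[i]
  expect_equal(ph$bw, rebuilt, tolerance = 1e-12)
  ## phenotypic variance of fixed-corrected records matches the truth,
  ## including the parent-offspring genetic covariance -sigma_am/ ... the
  ## dam term: var = sum of components + 2 * cov(a_i, m_dam)
  first <- ph[ph$sr == 1, ]
  y0 <- first$bw - tr$fixed_part[match(first$animal, tr$animal)]
  expected <- 8046 + 829 + 906 + 19860 + 1 + (-912)
  expect_equal(stats::var(y0), expected, tolerance = 0.15)
  ## male fixed effect recovered from the raw means
  delta <- mean(ph$bw[ph$sex == "M"]) - mean(ph$bw[ph$sex == "F"])
  expect_equal(delta, pop$config$sex_effect, tolerance = 0.15)
})

test_that("the simulated pedigree round-trips through the pedigree module", {
  pop <- small_population()
  ped <- as_pedigree(as.data.frame(
    pop$pedigree[c("animal", "sire", "dam", "sex", "sr")]
  ))
  expect_equal(nrow(ped), nrow(pop$pedigree))
  ## parents precede offspring and A-inverse builds cleanly
  expect_true(all(ped$.sire < seq_len(nrow(ped))))
  Ai <- a_inverse(ped)
  expect_true(Matrix::isSymmetric(Ai))
  ## every non-founder's parents come from earlier rounds
  born <- pop$truth$born[match(pop$pedigree$animal, pop$truth$animal)]
  nf <- pop$pedigree$.sire > 0
  expect_true(all(born[pop$pedigree$.sire[nf]] < born[nf]))
})

test_that("selection on BLUP breeding values creates a genetic trend", {
  cfg_sel <- sim_config(
    n_sr = 6, offspring_per_sr = 400, n_males_selected = 2,
    n_females_selected = 20, service_life_sr = 2, random_until_sr = 2
  )
  cfg_rand <- sim_config(
    n_sr = 6, offspring_per_sr = 400, n_males_selected = 2,
    n_females_selected = 20, service_life_sr = 2, random_until_sr = 6
  )
  pop_sel <- suppressMessages(run_program(cfg_sel, seed = 31))
  pop_rand <- suppressMessages(run_program(cfg_rand, seed = 31))
  trend <- function(pop) {
    tr <- pop$truth[pop$truth$born > 0, ]
    unname(tapply(tr$a, tr$born, mean))
  }
  t_sel <- trend(pop_sel)
  t_rand <- trend(pop_rand)
  ## selection response positive and clearly above drift
  expect_gt(t_sel[6] - t_sel[2], 2 * sqrt(8046) * 0.5)
  expect_gt(t_sel[6], t_rand[6] + sqrt(8046) * 0.5)
  ## random selection: trend indistinguishable from drift around zero
  expect_lt(abs(t_rand[6]), 2 * sqrt(8046) * 0.5)
  ## deterministic given the seed
  pop_sel2 <- suppressMessages(run_program(cfg_sel, seed = 31))
  expect_equal(pop_sel2$phenotypes$bw, pop_sel$phenotypes$bw)
})

test_that("degenerate truths produce degenerate phenotypes", {
  vc0 <- variance_components(
    model_config("modam"),
    c(sigma2_a = 0, sigma2_m = 0, sigma2_e = 0, sigma2_pe = 0)
  )
  cfg <- sim_config(
    n_sr = 2, offspring_per_sr = 100, n_males_selected = 2,
    n_females_selected = 20, service_life_sr = 1, random_until_sr = 2,
    vc = vc0, sigma2_dummy_noise = 0, base_weight = 0, hatch_sd = 0,
    sex_effect = 0, dam_age_slope = 0
  )
  pop <- suppressMessages(run_program(cfg, seed = 1))
  expect_true(all(pop$phenotypes$bw == 0))
})
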