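test_that("the restricted likelihood matches the dense formula and its laws", {
  ped <- random_pedigree(26, 6, seed = 31)
  recs <- random_records(ped, n_rec = 8)
  cfg <- model_config("coramepe")
  vc <- test_vc(cfg)
  m2l <- quiet(restricted_log_likelihood(recs, ped, cfg, vc))
  or <- quiet(dense_mixed_model_oracle(recs, ped, cfg, vc))
  expect_equal(as.numeric(m2l), or$minus2logL, tolerance = 1e-7)

  ## scaling the data by c and the components by c^2 shifts -2logL by
  ## (n - rank X) log(c^2)
  cc <- 3
  recs_s <- recs
  recs_s$bw <- recs$bw * cc
  vc_s <- variance_components(cfg, willham:::vc_free_values(vc) * cc^2,
    sigma2_dummy = cc^2
  )
  m2l_s <- quiet(restricted_log_likelihood(recs_s, ped, cfg, vc_s))
  ds <- quiet(build_design(recs, ped, cfg))
  expect_equal(
    as.numeric(m2l_s) - as.numeric(m2l),
    (nrow(recs) - ncol(ds$X)) * log(cc^2),
    tolerance = 1e-6
  )

  ## two independent copies (disjoint fixed levels) double the deviance
  ped_b <- random_pedigree(26, 6, seed = 31) # identical structure
  ped_b$animal <- paste0("B", ped_b$animal)
  ped_b$sire <- ifelse(is.na(ped_b$sire), NA, paste0("B", ped_b$sire))
  ped_b$dam <- ifelse(is.na(ped_b$dam), NA, paste0("B", ped_b$dam))
  ped2 <- as_pedigree(dplyr::bind_rows(
    as.data.frame(ped[c("animal", "sire", "dam", "sex")]),
    as.data.frame(ped_b[c("animal", "sire", "dam", "sex")])
  ))
  recs_b <- recs
  recs_b$animal <- paste0("B", recs$animal)
  recs_b$sr <- recs$sr + 10 # disjoint fixed-effect levels
  both <- dplyr::bind_rows(recs, recs_b)
  fixed <- ~ 0 + factor(sr)
  m2l_1 <- quiet(restricted_log_likelihood(recs, ped, cfg, vc, fixed = fixed))
  m2l_2 <- quiet(restricted_log_likelihood(both, ped2, cfg, vc, fixed = fixed))
  expect_equal(as.numeric(m2l_2), 2 * as.numeric(m2l_1), tolerance = 1e-6)
})

test_that("EM steps decrease the deviance and respect masks and the dummy", {
  cfg_sim <- sim_config(
    n_sr = 3, offspring_per_sr = 150, n_males_selected = 3,
    n_females_selected = 30, service_life_sr = 1, random_until_sr = 3
  )
  pop <- suppressMessages(run_program(cfg_sim, seed = 99))
  phen <- pop$phenotypes
  ped <- pop$pedigree
  cfg <- model_config("coramepe")
  vc0 <- variance_components(cfg, c(
    sigma2_a = 8046, sigma2_m = 829, sigma_am = -912,
    sigma2_e = 35000, sigma2_pe = 906, sigma_epe = 1272
  ))
  st <- quiet(em_step(phen, ped, cfg, vc0))
  m2l_new <- quiet(restricted_log_likelihood(phen, ped, cfg, st$vc))
  expect_lt(as.numeric(m2l_new), st$minus2logL)
  expect_equal(st$vc$sigma2_dummy, 1)

  ## a masked covariance stays exactly zero through EM and AI steps
  cfg_cor <- model_config("coram")
  vc_cor <- variance_components(cfg_cor, c(
    sigma2_a = 8046, sigma2_m = 829, sigma_am = -500,
    sigma2_e = 25000, sigma2_pe = 906
  ))
  st2 <- quiet(em_step(phen, ped, cfg_cor, vc_cor))
  expect_identical(st2$vc$E0["e", "pe"], 0)
  st3 <- quiet(ai_step(phen, ped, cfg_cor, vc_cor))
  expect_identical(st3$vc$E0["e", "pe"], 0)
  expect_lte(st3$minus2logL_new, st3$minus2logL)
  expect_equal(st3$vc$sigma2_dummy, 1)
})

test_that("estimation converges with monotone descent and a near-fixed point", {
  pop <- small_population()
  fit <- quiet(reml(pop$phenotypes, pop$pedigree, "modam"))
  expect_true(fit$converged)
  ## descent up to the numerical noise floor of the evaluation
  d <- diff(fit$trace$minus2logL)
  expect_true(all(d <= 1e-8 * abs(fit$minus2logL)))
  ## at the optimum one more AI step moves each parameter by a
  ## negligible fraction of its standard error and gains essentially no
  ## likelihood (weakly identified components sit in flat directions, so
  ## the SE is the right yardstick)
  st <- quiet(ai_step(
    pop$phenotypes, pop$pedigree, model_config("modam"), fit$vc
  ))
  move <- abs(willham:::vc_free_values(st$vc) - willham:::vc_free_values(fit$vc))
  expect_lt(max(move / fit$se[names(move)]), 0.05)
  expect_lt(st$minus2logL - st$minus2logL_new, 0.01)
  ## standard errors are finite and positive
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  ## tidiers
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$model, "modam")
  expect_equal(gl$n, nrow(pop$phenotypes))
})

test_that("estimates sit at the optimum of an exhaustive likelihood grid", {
  pop <- small_population()
  phen <- pop$phenotypes[pop$phenotypes$sr <= 5, ]
  fit <- quiet(reml(phen, pop$pedigree, "moda"))
  th <- fit$theta
  ## 2-d grid through the optimum in (sigma2_a, sigma2_e)
  grid <- expand.grid(
    sigma2_a = th["sigma2_a"] * c(0.7, 0.85, 1, 1.15, 1.3),
    sigma2_e = th["sigma2_e"] * c(0.9, 0.95, 1, 1.05, 1.1)
  )
  vc_hat <- fit$vc
  res <- quiet(grid_reml_oracle(phen, pop$pedigree, model_config("moda"), vc_hat, grid))
  expect_equal(unname(res$sigma2_a[1]), unname(th[["sigma2_a"]]))
  expect_equal(unname(res$sigma2_e[1]), unname(th[["sigma2_e"]]))
  expect_false(attr(res, "boundary"))
  ## a grid that excludes the optimum flags its edge
  grid_off <- expand.grid(
    sigma2_a = th["sigma2_a"] * c(1.5, 2),
    sigma2_e = th["sigma2_e"]
  )
  res_off <- quiet(grid_reml_oracle(
    phen, pop$pedigree, model_config("moda"), vc_hat, grid_off
  ))
  expect_true(attr(res_off, "boundary"))
  ## single-point grid returns that point
  res_one <- quiet(grid_reml_oracle(
    phen, pop$pedigree, model_config("moda"), vc_hat,
    data.frame(sigma2_a = 5000)
  ))
  expect_equal(nrow(res_one), 1L)
})

test_that("likelihood-ratio tests behave on nested pairs", {
  pop <- small_population()
  phen <- pop$phenotypes[pop$phenotypes$sr <= 5, ]
  f_modam <- quiet(reml(phen, pop$pedigree, "modam"))
  f_cam <- quiet(reml(phen, pop$pedigree, "coramepe"))
  out <- lrt(f_modam, f_cam)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 2)
  expect_true(out$p.value >= 0 && out$p.value <= 1)
  same <- lrt(f_modam, f_modam)
  expect_equal(same$statistic, 0)
  expect_error(lrt(f_cam, f_modam), "not nested")
})

test_that("a dummy variance rivaling the residual triggers a warning", {
  pop <- small_population()
  phen <- pop$phenotypes[pop$phenotypes$sr <= 4, ]
  expect_warning(
    quiet(reml(phen, pop$pedigree, "moda",
      init = c(sigma2_a = 8000, sigma2_pe = 900, sigma2_e = 15000),
      sigma2_dummy = 20000,
      control = reml_control(max_iter = 1)
    )),
    "dummy"
  )
})
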