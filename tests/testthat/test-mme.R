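test_that("design bookkeeping follows the incidence definitions", {
  ped <- as_pedigree(data.frame(
    animal = c("s", "d", "k1", "k2", "k3"),
    sire = c(NA, NA, "s", "s", "s"),
    dam = c(NA, NA, "d", "d", "d"),
    sex = c("M", "F", "F", "M", "F")
  ))
  recs <- data.frame(animal = c("k1", "k2", "k3"), bw = c(1900, 2100, 2000))
  cfg <- model_config("coramepe")
  ds <- quiet(build_design(recs, ped, cfg))
  ## one pe level for the single dam; an e level per record
  expect_equal(nrow(ds$pe_levels), 1L)
  inc <- willham:::design_incidence(ds, ped)
  expect_true(all(Matrix::rowSums(inc$B) == 2)) # own e + dam pe
  expect_true(all(Matrix::rowSums(inc$B^2) == 2))
  lay <- inc$env_layout
  expect_setequal(lay$comp[lay$.an == 2], "pe") # unphenotyped dam: pe only

  ## a phenotyped dam owns a joint (e, pe) covariance block
  recs2 <- rbind(recs, data.frame(animal = "d", bw = 1800))
  ds2 <- quiet(build_design(recs2, ped, cfg))
  prep2 <- quiet(willham:::mme_prep(ds2, ped))
  expect_setequal(
    prep2$env_cols$comp[prep2$env_cols$.an == 2],
    c("e", "pe")
  )

  ## unknown dam: no maternal linkage, counted
  ped3 <- as_pedigree(
    data.frame(animal = c("s", "k"), sire = c(NA, "s"), dam = NA, sex = c("M", "M"))
  )
  ds3 <- quiet(build_design(
    data.frame(animal = "k", bw = 2000), ped3, cfg
  ))
  expect_equal(ds3$n_unknown_dam, 1L)
  inc3 <- willham:::design_incidence(ds3, ped3)
  expect_equal(Matrix::rowSums(inc3$B), 1) # own e only, W row zero

  ## record for an animal not in the pedigree, duplicates
  expect_error(
    build_design(data.frame(animal = "zz", bw = 1), ped, cfg),
    "absent from pedigree"
  )
  expect_error(
    build_design(
      data.frame(animal = c("k1", "k1"), bw = c(1, 2)), ped, cfg
    ),
    "duplicate record"
  )
})

test_that("sparse equations equal the dense GLS oracle for every model", {
  for (traits in 1:2) {
    for (model in c("moda", "modam", "coram", "corepe", "coramepe")) {
      seed <- 1000 + 10 * traits + match(model, c("moda", "modam", "coram", "corepe", "coramepe"))
      ped <- random_pedigree(28, 6, seed = seed)
      recs <- random_records(ped, n_rec = 22)
      cfg <- model_config(model, traits)
      vc <- test_vc(cfg)
      or <- quiet(dense_mixed_model_oracle(recs, ped, cfg, vc))
      sol <- quiet(blup(recs, ped, cfg, vc))
      m2l <- quiet(restricted_log_likelihood(recs, ped, cfg, vc))
      expect_equal(as.numeric(m2l), or$minus2logL, tolerance = 1e-6)
      expect_equal(sol$fixed$estimate, unname(or$b), tolerance = 1e-6)
      a_name <- if (traits == 1) "a" else "a_F"
      expect_equal(
        sol$ebv[[a_name]],
        unname(or$u[paste0(a_name, ".", ped$animal)]),
        tolerance = 1e-6
      )
      ## residual random effects, including analytically recovered
      ## absorbed levels
      e_pref <- if (traits == 1) "e" else c("e_F", "e_M")[sol$residuals$trait]
      expect_equal(
        sol$residuals$e,
        unname(or$u[paste0(e_pref, ".", sol$residuals$animal)]),
        tolerance = 1e-6
      )
    }
  }
})

test_that("absorption of free-standing residual levels is exact", {
  ped <- random_pedigree(40, 8, seed = 77)
  recs <- random_records(ped, n_rec = 30)
  cfg <- model_config("coramepe")
  vc <- test_vc(cfg)
  ds <- quiet(build_design(recs, ped, cfg))
  p_abs <- quiet(willham:::mme_prep(ds, ped, absorb = TRUE))
  p_exp <- quiet(willham:::mme_prep(ds, ped, absorb = FALSE))
  f_abs <- willham:::mme_fit(p_abs, vc)
  f_exp <- willham:::mme_fit(p_exp, vc)
  expect_lt(p_abs$dim, p_exp$dim)
  expect_equal(f_abs$minus2logL, f_exp$minus2logL, tolerance = 1e-8)
  s_abs <- willham:::solution_tibbles(p_abs, f_abs)
  s_exp <- willham:::solution_tibbles(p_exp, f_exp)
  expect_equal(s_abs$ebv$a, s_exp$ebv$a, tolerance = 1e-8)
  expect_equal(s_abs$residuals$e, s_exp$residuals$e, tolerance = 1e-8)
})

test_that("solutions respect translation and permutation invariance", {
  ped <- random_pedigree(30, 6, seed = 55)
  recs <- random_records(ped, n_rec = 24)
  cfg <- model_config("modam")
  vc <- test_vc(cfg)
  s1 <- quiet(blup(recs, ped, cfg, vc))
  recs_shift <- recs
  recs_shift$bw <- recs$bw + 500
  s2 <- quiet(blup(recs_shift, ped, cfg, vc))
  expect_equal(s1$ebv$a, s2$ebv$a, tolerance = 1e-8)
  expect_equal(s1$ebv$m, s2$ebv$m, tolerance = 1e-8)
  ## only the intercept moves
  icpt <- s1$fixed$term == "(Intercept)"
  expect_equal(s2$fixed$estimate[icpt] - s1$fixed$estimate[icpt], 500, tolerance = 1e-8)
  expect_equal(s2$fixed$estimate[!icpt], s1$fixed$estimate[!icpt], tolerance = 1e-8)

  set.seed(2)
  perm <- sample(nrow(recs))
  s3 <- quiet(blup(recs[perm, ], ped, cfg, vc))
  expect_equal(s3$ebv, s1$ebv, tolerance = 1e-10)
  expect_equal(s3$minus2logL, s1$minus2logL, tolerance = 1e-10)
})

test_that("the full model collapses to nested models when covariances vanish", {
  ped <- random_pedigree(35, 6, seed = 91)
  recs <- random_records(ped, n_rec = 27)
  vc_full <- variance_components(
    model_config("coramepe"),
    c(
      sigma2_a = 8000, sigma2_m = 900, sigma_am = 0,
      sigma2_e = 20000, sigma2_pe = 950, sigma_epe = 0
    )
  )
  vc_nested <- variance_components(
    model_config("modam"),
    c(sigma2_a = 8000, sigma2_m = 900, sigma2_e = 20000, sigma2_pe = 950)
  )
  s_full <- quiet(blup(recs, ped, model_config("coramepe"), vc_full))
  s_nested <- quiet(blup(recs, ped, model_config("modam"), vc_nested))
  expect_equal(s_full$ebv$a, s_nested$ebv$a, tolerance = 1e-8)
  expect_equal(s_full$ebv$m, s_nested$ebv$m, tolerance = 1e-8)
  expect_equal(s_full$minus2logL, s_nested$minus2logL, tolerance = 1e-7)
})

test_that("with a vanishing pe variance the moda fit is the plain animal model", {
  ped <- random_pedigree(30, 6, seed = 13)
  recs <- random_records(ped, n_rec = 24)
  vc <- variance_components(
    model_config("moda"),
    c(sigma2_a = 8000, sigma2_pe = 1e-6, sigma2_e = 20000)
  )
  sol <- quiet(blup(recs, ped, model_config("moda"), vc))
  ## dense animal-model BLUP: V = sigma2_a * Z A Z' + (sigma2_e + 1) I
  ds <- quiet(build_design(recs, ped, model_config("moda")))
  A <- tabular_relationship(ped)
  X <- as.matrix(ds$X)
  Z <- matrix(0, nrow(recs), nrow(ped))
  Z[cbind(seq_len(nrow(recs)), ds$records$.an)] <- 1
  V <- 8000 * Z %*% A %*% t(Z) + diag(20001, nrow(recs))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ds$records$y)
  a_hat <- 8000 * A %*% t(Z) %*% Vi %*% (ds$records$y - X %*% b)
  expect_equal(sol$ebv$a, as.numeric(a_hat), tolerance = 1e-3)
})
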