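test_that("each model frees exactly the parameters of its covariance display", {
  free_terms <- function(model, traits = 1) {
    pm <- parameter_map(model_config(model, traits))
    pm$term[pm$free]
  }
  ## single trait: 3, 4, 5, 5, 6 free parameters
  expect_setequal(free_terms("moda"), c("sigma2_a", "sigma2_e", "sigma2_pe"))
  expect_setequal(
    free_terms("modam"),
    c("sigma2_a", "sigma2_m", "sigma2_e", "sigma2_pe")
  )
  expect_setequal(
    free_terms("coram"),
    c("sigma2_a", "sigma2_m", "sigma_am", "sigma2_e", "sigma2_pe")
  )
  expect_setequal(
    free_terms("corepe"),
    c("sigma2_a", "sigma2_m", "sigma2_e", "sigma2_pe", "sigma_epe")
  )
  expect_setequal(
    free_terms("coramepe"),
    c("sigma2_a", "sigma2_m", "sigma_am", "sigma2_e", "sigma2_pe", "sigma_epe")
  )

  ## two traits: the female residual may covary with both permanent
  ## environmental effects; the male residual never covaries with anything
  ft <- free_terms("corepe", 2)
  expect_true(all(c("sigma_eF.peF", "sigma_eF.peM", "sigma_peF.peM") %in% ft))
  expect_false(any(c("sigma_eM.peF", "sigma_eM.peM", "sigma_eF.eM") %in% ft))
  ## cross-sex genetic covariances always estimated; a-m crosses only
  ## with the genetic covariance switched on
  expect_true("sigma_aF.aM" %in% free_terms("moda", 2))
  expect_false("sigma_aF.mF" %in% free_terms("corepe", 2))
  expect_true(all(
    c("sigma_aF.mF", "sigma_aF.mM", "sigma_aM.mF", "sigma_aM.mM") %in%
      free_terms("coram", 2)
  ))
  ## moda excludes the maternal genetic factors altogether
  expect_false(any(grepl("_m|2_m", free_terms("moda"))))
  expect_equal(length(free_terms("moda", 2)), 8L)
  expect_equal(length(free_terms("coramepe", 2)), 17L)
})

test_that("masked entries are hard zeros and rejected as inputs", {
  cfg <- model_config("modam")
  vc <- variance_components(cfg, c(
    sigma2_a = 8046, sigma2_m = 829, sigma2_e = 19860, sigma2_pe = 906
  ))
  expect_equal(vc$G0["a", "m"], 0)
  expect_equal(vc$E0["e", "pe"], 0)
  expect_error(
    variance_components(cfg, c(
      sigma2_a = 8046, sigma2_m = 829, sigma2_e = 19860,
      sigma2_pe = 906, sigma_am = -912
    )),
    "structural zero"
  )
  expect_error(
    variance_components(cfg, c(sigma2_a = 8046)),
    "missing value"
  )
  expect_error(
    variance_components(
      model_config("coram"),
      c(
        sigma2_a = 100, sigma2_m = 100, sigma_am = -150,
        sigma2_e = 1000, sigma2_pe = 100
      )
    ),
    "not positive semi-definite"
  )
})

test_that("the true residual is the estimated residual plus the dummy", {
  vc <- variance_components(
    model_config("coramepe"),
    c(
      sigma2_a = 8046, sigma2_m = 829, sigma_am = -912,
      sigma2_e = 19918, sigma2_pe = 906, sigma_epe = 1272
    )
  )
  expect_equal(unname(total_residual_variance(vc)), 19919)

  vc0 <- variance_components(
    model_config("modam"),
    c(sigma2_a = 1, sigma2_m = 1, sigma2_e = 0, sigma2_pe = 1)
  )
  expect_equal(unname(total_residual_variance(vc0)), 1)

  vc2 <- variance_components(
    model_config("coramepe", 2),
    c(
      sigma2_aF = 4952, sigma2_aM = 8170, sigma_aF.aM = 5000,
      sigma2_mF = 1016, sigma2_mM = 1608, sigma_mF.mM = 800,
      sigma_aF.mF = -795, sigma_aF.mM = -600, sigma_aM.mF = -600,
      sigma_aM.mM = -1436,
      sigma2_eF = 14772, sigma2_eM = 23523,
      sigma2_peF = 727, sigma2_peM = 1254, sigma_peF.peM = 500,
      sigma_eF.peF = 1048, sigma_eF.peM = 1232
    )
  )
  expect_equal(total_residual_variance(vc2), c(F = 14773, M = 23524))
})

test_that("heritabilities and correlations reproduce the reference study", {
  ## single-trait truth: r_am = -912 / sqrt(8046 * 829)
  dr <- derived_ratios(true_vc())
  expect_equal(dr$r_am, -912 / sqrt(8046 * 829), tolerance = 1e-12)
  expect_equal(round(dr$r_am, 3), -0.353)
  expect_equal(dr$r_epe, 1272 / sqrt(19860 * 906), tolerance = 1e-12)

  ## real-data components reproduce the printed heritabilities to 2 dp,
  ## validating the phenotypic-variance convention (dummy included,
  ## covariances excluded)
  moda_f <- variance_components(
    model_config("moda"),
    c(sigma2_a = 5967, sigma2_pe = 792, sigma2_e = 14259)
  )
  expect_equal(round(derived_ratios(moda_f)$h2, 2), 0.28)

  cam2 <- variance_components(
    model_config("coramepe", 2),
    c(
      sigma2_aF = 4952, sigma2_aM = 8170, sigma_aF.aM = 5000,
      sigma2_mF = 1016, sigma2_mM = 1608, sigma_mF.mM = 900,
      sigma_aF.mF = -795, sigma_aF.mM = -700, sigma_aM.mF = -700,
      sigma_aM.mM = -1436,
      sigma2_eF = 14772, sigma2_eM = 23523,
      sigma2_peF = 727, sigma2_peM = 1254, sigma_peF.peM = 600,
      sigma_eF.peF = 1048, sigma_eF.peM = 1232
    )
  )
  dr2 <- derived_ratios(cam2)
  expect_equal(round(dr2$h2, 2), c(0.23, 0.24))
  expect_equal(round(dr2$r_am, 2), c(-0.35, -0.40))
  ## the dam's residual is the female one for both sexes
  expect_equal(round(dr2$r_epe, 2), c(0.32, 0.29))

  ## masked covariance gives correlation exactly 0; zero variance in a
  ## requested denominator is an error
  expect_equal(derived_ratios(variance_components(
    model_config("modam"),
    c(sigma2_a = 1, sigma2_m = 1, sigma2_e = 1, sigma2_pe = 1)
  ))$r_epe, 0)
  expect_error(
    derived_ratios(variance_components(
      model_config("coramepe"),
      c(
        sigma2_a = 1, sigma2_m = 1, sigma_am = 0,
        sigma2_e = 1, sigma2_pe = 0, sigma_epe = 0.5
      )
    )),
    "not positive semi-definite|undefined ratio"
  )
})

test_that("bending projects onto the cone without touching masked zeros", {
  cfg <- model_config("coram")
  bad <- willham:::vc_project(
    cfg,
    c(
      sigma2_a = 100, sigma2_m = 100, sigma_am = -150,
      sigma2_e = 1000, sigma2_pe = 100
    ),
    sigma2_dummy = 1
  )
  ev <- eigen(bad$G0, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(bad$E0["e", "pe"], 0) # mask survives bending
  ## PD input passes through unchanged
  ok <- willham:::vc_project(
    cfg,
    c(
      sigma2_a = 100, sigma2_m = 100, sigma_am = -50,
      sigma2_e = 1000, sigma2_pe = 100
    ),
    sigma2_dummy = 1
  )
  expect_equal(ok$G0["a", "m"], -50)
})
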