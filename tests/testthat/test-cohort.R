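# Synthetic cohort generator: configuration guards, calibrations, latents,
# impairment model, outcome model, covariate couplings, determinism.

test_that("configuration guards reject invalid settings", {
  expect_error(cohort_config(n_subjects = 1), "at least 2")
  expect_error(cohort_config(spacing = -1), "positive")
  expect_error(cohort_config(mace_rate = 1.2), "in \\(0,1\\)")
  expect_error(cohort_config(n_frames = 25, es_frame = 25), "interior")
})

test_that("zero-latent subject hits the healthy LVEF target exactly", {
  cfg <- fx_config()
  ed <- lvshape:::subject_ed_mesh(cfg)
  es <- deform_ed_to_es(ed, list(z_global = 0, z_anterior = 0, z_basal = 0),
                        cfg)
  expect_equal(lvef(mesh_cavity_volume(ed), mesh_cavity_volume(es)),
               cfg$lvef_healthy, tolerance = 1e-5)
})

test_that("outcome calibration meets the marginal rate and Bayes AUC", {
  cfg <- fx_config()
  set.seed(99)
  z <- matrix(rnorm(3 * 20000), ncol = 3)
  lp <- cfg$outcome_beta0 + drop(z %*% cfg$outcome_beta)
  expect_lt(abs(mean(plogis(lp)) - cfg$mace_rate), 0.005)
  y <- as.integer(runif(20000) < plogis(lp))
  expect_equal(auc(lp, y), cfg$bayes_auc, tolerance = 0.03)
})

test_that("latent draws are standard normal and reproducible", {
  cfg <- fx_config()
  lat <- sample_latents(cfg, n = 10000)
  expect_equal(ncol(lat), 22L)
  expect_named(lat, c("z_global", "z_anterior", "z_basal", "z_size",
                      "z_elongation", "z_thickness",
                      paste0("h_shape_", 1:8), paste0("h_contr_", 1:8)))
  expect_true(all(abs(colMeans(lat)) < 0.05))
  expect_true(all(vapply(lat, sd, numeric(1)) > 0.95))
  expect_true(all(vapply(lat, sd, numeric(1)) < 1.05))
  expect_identical(lat, sample_latents(cfg, n = 10000))
})

test_that("impairment field is in (0,1) and monotone in each latent", {
  cfg <- fx_config()
  base <- lvshape:::impairment_field(cfg, 0, 0, 0)
  expect_true(all(base > 0 & base < 1))
  expect_true(all(lvshape:::impairment_field(cfg, 2, 0, 0) > base))
  ant <- lvshape:::impairment_field(cfg, 0, 2, 0)
  bas <- lvshape:::impairment_field(cfg, 0, 0, 2)
  expect_true(all(ant >= base) && any(ant > base + 1e-6))
  expect_true(all(bas >= base) && any(bas > base + 1e-6))
  # anterior pattern is circumferential: strongest on the anterior meridian
  expect_gt(ant[1, 13] - base[1, 13], ant[25, 13] - base[25, 13])
  # basal pattern is longitudinal: zero at the apical half, maximal at base
  expect_equal(bas[1, 1], base[1, 1], tolerance = 1e-12)
  expect_gt(bas[1, cfg$n_long] - base[1, cfg$n_long], 0.01)
})

test_that("anatomical-variability harmonics vanish at apex and basal rim", {
  cfg <- fx_config()
  h <- lvshape:::harmonic_sum(cfg, rep(1, 8))
  expect_equal(unname(h[, 1]), rep(0, cfg$n_circ), tolerance = 1e-12)
  expect_equal(unname(h[, cfg$n_long]), rep(0, cfg$n_circ), tolerance = 1e-12)
  # zero coefficients are a no-op
  ed <- lvshape:::subject_ed_mesh(cfg)
  expect_identical(lvshape:::apply_shape_harmonics(ed, rep(0, 8), cfg), ed)
  expect_identical(lvshape:::contraction_modulation(cfg, list(z_global = 1)), 1)
})

test_that("ES meshes stay strictly inside ED with positive walls", {
  co <- fx_cohort_small()
  expect_true(all(co$table$esv < co$table$edv))
  expect_true(all(co$table$lvef > 0 & co$table$lvef < 100))
  for (s in co$subjects[1:5]) {
    expect_true(all(wall_thickness(s$es_mesh) > 0))
  }
})

test_that("inverted-wall contractions are rejected", {
  cfg <- fx_config()
  cfg$es_rho <- 2  # endocardium pushed beyond the epicardium
  ed <- lvshape:::subject_ed_mesh(cfg)
  expect_error(
    deform_ed_to_es(ed, list(z_global = 0, z_anterior = 0, z_basal = 0), cfg),
    "inverted")
})

test_that("cohort generation is deterministic and internally consistent", {
  co <- fx_cohort_small()
  co2 <- generate_cohort(fx_config(), keep_meshes = TRUE)
  expect_identical(co$table, co2$table)
  expect_identical(co$es_shapes, co2$es_shapes)
  # table volumes match the kept meshes
  i <- 7L
  expect_equal(co$table$edv[i], mesh_cavity_volume(co$subjects[[i]]$ed_mesh))
  expect_equal(co$table$esv[i], mesh_cavity_volume(co$subjects[[i]]$es_mesh))
  # shape matrices match the kept meshes
  expect_equal(co$es_shapes[i, ], as_shape_vector(co$subjects[[i]]$es_mesh))
  # contraction rows are bulk-free displacement fields
  d <- lvshape:::shape_vector_to_nodes(co$contractions[i, ])
  expect_equal(colMeans(d), c(0, 0, 0), tolerance = 1e-12)
})

test_that("outcome table follows the endpoint conventions", {
  co <- fx_cohort_headline()
  tab <- co$table
  expect_true(all(tab$mace %in% 0:1))
  expect_true(all(tab$event == tab$mace))
  expect_true(all(tab$time[tab$mace == 0] == co$config$horizon))
  expect_true(all(tab$time[tab$mace == 1] >= 0.5))
  expect_true(all(tab$time <= co$config$horizon))
  expect_true(all(is.na(tab$event_type[tab$mace == 0])))
  expect_true(all(tab$event_type[tab$mace == 1] %in%
                    c("death", "reinfarction", "heart_failure")))
  expect_lt(abs(mean(tab$mace) - co$config$mace_rate), 0.025)
})

test_that("infarct size couples to the global latent in the target window", {
  co <- fx_cohort_headline()
  rs <- spearman(co$table$is_ml, co$latents$z_global)
  expect_gt(rs, 0.35)
  expect_lt(rs, 0.55)
})

test_that("zero copula loadings decouple covariates from the latents", {
  cfg <- fx_config()
  cfg$is_loading <- 0
  cfg$mvo_loading <- 0
  cfg$age_loading <- 0
  lat <- sample_latents(cfg, n = 4000)
  cov <- lvshape:::simulate_covariates(lat, cfg, mass_ml = rep(120, 4000))
  expect_lt(abs(spearman(cov$is_ml, lat$z_global)), 0.07)
  expect_lt(abs(spearman(cov$age, lat$z_global)), 0.07)
  expect_lt(abs(spearman(cov$mvo_ml, lat$z_global)), 0.07)
})

test_that("baseline contraction equals the analytic anisotropic scaling", {
  cfg <- fx_config()
  ed <- lvshape:::subject_ed_mesh(cfg)
  d <- lvshape:::baseline_contraction(cfg, ed, cfg$es_rho)
  endo <- mesh_layer_array(ed, "endo")
  expect_equal(endo[, , 1] + d$endo[, , 1], cfg$es_rho * endo[, , 1],
               tolerance = 1e-12)
  expect_equal(endo[, , 3] + d$endo[, , 3], cfg$es_z_scale * endo[, , 3],
               tolerance = 1e-12)
  expect_equal(d$epi, cfg$epi_follow * d$endo, tolerance = 1e-12)
})

test_that("print methods summarize config and cohort", {
  expect_output(print(fx_config()), "Synthetic AMI cohort config")
  expect_output(print(fx_cohort_small()), "Synthetic AMI cohort: 24 subjects")
})
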