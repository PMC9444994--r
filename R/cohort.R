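# Synthetic AMI cohort generator.
#
# Each subject is a truncated-ellipsoid LV whose end-diastolic geometry
# carries pure nuisance variability (size, elongation, wall thickness) and
# whose ED -> ES contraction is modulated by three latent impairment factors:
# global (uniform), anterior (circumferentially localized) and basal
# (longitudinally localized). The 12-month MACE outcome depends on the three
# impairment latents only, through a logistic model whose intercept and
# effect magnitude are calibrated by root-finding so that the marginal event
# rate and the generative (Bayes-optimal) AUC match the configured targets.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a post-infarction CMR population: median EDV near 144 mL,
#' healthy-baseline LVEF of 55% at zero impairment, a 7.15% 12-month MACE
#' rate, and an infarct-size covariate coupled to the global impairment
#' latent with Spearman correlation near 0.45.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param n_circ,n_long Template resolution (default 49 x 25 per surface).
#' @param geometry Baseline template geometry, see [lv_geometry_params()].
#' @param sd_size,sd_elongation,sd_thickness Log-scale SDs of the nuisance
#'   geometry factors (overall size, long-axis elongation, wall thickness).
#'   Elongation is volume-preserving (`a_endo` scales by `1/sqrt(elong)`,
#'   `c_endo` by `elong`), so cavity volume varies as `size^3` and the
#'   default `sd_size` reproduces an EDV interquartile spread of roughly
#'   -17% / +21% around the median, typical of post-infarction populations.
#' @param lvef_healthy Target LVEF (%) at all latents zero; the endocardial
#'   systolic scale is calibrated to it by root-finding on mesh volumes.
#' @param es_z_scale Longitudinal shortening factor of the healthy ES.
#' @param epi_follow Epicardial displacement as a fraction of the
#'   endocardial displacement (< 1 gives systolic wall thickening).
#' @param effect_global,effect_anterior,effect_basal Impairment effect sizes
#'   (logistic slopes on the standard-normal latents).
#' @param w_anterior,w_basal Maximum weights of the anterior and basal
#'   impairment patterns relative to the global one. The defaults are
#'   distinct and large enough that each implanted pattern carries clearly
#'   more shape variance than any nuisance harmonic and than each other, so
#'   the three impairment modes are identifiable by PCA (non-degenerate
#'   eigenvalues).
#' @param anterior_sigma Angular SD (radians) of the anterior Gaussian
#'   weight around the anterior meridian. The default (0.45 rad, about a
#'   60 degree full width at half maximum) emulates a left anterior
#'   descending territory; a narrow bump also keeps the anterior pattern
#'   close to orthogonal to the uniform global pattern, so the anterior
#'   PCA mode carries little global counterweight and remains individually
#'   associated with outcome.
#' @param mace_rate Target marginal 12-month MACE probability.
#' @param bayes_auc Target AUC of the oracle score (the true latent linear
#'   predictor) against the MACE label.
#' @param hazard Per-latent log-hazard coefficients for event timing among
#'   MACE cases.
#' @param horizon Administrative censoring horizon (days).
#' @param median_event_time Median uncensored event time (days) at zero
#'   latents, setting the baseline exponential hazard.
#' @param is_loading,mvo_loading,age_loading Gaussian-copula loadings of
#'   infarct size, microvascular obstruction and age on the global latent.
#' @param harmonic_sd_shape SD of the fractional radial anatomical
#'   variability harmonics of the ED shape (per harmonic; 8 smooth
#'   circumferential x longitudinal harmonics).
#' @param harmonic_sd_contraction SD of the fractional contraction-scale
#'   variability harmonics (pure nuisance, outcome-decoupled). Kept small
#'   enough that the implanted impairment patterns retain more variance than
#'   any single nuisance harmonic, so the impairment modes survive a
#'   95%-variance atlas truncation.
#' @param spacing In-plane pixel spacing of rasterized stacks (mm).
#' @param slice_thickness Slice thickness = slice gap (mm).
#' @param n_frames Cine frames per slice (ED at frame 1).
#' @param es_frame Frame index of end-systole (1-based).
#' @param misalign_sd SD (mm) of per-slice in-plane misalignment.
#' @return An object of class `cohort_config` with all calibration constants
#'   (`es_rho`, `outcome_beta0`, `outcome_beta`) resolved.
#' @export
cohort_config <- function(n_subjects = 1000, seed = 1,
                          n_circ = 49, n_long = 25,
                          geometry = lv_geometry_params(),
                          sd_size = 0.05, sd_elongation = 0.015,
                          sd_thickness = 0.03,
                          lvef_healthy = 55, es_z_scale = 0.93,
                          epi_follow = 0.55,
                          effect_global = 1.2, effect_anterior = 1.5,
                          effect_basal = 1.5,
                          w_anterior = 1.2, w_basal = 0.8,
                          anterior_sigma = 0.45,
                          mace_rate = 0.0715, bayes_auc = 0.75,
                          hazard = c(0.3, 0.3, 0.3), horizon = 365,
                          median_event_time = 90,
                          is_loading = 0.4665, mvo_loading = 0.35,
                          age_loading = 0.25,
                          harmonic_sd_shape = 0.01,
                          harmonic_sd_contraction = 0.035,
                          spacing = 1.4, slice_thickness = 8,
                          n_frames = 25, es_frame = 9,
                          misalign_sd = 0.5) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (spacing <= 0 || slice_thickness <= 0) stop("spacing must be positive")
  if (mace_rate <= 0 || mace_rate >= 1) stop("mace_rate must be in (0,1)")
  if (es_frame < 2 || es_frame > n_frames - 1) {
    stop("es_frame must be an interior frame")
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    n_circ = as.integer(n_circ), n_long = as.integer(n_long),
    geometry = do.call(lv_geometry_params, geometry),
    sd_size = sd_size, sd_elongation = sd_elongation,
    sd_thickness = sd_thickness,
    lvef_healthy = lvef_healthy, es_z_scale = es_z_scale,
    epi_follow = epi_follow,
    effect_global = effect_global, effect_anterior = effect_anterior,
    effect_basal = effect_basal,
    w_anterior = w_anterior, w_basal = w_basal,
    anterior_sigma = anterior_sigma,
    mace_rate = mace_rate, bayes_auc = bayes_auc,
    hazard = hazard, horizon = horizon,
    median_event_time = median_event_time,
    is_loading = is_loading, mvo_loading = mvo_loading,
    age_loading = age_loading,
    harmonic_sd_shape = harmonic_sd_shape,
    harmonic_sd_contraction = harmonic_sd_contraction,
    spacing = spacing, slice_thickness = slice_thickness,
    n_frames = as.integer(n_frames), es_frame = as.integer(es_frame),
    misalign_sd = misalign_sd
  )
  class(cfg) <- "cohort_config"
  cfg$es_rho <- calibrate_es_rho(cfg)
  cal <- calibrate_outcome(cfg)
  cfg$outcome_beta0 <- cal$beta0
  cfg$outcome_beta <- cal$beta
  cfg
}

#' @method print cohort_config
#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic AMI cohort config: n = %d, seed = %d\n",
              x$n_subjects, x$seed))
  cat(sprintf("  template %d x %d, healthy LVEF target %.0f%% (es_rho = %.4f)\n",
              x$n_circ, x$n_long, x$lvef_healthy, x$es_rho))
  cat(sprintf("  MACE rate %.2f%%, Bayes AUC %.2f (beta0 = %.3f, |beta| = %.3f)\n",
              100 * x$mace_rate, x$bayes_auc, x$outcome_beta0,
              sqrt(sum(x$outcome_beta^2))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Impairment weights on the (u, v) grid.

impairment_weights <- function(config) {
  u <- 0:(config$n_circ - 1)
  v <- 0:(config$n_long - 1)
  phi <- 2 * pi * u / config$n_circ
  dphi <- ifelse(phi >= pi, phi - 2 * pi, phi)  # anterior meridian at phi = 0
  w_ant <- config$w_anterior * exp(-0.5 * (dphi / config$anterior_sigma)^2)
  t_long <- v / (config$n_long - 1)
  w_bas <- config$w_basal * pmax(0, (t_long - 0.5) / 0.5)^2
  list(w_ant = w_ant, w_bas = w_bas,
       norm = 1 + config$w_anterior + config$w_basal)
}

# Per-(u,v) impairment fraction in (0, 1) for one subject.
impairment_field <- function(config, z_global, z_anterior, z_basal) {
  w <- impairment_weights(config)
  g <- stats::plogis(config$effect_global * z_global)
  a <- stats::plogis(config$effect_anterior * z_anterior)
  b <- stats::plogis(config$effect_basal * z_basal)
  (g + outer(a * w$w_ant, rep(1, config$n_long)) * 1 +
     outer(rep(1, config$n_circ), b * w$w_bas)) / w$norm
}

# Subject ED template from nuisance latents.
subject_ed_mesh <- function(config, z_size = 0, z_elongation = 0,
                            z_thickness = 0) {
  g <- config$geometry
  size <- exp(config$sd_size * z_size)
  elong <- exp(config$sd_elongation * z_elongation)
  thick <- exp(config$sd_thickness * z_thickness)
  geom <- lv_geometry_params(
    a_endo = g$a_endo * size / sqrt(elong),
    c_endo = g$c_endo * size * elong,
    wall = g$wall * thick * size,
    apex_thickness = g$apex_thickness * thick * size,
    z_base = g$z_base * size * elong
  )
  mesh <- build_template(config$n_circ, config$n_long, geom)
  class(mesh) <- "lv_mesh"
  mesh$phase <- "ED"
  mesh
}

# Healthy (uncalibrated) baseline contraction: node-wise displacement from
# ED to a radially scaled (rho) and longitudinally shortened ES, the
# epicardium following a fraction of the endocardial displacement. Scaling
# c_endo and z_base by the same factor preserves the truncation-angle grid,
# so the baseline ES endocardium is exactly the anisotropically scaled ED
# endocardium; computing it node-wise lets anatomical-variability harmonics
# on the ED shape propagate consistently to the healthy ES.
baseline_contraction <- function(config, ed_mesh, rho) {
  endo_ed <- mesh_layer_array(ed_mesh, "endo")
  endo_es <- endo_ed
  endo_es[, , 1] <- rho * endo_ed[, , 1]
  endo_es[, , 2] <- rho * endo_ed[, , 2]
  endo_es[, , 3] <- config$es_z_scale * endo_ed[, , 3]
  d_endo <- endo_es - endo_ed
  d_epi <- config$epi_follow * d_endo
  list(endo = d_endo, epi = d_epi)
}

# ---------------------------------------------------------------------------
# Smooth anatomical-variability harmonics on the (u, v) grid: circumferential
# Fourier modes (k = 3, 4) times longitudinal half-wave modes sin(pi m t)
# (m = 1, 2) that vanish at the apex pole and the basal rim. Pure nuisance:
# outcome-decoupled, they broaden the shape and contraction spectra the way
# inter-subject anatomy does. Two deliberate choices keep the implanted
# impairment factors identifiable: the circumferential orders start at k = 3
# so the fields are nearly orthogonal to the anterior Gaussian impairment
# pattern (whose Fourier mass sits at k <= 2), and the amplitudes decay as
# 1/sqrt(j) so no nuisance eigenvalue is degenerate with an impairment-mode
# eigenvalue (degenerate eigenvalues let PCA mix otherwise-orthogonal modes).

harmonic_basis <- function(config) {
  u <- 0:(config$n_circ - 1)
  v <- 0:(config$n_long - 1)
  phi <- 2 * pi * u / config$n_circ
  t_long <- v / (config$n_long - 1)
  fields <- vector("list", 8L)
  j <- 0L
  for (k in 3:4) {
    for (m in 1:2) {
      lon <- sin(pi * m * t_long)
      fields[[j <- j + 1L]] <- outer(cos(k * phi), lon)
      fields[[j <- j + 1L]] <- outer(sin(k * phi), lon)
    }
  }
  for (j in seq_along(fields)) fields[[j]] <- fields[[j]] / sqrt(j)
  fields
}

# Weighted sum of the 8 harmonic basis fields.
harmonic_sum <- function(config, coefs) {
  basis <- harmonic_basis(config)
  out <- matrix(0, config$n_circ, config$n_long)
  for (j in seq_along(basis)) out <- out + coefs[j] * basis[[j]]
  out
}

# Fractional in-plane radial perturbation of both surfaces; clamped so the
# mesh stays far from self-intersection.
apply_shape_harmonics <- function(mesh, coefs, config) {
  if (all(coefs == 0)) return(mesh)
  h <- config$harmonic_sd_shape * harmonic_sum(config, coefs)
  f <- 1 + pmin(pmax(h, -0.2), 0.2)
  for (layer in c("endo", "epi")) {
    arr <- mesh_layer_array(mesh, layer)
    arr[, , 1] <- arr[, , 1] * f
    arr[, , 2] <- arr[, , 2] * f
    mesh <- mesh_set_layer(mesh, layer, arr)
  }
  mesh
}

# Multiplicative contraction-scale modulation field from the contraction
# harmonic coefficients (clamped so the ES stays strictly inside the ED).
contraction_modulation <- function(config, latents) {
  cols <- paste0("h_contr_", 1:8)
  if (!all(cols %in% names(latents))) return(1)
  coefs <- vapply(cols, function(cl) as.numeric(latents[[cl]][1]), 0)
  if (all(coefs == 0)) return(1)
  h <- config$harmonic_sd_contraction * harmonic_sum(config, coefs)
  pmin(pmax(1 + h, 0.55), 1.45)
}

# Root-find the endocardial systolic scale so that the zero-latent subject
# hits the healthy LVEF target exactly (on the discrete mesh volumes).
calibrate_es_rho <- function(config) {
  ed <- subject_ed_mesh(config)
  edv <- mesh_cavity_volume(ed)
  imp0 <- impairment_field(config, 0, 0, 0)
  f <- function(rho) {
    es <- apply_contraction(config, ed, rho, imp0)
    lvef(edv, mesh_cavity_volume(es)) - config$lvef_healthy
  }
  stats::uniroot(f, c(0.3, 0.98), tol = 1e-6)$root
}

# ES mesh = ED + (1 - impairment) * modulation * baseline contraction.
apply_contraction <- function(config, ed_mesh, rho, imp, modulation = 1) {
  d <- baseline_contraction(config, ed_mesh, rho)
  s <- (1 - imp) * modulation
  scale <- array(rep(s, 3), dim = c(dim(imp), 3))
  es <- ed_mesh
  es <- mesh_set_layer(es, "endo", mesh_layer_array(ed_mesh, "endo") +
                         scale * d$endo)
  es <- mesh_set_layer(es, "epi", mesh_layer_array(ed_mesh, "epi") +
                         scale * d$epi)
  es$phase <- "ES"
  es
}

#' Deform an ED mesh to ES under the latent impairment factors
#'
#' The end-systolic mesh is the end-diastolic mesh plus the healthy baseline
#' contraction field scaled node-wise by `1 - impairment`, where the
#' impairment combines a uniform global term, a circumferential Gaussian
#' anterior term and a longitudinal basal term, each a logistic function of
#' its standard-normal latent. The epicardium follows a fraction of the
#' endocardial displacement, so inward endocardial motion exceeds epicardial
#' motion and the wall thickens in systole.
#'
#' @param ed_mesh Canonical ED mesh built by the generator (carries its
#'   geometry parameters).
#' @param latents List or one-row data frame with `z_global`, `z_anterior`,
#'   `z_basal`; if harmonic coefficient columns `h_contr_1` .. `h_contr_8`
#'   are present (as drawn by [sample_latents()]) the contraction scale is
#'   additionally modulated by the smooth nuisance harmonics.
#' @param config A [cohort_config()].
#' @return The ES `lv_mesh`.
#' @export
deform_ed_to_es <- function(ed_mesh, latents, config) {
  imp <- impairment_field(config, latents$z_global, latents$z_anterior,
                          latents$z_basal)
  modulation <- contraction_modulation(config, latents)
  es <- apply_contraction(config, ed_mesh, config$es_rho, imp, modulation)
  if (walls_inverted(es)) {
    stop("effect sizes produce inverted walls at ES")
  }
  es
}

# Signed wall check on canonical (axis-aligned) generator meshes. Euclidean
# node-pair distances cannot detect a surface crossing, so the endocardium is
# required to sit strictly inside the epicardium ring by ring (in-plane
# radius) and along z at the degenerate apex pole.
walls_inverted <- function(mesh) {
  endo <- mesh_layer_array(mesh, "endo")
  epi <- mesh_layer_array(mesh, "epi")
  r_endo <- sqrt(endo[, , 1]^2 + endo[, , 2]^2)
  r_epi <- sqrt(epi[, , 1]^2 + epi[, , 2]^2)
  body <- 2:dim(endo)[2]
  any(r_epi[, body] <= r_endo[, body]) || any(epi[, 1, 3] >= endo[, 1, 3])
}

# ---------------------------------------------------------------------------
# Outcome model calibration.
#
# The oracle score s = beta' z is N(0, sigma^2); P(MACE | s) = plogis(b0+s).
# Gauss-Legendre-style fixed grid quadrature gives the marginal rate and the
# Bayes AUC; nested root-finding solves (b0, sigma) for the two targets.

outcome_grid <- function(sigma, n = 4001, span = 8) {
  s <- seq(-span * sigma, span * sigma, length.out = n)
  list(s = s, w = stats::dnorm(s, sd = sigma) * (s[2] - s[1]))
}

marginal_rate <- function(beta0, sigma) {
  g <- outcome_grid(sigma)
  sum(g$w * stats::plogis(beta0 + g$s))
}

oracle_auc <- function(beta0, sigma) {
  g <- outcome_grid(sigma)
  p <- stats::plogis(beta0 + g$s)
  w1 <- g$w * p
  w0 <- g$w * (1 - p)
  w1 <- w1 / sum(w1)
  w0 <- w0 / sum(w0)
  cum0 <- cumsum(w0)
  sum(w1 * (cum0 - 0.5 * w0))
}

calibrate_outcome <- function(config) {
  solve_beta0 <- function(sigma) {
    stats::uniroot(function(b0) marginal_rate(b0, sigma) - config$mace_rate,
                   c(-20, 5), tol = 1e-9)$root
  }
  f <- function(sigma) oracle_auc(solve_beta0(sigma), sigma) - config$bayes_auc
  sigma <- stats::uniroot(f, c(0.05, 6), tol = 1e-7)$root
  beta0 <- solve_beta0(sigma)
  list(beta0 = beta0, beta = rep(sigma / sqrt(3), 3))
}

#' Sample the subject latent factors
#'
#' Draws independent standard-normal impairment latents (global, anterior,
#' basal), nuisance geometry latents (size, elongation, thickness) and the
#' 8 + 8 anatomical-variability harmonic coefficients (ED shape and
#' contraction scale) for every subject. Reproducible: the configured seed
#' is set before drawing.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @param set_seed Set the config seed before drawing (default TRUE; the
#'   cohort generator passes FALSE because it manages the RNG stream).
#' @return Data frame with columns `z_global`, `z_anterior`, `z_basal`,
#'   `z_size`, `z_elongation`, `z_thickness`, `h_shape_1` .. `h_shape_8`,
#'   `h_contr_1` .. `h_contr_8`.
#' @export
sample_latents <- function(config, n = config$n_subjects, set_seed = TRUE) {
  if (set_seed) set.seed(config$seed)
  z <- matrix(stats::rnorm(22 * n), nrow = n)
  colnames(z) <- c("z_global", "z_anterior", "z_basal",
                   "z_size", "z_elongation", "z_thickness",
                   paste0("h_shape_", 1:8), paste0("h_contr_", 1:8))
  as.data.frame(z)
}

#' Simulate the 12-month MACE outcome
#'
#' MACE occurrence is Bernoulli with logistic probability in the impairment
#' latents (calibrated intercept and slopes). Cases receive an event time
#' drawn from an exponential distribution with per-latent log-hazard
#' coefficients, truncated to the administrative horizon; non-cases are
#' censored at the horizon. One event type per subject follows the endpoint
#' hierarchy death > reinfarction > heart failure.
#'
#' @param latents Data frame from [sample_latents()].
#' @param config A [cohort_config()].
#' @return Data frame with `mace`, `time` (days), `event`, `event_type`.
#' @export
simulate_outcome <- function(latents, config) {
  z <- as.matrix(latents[, c("z_global", "z_anterior", "z_basal")])
  lp <- config$outcome_beta0 + drop(z %*% config$outcome_beta)
  n <- nrow(z)
  mace <- as.integer(stats::runif(n) < stats::plogis(lp))
  rate0 <- log(2) / config$median_event_time
  rate <- rate0 * exp(drop(z %*% config$hazard))
  u <- stats::runif(n)
  t_trunc <- -log(1 - u * (1 - exp(-rate * config$horizon))) / rate
  type_draw <- stats::runif(n)
  event_type <- ifelse(type_draw < 32 / 73, "death",
                       ifelse(type_draw < 53 / 73, "reinfarction",
                              "heart_failure"))
  data.frame(
    mace = mace,
    time = ifelse(mace == 1, pmax(t_trunc, 0.5), config$horizon),
    event = mace,
    event_type = ifelse(mace == 1, event_type, NA_character_),
    stringsAsFactors = FALSE
  )
}

# Covariates coupled to the latents through Gaussian copula loadings;
# distributional scales emulate a post-infarction population.
simulate_covariates <- function(latents, config, mass_ml) {
  n <- nrow(latents)
  zg <- latents$z_global
  couple <- function(loading) {
    loading * zg + sqrt(1 - loading^2) * stats::rnorm(n)
  }
  age <- pmin(95, pmax(30, round(63 + 14.8 * couple(config$age_loading))))
  is_ml <- exp(2.845 + 1.15 * couple(config$is_loading))
  g_mvo <- couple(config$mvo_loading)
  mvo_ml <- ifelse(g_mvo <= 0.1, 0, 1.07 * exp(g_mvo - 0.1) - 1.0)
  mvo_ml <- pmax(mvo_ml, 0)
  mass <- pmax(mass_ml, 40)
  data.frame(
    age = age,
    sex_male = as.integer(stats::runif(n) < 0.745),
    smoking = as.integer(stats::runif(n) < 0.433),
    hypertension = as.integer(stats::runif(n) < 0.709),
    hyperlipoproteinemia = as.integer(stats::runif(n) < 0.621),
    diabetes = as.integer(stats::runif(n) < 0.229),
    bmi = round(27.4 + 4.0 * stats::rnorm(n), 1),
    bsa = round(1.95 + 0.19 * stats::rnorm(n), 2),
    killip = sample(1:4, n, replace = TRUE,
                    prob = c(0.889, 0.075, 0.020, 0.016)),
    vessels = sample(1:3, n, replace = TRUE, prob = c(0.497, 0.307, 0.196)),
    timi = sample(0:3, n, replace = TRUE,
                  prob = c(0.019, 0.021, 0.077, 0.883)),
    is_ml = round(is_ml, 1),
    is_pct = round(pmin(100 * is_ml / mass, 75), 1),
    mvo_ml = round(mvo_ml, 2),
    mvo_pct = round(pmin(100 * mvo_ml / mass, 30), 2)
  )
}

#' Generate a synthetic AMI cohort
#'
#' Draws latents, builds ground-truth ED/ES meshes per subject, simulates the
#' MACE outcome and coupled covariates, and (optionally) rasterizes cine
#' short-axis mask stacks. Deterministic given the configuration.
#'
#' @param config A [cohort_config()].
#' @param rasterize Also rasterize a [cine_stack] per subject (costly; off by
#'   default, the pipeline runner switches it on).
#' @param keep_meshes Keep per-subject `lv_mesh` objects in the result (in
#'   addition to the flat shape-vector matrices).
#' @return An object of class `lv_cohort`: list with `table` (covariates,
#'   volumes, outcome), `latents` (ground truth, for validation harnesses
#'   only), matrices `ed_shapes`, `es_shapes`, `contractions` (subjects x
#'   coordinates), optional `subjects` (meshes, stacks), and the `config`.
#' @export
generate_cohort <- function(config, rasterize = FALSE, keep_meshes = FALSE) {
  set.seed(config$seed)
  n <- config$n_subjects
  latents <- sample_latents(config, n, set_seed = FALSE)
  outcome <- simulate_outcome(latents, config)

  p <- 3L * 2L * config$n_circ * config$n_long
  ed_shapes <- matrix(NA_real_, n, p)
  es_shapes <- matrix(NA_real_, n, p)
  contractions <- matrix(NA_real_, n, p)
  edv <- esv <- mass <- numeric(n)
  subjects <- if (keep_meshes || rasterize) vector("list", n) else NULL

  for (i in seq_len(n)) {
    ed <- subject_ed_mesh(config, latents$z_size[i], latents$z_elongation[i],
                          latents$z_thickness[i])
    ed <- apply_shape_harmonics(
      ed, as.numeric(latents[i, paste0("h_shape_", 1:8)]), config)
    es <- deform_ed_to_es(ed, latents[i, ], config)
    ed_shapes[i, ] <- as_shape_vector(ed)
    es_shapes[i, ] <- as_shape_vector(es)
    contractions[i, ] <- as_shape_vector(contraction_field(ed, es)$displacements)
    edv[i] <- mesh_cavity_volume(ed)
    esv[i] <- mesh_cavity_volume(es)
    mass[i] <- mesh_myocardial_volume(ed)
    if (!is.null(subjects)) {
      subj <- list(ed_mesh = if (keep_meshes) ed, es_mesh = if (keep_meshes) es)
      if (rasterize) subj$stack <- rasterize_stack(ed, es, config)
      subjects[[i]] <- subj
    }
  }

  covar <- simulate_covariates(latents, config, mass)
  tab <- cbind(
    data.frame(id = seq_len(n)),
    covar,
    data.frame(edv = edv, esv = esv, lvef = lvef(edv, esv),
               mass_ml = mass),
    outcome
  )
  structure(
    list(table = tab, latents = latents, ed_shapes = ed_shapes,
         es_shapes = es_shapes, contractions = contractions,
         subjects = subjects, config = config),
    class = "lv_cohort"
  )
}

#' @method print lv_cohort
#' @export
print.lv_cohort <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Synthetic AMI cohort: %d subjects (seed %d)\n",
              nrow(tab), x$config$seed))
  cat(sprintf("  EDV %.0f (%.0f-%.0f) mL, ESV %.0f (%.0f-%.0f) mL, LVEF %.1f%%\n",
              stats::median(tab$edv), stats::quantile(tab$edv, .25),
              stats::quantile(tab$edv, .75),
              stats::median(tab$esv), stats::quantile(tab$esv, .25),
              stats::quantile(tab$esv, .75), stats::median(tab$lvef)))
  cat(sprintf("  MACE: %d (%.1f%%)\n", sum(tab$mace),
              100 * mean(tab$mace)))
  if (!is.null(x$subjects) && !is.null(x$subjects[[1]]$stack)) {
    cat("  cine mask stacks attached\n")
  }
  invisible(x)
}
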