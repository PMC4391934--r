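# Synthetic data: multispectral tissue scenes with known ground truth, and
# patient cohorts with proportional-hazards outcomes.

#' Scene parameters for a synthetic multispectral field
#'
#' Describes a simplified tumour-tissue field: elliptical CK-positive tumour
#' nests on an autofluorescent background, packed with nuclei of which a
#' controlled fraction is Ki67-positive. Defaults give a 256 x 256 field
#' emulating a tumour-dense core view: nests cover roughly half the frame,
#' nuclei pack most of each nest, and band noise sits at 1% of the CK
#' amplitude.
#'
#' @param height,width Field size in pixels.
#' @param n_nests Number of tumour nests (ellipses).
#' @param nest_axes Length-2 range (pixels) the ellipse semi-axes are drawn
#'   from.
#' @param nuclei_radius Nucleus disk radius in pixels.
#' @param nuclei_density Nuclei per pixel of nest area.
#' @param proliferation_fraction Probability in \[0, 1\] that a nucleus is
#'   Ki67-positive.
#' @param ck_amplitude,ki67_amplitude,af_amplitude Abundance amplitudes
#'   (a.u.) of cytoplasmic CK inside nests, Ki67 on positive nuclei, and
#'   autofluorescence everywhere.
#' @param noise_sd Standard deviation (a.u.) of additive Gaussian band noise;
#'   the noisy cube is clipped at 0.
#' @param seed Integer RNG seed.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(height = 256, width = 256, n_nests = 6,
                         nest_axes = c(28, 48), nuclei_radius = 3,
                         nuclei_density = 0.03, proliferation_fraction = 0.25,
                         ck_amplitude = 100, ki67_amplitude = 200,
                         af_amplitude = 10, noise_sd = 1, seed = 1) {
  if (height < 8 || width < 8) stop("field must be at least 8 x 8 pixels", call. = FALSE)
  if (proliferation_fraction < 0 || proliferation_fraction > 1)
    stop("proliferation_fraction must lie in [0, 1]", call. = FALSE)
  if (min(ck_amplitude, ki67_amplitude, af_amplitude) < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (length(nest_axes) != 2 || nest_axes[1] <= 0 || nest_axes[1] > nest_axes[2])
    stop("nest_axes must be an increasing positive range", call. = FALSE)
  structure(list(height = height, width = width, n_nests = n_nests,
                 nest_axes = nest_axes, nuclei_radius = nuclei_radius,
                 nuclei_density = nuclei_density,
                 proliferation_fraction = proliferation_fraction,
                 ck_amplitude = ck_amplitude, ki67_amplitude = ki67_amplitude,
                 af_amplitude = af_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "scene_params")
}

ellipse_mask <- function(height, width, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(width), each = height), height, width)
  y <- matrix(rep(seq_len(height), times = width), height, width)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

disk_mask <- function(height, width, cx, cy, r) {
  xs <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
  idx <- expand.grid(y = ys, x = xs)
  keep <- (idx$x - cx)^2 + (idx$y - cy)^2 <= r^2
  cbind(idx$y[keep], idx$x[keep])
}

#' Simulate one multispectral view field
#'
#' Draws elliptical tumour nests with non-overlapping centres (each new
#' centre is rejected while it falls closer to an existing nest than the sum
#' of semi-major axes allows), paints cytoplasmic CK abundance inside nests,
#' scatters nuclei inside each nest, marks each nucleus Ki67-positive with
#' probability `proliferation_fraction`, adds a constant autofluorescence
#' layer, and synthesises the cube as `E %*% abundance` plus Gaussian noise
#' clipped at 0. Ground-truth sums are computed from the noise-free
#' abundance maps, so the true ratio is unaffected by noise or
#' autofluorescence settings.
#'
#' Nucleus positivity is drawn as `runif(n) < proliferation_fraction`, so for
#' a fixed seed the set of positive nuclei grows monotonically with the
#' proliferation fraction.
#'
#' @param params A [scene_params()].
#' @param library An [endmember_library()]; default [build_default_library()].
#' @return A list with `cube` (a [spectral_cube()]) and `truth` (class
#'   `ground_truth`: the noise-free `ck_map`, `ki67_map`, `af_map` and
#'   `true_ki67_sum`, `true_ck_sum`, `true_ratio`).
#' @examples
#' f <- simulate_field(scene_params(height = 64, width = 64, n_nests = 2, seed = 7))
#' f$truth$true_ratio
#' @export
simulate_field <- function(params, library = build_default_library()) {
  stopifnot(inherits(params, "scene_params"), inherits(library, "endmember_library"))
  set.seed(params$seed)
  h <- params$height; w <- params$width
  ck_map <- matrix(0, h, w)
  ki67_map <- matrix(0, h, w)

  # nest placement with rejection sampling on centre spacing
  nests <- list()
  tries <- 0L
  while (length(nests) < params$n_nests && tries < 200L * params$n_nests) {
    tries <- tries + 1L
    a <- stats::runif(1, params$nest_axes[1], params$nest_axes[2])
    b <- stats::runif(1, params$nest_axes[1], params$nest_axes[2])
    r <- max(a, b)
    if (2 * r + 2 >= min(h, w)) next
    cx <- stats::runif(1, r + 1, w - r)
    cy <- stats::runif(1, r + 1, h - r)
    ok <- all(vapply(nests, function(n) {
      sqrt((n$cx - cx)^2 + (n$cy - cy)^2) >= 0.7 * (max(n$a, n$b) + r)
    }, logical(1)))
    if (ok) nests[[length(nests) + 1L]] <- list(cx = cx, cy = cy, a = a, b = b,
                                                theta = stats::runif(1, 0, pi))
  }
  if (length(nests) < params$n_nests)
    warning(sprintf("placed %d of %d nests; frame too crowded for the rest",
                    length(nests), params$n_nests), call. = FALSE)

  for (n in nests) {
    m <- ellipse_mask(h, w, n$cx, n$cy, n$a, n$b, n$theta)
    ck_map[m] <- params$ck_amplitude
    n_nuc <- round(params$nuclei_density * pi * n$a * n$b)
    if (n_nuc < 1) next
    # uniform nucleus centres inside the ellipse via its parametrisation
    rr <- sqrt(stats::runif(n_nuc)); ang <- stats::runif(n_nuc, 0, 2 * pi)
    u <- rr * n$a * cos(ang); v <- rr * n$b * sin(ang)
    ncx <- n$cx + u * cos(n$theta) - v * sin(n$theta)
    ncy <- n$cy + u * sin(n$theta) + v * cos(n$theta)
    pos <- stats::runif(n_nuc) < params$proliferation_fraction
    for (k in which(pos)) {
      px <- disk_mask(h, w, ncx[k], ncy[k], params$nuclei_radius)
      if (nrow(px)) ki67_map[px] <- params$ki67_amplitude
    }
  }
  af_map <- matrix(params$af_amplitude, h, w)

  E <- library$matrix
  A <- rbind(as.vector(ck_map), as.vector(ki67_map), as.vector(af_map))
  Y <- E %*% A
  if (params$noise_sd > 0)
    Y <- Y + stats::rnorm(length(Y), sd = params$noise_sd)
  Y <- pmax(Y, 0)
  cube <- spectral_cube(array(t(Y), dim = c(h, w, nrow(E))), grid = library$grid)

  true_ck <- sum(ck_map); true_ki <- sum(ki67_map)
  truth <- structure(list(
    ck_map = ck_map, ki67_map = ki67_map, af_map = af_map,
    true_ki67_sum = true_ki, true_ck_sum = true_ck,
    true_ratio = if (true_ck > 0) true_ki / true_ck else 0), class = "ground_truth")
  list(cube = cube, truth = truth)
}

#' Simulate a tissue-microarray core (several fields)
#'
#' Generates `n_fields` independent fields (field `i` uses seed
#' `params$seed + i`) and aggregates the ground truth by summing the
#' noise-free per-field sums.
#'
#' @param params A [scene_params()]; its seed anchors the per-field seeds.
#' @param library An [endmember_library()].
#' @param n_fields Number of view fields per core (default 6).
#' @return A list with `cubes` (list of [spectral_cube()]), `truths`
#'   (per-field `ground_truth`) and `truth` (aggregated `ground_truth` with
#'   the summed `true_ki67_sum`, `true_ck_sum` and their ratio).
#' @export
simulate_core <- function(params, library = build_default_library(), n_fields = 6) {
  stopifnot(inherits(params, "scene_params"))
  if (n_fields < 1) stop("n_fields must be at least 1", call. = FALSE)
  fields <- lapply(seq_len(n_fields), function(i) {
    p <- params; p$seed <- params$seed + i
    simulate_field(p, library)
  })
  ki <- sum(vapply(fields, function(f) f$truth$true_ki67_sum, numeric(1)))
  ck <- sum(vapply(fields, function(f) f$truth$true_ck_sum, numeric(1)))
  agg <- structure(list(ck_map = NULL, ki67_map = NULL, af_map = NULL,
                        true_ki67_sum = ki, true_ck_sum = ck,
                        true_ratio = if (ck > 0) ki / ck else 0),
                   class = "ground_truth")
  list(cubes = lapply(fields, `[[`, "cube"),
       truths = lapply(fields, `[[`, "truth"),
       truth = agg)
}

#' Cohort parameters for synthetic patient outcomes
#'
#' Emulates a 240-patient breast-cancer cohort followed for five-year
#' disease-free survival. The Ki67/CK ratio and the CK sum are independent
#' log-normals; defaults put the median ratio at 0.186 and the median Ki67
#' sum (= ratio x CK sum) at 2.30e7. Event times are exponential under a
#' proportional-hazards model: patients with ratio above `true_cutoff` have
#' their hazard multiplied by `exp(log_hr)`.
#'
#' @param n_patients Cohort size (>= 2); default 240.
#' @param ratio_log_mean,ratio_log_sd Log-normal parameters of the Ki67/CK
#'   ratio; defaults `log(0.186)` and 1.6.
#' @param ck_log_mean,ck_log_sd Log-normal parameters of the CK sum;
#'   defaults `log(2.30e7 / 0.186)` and 0.8.
#' @param true_cutoff Ratio threshold above which the hazard is elevated;
#'   default 0.186.
#' @param log_hr Log hazard ratio of the high-ratio group; default `log(2)`.
#' @param baseline_hazard Baseline event hazard per month; default 0.004
#'   (about 21% five-year event risk in the low-ratio group).
#' @param followup_months Administrative censoring horizon; default 60.
#' @param censor_rate Random-censoring hazard per month; default 0.002.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 240,
                          ratio_log_mean = log(0.186), ratio_log_sd = 1.6,
                          ck_log_mean = log(2.30e7 / 0.186), ck_log_sd = 0.8,
                          true_cutoff = 0.186, log_hr = log(2),
                          baseline_hazard = 0.004, followup_months = 60,
                          censor_rate = 0.002, seed = 1) {
  if (n_patients < 2) stop("n_patients must be at least 2", call. = FALSE)
  if (followup_months <= 0) stop("followup_months must be positive", call. = FALSE)
  if (baseline_hazard < 0 || censor_rate < 0)
    stop("hazards must be non-negative", call. = FALSE)
  if (ratio_log_sd < 0 || ck_log_sd < 0)
    stop("log-sd parameters must be non-negative", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 ratio_log_mean = ratio_log_mean, ratio_log_sd = ratio_log_sd,
                 ck_log_mean = ck_log_mean, ck_log_sd = ck_log_sd,
                 true_cutoff = true_cutoff, log_hr = log_hr,
                 baseline_hazard = baseline_hazard,
                 followup_months = followup_months,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "cohort_params")
}

# Clinico-pathological marginals of the emulated cohort (fractions of 240).
covariate_marginals <- list(
  age_le_50 = 149 / 240,
  menopausal = c(pre = 134, post = 106) / 240,
  t_stage = c(`1` = 36, `2` = 162, `3` = 42) / 240,
  n_stage = c(`0` = 109, `1` = 66, `2` = 30, `3` = 35) / 240,
  histo_grade = c(`1` = 40, `2` = 141, `3` = 59) / 240,
  er = c(positive = 106, negative = 134) / 240,
  her2 = c(amplified = 51, `non-amplified` = 189) / 240)

#' Simulate a patient cohort
#'
#' Per patient: Ki67/CK ratio and CK sum are drawn log-normally (Ki67 sum is
#' their product); the event time is exponential with hazard
#' `baseline_hazard * exp(log_hr * (ratio > true_cutoff))`; censoring is the
#' minimum of an exponential censoring time and the follow-up horizon.
#' Clinico-pathological covariates are drawn independently from realistic
#' marginal distributions (joint dependence is deliberately not modelled).
#'
#' @param params A [cohort_params()].
#' @return A data frame of class `cohort` with one row per patient:
#'   `patient_id`, `age`, `menopausal`, `t_stage`, `n_stage`, `histo_grade`,
#'   `er`, `her2`, `ki67_sum`, `ck_sum`, `ki67_ck_ratio`, `dfs_months`,
#'   `event`.
#' @examples
#' head(simulate_cohort(cohort_params(n_patients = 10, seed = 3)))
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  ratio <- stats::rlnorm(n, params$ratio_log_mean, params$ratio_log_sd)
  ck <- stats::rlnorm(n, params$ck_log_mean, params$ck_log_sd)
  ki67 <- ratio * ck
  high <- ratio > params$true_cutoff
  hz <- params$baseline_hazard * exp(params$log_hr * high)
  t_event <- if (params$baseline_hazard > 0) stats::rexp(n, hz) else rep(Inf, n)
  t_cens <- if (params$censor_rate > 0) stats::rexp(n, params$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, params$followup_months)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  m <- covariate_marginals
  age_young <- stats::runif(n) < m$age_le_50
  age <- ifelse(age_young, sample(28:50, n, replace = TRUE), sample(51:78, n, replace = TRUE))
  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age,
    menopausal = sample(names(m$menopausal), n, replace = TRUE, prob = m$menopausal),
    t_stage = as.integer(sample(names(m$t_stage), n, replace = TRUE, prob = m$t_stage)),
    n_stage = as.integer(sample(names(m$n_stage), n, replace = TRUE, prob = m$n_stage)),
    histo_grade = as.integer(sample(names(m$histo_grade), n, replace = TRUE, prob = m$histo_grade)),
    er = sample(names(m$er), n, replace = TRUE, prob = m$er),
    her2 = sample(names(m$her2), n, replace = TRUE, prob = m$her2),
    ki67_sum = ki67, ck_sum = ck, ki67_ck_ratio = ratio,
    dfs_months = time, event = event,
    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}
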