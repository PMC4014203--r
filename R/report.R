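#' Default simulation scenario
#'
#' Configuration of the synthetic verification batch: phantom resolution,
#' plan prescription (simultaneous-integrated-boost levels for the three
#' nested targets; synthetic defaults, since clinical prescriptions vary),
#' beam arrangement, the detector angular-response model, the per-case
#' delivery perturbation magnitudes, and the gamma criteria. Values can be
#' overridden by a YAML scenario file read with [read_scenario()].
#'
#' @return Named list of scenario settings.
#' @export
default_scenario <- function() {
  list(
    cases = 3L,
    seed = 1L,
    spacing_mm = 3,
    penumbra_sigma_mm = 4,
    isocenter_z_mm = 10,
    prescription = list(PTVnx = 7000, PTV1 = 6600, PTV2 = 6000),
    beams = 9L,
    sad_mm = 1000,
    anatomy_jitter_mm = 2,
    response = list(A = 0.2, w = 10, ripple = 0.005),
    perturbation = list(shift_sd_mm = 1.0, scale_sd = 0.01,
                        blur_sd_mm = 1.0, noise_pct = 0.3),
    criteria = list(dose_tol = 3, dta = 3, threshold_cgy = 20),
    gamma_subsample = 10
  )
}

#' Read a scenario YAML file
#'
#' Loads a scenario configuration and fills unset entries from
#' [default_scenario()].
#'
#' @param file path to a YAML scenario file, or `NULL` for the defaults.
#' @return Named scenario list.
#' @export
read_scenario <- function(file = NULL) {
  cfg <- default_scenario()
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      else cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Simulate one verification case
#'
#' Generates everything one patient-specific QA session produces, with known
#' ground truth: jittered NPC-like anatomy, the analytic planned dose, a
#' perturbed delivered/reconstructed dose (rigid shift, output scale,
#' penumbra broadening and noise drawn from the scenario's magnitudes), the
#' planar reference sampled on the detector array at the isocenter plane,
#' per-beam measured frames with the angular response imprinted — once with
#' all beams at gantry 0 (the single-gantry-angle composite, SGAC) and once
#' at the planned beam angles (the multi-gantry-angle composite, MGAC) —
#' and the angular correction table built from a central-detector angle
#' series.
#'
#' @param case_seed integer seed; identical seeds reproduce the case.
#' @param cfg scenario list from [default_scenario()] / [read_scenario()].
#' @return List with `plan`, `recon`, `structures`, `rx`, `spec`,
#'   `ref_planar`, `sgac`, `mgac`, `frames` (per-beam measured frames),
#'   `table`, `model`.
#' @export
simulate_case <- function(case_seed, cfg = default_scenario()) {
  grid <- make_phantom(cfg$spacing_mm)
  structures <- make_npc_structures(grid, seed = case_seed,
                                    jitter = cfg$anatomy_jitter_mm)
  rx <- prescription(unlist(cfg$prescription))
  plan <- make_planned_dose(structures, rx, sigma = cfg$penumbra_sigma_mm,
                            normalize = TRUE)

  pcfg <- cfg$perturbation
  rng <- local_rng(case_seed * 7L + 1L)
  shift <- stats::rnorm(3, 0, pcfg$shift_sd_mm)
  scale <- 1 + stats::rnorm(1, 0, pcfg$scale_sd)
  blur <- abs(stats::rnorm(1, 0, pcfg$blur_sd_mm))
  rng()
  spec <- perturbation_spec(shift = shift, scale = scale, blur = blur,
                            noise = pcfg$noise_pct,
                            seed = case_seed * 7L + 2L)
  recon <- perturb_dose(plan, spec, noise_ref = rx$normalization)

  model <- response_model(cfg$response$A, cfg$response$w, cfg$response$ripple)
  angles <- angle_sampling_grid()
  calc <- rep(100, length(angles)) # central-detector TPS dose, any level
  meas <- calc * response_at(model, angles)
  table <- build_correction_table(angles, meas, calc, SAD = cfg$sad_mm)

  z0 <- cfg$isocenter_z_mm
  ref_planar <- sample_detector_array(extract_plane(plan, "z", z0))
  true_plane <- extract_plane(recon, "z", z0)
  beam_angles <- seq(0, 360, length.out = cfg$beams + 1L)[seq_len(cfg$beams)]
  frame_of <- function(theta) {
    f <- sample_detector_array(true_plane, gantry_angle = theta)
    f$values <- f$values / cfg$beams
    f
  }
  frames <- lapply(beam_angles, function(th)
    simulate_angular_response(frame_of(th), model, cfg$sad_mm))
  sgac_frames <- lapply(beam_angles, function(th)
    simulate_angular_response(frame_of(0), model, cfg$sad_mm))
  list(plan = plan, recon = recon, structures = structures, rx = rx,
       spec = spec, ref_planar = ref_planar,
       sgac = sum_planar(sgac_frames), mgac = sum_planar(frames),
       frames = frames, table = table, model = model)
}

# structures carried into the per-organ pass-rate and DVH comparison
report_structures <- c("PTVnx", "PTV1", "PTV2", "brainstem", "spinal_cord",
                       "parotid_l", "parotid_r")

#' Verify one simulated case
#'
#' Runs the full comparison for one case: 2D gamma pass rates of the SGAC
#' and MGAC composites against the planar reference (MGAC both uncorrected
#' and with per-detector angular correction), the global and per-structure
#' 3D gamma pass rates of the reconstructed dose against the plan, and the
#' plan-vs-reconstruction DVH/HI/CI deviations.
#'
#' @param case output of [simulate_case()].
#' @param cfg the scenario used.
#' @return List with `rates` (named pass rates, fractions), `deviations`
#'   (data frame: structure, parameter, planned, reconstructed, delta_pct).
#' @export
verify_case <- function(case, cfg = default_scenario()) {
  cc <- cfg$criteria
  crit2d <- gamma_criteria(cc$dose_tol, cc$dta, "global_reference_max",
                           cc$threshold_cgy)
  crit3d <- gamma_criteria(cc$dose_tol, cc$dta, "prescription",
                           cc$threshold_cgy)
  ss <- cfg$gamma_subsample

  mgac_corr <- sum_planar(lapply(case$frames, apply_correction,
                                 table = case$table))
  g2 <- function(ev) pass_rate(compute_gamma(case$ref_planar, ev, crit2d,
                                             subsample = ss))
  rates <- c(sgac = g2(case$sgac),
             mgac_uncorrected = g2(case$mgac),
             mgac_corrected = g2(mgac_corr))

  g3 <- compute_gamma(case$plan, case$recon, crit3d,
                      norm_dose = case$rx, subsample = ss)
  rates["global_3d"] <- pass_rate(g3)
  for (nm in report_structures)
    rates[nm] <- pass_rate(g3, nm, case$structures)

  dev <- case_deviations(case)
  list(rates = rates, deviations = dev)
}

# Plan-vs-reconstruction DVH parameter deviations for one case, mirroring
# the usual clinical comparison: D98/D2/D95/V100/V95 + HI/CI for targets,
# D2 for serial OARs, Dmean for the parotids.
case_deviations <- function(case) {
  rows <- list()
  add <- function(structure, parameter, planned, reconstructed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, parameter = parameter, planned = planned,
      reconstructed = reconstructed,
      delta_pct = relative_deviation(reconstructed, planned))
  }
  for (t in c("PTVnx", "PTV1", "PTV2")) {
    mp <- metric_set(case$plan, t, case$rx, structures = case$structures)
    mr <- metric_set(case$recon, t, case$rx, structures = case$structures)
    for (p in c("D98", "D2", "D95", "Dmean", "V100", "V95"))
      add(t, p, mp[[p]], mr[[p]])
    if (t == "PTVnx") add(t, "HI", mp$HI, mr$HI)
    add(t, "CI", mp$CI, mr$CI)
  }
  for (o in c("brainstem", "spinal_cord")) {
    cp <- cumulative_dvh(case$plan, o, case$structures)
    cr <- cumulative_dvh(case$recon, o, case$structures)
    add(o, "D2", dose_at_volume(cp, 0.02), dose_at_volume(cr, 0.02))
  }
  for (o in c("parotid_l", "parotid_r")) {
    cp <- cumulative_dvh(case$plan, o, case$structures)
    cr <- cumulative_dvh(case$recon, o, case$structures)
    add(o, "Dmean", mean(cp$doses), mean(cr$doses))
  }
  do.call(rbind, rows)
}

#' Run a simulated verification batch
#'
#' Simulates and verifies `cfg$cases` cases (case i uses seed
#' `cfg$seed * 100 + i`) and assembles the verification report: one row of
#' pass rates per case plus the across-case deviation summaries (range,
#' mean +/- sd and the one-sample t-test p-value per structure/parameter).
#'
#' @param cfg scenario list.
#' @return List of class `verification_batch`: `cases` (data frame of
#'   per-case pass rates, percent), `summary` (data frame of deviation
#'   statistics), `deviations` (per-case deviation rows), `cfg`.
#' @export
run_batch <- function(cfg = default_scenario()) {
  rows <- list(); devs <- list()
  for (i in seq_len(cfg$cases)) {
    case <- simulate_case(cfg$seed * 100L + i, cfg)
    v <- verify_case(case, cfg)
    rows[[i]] <- data.frame(case = sprintf("case_%02d", i),
                            t(100 * v$rates), check.names = FALSE)
    d <- v$deviations
    d$case <- sprintf("case_%02d", i)
    devs[[i]] <- d
  }
  cases <- do.call(rbind, rows)
  deviations <- do.call(rbind, devs)
  summ <- list()
  for (key in unique(paste(deviations$structure, deviations$parameter))) {
    sel <- paste(deviations$structure, deviations$parameter) == key
    dd <- deviations$delta_pct[sel]
    s <- if (length(dd) >= 2) deviation_summary(dd)
         else list(min = min(dd), max = max(dd), mean = mean(dd),
                   sd = NA_real_, p = NA_real_)
    summ[[length(summ) + 1L]] <- data.frame(
      structure = deviations$structure[sel][1],
      parameter = deviations$parameter[sel][1],
      delta_min = s$min, delta_max = s$max,
      delta_mean = s$mean, delta_sd = s$sd, p_value = s$p)
  }
  structure(list(cases = cases, summary = do.call(rbind, summ),
                 deviations = deviations, cfg = cfg),
            class = "verification_batch")
}

#' @export
print.verification_batch <- function(x, ...) {
  cat(sprintf("<verification_batch> %d case(s), seed %d\n",
              nrow(x$cases), x$cfg$seed))
  print(x$cases, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a verification report to CSV
#'
#' Writes the per-case pass-rate table (one row per case: SGAC, MGAC
#' uncorrected/corrected, global 3D and per-structure gamma pass rates in
#' percent) and, next to it, `<stem>_summary.csv` with the deviation
#' statistics. Numeric formatting is fixed (4 decimals for rates and
#' deviations, 6 significant digits for p-values) so identical batches
#' produce byte-identical files.
#'
#' @param batch a `verification_batch` from [run_batch()].
#' @param file output CSV path for the per-case table.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(batch, file) {
  stopifnot(inherits(batch, "verification_batch"))
  cases <- batch$cases
  num <- vapply(cases, is.numeric, logical(1))
  cases[num] <- lapply(cases[num], function(x) sprintf("%.4f", x))
  utils::write.csv(cases, file, row.names = FALSE, quote = FALSE)
  sfile <- sub("(\\.csv)?$", "_summary.csv", file)
  s <- batch$summary
  for (nm in c("delta_min", "delta_max", "delta_mean", "delta_sd"))
    s[[nm]] <- sprintf("%.4f", s[[nm]])
  s$p_value <- sprintf("%.6g", s$p_value)
  utils::write.csv(s, sfile, row.names = FALSE, quote = FALSE)
  invisible(c(file, sfile))
}
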