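# End-to-end orchestration: simulate (or load) -> preprocess -> tensor fit
# -> geometry -> angle maps -> transmural statistics, with a manifest
# recording the configuration, seed and per-stage counts.

#' Images per cardiac phase for a diffusion protocol
#'
#' `count = n_reps * (n_dirs + 1)` when a b = 0 image is acquired every
#' repetition, else `n_reps * n_dirs`. The published protocol (12
#' directions, 8 repetitions, per-repetition b0) gives 104 images per
#' phase; the TD scout (3 directions over 30 TDs) gives 90.
#'
#' @param n_dirs number of diffusion directions.
#' @param n_reps number of repetitions (or scouted phases).
#' @param b0_per_rep logical; is a b = 0 image acquired per repetition?
#' @return Integer image count.
#' @export
#' @examples
#' protocol_count(12, 8, TRUE)   # 104
#' protocol_count(3, 30, FALSE)  # 90
protocol_count <- function(n_dirs, n_reps, b0_per_rep = TRUE) {
  stopifnot(n_dirs >= 1, n_reps >= 1)
  as.integer(n_reps * (n_dirs + as.integer(b0_per_rep)))
}

#' Pipeline configuration
#'
#' Validated run configuration for [run_pipeline()].
#'
#' @param phases cardiac phases to simulate and analyse.
#' @param n,pixel_spacing phantom grid.
#' @param n_reps,shift_sigma,noise_sigma acquisition corruption model; set
#'   `noise_sigma = 0, shift_sigma = 0` for a noiseless run.
#' @param register,zero_fill_factor processing toggles.
#' @param unwrap apply the helix-angle unwrap filter before profiling.
#' @param n_nodes transmural profile nodes.
#' @param anterior_ref_deg AHA anterior reference angle (degrees).
#' @param seed RNG seed for all simulation randomness.
#' @return A validated `cdti_config` list.
#' @export
pipeline_config <- function(phases = c("early_systole", "late_systole", "diastasis"),
                            n = 72, pixel_spacing = 1.6,
                            n_reps = 8, shift_sigma = 0.8, noise_sigma = 0.05,
                            register = TRUE, zero_fill_factor = 2,
                            unwrap = TRUE, n_nodes = 9,
                            anterior_ref_deg = 90, seed = 1L) {
  known <- phase_prescriptions()$phase
  if (!all(phases %in% known)) {
    stop("unknown phase(s): ", paste(setdiff(phases, known), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n >= 16, pixel_spacing > 0, n_reps >= 1,
            shift_sigma >= 0, noise_sigma >= 0,
            zero_fill_factor >= 1, n_nodes >= 2)
  structure(list(phases = phases, n = n, pixel_spacing = pixel_spacing,
                 n_reps = n_reps, shift_sigma = shift_sigma,
                 noise_sigma = noise_sigma, register = register,
                 zero_fill_factor = zero_fill_factor, unwrap = unwrap,
                 n_nodes = n_nodes, anterior_ref_deg = anterior_ref_deg,
                 seed = as.integer(seed)),
            class = "cdti_config")
}

#' Analyse one cardiac phase of one subject
#'
#' Runs the full chain on a phantom acquisition: simulate, corrupt
#' (repetitions, shifts, Rician noise), register, average repetitions,
#' zero-fill, tensor fit (log-linear init + nonlinear least squares),
#' LV geometry from the contours, angle maps, transmural profile and HAR.
#'
#' @param spec a [phantom_spec()].
#' @param config a [pipeline_config()].
#' @param seed RNG seed for this phase run.
#' @return A `cdti_phase_result` list: `maps` (HA/TA/E2A/MD/FA matrices),
#'   `profile`, `har`, `invariants`, `geometry`, `truth`, `counts`.
#' @export
run_phase <- function(spec, config = pipeline_config(), seed = config$seed) {
  ph <- make_phantom(spec)
  counts <- list(simulated = length(ph$stack$images))

  stack <- ph$stack
  if (config$noise_sigma > 0 || config$shift_sigma > 0 || config$n_reps > 1) {
    stack <- corrupt_stack(stack, n_reps = config$n_reps,
                           shift_sigma = config$shift_sigma,
                           noise_sigma = config$noise_sigma, seed = seed)
  }
  counts$acquired <- length(stack$images)
  shifts <- NULL
  if (config$register && config$shift_sigma > 0) {
    reg <- register_stack(stack)
    shifts <- reg$shifts
    stack <- recenter_stack(reg$stack)$stack
  }
  stack <- average_repetitions(stack)
  counts$averaged <- length(stack$images)
  if (config$zero_fill_factor > 1) {
    stack <- zero_fill_stack(stack, config$zero_fill_factor)
  }

  grid <- cdti_grid(dim(stack$images[[1]]), stack$pixel_spacing)
  contours <- load_contours(ph$truth$contours)
  geom <- lv_geometry(contours, grid, config$anterior_ref_deg)

  fit <- fit_nlls(stack, geom$mask)
  eig <- tensor_eigen(fit)
  inv <- tensor_invariants(eig)

  e1 <- eig$vectors[, 1:3, drop = FALSE]
  e2 <- eig$vectors[, 4:6, drop = FALSE]
  ha <- helix_angle(e1, geom$frames)
  ta <- transverse_angle(e1, geom$frames)
  e2a <- e2_angle(e1, e2, geom$frames)
  depth <- geom$depth[geom$frames$voxel_index]
  seg <- geom$segments[geom$frames$voxel_index]

  profile <- transmural_profile(ha, depth, segments = seg,
                                n_nodes = config$n_nodes,
                                unwrap = config$unwrap)
  har_tbl <- har(profile)

  dims <- grid$dim; vi <- geom$frames$voxel_index
  maps <- list(
    ha = as_map(ha, dims, vi), ta = as_map(ta, dims, vi),
    e2a = as_map(e2a, dims, vi), md = as_map(inv$md, dims, vi),
    fa = as_map(inv$fa, dims, vi)
  )
  structure(list(
    phase = spec$phase, maps = maps, profile = profile, har = har_tbl,
    invariants = inv, geometry = geom, truth = ph$truth,
    shifts = shifts, counts = counts,
    angles = tibble::tibble(voxel_index = vi, ha = ha, ta = ta, e2a = e2a,
                            depth = depth, segment = seg)
  ), class = "cdti_phase_result")
}

#' Run the multi-phase pipeline
#'
#' Executes [run_phase()] for every configured cardiac phase and collects
#' angle maps, transmural profiles, HAR and delta-HAR mobility tables and
#' a run manifest (configuration hash, seed, per-stage image counts).
#'
#' @param config a [pipeline_config()].
#' @return A `cdti_run` list: `phases` (named `cdti_phase_result`s),
#'   `mobility` (HAR per phase and delta HAR per phase pair, per segment),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  results <- list()
  for (i in seq_along(config$phases)) {
    ph <- config$phases[i]
    spec <- phantom_spec(ph, n = config$n, pixel_spacing = config$pixel_spacing,
                         noise_sigma = config$noise_sigma,
                         n_reps = config$n_reps,
                         shift_sigma = config$shift_sigma,
                         seed = config$seed + i)
    results[[ph]] <- tryCatch(
      run_phase(spec, config, seed = config$seed + i),
      error = function(e) {
        stop("pipeline stage failed for phase '", ph, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  har_all <- purrr::imap_dfr(results, function(res, ph) {
    dplyr::mutate(res$har, phase = ph, .before = 1)
  })
  pairs <- if (length(config$phases) >= 2) {
    utils::combn(config$phases, 2, simplify = FALSE)
  } else {
    list()
  }
  dhar <- purrr::map_dfr(pairs, function(pr) {
    a <- har_all[har_all$phase == pr[1], ]
    b <- har_all[har_all$phase == pr[2], ]
    j <- dplyr::inner_join(a, b, by = "segment", suffix = c("_a", "_b"))
    tibble::tibble(from = pr[1], to = pr[2], segment = j$segment,
                   delta_har = delta_har(j$har_a, j$har_b))
  })
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    counts = lapply(results, function(r) r$counts),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  structure(list(phases = results, har = har_all, delta_har = dhar,
                 manifest = manifest),
            class = "cdti_run")
}

#' @export
print.cdti_run <- function(x, ...) {
  cat("<cdti_run> phases:", paste(names(x$phases), collapse = ", "), "\n")
  cat("global HAR per phase:\n")
  print(x$har[x$har$segment == "global", ])
  invisible(x)
}

#' Simulate paired-phase myofiber mobility (delta HAR)
#'
#' Draws subjects imaged at two cardiac phases with a shared per-subject
#' random effect on the endo/epi helix angles (so the pairing structure of
#' a longitudinal study is preserved), analyses each phase, and returns the
#' per-subject HAR at both phases and their difference.
#'
#' @param n_subjects number of paired subjects.
#' @param phases the two phases to contrast (`to` minus `from`).
#' @param sd_ha between-subject SD on each boundary helix angle (degrees).
#' @param config a [pipeline_config()] for the per-phase analysis.
#' @param seed RNG seed.
#' @return Tibble: `subject`, `har_from`, `har_to`, `delta_har`.
#' @export
simulate_paired_mobility <- function(n_subjects = 7,
                                     phases = c("early_systole", "late_systole"),
                                     sd_ha = 6,
                                     config = pipeline_config(n = 48,
                                                              pixel_spacing = 2.4,
                                                              shift_sigma = 0,
                                                              register = FALSE,
                                                              zero_fill_factor = 1),
                                     seed = 1L) {
  stopifnot(length(phases) == 2)
  withr::local_seed(seed)
  pres <- phase_prescriptions()
  out <- list()
  for (s in seq_len(n_subjects)) {
    off_endo <- stats::rnorm(1, 0, sd_ha)
    off_epi <- stats::rnorm(1, 0, sd_ha)
    hars <- vapply(phases, function(ph) {
      base <- pres[pres$phase == ph, ]
      spec <- phantom_spec(ph, n = config$n,
                           pixel_spacing = config$pixel_spacing,
                           ha_endo = max(-90, min(90, base$ha_endo + off_endo)),
                           ha_epi = max(-90, min(90, base$ha_epi + off_epi)),
                           noise_sigma = config$noise_sigma,
                           shift_sigma = config$shift_sigma)
      res <- run_phase(spec, config, seed = sample.int(2^30, 1))
      res$har$har[res$har$segment == "global"]
    }, numeric(1))
    out[[s]] <- tibble::tibble(subject = s, har_from = hars[1],
                               har_to = hars[2],
                               delta_har = delta_har(hars[1], hars[2]))
  }
  dplyr::bind_rows(out)
}

#' Simulate a volunteer study of HAR/E2A group statistics
#'
#' Draws per-subject endocardial/epicardial helix angles and E2A around the
#' per-phase population medians (between-subject SD `sd_ha`/`sd_e2a`), runs
#' the analysis per subject-phase on a small phantom, and returns the
#' per-subject metric table ready for [compare_phases()]. Sample sizes
#' default to the study design (7 early systole, 9 late systole,
#' 6 diastasis).
#'
#' @param n_per_phase named integer vector of subjects per phase.
#' @param sd_ha,sd_e2a between-subject SDs (degrees).
#' @param config a [pipeline_config()]; defaults to a compact grid with
#'   noise but no misregistration, sized for replicate studies.
#' @param seed RNG seed.
#' @return Tibble: `subject`, `phase`, `har`, `e2a_median`.
#' @export
simulate_study <- function(n_per_phase = c(early_systole = 7,
                                           late_systole = 9, diastasis = 6),
                           sd_ha = 6, sd_e2a = 6,
                           config = pipeline_config(n = 48, pixel_spacing = 2.4,
                                                    shift_sigma = 0,
                                                    register = FALSE,
                                                    zero_fill_factor = 1),
                           seed = 1L) {
  withr::local_seed(seed)
  out <- list()
  subj <- 0
  for (ph in names(n_per_phase)) {
    base <- phase_prescriptions()
    base <- base[base$phase == ph, ]
    for (s in seq_len(n_per_phase[[ph]])) {
      subj <- subj + 1
      spec <- phantom_spec(
        ph, n = config$n, pixel_spacing = config$pixel_spacing,
        ha_endo = stats::rnorm(1, base$ha_endo, sd_ha),
        ha_epi = stats::rnorm(1, base$ha_epi, sd_ha),
        e2a = min(90, max(0, stats::rnorm(1, base$e2a, sd_e2a))),
        noise_sigma = config$noise_sigma, n_reps = config$n_reps,
        shift_sigma = config$shift_sigma
      )
      res <- run_phase(spec, config, seed = sample.int(2^30, 1))
      g <- res$har[res$har$segment == "global", ]
      out[[subj]] <- tibble::tibble(
        subject = subj, phase = ph, har = g$har,
        e2a_median = stats::median(res$angles$e2a, na.rm = TRUE)
      )
    }
  }
  dplyr::bind_rows(out)
}
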