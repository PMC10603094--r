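#' Simulation specification for the synthetic-data generators
#'
#' One object collects the conditions every generator emulates: cohort and
#' matrix sizes, the regulated fraction and effect size of the proteomics
#' arm, the missing-not-at-random dropout model, the imaging grid geometry,
#' per-modality noise levels (native units) and the ground-truth
#' viscoelastic parameters of the AFM arm. Defaults mirror the study
#' conditions: 3 biological replicates per condition, a 0.5 um imaging
#' step, an 18.5 um bead indenting at 7 um/s to a 12 nN setpoint.
#'
#' Each generator draws from its own RNG stream derived from `seed` by
#' stable sub-seeding, so adding a generator never perturbs the others, and
#' a fixed spec yields byte-identical outputs.
#'
#' @param seed master RNG seed.
#' @param n_proteins number of protein groups.
#' @param n_replicates replicates per condition.
#' @param frac_regulated fraction of proteins truly regulated (in 0..1).
#' @param effect_log2fc log2 fold-change magnitude of regulated proteins.
#' @param baseline_log2_mean,baseline_log2_sd log2 intensity distribution
#'   across proteins.
#' @param replicate_sd within-protein replicate noise (log2 units).
#' @param missingness_shift,missingness_width dropout-threshold position and
#'   softness in sample-SD units (MNAR model: values far below the sample
#'   mean are likely masked).
#' @param frac_flagged fraction of decoy rows carrying a QC flag.
#' @param map_shape Brillouin/RI map size in pixels (rows, cols).
#' @param pixel_size_um imaging step size.
#' @param lesion_nu_B,background_nu_B true region means of the Brillouin
#'   map, GHz.
#' @param lesion_ri,background_ri true region means of the RI field.
#' @param noise_brillouin_GHz,noise_ri,noise_amplitude,noise_force_N
#'   per-modality Gaussian noise SDs in native units.
#' @param delta_true true co-polarization ratio of the CP-OCT ROI.
#' @param n_slices CP-OCT stack depth.
#' @param E_true_Pa,eta_true_Pa_s,contact_point_m AFM ground truth.
#' @param afm_points samples per force curve (dense enough for stable
#'   contact-point estimation).
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(seed = 1,
                            n_proteins = 1000, n_replicates = 3,
                            frac_regulated = 0.05, effect_log2fc = 2,
                            baseline_log2_mean = 27, baseline_log2_sd = 2,
                            replicate_sd = 0.3,
                            missingness_shift = 1.8, missingness_width = 0.3,
                            frac_flagged = 0.02,
                            map_shape = c(120, 160), pixel_size_um = 0.5,
                            lesion_nu_B = 5.324, background_nu_B = 5.40,
                            lesion_ri = 1.3636, background_ri = 1.3680,
                            noise_brillouin_GHz = 0.02, noise_ri = 0.001,
                            noise_amplitude = 0.02, delta_true = 0.709,
                            n_slices = 5,
                            E_true_Pa = 500, eta_true_Pa_s = 0,
                            contact_point_m = 2e-6, noise_force_N = 0.1e-9,
                            afm_points = 500) {
  assert_scalar_number(n_proteins, "n_proteins", lower = 1)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  assert_scalar_number(frac_regulated, "frac_regulated", lower = 0, upper = 1)
  assert_scalar_number(E_true_Pa, "E_true_Pa", lower = 0, strict_lower = TRUE)
  assert_scalar_number(eta_true_Pa_s, "eta_true_Pa_s", lower = 0)
  if (length(map_shape) != 2L || any(map_shape < 1))
    stop("`map_shape` must be two positive pixel counts", call. = FALSE)
  spec <- as.list(environment())
  structure(spec, class = "simulation_spec")
}

#' Synthetic label-free proteomics table
#'
#' Log-normal baseline intensities per protein, replicate noise, a seeded
#' subset of proteins shifted by +/- `effect_log2fc` in the second
#' condition, missing-not-at-random dropout (a value is masked with
#' probability \eqn{\Phi((thr - x)/(width\,\sigma))} where
#' \eqn{thr = \bar{x} - shift\,\sigma} per sample), and a few decoy rows
#' carrying QC flags. Ground-truth regulation labels are attached.
#'
#' @param spec a [simulation_spec()].
#' @return An [abundance_matrix()] with attribute `truth`: data.frame
#'   (`protein_id`, `regulation` in up/down/null, `true_log2fc`).
#' @export
generate_lfq_table <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(sub_seed(spec$seed, "lfq"), {
    np <- spec$n_proteins; nr <- spec$n_replicates
    n_flag <- round(spec$frac_flagged * np)
    n_reg <- round(spec$frac_regulated * np)
    ids <- sprintf("P%05d", seq_len(np))
    reg <- rep("null", np)
    if (n_reg > 0) {
      idx <- sample.int(np, n_reg)
      reg[idx] <- rep_len(c("up", "down"), n_reg)
    }
    true_fc <- ifelse(reg == "up", spec$effect_log2fc,
               ifelse(reg == "down", -spec$effect_log2fc, 0))
    base <- stats::rnorm(np, spec$baseline_log2_mean, spec$baseline_log2_sd)
    cond <- rep(c("control", "lesioned"), each = nr)
    mu <- outer(base, rep(1, 2 * nr)) +
      outer(true_fc, as.numeric(cond == "lesioned"))
    x <- mu + matrix(stats::rnorm(np * 2 * nr, 0, spec$replicate_sd), np)
    colnames(x) <- paste0(cond, "_", rep(seq_len(nr), 2))
    # MNAR dropout: soft threshold below the sample mean
    for (s in seq_len(ncol(x))) {
      m_s <- mean(x[, s]); sd_s <- stats::sd(x[, s])
      thr <- m_s - spec$missingness_shift * sd_s
      p_miss <- stats::pnorm((thr - x[, s]) / (spec$missingness_width * sd_s))
      x[stats::runif(np) < p_miss, s] <- NA
    }
    flagged <- sample.int(np, n_flag)
    flags <- matrix(FALSE, np, 3)
    if (n_flag > 0)
      flags[cbind(flagged, sample.int(3, n_flag, replace = TRUE))] <- TRUE
    m <- abundance_matrix(x, cond, protein_id = ids,
                          gene_symbol = tolower(ids),
                          reverse = flags[, 1], contaminant = flags[, 2],
                          only_site = flags[, 3])
    attr(m, "truth") <- data.frame(protein_id = ids, regulation = reg,
                                   true_log2fc = true_fc)
    m
  })
}

#' Synthetic Brillouin shift map and co-registered refractive-index field
#'
#' A two-region scene — a lesion rectangle of the study ROI size centered
#' in the map over a uniform background — with independent Gaussian pixel
#' noise per modality. Region-true means are recorded.
#'
#' @param spec a [simulation_spec()].
#' @param roi optional [roi_spec()] defining the lesion region; default: a
#'   40 x 20 um rectangle centered in the map.
#' @return list with `map` (a [brillouin_map()]), `ri` (numeric matrix),
#'   `roi`, and `truth` (region-true means).
#' @export
generate_brillouin_scene <- function(spec, roi = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  dims <- spec$map_shape
  px <- spec$pixel_size_um
  if (is.null(roi)) {
    cx <- dims[2] * px / 2; cy <- dims[1] * px / 2
    roi <- roi_spec(cx - 20, cy - 10, 40, 20)
  }
  mask <- roi_mask(dims, px, roi)
  if (!any(mask)) stop("ROI larger than map or outside it", call. = FALSE)
  with_seed(sub_seed(spec$seed, "brillouin"), {
    nu <- matrix(spec$background_nu_B, dims[1], dims[2])
    nu[mask] <- spec$lesion_nu_B
    nu <- nu + matrix(stats::rnorm(prod(dims), 0, spec$noise_brillouin_GHz),
                      dims[1])
    ri <- matrix(spec$background_ri, dims[1], dims[2])
    ri[mask] <- spec$lesion_ri
    ri <- ri + matrix(stats::rnorm(prod(dims), 0, spec$noise_ri), dims[1])
    list(map = brillouin_map(nu, px), ri = ri, roi = roi,
         truth = list(lesion_nu_B = spec$lesion_nu_B,
                      background_nu_B = spec$background_nu_B,
                      lesion_ri = spec$lesion_ri,
                      background_ri = spec$background_ri))
  })
}

#' Synthetic co-/cross-polarized OCT stack
#'
#' Non-negative amplitude stacks whose ROI-true co-polarization ratio is
#' `spec$delta_true`: the total amplitude is split as
#' \eqn{A_{co} = \delta A}, \eqn{A_{cross} = (1-\delta) A}, then Gaussian
#' amplitude noise is added and clipped at zero.
#'
#' @param spec a [simulation_spec()]; `delta_true` must be in 0..1 and
#'   amplitudes non-negative.
#' @param base_amplitude mean total amplitude (arbitrary units).
#' @return A [polarized_stack()] with attribute `truth` (`delta_true`).
#' @export
generate_cpoct_stack <- function(spec, base_amplitude = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (base_amplitude < 0) stop("negative amplitude request", call. = FALSE)
  if (spec$delta_true < 0 || spec$delta_true > 1)
    stop("`delta_true` must be in [0, 1]", call. = FALSE)
  dims <- c(spec$map_shape, spec$n_slices)
  with_seed(sub_seed(spec$seed, "cpoct"), {
    A <- array(base_amplitude, dims)
    co <- spec$delta_true * A
    cross <- (1 - spec$delta_true) * A
    if (spec$noise_amplitude > 0) {
      co <- pmax(co + array(stats::rnorm(prod(dims), 0, spec$noise_amplitude),
                            dims), 0)
      cross <- pmax(cross + array(stats::rnorm(prod(dims), 0,
                                               spec$noise_amplitude), dims), 0)
    }
    st <- polarized_stack(co, cross, pixel_size_um = spec$pixel_size_um)
    attr(st, "truth") <- list(delta_true = spec$delta_true)
    st
  })
}

#' Synthetic AFM force-indentation curve
#'
#' Constant-speed approach sampled at `afm_points` positions: a flat
#' pre-contact baseline up to `contact_point_m`, then the forward contact
#' model — Hertz sphere when `eta_true_Pa_s = 0`, otherwise the
#' Kelvin-Voigt-Maxwell solution [kvm_force()] — until the 12 nN setpoint,
#' plus additive Gaussian force noise. Truth parameters are recorded.
#'
#' @param spec a [simulation_spec()].
#' @param speed_m_s approach speed (default 7 um/s).
#' @param setpoint_N force setpoint ending the approach (default 12 nN).
#' @return A [force_curve()] with attribute `truth`.
#' @export
generate_force_curve <- function(spec, speed_m_s = 7e-6, setpoint_N = 12e-9) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (speed_m_s <= 0) stop("`speed_m_s` must be > 0", call. = FALSE)
  E <- spec$E_true_Pa; eta <- spec$eta_true_Pa_s
  R <- 18.5e-6; nu <- 0.5
  fwd <- function(d) if (eta == 0) hertz_force(d, E, R, nu)
                     else kvm_force(d, E, eta, speed_m_s, R, nu)
  # indentation depth reaching the setpoint
  d_max <- stats::uniroot(function(d) fwd(d) - setpoint_N,
                          c(1e-9, 100e-6), tol = 1e-13)$root
  travel <- spec$contact_point_m + d_max
  z <- seq(0, travel, length.out = spec$afm_points)
  t <- z / speed_m_s
  f <- fwd(z - spec$contact_point_m)
  with_seed(sub_seed(spec$seed, "afm"), {
    if (spec$noise_force_N > 0)
      f <- f + stats::rnorm(length(f), 0, spec$noise_force_N)
    cv <- force_curve(t, z, f, bead_radius_m = R, poisson_ratio = nu,
                      speed_m_s = speed_m_s, setpoint_N = setpoint_N)
    attr(cv, "truth") <- list(E_true_Pa = E, eta_true_Pa_s = eta,
                              contact_point_m = spec$contact_point_m)
    cv
  })
}

#' Synthetic per-animal group table
#'
#' Per-animal values from a normal or log-normal distribution with a
#' specified additive group shift, emulating the per-figure quantification
#' tables (one value per animal).
#'
#' @param spec a [simulation_spec()].
#' @param n_per_group animals per group (>= 2).
#' @param shift additive shift of the treated group.
#' @param distribution `"normal"` or `"lognormal"` (the latter violates the
#'   Shapiro-Wilk gate at moderate n).
#' @param sd group standard deviation (normal case) / log-SD (lognormal).
#' @return data.frame with `animal`, `condition`, `value` and attribute
#'   `truth`.
#' @export
generate_group_table <- function(spec, n_per_group = 12, shift = 0,
                                 distribution = c("normal", "lognormal"),
                                 sd = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  distribution <- match.arg(distribution)
  if (n_per_group < 2L) stop("need n >= 2 per group", call. = FALSE)
  with_seed(sub_seed(spec$seed, "group"), {
    draw <- function(n) switch(distribution,
      normal = stats::rnorm(n, 10, sd),
      lognormal = stats::rlnorm(n, meanlog = 2, sdlog = sd))
    ctrl <- draw(n_per_group)
    trt <- draw(n_per_group) + shift
    out <- data.frame(
      animal = paste0("A", seq_len(2 * n_per_group)),
      condition = rep(c("control", "treated"), each = n_per_group),
      value = c(ctrl, trt))
    attr(out, "truth") <- list(shift = shift, distribution = distribution)
    out
  })
}

#' Synthetic qRT-PCR Ct table
#'
#' Ct values (technical triplicates) for a target and a reference gene in
#' control and treated groups, constructed so the true
#' \eqn{\Delta\Delta Ct} equals `ddct_true`.
#'
#' @param spec a [simulation_spec()].
#' @param ddct_true ground-truth delta-delta-Ct.
#' @param ct_noise technical-replicate SD (Ct units).
#' @param n_replicates technical replicates per well (default 3).
#' @return data.frame with `gene`, `condition`, `replicate`, `ct` and
#'   attribute `truth` (`ddct_true`, `fc_true`).
#' @export
generate_ct_table <- function(spec, ddct_true = -2, ct_noise = 0.05,
                              n_replicates = 3) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(sub_seed(spec$seed, "ct"), {
    base <- expand.grid(gene = c("target", "reference"),
                        condition = c("control", "treated"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    mu <- with(base, ifelse(gene == "reference", 15,
                     ifelse(condition == "control", 22, 22 + ddct_true)))
    base$ct <- mu + stats::rnorm(nrow(base), 0, ct_noise)
    attr(base, "truth") <- list(ddct_true = ddct_true,
                                fc_true = 2^(-ddct_true))
    base
  })
}
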