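test_that("generators are byte-identical under a fixed spec and seed", {
  spec <- simulation_spec(seed = 11, n_proteins = 200)
  expect_identical(generate_lfq_table(spec), generate_lfq_table(spec))
  expect_identical(generate_brillouin_scene(spec), generate_brillouin_scene(spec))
  expect_identical(generate_cpoct_stack(spec), generate_cpoct_stack(spec))
  expect_identical(generate_force_curve(spec), generate_force_curve(spec))
  expect_identical(generate_group_table(spec), generate_group_table(spec))
  expect_identical(generate_ct_table(spec), generate_ct_table(spec))
})

test_that("lfq generator constructs the requested truth set", {
  spec <- simulation_spec(seed = 2, n_proteins = 1000,
                          frac_regulated = 0.05, effect_log2fc = 2)
  m <- generate_lfq_table(spec)
  truth <- attr(m, "truth")
  expect_equal(sum(truth$regulation != "null"), 50)
  expect_setequal(unique(truth$regulation), c("up", "down", "null"))

  # null case: no truth-regulated rows, group means differ only by noise
  m0 <- generate_lfq_table(simulation_spec(seed = 2, n_proteins = 300,
                                           frac_regulated = 0))
  t0 <- attr(m0, "truth")
  expect_true(all(t0$regulation == "null"))
  fc <- rowMeans(m0$exprs[, m0$condition == "lesioned"], na.rm = TRUE) -
        rowMeans(m0$exprs[, m0$condition == "control"], na.rm = TRUE)
  expect_lt(abs(mean(fc, na.rm = TRUE)), 0.1)

  # flag columns exist and invalid counts rejected
  expect_true(all(c("reverse", "contaminant", "only_site") %in% names(m)))
  expect_error(simulation_spec(n_proteins = 0), "n_proteins")
})

test_that("brillouin scene recovers region-true means", {
  clean <- simulation_spec(seed = 3, noise_brillouin_GHz = 0, noise_ri = 0)
  sc <- generate_brillouin_scene(clean)
  st <- roi_statistics(sc$map, sc$roi)
  expect_equal(st$mean_GHz, sc$truth$lesion_nu_B)
  expect_equal(st$sem_GHz, 0)

  noisy <- simulation_spec(seed = 4, lesion_nu_B = 5.324,
                           background_nu_B = 5.40)
  sn <- generate_brillouin_scene(noisy)
  stn <- roi_statistics(sn$map, sn$roi)
  expect_lt(abs(stn$mean_GHz - 5.324), 3 * stn$sem_GHz)

  # ROI larger than the map is an error
  big_roi <- roi_spec(0, 0, 1e4, 1e4)
  expect_error(generate_brillouin_scene(
    simulation_spec(seed = 1, map_shape = c(10, 10)),
    roi = roi_spec(100, 100, 40, 20)), "ROI")
  expect_true(any(roi_mask(c(10, 10), 0.5, big_roi)))  # covering ROI is fine
})

test_that("cpoct generator hits its specified polarization ratio", {
  all_co <- generate_cpoct_stack(simulation_spec(seed = 5, delta_true = 1,
                                                 noise_amplitude = 0))
  expect_true(all(all_co$cross == 0))
  even <- generate_cpoct_stack(simulation_spec(seed = 5, delta_true = 0.5,
                                               noise_amplitude = 0))
  expect_identical(even$co, even$cross)
  # closed loop: recovered ROI delta converges to truth as noise -> 0
  for (ns in c(0.02, 0.002)) {
    st <- generate_cpoct_stack(simulation_spec(seed = 6, delta_true = 0.75,
                                               noise_amplitude = ns))
    d <- roi_mean_ratio(reflectivity_and_ratio(st))
    expect_lt(abs(d - 0.75), 5 * ns + 1e-12)
  }
  expect_error(generate_cpoct_stack(simulation_spec(seed = 1),
                                    base_amplitude = -1), "negative")
})

test_that("force-curve generator matches the Hertz closed form", {
  # F(3 um) for E = 500 Pa, nu = 0.5, R = 18.5 um
  f_expected <- (4 / 3) * (500 / (1 - 0.25)) * sqrt(18.5e-6) * (3e-6)^1.5
  expect_equal(hertz_force(3e-6, 500, 18.5e-6, 0.5), f_expected)
  expect_equal(f_expected * 1e9, 19.87, tolerance = 5e-4)

  cv <- generate_force_curve(simulation_spec(seed = 7, noise_force_N = 0))
  fit <- hertz_sphere_fit(cv)
  expect_lt(abs(fit$E_Pa - 500) / 500, 1e-3)   # zero-noise round trip
  expect_error(generate_force_curve(simulation_spec(seed = 1),
                                    speed_m_s = -1), "speed")
  expect_error(simulation_spec(E_true_Pa = -5), "E_true")
})

test_that("group and Ct tables encode their stated truths", {
  spec <- simulation_spec(seed = 8)
  g0 <- generate_group_table(spec, n_per_group = 30, shift = 0)
  sp <- split(g0$value, g0$condition)
  d <- cohens_d(sp$control, sp$treated)
  expect_lt(abs(d$d), 2 * d$se + 0.3)          # null shift: d near 0

  # lognormal option trips the Shapiro-Wilk gate at n = 60
  gl <- generate_group_table(simulation_spec(seed = 9), n_per_group = 60,
                             distribution = "lognormal", sd = 1)
  p <- shapiro.test(gl$value[gl$condition == "control"])$p.value
  expect_lt(p, 0.05)

  ct <- generate_ct_table(spec, ddct_true = -2, ct_noise = 0)
  agg <- tapply(ct$ct, list(ct$gene, ct$condition), mean)
  fc <- ddct_fold_change(agg["target", "control"], agg["target", "treated"],
                         agg["reference", "control"], agg["reference", "treated"])
  expect_equal(fc$fold_change, attr(ct, "truth")$fc_true)
  expect_error(generate_group_table(spec, n_per_group = 1), "n >= 2")
})
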