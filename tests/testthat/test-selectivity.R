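# Bi-ionic I-V analysis: normalization, reversal potentials, permeability.

test_that("normalization scales each replicate to its +100 mV current", {
  fam <- linear_family(erev = -40, g = 0.5, replicates = 1)
  norm <- normalize_iv(fam)
  expect_equal(norm$current[norm$voltage == 100], 1.0)
  expect_true(attr(norm, "normalized"))

  # scale invariance: doubling all currents changes nothing after normalizing
  doubled <- fam
  doubled$current <- doubled$current * 2
  doubled <- iv_family(tibble::as_tibble(doubled))
  expect_equal(tibble::as_tibble(normalize_iv(doubled)), tibble::as_tibble(norm))

  # replicates with different maxima normalize independently
  recs <- dplyr::bind_rows(
    tibble::tibble(voltage = z_protocol,
                   current = 3 * (z_protocol + 20), replicate = "a"),
    tibble::tibble(voltage = z_protocol,
                   current = 11 * (z_protocol + 20), replicate = "b"))
  two <- normalize_iv(iv_family(recs))
  at100 <- two$current[two$voltage == 100]
  expect_equal(at100, c(1, 1))
  expect_equal(mean(at100), 1)

  # missing or zero reference current
  no100 <- iv_family(tibble::tibble(voltage = c(-100, 0, 80),
                                    current = c(-1, 0.5, 2),
                                    replicate = "a"))
  expect_error(normalize_iv(no100), class = "ionpore_normalization_error")
  z100 <- iv_family(tibble::tibble(voltage = c(-100, 0, 100),
                                   current = c(-1, 0.5, 0),
                                   replicate = "a"))
  expect_error(normalize_iv(z100), class = "ionpore_degenerate_recording")
})

test_that("reversal potentials come from linear zero-crossing interpolation", {
  # linear I-V sampled on the 11-step protocol recovers E0 exactly
  fit <- estimate_erev(linear_family(erev = -40, replicates = 3))
  expect_equal(fit$erev, -40)
  expect_equal(fit$erev_sem, 0)
  expect_equal(fit$n_replicates, 3)

  # odd-symmetric I-V reverses at zero
  odd <- iv_family(tibble::tibble(voltage = z_protocol,
                                  current = z_protocol^3,
                                  replicate = "a"))
  expect_equal(estimate_erev(odd)$erev, 0)

  # interpolation between bracketing steps, computed by hand:
  # I(-60) = -5, I(-40) = 15 -> crossing at -60 + 5/20*20 = -55
  vals <- c(-25, -15, -5, 15, 35, 55, 75, 95, 115, 135, 155)
  hand <- iv_family(tibble::tibble(voltage = z_protocol, current = vals,
                                   replicate = "a"))
  expect_equal(estimate_erev(hand)$erev, -55)

  # failure modes name the replicate
  flat <- iv_family(tibble::tibble(voltage = z_protocol,
                                   current = rep(1, 11) + z_protocol * 1e-4,
                                   replicate = "r1"))
  expect_error(estimate_erev(flat), "r1", class = "ionpore_out_of_range")
  wiggly <- iv_family(tibble::tibble(voltage = c(-100, -50, 0, 50, 100),
                                     current = c(-1, 1, -1, 1, 1),
                                     replicate = "r2"))
  expect_error(estimate_erev(wiggly), class = "ionpore_ambiguous_crossing")
})

test_that("noisy simulated families recover the true reversal potential", {
  sim <- simulate_iv(true_ratio = 8.5, noise_frac = 0.05,
                     n_replicates = 3, seed = 101)
  fit <- estimate_erev(sim$family)
  expect_lt(abs(fit$erev - sim$truth$true_erev_mv), 2)

  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  g <- glance(fit)
  expect_equal(g$n_replicates, 3)
  expect_equal(g$erev_mv, fit$erev)
})

test_that("the bi-ionic equation gives the paper-scale ratios", {
  cond <- bi_ionic_condition()
  expect_equal(permeability_ratio(0, cond), 1)

  # -55 mV -> ~8.5 (rounds to 9); -65 mV -> ~12.6 (rounds to 13)
  expect_equal(round(permeability_ratio(-55, cond)), 9)
  expect_equal(round(permeability_ratio(-65, cond)), 13)
  expect_equal(permeability_ratio(-55, cond), 8.5, tolerance = 0.01)
  expect_equal(permeability_ratio(-65, cond), 12.6, tolerance = 0.01)

  # inverse consistency: swapping species/sign gives the reciprocal
  r <- permeability_ratio(-55, bi_ionic_condition(conc_internal = 150,
                                                  conc_external = 30))
  r_swapped <- permeability_ratio(55, bi_ionic_condition(conc_internal = 30,
                                                         conc_external = 150))
  expect_equal(r * r_swapped, 1, tolerance = 1e-12)

  # strictly decreasing in Erev; concentration-scale invariant
  es <- seq(-80, 80, by = 10)
  expect_true(all(diff(vapply(es, permeability_ratio, numeric(1),
                              condition = cond)) < 0))
  big <- bi_ionic_condition(conc_internal = 300, conc_external = 300)
  expect_equal(permeability_ratio(-42, big), permeability_ratio(-42, cond))

  expect_error(bi_ionic_condition(temperature = 400),
               class = "ionpore_parameter_error")
  expect_error(bi_ionic_condition(conc_internal = -1),
               class = "ionpore_parameter_error")
})

test_that("selectivity tables flag non-functional constructs", {
  wt <- simulate_iv(true_ratio = 8.5, seed = 7)$family
  mut <- simulate_iv(true_ratio = 2.3, seed = 8)$family
  flat <- iv_family(tibble::tibble(
    voltage = rep(z_protocol, 2),
    current = rep(c(0.4, 0.5), each = 11) + 0.001 * rep(z_protocol, 2),
    replicate = rep(c("a", "b"), each = 11)))
  tab <- selectivity_table(list(WT = wt, I46M_like = mut,
                                untransfected = flat))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$functional, c(TRUE, TRUE, FALSE))
  expect_equal(tab$ratio[1], 8.5, tolerance = 0.15)
  expect_equal(tab$ratio[2], 2.3, tolerance = 0.15)
  expect_true(is.na(tab$ratio[3]))
  expect_error(selectivity_table(list()), class = "ionpore_empty_input")
})

test_that("delimited I-V files load into per-construct families", {
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- dplyr::bind_rows(
    tibble::tibble(voltage_mV = z_protocol,
                   current_pA = 10 * (z_protocol + 55),
                   replicate = "c1", construct = "WT"),
    tibble::tibble(voltage_mV = z_protocol,
                   current_pA = 8 * (z_protocol + 21),
                   replicate = "c1", construct = "I46M"))
  utils::write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
  fams <- read_iv(f)
  expect_setequal(names(fams), c("WT", "I46M"))
  expect_equal(estimate_erev(fams$WT)$erev, -55)
  expect_equal(estimate_erev(fams$I46M)$erev, -21)
})
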