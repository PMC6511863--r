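base_scheme <- function() kinetic_scheme(packaged_rates())

test_that("selection scales exactly the four documented non-cognate rates", {
  sel <- selection_energetics(4, 4, 2, 1)
  sch <- apply_selection(base_scheme(), sel)
  ed <- polfid:::scheme_edges(sch, err = 0.1)
  rate_of <- function(from, to) ed$rate[ed$from_name == from & ed$to_name == to]
  r <- sch$rates
  expect_equal(rate_of("IIInc", "II") / r[["k_III_minus"]], exp(4))
  expect_equal(rate_of("IIInc", "IVnc") / r[["k_III_plus"]], exp(-4))
  expect_equal(rate_of("IVnc", "IIInc") / r[["k_IV_minus"]], exp(2))
  expect_equal(rate_of("IVnc", "Vnc") / r[["k_IV_plus"]], exp(-1))
  # cognate branch untouched
  expect_equal(rate_of("IIIc", "IVc"), r[["k_III_plus"]])
  # closure partition follows the supplied error rate
  expect_equal(rate_of("I", "Vnc"), 0.1 * r[["k_I_minus"]])
})

test_that("zero selection gives Err = 1/2 and equal branch populations", {
  res <- steady_state(base_scheme())
  expect_equal(res$err, 0.5, tolerance = 1e-9)
  expect_equal(unname(res$populations["IIIc"]),
               unname(res$populations["IIInc"]), tolerance = 1e-9)
  expect_equal(sum(res$populations), 1, tolerance = 1e-12)
  expect_gt(res$J, 0)
})

test_that("split mode with zero selection reproduces the lumped branch", {
  sel <- selection_energetics(0, 0, 0, 0, f_on = 0.3, f_off = 0.7)
  lump <- steady_state(apply_selection(base_scheme(),
                                       selection_energetics(0, 0, 0, 0)))
  split <- steady_state(apply_selection(base_scheme(), sel, mode = "split"))
  expect_equal(split$err, lump$err, tolerance = 1e-9)
  expect_equal(split$J, lump$J, tolerance = 1e-6)
  expect_equal(unname(split$populations["IIIon"] +
                        split$populations["IIIoff"]),
               unname(lump$populations["IIInc"]), tolerance = 1e-9)
})

test_that("populations sum to 1 and fluxes are consistent across schemes", {
  set.seed(31)
  for (rep in 1:10) {
    sel <- selection_energetics(runif(1, 0, 6), runif(1, 0, 6),
                                runif(1, 0, 4), runif(1, 0, 6))
    res <- steady_state(apply_selection(base_scheme(), sel))
    expect_equal(sum(res$populations), 1, tolerance = 1e-10)
    expect_true(all(res$populations >= 0))
    expect_equal(res$err, res$J_nc / res$J, tolerance = 1e-8)
  }
})

test_that("the quasi-equilibrium single-checkpoint limit is Boltzmann", {
  # slow insertion after a fast pre-insertion equilibrium: a single 4 kBT
  # rejection checkpoint gives Err -> 1 / (1 + exp(4))
  r <- packaged_rates()
  r["k_III_minus"] <- 1e6
  r["k_III_plus"] <- 1e-2
  r["k_V_minus"] <- 0
  r["k_I_minus"] <- 0
  sel <- selection_energetics(4, 0, 0, 0)
  res <- steady_state(apply_selection(kinetic_scheme(r), sel))
  expect_equal(res$err, 1 / (1 + exp(4)), tolerance = 1e-4)
})

test_that("error rate is monotone in every selection energy", {
  grid <- seq(0, 6, by = 1.5)
  for (which in 1:4) {
    errs <- vapply(grid, function(d) {
      a <- numeric(4); a[which] <- d
      sel <- selection_energetics(a[1], a[2], a[3], a[4])
      steady_state(apply_selection(base_scheme(), sel))$err
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})

test_that("checkpoint thermodynamic consistency: equal equilibrium shifts", {
  # delta_in_plus and delta_in_minus both disfavor the non-cognate insertion
  # equilibrium; applied alone with the same magnitude they change the
  # IIInc <-> IVnc equilibrium constant identically
  sch1 <- apply_selection(base_scheme(), selection_energetics(0, 2, 0, 0))
  sch2 <- apply_selection(base_scheme(), selection_energetics(0, 0, 2, 0))
  keq <- function(sch) {
    ed <- polfid:::scheme_edges(sch, 0.5)
    fwd <- ed$rate[ed$from_name == "IIInc" & ed$to_name == "IVnc"]
    rev <- ed$rate[ed$from_name == "IVnc" & ed$to_name == "IIInc"]
    fwd / rev
  }
  expect_equal(keq(sch1), keq(sch2), tolerance = 1e-12)
})

test_that("reducible or invalid schemes are rejected", {
  r <- packaged_rates()
  r["k_IV_plus"] <- 0; r["k_V_minus"] <- 0; r["k_I_minus"] <- 0
  expect_error(steady_state(kinetic_scheme(r)), "reducible")
  r <- packaged_rates(); r["k_I_plus"] <- -1
  expect_error(kinetic_scheme(r), ">= 0")
  expect_error(kinetic_scheme(packaged_rates()[1:5]), "rates must contain")
  expect_error(kinetic_scheme(packaged_rates(), ntp_ratio = 0), "> 0")
})

test_that("Gillespie agrees with the deterministic solver", {
  # deterministic single-branch limit: no non-cognate entry possible
  sel <- selection_energetics(30, 30, 0, 30)
  res <- steady_state(apply_selection(base_scheme(), sel))
  expect_lt(res$err, 1e-10)
  # symmetric scheme: binomial check at p = 1/2
  g <- gillespie_validate(base_scheme(), n_cycles = 2000, seed = 3)
  expect_lt(abs(g$err - 0.5), 3 * sqrt(0.25 / 2000))
  # 20 random schemes within 3 binomial SE of the deterministic error rate
  # (one 3-4 SE excursion tolerated: 20 draws at the 99.7% level)
  set.seed(99)
  z <- vapply(1:20, function(rep) {
    sel <- selection_energetics(runif(1, 0, 3), runif(1, 0, 3),
                                runif(1, 0, 2), runif(1, 0, 3))
    sch <- apply_selection(base_scheme(), sel)
    det <- steady_state(sch)$err
    n <- 1500
    g <- gillespie_validate(sch, n_cycles = n, seed = 100 + rep)
    abs(g$err - det) / sqrt(det * (1 - det) / n)
  }, numeric(1))
  expect_lt(max(z), 4)
  expect_gte(sum(z < 3), 19)
})

test_that("Gillespie rate matches the deterministic completion flux", {
  res <- steady_state(base_scheme())
  g <- gillespie_validate(base_scheme(), n_cycles = 4000, seed = 7)
  expect_equal(g$rate, res$J, tolerance = 0.1)
})

test_that("catalytic-selection fitting round-trips a planted value", {
  sel <- selection_energetics(4, 4, 0, 5,
                              f_on = path_populations(5.3)["f_on"],
                              f_off = path_populations(5.3)["f_off"])
  sch <- apply_selection(base_scheme(), sel)
  target <- steady_state(sch)$err
  fit <- fit_catalytic_selection(sch, target, tol = 1e-6)
  expect_equal(as.numeric(fit), 5, tolerance = 1e-3)
  expect_equal(attr(fit, "err"), target, tolerance = 1e-5)
  # boundary and unreachable targets
  e0 <- steady_state(apply_selection(base_scheme(),
          selection_energetics(4, 4, 0, 0)))$err
  expect_error(fit_catalytic_selection(apply_selection(base_scheme(),
                 selection_energetics(4, 4, 0, NA)), 2 * e0),
               "not achievable")
  expect_error(fit_catalytic_selection(apply_selection(base_scheme(),
                 selection_energetics(4, 4, 0, NA)), 1e-30),
               "not achievable")
})

test_that("early checkpoints are at least as effective as late ones", {
  scan <- checkpoint_placement_scan(8, baseline = base_scheme())
  expect_equal(nrow(scan), choose(4 + 3, 3))   # quarter-step enumeration
  all_early <- scan$err[scan$delta_b_minus == 8]
  all_late <- scan$err[scan$delta_c_plus == 8]
  expect_lte(all_early, all_late)
  # explicit pairwise comparison of the documented allocations
  s2 <- checkpoint_placement_scan(8, splits = rbind(c(4, 4, 0, 0),
                                                    c(0, 0, 4, 4)),
                                  baseline = base_scheme())
  expect_lte(s2$err[1], s2$err[2])
  # zero total selection: no discrimination
  expect_equal(checkpoint_placement_scan(0)$err, 0.5, tolerance = 1e-8)
  expect_error(checkpoint_placement_scan(4, splits = cbind(1, 1)), "4 columns")
  expect_error(checkpoint_placement_scan(4, splits = rbind(c(1, 1, 1, 2))),
               "sum to total_delta")
})
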