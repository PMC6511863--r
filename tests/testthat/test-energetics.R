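# noiseless pmf_profile built directly from a reference profile
pmf_from_profile <- function(species, path, bin_width = 0.02) {
  prof <- packaged_profile(species, path)
  grid <- seq(prof$domain[1] + bin_width / 2, prof$domain[2], by = bin_width)
  G <- profile_eval(prof, grid)
  structure(list(grid = grid, G = G, sigma = rep(NA_real_, length(G)),
                 n_samples = rep(1000L, length(G)), bin_width = bin_width,
                 zero = "none", f = 0, iterations = 1L, residual = 0,
                 windows = list(centers = grid, k = 210000)),
            class = "pmf_profile")
}

test_that("path populations reproduce the two-state Boltzmann weights", {
  p <- path_populations(5.3)
  expect_equal(unname(p["f_on"]), exp(-5.3) / (1 + exp(-5.3)))
  expect_equal(round(100 * unname(p["f_on"]), 1), 0.5)
  expect_equal(round(100 * unname(p["f_off"]), 1), 99.5)
  expect_equal(unname(path_populations(0)), c(0.5, 0.5))
  expect_equal(sum(path_populations(2.7)), 1)
  # monotone decreasing in the offset, saturating at the extremes
  offs <- seq(-10, 10, by = 0.5)
  fon <- vapply(offs, function(d) path_populations(d)["f_on"], numeric(1))
  expect_true(all(diff(fon) < 0))
  expect_equal(unname(path_populations(800)["f_on"]), 0)
})

test_that("landscape alignment applies the documented additive offsets", {
  cog <- pmf_from_profile("rATP", "cognate")
  on <- pmf_from_profile("rGTP", "on")
  off <- pmf_from_profile("rGTP", "off")
  land <- align_landscape(cog, on, off, ddG_b = 3,
                          merge_rule = "equal_config5")
  a <- land$anchors
  # cognate pre-insertion minimum defines the zero
  expect_equal(a$pre_insertion[a$path == "cognate"], 0)
  # on-path pre-insertion minimum sits at ddG_b
  expect_equal(a$pre_insertion[a$path == "on"], 3)
  # off-path insertion end is merged onto the on-path insertion state
  expect_equal(a$insertion[a$path == "off"], a$insertion[a$path == "on"])
  # aligned on-path insertion: -4 relative to its pre-min, raised by 3
  expect_equal(a$insertion[a$path == "on"], -1, tolerance = 0.05)
  # offsets are pure shifts: barriers are invariant
  expect_equal(land$summaries$on$dE_in, 3.3, tolerance = 0.05)
})

test_that("the dATP merge rule places config 5 between the on-path levels", {
  cog <- pmf_from_profile("rATP", "cognate")
  on <- pmf_from_profile("dATP", "on")
  off <- pmf_from_profile("dATP", "off")
  land <- align_landscape(cog, on, off, ddG_b = -1,
                          merge_rule = "between_config4_and_5")
  a <- land$anchors
  expect_equal(a$pre_insertion[a$path == "on"], -1)
  son <- land$summaries$on
  cfg5 <- a$insertion[a$path == "on"]
  mid_coord <- (son$ts_max["coord"] + son$ins_min["coord"]) / 2
  cfg4 <- on$G[which.min(abs(on$grid - mid_coord))] + land$offsets["on"]
  tgt <- a$insertion[a$path == "off"]
  expect_equal(unname(tgt), unname((cfg4 + cfg5) / 2), tolerance = 1e-9)
  # fraction endpoints bracket the default
  l0 <- align_landscape(cog, on, off, ddG_b = -1,
                        merge_rule = "between_config4_and_5", fraction = 0)
  expect_equal(l0$anchors$insertion[3], cfg5, tolerance = 1e-9)
  expect_error(align_landscape(cog, on, off, ddG_b = NA), "finite")
})

test_that("selection energies follow the barrier-difference arithmetic", {
  cog <- extract_barriers(pmf_from_profile("rATP", "cognate"))
  don <- extract_barriers(pmf_from_profile("dATP", "on"))
  sel <- derive_selection_energies(cog, don, dE_d_c = 4, dE_d_nc = 4)
  # insertion inhibition: 6 - 3 = 3 kBT
  expect_equal(sel$delta_in_plus, 3, tolerance = 0.05)
  expect_equal(sel$delta_b_minus, 0)
  # destabilization: cognate reverse barrier minus non-cognate reverse barrier
  expect_equal(sel$delta_in_minus, cog$dE_rev - don$dE_rev)
  expect_true(is.na(sel$delta_c_plus))
  # off-path rejection from the packaged dissociation barriers: 4 - 0 = 4
  konst <- packaged_constants()
  sel_off <- derive_selection_energies(cog, don, dE_d_c = konst$dE_d_c,
                                       dE_d_nc = konst$dE_d_off)
  expect_equal(sel_off$delta_b_minus, 4)
  expect_error(derive_selection_energies(cog, don), "required")
})

test_that("the direct constructor validates its arguments", {
  s <- selection_energetics(4, 4, 0, f_on = 0.005, f_off = 0.995)
  expect_equal(s$delta_b_minus, 4)
  expect_error(selection_energetics(Inf, 0, 0), "finite")
  expect_error(selection_energetics(0, 0, 0, f_on = 0.7, f_off = 0.7),
               "sum to 1")
  expect_error(selection_energetics(0, 0, 0, f_on = -0.1, f_off = 1.1),
               "non-negative|sum to 1")
})

test_that("packaged constants carry the documented values", {
  konst <- packaged_constants()
  expect_equal(konst$dE_d_c, 4)
  expect_equal(konst$dE_d_on, 4)
  expect_equal(konst$dE_d_off, 0)
  expect_equal(konst$on_path_offset_rGTP, 5.3)
})
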