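test_that("steady Poiseuille limit reproduces the plane-channel closed forms", {
  fx <- poiseuille_fixture()
  sol <- fx$sol; props <- fx$props
  # centerline / mean velocity = 1.5
  vc <- evaluate_velocity(sol, c(fx$L / 2, 0))
  expect_equal(vc[1] / fx$U, 1.5, tolerance = 0.02)
  expect_lt(abs(vc[2]), 1e-4 * fx$U)
  # wall shear magnitude 6 mu U / h away from the ends
  tau <- sol$tau[, ncol(sol$tau)]
  interior <- fx$sol$wall$mid[, 1] > fx$L / 4 & fx$sol$wall$mid[, 1] < 3 * fx$L / 4
  expected <- 6 * props$viscosity * fx$U / fx$w
  expect_equal(median(abs(tau[interior])), expected, tolerance = 0.03)
  # pressure drop 12 mu L U / h^2 (zero-pressure outlet)
  dp <- unname(sol$boundary_pressure["inlet", 2] - sol$boundary_pressure["outlet_ica", 2])
  expect_equal(dp, 12 * props$viscosity * fx$L * fx$U / fx$w^2, tolerance = 0.05)
  expect_lt(abs(sol$boundary_pressure["outlet_ica", 2]), 0.02 * dp)
  # mass conservation and weak incompressibility
  expect_equal(unname(sol$flux["outlet_ica", 2]), unname(sol$flux["inlet", 2]),
               tolerance = 0.01)
  expect_lt(max(sol$div_residual), 1e-6)
})

test_that("zero inflow produces identically zero fields", {
  g <- straight_channel_geometry(4e-3, 2e-3)
  m <- mesh_domain(g, h_max = 8e-4)
  sol <- solve_steady(m, flow_bc(0, "inlet"))
  expect_lt(max(abs(sol$U)), 1e-14)
  expect_lt(max(abs(sol$P)), 1e-10)
  expect_lt(max(abs(sol$tau)), 1e-10)
})

test_that("reversing the inflow flips the wall shear sign in the Stokes regime", {
  g <- straight_channel_geometry(6e-3, 2e-3)
  m <- mesh_domain(g, h_max = 6e-4)
  mdot <- fluid_props()$density * 1e-6 * 2e-3   # creeping flow
  s1 <- solve_steady(m, flow_bc(mdot, "inlet"), tol = 1e-10)
  s2 <- solve_steady(m, flow_bc(-mdot, "inlet"), tol = 1e-10)
  t1 <- s1$tau[, 2]; t2 <- s2$tau[, 2]
  expect_lt(max(abs(t1 + t2)), 1e-4 * max(abs(t1)))
})

test_that("wall shear error decreases monotonically under mesh refinement", {
  # cosine-constricted channel (non-polynomial solution): self-convergence of
  # the peak wall shear toward a finer reference
  props <- fluid_props()
  w <- 2e-3; L <- 8e-3
  constricted <- function() {
    hi <- function(x) w / 2 * (1 - 0.25 * (1 + cos(2 * pi * (x - L / 2) / L)) / 2)
    list(blocks = list(ch = list(
      name = "ch", x_range = c(0, L), x_knots = c(0, L / 2, L),
      lo = function(x) -hi(x), hi = hi,
      tag_left = "inlet", tag_right = "outlet_ica",
      tag_top = function(x) rep("wall", length(x)),
      tag_bottom = function(x) rep("wall", length(x)))))
  }
  g <- constricted()
  mdot <- props$density * 0.05 * w
  peak <- function(h) {
    s <- solve_steady(mesh_domain(g, h_max = h), flow_bc(mdot, "inlet"), tol = 1e-8)
    max(abs(s$tau[, 2]))
  }
  ref <- peak(w / 14)
  errs <- abs(c(peak(w / 4), peak(w / 6), peak(w / 9)) - ref)
  expect_true(all(diff(errs) < 0))
})

test_that("transient bifurcation run conserves mass and stays near-periodic", {
  fx <- transient_fixture()
  sol <- fx$sol
  # mass conservation at every stored step (skip the t=0 rest state)
  fin <- sol$flux["inlet", -1]
  fout <- sol$flux["outlet_ica", -1] + sol$flux["outlet_eca", -1]
  expect_lt(max(abs(fin - fout) / abs(fin)), 0.01)
  # weak incompressibility per step
  expect_lt(max(sol$div_residual), 1e-6)
  # cycle-to-cycle TAWSS difference between the last two cycles
  expect_lt(cycle_periodicity(sol), 0.02)
  # ICA outlet is the zero-pressure reference at all times
  p_ica <- sol$boundary_pressure["outlet_ica", -1]
  p_cca <- sol$boundary_pressure["inlet", -1]
  expect_lt(max(abs(p_ica)), 0.02 * max(abs(p_cca)))
})

test_that("wall shear record and pressure traces expose the final cycle", {
  fx <- transient_fixture()
  rec <- wall_shear_series(fx$sol)
  expect_s3_class(rec, "wall_shear_record")
  expect_equal(ncol(rec$tau), fx$sol$nsteps + 1)
  expect_equal(rec$times[1], 0)
  expect_equal(rec$times[length(rec$times)], fx$period)
  expect_true(all(diff(rec$arclength) > 0))
  bp <- boundary_pressure_series(fx$sol)
  expect_named(bp, c("times", "cca", "ica", "eca"))
  expect_equal(length(bp$cca), fx$sol$nsteps + 1)
  # downstream feature summary passes its own invariants
  feats <- feature_summary(tawss(rec), osi(rec), rec$arclength,
                           list(cca = bp$cca, ica = bp$ica, eca = bp$eca))
  expect_s3_class(feats, "hemodynamic_features")
  expect_gt(feats$peak_tawss, feats$vessel_avg_tawss)
})
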