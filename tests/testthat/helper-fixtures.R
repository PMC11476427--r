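# Lazily built, memoized fixtures shared across test files. Everything is
# generated in code at test time; sizes are kept small (coarse meshes, short
# runs) since these tests check invariants and closed forms, not resolution.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# steady plane-Poiseuille benchmark solution on a straight channel
poiseuille_fixture <- function() {
  get_fixture("poiseuille", function() {
    props <- fluid_props()
    w <- 2e-3; L <- 8e-3; U <- 0.2
    g <- straight_channel_geometry(L, w)
    m <- mesh_domain(g, h_max = w / 5)
    sol <- solve_steady(m, flow_bc(props$density * U * w, "inlet"), props = props)
    list(sol = sol, mesh = m, props = props, w = w, L = L, U = U)
  })
}

# small transient bifurcation run (2 cycles), shared by solver/metrics tests
transient_fixture <- function() {
  get_fixture("transient", function() {
    props <- fluid_props()
    g <- generate_geometry(stenosis_severity = 0.4, seed = 8)
    m <- mesh_domain(g, h_max = 1.0e-3)
    T <- cycle_duration(75)
    v <- velocity_waveform(psv = 0.8, edv = 0.2, period = T)
    cca <- flow_bc(mass_flow_waveform(v, area = g$d_cca, props), "inlet")
    ve <- velocity_waveform(psv = 0.5, edv = 0.125, period = T)
    eca <- flow_bc(mass_flow_waveform(ve, area = g$d_eca, props), "outlet_eca")
    sol <- suppressMessages(suppressWarnings(
      solve_transient(m, cca, eca, props, dt = T / 40, n_cycles = 3, max_iter = 35)))
    list(sol = sol, mesh = m, geom = g, props = props, period = T)
  })
}

# small plaque-bearing structural case shared by stress tests
structural_fixture <- function() {
  get_fixture("structural", function() {
    cs <- generate_cross_section(wall_thickness = 1.2e-3, plaque_arc_extent = 110,
                                 cap_thickness = 2.2e-4, seed = 5)
    m <- mesh_cross_section(cs, face_size = 4e-4)
    mats <- list(wall = arterial_wall_material(), plaque = fibrosis_material())
    sol <- solve_structural(m, mats, luminal_pressure = 16000)
    list(sol = sol, mesh = m, geom = cs, mats = mats, pressure = 16000)
  })
}

# small encoded cohort + fitted gradient-boosting model for ML/attribution
gbt_fixture <- function() {
  get_fixture("gbt", function() {
    spec <- generative_risk_spec(seed = 42)
    cohort <- generate_cohort(spec)
    fm <- encode_features(cohort)
    sp <- stratified_split(fm, test_fraction = 0.3, seed = 7)
    bal <- smote_oversample(sp$train, k_neighbors = 5, seed = 7)
    model <- gbt_fit(bal, n_estimators = 100, learning_rate = 0.1, max_depth = 3)
    list(spec = spec, cohort = cohort, fm = fm, split = sp, train_bal = bal,
         model = model)
  })
}

# 8-feature fitted model for Shapley axiom and estimator-agreement checks
small_model_fixture <- function() {
  get_fixture("shap_model", function() {
    set.seed(31)
    p <- 8
    X <- matrix(rnorm(400 * p), ncol = p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- as.integer(rbinom(400, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 2] + 0.5 * X[, 3])))
    fm <- structure(list(X = X, y = y,
                         meta = data.frame(name = colnames(X), source = colnames(X),
                                           group = "ecrf", binary = FALSE)),
                    class = "feature_matrix")
    model <- gbt_fit(fm, n_estimators = 40)
    list(model = model, fm = fm, X_explain = X[1:6, , drop = FALSE],
         background = X[101:150, , drop = FALSE])
  })
}

# pressurized neo-Hookean ring benchmark shared by structural and acceptance
lame_fixture <- function() {
  get_fixture("lame_ring", function() {
    a <- 2e-3; b <- 3e-3
    mat <- material_mr(c10 = 0.07e6, d = 1e-5, name = "neo-hookean")
    m <- mesh_cross_section(cross_section_geometry(a, b - a), face_size = 3e-4)
    sol <- solve_structural(m, list(wall = mat), luminal_pressure = 1000)
    list(sol = sol, a = a, b = b, mat = mat, p = 1000)
  })
}
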