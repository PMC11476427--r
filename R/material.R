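# Polynomial Mooney-Rivlin hyperelasticity with isochoric invariants and a
# quadratic volumetric penalty:
#   W = sum_ij C_ij (I1bar - 3)^i (I2bar - 3)^j + (1/d) (J - 1)^2,  i + j <= 3
# The third-order terms are retained so the printed arterial-wall constants
# (C10, C20, C21) are representable verbatim.

#' Polynomial Mooney-Rivlin material
#'
#' @param c10,c01,c20,c11,c02,c30,c21,c12,c03 coefficients `C_ij` (Pa).
#' @param d incompressibility parameter (1/Pa); the volumetric energy is
#'   `(1/d) (J-1)^2`, giving an initial bulk modulus `2/d`.
#' @param name optional material name.
#' @return an object of class `material_mr`.
#' @export
material_mr <- function(c10 = 0, c01 = 0, c20 = 0, c11 = 0, c02 = 0,
                        c30 = 0, c21 = 0, c12 = 0, c03 = 0, d = 1e-5,
                        name = "material") {
  if (!is.numeric(d) || d <= 0) stop_module("plaque_stress", "incompressibility parameter d must be > 0")
  if (2 * (c10 + c01) < 0) {
    stop_module("plaque_stress", "initial shear modulus 2(C10 + C01) must be >= 0")
  }
  coef <- data.frame(
    i = c(1, 0, 2, 1, 0, 3, 2, 1, 0),
    j = c(0, 1, 0, 1, 2, 0, 1, 2, 3),
    C = c(c10, c01, c20, c11, c02, c30, c21, c12, c03)
  )
  coef <- coef[coef$C != 0, , drop = FALSE]
  structure(list(coef = coef, d = d, name = name,
                 shear_modulus = 2 * (c10 + c01), bulk_modulus = 2 / d),
            class = "material_mr")
}

#' Arterial wall Mooney-Rivlin constants
#' @return `material_mr` with C10 = 0.07 MPa, C20 = 3.2 MPa, C21 = 0.0716 MPa,
#'   d = 1e-5 1/Pa.
#' @export
arterial_wall_material <- function() {
  material_mr(c10 = 0.07e6, c20 = 3.2e6, c21 = 0.0716e6, d = 1e-5, name = "arterial_wall")
}

#' Fibrotic plaque Mooney-Rivlin constants (5-parameter fit)
#' @return `material_mr` with the fibrosis constants
#'   C10 = -3.3232 MPa, C01 = 3.4296 MPa, C20 = 453.87 MPa,
#'   C11 = -1021 MPa, C02 = 581.32 MPa, d = 1e-5 1/Pa.
#' @export
fibrosis_material <- function() {
  material_mr(c10 = -3.3232e6, c01 = 3.4296e6, c20 = 4.5387e8,
              c11 = -1.021e9, c02 = 5.8132e8, d = 1e-5, name = "fibrosis")
}

#' @export
print.material_mr <- function(x, ...) {
  cat(sprintf("<material_mr> %s: %d nonzero C_ij, d = %.3g 1/Pa (mu0 = %.3g Pa)\n",
              x$name, nrow(x$coef), x$d, x$shear_modulus))
  invisible(x)
}

# dW/dI1bar and dW/dI2bar at (a, b) = (I1bar - 3, I2bar - 3); vectorized
mr_wa_wb <- function(mat, a, b) {
  wa <- numeric(length(a)); wb <- numeric(length(a))
  pw <- function(base, e) if (e == 0) rep(1, length(base)) else base^e
  for (r in seq_len(nrow(mat$coef))) {
    i <- mat$coef$i[r]; j <- mat$coef$j[r]; C <- mat$coef$C[r]
    if (i > 0) wa <- wa + C * i * pw(a, i - 1) * pw(b, j)
    if (j > 0) wb <- wb + C * j * pw(a, i) * pw(b, j - 1)
  }
  list(wa = wa, wb = wb)
}

#' Strain energy density of a Mooney-Rivlin material
#' @param mat a `material_mr`.
#' @param F deformation gradient, 3x3 (or 2x2, embedded as plane strain).
#' @return W in Pa.
#' @export
strain_energy <- function(mat, F) {
  F <- embed_F(F)
  if (det(F) <= 0) stop_module("plaque_stress", "deformation gradient must have positive determinant")
  mr_energy_C(mat, t(F) %*% F)
}

# strain energy as a function of the right Cauchy-Green tensor (entries
# treated independently, so S = 2 dW/dC can be checked by finite differences)
mr_energy_C <- function(mat, C) {
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * t(C))) / 2
  J <- sqrt(det(C))
  a <- J^(-2 / 3) * I1 - 3
  b <- J^(-4 / 3) * I2 - 3
  W <- (1 / mat$d) * (J - 1)^2
  for (r in seq_len(nrow(mat$coef))) {
    W <- W + mat$coef$C[r] * a^mat$coef$i[r] * b^mat$coef$j[r]
  }
  W
}

embed_F <- function(F) {
  F <- as.matrix(F)
  if (all(dim(F) == c(2, 2))) {
    F3 <- diag(3); F3[1:2, 1:2] <- F
    F3
  } else if (all(dim(F) == c(3, 3))) F else {
    stop_module("plaque_stress", "deformation gradient must be 2x2 or 3x3")
  }
}

#' Cauchy stress of a Mooney-Rivlin material at a deformation gradient
#'
#' Second Piola-Kirchhoff stress `S = 2 dW/dC` derived analytically from the
#' strain-energy function, pushed forward to Cauchy stress
#' `sigma = F S F^T / J`.
#'
#' @param mat a `material_mr`.
#' @param F deformation gradient, 3x3 (or 2x2 plane-strain block).
#' @return 3x3 symmetric Cauchy stress (Pa).
#' @export
mooney_rivlin_stress <- function(mat, F) {
  F <- embed_F(F)
  J <- det(F)
  if (J <= 0) stop_module("plaque_stress", "deformation gradient must have positive determinant")
  S <- mr_second_pk(mat, t(F) %*% F)
  (F %*% S %*% t(F)) / J
}

# second Piola-Kirchhoff stress for a full 3x3 right Cauchy-Green tensor
mr_second_pk <- function(mat, C) {
  I <- diag(3)
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  detC <- det(C)
  J <- sqrt(detC)
  Cinv <- solve(C)
  a <- J^(-2 / 3) * I1 - 3
  b <- J^(-4 / 3) * I2 - 3
  w <- mr_wa_wb(mat, a, b)
  S_iso <- 2 * (w$wa * J^(-2 / 3) * (I - I1 / 3 * Cinv) +
                  w$wb * J^(-4 / 3) * (I1 * I - C - 2 * I2 / 3 * Cinv))
  S_vol <- (2 / mat$d) * (J - 1) * J * Cinv
  S_iso + S_vol
}

# vectorized plane-strain constitutive evaluation: inputs are vectors of the
# in-plane right Cauchy-Green components (C33 = 1); returns S components
mr_stress_ps <- function(mat, C11, C12, C22) {
  I1 <- C11 + C22 + 1
  trC2 <- C11^2 + 2 * C12^2 + C22^2 + 1
  I2 <- (I1^2 - trC2) / 2
  det2 <- C11 * C22 - C12^2
  J <- sqrt(det2)
  Ci11 <- C22 / det2; Ci12 <- -C12 / det2; Ci22 <- C11 / det2
  J23 <- J^(-2 / 3); J43 <- J^(-4 / 3)
  w <- mr_wa_wb(mat, J23 * I1 - 3, J43 * I2 - 3)
  vol <- (2 / mat$d) * (J - 1) * J
  S11 <- 2 * (w$wa * J23 * (1 - I1 / 3 * Ci11) +
                w$wb * J43 * (I1 - C11 - 2 * I2 / 3 * Ci11)) + vol * Ci11
  S12 <- 2 * (w$wa * J23 * (-I1 / 3 * Ci12) +
                w$wb * J43 * (-C12 - 2 * I2 / 3 * Ci12)) + vol * Ci12
  S22 <- 2 * (w$wa * J23 * (1 - I1 / 3 * Ci22) +
                w$wb * J43 * (I1 - C22 - 2 * I2 / 3 * Ci22)) + vol * Ci22
  S33 <- 2 * (w$wa * J23 * (1 - I1 / 3) +
                w$wb * J43 * (I1 - 1 - 2 * I2 / 3)) + vol
  list(S11 = S11, S12 = S12, S22 = S22, S33 = S33, J = J)
}
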