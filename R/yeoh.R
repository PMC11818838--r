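# Incompressible second-order Yeoh law and its uniaxial response.
# Sign convention: compression is lam < 1 with negative Cauchy stress;
# contact pressure downstream is -sigma. Stress units are MPa throughout.

#' Yeoh material parameters
#'
#' Container for the two constants of the second-order reduced-polynomial
#' (Yeoh) strain-energy function `W = C10*(I1 - 3) + C20*(I1 - 3)^2`, with
#' `I1` the first deviatoric invariant of the right Cauchy-Green tensor.
#'
#' @param C10 Stress-like constant (MPa), strictly positive.
#' @param C20 Stress-like constant (MPa), non-negative (zero is a valid
#'   lower bound for healthy femoral cartilage).
#' @return An object of class `yeoh_params`.
#' @examples
#' yeoh_params(C10 = 1.4, C20 = 3.65)
#' @export
yeoh_params <- function(C10, C20) {
  stopifnot(is.numeric(C10), length(C10) == 1L, is.finite(C10),
            is.numeric(C20), length(C20) == 1L, is.finite(C20))
  if (C10 <= 0) stop("C10 must be > 0", call. = FALSE)
  if (C20 < 0) stop("C20 must be >= 0", call. = FALSE)
  structure(list(C10 = as.numeric(C10), C20 = as.numeric(C20)),
            class = "yeoh_params")
}

#' @export
print.yeoh_params <- function(x, ...) {
  cat(sprintf("Yeoh parameters: C10 = %g MPa, C20 = %g MPa\n", x$C10, x$C20))
  invisible(x)
}

#' First deviatoric invariant under incompressible uniaxial loading
#'
#' For an incompressible uniaxial state the principal stretches are
#' `(lam, lam^(-1/2), lam^(-1/2))`, so `I1 = lam^2 + 2/lam`. The invariant
#' is at least 3, with equality only in the undeformed state `lam = 1`.
#'
#' @param lam Principal stretch along the loading axis (> 0); vectorised.
#' @return `lam^2 + 2/lam`.
#' @examples
#' first_invariant_uniaxial(1)    # 3
#' first_invariant_uniaxial(0.8)  # 3.14
#' @export
first_invariant_uniaxial <- function(lam) {
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0))
    stop("stretch 'lam' must be finite and > 0", call. = FALSE)
  lam^2 + 2 / lam
}

#' Yeoh strain-energy density
#'
#' @param p A [yeoh_params()] object.
#' @param I1 First deviatoric invariant (>= 3); vectorised.
#' @return Energy density `C10*(I1-3) + C20*(I1-3)^2` in MPa.
#' @examples
#' strain_energy(yeoh_params(0.6, 7.3), 3.2)  # 0.412
#' @export
strain_energy <- function(p, I1) {
  stopifnot(inherits(p, "yeoh_params"))
  if (!is.numeric(I1) || any(!is.finite(I1)) || any(I1 < 3))
    stop("invariant 'I1' must be >= 3", call. = FALSE)
  x <- I1 - 3
  p$C10 * x + p$C20 * x^2
}

#' Uniaxial Cauchy stress of an incompressible Yeoh solid
#'
#' Axial Cauchy stress for incompressible uniaxial loading,
#' `sigma = 2*(lam^2 - 1/lam) * (C10 + 2*C20*(I1 - 3))`, obtained from the
#' strain-energy function along the path `(lam, lam^(-1/2), lam^(-1/2))`.
#' Negative for compression (`lam < 1`), zero at `lam = 1`.
#'
#' @inheritParams strain_energy
#' @param lam Principal stretch (> 0); vectorised.
#' @return Axial Cauchy stress in MPa.
#' @examples
#' uniaxial_cauchy_stress(yeoh_params(1, 0), 0.9)  # -0.6022
#' @export
uniaxial_cauchy_stress <- function(p, lam) {
  stopifnot(inherits(p, "yeoh_params"))
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0))
    stop("stretch 'lam' must be finite and > 0", call. = FALSE)
  .yeoh_sigma(p$C10, p$C20, lam)
}

# sigma(lam) and d sigma / d lam, plain-double internals used by the
# vectorised contact solvers.
.yeoh_sigma <- function(C10, C20, lam) {
  I1m3 <- lam^2 + 2 / lam - 3
  2 * (lam^2 - 1 / lam) * (C10 + 2 * C20 * I1m3)
}

.yeoh_dsigma <- function(C10, C20, lam) {
  I1m3 <- lam^2 + 2 / lam - 3
  dI1 <- 2 * lam - 2 / lam^2
  2 * (2 * lam + 1 / lam^2) * (C10 + 2 * C20 * I1m3) +
    2 * (lam^2 - 1 / lam) * 2 * C20 * dI1
}
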