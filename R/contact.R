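# Layered sphere-plane contact solved with a nonlinear elastic-foundation
# (columnar) model: every surface point acts as an independent column made
# of the femoral and tibial cartilage layers in series on rigid bone,
# with the column pressure given by the incompressible uniaxial Yeoh
# response. Pressures in MPa, lengths in mm, forces in N (MPa * mm^2 = N).

.LAM_MIN <- 0.2          # validity limit of the column response
.LAM_TOL <- 1e-10        # absolute tolerance on the stretch root
.P_TOL <- 1e-8           # absolute tolerance on the column pressure (MPa)
.N_RADIAL <- 400         # trapezoid intervals of the radial quadrature

#' Cartilage layer
#'
#' One cartilage layer of the contact pair: its undeformed thickness and
#' Yeoh material.
#'
#' @param thickness Layer thickness in mm (> 0); 2.3 mm femoral and 2.1 mm
#'   tibial in the reference geometry.
#' @param material A [yeoh_params()] object.
#' @return An object of class `cartilage_layer`.
#' @export
cartilage_layer <- function(thickness, material) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L,
            is.finite(thickness), inherits(material, "yeoh_params"))
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  structure(list(thickness = as.numeric(thickness), material = material),
            class = "cartilage_layer")
}

#' Condylar contact pair specification
#'
#' Geometry and materials of one sphere-plane condylar pair: a rigid
#' sphere of radius `sphere_radius` carrying the femoral cartilage layer,
#' pressed into a rigid plane carrying the tibial layer. The bone modulus
#' and Poisson ratio are retained for documentation only: bone compliance
#' is negligible at these contact pressures and the backing is rigid.
#'
#' @param femoral,tibial [cartilage_layer()] objects.
#' @param sphere_radius Sphere radius in mm (default 40).
#' @param bone_modulus,bone_poisson Bone properties (MPa / ratio),
#'   documentation only; defaults 17200 MPa and 0.39.
#' @return An object of class `contact_pair_spec`.
#' @export
contact_pair_spec <- function(femoral, tibial, sphere_radius = 40,
                              bone_modulus = 17200, bone_poisson = 0.39) {
  stopifnot(inherits(femoral, "cartilage_layer"),
            inherits(tibial, "cartilage_layer"),
            is.numeric(sphere_radius), length(sphere_radius) == 1L)
  if (sphere_radius <= femoral$thickness + tibial$thickness)
    stop("sphere radius must exceed the total cartilage thickness",
         call. = FALSE)
  structure(list(sphere_radius = as.numeric(sphere_radius),
                 femoral = femoral, tibial = tibial,
                 bone_modulus = bone_modulus, bone_poisson = bone_poisson),
            class = "contact_pair_spec")
}

# Vectorised solve of -sigma(lam) = p for lam in (.LAM_MIN, 1], by Newton
# iteration safeguarded with bisection on a maintained bracket. sigma is
# strictly increasing on the bracket so the root is unique.
.lam_of_pressure <- function(C10, C20, p, tol = .LAM_TOL) {
  n <- length(p)
  pmax <- -.yeoh_sigma(C10, C20, .LAM_MIN)
  if (any(p > pmax))
    stop(sprintf(paste0("column pressure %.4g MPa exceeds the model's",
                        " validity limit (lam < %.2g)"),
                 max(p), .LAM_MIN), call. = FALSE)
  lo <- rep(.LAM_MIN, n)
  hi <- rep(1.0, n)
  # linearised start: sigma ~ 6*C10*(lam - 1) near lam = 1
  lam <- pmin(1, pmax(.LAM_MIN + 1e-6, 1 - p / (6 * C10)))
  for (it in 1:100) {
    f <- .yeoh_sigma(C10, C20, lam) + p
    pos <- f > 0
    hi[pos] <- lam[pos]
    lo[!pos] <- lam[!pos]
    step <- -f / .yeoh_dsigma(C10, C20, lam)
    cand <- lam + step
    bad <- !(cand >= lo & cand <= hi)
    cand[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(cand - lam) < tol
    lam <- cand
    if (all(done)) break
  }
  lam[p == 0] <- 1.0
  lam
}

#' Compression of one cartilage layer under uniform pressure
#'
#' Column response of a single layer: the stretch `lam*` solving
#' `-sigma(lam) = p` for the layer material gives the through-thickness
#' compression `thickness * (1 - lam*)`. Zero at zero pressure and
#' strictly increasing in pressure.
#'
#' @param layer A [cartilage_layer()] object.
#' @param p Pressure in MPa (>= 0); vectorised.
#' @return Compression in mm.
#' @examples
#' lay <- cartilage_layer(2.0, yeoh_params(1, 0))
#' layer_compression(lay, 0.6022)  # ~0.2 mm (inverse of lam = 0.9)
#' @export
layer_compression <- function(layer, p) {
  stopifnot(inherits(layer, "cartilage_layer"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("pressure 'p' must be finite and >= 0", call. = FALSE)
  m <- layer$material
  layer$thickness * (1 - .lam_of_pressure(m$C10, m$C20, p))
}

# Vectorised core: pressure p(u) of the two-layer column at total
# interpenetration u (mm), via safeguarded Newton on p with the analytic
# compliance du/dp = sum_i t_i / sigma_i'(lam_i).
.column_pressure_vec <- function(spec, u, tol = .P_TOL) {
  f <- spec$femoral; t <- spec$tibial
  tf <- f$thickness; tt <- t$thickness
  cf <- f$material; ct <- t$material
  ttot <- tf + tt
  if (any(u >= ttot))
    stop("interpenetration must be smaller than the total cartilage thickness",
         call. = FALSE)
  n <- length(u)
  pmax <- min(-.yeoh_sigma(cf$C10, cf$C20, .LAM_MIN),
              -.yeoh_sigma(ct$C10, ct$C20, .LAM_MIN)) * (1 - 1e-9)
  u_of <- function(p) {
    lf <- .lam_of_pressure(cf$C10, cf$C20, p)
    lt <- .lam_of_pressure(ct$C10, ct$C20, p)
    list(u = tf * (1 - lf) + tt * (1 - lt), lf = lf, lt = lt)
  }
  umax <- u_of(pmax)$u
  if (any(u > umax))
    stop("interpenetration beyond the validity of the column model",
         call. = FALSE)
  lo <- rep(0, n); hi <- rep(pmax, n)
  # linear-foundation start
  p <- pmin(pmax, u / (tf / (6 * cf$C10) + tt / (6 * ct$C10)))
  for (it in 1:100) {
    s <- u_of(p)
    g <- s$u - u
    pos <- g > 0
    hi[pos] <- p[pos]
    lo[!pos] <- p[!pos]
    dudp <- tf / .yeoh_dsigma(cf$C10, cf$C20, s$lf) +
            tt / .yeoh_dsigma(ct$C10, ct$C20, s$lt)
    cand <- p - g / dudp
    bad <- !(cand >= lo & cand <= hi)
    cand[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(cand - p) < tol
    p <- cand
    if (all(done)) break
  }
  p[u <= 0] <- 0
  p
}

#' Pressure of the two-layer cartilage column
#'
#' The two layers act in series and share one pressure: `column_pressure`
#' returns the `p >= 0` at which the femoral plus tibial compressions
#' equal the prescribed total interpenetration `u`.
#'
#' @param spec A [contact_pair_spec()] object.
#' @param u Total interpenetration in mm, `0 <= u < ` total thickness;
#'   vectorised.
#' @return Pressure in MPa.
#' @export
column_pressure <- function(spec, u) {
  stopifnot(inherits(spec, "contact_pair_spec"))
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0))
    stop("interpenetration 'u' must be finite and >= 0", call. = FALSE)
  .column_pressure_vec(spec, u)
}

#' Contact force of the indented sphere
#'
#' Integrates the column pressure over the contact patch,
#' `F = int_0^a p(u(r)) 2 pi r dr`, with the exact sphere profile
#' `u(r) = delta - (R - sqrt(R^2 - r^2))` and the contact radius `a`
#' defined by `u(a) = 0`. The radial quadrature is a fixed trapezoid grid
#' (400 intervals by default); its discretisation error is checked against
#' a 10x finer grid in the test suite.
#'
#' @param spec A [contact_pair_spec()] object.
#' @param delta Indentation in mm, `0 <= delta <= 1.05` (the working range
#'   of the study).
#' @param n_radial Number of trapezoid intervals (default 400).
#' @return Contact force in N.
#' @export
indentation_force <- function(spec, delta, n_radial = .N_RADIAL) {
  stopifnot(inherits(spec, "contact_pair_spec"),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta < 0) stop("indentation must be >= 0", call. = FALSE)
  if (delta > 1.05)
    stop("indentation beyond the 1.05 mm working range", call. = FALSE)
  if (delta == 0) return(0)
  R <- spec$sphere_radius
  a <- sqrt(R^2 - (R - delta)^2)
  r <- seq(0, a, length.out = n_radial + 1L)
  u <- delta - (R - sqrt(pmax(0, R^2 - r^2)))
  u[length(u)] <- 0  # exact boundary of the contact patch
  p <- .column_pressure_vec(spec, pmax(0, u))
  y <- p * 2 * pi * r
  sum((y[-1] + y[-length(y)]) / 2) * (a / n_radial)
}

#' Force-indentation curve of a condylar pair
#'
#' Solves the foundation contact model on the indentation grid
#' `{0, delta_max/n_steps, ..., delta_max}` (21 points for the default 20
#' steps to 1.00 mm; the explicit zero point anchors interpolation).
#'
#' @inheritParams indentation_force
#' @param delta_max Largest indentation in mm (default 1.00).
#' @param n_steps Number of indentation steps (default 20).
#' @return An object of class `fi_curve` with components `indentations`
#'   (mm) and `forces` (N), both of length `n_steps + 1`.
#' @export
compute_curve <- function(spec, delta_max = 1.00, n_steps = 20,
                          n_radial = .N_RADIAL) {
  stopifnot(delta_max > 0, n_steps >= 2)
  deltas <- seq(0, delta_max, length.out = n_steps + 1L)
  forces <- vapply(deltas, function(d) indentation_force(spec, d, n_radial),
                   numeric(1))
  fi_curve(deltas, forces)
}

#' Force-indentation curve container
#'
#' @param indentations Ascending grid of indentations in mm starting at 0.
#' @param forces Matching non-decreasing contact forces in N with
#'   `forces[1] = 0`.
#' @return An object of class `fi_curve`.
#' @export
fi_curve <- function(indentations, forces) {
  stopifnot(is.numeric(indentations), is.numeric(forces),
            length(indentations) == length(forces),
            length(indentations) >= 2L)
  if (indentations[1] != 0 || forces[1] != 0)
    stop("curve must start at (0, 0)", call. = FALSE)
  if (any(diff(indentations) <= 0))
    stop("indentation grid must be strictly increasing", call. = FALSE)
  if (any(diff(forces) < 0))
    stop("forces must be non-decreasing", call. = FALSE)
  structure(list(indentations = as.numeric(indentations),
                 forces = as.numeric(forces)),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("Force-indentation curve: %d points, F(%.2f mm) = %.1f N\n",
              length(x$forces), max(x$indentations), max(x$forces)))
  invisible(x)
}

#' Evaluate a force-indentation curve
#'
#' Piecewise-linear interpolation inside the stored grid, linear
#' extrapolation along the last segment beyond it, and zero force for
#' non-positive indentation (no tension through contact).
#'
#' @param curve An [fi_curve()] object.
#' @param delta Indentation in mm; vectorised.
#' @return Contact force in N.
#' @examples
#' cv <- fi_curve(c(0, 0.5, 1), c(0, 100, 300))
#' eval_curve(cv, 1.25)  # 400
#' @export
eval_curve <- function(curve, delta) {
  stopifnot(inherits(curve, "fi_curve"))
  g <- curve$indentations; f <- curve$forces
  m <- length(g)
  out <- numeric(length(delta))
  pos <- delta > 0
  if (any(pos)) {
    d <- delta[pos]
    i <- pmin(findInterval(d, g), m - 1L)
    out[pos] <- f[i] + (d - g[i]) * (f[i + 1L] - f[i]) / (g[i + 1L] - g[i])
  }
  out
}

#' Write/read a force-indentation curve as CSV
#'
#' Two-column CSV (`indentation_mm`, `force_N`), one file per sample.
#'
#' @param curve An [fi_curve()] object.
#' @param path File path.
#' @return `write_fi_curve` returns `path` invisibly; `read_fi_curve`
#'   returns the [fi_curve()].
#' @export
write_fi_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fi_curve"))
  utils::write.csv(data.frame(indentation_mm = curve$indentations,
                              force_N = curve$forces),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fi_curve
#' @export
read_fi_curve <- function(path) {
  d <- utils::read.csv(path)
  fi_curve(d$indentation_mm, d$force_N)
}
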