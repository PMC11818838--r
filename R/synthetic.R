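# Nominal planar knee stand-in. The condyle radius (40 mm), cartilage
# thicknesses (2.3/2.1 mm), neutral pose (~55 deg flexion) and motion
# range (~74 deg under +/-3.5 N m) are printed anchors of the study; the
# remaining geometry, masses, stiffnesses and damping are synthetic
# values calibrated once so that the anchors hold (see the methods
# vignette for the calibration procedure). Every parameter is labelled
# `printed` or `synthetic` in the provenance manifest.

# Neutral-pose layout (world frame, mm, at theta0): ligament attachments
# are given at their neutral world positions and converted to femur-local
# coordinates when the model is built. Tibial attachments sit on or below
# the plateau (y = 0); femoral points ride with the femur.
.nominal_layout <- function() {
  list(
    theta0_deg = 55,
    condyle_x = c(0, 16),        # mm, condyle center x at neutral (ant, post)
    condyle_radius = 40,         # printed
    seat_indentation = 0.30,     # mm, nominal neutral indentation
    # fem = c(x, y relative to the femur reference height), world frame at
    # the neutral pose; slack > 0 means the cable is slack at neutral by
    # that strain fraction, < 0 pre-strained (taut).
    ACL = list(fem = c(16, -20), tib = c(-20, -4), k = 2000, slack = 0.06),
    PCL = list(fem = c(-12, -8), tib = c(30, 3), k = 9000, slack = 0.065),
    MCL = list(fem = c(16, 0), tib = c(-3, -14), k = 800, slack = -0.06),
    LCL = list(fem = c(0, 0), tib = c(3, -14), k = 800, slack = -0.035),
    mass = 4.0,                  # kg, femur segment
    inertia = 0.02,              # kg m^2 about the reference point
    damping_lin = 600,           # N s/m
    damping_ang = 0.25           # N m s/rad
  )
}

# Build a knee_model from a neutral-pose layout description.
.build_nominal <- function(lay) {
  th0 <- lay$theta0_deg * pi / 180
  h0 <- lay$condyle_radius - lay$seat_indentation
  q0 <- c(0, h0)
  # inverse (counter-clockwise) rotation world -> femur local
  to_local <- function(w) {
    ct <- cos(th0); st <- sin(th0)
    rel <- w - q0
    c(ct * rel[1] - st * rel[2], st * rel[1] + ct * rel[2])
  }
  cc <- rbind(to_local(c(lay$condyle_x[1], h0)),
              to_local(c(lay$condyle_x[2], h0)))
  mk <- function(nm) {
    d <- lay[[nm]]
    fem_w <- c(d$fem[1], h0 + d$fem[2])
    tib_w <- d$tib
    len0 <- sqrt(sum((fem_w - tib_w)^2))
    ligament(nm, femoral = to_local(fem_w), tibial = tib_w,
             k = d$k, L0 = len0 * (1 + d$slack))
  }
  knee_model(ligaments = lapply(.LIGAMENT_NAMES, mk),
             condyle_centers = cc,
             condyle_radius = lay$condyle_radius,
             mass = lay$mass, inertia = lay$inertia,
             damping_lin = lay$damping_lin, damping_ang = lay$damping_ang,
             theta0_deg = lay$theta0_deg, q0 = q0)
}

#' Nominal planar knee model
#'
#' Deterministic synthetic stand-in for the reference planar knee: four
#' ligament cables, two condylar pairs of radius 40 mm, neutral pose near
#' 55 degrees of flexion, and a flexion-extension range of roughly 74
#' degrees under +/-3.5 N m with mid-range healthy cartilage curves. The
#' ACL is slack on the whole flexion branch. Two calls return identical
#' models.
#'
#' @return A [knee_model()] object.
#' @export
default_model <- function() {
  .build_nominal(.nominal_layout())
}

#' Provenance of the nominal model parameters
#'
#' Tags every nominal parameter as `printed` (a value stated for the
#' reference system: condyle radius, cartilage thicknesses, neutral pose,
#' load protocol) or `synthetic` (a calibrated stand-in value: attachment
#' sites, stiffnesses, slack strains, mass, inertia, damping).
#'
#' @return A data frame with columns `parameter`, `value`, `provenance`.
#' @export
nominal_provenance <- function() {
  lay <- .nominal_layout()
  rows <- list(
    c("condyle_radius_mm", lay$condyle_radius, "printed"),
    c("theta0_deg", lay$theta0_deg, "printed (approximate anchor)"),
    c("femoral_thickness_mm", 2.3, "printed"),
    c("tibial_thickness_mm", 2.1, "printed"),
    c("condyle_x_mm", paste(lay$condyle_x, collapse = "/"), "synthetic"),
    c("seat_indentation_mm", lay$seat_indentation, "synthetic"),
    c("mass_kg", lay$mass, "synthetic"),
    c("inertia_kgm2", lay$inertia, "synthetic"),
    c("damping_lin_Nsm", lay$damping_lin, "synthetic"),
    c("damping_ang_Nms", lay$damping_ang, "synthetic")
  )
  for (nm in .LIGAMENT_NAMES) {
    d <- lay[[nm]]
    rows <- c(rows, list(
      c(paste0(nm, "_k_N"), d$k, "synthetic"),
      c(paste0(nm, "_slack_strain"), d$slack, "synthetic"),
      c(paste0(nm, "_attachments_mm"),
        paste(c(d$fem, d$tib), collapse = "/"), "synthetic")))
  }
  data.frame(parameter = vapply(rows, `[`, character(1), 1),
             value = vapply(rows, `[`, character(1), 2),
             provenance = vapply(rows, `[`, character(1), 3))
}

#' Apply a stage-2 ligament perturbation
#'
#' Shifts every ligament attachment by the perturbation's 16 coordinate
#' offsets (femoral offsets in the femur's local frame, tibial offsets in
#' the tibia frame) and multiplies each stiffness by its factor. All other
#' model fields are untouched; the input model is not modified.
#'
#' @param model A [knee_model()] object.
#' @param pert A [ligament_perturbation()] object.
#' @return A new [knee_model()].
#' @export
apply_perturbation <- function(model, pert) {
  stopifnot(inherits(model, "knee_model"),
            inherits(pert, "ligament_perturbation"))
  ligs <- model$ligaments
  for (i in seq_along(.LIGAMENT_NAMES)) {
    o <- unname(pert$offsets[(4 * (i - 1) + 1):(4 * i)])
    l <- ligs[[i]]
    l$femoral <- l$femoral + o[1:2]
    l$tibial <- l$tibial + o[3:4]
    l$k <- unname(l$k * pert$multipliers[i])
    ligs[[i]] <- l
  }
  model$ligaments <- ligs
  model
}

#' Build the full two-stage run matrix
#'
#' Crosses the ligament-system variants with the per-group contact curve
#' samples into one descriptor per (variant, group, sample) simulation,
#' with stable ids and integer seeds.
#'
#' @param models List of [knee_model()] variants (stage 2).
#' @param curves_healthy,curves_oa Lists of [fi_curve()] objects (stage
#'   1), one per material sample, equal lengths.
#' @return A data frame with columns `run_id`, `variant`, `group`,
#'   `sample`, `seed`.
#' @export
build_study <- function(models, curves_healthy, curves_oa) {
  stopifnot(is.list(models), length(models) >= 1L,
            is.list(curves_healthy), is.list(curves_oa),
            length(curves_healthy) == length(curves_oa),
            length(curves_healthy) >= 1L)
  nv <- length(models); ns <- length(curves_healthy)
  g <- expand.grid(sample = seq_len(ns), group = c("healthy", "oa"),
                   variant = seq_len(nv), stringsAsFactors = FALSE)
  data.frame(
    run_id = sprintf("v%02d_%s_s%03d", g$variant, g$group, g$sample),
    variant = g$variant, group = g$group, sample = g$sample,
    seed = g$variant * 1000L + g$sample * 2L +
      as.integer(g$group == "oa"))
}
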