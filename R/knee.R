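# Planar hybrid tibiofemoral model: a rigid femur moving in the sagittal
# plane over a fixed tibia, four tension-only nonlinear ligament cables,
# and two condylar contact pairs whose normal force comes from
# precomputed force-indentation curves. Dynamics are integrated with the
# semi-implicit (symplectic) Euler method.
#
# Frames and conventions:
#   * tibia frame == world frame; the tibial plateau is the line y = 0
#     with outward normal +y; +x points posteriorly, +y upward;
#   * the femur pose is q = (x, y, theta) with theta the knee flexion
#     angle (0 deg = full extension, increasing with flexion); a femoral
#     local point a maps to world as q_xy + R_cw(theta) %*% a, i.e.
#     flexion rotates the femur clockwise in the (x, y) plane;
#   * the external moment is signed extension-positive at the protocol
#     interface (the printed load convention); the generalized moment
#     conjugate to theta is flexion-positive, so an extension branch
#     applies a negative generalized moment;
#   * lengths are mm and angles deg at all interfaces; the integrator
#     works in SI (m, rad, N, s).

.EPS_TOE <- 0.03  # ligament toe-region strain limit parameter

#' Ligament cable
#'
#' Tension-only nonlinear cable between a femoral attachment (femur local
#' frame, mm) and a tibial attachment (tibia/world frame, mm), with
#' stiffness `k` (N, per unit strain in the linear branch) and reference
#' length `L0` (mm). The cable is slack (zero force) whenever its current
#' length does not exceed `L0`.
#'
#' @param name One of `"ACL"`, `"PCL"`, `"MCL"`, `"LCL"`.
#' @param femoral,tibial Length-2 numeric attachment coordinates in mm.
#' @param k Stiffness in N (> 0).
#' @param L0 Reference (slack) length in mm (> 0).
#' @return An object of class `ligament`.
#' @export
ligament <- function(name, femoral, tibial, k, L0) {
  name <- match.arg(name, .LIGAMENT_NAMES)
  stopifnot(length(femoral) == 2L, length(tibial) == 2L,
            is.numeric(femoral), is.numeric(tibial),
            length(k) == 1L, length(L0) == 1L)
  if (k <= 0 || L0 <= 0) stop("k and L0 must be > 0", call. = FALSE)
  structure(list(name = name, femoral = as.numeric(femoral),
                 tibial = as.numeric(tibial),
                 k = as.numeric(k), L0 = as.numeric(L0)),
            class = "ligament")
}

#' Planar knee model
#'
#' @param ligaments List of 4 [ligament()] objects in the order ACL, PCL,
#'   MCL, LCL.
#' @param condyle_centers 2 x 2 matrix of condyle-circle centers in the
#'   femur frame (mm), one row per condylar pair.
#' @param condyle_radius Condyle circle radius in mm (default 40, the
#'   sphere radius of the contact stage).
#' @param mass Femur segment mass in kg.
#' @param inertia Moment of inertia about the femur reference point in
#'   kg m^2.
#' @param damping_lin Linear viscous damping on translation (N s/m).
#' @param damping_ang Viscous damping on rotation (N m s/rad).
#' @param theta0_deg Initial (neutral) flexion angle in degrees.
#' @param q0 Initial femur reference position `c(x, y)` in mm.
#' @return An object of class `knee_model`.
#' @export
knee_model <- function(ligaments, condyle_centers, condyle_radius = 40,
                       mass, inertia, damping_lin, damping_ang,
                       theta0_deg, q0) {
  stopifnot(is.list(ligaments), length(ligaments) == 4L,
            all(vapply(ligaments, inherits, logical(1), "ligament")),
            is.matrix(condyle_centers), identical(dim(condyle_centers), c(2L, 2L)),
            condyle_radius > 0, mass > 0, inertia > 0,
            damping_lin >= 0, damping_ang >= 0, length(q0) == 2L)
  nm <- unname(vapply(ligaments, `[[`, character(1), "name"))
  if (!identical(nm, .LIGAMENT_NAMES))
    stop("ligaments must be given in the order ACL, PCL, MCL, LCL",
         call. = FALSE)
  names(ligaments) <- nm
  structure(list(ligaments = ligaments,
                 condyle_centers = condyle_centers,
                 condyle_radius = as.numeric(condyle_radius),
                 mass = as.numeric(mass), inertia = as.numeric(inertia),
                 damping_lin = as.numeric(damping_lin),
                 damping_ang = as.numeric(damping_ang),
                 theta0_deg = as.numeric(theta0_deg),
                 q0 = as.numeric(q0)),
            class = "knee_model")
}

#' Planar state of the femur
#'
#' @param q Pose `c(x_mm, y_mm, theta_deg)`.
#' @param v Velocity `c(xdot_mm_s, ydot_mm_s, thetadot_deg_s)`; defaults
#'   to rest.
#' @return An object of class `planar_state`.
#' @export
planar_state <- function(q, v = c(0, 0, 0)) {
  stopifnot(length(q) == 3L, length(v) == 3L,
            all(is.finite(q)), all(is.finite(v)))
  structure(list(q = as.numeric(q), v = as.numeric(v)),
            class = "planar_state")
}

#' Load protocol of one flexion or extension branch
#'
#' The external moment ramps from zero to `M_max` in `n_steps` equal
#' increments applied at the start of equally long plateaus spanning
#' `duration` seconds in total; extension is moment-positive.
#'
#' @param direction `"extension"` or `"flexion"`.
#' @param M_max Peak moment magnitude in N m (default 3.5).
#' @param n_steps Number of moment increments (default 5).
#' @param duration Branch duration in s (default 16).
#' @param dt Integrator time step in s (default 0.001).
#' @return An object of class `load_protocol`.
#' @export
load_protocol <- function(direction = c("extension", "flexion"),
                          M_max = 3.5, n_steps = 5, duration = 16.0,
                          dt = 0.001) {
  direction <- match.arg(direction)
  stopifnot(M_max >= 0, n_steps >= 1, duration > 0, dt > 0)
  structure(list(direction = direction, M_max = as.numeric(M_max),
                 n_steps = as.integer(n_steps),
                 duration = as.numeric(duration), dt = as.numeric(dt)),
            class = "load_protocol")
}

#' Tension of a ligament cable at a given length
#'
#' Quadratic-toe/linear tension-only law in terms of the strain
#' `eps = (length - L0)/L0`: zero when slack, `k*eps^2/(4*eps_l)` in the
#' toe region `0 < eps <= 2*eps_l`, and `k*(eps - eps_l)` beyond, with
#' toe parameter `eps_l = 0.03`. Force and stiffness are continuous at
#' the toe-to-linear transition.
#'
#' @param lig A [ligament()] object.
#' @param length Current cable length in mm (> 0); vectorised.
#' @return Tension in N (>= 0).
#' @examples
#' lig <- ligament("ACL", c(0, 0), c(0, 0), k = 1000, L0 = 100)
#' ligament_force(lig, 106)  # toe branch: 30 N
#' ligament_force(lig, 110)  # linear branch: 70 N
#' @export
ligament_force <- function(lig, length) {
  stopifnot(inherits(lig, "ligament"))
  if (!is.numeric(length) || any(!is.finite(length)) || any(length <= 0))
    stop("cable length must be finite and > 0", call. = FALSE)
  eps <- (length - lig$L0) / lig$L0
  .cable_tension(eps, lig$k)
}

# vectorised tension law on strain
.cable_tension <- function(eps, k) {
  el <- .EPS_TOE
  f <- numeric(length(eps))
  toe <- eps > 0 & eps <= 2 * el
  lin <- eps > 2 * el
  f[toe] <- k * eps[toe]^2 / (4 * el)
  f[lin] <- k * (eps[lin] - el)
  f
}

# clockwise rotation matrix action used throughout: local (ax, ay) at
# flexion angle th (rad) maps to offset (ct*ax + st*ay, -st*ax + ct*ay).
.rot_cw <- function(th, ax, ay) {
  ct <- cos(th); st <- sin(th)
  cbind(ct * ax + st * ay, -st * ax + ct * ay)
}

#' Contact state of the condylar pairs
#'
#' For each condylar pair, the indentation is the penetration of the
#' lowest point of the condyle circle past the tibial plateau line
#' (clamped at zero when separated) and the contact force follows the
#' pair's force-indentation curve along the plateau normal.
#'
#' @param model A [knee_model()] object.
#' @param state A [planar_state()] object.
#' @param curves List of 2 [fi_curve()] objects, one per condylar pair.
#' @return A data frame with one row per pair: `indentation_mm`,
#'   `force_N`, `point_x_mm`, `point_y_mm`, `normal_x`, `normal_y`.
#' @export
contact_state <- function(model, state, curves) {
  stopifnot(inherits(model, "knee_model"), inherits(state, "planar_state"),
            is.list(curves), length(curves) == 2L)
  th <- state$q[3] * pi / 180
  cc <- model$condyle_centers
  off <- .rot_cw(th, cc[, 1], cc[, 2])
  cx <- state$q[1] + off[, 1]
  cy <- state$q[2] + off[, 2]
  ind <- pmax(0, model$condyle_radius - cy)
  force <- vapply(1:2, function(i) eval_curve(curves[[i]], ind[i]),
                  numeric(1))
  data.frame(indentation_mm = ind, force_N = force,
             point_x_mm = cx, point_y_mm = 0,
             normal_x = 0, normal_y = 1)
}

#' Generalized force on the femur
#'
#' Sums ligament tensions along their cable lines, contact forces at the
#' contact points, viscous damping and the applied moment into the
#' generalized force `(Fx, Fy, Q_theta)` about the femur reference point.
#' `Fx`/`Fy` are in N; `Q_theta` is in N m and conjugate to the flexion
#' angle (flexion-positive). Gravity is omitted; the protocol is purely
#' moment-driven.
#'
#' @inheritParams contact_state
#' @param M_ext Applied generalized moment in N m, flexion-positive.
#' @return Numeric length-3 vector `(Fx_N, Fy_N, Q_Nm)`.
#' @export
net_wrench <- function(model, state, curves, M_ext = 0) {
  stopifnot(inherits(model, "knee_model"), inherits(state, "planar_state"))
  th <- state$q[3] * pi / 180
  x <- state$q[1]; y <- state$q[2]
  Fx <- 0; Fy <- 0; tau_ccw <- 0  # forces N, torque N mm, ccw-positive
  for (lig in model$ligaments) {
    off <- .rot_cw(th, lig$femoral[1], lig$femoral[2])
    px <- x + off[1]; py <- y + off[2]
    dx <- lig$tibial[1] - px; dy <- lig$tibial[2] - py
    len <- sqrt(dx^2 + dy^2)
    f <- ligament_force(lig, len)
    if (f > 0) {
      fx <- f * dx / len; fy <- f * dy / len
      Fx <- Fx + fx; Fy <- Fy + fy
      tau_ccw <- tau_ccw + (px - x) * fy - (py - y) * fx
    }
  }
  cs <- contact_state(model, state, curves)
  Fy <- Fy + sum(cs$force_N)
  tau_ccw <- tau_ccw + sum((cs$point_x_mm - x) * cs$force_N)
  # damping (interface velocities are mm/s and deg/s)
  Fx <- Fx - model$damping_lin * state$v[1] / 1000
  Fy <- Fy - model$damping_lin * state$v[2] / 1000
  Q <- -tau_ccw / 1000 + M_ext - model$damping_ang * state$v[3] * pi / 180
  c(Fx, Fy, Q)
}

#' One semi-implicit Euler step
#'
#' Updates the velocity first with the current generalized force, then the
#' position with the new velocity (symplectic Euler), which is stable for
#' stiff unilateral contact at small steps.
#'
#' @inheritParams contact_state
#' @param wrench Generalized force `(Fx_N, Fy_N, Q_Nm)` as returned by
#'   [net_wrench()].
#' @param dt Time step in s.
#' @return The new [planar_state()].
#' @export
step_semi_implicit <- function(state, wrench, dt, model) {
  stopifnot(inherits(state, "planar_state"), length(wrench) == 3L, dt > 0,
            inherits(model, "knee_model"))
  # SI: m, rad
  v <- c(state$v[1] / 1000, state$v[2] / 1000, state$v[3] * pi / 180)
  q <- c(state$q[1] / 1000, state$q[2] / 1000, state$q[3] * pi / 180)
  minv <- c(1 / model$mass, 1 / model$mass, 1 / model$inertia)
  v <- v + minv * wrench * dt
  q <- q + v * dt
  planar_state(q = c(q[1] * 1000, q[2] * 1000, q[3] * 180 / pi),
               v = c(v[1] * 1000, v[2] * 1000, v[3] * 180 / pi))
}

#' Simulate one loading branch
#'
#' Runs the stepped-moment protocol from the model's neutral pose: the
#' moment grows by `M_max/n_steps` at the start of each plateau and is
#' held constant until the next increment; global viscous damping lets
#' every plateau settle to equilibrium. Flexion angle, ligament forces
#' and contact forces are recorded along the trajectory (decimated by
#' `record_every`), running per-ligament maxima are tracked at every
#' step, and the equilibrium angle and residual generalized force are
#' stored at the end of each plateau.
#'
#' @inheritParams contact_state
#' @param protocol A [load_protocol()] object.
#' @param record_every Trajectory decimation stride (default 10 steps).
#' @return An object of class `knee_sim`: a list with `time_s`,
#'   `M_ext_Nm`, `theta_deg`, `lig_forces_N` (matrix, columns ACL, PCL,
#'   MCL, LCL), `contact_forces_N` (matrix, 2 columns), `max_lig_N`,
#'   `max_contact_N`, `plateau` (data frame with equilibrium angle,
#'   residual norm and kinetic energy per plateau), `final_state`,
#'   `kinetic_energy_J` and the protocol.
#' @export
run_branch <- function(model, curves, protocol, record_every = 10L) {
  stopifnot(inherits(model, "knee_model"), inherits(protocol, "load_protocol"),
            is.list(curves), length(curves) == 2L,
            all(vapply(curves, inherits, logical(1), "fi_curve")))
  dt <- protocol$dt
  n_steps_total <- round(protocol$duration / dt)
  plateau_len <- n_steps_total %/% protocol$n_steps
  dM <- protocol$M_max / protocol$n_steps
  sgn <- if (protocol$direction == "extension") +1 else -1

  # everything below is SI; geometry converted once
  ligs <- model$ligaments
  afx <- vapply(ligs, function(l) l$femoral[1], numeric(1)) / 1000
  afy <- vapply(ligs, function(l) l$femoral[2], numeric(1)) / 1000
  atx <- vapply(ligs, function(l) l$tibial[1], numeric(1)) / 1000
  aty <- vapply(ligs, function(l) l$tibial[2], numeric(1)) / 1000
  kk <- vapply(ligs, `[[`, numeric(1), "k")
  L0 <- vapply(ligs, `[[`, numeric(1), "L0") / 1000
  el <- .EPS_TOE
  ccx <- model$condyle_centers[, 1] / 1000
  ccy <- model$condyle_centers[, 2] / 1000
  rad <- model$condyle_radius / 1000
  g1 <- curves[[1]]$indentations; f1 <- curves[[1]]$forces
  g2 <- curves[[2]]$indentations; f2 <- curves[[2]]$forces
  m1 <- length(g1); m2 <- length(g2)
  mass <- model$mass; inertia <- model$inertia
  clin <- model$damping_lin; cang <- model$damping_ang

  x <- model$q0[1] / 1000; y <- model$q0[2] / 1000
  th <- model$theta0_deg * pi / 180
  vx <- 0; vy <- 0; om <- 0

  nrec <- n_steps_total %/% record_every + 1L
  rec_t <- numeric(nrec); rec_M <- numeric(nrec); rec_th <- numeric(nrec)
  rec_x <- numeric(nrec); rec_y <- numeric(nrec)
  rec_lig <- matrix(0, nrec, 4L); rec_con <- matrix(0, nrec, 2L)
  max_lig <- numeric(4L); max_con <- numeric(2L)
  plateau <- data.frame(time_s = numeric(0), M_ext_Nm = numeric(0),
                        theta_deg = numeric(0), residual = numeric(0),
                        kinetic_energy_J = numeric(0))
  irec <- 0L
  guard <- 50  # m/s and rad/s divergence guard

  eval1 <- function(d) {
    if (d <= 0) return(0)
    i <- findInterval(d, g1); if (i >= m1) i <- m1 - 1L
    f1[i] + (d - g1[i]) * (f1[i + 1L] - f1[i]) / (g1[i + 1L] - g1[i])
  }
  eval2 <- function(d) {
    if (d <= 0) return(0)
    i <- findInterval(d, g2); if (i >= m2) i <- m2 - 1L
    f2[i] + (d - g2[i]) * (f2[i + 1L] - f2[i]) / (g2[i + 1L] - g2[i])
  }

  for (step in 0:(n_steps_total - 1L)) {
    lvl <- min(protocol$n_steps, step %/% plateau_len + 1L)
    M_signed <- sgn * dM * lvl          # extension-positive convention
    Q_applied <- -M_signed              # flexion-positive generalized moment

    ct <- cos(th); st <- sin(th)
    px <- x + ct * afx + st * afy
    py <- y - st * afx + ct * afy
    dx <- atx - px; dy <- aty - py
    len <- sqrt(dx * dx + dy * dy)
    eps <- (len - L0) / L0
    fl <- numeric(4L)
    toe <- eps > 0 & eps <= 2 * el
    lin <- eps > 2 * el
    fl[toe] <- kk[toe] * eps[toe]^2 / (4 * el)
    fl[lin] <- kk[lin] * (eps[lin] - el)
    fxl <- fl * dx / len; fyl <- fl * dy / len
    Fx <- sum(fxl); Fy <- sum(fyl)
    tau <- sum((px - x) * fyl - (py - y) * fxl)

    cx <- x + ct * ccx + st * ccy
    cy <- y - st * ccx + ct * ccy
    d1 <- (rad - cy[1]) * 1000; d2 <- (rad - cy[2]) * 1000
    Fc1 <- eval1(d1); Fc2 <- eval2(d2)
    Fy <- Fy + Fc1 + Fc2
    tau <- tau + (cx[1] - x) * Fc1 + (cx[2] - x) * Fc2

    Fx <- Fx - clin * vx
    Fy <- Fy - clin * vy
    Q <- -tau + Q_applied - cang * om

    vx <- vx + Fx / mass * dt
    vy <- vy + Fy / mass * dt
    om <- om + Q / inertia * dt
    x <- x + vx * dt
    y <- y + vy * dt
    th <- th + om * dt

    if (fl[1] > max_lig[1]) max_lig[1] <- fl[1]
    if (fl[2] > max_lig[2]) max_lig[2] <- fl[2]
    if (fl[3] > max_lig[3]) max_lig[3] <- fl[3]
    if (fl[4] > max_lig[4]) max_lig[4] <- fl[4]
    if (Fc1 > max_con[1]) max_con[1] <- Fc1
    if (Fc2 > max_con[2]) max_con[2] <- Fc2

    if (step %% record_every == 0L) {
      irec <- irec + 1L
      rec_t[irec] <- step * dt; rec_M[irec] <- M_signed
      rec_th[irec] <- th * 180 / pi
      rec_x[irec] <- x * 1000; rec_y[irec] <- y * 1000
      rec_lig[irec, ] <- fl; rec_con[irec, ] <- c(Fc1, Fc2)
    }
    if (step %% 200L == 0L &&
        !(abs(vx) <= guard && abs(vy) <= guard && abs(om) <= guard))
      stop(sprintf("integration diverged at step %d (t = %.3f s)",
                   step, step * dt), call. = FALSE)
    if ((step + 1L) %% plateau_len == 0L) {
      ke <- 0.5 * mass * (vx^2 + vy^2) + 0.5 * inertia * om^2
      res <- sqrt(Fx^2 + Fy^2 + Q^2)
      plateau <- rbind(plateau, data.frame(
        time_s = (step + 1L) * dt, M_ext_Nm = M_signed,
        theta_deg = th * 180 / pi, residual = res,
        kinetic_energy_J = ke))
    }
  }

  names(max_lig) <- .LIGAMENT_NAMES
  final <- planar_state(q = c(x * 1000, y * 1000, th * 180 / pi),
                        v = c(vx * 1000, vy * 1000, om * 180 / pi))
  structure(list(
    time_s = rec_t[seq_len(irec)], M_ext_Nm = rec_M[seq_len(irec)],
    theta_deg = rec_th[seq_len(irec)],
    x_mm = rec_x[seq_len(irec)], y_mm = rec_y[seq_len(irec)],
    lig_forces_N = `colnames<-`(rec_lig[seq_len(irec), , drop = FALSE],
                                .LIGAMENT_NAMES),
    contact_forces_N = rec_con[seq_len(irec), , drop = FALSE],
    max_lig_N = max_lig, max_contact_N = max_con,
    plateau = plateau, final_state = final,
    kinetic_energy_J = 0.5 * model$mass * ((vx)^2 + (vy)^2) +
      0.5 * model$inertia * om^2,
    protocol = protocol), class = "knee_sim")
}

#' @export
print.knee_sim <- function(x, ...) {
  cat(sprintf(
    "Knee branch (%s): final theta %.2f deg, max contact %.1f N\n",
    x$protocol$direction, x$final_state$q[3], max(x$max_contact_N)))
  invisible(x)
}

#' Angular range of a flexion-extension pair
#'
#' Difference between the settled end-of-branch flexion angles of the
#' flexion and extension branches of the same model.
#'
#' @param res_ext,res_flex [run_branch()] results for the extension and
#'   flexion branches.
#' @return Range of angular displacement in degrees (>= 0 for a sane
#'   model).
#' @export
angular_range <- function(res_ext, res_flex) {
  stopifnot(inherits(res_ext, "knee_sim"), inherits(res_flex, "knee_sim"))
  res_flex$final_state$q[3] - res_ext$final_state$q[3]
}
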