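# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (bisection, quadrature refinement, finite
# differences) and share no code with the package's solvers.

midrange_params <- function(group = "healthy") {
  r <- material_ranges()[[group]]
  m <- (r[, 1] + r[, 2]) / 2
  list(femoral = yeoh_params(m[1], m[2]), tibial = yeoh_params(m[3], m[4]))
}

midrange_spec <- function(group = "healthy") {
  m <- midrange_params(group)
  contact_pair_spec(femoral = cartilage_layer(2.3, m$femoral),
                    tibial = cartilage_layer(2.1, m$tibial))
}

# draw n (C10, C20) pairs uniformly inside the hull of all Table-style
# ranges (both groups pooled)
random_yeoh <- function(n, seed = 1) {
  set.seed(seed)
  ranges <- material_ranges()
  lo <- pmin(ranges$healthy[, 1], ranges$oa[, 1])
  hi <- pmax(ranges$healthy[, 2], ranges$oa[, 2])
  c10 <- runif(n, min(lo[c(1, 3)]), max(hi[c(1, 3)]))
  c10[c10 <= 0] <- 0.1
  c20 <- runif(n, min(lo[c(2, 4)]), max(hi[c(2, 4)]))
  Map(yeoh_params, c10, c20)
}

# plain-bisection layer compression oracle: solve -sigma(lam) = p on
# [0.2, 1] by 60 bisections, return thickness * (1 - lam)
oracle_layer_compression <- function(layer, p) {
  if (p <= 0) return(0)
  lo <- 0.2; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (-uniaxial_cauchy_stress(layer$material, mid) > p) lo <- mid
    else hi <- mid
  }
  layer$thickness * (1 - (lo + hi) / 2)
}

# nested-bisection column pressure oracle: outer bisection on pressure,
# inner bisection on each layer stretch
oracle_column_pressure <- function(spec, u, tol = 1e-10) {
  comp <- function(layer, p) {
    f <- function(l) -uniaxial_cauchy_stress(layer$material, l) - p
    lo <- 0.2; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    layer$thickness * (1 - (lo + hi) / 2)
  }
  if (u <= 0) return(0)
  lo <- 0; hi <- -uniaxial_cauchy_stress(spec$femoral$material, 0.2)
  hi <- min(hi, -uniaxial_cauchy_stress(spec$tibial$material, 0.2)) * 0.999
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    tot <- comp(spec$femoral, mid) + comp(spec$tibial, mid)
    if (tot < u) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exact energy stored in a piecewise-linear force-indentation curve up to
# indentation d (mm); returns J (N mm / 1000)
curve_energy <- function(curve, d) {
  if (d <= 0) return(0)
  g <- curve$indentations; f <- curve$forces
  knots <- g[g < d]
  xs <- c(knots, d)
  fs <- c(f[seq_along(knots)], eval_curve(curve, d))
  sum(diff(xs) * (fs[-1] + fs[-length(fs)]) / 2) / 1000
}

# total elastic potential energy (J) of a knee configuration at rest;
# q_si = (x_m, y_m, theta_rad). Independent statics oracle for net_wrench.
knee_energy <- function(model, q_si, curves) {
  el <- 0.03
  x <- q_si[1] * 1000; y <- q_si[2] * 1000; th <- q_si[3]
  ct <- cos(th); st <- sin(th)
  E <- 0
  for (lig in model$ligaments) {
    px <- x + ct * lig$femoral[1] + st * lig$femoral[2]
    py <- y - st * lig$femoral[1] + ct * lig$femoral[2]
    len <- sqrt((lig$tibial[1] - px)^2 + (lig$tibial[2] - py)^2)
    eps <- (len - lig$L0) / lig$L0
    L0m <- lig$L0 / 1000
    if (eps > 0 && eps <= 2 * el) {
      E <- E + lig$k * L0m * eps^3 / (12 * el)
    } else if (eps > 2 * el) {
      E <- E + lig$k * L0m * (2 * el^2 / 3 + ((eps - el)^2 - el^2) / 2)
    }
  }
  cc <- model$condyle_centers
  for (i in 1:2) {
    cy <- y - st * cc[i, 1] + ct * cc[i, 2]
    ind <- model$condyle_radius - cy
    if (ind > 0) E <- E + curve_energy(curves[[i]], ind)
  }
  E
}

# simple stiff test curve for knee unit tests (linear, 500 N/mm)
linear_curve <- function(k = 500, dmax = 2) {
  fi_curve(c(0, dmax), c(0, k * dmax))
}
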