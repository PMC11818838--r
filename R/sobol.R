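# Deterministic unscrambled base-2 Sobol designs and their scaling to the
# two study stages: Yeoh material constants (4-dim) and ligament
# attachment/stiffness perturbations (20-dim).

# Primitive polynomials (encoded as integers, leading and trailing 1 bits
# included) and initial direction numbers m_k for dimensions 2..20, after
# Joe & Kuo's standard table. Dimension 1 is the van der Corput sequence
# (all m_k = 1).
.sobol_poly <- c(3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L,
                 55L, 59L, 61L, 67L, 91L, 97L, 103L, 109L, 115L, 131L)
.sobol_minit <- list(
  c(1L),
  c(1L, 3L),
  c(1L, 3L, 1L),
  c(1L, 1L, 1L),
  c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L),
  c(1L, 1L, 5L, 5L, 17L),
  c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L),
  c(1L, 1L, 5L, 1L, 1L),
  c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L),
  c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L),
  c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L),
  c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L),
  c(1L, 3L, 7L, 11L, 23L, 15L, 103L)
)
.SOBOL_MAXDIM <- 20L
.SOBOL_BITS <- 30L

# Direction numbers v_k (integers scaled by 2^(30 - k)) for one dimension.
.sobol_directions <- function(dim) {
  nb <- .SOBOL_BITS
  v <- integer(nb)
  if (dim == 1L) {
    for (k in seq_len(nb)) v[k] <- bitwShiftL(1L, nb - k)
    return(v)
  }
  poly <- .sobol_poly[dim - 1L]
  m <- .sobol_minit[[dim - 1L]]
  s <- length(m)  # degree of the primitive polynomial
  for (k in seq_len(s)) v[k] <- bitwShiftL(m[k], nb - k)
  # coefficient bits a_1..a_(s-1) of the polynomial, highest power first
  a <- integer(max(s - 1L, 0L))
  if (s > 1L) {
    for (i in seq_len(s - 1L))
      a[i] <- bitwAnd(bitwShiftR(poly, s - i), 1L)
  }
  if (s < nb) {
    for (k in (s + 1L):nb) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1L) {
        for (i in seq_len(s - 1L))
          if (a[i] == 1L) vk <- bitwXor(vk, v[k - i])
      }
      v[k] <- vk
    }
  }
  v
}

#' Unscrambled Sobol design on the unit hypercube
#'
#' Deterministic base-2 Sobol points generated with Joe-Kuo direction
#' numbers and Gray-code ordering. The sequence is unscrambled and includes
#' the origin as its first point, so repeated calls with the same arguments
#' are bit-identical and prefixes of longer designs are themselves valid
#' designs. Power-of-two sizes (64 and 32 in this study) give perfectly
#' balanced one-dimensional stratification.
#'
#' @param dim Number of dimensions (1 to 20).
#' @param n Number of points (1 to 2^30 - 1).
#' @return An object of class `sobol_design`: a list with elements `dim`,
#'   `n` and `samples` (an `n x dim` matrix with entries in `[0, 1)`).
#' @examples
#' d <- sobol_unit(4, 8)
#' d$samples[1:2, ]  # origin, then the all-0.5 point
#' @export
sobol_unit <- function(dim, n) {
  stopifnot(length(dim) == 1L, length(n) == 1L)
  dim <- as.integer(dim); n <- as.integer(n)
  if (is.na(dim) || dim < 1L || dim > .SOBOL_MAXDIM)
    stop("'dim' must be between 1 and ", .SOBOL_MAXDIM, call. = FALSE)
  if (is.na(n) || n < 1L || n >= bitwShiftL(1L, .SOBOL_BITS))
    stop("'n' must be between 1 and 2^30 - 1", call. = FALSE)
  v <- vapply(seq_len(dim), .sobol_directions, integer(.SOBOL_BITS))
  x <- matrix(0L, nrow = n, ncol = dim)
  if (n > 1L) {
    acc <- integer(dim)
    for (i in 2:n) {
      # Antonov-Saleev: XOR with the direction numbers of the rightmost
      # zero bit of i - 2 (0-based index of the previous point)
      j <- i - 2L
      c <- 1L
      while (bitwAnd(j, 1L) == 1L) {
        j <- bitwShiftR(j, 1L)
        c <- c + 1L
      }
      acc <- bitwXor(acc, v[c, ])
      x[i, ] <- acc
    }
  }
  structure(list(dim = dim, n = n, samples = x / 2^.SOBOL_BITS),
            class = "sobol_design")
}

#' @export
print.sobol_design <- function(x, ...) {
  cat(sprintf("Unscrambled Sobol design: %d points in %d dimensions\n",
              x$n, x$dim))
  invisible(x)
}

#' Yeoh constant ranges for healthy and osteoarthritic cartilage
#'
#' Sampling ranges (mean +/- 1 SD of experimental fits) for the four
#' material variables of the contact model: femoral C10, femoral C20,
#' tibial C10 and tibial C20, for healthy and OA-degenerated tissue.
#' The defaults are the study's reference ranges in MPa.
#'
#' @param healthy,oa 4 x 2 numeric matrices (columns `min`, `max`; rows in
#'   the fixed variable order above).
#' @return An object of class `material_ranges`.
#' @export
material_ranges <- function(healthy = NULL, oa = NULL) {
  vars <- c("femoral_C10", "femoral_C20", "tibial_C10", "tibial_C20")
  default_h <- matrix(c(0.6, 2.2,
                        0.0, 7.3,
                        1.2, 2.8,
                        1.8, 7.2), ncol = 2, byrow = TRUE)
  default_oa <- matrix(c(0.4, 2.0,
                         0.3, 4.1,
                         0.3, 1.9,
                         1.8, 3.6), ncol = 2, byrow = TRUE)
  if (is.null(healthy)) healthy <- default_h
  if (is.null(oa)) oa <- default_oa
  check <- function(m, nm) {
    if (!is.matrix(m) || !identical(dim(m), c(4L, 2L)))
      stop("'", nm, "' must be a 4 x 2 matrix", call. = FALSE)
    if (any(m[, 1] > m[, 2]))
      stop("'", nm, "': min must not exceed max", call. = FALSE)
    dimnames(m) <- list(vars, c("min", "max"))
    m
  }
  structure(list(healthy = check(healthy, "healthy"), oa = check(oa, "oa")),
            class = "material_ranges")
}

#' Scale a unit design to Yeoh material parameter sets (stage 1)
#'
#' Affine map `min + u * (max - min)` applied column-wise to a 4-dimensional
#' unit design, with the fixed column order (femoral C10, femoral C20,
#' tibial C10, tibial C20). The same unit design is intended to be scaled
#' to both tissue groups so that healthy and OA samples are paired.
#'
#' @param design A 4-dimensional [sobol_unit()] design.
#' @param ranges A [material_ranges()] object.
#' @param group `"healthy"` or `"oa"`.
#' @return A list of length `design$n`; each element has components
#'   `femoral` and `tibial` ([yeoh_params()] objects). The scaled matrix is
#'   attached as attribute `"matrix"`.
#' @export
scale_stage1 <- function(design, ranges = material_ranges(),
                         group = c("healthy", "oa")) {
  stopifnot(inherits(design, "sobol_design"), inherits(ranges, "material_ranges"))
  group <- match.arg(group)
  if (design$dim != 4L)
    stop("stage-1 design must be 4-dimensional", call. = FALSE)
  r <- ranges[[group]]
  m <- sweep(sweep(design$samples, 2, r[, "max"] - r[, "min"], `*`),
             2, r[, "min"], `+`)
  colnames(m) <- rownames(r)
  out <- lapply(seq_len(nrow(m)), function(i) {
    list(femoral = yeoh_params(m[i, 1], m[i, 2]),
         tibial  = yeoh_params(m[i, 3], m[i, 4]))
  })
  attr(out, "matrix") <- m
  attr(out, "group") <- group
  out
}

.LIGAMENT_NAMES <- c("ACL", "PCL", "MCL", "LCL")

#' Ligament geometry/stiffness perturbation
#'
#' @param offsets Named numeric vector of 16 attachment offsets in mm, in
#'   the fixed nesting order (ACL, PCL, MCL, LCL) x (femoral, tibial
#'   attachment) x (x, y); each in `[-1, 1]`.
#' @param multipliers Numeric vector of 4 stiffness multipliers in
#'   `[0.9, 1.1]`, in ligament order.
#' @return An object of class `ligament_perturbation`.
#' @export
ligament_perturbation <- function(offsets, multipliers) {
  if (length(offsets) != 16L || any(!is.finite(offsets)))
    stop("'offsets' must be 16 finite values", call. = FALSE)
  if (any(offsets < -1 - 1e-12) || any(offsets > 1 + 1e-12))
    stop("attachment offsets must lie in [-1, 1] mm", call. = FALSE)
  if (length(multipliers) != 4L || any(!is.finite(multipliers)))
    stop("'multipliers' must be 4 finite values", call. = FALSE)
  if (any(multipliers < 0.9 - 1e-12) || any(multipliers > 1.1 + 1e-12))
    stop("stiffness multipliers must lie in [0.9, 1.1]", call. = FALSE)
  names(offsets) <- as.vector(t(outer(
    .LIGAMENT_NAMES,
    c("fem_x", "fem_y", "tib_x", "tib_y"), paste, sep = "_")))
  names(multipliers) <- .LIGAMENT_NAMES
  offsets[] <- as.numeric(offsets)
  multipliers[] <- as.numeric(multipliers)
  structure(list(offsets = offsets, multipliers = multipliers),
            class = "ligament_perturbation")
}

#' Scale a unit design to ligament perturbations (stage 2)
#'
#' Columns 1-16 of a 20-dimensional unit design are mapped affinely to
#' attachment offsets in `[-1, +1]` mm, in the fixed nesting order
#' (ACL, PCL, MCL, LCL) x (femoral, tibial) x (x, y); columns 17-20 map to
#' stiffness multipliers in `[0.9, 1.1]`, in ligament order.
#'
#' @param design A 20-dimensional [sobol_unit()] design.
#' @return A list of `design$n` [ligament_perturbation()] objects.
#' @export
scale_stage2 <- function(design) {
  stopifnot(inherits(design, "sobol_design"))
  if (design$dim != 20L)
    stop("stage-2 design must be 20-dimensional", call. = FALSE)
  lapply(seq_len(design$n), function(i) {
    u <- design$samples[i, ]
    ligament_perturbation(offsets = -1 + 2 * u[1:16],
                          multipliers = 0.9 + 0.2 * u[17:20])
  })
}
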