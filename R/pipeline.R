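# End-to-end orchestration of the two studies: the compression stage
# (stage-1 material design -> force-indentation curves -> force summary)
# and the flexion-extension stage (stage-2 ligament variants x stage-1
# curves -> per-variant range and force statistics). Everything is
# deterministic: identical configurations give identical outputs.

#' Study configuration
#'
#' Bundles the printed study constants with the scale factors used for
#' reduced test runs. The defaults reproduce the reference conditions:
#' a 64-sample 4-dimensional material design, a 32-sample 20-dimensional
#' ligament design, 1.00 mm maximum indentation in 20 steps, and the
#' +/-3.5 N m five-step, 16 s, 1 ms load protocol.
#'
#' @param n_stage1 Material samples per group (default 64).
#' @param n_stage2 Ligament-system variants (default 32).
#' @param delta_max Maximum indentation in mm (default 1.00).
#' @param n_delta_steps Indentation steps (default 20).
#' @param M_max Peak external moment magnitude in N m (default 3.5).
#' @param n_moment_steps Moment increments per branch (default 5).
#' @param duration Branch duration in s (default 16).
#' @param dt Integrator step in s (default 0.001).
#' @param ranges A [material_ranges()] object.
#' @param out_dir Output directory for CSV/JSON exports, or `NULL` to
#'   keep results in memory only.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_stage1 = 64L, n_stage2 = 32L,
                         delta_max = 1.00, n_delta_steps = 20L,
                         M_max = 3.5, n_moment_steps = 5L,
                         duration = 16.0, dt = 0.001,
                         ranges = material_ranges(), out_dir = NULL) {
  stopifnot(n_stage1 >= 1L, n_stage2 >= 1L, delta_max > 0,
            n_delta_steps >= 2L, M_max >= 0, n_moment_steps >= 1L,
            duration > 0, dt > 0, inherits(ranges, "material_ranges"))
  structure(list(n_stage1 = as.integer(n_stage1),
                 n_stage2 = as.integer(n_stage2),
                 delta_max = delta_max, n_delta_steps = as.integer(n_delta_steps),
                 M_max = M_max, n_moment_steps = as.integer(n_moment_steps),
                 duration = duration, dt = dt,
                 ranges = ranges, out_dir = out_dir),
            class = "study_config")
}

.reference_pair_spec <- function(mats) {
  contact_pair_spec(femoral = cartilage_layer(2.3, mats$femoral),
                    tibial = cartilage_layer(2.1, mats$tibial))
}

#' Run the compression study
#'
#' Generates the shared stage-1 Sobol design, scales it to the healthy
#' and OA ranges, solves the layered sphere-plane contact model for all
#' `2 * n_stage1` material sets, and summarises the contact forces at the
#' full indentation. With an `out_dir`, writes one curve CSV per sample,
#' a JSON manifest mapping sample index to group and Yeoh parameters, and
#' the summary JSON.
#'
#' @param config A [study_config()] object.
#' @return A list with `design` (the unit design), `samples` (per-group
#'   scaled parameter lists), `curves` (per-group lists of [fi_curve()]),
#'   `forces` (per-group force vectors at `delta_max`) and `summary`
#'   (a [summarize_compression()] result).
#' @export
run_compression_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  design <- sobol_unit(4L, config$n_stage1)
  groups <- c("healthy", "oa")
  samples <- lapply(groups, function(g) scale_stage1(design, config$ranges, g))
  names(samples) <- groups
  curves <- lapply(samples, function(ss)
    lapply(seq_along(ss), function(i) {
      cv <- try(compute_curve(.reference_pair_spec(ss[[i]]),
                              config$delta_max, config$n_delta_steps),
                silent = TRUE)
      if (inherits(cv, "try-error"))
        stop("contact solve failed for sample ", i, ": ",
             attr(cv, "condition")$message, call. = FALSE)
      cv
    }))
  forces <- lapply(curves, function(cs)
    vapply(cs, function(cv) cv$forces[length(cv$forces)], numeric(1)))
  summary <- summarize_compression(forces$healthy, forces$oa)
  out <- list(design = design, samples = samples, curves = curves,
              forces = forces, summary = summary)
  if (!is.null(config$out_dir)) .write_compression(out, config)
  out
}

.write_compression <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (g in names(out$curves)) {
    m <- attr(out$samples[[g]], "matrix")
    for (i in seq_along(out$curves[[g]])) {
      fn <- sprintf("curve_%s_s%03d.csv", g, i)
      write_fi_curve(out$curves[[g]][[i]], file.path(config$out_dir, fn))
      manifest[[length(manifest) + 1L]] <- list(
        sample = i, group = g, file = fn,
        femoral_C10 = m[i, 1], femoral_C20 = m[i, 2],
        tibial_C10 = m[i, 3], tibial_C20 = m[i, 4])
    }
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "curves_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(as.data.frame(out$summary)),
                       file.path(config$out_dir, "compression_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the flexion-extension study
#'
#' Builds `n_stage2` ligament-system variants from the 20-dimensional
#' stage-2 design applied to the nominal knee, simulates each variant
#' against every stage-1 contact curve for both tissue groups (two
#' branches per run: extension and flexion), and returns per-variant
#' summaries plus the AVG row. Runs are independent and deterministic.
#'
#' @param config A [study_config()] object; `n_stage1` and `n_stage2`
#'   control the scale.
#' @param compression Optional result of [run_compression_study()] to
#'   reuse; computed on the fly when `NULL`.
#' @return A list with `records` (one row per branch pair), `variants`
#'   (the per-variant summary table with an `"AVG"` row appended) and
#'   `run_matrix` (the [build_study()] descriptor table).
#' @export
run_flexion_extension_study <- function(config = study_config(),
                                        compression = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(compression)) compression <- run_compression_study(config)
  perts <- scale_stage2(sobol_unit(20L, config$n_stage2))
  base <- default_model()
  models <- lapply(perts, apply_perturbation, model = base)
  run_matrix <- build_study(models, compression$curves$healthy,
                            compression$curves$oa)
  proto_e <- load_protocol("extension", M_max = config$M_max,
                           n_steps = config$n_moment_steps,
                           duration = config$duration, dt = config$dt)
  proto_f <- load_protocol("flexion", M_max = config$M_max,
                           n_steps = config$n_moment_steps,
                           duration = config$duration, dt = config$dt)
  records <- list()
  for (v in seq_along(models)) {
    for (g in c("healthy", "oa")) {
      cvs <- compression$curves[[g]]
      for (s in seq_along(cvs)) {
        cr <- list(cvs[[s]], cvs[[s]])
        e <- run_branch(models[[v]], cr, proto_e)
        f <- run_branch(models[[v]], cr, proto_f)
        records[[length(records) + 1L]] <- data.frame(
          variant = v, group = g, sample = s,
          range_deg = angular_range(e, f),
          theta_ext_deg = e$final_state$q[3],
          theta_flex_deg = f$final_state$q[3],
          ACL_ext_N = e$max_lig_N[["ACL"]],
          ACL_flex_N = f$max_lig_N[["ACL"]],
          PCL_flex_N = f$max_lig_N[["PCL"]],
          MCL_flex_N = f$max_lig_N[["MCL"]],
          LCL_flex_N = f$max_lig_N[["LCL"]],
          max_contact_N = max(e$max_contact_N, f$max_contact_N),
          residual = max(e$plateau$residual, f$plateau$residual))
      }
    }
  }
  records <- do.call(rbind, records)
  variants <- do.call(rbind, lapply(seq_along(models), function(v)
    summarize_variant(records[records$variant == v, ], variant = v)))
  avg <- variants[1, ]
  avg$variant <- NA
  for (cn in setdiff(names(variants), "variant"))
    avg[[cn]] <- mean(variants[[cn]])
  tab <- rbind(variants, avg)
  rownames(tab) <- c(as.character(variants$variant), "AVG")
  out <- list(records = records, variants = tab, run_matrix = run_matrix)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records,
                     file.path(config$out_dir, "flexion_extension_runs.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(id = rownames(tab), tab),
                     file.path(config$out_dir, "variant_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(run_matrix, file.path(config$out_dir, "run_matrix.csv"),
                     row.names = FALSE)
  }
  out
}
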