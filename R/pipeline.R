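#' Pipeline run configuration
#'
#' Bundles every tunable of the per-sample analysis chain with explicit
#' defaults; the configuration is attached to every results bundle so a run
#' is reproducible from (inputs, config, seed).
#'
#' @param n_mil_directions MIL test directions per sample (study default
#'   5000).
#' @param line_spacing MIL test-line spacing, voxels.
#' @param mil_step MIL marching step, voxels.
#' @param seed integer master seed.
#' @param constants a [kabel_constants()] set (or path to a JSON file).
#' @param sensitivity_factors voxel-size degradation factors for
#'   [voxel_sensitivity()].
#' @param ef_seeds ellipsoid-factor seed points (0 skips EF).
#' @param thickness compute Tb.Th./Tb.Sp. (the costliest morphometric step).
#' @param morphometry compute morphometric indices at all (fabric and
#'   elasticity only when `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_mil_directions = 5000, line_spacing = 1,
                       mil_step = 0.5, seed = 1,
                       constants = kabel_constants(),
                       sensitivity_factors = 1:4, ef_seeds = 100,
                       thickness = TRUE, morphometry = TRUE) {
  if (is.character(constants)) constants <- kabel_constants(file = constants)
  structure(list(n_mil_directions = n_mil_directions,
                 line_spacing = line_spacing, mil_step = mil_step,
                 seed = as.integer(seed), constants = constants,
                 sensitivity_factors = sensitivity_factors,
                 ef_seeds = ef_seeds, thickness = thickness,
                 morphometry = morphometry),
            class = "run_config")
}

#' Analyze one sample end-to-end
#'
#' Morphometry, MIL fabric measurement and fabric-elasticity homogenization
#' of a single volume, collected into one flat record.  Any stage error is
#' captured in the record (field `error`) rather than aborting, so cohort
#' runs always complete.
#'
#' @param vol a [binary_volume()].
#' @param cfg a [run_config()].
#' @return A list of class `sample_record`; numeric fields are `NA` for
#'   stages that failed.
#' @export
analyze_sample <- function(vol, cfg = run_config()) {
  stopifnot(inherits(vol, "binary_volume"))
  rec <- list(label = vol$label %||% NA_character_,
              level = vol$level %||% NA_character_,
              region = vol$region %||% NA_character_,
              voxel_size_um = vol$voxel_size_um,
              error = NA_character_)
  num_fields <- c("bv_tv", "bs_tv", "tb_th_um", "tb_sp_um", "conn_d", "ef",
                  "d1", "d2", "d3", "da", "lambda1", "lambda2", "lambda3",
                  "alpha_deg", "beta_deg", "gamma_deg",
                  "E_x", "E_y", "E_z", "G_yz", "G_xz", "G_xy",
                  "E_x_gpa", "E_y_gpa", "E_z_gpa",
                  "G_yz_gpa", "G_xz_gpa", "G_xy_gpa",
                  "nu_yz", "nu_xz", "nu_xy", "nu_zy", "nu_zx", "nu_yx")
  for (f in num_fields) rec[[f]] <- NA_real_
  rec$valid <- NA
  fail <- function(stage, e) {
    msg <- paste0(stage, ": ", conditionMessage(e))
    rec$error <<- if (is.na(rec$error)) msg else paste(rec$error, msg, sep = "; ")
  }
  rec$bv_tv <- bone_volume_fraction(vol)
  if (isTRUE(cfg$morphometry)) tryCatch({
    rec$bs_tv <- bone_surface_density(vol)
    rec$conn_d <- as.numeric(connectivity_density(vol))
    if (isTRUE(cfg$thickness)) {
      rec$tb_th_um <- local_thickness(vol, "foreground")$stats$mean
      rec$tb_sp_um <- local_thickness(vol, "background")$stats$mean
    }
    if (cfg$ef_seeds > 0)
      rec$ef <- ellipsoid_factor(vol, n_seeds = cfg$ef_seeds,
                                 seed = cfg$seed)$stats$mean
  }, error = function(e) fail("morphometry", e))
  fab <- tryCatch(
    measure_fabric(vol, n_directions = cfg$n_mil_directions,
                   line_spacing = cfg$line_spacing, seed = cfg$seed,
                   step = cfg$mil_step),
    error = function(e) { fail("fabric", e); NULL })
  if (!is.null(fab)) {
    tens <- attr(fab, "tensor")
    rec$d1 <- tens$eigenvalues[1]; rec$d2 <- tens$eigenvalues[2]
    rec$d3 <- tens$eigenvalues[3]
    rec$da <- fab$da
    rec$lambda1 <- fab$lambda[1]; rec$lambda2 <- fab$lambda[2]
    rec$lambda3 <- fab$lambda[3]
    rec$alpha_deg <- fab$angles_deg[["alpha"]]
    rec$beta_deg <- fab$angles_deg[["beta"]]
    rec$gamma_deg <- fab$angles_deg[["gamma"]]
    el <- tryCatch(
      suppressWarnings(assemble_stiffness(fab$lambda, rec$bv_tv,
                                          cfg$constants,
                                          eigenvectors = fab$eigenvectors)),
      error = function(e) { fail("homogenization", e); NULL })
    if (!is.null(el)) {
      rec$valid <- el$valid
      if (el$valid) {
        rec$E_x <- el$E[["E_x"]]; rec$E_y <- el$E[["E_y"]]; rec$E_z <- el$E[["E_z"]]
        rec$G_yz <- el$G[["G_yz"]]; rec$G_xz <- el$G[["G_xz"]]; rec$G_xy <- el$G[["G_xy"]]
        rec$E_x_gpa <- el$E_GPa[[1]]; rec$E_y_gpa <- el$E_GPa[[2]]
        rec$E_z_gpa <- el$E_GPa[[3]]
        rec$G_yz_gpa <- el$G_GPa[[1]]; rec$G_xz_gpa <- el$G_GPa[[2]]
        rec$G_xy_gpa <- el$G_GPa[[3]]
        for (nm in names(el$nu)) rec[[nm]] <- el$nu[[nm]]
      } else fail("homogenization",
                  simpleError("stiffness not positive definite"))
    }
  }
  structure(rec, class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat("<sample_record>", if (!is.na(x$label)) x$label else "",
      sprintf(" BV/TV = %.4f, DA = %.3f, gamma = %.1f deg\n",
              x$bv_tv, x$da, x$gamma_deg))
  if (isTRUE(x$valid))
    cat(sprintf("  E (GPa): %.4f %.4f %.4f\n", x$E_x_gpa, x$E_y_gpa, x$E_z_gpa))
  if (!is.na(x$error)) cat("  error:", x$error, "\n")
  invisible(x)
}

#' Run a cohort analysis
#'
#' Analyzes a list of volumes, assembles the per-sample records into a
#' cohort table, and fits the cohort-level models: a power law
#' `y = a * x^b` of each Young's and shear modulus against BV/TV, and the
#' one-parameter surface-fraction model `BS/TV = K * BV/TV * (1 - BV/TV)`.
#'
#' @param volumes list of [binary_volume()] objects (or of
#'   `list(volume = , truth = )` pairs as produced by [make_cohort()]).
#'   Duplicate sample labels are an error.
#' @param cfg a [run_config()].
#' @return A list of class `cohort_result`: `table` (data.frame, one row
#'   per sample), `fits` (named list of [fit_power_law()] objects for
#'   `E_x, E_y, E_z, G_yz, G_xz, G_xy` vs BV/TV, in units of Et),
#'   `surface_fit` ([fit_surface_model()]), `summaries`
#'   (per-column [describe_stats()]), and `config`.
#' @export
run_cohort <- function(volumes, cfg = run_config()) {
  vols <- lapply(volumes, function(v)
    if (inherits(v, "binary_volume")) v else v$volume)
  labels <- vapply(seq_along(vols), function(i)
    vols[[i]]$label %||% sprintf("S%03d", i), character(1))
  if (anyDuplicated(labels))
    stop("duplicate sample ids: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  records <- lapply(vols, analyze_sample, cfg = cfg)
  table <- do.call(rbind, lapply(records, function(r)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)))
  table$label <- labels
  rownames(table) <- labels
  ok <- !is.na(table$E_z) & !is.na(table$bv_tv)
  fits <- NULL
  if (sum(ok) >= 3) {
    fit_cols <- c("E_x", "E_y", "E_z", "G_yz", "G_xz", "G_xy")
    fits <- lapply(setNames(fit_cols, fit_cols), function(cl)
      fit_power_law(table$bv_tv[ok], table[[cl]][ok]))
  } else message("fewer than 3 valid samples: power-law fits skipped")
  sok <- !is.na(table$bs_tv)
  surface_fit <- if (sum(sok) >= 2)
    fit_surface_model(table$bv_tv[sok], table$bs_tv[sok]) else NULL
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  summaries <- lapply(setNames(num_cols, num_cols), function(cl) {
    v <- table[[cl]][is.finite(table[[cl]])]
    if (length(v)) describe_stats(v) else NULL
  })
  structure(list(table = table, fits = fits, surface_fit = surface_fit,
                 summaries = summaries, config = cfg),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>", nrow(x$table), "samples\n")
  if (!is.null(x$summaries$bv_tv))
    cat(sprintf("  BV/TV: mean %.4f, range [%.4f, %.4f]\n",
                x$summaries$bv_tv$mean, x$summaries$bv_tv$min,
                x$summaries$bv_tv$max))
  if (!is.null(x$fits)) {
    cat("  power-law fits vs BV/TV (units of Et):\n")
    for (nm in names(x$fits)) {
      f <- x$fits[[nm]]
      cat(sprintf("    %-5s a = %.4g, b = %.3f, R^2 = %.4f\n",
                  nm, f$a, f$b, f$r_squared))
    }
  }
  if (!is.null(x$surface_fit))
    cat(sprintf("  surface model: K = %.3f (R^2 = %.4f)\n",
                x$surface_fit$K, x$surface_fit$r_squared))
  invisible(x)
}

#' Voxel-size sensitivity of the elastic constants
#'
#' Degrades a volume step-wise to coarser voxel sizes, re-runs the fabric
#' and homogenization chain at each resolution, and reports each modulus
#' normalized to its finest-resolution value — the classic resolution-error
#' estimate for homogenized stiffness.
#'
#' @param vol a [binary_volume()] at the finest resolution.
#' @param factors integer degradation factors (must include the baseline 1;
#'   the coarsest factor must leave >= 16 voxels per axis).
#' @param cfg a [run_config()] (morphometry beyond BV/TV is skipped).
#' @return A data.frame of class `sensitivity_table`: one row per factor
#'   with voxel size, BV/TV, absolute and normalized `E` and `G` values.
#' @export
voxel_sensitivity <- function(vol, factors = 1:4, cfg = run_config()) {
  stopifnot(inherits(vol, "binary_volume"))
  factors <- sort(unique(as.integer(factors)))
  if (factors[1] != 1L) factors <- c(1L, factors)
  if (any(dim(vol$grid) %/% max(factors) < 16L))
    stop("volume too small: factor ", max(factors),
         " leaves fewer than 16 voxels per axis")
  cfg$morphometry <- FALSE
  rows <- lapply(factors, function(f) {
    dv <- degrade_voxel_size(vol, f)
    rec <- analyze_sample(dv, cfg)
    data.frame(factor = f, voxel_size_um = dv$voxel_size_um,
               bv_tv = rec$bv_tv, E_x = rec$E_x, E_y = rec$E_y,
               E_z = rec$E_z, G_yz = rec$G_yz, G_xz = rec$G_xz,
               G_xy = rec$G_xy,
               error = rec$error, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- out[out$factor == 1L, ]
  for (cl in c("E_x", "E_y", "E_z", "G_yz", "G_xz", "G_xy"))
    out[[paste0(cl, "_norm")]] <- out[[cl]] / base[[cl]]
  class(out) <- c("sensitivity_table", "data.frame")
  out
}
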