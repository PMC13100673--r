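# End-to-end study replica on the synthetic phantom: generation ->
# three-model localization -> convergence -> coil optimization +
# controls -> validation simulation -> statistics.

#' Study configuration with protocol defaults
#'
#' Bundles all tunable parameters of the study replica. Defaults follow
#' the mapping protocol: 500 localization pulses scattered within 30 mm
#' and +/- 60 degrees of the reference placement, the 40 V/m / 25%
#' exposure mask, convergence thresholds of 5% NRMSD and 1 mm geodesic
#' distance, a 20 mm / 2 mm / 360 deg / 4 deg search grid, and a
#' 7-placement validation with 50 pulses each at 120%-of-rMT intensity
#' (0.8 of the 150%-rMT localization intensity). Convergence runs at a
#' reduced desk-scale schedule by default (`n_max = 200`, `n_step = 10`,
#' `n_rand = 10`); the full protocol is `n_max = 800`, `n_step = 1`,
#' `n_rand = 100`.
#'
#' @param seed master seed; every stage derives its own sub-seed via
#'   [derive_seed()].
#' @param phantom,protocol,truth,lut,layers,localize,convergence,grid,validation
#'   named lists overriding individual defaults.
#' @return nested list of class `study_config`.
#' @export
study_config <- function(seed = 1, phantom = list(), protocol = list(),
                         truth = list(), lut = list(), layers = list(),
                         localize = list(), convergence = list(),
                         grid = list(), validation = list()) {
  merge_in <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    utils::modifyList(defaults, user)
  }
  structure(list(
    seed = seed,
    phantom = merge_in(list(n_x = 29, n_y = 29, amplitude = 4,
                            thickness = 2.5, extent = c(60, 40),
                            wavelength = 20, scalp_offset = 15,
                            band_halfwidth = 7.5, jitter = 0.15), phantom),
    protocol = merge_in(list(n_pulses = 500, radius = 30, max_angle = 60,
                             intensity = 1, wing = 20,
                             target_field = 100), protocol),
    truth = merge_in(list(model = "magnitude", y0 = 0.02, a = 2, r = 0.1,
                          x0 = 60, noise_sd_log = 0.3), truth),
    lut = merge_in(list(kappa = 0.3, grad_slope = 0.005), lut),
    layers = merge_in(list(midlayer = 0.5, L5 = 0.65, grad_frac = 0.1),
                      layers),
    localize = merge_in(list(e_min = 40, p_min = 0.25,
                             roi_label = "precentral", n_starts = 5),
                        localize),
    convergence = merge_in(list(n_min = 10, n_max = 200, n_step = 10,
                                n_rand = 10, nrmsd_threshold = 0.05,
                                dist_threshold = 1), convergence),
    grid = merge_in(list(radius = 20, spacing = 2, angle_range = 360,
                         angle_step = 4), grid),
    validation = merge_in(list(n_pulses = 50, n_subjects = 8,
                               intensity_factor = 0.8,
                               subject_sd_log = 0.5), validation)),
    class = "study_config")
}

#' Read / write a study configuration as YAML
#' @param config a [study_config()].
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' Geometry inputs of one cortical layer of the phantom
#'
#' Builds the layer surface at the requested normalized depth together
#' with its element frames and, for the effective-field model, the
#' centroids of the two gradient sampling surfaces (10% of the way
#' toward GM and WM) and their per-element separation.
#'
#' @param phantom a [gyral_phantom()].
#' @param depth normalized layer depth.
#' @param grad_frac gradient sampling offset fraction.
#' @return list: `mesh`, `frames`, `cen_shallow`, `cen_deep`,
#'   `separation` (mm).
#' @export
layer_inputs <- function(phantom, depth, grad_frac = 0.1) {
  stack <- phantom$stack
  mesh <- build_layer_surface(stack, depth)
  frames <- element_frames(mesh, stack$gm, stack$wm)
  d <- gradient_sample_depths(depth, grad_frac)
  cs <- element_centroids(build_layer_surface(stack, d[["shallow"]]))
  cd <- element_centroids(build_layer_surface(stack, d[["deep"]]))
  list(mesh = mesh, frames = frames, cen_shallow = cs, cen_deep = cd,
       separation = row_norms(cd - cs))
}

#' Field arrays of a placement list on a layer
#'
#' Evaluates the figure-of-eight primary field of every placement at the
#' layer element centroids (and optionally at the gradient sampling
#' points).
#'
#' @param placements list of [coil_placement()] objects.
#' @param inputs a [layer_inputs()] list.
#' @param wing,scale forwarded to [primary_efield()].
#' @param gradient_points also evaluate at the shallow/deep sampling
#'   surfaces (needed by the neuron model).
#' @return list of field arrays: `layer` and, if requested, `shallow`
#'   and `deep`.
#' @export
compute_fields <- function(placements, inputs, wing = 20, scale = 1,
                           gradient_points = FALSE) {
  at <- function(points)
    field_array(lapply(placements, primary_efield, points = points,
                       wing = wing, scale = scale))
  out <- list(layer = at(inputs$frames$centroid))
  if (gradient_points) {
    out$shallow <- at(inputs$cen_shallow)
    out$deep <- at(inputs$cen_deep)
  }
  out
}

#' Quantity matrix of one model on the phantom
#'
#' Convenience glue: fields plus [quantity_map()] for one model, with
#' the magnitude matrix of the same layer attached as attribute
#' `emag` for the exposure mask.
#'
#' @param model `"magnitude"`, `"cosine"` or `"neuron"`.
#' @param placements list of [coil_placement()] objects.
#' @param inputs a [layer_inputs()] list for the model's layer.
#' @param lut [threshold_lut()] (neuron model).
#' @param wing,scale forwarded to [primary_efield()].
#' @return `n_pulses x m` quantity matrix with attributes `model` and
#'   `emag`.
#' @export
model_quantity <- function(model, placements, inputs, lut = NULL,
                           wing = 20, scale = 1) {
  f <- compute_fields(placements, inputs, wing, scale,
                      gradient_points = (model == "neuron"))
  x <- quantity_map(model, f$layer, inputs$frames, lut = lut,
                    fields_shallow = f$shallow, fields_deep = f$deep,
                    separation = inputs$separation)
  attr(x, "emag") <- magnitude_map(f$layer)
  x
}

#' Run the full synthetic study replica
#'
#' Executes phantom generation, MEP simulation under the configured
#' ground truth, three-model localization, convergence analysis, coil
#' placement optimization with four 10 mm shifted controls, the
#' validation-experiment simulation and its mixed-model statistics.
#' Writes all tables plus a JSON manifest (config hash, seed, headline
#' numbers) when `out_dir` is given. Re-running with the same config is
#' reproducible bit for bit.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed), or `NULL` to
#'   skip writing.
#' @param models models to analyze (default all three).
#' @param run_convergence set `FALSE` to skip the convergence stage.
#' @return list with all stage results (invisibly self-describing).
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      models = c("magnitude", "cosine", "neuron"),
                      run_convergence = TRUE) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name) message("[tmsmap] stage: ", name)
  seed <- config$seed

  stage("phantom")
  phantom <- do.call(gyral_phantom,
                     c(config$phantom, seed = derive_seed(seed, "phantom")))
  true_elem <- phantom_true_element(phantom)
  lay <- list(
    midlayer = layer_inputs(phantom, config$layers$midlayer,
                            config$layers$grad_frac),
    L5 = layer_inputs(phantom, config$layers$L5, config$layers$grad_frac))
  model_layer <- c(magnitude = "midlayer", cosine = "midlayer",
                   neuron = "L5")

  stage("protocol")
  reference <- reference_placement(phantom,
                                   intensity = config$protocol$intensity)
  placements <- sample_coil_placements(
    reference, config$protocol$n_pulses, config$protocol$radius,
    config$protocol$max_angle, seed = derive_seed(seed, "placements"),
    scalp = phantom$scalp)
  scale <- calibrate_primary_scale(
    reference, lay$midlayer$frames$centroid[true_elem, ],
    target = config$protocol$target_field, wing = config$protocol$wing)
  lut <- surrogate_lut(config$lut$kappa, config$lut$grad_slope)

  stage("quantities")
  xq <- list()
  for (m in models)
    xq[[m]] <- model_quantity(m, placements, lay[[model_layer[[m]]]],
                              lut = lut, wing = config$protocol$wing,
                              scale = scale)
  truth <- ground_truth(true_elem, config$truth$model, config$truth$y0,
                        config$truth$a, config$truth$r, config$truth$x0,
                        config$truth$noise_sd_log)
  x_truth <- if (truth$model %in% models) xq[[truth$model]] else
    model_quantity(truth$model, placements,
                   lay[[model_layer[[truth$model]]]], lut = lut,
                   wing = config$protocol$wing, scale = scale)
  meps <- generate_meps(truth, x_truth[, true_elem],
                        seed = derive_seed(seed, "meps"))

  stage("localization")
  loc_cfg <- localize_config(config$localize$e_min, config$localize$p_min,
                             config$localize$roi_label,
                             fit_config(n_starts = config$localize$n_starts,
                                        seed = derive_seed(seed, "fits")))
  labels <- phantom$stack$gm$labels
  maps <- lapply(xq, function(x)
    localize(x, meps, attr(x, "emag"), labels, loc_cfg))

  conv <- NULL
  if (run_convergence) {
    stage("convergence")
    conv <- lapply(models, function(m)
      sequential_maps(xq[[m]], meps, attr(xq[[m]], "emag"), labels,
                      lay[[model_layer[[m]]]]$mesh,
                      n_min = config$convergence$n_min,
                      n_max = min(config$convergence$n_max,
                                  config$protocol$n_pulses),
                      n_step = config$convergence$n_step,
                      n_rand = config$convergence$n_rand,
                      seed = derive_seed(seed, paste0("conv_", m)),
                      config = loc_cfg, reference = maps[[m]]))
    names(conv) <- models
  }

  stage("optimization")
  opt <- list()
  for (m in models) {
    hotspot <- maps[[m]]$hotspot
    inp <- lay[[model_layer[[m]]]]
    center <- project_to_scalp(inp$frames$centroid[hotspot, ],
                               phantom$scalp)
    grid <- make_search_grid(center, config$grid$radius,
                             config$grid$spacing, config$grid$angle_range,
                             config$grid$angle_step, scalp = phantom$scalp)
    objective <- placement_objective(m, hotspot, inp, lut,
                                     wing = config$protocol$wing,
                                     scale = scale)
    opt[[m]] <- optimize_placement(grid, reference, objective)
  }
  controls <- control_placements(opt[["magnitude"]]$best %||%
                                   opt[[models[1]]]$best,
                                 shift = 10, scalp = phantom$scalp)

  stage("validation")
  val_pl <- c(lapply(opt, function(o) o$best), controls)
  val_int <- config$protocol$intensity * config$validation$intensity_factor
  inp_truth <- lay[[model_layer[[truth$model]]]]
  x_by_placement <- vapply(val_pl, function(pl) {
    pl$intensity <- val_int
    quantity_at_element(truth$model, pl, truth$true_element, inp_truth,
                        lut, wing = config$protocol$wing, scale = scale)
  }, 0)
  vtab <- simulate_validation(x_by_placement, truth,
                              n_subjects = config$validation$n_subjects,
                              n_pulses = config$validation$n_pulses,
                              subject_sd_log = config$validation$subject_sd_log,
                              seed = derive_seed(seed, "validation"))
  stage("statistics")
  report <- fit_placement_lmm(vtab)

  res <- list(config = config, phantom = phantom, truth = truth,
              reference = reference, placements = placements,
              scale = scale, lut = lut, quantities = xq, meps = meps,
              maps = maps, convergence = conv, optimization = opt,
              controls = controls, validation = vtab, report = report)
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  invisible(res)
}

#' Field-quantity objective at one element for placement search
#'
#' Returns a function(placement) evaluating the model's quantity at a
#' single element — the objective maximized by [optimize_placement()].
#'
#' @param model `"magnitude"`, `"cosine"` or `"neuron"`.
#' @param element element id (the hotspot).
#' @param inputs [layer_inputs()] of the model's layer.
#' @param lut [threshold_lut()] (neuron model).
#' @param wing,scale forwarded to [primary_efield()].
#' @return function of a [coil_placement()] returning V/m.
#' @export
placement_objective <- function(model, element, inputs, lut = NULL,
                                wing = 20, scale = 1) {
  force(model); force(element); force(inputs); force(lut)
  function(placement)
    quantity_at_element(model, placement, element, inputs, lut, wing, scale)
}

#' Model quantity of one placement at one element
#' @inheritParams placement_objective
#' @param placement a [coil_placement()].
#' @return scalar quantity, V/m.
#' @export
quantity_at_element <- function(model, placement, element, inputs,
                                lut = NULL, wing = 20, scale = 1) {
  cen <- inputs$frames$centroid[element, , drop = FALSE]
  e <- primary_efield(placement, cen, wing = wing, scale = scale)
  mag <- vec_norm(e[1, ])
  if (model == "magnitude") return(mag)
  ax <- inputs$frames$axis[element, ]
  if (model == "cosine") return(abs(sum(e[1, ] * ax)))
  if (mag == 0) return(0)
  es <- primary_efield(placement, inputs$cen_shallow[element, , drop = FALSE],
                       wing = wing, scale = scale)
  ed <- primary_efield(placement, inputs$cen_deep[element, , drop = FALSE],
                       wing = wing, scale = scale)
  grad <- 100 * (vec_norm(ed[1, ]) - vec_norm(es[1, ])) /
    (mag * inputs$separation[element])
  th <- acos(pmin(1, pmax(-1, sum(e[1, ] * ax) / mag))) * 180 / pi
  mag / as.numeric(lut_lookup(lut, th, grad))
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_study_config(res$config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  write_pulse_set(res$placements, res$meps,
                  file.path(out_dir, "pulses.csv"), config_hash = hash)
  write_ply(res$phantom$stack$gm, file.path(out_dir, "gm.ply"))
  write_ply(res$phantom$stack$wm, file.path(out_dir, "wm.ply"))
  write_mesh_labels(res$phantom$stack$gm, file.path(out_dir, "labels.csv"))
  write_lut(res$lut, file.path(out_dir, "lut.csv"))
  model_layer <- c(magnitude = "midlayer", cosine = "midlayer",
                   neuron = "L5")
  for (m in names(res$maps))
    write_r2_map(res$maps[[m]],
                 file.path(out_dir, paste0("r2map_", m, ".csv")),
                 layer = model_layer[[m]], config_hash = hash)
  if (!is.null(res$convergence))
    for (m in names(res$convergence))
      write_traces(res$convergence[[m]],
                   file.path(out_dir, paste0("convergence_", m, ".csv")),
                   config_hash = hash)
  write_csv_with_header(res$validation,
                        file.path(out_dir, "validation.csv"),
                        tmsmap_header(kind = "validation", units = "mV",
                                      config = hash))
  manifest <- list(
    config_hash = hash, seed = res$config$seed,
    true_element = res$truth$true_element,
    hotspots = lapply(res$maps, function(m) m$hotspot),
    peak_r2 = lapply(res$maps, function(m) m$r2[m$hotspot]),
    marginal_means_mv = setNames(as.list(res$report$emm$emm_mv),
                                 res$report$emm$placement),
    lrt = res$report$lrt)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
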