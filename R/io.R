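#' Read a two-layer medium or grid specification from YAML
#'
#' The file mirrors the training-grid field names: a `fixed` block
#' (extra_mua, extra_musp, rho, beta, wavelength, n0) and per-axis entries
#' that are either scalars (a single medium) or vectors (a grid).
#'
#' @param path YAML file
#' @return a `grid_spec`
#' @export
read_grid_config <- function(path) {
  y <- yaml::read_yaml(path)
  fx <- y$fixed %||% list()
  grid_spec(brain_mua = unlist(y$brain_mua),
            brain_musp = unlist(y$brain_musp),
            thickness = unlist(y$thickness),
            Db_brain = if (!is.null(y$Db_brain$from))
              seq(y$Db_brain$from, y$Db_brain$to, length.out = y$Db_brain$steps)
            else unlist(y$Db_brain),
            fraction = if (!is.null(y$fraction$from))
              seq(y$fraction$from, y$fraction$to, length.out = y$fraction$steps)
            else unlist(y$fraction),
            extra_mua = fx$extra_mua %||% 0.019,
            extra_musp = fx$extra_musp %||% 0.86,
            rho = fx$rho %||% 35, beta = fx$beta %||% 0.5,
            wavelength = fx$wavelength %||% 785, n0 = fx$n0 %||% 1.4)
}

#' Read a layered head model from YAML
#'
#' Expects a `layers` list (name, thickness, mua, musp, Db; thickness
#' `.inf` or missing for the last layer) plus optional `g_anisotropy`,
#' `n_tissue`, `wavelength`.
#'
#' @param path YAML file
#' @return a `head_model`
#' @export
read_head_config <- function(path) {
  y <- yaml::read_yaml(path)
  lay <- do.call(rbind, lapply(y$layers, function(l)
    data.frame(name = l$name,
               thickness = if (is.null(l$thickness)) Inf else l$thickness,
               mua = l$mua, musp = l$musp, Db = l$Db,
               stringsAsFactors = FALSE)))
  head_model(lay, g_anisotropy = y$g_anisotropy %||% 0.89,
             n_tissue = y$n_tissue %||% 1.4,
             wavelength = y$wavelength %||% 785)
}

#' Write / read ACF frame stacks as delimited text
#'
#' Header `frame_id, tau_<lag in us>...`, one frame per row.
#'
#' @param stack a `frame_stack`
#' @param path CSV file
#' @return `read_frames` returns a `frame_stack`
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  df <- data.frame(frame_id = seq_len(nrow(stack$frames)), stack$frames)
  names(df) <- c("frame_id", sprintf("tau_%.2fus", stack$lags * 1e6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lag_cols <- grep("^tau_", names(df), value = TRUE)
  lags <- as.numeric(sub("us$", "", sub("^tau_", "", lag_cols))) * 1e-6
  frame_stack(as.matrix(df[, lag_cols]), lags = lags)
}

#' Write / read a per-lag noise profile as two-column delimited text
#'
#' @param profile a `sigma_profile`
#' @param path CSV file
#' @return `read_sigma_profile` returns a `sigma_profile`
#' @export
write_sigma_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sigma_profile"))
  utils::write.csv(data.frame(tau_s = profile$lags, sigma = profile$sigma),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sigma_profile
#' @export
read_sigma_profile <- function(path, level_tag = "file") {
  df <- utils::read.csv(path)
  sigma_profile(df$tau_s, df$sigma, level_tag = level_tag)
}

#' Save / load a trained regressor (JSON archive)
#'
#' Stores weights, configuration and data manifest in one JSON file;
#' loading refuses a model whose lag grid length differs from its input
#' size.
#'
#' @param model a `dcs_regressor`
#' @param path file path
#' @return `load_regressor` returns the `dcs_regressor`
#' @export
save_regressor <- function(model, path) {
  stopifnot(inherits(model, "dcs_regressor"))
  obj <- list(format_version = 1L,
              config = unclass(model$config),
              weights = lapply(model$weights, function(w)
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = length(w), data = as.numeric(w))),
              trained = model$trained,
              feature_center = model$feature_center,
              feature_scale = model$feature_scale,
              loss_history = model$loss_history,
              data_manifest = model$data_manifest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(regressor_config,
                 obj$config[setdiff(names(obj$config), c("loss", "optimizer"))])
  weights <- lapply(seq_len(nrow(obj$weights)), function(i) {
    d <- obj$weights$dim[[i]]; x <- obj$weights$data[[i]]
    if (length(d) == 2) matrix(x, d[1], d[2]) else as.numeric(x)
  })
  manifest <- obj$data_manifest
  if (!is.null(manifest$lags) && length(manifest$lags) != cfg$input_size)
    stop("lag-grid mismatch: stored grid length differs from model input size")
  structure(list(weights = weights, config = cfg,
                 parameter_count = count_parameters(cfg),
                 trained = isTRUE(obj$trained),
                 feature_center = obj$feature_center,
                 feature_scale = obj$feature_scale,
                 loss_history = obj$loss_history,
                 data_manifest = manifest),
            class = "dcs_regressor")
}
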