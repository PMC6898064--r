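#' Shuffled train/validation/test split
#'
#' Partitions `1:n_total` by shuffling with the given seed and cutting at
#' `round(f_train * n_total)` and `round(f_val * n_total)`; the remainder is
#' the test set. With the corpus size 90,941 and fractions 0.8/0.1/0.1 this
#' yields 72,753 / 9,094 / 9,094.
#'
#' @param n_total Corpus size (>= 3).
#' @param fractions Length-3 fractions summing to 1 (train, validation,
#'   test).
#' @param seed Shuffle seed.
#' @return List of disjoint, exhaustive integer index vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(n_total, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (n_total < 3) stop("need at least 3 samples to split")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  n_train <- round(fractions[1] * n_total)
  n_val <- round(fractions[2] * n_total)
  if (n_train + n_val > n_total)
    stop("rounded train + validation sizes exceed the corpus")
  perm <- withr::with_seed(seed, sample.int(n_total))
  list(train = perm[seq_len(n_train)],
       validation = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1):n_total])
}

# deformed control-point matrix (3 leaflets stacked) from texture + u arrays
.stack_deformed <- function(ref, u) {
  do.call(rbind, lapply(1:3, function(l)
    .ctrl_mat(ref[l, , , ] + u[l, , , ])))
}

#' Evaluate a trained model on a dataset split
#'
#' Computes per-valve shape metrics between predicted and simulated deformed
#' configurations (Euclidean and Procrustes on the matched control points;
#' Hausdorff between sampled surfaces), their corpus-level max/mean/median,
#' and the coaptation RMSE and Pearson correlation.
#'
#' @param model A trained `valve_cae`.
#' @param dataset A `valve_dataset`.
#' @param idx Indices of the split to evaluate.
#' @param metrics Subset of `c("euclidean", "hausdorff", "procrustes")`.
#' @param hausdorff_grid Per-leaflet surface sampling grid for the Hausdorff
#'   metric; the default `c(20, 20)` keeps corpus-level evaluation cheap
#'   (use [hausdorff_distance()] with its denser default for single pairs).
#' @param csv Optional path; per-valve metrics are written there as CSV.
#' @return Object of class `metrics_report`: `per_valve` data.frame,
#'   `aggregates` (max/mean/median per metric), `coaptation`
#'   (`rmse`, `r`), and `n`.
#' @export
evaluate_run <- function(model, dataset, idx,
                         metrics = c("euclidean", "hausdorff", "procrustes"),
                         hausdorff_grid = c(20, 20), csv = NULL) {
  if (length(idx) < 1) stop("empty split")
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!all(model$config$grid == dataset$meta$grid))
    stop("model and dataset grids differ")
  pr <- predict_dataset(model, dataset, idx)
  template <- dataset$meta$template
  per <- data.frame(sample = idx)
  eu <- ha <- pc <- rep(NA_real_, length(idx))
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    ref <- dataset$inputs$reference[i, , , , ]
    utru <- dataset$targets$displacement[i, , , , ]
    upred <- pr$displacement[ii, , , , ]
    ptru <- .stack_deformed(ref, utru)
    ppred <- .stack_deformed(ref, upred)
    if ("euclidean" %in% metrics) eu[ii] <- mean_euclidean(ppred, ptru)
    if ("procrustes" %in% metrics) pc[ii] <- procrustes_distance(ppred, ptru)
    if ("hausdorff" %in% metrics) {
      spts <- function(uarr) do.call(rbind, lapply(1:3, function(l) {
        s <- from_texture(ref[l, , , ] + uarr[l, , , ], template)
        gb <- .grid_basis(s, hausdorff_grid, midpoint = FALSE)
        gb$R %*% .ctrl_mat(s$control)
      }))
      ha[ii] <- .hausdorff_points(spts(upred), spts(utru))
    }
  }
  if ("euclidean" %in% metrics) per$euclidean <- eu
  if ("hausdorff" %in% metrics) per$hausdorff <- ha
  if ("procrustes" %in% metrics) per$procrustes <- pc
  per$coaptation_pred <- pr$coaptation
  per$coaptation_true <- dataset$targets$coaptation[idx]
  agg <- lapply(intersect(c("euclidean", "hausdorff", "procrustes"),
                          names(per)), function(mn)
    c(max = max(per[[mn]]), mean = mean(per[[mn]]),
      median = stats::median(per[[mn]])))
  names(agg) <- intersect(c("euclidean", "hausdorff", "procrustes"),
                          names(per))
  cs <- coaptation_stats(per$coaptation_pred, per$coaptation_true)
  if (!is.null(csv)) utils::write.csv(per, csv, row.names = FALSE)
  structure(list(per_valve = per, aggregates = agg, coaptation = cs,
                 n = length(idx)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d valves\n", x$n))
  for (mn in names(x$aggregates)) {
    a <- x$aggregates[[mn]]
    cat(sprintf("  %-10s max %.4f  mean %.4f  median %.4f cm\n",
                mn, a["max"], a["mean"], a["median"]))
  }
  cat(sprintf("  coaptation RMSE %.4f cm^2, R = %.4f\n",
              x$coaptation$rmse, x$coaptation$r))
  invisible(x)
}

.sweep_params <- c("pressure", "c0", "c1", "c2", "thickness",
                   "belly", "free_edge", "free_edge_height", "diameter",
                   "commissure_height")

# model inputs for one (params, material, pressure) configuration
.config_inputs <- function(params, material, pressure, grid, degree) {
  valve <- build_valve(params, grid, degree)
  tex <- array(NA_real_, c(1, 3, grid[1], grid[2], 3))
  for (k in 1:3) tex[1, k, , , ] <- valve$leaflets[[k]]$control
  list(valve = valve, textures = tex,
       material = c(material$c0, material$c1, material$c2,
                    material$thickness),
       pressure = pressure)
}

#' Dense one-parameter sweep of predicted coaptation area
#'
#' Varies a single input -- pressure, a material coefficient, the thickness,
#' or a valve design parameter (design parameters regenerate the geometry)
#' -- over a range, holding everything else at the base configuration, and
#' predicts the coaptation area along the sweep. Optionally runs the closure
#' simulator (noiseless) at random spot values and reports whether each
#' simulated area falls within the +/-10% band around the prediction.
#'
#' @param model A trained `valve_cae`.
#' @param base List with `params` ([valve_params()]), `material`
#'   ([material_properties()]), `pressure` (mmHg).
#' @param param One of `r toString(.sweep_params)`.
#' @param range Length-2 numeric range of the swept parameter.
#' @param n Number of sweep points (>= 2, default 1000).
#' @param spot_checks Number of random simulated spot checks (default 0).
#' @param band Relative half-width of the agreement band (default 0.1).
#' @param seed Seed of the spot-check locations.
#' @param degree Surface degrees used when regenerating geometry.
#' @return Object of class `sweep_result`: `curve` (data.frame of `value`,
#'   `coaptation_pred`) and, if requested, `spots` (data.frame of `value`,
#'   `coaptation_pred`, `coaptation_sim`, `in_band`).
#' @export
parameter_sweep <- function(model, base, param, range, n = 1000,
                            spot_checks = 0, band = 0.1, seed = 1,
                            degree = c(3, 3)) {
  if (!param %in% .sweep_params)
    stop("unsupported sweep parameter: ", param)
  if (n < 2) stop("a sweep needs at least 2 points")
  grid <- model$config$grid
  values <- seq(range[1], range[2], length.out = n)
  spot_values <- if (spot_checks > 0)
    withr::with_seed(seed, stats::runif(spot_checks, range[1], range[2]))
  else numeric(0)
  all_values <- c(values, spot_values)

  make_cfg <- function(v) {
    params <- base$params; material <- base$material; pressure <- base$pressure
    if (param == "pressure") pressure <- v
    else if (param %in% c("c0", "c1", "c2")) material[[param]] <- v
    else if (param == "thickness") material$thickness <- v
    else params[[param]] <- v
    list(params = do.call(valve_params, unclass(params)),
         material = do.call(material_properties, unclass(material)),
         pressure = pressure)
  }

  geom_varies <- param %in% c("belly", "free_edge", "free_edge_height",
                              "diameter", "commissure_height")
  N <- length(all_values)
  tex <- array(NA_real_, c(N, 3, grid[1], grid[2], 3))
  mat <- matrix(NA_real_, N, 4)
  pres <- numeric(N)
  base_ci <- NULL
  for (ii in seq_len(N)) {
    cfgi <- make_cfg(all_values[ii])
    if (geom_varies || is.null(base_ci)) {
      ci <- .config_inputs(cfgi$params, cfgi$material, cfgi$pressure,
                           grid, degree)
      if (!geom_varies) base_ci <- ci
    } else {
      ci <- base_ci
      ci$material <- c(cfgi$material$c0, cfgi$material$c1, cfgi$material$c2,
                       cfgi$material$thickness)
      ci$pressure <- cfgi$pressure
    }
    tex[ii, , , , ] <- ci$textures[1, , , , ]
    mat[ii, ] <- ci$material
    pres[ii] <- ci$pressure
  }
  pr <- predict(model, tex, pres, mat)
  out <- list(param = param,
              curve = data.frame(value = values,
                                 coaptation_pred = pr$coaptation[seq_len(n)]))
  if (spot_checks > 0) {
    sim <- vapply(seq_len(spot_checks), function(k) {
      cfgi <- make_cfg(spot_values[k])
      valve <- build_valve(cfgi$params, grid, degree)
      simulate_closure(valve, cfgi$material, cfgi$pressure,
                       noise_seed = NULL)$coaptation_area
    }, 0)
    predv <- pr$coaptation[n + seq_len(spot_checks)]
    out$spots <- data.frame(value = spot_values, coaptation_pred = predv,
                            coaptation_sim = sim,
                            in_band = abs(sim - predv) <= band * abs(predv))
  }
  structure(out, class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over [%g, %g], %d points\n", x$param,
              min(x$curve$value), max(x$curve$value), nrow(x$curve)))
  if (!is.null(x$spots))
    cat(sprintf("  spot checks in band: %d / %d\n",
                sum(x$spots$in_band), nrow(x$spots)))
  invisible(x)
}

#' Embed code vectors with t-SNE
#'
#' Seeded 2D embedding of code-layer activations. Labels (for example design
#' parameters) are attached for colouring only and are not used by the
#' embedding.
#'
#' @param codes Matrix of code vectors (>= 50 rows).
#' @param labels Optional vector/data.frame of per-row labels.
#' @param perplexity,seed,n_iter Passed to [fit_tsne()].
#' @return data.frame with columns `ts1`, `ts2` and any label columns.
#' @export
tsne_embed <- function(codes, labels = NULL, perplexity = 30, seed = 0,
                       n_iter = 500) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 50) stop("need at least 50 code vectors")
  Y <- fit_tsne(codes, perplexity = perplexity, n_iter = n_iter, seed = seed)
  out <- data.frame(ts1 = Y[, 1], ts2 = Y[, 2])
  if (!is.null(labels)) out <- cbind(out, labels)
  out
}

#' @importFrom ggplot2 .data
NULL

#' Diagnostic plots
#'
#' `plot_sweep` draws the predicted coaptation curve with its +/-10% band and
#' any simulated spot checks; `plot_embedding` draws the 2D embedding
#' coloured by a label; `plot_error_histograms` draws the per-valve
#' Euclidean/Hausdorff histograms of a [evaluate_run()] report.
#'
#' @param x A `sweep_result`, embedding data.frame, or `metrics_report`.
#' @param colour Label column used to colour the embedding.
#' @param band Relative band half-width drawn around the sweep curve.
#' @return A ggplot object.
#' @export
plot_sweep <- function(x, band = 0.1) {
  cv <- x$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$value,
                                        y = .data$coaptation_pred)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$coaptation_pred * (1 - band),
      ymax = .data$coaptation_pred * (1 + band)), fill = "grey80") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = x$param, y = "predicted coaptation area (cm^2)")
  if (!is.null(x$spots))
    p <- p + ggplot2::geom_point(
      data = x$spots, ggplot2::aes(y = .data$coaptation_sim),
      colour = "firebrick")
  p
}

#' @rdname plot_sweep
#' @export
plot_embedding <- function(x, colour = NULL) {
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$ts1, y = .data$ts2))
  if (!is.null(colour))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 1)
  else p <- p + ggplot2::geom_point(size = 1)
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}

#' @rdname plot_sweep
#' @export
plot_error_histograms <- function(x) {
  pv <- x$per_valve
  long <- do.call(rbind, lapply(intersect(c("euclidean", "hausdorff"),
                                          names(pv)), function(mn)
    data.frame(metric = mn, value = pv[[mn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "distance (cm)", y = "valves")
}
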