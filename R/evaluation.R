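#' Threshold a tissue probability map into a binary mask
#'
#' Keeps voxels at or above a fraction of the map's maximum, the standard
#' rule for turning segmentation probability maps into binary tissue masks.
#'
#' @param prob Non-negative numeric matrix/array.
#' @param frac Fraction of the maximum (default 0.8, i.e. 80% of max).
#' @return Binary mask of the same shape.
#' @export
#' @examples
#' threshold_probability_map(matrix(c(0.1, 0.5, 0.9, 1.0), 2), 0.8)
threshold_probability_map <- function(prob, frac = 0.8) {
  if (any(prob < 0, na.rm = TRUE)) abort("`prob` must be non-negative.")
  mx <- max(prob, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) abort("`prob` must contain positive values.")
  (prob >= frac * mx) + 0L
}

#' Mean absolute percentage error
#'
#' `100 * mean(|reference - predicted| / reference)`, in percent.
#'
#' @param reference Positive reference values (ms).
#' @param predicted Predicted values, same length.
#' @return Percentage.
#' @export
#' @examples
#' mape(1000, 970) # 3
mape <- function(reference, predicted) {
  reference <- as.numeric(reference); predicted <- as.numeric(predicted)
  if (length(reference) != length(predicted)) abort("lengths differ.")
  if (any(reference <= 0)) abort("`reference` values must be positive.")
  100 * mean(abs(reference - predicted) / reference)
}

#' Intraclass correlation coefficient, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between
#' two paired measurement series (e.g. dictionary matching vs model
#' prediction), computed from the ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2 raters
#' and n subjects.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return ICC in \[-1, 1\].
#' @export
icc_agreement <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("lengths differ.")
  n <- length(x)
  if (n < 3L) abort("need at least 3 pairs.")
  if (sd(x) == 0 && sd(y) == 0 && sd(x - y) == 0) {
    abort("zero variance in both series; ICC undefined.")
  }
  k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)            # rows (subjects)
  msc <- n * sum((col_m - grand)^2) / (k - 1)            # columns (raters)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Bland-Altman agreement analysis
#'
#' For each pair, computes the mean `(x + y) / 2` and the difference
#' `x - y`; summarizes the differences and tests, via Pearson correlation,
#' whether the difference depends on the magnitude (proportional bias).
#' Degenerate inputs (all differences identical, or constant means) yield
#' `NA` correlation with a flag instead of an error.
#'
#' @param x Reference series (e.g. dictionary matching).
#' @param y Predicted series, same length (>= 3).
#' @return List of class `mrf_bland_altman`: tibble `data`
#'   (`mean`, `diff`), `mean_diff`, `diff_sd`, `loa` (95% limits of
#'   agreement), `pearson_r`, `p_value`, `degenerate`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("lengths differ.")
  if (length(x) < 3L) abort("need at least 3 pairs.")
  m <- (x + y) / 2
  d <- x - y
  mean_diff <- mean(d)
  diff_sd <- sd(d)
  degenerate <- diff_sd == 0 || sd(m) == 0
  if (degenerate) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(d, m)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(
    list(data = tibble::tibble(mean = m, diff = d),
         mean_diff = mean_diff, diff_sd = diff_sd,
         loa = mean_diff + c(-1.96, 1.96) * diff_sd,
         pearson_r = r, p_value = p, degenerate = degenerate),
    class = "mrf_bland_altman"
  )
}

#' @export
print.mrf_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<mrf_bland_altman> mean diff %.3g +/- %.3g (LoA %.3g to %.3g), r = %.3g (p = %.3g)\n",
    x$mean_diff, x$diff_sd, x$loa[1], x$loa[2], x$pearson_r, x$p_value
  ))
  invisible(x)
}

#' Evaluate predicted maps against a reference, per tissue
#'
#' For each tissue mask and each parameter (T1, T2*), computes the MAPE over
#' masked voxels plus agreement statistics between the reference and
#' predicted per-voxel values: ICC(A,1), the Bland-Altman mean difference
#' and its SD, and the Pearson correlation (with p-value) of difference
#' against mean.
#'
#' @param reference,predicted `mrf_maps` or `mrf_match` objects (anything
#'   with `t1_map` and `t2s_map`).
#' @param masks Named list of binary `X x Y` matrices (e.g. from
#'   [phantom_masks()] or [threshold_probability_map()]).
#' @param min_voxels Tissues with fewer masked voxels are skipped.
#' @return Object of class `mrf_eval`: tibble with one row per tissue and
#'   parameter: `tissue`, `parameter`, `n_voxels`, `mape_pct`, `icc`,
#'   `mean_ms`, `ref_mean_ms`, `pred_mean_ms`, `mean_diff_ms`, `diff_sd_ms`,
#'   `pearson_r`, `p_value`.
#' @export
evaluate_maps <- function(reference, predicted, masks, min_voxels = 3L) {
  get_map <- function(obj, which) {
    m <- obj[[which]]
    if (is.null(m)) abort("reference/predicted must carry t1_map and t2s_map.")
    m
  }
  rows <- list()
  for (tissue in names(masks)) {
    mask <- masks[[tissue]]
    vox <- which(mask != 0)
    for (param in c("t1", "t2s")) {
      field <- paste0(param, "_map")
      ref <- get_map(reference, field)[vox]
      prd <- get_map(predicted, field)[vox]
      ok <- ref > 0
      ref <- ref[ok]; prd <- prd[ok]
      if (length(ref) < min_voxels) next
      ba <- bland_altman(ref, prd)
      icc <- tryCatch(icc_agreement(ref, prd), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tissue = tissue, parameter = ifelse(param == "t1", "T1", "T2*"),
        n_voxels = length(ref),
        mape_pct = mape(ref, prd),
        icc = icc,
        mean_ms = mean((ref + prd) / 2),
        ref_mean_ms = mean(ref), pred_mean_ms = mean(prd),
        mean_diff_ms = ba$mean_diff, diff_sd_ms = ba$diff_sd,
        pearson_r = ba$pearson_r, p_value = ba$p_value
      )
    }
  }
  if (!length(rows)) abort("no tissue had enough voxels to evaluate.")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mrf_eval", class(out))
  out
}

#' @export
print.mrf_eval <- function(x, ...) {
  cat("<mrf_eval> per-tissue agreement between reference and prediction\n")
  NextMethod()
}

#' Tidy an evaluation report
#' @param x An `mrf_eval`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.mrf_eval <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mrf_eval")
  out
}

#' One-row summary of an evaluation report
#' @param x An `mrf_eval`.
#' @param ... Unused.
#' @return Tibble with overall mean MAPE and worst-tissue MAPE per parameter.
#' @export
glance.mrf_eval <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tidy(x), .data$parameter),
    mean_mape_pct = mean(.data$mape_pct),
    max_mape_pct = max(.data$mape_pct),
    min_icc = min(.data$icc, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Write an evaluation report as CSV
#' @param x An `mrf_eval`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(x, path) {
  utils::write.csv(tidy(x), path, row.names = FALSE)
  invisible(path)
}

# --- plots -------------------------------------------------------------------

#' Bland-Altman plot
#' @param object An `mrf_bland_altman`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrf_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Mean of methods (ms)", y = "Difference (ms)",
                  title = "Bland-Altman agreement")
}

#' Per-tissue MAPE bar chart for an evaluation report
#' @param object An `mrf_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrf_eval <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$tissue, y = .data$mape_pct,
                               fill = .data$parameter)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "MAPE (%)", fill = NULL,
                  title = "Reference vs prediction, per tissue")
}

#' Training-history curves for a trained model
#' @param model An `mrf_denoiser` or `mrf_regressor` with a `history`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  h <- model$history
  if (is.null(h)) abort("model carries no training history.")
  if ("set" %in% names(h)) {
    ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                    colour = .data$set)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "Loss", title = "Training history")
  } else {
    ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "Loss", title = "Training history")
  }
}

#' Parametric-map heatmap
#' @param maps An `mrf_maps` or `mrf_match`.
#' @param which `"t1"` or `"t2s"`.
#' @return A ggplot object.
#' @export
plot_map <- function(maps, which = c("t1", "t2s")) {
  which <- match.arg(which)
  m <- maps[[paste0(which, "_map")]]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$value <- m[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = sprintf("%s (ms)", toupper(gsub("t2s", "T2*", which))),
                  title = NULL)
}
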