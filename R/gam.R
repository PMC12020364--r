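# Cross-validated additive modelling of nEQR.

#' Fit the cross-validated GAM of nEQR on four components
#'
#' Additive model `neqr ~ s(abund_S) + s(abund_N) + s(depth) + s(distance)`
#' with cubic regression spline smooths (basis dimension `gam_knots`,
#' smoothing selected by GCV within each training fold) and k-fold
#' cross-validation.  Every sample is predicted by a model not trained on
#' it; predictions are clipped to the nEQR domain \[0,1\] (raw values kept).
#' Constant components are dropped with a warning.  The hierarchical
#' (site/region) structure of real cohorts is deliberately ignored.
#'
#' @param data data.frame containing `neqr` and the component columns.
#' @param components model components (default the four of the reference
#'   analysis).
#' @param cfg a [run_config()] (folds, knots, seed).
#' @return list of class `neqr_gam`: full-data `model`, `components`,
#'   `folds` assignment, `cv_pred` (clipped), `cv_pred_raw`, `observed`,
#'   `cv_rho` (Spearman), `cv_rmse`.
#' @export
fit_gam_cv <- function(data, components = c("abund_S", "abund_N", "depth",
                                            "distance"),
                       cfg = run_config()) {
  stopifnot("neqr" %in% names(data))
  keep <- !is.na(data$neqr) &
    Reduce(`&`, lapply(components, function(f) !is.na(data[[f]])))
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 50) stop("need >= 50 complete samples for the GAM")
  const <- vapply(components, function(f) var(data[[f]]) == 0, TRUE)
  if (any(const)) {
    warning("dropping constant component(s): ",
            paste(components[const], collapse = ", "))
    components <- components[!const]
  }
  if (!length(components)) stop("all components constant")
  k <- cfg$gam_folds
  form <- stats::as.formula(paste("neqr ~",
                                  paste(sprintf("s(%s, bs = 'cr', k = %d)",
                                                components, cfg$gam_knots),
                                        collapse = " + ")))
  n <- nrow(data)
  folds <- with_seed(cfg$seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    m <- mgcv::gam(form, data = train, method = "GCV.Cp")
    pred[folds == f] <- predict(m, newdata = data[folds == f, , drop = FALSE])
  }
  full <- mgcv::gam(form, data = data, method = "GCV.Cp")
  clipped <- pmin(1, pmax(0, pred))
  structure(list(model = full, components = components, folds = folds,
                 data = data,
                 cv_pred = clipped, cv_pred_raw = pred,
                 observed = data$neqr,
                 cv_rho = cor(clipped, data$neqr, method = "spearman"),
                 cv_rmse = sqrt(mean((clipped - data$neqr)^2))),
            class = "neqr_gam")
}

#' Partial dependence and ICE curves for one model component
#'
#' ICE (individual conditional expectation): for every sample, the model
#' prediction as the chosen component sweeps a grid over its observed range
#' while all other components stay at that sample's values.  The partial
#' dependence curve is the pointwise mean of the ICE curves.
#'
#' @param m a [fit_gam_cv()] result.
#' @param component one of `m$components`.
#' @param grid_size number of grid points.
#' @return list of class `partial_dependence`: `component`, `grid`, `pd`,
#'   `ice` (samples x grid).
#' @export
partial_dependence <- function(m, component, grid_size = 50) {
  if (!component %in% m$components) {
    stop("unknown component: ", component)
  }
  v <- m$data[[component]]
  grid <- seq(min(v), max(v), length.out = grid_size)
  ice <- vapply(grid, function(g) {
    nd <- m$data
    nd[[component]] <- g
    as.numeric(predict(m$model, newdata = nd))
  }, numeric(nrow(m$data)))
  structure(list(component = component, grid = grid,
                 pd = colMeans(ice), ice = ice),
            class = "partial_dependence")
}
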