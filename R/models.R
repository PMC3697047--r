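# Published linear models linking tetranucleotide features to miRNA
# abundance and Argonaute affinity. The numeric coefficients are shipped
# verbatim as published constants (their derivation from the training
# tables was never disclosed and is not plain least squares on the
# printed, 2-decimal feature columns), so no fitting path in this package
# claims to reproduce them.

#' Published model constants
#'
#' @return Named list of the shipped constant linear models: intercept and
#'   named coefficients per model.
#' @export
published_models <- function() {
  list(
    ARABIDOPSIS = list(intercept = 0.78, coefficients = c(wrhw_f1 = 1.31, dryd_f2 = 0.76)),
    AGO2 = list(intercept = 4.97, coefficients = c(rhhk_f3 = 0.52, yrhb_f4 = 1.35)),
    AGO3 = list(intercept = 6.11, coefficients = c(rhhk_f3 = -0.52, yrhb_f4 = 1.35)),
    AGO_DIFF = list(intercept = -1.14, coefficients = c(rhhk_f3 = 1.04, yrhb_f4 = 0)),
    HEK_NORMAL = list(intercept = -2.74, coefficients = c(rhhk_f3 = 1.32, yrhb_f4 = -1.71)),
    HEK_ACTINOMYCIN = list(intercept = -4.56, coefficients = c(rhhk_f3 = 2.20, yrhb_f4 = -1.90))
  )
}

#' Predicted Arabidopsis miRNA ln-abundance
#'
#' The published plant model: `0.78 + 1.31 * wrhw + 0.76 * dryd`, where
#' `wrhw` is the center-weighted WRHW feature and `dryd` the 3'-end-
#' weighted DRYD feature of the 20-nt fragment.
#'
#' @param wrhw,dryd Numeric feature values (non-negative).
#' @return Predicted ln-abundance.
#' @examples
#' predict_arabidopsis(0.97, 2.08)  # 3.6315
#' @export
predict_arabidopsis <- function(wrhw, dryd) {
  stopifnot(is.numeric(wrhw), is.numeric(dryd), all(is.finite(c(wrhw, dryd))))
  0.78 + 1.31 * wrhw + 0.76 * dryd
}

#' Predicted ln-affinities of a miRNA for Ago2 and Ago3
#'
#' The published human model pair:
#' `ago2 = 4.97 + 0.52 * rhhk + 1.35 * yrhb` and
#' `ago3 = 6.11 - 0.52 * rhhk + 1.35 * yrhb`, with `rhhk` the
#' center-weighted RHHK feature (Ago2-vs-Ago3 preference) and `yrhb` the
#' 3'-end-weighted YRHB feature (overall loading) of the 22-nt fragment.
#'
#' @param rhhk,yrhb Numeric feature values.
#' @return data.frame with columns `ago2` and `ago3`.
#' @examples
#' predict_ago(0, 0)  # intercepts 4.97, 6.11
#' @export
predict_ago <- function(rhhk, yrhb) {
  stopifnot(is.numeric(rhhk), is.numeric(yrhb), all(is.finite(c(rhhk, yrhb))))
  data.frame(ago2 = 4.97 + 0.52 * rhhk + 1.35 * yrhb,
             ago3 = 6.11 - 0.52 * rhhk + 1.35 * yrhb)
}

#' Ago2-vs-Ago3 preference of a miRNA
#'
#' The published difference model `1.04 * rhhk - 1.14`, identical to the
#' coefficient-wise difference of the two [predict_ago()] equations
#' (1.04 = 0.52 + 0.52; -1.14 = 4.97 - 6.11; the YRHB terms cancel).
#' Positive values mean Ago2 preference; the indifference point is at
#' `rhhk = 1.14 / 1.04`.
#'
#' @param rhhk Numeric RHHK feature value(s).
#' @return Predicted affinity difference (ln-units).
#' @export
ago_preference <- function(rhhk) {
  stopifnot(is.numeric(rhhk), all(is.finite(rhhk)))
  1.04 * rhhk - 1.14
}

#' Predicted miRNA abundance in HEK293T cells
#'
#' The two condition-specific inverse-problem solutions:
#' normal conditions `-2.74 + 1.32 * rhhk - 1.71 * yrhb`, and after
#' actinomycin D transcription inhibition
#' `-4.56 + 2.20 * rhhk - 1.90 * yrhb`. See [build_condition_model()] for
#' how models of this shape arise from the Ago affinity pair by the
#' availability heuristic plus range calibration.
#'
#' @param rhhk,yrhb Numeric feature values.
#' @param condition `"normal"` or `"actinomycin"`.
#' @return Predicted relative ln-abundance.
#' @export
predict_hek <- function(rhhk, yrhb, condition = c("normal", "actinomycin")) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(rhhk), is.numeric(yrhb), all(is.finite(c(rhhk, yrhb))))
  m <- published_models()[[if (condition == "normal") "HEK_NORMAL" else "HEK_ACTINOMYCIN"]]
  m$intercept + m$coefficients["rhhk_f3"] * rhhk + m$coefficients["yrhb_f4"] * yrhb
}

#' Limiting-stage estimate of miRNA abundance
#'
#' The roughest published approximation: abundance is set by the
#' rate-limiting (smaller) of the two Ago linear forms,
#' `exp(min(0.52*rhhk + 1.35*yrhb, 1.14 - 0.52*rhhk + 1.35*yrhb))`,
#' which equals `exp(min(ago2, ago3) - 4.97)` identically. The two
#' arguments meet at the Ago indifference point `rhhk = 1.14 / 1.04`.
#'
#' @param rhhk,yrhb Numeric feature values.
#' @return Estimated relative abundance (exponential scale).
#' @examples
#' limiting_stage(0, 0)  # 1
#' @export
limiting_stage <- function(rhhk, yrhb) {
  stopifnot(is.numeric(rhhk), is.numeric(yrhb), all(is.finite(c(rhhk, yrhb))))
  exp(pmin(0.52 * rhhk + 1.35 * yrhb, 1.14 - 0.52 * rhhk + 1.35 * yrhb))
}

#' Ordinary least-squares fit of activity on feature columns
#'
#' Generic fitting for user datasets: fits
#' `activity ~ intercept + features` by OLS and reports the Pearson,
#' Spearman and Kendall correlations between fitted and observed
#' activities.
#'
#' @param features Numeric matrix or data.frame of feature columns.
#' @param activity Numeric response, `length > ncol(features) + 1`.
#' @return A `tetra_fit`: list with `intercept`, `coefficients`,
#'   `fitted`, `residuals` and `correlations` (r, rho, tau with alphas).
#' @export
fit_linear <- function(features, activity) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(activity) != n) stop("activity length must match features", call. = FALSE)
  if (n <= ncol(X) + 1L)
    stop("need more observations than features + 1", call. = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    cm <- stats::cor(X)
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stop("collinear features: ", colnames(X)[worst[1]], " and ",
         colnames(X)[worst[2]], call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), activity)
  fitted <- activity - fit$residuals
  corr <- list(
    pearson = cor_test_pearson(fitted, activity),
    spearman = cor_test_spearman(fitted, activity),
    kendall = cor_test_kendall(fitted, activity)
  )
  structure(
    list(intercept = unname(fit$coefficients[1]),
         coefficients = fit$coefficients[-1],
         fitted = fitted, residuals = fit$residuals,
         correlations = corr),
    class = "tetra_fit"
  )
}

#' @export
print.tetra_fit <- function(x, ...) {
  cat("<tetra_fit> intercept ", format(x$intercept, digits = 4), "; ",
      paste(names(x$coefficients),
            format(x$coefficients, digits = 4), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  fitted vs observed: r = %.3f, rho = %.3f, tau = %.3f\n",
              x$correlations$pearson$statistic,
              x$correlations$spearman$statistic,
              x$correlations$kendall$statistic))
  invisible(x)
}
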