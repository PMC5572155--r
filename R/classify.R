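#' Risk dataset
#'
#' Pairs one scalar metric value per drug with its known torsade risk
#' category (1 low, 2 intermediate, 3 high).
#'
#' @param drug character vector of drug names.
#' @param metric numeric metric values (e.g. qNet), one per drug.
#' @param category integer risk categories in \{1, 2, 3\}.
#' @return \code{data.frame} of class \code{"risk_dataset"}.
#' @export
risk_dataset <- function(drug, metric, category) {
  if (length(drug) != length(metric) || length(drug) != length(category))
    stop("drug, metric and category must have equal length", call. = FALSE)
  if (anyNA(metric)) stop("metric values must not be NA", call. = FALSE)
  if (!all(category %in% 1:3))
    stop("categories must be 1, 2 or 3", call. = FALSE)
  structure(data.frame(drug = drug, metric = metric, category = category,
                       stringsAsFactors = FALSE),
            class = c("risk_dataset", "data.frame"))
}

## negative penalized log-likelihood of the cumulative-logit model
## theta = (zeta1, log(zeta2 - zeta1), beta);  P(Y<=k) = plogis(zeta_k - b x)
.polr_nll <- function(theta, x, y, lambda) {
  z1 <- theta[1]
  z2 <- z1 + exp(theta[2])
  b <- theta[3]
  p1 <- stats::plogis(z1 - b * x)
  p2 <- stats::plogis(z2 - b * x)
  p <- cbind(p1, p2 - p1, 1 - p2)
  p <- pmax(p, 1e-12)
  lik <- p[cbind(seq_along(y), y)]
  -sum(log(lik)) + lambda * b^2
}

#' Fit a proportional-odds risk model
#'
#' Maximum-likelihood cumulative-logit (proportional-odds) regression of the
#' 3-level risk category on a single metric, with a small ridge penalty on
#' the slope so that completely separated data (common with 12 drugs and a
#' clean metric ordering) still yield a finite, reproducible fit.
#'
#' @param data a [risk_dataset()].
#' @param lambda ridge penalty on the slope (default 1e-3; 0 disables it).
#' @return Object of class \code{"risk_model"}: list with \code{zeta}
#'   (two cutpoints), \code{beta} (slope), \code{scale} (centering/scaling
#'   applied to the metric before fitting), \code{convergence}.
#' @export
fit_risk_model <- function(data, lambda = 1e-3) {
  stopifnot(inherits(data, "risk_dataset"))
  x <- data$metric
  y <- data$category
  if (length(unique(y)) < 2)
    stop("need at least two distinct categories to fit", call. = FALSE)
  mu <- mean(x)
  sdv <- stats::sd(x)
  if (sdv == 0) sdv <- 1
  xs <- (x - mu) / sdv
  # start from a monotone guess in the direction of the metric/category trend
  b0 <- -sign(stats::cor(xs, y))
  if (b0 == 0) b0 <- 1
  fit <- stats::optim(c(-0.5, log(1), 4 * b0), .polr_nll, x = xs, y = y,
                      lambda = lambda, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  z1 <- fit$par[1]
  z2 <- z1 + exp(fit$par[2])
  structure(list(zeta = c(z1, z2), beta = fit$par[3],
                 scale = c(center = mu, scale = sdv),
                 convergence = fit$convergence, lambda = lambda),
            class = "risk_model")
}

#' Category probabilities and predictions
#'
#' \code{predict_risk_prob} returns the 3-column matrix of category
#' probabilities; \code{predict_risk} the most probable category (ties
#' resolved toward the lower category).
#'
#' @param model a [fit_risk_model()] object.
#' @param metric numeric metric values.
#' @return Probability matrix, or integer vector of categories.
#' @export
predict_risk_prob <- function(model, metric) {
  stopifnot(inherits(model, "risk_model"))
  xs <- (metric - model$scale[["center"]]) / model$scale[["scale"]]
  p1 <- stats::plogis(model$zeta[1] - model$beta * xs)
  p2 <- stats::plogis(model$zeta[2] - model$beta * xs)
  cbind(`1` = p1, `2` = p2 - p1, `3` = 1 - p2)
}

#' @rdname predict_risk_prob
#' @export
predict_risk <- function(model, metric) {
  p <- predict_risk_prob(model, metric)
  apply(p, 1, function(r) which(r >= max(r) - 1e-12)[1])
}

#' Training error of a risk model
#'
#' Mean absolute difference between predicted and known category over the
#' training drugs (0 = perfect; a high/low confusion contributes 2).
#'
#' @param data a [risk_dataset()].
#' @param lambda ridge penalty passed to [fit_risk_model()].
#' @return List with \code{error}, \code{predicted}, \code{model}.
#' @export
risk_training_error <- function(data, lambda = 1e-3) {
  model <- fit_risk_model(data, lambda)
  pred <- predict_risk(model, data$metric)
  list(error = mean(abs(pred - data$category)), predicted = pred,
       model = model)
}

#' Leave-one-out error of a risk model
#'
#' Refits the model leaving out each drug in turn and scores the held-out
#' prediction; the error is the mean absolute category difference.
#'
#' @inheritParams risk_training_error
#' @return List with \code{error} and \code{predicted} (held-out
#'   predictions in the dataset's row order).
#' @export
risk_loo_error <- function(data, lambda = 1e-3) {
  stopifnot(inherits(data, "risk_dataset"))
  n <- nrow(data)
  pred <- integer(n)
  for (i in seq_len(n)) {
    m <- fit_risk_model(risk_dataset(data$drug[-i], data$metric[-i],
                                     data$category[-i]), lambda)
    pred[i] <- predict_risk(m, data$metric[i])
  }
  list(error = mean(abs(pred - data$category)), predicted = pred)
}

#' Risk dataset from a metric panel table
#'
#' Extracts one metric at one dose for every drug of a panel table (after
#' invalid-dose substitution) and joins the known risk categories.
#'
#' @param panel_table output of [metric_panel_table()] (ideally passed
#'   through [substitute_invalid_doses()]).
#' @param drugs named list of [drug_profile()]s carrying risk categories.
#' @param metric metric column name (default \code{"qNet"}).
#' @param dose concentration multiple to extract.
#' @return A [risk_dataset()].
#' @export
risk_dataset_from_panel <- function(panel_table, drugs, metric = "qNet",
                                    dose = 1) {
  rows <- panel_table[panel_table$conc_multiple == dose &
                        panel_table$drug != "control", ]
  if (!nrow(rows)) stop("no rows at dose ", dose, call. = FALSE)
  cat <- vapply(rows$drug, function(d) {
    rc <- drugs[[d]]$risk_category
    if (is.na(rc)) stop("drug without risk category: ", d, call. = FALSE)
    as.integer(rc)
  }, integer(1))
  risk_dataset(rows$drug, rows[[metric]], cat)
}
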