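# DMSO normalization of plate luminescence and four-parameter logistic (4PL)
# IC50 estimation for inhibitor screens.
#
# Model (GraphPad convention, x = log10 concentration):
#   y = bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill))
# For an inhibitor hill < 0: y -> top at vanishing dose and y -> bottom at
# saturating dose; the fitted value at x = log_ic50 is (top + bottom) / 2.

fourpl_value <- function(x, top, bottom, hill, log_ic50) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill))
}

#' Normalize raw plate luminescence to DMSO controls
#'
#' Responses are expressed as a relative percentage of the averaged DMSO
#' control wells: `100 * raw / mean(DMSO)`.
#'
#' @param plate long-format data.frame with columns compound, concentration,
#'   replicate, luminescence.
#' @param control compound label of the control wells (default "DMSO").
#' @return the treated rows with a `response` column (percent of control).
#' @export
normalize_to_control <- function(plate, control = "DMSO") {
  ctrl <- plate$luminescence[plate$compound == control]
  if (!length(ctrl)) stopf("no control ('%s') wells on the plate", control)
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) stopf("control mean luminescence must be positive")
  out <- plate[plate$compound != control, , drop = FALSE]
  out$response <- 100 * out$luminescence / m
  rownames(out) <- NULL
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model over x = log10(concentration).
#' Initialization: top = max response, bottom = min response, log_ic50 =
#' median x, hill = -1; on failure up to three jittered restarts are tried.
#' Parameters are unconstrained (the hill sign is decided by the data).
#'
#' @param data data.frame with columns concentration (strictly positive; the
#'   package treats values as micromolar) and response (percent of control),
#'   replicate rows allowed.
#' @return object of class `fourpl`: coefficients top, bottom, hill,
#'   log_ic50; `ic50` (= 10^log_ic50, same units as the input concentrations);
#'   `rss`; `converged`.
#' @export
fit_4pl <- function(data) {
  if (!all(c("concentration", "response") %in% names(data)))
    stopf("data must have concentration and response columns")
  if (any(data$concentration <= 0)) stopf("concentrations must be strictly positive")
  if (length(unique(data$concentration)) < 4)
    stopf("at least 4 distinct concentrations required")
  x <- log10(data$concentration)
  y <- data$response
  mu <- tapply(y, x, mean)
  if (stats::sd(mu) < 1e-9 * max(1, mean(abs(mu))))
    stopf("no dose dependence in the responses")
  df <- data.frame(x = x, y = y)
  start0 <- list(top = max(mu), bottom = min(mu),
                 log_ic50 = stats::median(x), hill = -1)
  fit <- NULL
  converged <- FALSE
  set_jitter <- function(s, i) {
    if (i == 0) return(s)
    list(top = s$top * (1 + 0.05 * i), bottom = s$bottom - i,
         log_ic50 = s$log_ic50 + 0.3 * (-1)^i * i, hill = -1 - 0.4 * i)
  }
  for (i in 0:3) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + 10^((log_ic50 - x) * hill)),
                        data = df, start = set_jitter(start0, i),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) { converged <- TRUE; break }
  }
  if (is.null(fit)) {
    co <- unlist(start0)
    return(structure(list(coefficients = co, ic50 = 10^co[["log_ic50"]],
                          rss = sum((y - fourpl_value(x, co["top"], co["bottom"],
                                                      co["hill"], co["log_ic50"]))^2),
                          converged = FALSE, data = df, fit = NULL),
                     class = "fourpl"))
  }
  co <- stats::coef(fit)[c("top", "bottom", "hill", "log_ic50")]
  structure(list(coefficients = co, ic50 = unname(10^co["log_ic50"]),
                 rss = sum(stats::residuals(fit)^2), converged = converged,
                 data = df, fit = fit),
            class = "fourpl")
}

#' @export
print.fourpl <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  IC50:   %.4g (10^%.4f)\n", x$ic50, x$coefficients[["log_ic50"]]))
  cat(sprintf("  top:    %.4g   bottom: %.4g   hill: %.4g\n",
              x$coefficients[["top"]], x$coefficients[["bottom"]],
              x$coefficients[["hill"]]))
  cat(sprintf("  RSS:    %.4g   converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
summary.fourpl <- function(object, ...) {
  cat(sprintf("4PL fit on %d points (%d distinct doses)\n", nrow(object$data),
              length(unique(object$data$x))))
  print(object)
  invisible(object)
}

#' Predicted response at given concentrations
#' @param object a `fourpl` fit.
#' @param newdata data.frame with a concentration column (defaults to the
#'   fitted doses).
#' @param ... unused.
#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else log10(newdata$concentration)
  co <- object$coefficients
  fourpl_value(x, co[["top"]], co[["bottom"]], co[["hill"]], co[["log_ic50"]])
}

#' @export
residuals.fourpl <- function(object, ...) {
  object$data$y - predict.fourpl(object)
}

#' Base-graphics dose-response plot with the fitted curve
#' @param x a `fourpl` fit.
#' @param ... passed to `plot()`.
#' @export
plot.fourpl <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "log10 concentration",
       ylab = "response (% of control)", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 200)
  co <- x$coefficients
  graphics::lines(xs, fourpl_value(xs, co[["top"]], co[["bottom"]],
                                   co[["hill"]], co[["log_ic50"]]))
  graphics::abline(v = co[["log_ic50"]], lty = 2)
  invisible(x)
}

#' Simulate responses from a fitted 4PL curve
#' @param object a `fourpl` fit.
#' @param nsim number of simulated response sets.
#' @param seed optional seed.
#' @param sd residual standard deviation (default: estimated from the fit).
#' @param ... unused.
#' @export
simulate.fourpl <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict.fourpl(object)
  s <- sd %||% stats::sd(residuals.fourpl(object))
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, s)))
}

#' Read a long-format plate CSV
#' @param path CSV with columns compound, concentration, replicate,
#'   luminescence.
#' @export
read_plate <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit every compound on a plate
#'
#' Normalizes to the control wells, fits each compound, and returns a Table-3
#' style summary.
#'
#' @param plate long-format plate data.frame (see [read_plate()]).
#' @param control control compound label.
#' @return data.frame with compound, ic50, top, bottom, hill, rss, converged.
#' @export
fit_plate <- function(plate, control = "DMSO") {
  norm <- normalize_to_control(plate, control)
  out <- lapply(split(norm, norm$compound), function(d) {
    f <- fit_4pl(d)
    data.frame(compound = d$compound[1], ic50 = f$ic50,
               top = f$coefficients[["top"]], bottom = f$coefficients[["bottom"]],
               hill = f$coefficients[["hill"]], rss = f$rss,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
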