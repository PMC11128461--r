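# Used-available selection models: the wolf resource selection function
# (RSF) fit to GPS fixes vs availability, and the risky-places (RP) model
# fit to kill sites vs availability.  Both are mixed-effects logistic
# regressions scored on the exponential scale without the intercept.

#' Sample available points within a UD isopleth
#'
#' Uniform random points within the territory defined by the smallest set of
#' cells holding `isopleth` of the UD mass.
#'
#' @param ud a normalized `ud_raster`.
#' @param n number of points.
#' @param isopleth mass fraction defining the territory (0.95).
#' @param seed RNG seed.
#' @return A tibble with `x`, `y`.
#' @export
sample_available <- function(ud, n, isopleth = 0.95, seed = 1L) {
  v <- as.vector(ud$values)
  ord <- order(v, decreasing = TRUE)
  keep <- ord[cumsum(v[ord]) <= isopleth]
  if (length(keep) == 0) keep <- ord[1]
  with_seed(seed, {
    cells <- keep[sample.int(length(keep), n, replace = TRUE)]
    row <- (cells - 1L) %% nrow(ud$values) + 1L
    col <- (cells - 1L) %/% nrow(ud$values) + 1L
    tibble::tibble(
      x = ud$xmin + (col - stats::runif(n)) * ud$cell_x,
      y = ud$ymin + (row - stats::runif(n)) * ud$cell_y
    )
  })
}

penalized_logistic <- function(X, y, ridge = 1e-4) {
  # ridge on slopes only; used when the ordinary fit separates
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta) + ridge * sum(b[-1]^2) / 2
  }
  gr <- function(b) {
    eta <- drop(X %*% b)
    g <- drop(crossprod(X, stats::plogis(eta) - y))
    g[-1] <- g[-1] + ridge * b[-1]
    g
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500))
  stats::setNames(opt$par, colnames(X))
}

#' Fit a used-available selection model
#'
#' Logistic regression of case (used / kill) points against available points
#' with an optional random intercept per grouping unit (pack).  Continuous
#' covariates are standardized internally and the constants stored so new
#' points are scored on the training scale.  Complete separation is flagged
#' and the fit redone with a weak ridge penalty on the slopes.
#'
#' @param data data frame with a 0/1 `used` column and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param group optional name of the grouping column for the random
#'   intercept.
#' @param used name of the case indicator column.
#' @return An object of class `selection_model`.
#' @export
fit_selection <- function(data, covariates, group = NULL, used = "used") {
  y <- data[[used]]
  if (!any(y == 1) || !any(y == 0)) {
    stop("need both case and available points", call. = FALSE)
  }
  std <- standardize_covariates(tibble::as_tibble(data)[covariates])
  X <- cbind(`(Intercept)` = 1, as.matrix(std$data))
  method <- "glm"; group_sd <- NA_real_; separation <- FALSE
  multi_group <- !is.null(group) &&
    length(unique(data[[group]])) >= 2
  if (multi_group) {
    df <- std$data
    df$.used <- y
    df$.group <- factor(data[[group]])
    fml <- stats::as.formula(paste(
      ".used ~", paste(covariates, collapse = " + "), "+ (1 | .group)"))
    fit <- try(suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = df, family = stats::binomial()))), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      coefs <- lme4::fixef(fit)
      group_sd <- sqrt(unname(lme4::VarCorr(fit)$.group[1]))
      method <- "glmer"
    }
  }
  if (method == "glm") {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    coefs <- stats::setNames(fit$coefficients, colnames(X))
  }
  if (any(!is.finite(coefs)) || any(abs(coefs[-1]) > 10)) {
    separation <- TRUE
    coefs <- penalized_logistic(X, y)
    method <- paste0(method, "+ridge")
  }
  structure(list(
    coefficients = coefs, covariates = covariates,
    constants = std$constants, group_sd = group_sd, method = method,
    separation = separation, n_case = sum(y == 1), n_available = sum(y == 0)
  ), class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> %s; %d case / %d available%s\n",
              x$method, x$n_case, x$n_available,
              if (x$separation) " (separation: ridge-penalized)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.selection_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.selection_model <- function(x, ...) {
  tibble::tibble(n_case = x$n_case, n_available = x$n_available,
                 method = x$method, group_sd = x$group_sd,
                 separation = x$separation)
}

#' Score points with a selection model
#'
#' Exponential-form selection score: `exp` of the fixed-effect linear
#' predictor without the intercept, with covariates standardized by the
#' stored training constants.  A point at the training covariate means
#' scores exactly 1.
#'
#' @param model a [fit_selection()] model.
#' @param data data frame containing the model's covariate columns on the
#'   original scale.
#' @return Numeric vector of strictly positive scores.
#' @export
score_selection <- function(model, data) {
  miss <- setdiff(model$covariates, names(data))
  if (length(miss)) {
    stop("missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  z <- apply_standardization(tibble::as_tibble(data)[model$covariates],
                             model$constants)
  slopes <- model$coefficients[model$covariates]
  exp(drop(as.matrix(z) %*% slopes))
}
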