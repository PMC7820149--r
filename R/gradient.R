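#' Fit a metric-on-nutrient regression
#'
#' Ordinary least squares of a web metric on dissolved inorganic nitrogen
#' (DIN) in one of four functional forms: `linear` (y ~ x), `log_log`
#' (log y ~ log x), `log_linear` (y ~ log x), `quadratic` (y ~ x + x^2).
#' Natural logs are used; R-squared, the overall F statistic and its
#' p-value do not depend on the base. The metric is modeled as the
#' response and the nutrient as the predictor; for the single-predictor
#' forms R-squared is symmetric in that choice.
#'
#' @param x predictor vector (DIN, mg/L).
#' @param y response vector (metric values), same length.
#' @param form one of "linear", "log_log", "log_linear", "quadratic".
#' @return object of class `gradient_fit`: list with `form`,
#'   `coefficients`, `r.squared`, `fstatistic`, `df` (numerator,
#'   denominator), `p.value`, `lambda` (Box-Cox exponent if the predictor
#'   was transformed upstream, else `NULL`) and the underlying `lm` fit.
#' @export
fit_regression <- function(x, y, form = c("linear", "log_log",
                                          "log_linear", "quadratic")) {
  form <- match.arg(form)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 sites to fit")
  check_pos <- function(v, who) {
    if (any(v <= 0)) {
      stop("non-positive ", who, " value(s) at position(s) ",
           paste(which(v <= 0), collapse = ", "), " under a log form")
    }
  }
  df <- data.frame(x = x, y = y)
  fml <- switch(form,
    linear = y ~ x,
    log_log = { check_pos(x, "predictor"); check_pos(y, "response"); log(y) ~ log(x) },
    log_linear = { check_pos(x, "predictor"); y ~ log(x) },
    quadratic = y ~ x + I(x^2)
  )
  fit <- stats::lm(fml, data = df)
  s <- summary(fit)
  fs <- s$fstatistic
  p <- stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  structure(list(form = form, coefficients = stats::coef(fit),
                 r.squared = s$r.squared, fstatistic = unname(fs[["value"]]),
                 df = c(fs[["numdf"]], fs[["dendf"]]), p.value = unname(p),
                 lambda = NULL, lm = fit),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("gradient_fit [%s]: R2 = %.3f, F(%d,%d) = %.3f, p = %.4g\n",
              x$form, x$r.squared, x$df[1], x$df[2], x$fstatistic, x$p.value))
  if (!is.null(x$lambda)) cat("  Box-Cox lambda on predictor:", x$lambda, "\n")
  invisible(x)
}

#' Box-Cox power transform with profile-likelihood lambda
#'
#' Transforms a positive vector by `(x^lambda - 1) / lambda` (log at
#' `lambda = 0`). When `lambda` is not supplied it is chosen by
#' maximizing the normal profile log-likelihood
#' `-n/2 log(sigma2_hat(lambda)) + (lambda - 1) sum(log x)` over a grid
#' (default -2 to 2 in steps of 0.05).
#'
#' @param x positive numeric vector.
#' @param lambda optional fixed exponent; skip the grid search.
#' @param grid candidate lambda values for the search.
#' @return list with `transformed` and `lambda`.
#' @export
boxcox_transform <- function(x, lambda = NULL,
                             grid = seq(-2, 2, by = 0.05)) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  bc <- function(x, l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  if (is.null(lambda)) {
    n <- length(x)
    slog <- sum(log(x))
    ll <- vapply(grid, function(l) {
      z <- bc(x, l)
      s2 <- mean((z - mean(z))^2)
      -n / 2 * log(s2) + (l - 1) * slog
    }, numeric(1))
    lambda <- grid[which.max(ll)]
  }
  list(transformed = bc(x, lambda), lambda = lambda)
}

#' Fit a linear regression on Box-Cox-transformed DIN
#'
#' Used for the Keystone Sensitivity Index fits: the predictor is
#' Box-Cox transformed (lambda by profile likelihood) and the response
#' regressed linearly on the result.
#'
#' @inheritParams fit_regression
#' @return a `gradient_fit` with the selected `lambda` recorded.
#' @export
fit_boxcox_linear <- function(x, y) {
  bc <- boxcox_transform(x)
  fit <- fit_regression(bc$transformed, y, "linear")
  fit$form <- "boxcox_linear"
  fit$lambda <- bc$lambda
  fit
}

#' Default metric-to-form regression mapping
#'
#' The functional forms used for the ten web metrics (log-log for TST,
#' respiration and exports; log-linear for indirect flow intensity;
#' quadratic for relative ascendency; linear otherwise) and Box-Cox
#' linear for the five KSI columns.
#'
#' @return named character vector mapping column name to form.
#' @export
default_form_map <- function() {
  c(TST = "log_log", Resp = "log_log", Exports = "log_log",
    NetAgg = "linear", IFI = "log_linear", HmgInput = "linear",
    RelAsc = "quadratic", TSS = "linear", MutFlow = "linear",
    SynFlow = "linear",
    KSI_body_form = "boxcox_linear", KSI_locomotion = "boxcox_linear",
    KSI_respiration_mode = "boxcox_linear", KSI_dispersal = "boxcox_linear",
    KSI_mci = "boxcox_linear")
}

#' Regress web metrics on the nutrient gradient
#'
#' One fit per requested column of a site gradient table. Failures for
#' individual metrics (e.g. a log form on a column with zeros) are
#' recorded in the `error` column and do not abort the remaining fits.
#'
#' @param table data.frame with columns `site`, `DIN` and one column per
#'   metric / KSI.
#' @param forms named character vector mapping column names to forms
#'   ("linear", "log_log", "log_linear", "quadratic", "boxcox_linear");
#'   defaults to [default_form_map()] restricted to the columns present.
#' @return data.frame with one row per metric: metric, form, r2, F, df1,
#'   df2, p, lambda, error. The `fits` attribute keeps the underlying
#'   `gradient_fit` objects.
#' @export
run_gradient_analysis <- function(table, forms = NULL) {
  if (!all(c("site", "DIN") %in% names(table))) {
    stop("gradient table needs 'site' and 'DIN' columns")
  }
  if (is.null(forms)) {
    fm <- default_form_map()
    forms <- fm[names(fm) %in% names(table)]
  }
  rows <- list()
  fits <- list()
  for (metric in names(forms)) {
    form <- forms[[metric]]
    row <- data.frame(metric = metric, form = form, r2 = NA_real_,
                      F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                      p = NA_real_, lambda = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (!metric %in% names(table)) stop("column '", metric, "' not in table")
      y <- table[[metric]]
      if (form == "boxcox_linear") fit_boxcox_linear(table$DIN, y)
      else fit_regression(table$DIN, y, form)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$r2 <- res$r.squared
      row$F <- res$fstatistic
      row$df1 <- res$df[1]; row$df2 <- res$df[2]
      row$p <- res$p.value
      row$lambda <- if (is.null(res$lambda)) NA_real_ else res$lambda
      fits[[metric]] <- res
    }
    rows[[metric]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' The Manawatu 12-site nutrient gradient table
#'
#' Seven-year average dissolved inorganic nitrogen (DIN, mg/L) and
#' dissolved reactive phosphorus (DRP, mg/L), taxonomic richness,
#' connectance and total system throughflow (TST, J/m^2/yr) for the
#' twelve Manawatu river food webs, shipped as a plain-text fixture.
#'
#' @return data.frame with columns site, DIN, DRP, richness, connectance,
#'   TST.
#' @export
manawatu_gradient <- function() {
  path <- system.file("extdata", "manawatu_gradient.csv",
                      package = "riverena", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
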