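#' Declarative mixed-model specification
#'
#' A fitted-model recipe for the inspection responses: response (with its
#' transform), fixed terms, random terms (lme4 syntax), and family. An
#' interaction may appear only when both of its main effects do.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (e.g.
#'   `c("brain_size", "shoal_size", "brain_size:shoal_size")`); may be empty
#'   for an intercept-only model.
#' @param random Character vector of lme4 random-term strings (e.g.
#'   `"(brain_size | replicate)"`); `NULL` for none.
#' @param family `"gaussian"` or `"binomial_logit"`.
#' @param transform Optional transform spec applied to the response before
#'   fitting: a list with `kind` plus arguments for [transform_response()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(), random = NULL,
                       family = c("gaussian", "binomial_logit"), transform = NULL) {
  family <- match.arg(family)
  inter <- grep(":", fixed, value = TRUE)
  for (term in inter) {
    mains <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% fixed)) {
      abort("interaction term present without both main effects", class = "shoalwatch_error")
    }
  }
  structure(list(response = response, fixed = fixed, random = random,
                 family = family, transform = transform),
            class = "model_spec")
}

spec_formula <- function(spec, response_name = ".response") {
  rhs <- c(spec$fixed, spec$random)
  if (length(rhs) == 0) rhs <- "1"
  as.formula(paste(response_name, "~", paste(rhs, collapse = " + ")))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family, ":", deparse(spec_formula(x, x$response)), "\n")
  invisible(x)
}

#' Candidate model set for an inspection response
#'
#' The nested candidate sequence used for term retention, ordered from most
#' to least complex. For the three gaussian inspection responses the
#' candidates are: brain size x shoal size interaction, both mains, brain
#' size only — brain size and the per-replicate random intercept + brain-size
#' slope appear in every candidate. The binary occurrence response has a
#' single specification: treatment fixed effect with random intercepts for
#' replicate and shoal identity.
#'
#' @param response One of `"n_inspections"`, `"mean_duration_s"`,
#'   `"time_per_fish_s"` (gaussian, with their standard transforms) or
#'   `"occurred"` (binomial).
#' @return A list of [model_spec()]s, most complex first.
#' @export
candidate_specs <- function(response) {
  gauss_random <- "(brain_size | replicate)"
  tr <- switch(response,
    n_inspections = list(kind = "log_offset"),
    mean_duration_s = list(kind = "log_offset"),
    time_per_fish_s = list(kind = "power"),
    occurred = NULL,
    abort(paste0("unknown response: ", response), class = "shoalwatch_error")
  )
  if (response == "occurred") {
    return(list(model_spec("occurred", fixed = "treatment",
                           random = c("(1 | replicate)", "(1 | shoal_id)"),
                           family = "binomial_logit")))
  }
  list(
    model_spec(response,
               fixed = c("brain_size", "shoal_size", "brain_size:shoal_size"),
               random = gauss_random, transform = tr),
    model_spec(response, fixed = c("brain_size", "shoal_size"),
               random = gauss_random, transform = tr),
    model_spec(response, fixed = "brain_size",
               random = gauss_random, transform = tr)
  )
}

#' Fit a model specification to the per-trial response table
#'
#' Thin adapter onto the mixed-model engine: gaussian specifications go to
#' `lmerTest::lmer` (Satterthwaite denominator df for the term tests),
#' binomial ones to `lme4::glmer`; specifications without random terms fall
#' back to `lm`/`glm`. The package asserts structural properties of the
#' result only — estimation internals (REML/ML, optimiser, Satterthwaite)
#' are the engine's concern. Non-convergence is surfaced as a warning with
#' the specification attached, never silently ignored.
#'
#' @param spec A [model_spec()].
#' @param table Per-trial response table (one row per trial, the shoal being
#'   the sampling unit) containing the response and all term columns.
#' @param REML Use REML for gaussian fits? Default `FALSE` (ML), so AICs of
#'   different fixed-effect structures are comparable.
#' @return An object of class `inspection_fit`: list with `spec`, `fit`,
#'   `aic`, `converged`, and the engine name.
#' @export
fit_inspection_model <- function(spec, table, REML = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  table <- as.data.frame(table)
  resp <- table[[spec$response]]
  if (is.null(resp)) {
    abort(paste0("response column missing: ", spec$response), class = "shoalwatch_error")
  }
  if (!is.null(spec$transform)) {
    resp <- do.call(transform_response, c(list(values = resp), spec$transform))
  }
  table$.response <- if (spec$family == "binomial_logit") as.numeric(resp) else resp
  fml <- spec_formula(spec)
  has_random <- length(spec$random) > 0
  converged <- TRUE
  fit <- withCallingHandlers(
    {
      if (!has_random) {
        if (spec$family == "gaussian") stats::lm(fml, data = table)
        else stats::glm(fml, data = table, family = stats::binomial())
      } else if (spec$family == "gaussian") {
        lmerTest::lmer(fml, data = table, REML = REML,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
      } else {
        lme4::glmer(fml, data = table, family = stats::binomial(),
                    control = lme4::glmerControl(check.conv.singular = "ignore"))
      }
    },
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        warn(paste0("engine did not converge for ",
                    deparse(spec_formula(spec, spec$response))))
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(list(spec = spec, fit = fit, aic = AIC(fit), converged = converged,
                 engine = class(fit)[1]),
            class = "inspection_fit")
}

#' @export
print.inspection_fit <- function(x, ...) {
  cat("<inspection_fit>", x$engine, "AIC", format(x$aic, digits = 6), "\n")
  print(x$spec)
  invisible(x)
}

#' Term retention by the delta-AIC rule
#'
#' Walks a nested candidate sequence (most to least complex) and keeps a more
#' complex model over the next simpler one only when it improves AIC by more
#' than the threshold (default 2); otherwise the simpler model is taken and
#' the walk continues. Deterministic, and invariant to adding a constant to
#' every AIC.
#'
#' @param fits List of [fit_inspection_model()] results ordered most to least
#'   complex.
#' @param threshold AIC improvement required to retain extra complexity.
#' @return The selected `inspection_fit`.
#' @export
select_by_delta_aic <- function(fits, threshold = 2) {
  if (length(fits) == 0) abort("no fitted candidates", class = "shoalwatch_error")
  current <- fits[[1]]
  for (k in seq_along(fits)[-1]) {
    simpler <- fits[[k]]
    if (simpler$aic - current$aic > threshold) {
      return(current) # the complexity pays for itself
    }
    current <- simpler
  }
  current
}

#' Fit candidates and select a model for one response
#'
#' Convenience wrapper: builds [candidate_specs()], fits each with
#' [fit_inspection_model()], and applies [select_by_delta_aic()]. Model
#' selection per sex is performed by subsetting `table` before the call.
#'
#' @inheritParams fit_inspection_model
#' @param response Response name as in [candidate_specs()].
#' @param threshold Delta-AIC retention threshold.
#' @return The selected `inspection_fit`.
#' @export
select_inspection_model <- function(response, table, threshold = 2, REML = FALSE) {
  specs <- candidate_specs(response)
  fits <- lapply(specs, fit_inspection_model, table = table, REML = REML)
  select_by_delta_aic(fits, threshold = threshold)
}

#' @export
tidy.inspection_fit <- function(x, ...) {
  fit <- x$fit
  if (inherits(fit, "merMod")) {
    cf <- as.data.frame(stats::coef(summary(fit)))
    out <- tibble::tibble(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      std.error = cf[, "Std. Error"],
      statistic = cf[, grep("value", names(cf), value = TRUE)[1]],
      df = if ("df" %in% names(cf)) cf[["df"]] else NA_real_,
      p.value = if ("Pr(>|t|)" %in% names(cf)) cf[["Pr(>|t|)"]]
                else if ("Pr(>|z|)" %in% names(cf)) cf[["Pr(>|z|)"]]
                else NA_real_
    )
  } else {
    cf <- as.data.frame(stats::coef(summary(fit)))
    out <- tibble::tibble(
      term = rownames(cf),
      estimate = cf[, 1], std.error = cf[, 2],
      statistic = cf[, 3], df = NA_real_,
      p.value = if (ncol(cf) >= 4) cf[, 4] else NA_real_
    )
  }
  out
}

#' @export
glance.inspection_fit <- function(x, ...) {
  tibble::tibble(
    aic = x$aic,
    logLik = as.numeric(logLik(x$fit)),
    nobs = stats::nobs(x$fit),
    engine = x$engine,
    converged = x$converged,
    formula = deparse(spec_formula(x$spec, x$spec$response))
  )
}
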