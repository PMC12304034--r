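# Segmented (broken-stick) linear mixed-effects estimation of
# thermoregulatory inflection points.
#
# A physiological response y (metabolic rate, evaporative water loss,
# subcutaneous temperature, ...) measured on repeated individuals across
# air-temperature setpoints is modelled as piecewise linear in Ta with a
# single breakpoint psi shared by the fitted group and a random intercept
# per individual:
#
#   y_ij = a + b_i + beta * Ta_ij + delta * (Ta_ij - psi)_+ + e_ij
#
# The breakpoint is estimated by iterative linearization: at each step the
# working model adds U = (Ta - psi_k)_+ and V = -1{Ta > psi_k}; the fitted
# ratio gamma/delta of the V and U coefficients is the first-order update
# to psi. At convergence gamma ~ 0 and SE(psi) = SE(gamma)/|delta| by the
# delta method. Multi-start over a quantile grid guards against local
# optima.

#' Specify a thermoregulatory mixed model
#'
#' @param response name of the response column.
#' @param fixed character vector of fixed terms among `"ta"`, `"sex"`,
#'   `"mass"` and their pairwise interactions (`"ta:sex"`, `"ta:mass"`,
#'   `"sex:mass"`). `"ta"` is always included; an interaction implies its
#'   main effects (added automatically).
#' @param scope `"pooled"` or `"per_sex"` fitting scope (metadata used by
#'   the pipeline).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response,
                       fixed = c("ta", "sex", "mass", "ta:sex", "ta:mass",
                                 "sex:mass"),
                       scope = c("pooled", "per_sex")) {
  scope <- match.arg(scope)
  allowed <- c("ta", "sex", "mass", "ta:sex", "ta:mass", "sex:mass")
  fixed <- unique(fixed)
  bad <- setdiff(fixed, allowed)
  if (length(bad)) stopf("unknown terms: %s", paste(bad, collapse = ", "))
  # marginality: interactions imply main effects; ta always present
  for (tm in grep(":", fixed, value = TRUE))
    fixed <- union(fixed, strsplit(tm, ":")[[1]])
  fixed <- union("ta", fixed)
  fixed <- allowed[allowed %in% fixed]
  structure(list(response = response, fixed = fixed, scope = scope),
            class = "model_spec")
}

#' @keywords internal
#' @noRd
term_to_var <- function(tm) {
  map <- c(ta = "ta", sex = "sex", mass = "mass_g")
  vapply(strsplit(tm, ":"), function(p) paste(map[p], collapse = ":"),
         character(1))
}

#' @keywords internal
#' @noRd
spec_formula <- function(spec) {
  stats::reformulate(term_to_var(spec$fixed), response = spec$response)
}

#' Fit a linear mixed model with a random intercept per individual
#'
#' Thin wrapper over [nlme::lme()] used throughout the module: fixed
#' effects from a [model_spec()], random intercept for `id`. `"ML"` fits
#' are used for model comparison and term elimination, `"REML"` for
#' reported coefficients. If the mixed fit fails (e.g. the
#' between-individual variance degenerates), the model falls back to
#' ordinary least squares with a warning.
#'
#' @param data data.frame with columns `id`, `ta`, the response and any
#'   further predictors (`sex`, `mass_g`).
#' @param spec a [model_spec()] (or a formula whose response and terms use
#'   the data's column names directly).
#' @param method `"ML"` or `"REML"`.
#' @return object of class `lmm_fit`: list with the underlying `fit`
#'   (`lme` or `lm`), `engine`, `formula`, `method`, `loglik`,
#'   `var_individual`, `var_residual`, `coefficients` (Wald table) and the
#'   model `data`.
#' @export
fit_lmm <- function(data, spec, method = c("REML", "ML")) {
  method <- match.arg(method)
  form <- if (inherits(spec, "model_spec")) spec_formula(spec) else
    stats::as.formula(spec)
  resp <- all.vars(form)[1]
  if (!all(c("id", resp) %in% names(data)))
    stopf("`data` must contain `id` and `%s`", resp)
  if (length(unique(data$id)) < 2)
    stopf("need at least 2 individuals")
  fit <- tryCatch(
    nlme::lme(fixed = form, random = ~ 1 | id, data = data, method = method,
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warnf("mixed fit failed (%s); falling back to ordinary least squares",
          conditionMessage(fit))
    fit <- stats::lm(form, data = data)
  }
  as_lmm_fit(fit, form, method, data)
}

#' @keywords internal
#' @noRd
as_lmm_fit <- function(fit, form, method, data) {
  if (inherits(fit, "lme")) {
    vc <- nlme::VarCorr(fit)
    var_ind <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
    var_res <- fit$sigma^2
    tt <- summary(fit)$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"], df = tt[, "DF"],
                        statistic = tt[, "t-value"],
                        p_value = tt[, "p-value"], row.names = NULL)
    ll <- as.numeric(stats::logLik(fit))
    engine <- "lme"
  } else {
    s <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                        df = fit$df.residual, statistic = s[, 3],
                        p_value = s[, 4], row.names = NULL)
    var_ind <- 0
    var_res <- summary(fit)$sigma^2
    ll <- as.numeric(stats::logLik(fit))
    engine <- "lm"
  }
  structure(list(fit = fit, engine = engine, formula = form, method = method,
                 loglik = ll, var_individual = var_ind,
                 var_residual = var_res, coefficients = coefs, data = data),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s, %s): %s\n", x$engine, x$method,
              deparse(x$formula)))
  cat(sprintf("  logLik %.3f | var(individual) %.4g | var(residual) %.4g\n",
              x$loglik, x$var_individual, x$var_residual))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# One inner working-model fit of the linearized segmented model.
#' @keywords internal
#' @noRd
seg_inner_fit <- function(data, resp, psi, method, with_v = TRUE) {
  d <- data
  d$.U <- pmax(0, d$ta - psi)
  if (with_v) d$.V <- -as.numeric(d$ta > psi)
  rhs <- if (with_v) ".U + .V" else ".U"
  form <- stats::as.formula(paste(resp, "~ ta +", rhs))
  fit <- tryCatch(
    nlme::lme(fixed = form, random = ~ 1 | id, data = d, method = method,
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) e
  )
  fallback <- inherits(fit, "error")
  if (fallback) fit <- stats::lm(form, data = d)
  list(fit = fit, fallback = fallback)
}

#' @keywords internal
#' @noRd
fixef_any <- function(fit) if (inherits(fit, "lme")) nlme::fixef(fit) else
  stats::coef(fit)

#' @keywords internal
#' @noRd
se_any <- function(fit) {
  if (inherits(fit, "lme")) summary(fit)$tTable[, "Std.Error"] else
    summary(fit)$coefficients[, "Std.Error"]
}

#' Fit a segmented linear mixed model
#'
#' Estimates the breakpoint (inflection point) of a piecewise-linear
#' response to air temperature with a random intercept per individual, by
#' iterative linearization (see the module notes above). The update
#' `psi <- psi + gamma/delta` is damped by halving whenever it would leave
#' the observed Ta range; convergence is `|gamma| < tol`. The fit is
#' multi-started from `psi_init` (default: five Ta quantiles, 0.2--0.8) and
#' the converged solution with the best ML log-likelihood (ties: smallest
#' |gamma|) is kept. The 95% CI for psi is the delta-method interval
#' `psi +/- 1.96 SE(gamma)/|delta|`.
#'
#' @param data data.frame with `id`, `ta` and the response column.
#' @param response name of the response column.
#' @param psi_init numeric vector of starting breakpoints (degC), or `NULL`
#'   for the quantile grid.
#' @param psi_bounds length-2 numeric: the interval the breakpoint may lie
#'   in (default the observed Ta range). In a stepped protocol a reported
#'   post-inflection slope needs at least two setpoints above the
#'   breakpoint, so capping the upper bound at the second-highest setpoint
#'   excludes candidates whose "slope change" would rest on a single
#'   temperature level.
#' @param tol convergence tolerance on |gamma| (response units).
#' @param max_iter maximum iterations per start.
#' @param conf_level confidence level for the breakpoint interval.
#' @return object of class `segmented_lmm`: `psi`, `psi_se`, `psi_ci`,
#'   `slope_below`, `slope_above`, `intercept`, `gamma_final`,
#'   `var_individual`, `var_residual`, `loglik` (ML, of the final
#'   `y ~ ta + (ta - psi)_+` model), `n_iter`, `converged`, `flat` (TRUE
#'   when the slope difference collapsed: "no inflection" candidate),
#'   `starts` (per-start summary), `fit_ml`, `fit_reml`, `response`,
#'   `ta_range`.
#' @examples
#' sim <- gen_respirometry(resp_sim_config(
#'   n = c(f = 6), psi = 36, slope_above = 0.05, intercept = 0.05,
#'   residual_sd = 0.005, random_intercept_sd = 0.01, seed = 7))
#' fit_segmented_lmm(sim$points, "value")
#' @export
fit_segmented_lmm <- function(data, response, psi_init = NULL,
                              psi_bounds = NULL, tol = 1e-4,
                              max_iter = 50, conf_level = 0.95) {
  if (!all(c("id", "ta", response) %in% names(data)))
    stopf("`data` must contain id, ta and `%s`", response)
  ta <- data$ta
  if (length(unique(ta)) < 4) stopf("need at least 4 distinct Ta values")
  rng <- range(ta)
  if (!is.null(psi_bounds)) {
    if (length(psi_bounds) != 2 || psi_bounds[1] >= psi_bounds[2])
      stopf("`psi_bounds` must be an increasing length-2 interval")
    rng <- c(max(rng[1], psi_bounds[1]), min(rng[2], psi_bounds[2]))
  }
  if (is.null(psi_init)) {
    # quantile grid plus near-boundary starts: breakpoints hugging the
    # protocol floor/ceiling are otherwise never reached by the updates
    psi_init <- unique(stats::quantile(ta, c(0.05, 0.2, 0.35, 0.5, 0.65,
                                             0.8, 0.95), names = FALSE))
    psi_init <- unique(pmin(pmax(psi_init, rng[1] + 0.02 * diff(rng)),
                            rng[2] - 0.02 * diff(rng)))
  }
  if (any(psi_init <= rng[1] | psi_init >= rng[2]))
    stopf("`psi_init` must lie strictly inside the allowed breakpoint interval")

  tol_psi <- 1e-5 * diff(rng)
  run_start <- function(psi0) {
    psi <- psi0
    gamma <- Inf; b_u <- NA_real_; fit <- NULL; fallback <- FALSE
    prev_step <- NA_real_; damp <- 1; relocated <- FALSE
    d_ta <- sort(unique(ta))
    for (it in seq_len(max_iter)) {
      res <- seg_inner_fit(data, response, psi, "ML")
      fit <- res$fit; fallback <- fallback || res$fallback
      cf <- fixef_any(fit)
      b_u <- unname(cf[".U"]); gamma <- unname(cf[".V"])
      if (is.null(b_u) || !is.finite(b_u) || abs(b_u) < 1e-10)
        return(list(ok = FALSE, flat = TRUE, psi = psi, n_iter = it))
      if (is.null(gamma) || !is.finite(gamma)) {
        # the V working model is rank-deficient when a single distinct Ta
        # lies on one side of psi; relocate the start into the identifiable
        # interior once before giving up
        lo2 <- d_ta[2] + 1e-6 * diff(rng)
        hi2 <- d_ta[length(d_ta) - 1] - 1e-6 * diff(rng)
        if (!relocated && lo2 < hi2 && (psi < lo2 || psi > hi2)) {
          psi <- min(max(psi, lo2), hi2)
          relocated <- TRUE
          next
        }
        return(list(ok = FALSE, flat = FALSE, psi = psi, n_iter = it))
      }
      if (abs(gamma) < tol)
        return(list(ok = TRUE, flat = FALSE, psi = psi, gamma = gamma,
                    b_u = b_u, fit = fit, n_iter = it, fallback = fallback))
      step <- gamma / b_u
      # gamma is discontinuous across observations, so the raw update can
      # cycle between two psi values; damp the step whenever its sign flips
      if (!is.na(prev_step) && sign(step) != sign(prev_step)) damp <- damp / 2
      prev_step <- step
      step <- damp * step
      new_psi <- psi + step
      halvings <- 0
      while ((new_psi <= rng[1] || new_psi >= rng[2]) && halvings < 30) {
        step <- step / 2
        new_psi <- psi + step
        halvings <- halvings + 1
      }
      if (halvings >= 30)
        return(list(ok = FALSE, flat = FALSE, psi = psi, n_iter = it))
      # psi has stabilised: the working model cannot move the breakpoint
      # any further even though the discontinuous gamma is not yet inside
      # the gamma tolerance
      if (abs(step) < tol_psi)
        return(list(ok = TRUE, flat = FALSE, psi = new_psi, gamma = gamma,
                    b_u = b_u, fit = fit, n_iter = it, fallback = fallback))
      psi <- new_psi
    }
    list(ok = FALSE, flat = FALSE, psi = psi, n_iter = max_iter,
         gamma = gamma)
  }

  runs <- lapply(psi_init, run_start)
  ok <- vapply(runs, `[[`, logical(1), "ok")
  starts <- data.frame(
    psi_init = psi_init,
    converged = ok,
    psi = vapply(runs, `[[`, numeric(1), "psi"),
    n_iter = vapply(runs, `[[`, numeric(1), "n_iter")
  )
  if (!any(ok)) {
    if (all(vapply(runs, `[[`, logical(1), "flat")))
      stopf("slope difference collapsed at every start: no inflection detectable")
    stopf("segmented fit did not converge from any start (tried %s)",
          paste(format(psi_init, digits = 3), collapse = ", "))
  }
  # score converged starts by ML loglik of the final y ~ ta + U model
  score <- function(r) {
    fin <- seg_inner_fit(data, response, r$psi, "ML", with_v = FALSE)
    as.numeric(stats::logLik(fin$fit))
  }
  lls <- rep(-Inf, length(runs))
  lls[ok] <- vapply(runs[ok], score, numeric(1))
  gam <- abs(vapply(runs, function(r) if (r$ok) r$gamma else Inf, numeric(1)))
  ses <- rep(Inf, length(runs))
  ses[ok] <- vapply(runs[ok], function(r) {
    s <- unname(se_any(r$fit)[".V"]) / abs(r$b_u)
    if (is.finite(s)) s else Inf
  }, numeric(1))
  # candidates whose likelihood is statistically indistinguishable from the
  # best (within half the 95% chi-squared(1) quantile) are treated as ties;
  # among ties prefer the sharply identified breakpoint (smallest
  # delta-method SE), then the smallest residual |gamma|
  best_ll <- max(lls)
  cand <- which(lls > best_ll - stats::qchisq(0.95, 1) / 2)
  cand <- cand[order(ses[cand], gam[cand])]
  best <- cand[1]
  r <- runs[[best]]

  fin_ml <- seg_inner_fit(data, response, r$psi, "ML", with_v = FALSE)
  fin_reml <- seg_inner_fit(data, response, r$psi, "REML", with_v = FALSE)
  cf <- fixef_any(fin_reml$fit)
  se_gamma <- unname(se_any(r$fit)[".V"])
  psi_se <- se_gamma / abs(r$b_u)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  vc <- if (inherits(fin_reml$fit, "lme")) {
    c(ind = suppressWarnings(as.numeric(
        nlme::VarCorr(fin_reml$fit)["(Intercept)", "Variance"])),
      res = fin_reml$fit$sigma^2)
  } else c(ind = 0, res = summary(fin_reml$fit)$sigma^2)

  structure(list(
    psi = r$psi, psi_se = psi_se,
    psi_ci = c(r$psi - z * psi_se, r$psi + z * psi_se),
    slope_below = unname(cf["ta"]),
    slope_above = unname(cf["ta"] + cf[".U"]),
    intercept = unname(cf["(Intercept)"]),
    gamma_final = r$gamma,
    var_individual = unname(vc["ind"]), var_residual = unname(vc["res"]),
    loglik = as.numeric(stats::logLik(fin_ml$fit)),
    n_iter = r$n_iter, converged = TRUE, flat = FALSE,
    fallback_ols = isTRUE(r$fallback),
    starts = starts, fit_ml = fin_ml$fit, fit_reml = fin_reml$fit,
    response = response, ta_range = rng, conf_level = conf_level
  ), class = "segmented_lmm")
}

#' @export
print.segmented_lmm <- function(x, ...) {
  cat(sprintf("Segmented mixed model for %s\n", x$response))
  cat(sprintf("  breakpoint psi = %.2f degC (%.0f%% CI %.2f-%.2f)\n",
              x$psi, 100 * x$conf_level, x$psi_ci[1], x$psi_ci[2]))
  cat(sprintf("  slope below %.4g, above %.4g (per degC)\n",
              x$slope_below, x$slope_above))
  cat(sprintf("  var(individual) %.4g, var(residual) %.4g; logLik(ML) %.3f\n",
              x$var_individual, x$var_residual, x$loglik))
  cat(sprintf("  converged in %d iteration(s), |gamma| = %.2g\n",
              x$n_iter, abs(x$gamma_final)))
  invisible(x)
}

#' Choose between the linear and segmented model
#'
#' Likelihood-ratio comparison of the ML fits: the segmented model spends
#' two extra parameters (the breakpoint and the slope change), so the
#' statistic is referred to a chi-squared distribution with 2 df. This
#' reference is approximate -- the breakpoint is not a regular parameter --
#' and can be replaced by a parametric bootstrap of the null when exact
#' calibration matters. If the segmented log-likelihood falls below the
#' linear one beyond tolerance (an optimisation failure) the linear model
#' is preferred with a warning.
#'
#' @param linear an ML [fit_lmm()] of `response ~ ta`.
#' @param segmented a [fit_segmented_lmm()] on the same data.
#' @param alpha significance level (default 0.05).
#' @return object of class `model_choice`: `preferred` (`"segmented"` or
#'   `"linear"`), `lrt_stat`, `df`, `p_value`.
#' @export
choose_model <- function(linear, segmented, alpha = 0.05) {
  stopifnot(inherits(linear, "lmm_fit"), inherits(segmented, "segmented_lmm"))
  if (linear$method != "ML")
    stopf("the linear fit must be an ML fit for a likelihood-ratio comparison")
  lrt <- 2 * (segmented$loglik - linear$loglik)
  if (lrt < -1e-6) {
    warnf("segmented log-likelihood below linear (%.3g): optimisation issue; preferring linear",
          lrt)
    lrt <- 0
  }
  lrt <- max(lrt, 0)
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  structure(list(preferred = if (p < alpha) "segmented" else "linear",
                 lrt_stat = lrt, df = 2L, p_value = p, alpha = alpha),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf("Model choice: %s (LRT = %.3f, df = %d, p = %.4g)\n",
              x$preferred, x$lrt_stat, x$df, x$p_value))
  invisible(x)
}

#' Compare two breakpoints by confidence-interval overlap
#'
#' Two group breakpoints are called significantly different when their
#' confidence intervals do not overlap. The signed gap is the distance
#' between the nearer interval endpoints (positive when disjoint).
#'
#' @param fit_a,fit_b converged [fit_segmented_lmm()] objects.
#' @return list with `significant` (logical), `gap` (degC) and the two
#'   intervals.
#' @export
compare_breakpoints <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "segmented_lmm"), inherits(fit_b, "segmented_lmm"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stopf("both fits must have converged")
  gap <- max(fit_a$psi_ci[1], fit_b$psi_ci[1]) -
    min(fit_a$psi_ci[2], fit_b$psi_ci[2])
  list(significant = gap > 0, gap = gap,
       ci_a = fit_a$psi_ci, ci_b = fit_b$psi_ci)
}

#' Backward model reduction by null-hypothesis testing
#'
#' Starting from the global fixed-effects structure, repeatedly drops the
#' currently removable term (one not contained in a retained interaction;
#' `ta` is never dropped) with the largest marginal p-value at or above
#' `alpha`, refitting by ML after each drop. The final model is refitted by
#' REML.
#'
#' @param data data.frame with `id`, `ta`, `sex`, `mass_g` and the
#'   response.
#' @param spec the global [model_spec()].
#' @param alpha retention threshold (default 0.05).
#' @return list with `spec` (final [model_spec()]), `fit` (REML
#'   [fit_lmm()]) and `path` (elimination log: term dropped and its
#'   p-value at each step).
#' @export
reduce_model <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- spec$fixed
  path <- data.frame(step = integer(), dropped = character(),
                     p_value = numeric())
  repeat {
    cur <- model_spec(spec$response, terms, spec$scope)
    fit <- fit_lmm(data, cur, method = "ML")
    inter <- grep(":", terms, value = TRUE)
    in_inter <- unique(unlist(strsplit(inter, ":")))
    removable <- setdiff(terms, c("ta", in_inter))
    removable <- union(removable, inter)
    removable <- setdiff(removable, "ta")
    if (!length(removable)) break
    pv <- term_p_values(fit)
    pv <- pv[names(pv) %in% term_to_var(removable)]
    if (!length(pv) || max(pv, na.rm = TRUE) < alpha) break
    worst_var <- names(pv)[which.max(pv)]
    worst <- terms[term_to_var(terms) == worst_var][1]
    path <- rbind(path, data.frame(step = nrow(path) + 1L, dropped = worst,
                                   p_value = max(pv, na.rm = TRUE)))
    terms <- setdiff(terms, worst)
  }
  final_spec <- model_spec(spec$response, terms, spec$scope)
  list(spec = final_spec,
       fit = fit_lmm(data, final_spec, method = "REML"),
       path = path)
}

# Marginal (type-III-style) per-term p-values of an lmm_fit.
#' @keywords internal
#' @noRd
term_p_values <- function(fit) {
  if (fit$engine == "lme") {
    a <- stats::anova(fit$fit, type = "marginal")
    pv <- a[["p-value"]]
    names(pv) <- rownames(a)
    pv[setdiff(names(pv), "(Intercept)")]
  } else {
    a <- stats::drop1(fit$fit, test = "F")
    pv <- a[["Pr(>F)"]]
    names(pv) <- rownames(a)
    pv[!is.na(pv)]
  }
}

#' Estimated marginal means by group
#'
#' Model-based group means averaged over the reference grid (covariates at
#' their means), with delta-method standard errors from the fixed-effect
#' covariance; computed with the emmeans package.
#'
#' @param fit an [fit_lmm()] result whose model contains the grouping term.
#' @param by name of the grouping variable (default `"sex"`).
#' @return data.frame with the group levels, `emmean`, `se`, `df` and
#'   confidence limits.
#' @export
estimated_marginal_means <- function(fit, by = "sex") {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!by %in% all.vars(fit$formula))
    stopf("term '%s' is not in the fitted model", by)
  em <- emmeans::emmeans(fit$fit, specs = by, data = fit$data)
  out <- as.data.frame(em)
  names(out)[names(out) == "SE"] <- "se"
  out
}
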