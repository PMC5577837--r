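# Count models for bottom-phase prey-encounter events. The response is the
# PEE count with the log prospected volume as an offset, so the linear
# predictor models the encounter density while the likelihood stays a proper
# count distribution. The ladder runs Poisson -> negative binomial ->
# zero-inflated NB; exhaustive AIC selection keeps the best model whose every
# explanatory variable is significant at 5%.

#' Add centred quadratic terms to a metrics table
#'
#' Creates `<col>_sq` columns as the square of the centred covariate
#' (centring before squaring reduces collinearity with the linear term in
#' exhaustive search).
#'
#' @param data a data frame.
#' @param cols character vector of numeric column names.
#' @return `data` with the extra `_sq` columns.
#' @export
add_quadratic <- function(data, cols) {
  for (cl in cols) {
    data[[paste0(cl, "_sq")]] <- (data[[cl]] - mean(data[[cl]], na.rm = TRUE))^2
  }
  data
}

standardize_covariates <- function(data, covs) {
  scaling <- list()
  for (cl in covs) {
    x <- data[[cl]]
    if (is.numeric(x)) {
      mu <- mean(x, na.rm = TRUE)
      s <- sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      data[[cl]] <- (x - mu) / s
      scaling[[cl]] <- c(mean = mu, sd = s)
    }
  }
  list(data = data, scaling = scaling)
}

#' Fit a count model for PEE density with a log-volume offset
#'
#' Maximum-likelihood fit of the PEE count on standardized covariates with a
#' log link and `offset(log(volume))`, under one of four families: `poisson`
#' (stats::glm), `negbin` (MASS::glm.nb), or the zero-inflated variants
#' `zip` / `zinb` (glmmTMB, families poisson / nbinom2 with a logistic
#' zero-inflation part). The zero part models the probability of an excess
#' (structural) zero — i.e. it predicts the *absence* of prey encounters;
#' [tidy()] reports this orientation explicitly in the `part` column.
#'
#' @param data per-dive table with a count column, a volume column and the
#'   covariates. Covariate pairs correlated beyond `max_cor` are rejected
#'   (multicollinearity screen).
#' @param count_covariates character vector of covariates for the count part
#'   (may be empty: intercept-only).
#' @param zero_covariates covariates for the zero-inflation part (`zip`/`zinb`
#'   only; `NULL` or empty gives an intercept-only zero part).
#' @param family one of `"poisson"`, `"negbin"`, `"zip"`, `"zinb"`.
#' @param response,offset_col names of the count and volume columns.
#' @param standardize centre/scale numeric covariates before fitting
#'   (coefficients are then per-SD effects).
#' @param max_cor multicollinearity screen threshold (absolute Pearson r).
#' @return A `pee_fit` object; see [tidy.pee_fit()], [glance.pee_fit()],
#'   [overdispersion()], [vuong_compare()].
#' @export
fit_count_model <- function(data, count_covariates = character(),
                            zero_covariates = NULL,
                            family = c("poisson", "negbin", "zip", "zinb"),
                            response = "pee_count", offset_col = "volume",
                            standardize = TRUE, max_cor = 0.9) {
  family <- match.arg(family)
  covs <- union(count_covariates, zero_covariates %||% character())
  need <- c(response, offset_col, covs)
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  data <- as_tibble(data)[complete.cases(data[, need]), ]
  if (nrow(data) < 20) abort("need at least 20 complete rows")
  num_covs <- covs[vapply(data[covs], is.numeric, logical(1))]
  if (length(num_covs) > 1) {
    cm <- stats::cor(data[num_covs])
    cm[upper.tri(cm, diag = TRUE)] <- 0
    if (any(abs(cm) > max_cor)) {
      bad <- which(abs(cm) > max_cor, arr.ind = TRUE)[1, ]
      abort(sprintf("covariates %s and %s are collinear (|r| > %.2f); drop one",
                    num_covs[bad[2]], num_covs[bad[1]], max_cor))
    }
  }
  scaling <- list()
  if (standardize) {
    st <- standardize_covariates(data, num_covs)
    data <- st$data
    scaling <- st$scaling
  }
  data$.log_offset <- log(data[[offset_col]])
  rhs <- if (length(count_covariates)) paste(count_covariates, collapse = " + ") else "1"
  f_count <- stats::as.formula(
    paste(response, "~", rhs, "+ offset(.log_offset)")
  )
  fit <- switch(family,
    poisson = stats::glm(f_count, family = stats::poisson(), data = data),
    negbin = MASS::glm.nb(f_count, data = data),
    zip = ,
    zinb = {
      zr <- if (length(zero_covariates %||% character())) {
        paste(zero_covariates, collapse = " + ")
      } else "1"
      glmmTMB::glmmTMB(
        f_count, ziformula = stats::as.formula(paste("~", zr)),
        family = if (family == "zip") stats::poisson() else glmmTMB::nbinom2(),
        data = data
      )
    }
  )
  converged <- model_converged(fit, family)
  structure(list(
    fit = fit, family = family, data = data,
    count_covariates = count_covariates,
    zero_covariates = zero_covariates %||% character(),
    response = response, offset_col = offset_col,
    scaling = scaling, converged = converged
  ), class = "pee_fit")
}

model_converged <- function(fit, family) {
  if (family %in% c("poisson", "negbin")) {
    isTRUE(fit$converged)
  } else {
    isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  }
}

#' @export
print.pee_fit <- function(x, ...) {
  cat(sprintf("<pee_fit> family %s; %d rows; AIC %.1f%s\n",
              x$family, nrow(x$data), AIC(x$fit),
              if (x$converged) "" else " (NOT converged)"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a PEE count-model fit
#'
#' One row per coefficient with the model part it belongs to: `"count"`
#' (log-density scale) or `"zero (P excess zero)"` (logistic scale for the
#' probability of a structural zero, i.e. predicting absence of encounters).
#'
#' @param x a `pee_fit`.
#' @param ... unused.
#' @return A tibble `part`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy pee_fit
#' @export
tidy.pee_fit <- function(x, ...) {
  to_tbl <- function(m, part) {
    tibble(part = part, term = rownames(m),
           estimate = m[, 1], std.error = m[, 2],
           statistic = m[, 3], p.value = m[, 4])
  }
  if (x$family %in% c("poisson", "negbin")) {
    to_tbl(summary(x$fit)$coefficients, "count")
  } else {
    sm <- summary(x$fit)$coefficients
    bind_rows(to_tbl(sm$cond, "count"),
              to_tbl(sm$zi, "zero (P excess zero)"))
  }
}

#' Glance at a PEE count-model fit
#'
#' @param x a `pee_fit`.
#' @param ... unused.
#' @return A one-row tibble: family, n, AIC, log-likelihood, overdispersion
#'   theta (NB families), deviance explained (where a null deviance exists)
#'   and pseudo-r2 (squared correlation between observed and predicted PEE
#'   density).
#' @method glance pee_fit
#' @export
glance.pee_fit <- function(x, ...) {
  y <- x$data[[x$response]]
  vol <- x$data[[x$offset_col]]
  mu <- predicted_mean(x)
  obs_d <- y / vol
  pred_d <- mu / vol
  dev_expl <- if (!is.null(x$fit$null.deviance)) {
    1 - x$fit$deviance / x$fit$null.deviance
  } else NA_real_
  tibble(
    family = x$family, n = length(y), aic = AIC(x$fit),
    log_lik = as.numeric(logLik(x$fit)),
    theta = switch(x$family,
                   negbin = x$fit$theta,
                   zinb = glmmTMB::sigma(x$fit),
                   NA_real_),
    deviance_explained = dev_expl,
    pseudo_r2 = suppressWarnings(stats::cor(obs_d, pred_d)^2),
    converged = x$converged
  )
}

# Expected response count (including the zero part for zi families).
predicted_mean <- function(x) {
  if (x$family %in% c("poisson", "negbin")) {
    as.numeric(fitted(x$fit))
  } else {
    as.numeric(predict(x$fit, type = "response"))
  }
}

# Pointwise log-likelihood contributions, used by Vuong's test.
loglik_pointwise <- function(x) {
  y <- x$data[[x$response]]
  if (x$family == "poisson") {
    return(dpois(y, fitted(x$fit), log = TRUE))
  }
  if (x$family == "negbin") {
    return(dnbinom(y, mu = fitted(x$fit), size = x$fit$theta, log = TRUE))
  }
  p0 <- as.numeric(predict(x$fit, type = "zprob"))
  mu <- as.numeric(predict(x$fit, type = "conditional"))
  base <- if (x$family == "zip") {
    dpois(y, mu)
  } else {
    dnbinom(y, mu = mu, size = glmmTMB::sigma(x$fit))
  }
  log((y == 0) * p0 + (1 - p0) * base)
}

#' Overdispersion of a Poisson fit
#'
#' Pearson-residual estimate of the variance-to-mean ratio,
#' `sum(pearson^2) / df.residual`; values well above 1 indicate
#' overdispersion and motivate the negative-binomial step of the ladder.
#'
#' @param x a `pee_fit` with `family = "poisson"`.
#' @return Numeric theta estimate (`NA` with a warning for a degenerate
#'   all-zero response).
#' @export
overdispersion <- function(x) {
  stopifnot(inherits(x, "pee_fit"))
  if (x$family != "poisson") abort("overdispersion() expects a Poisson fit")
  y <- x$data[[x$response]]
  if (all(y == 0)) {
    warn("all-zero response: overdispersion undefined")
    return(NA_real_)
  }
  sum(stats::residuals(x$fit, type = "pearson")^2) / stats::df.residual(x$fit)
}

#' Exhaustive AIC model selection
#'
#' Fits every subset of `count_menu` (and, for zero-inflated families, every
#' subset of `zero_menu`), ranks candidates by AIC, and returns the
#' lowest-AIC fit whose every explanatory variable (both parts, intercepts
#' excluded) is significant at level `alpha`. When no candidate passes the
#' significance filter the overall lowest-AIC fit is returned flagged
#' non-conforming.
#'
#' @param data per-dive metrics table (see [fit_count_model()]).
#' @param count_menu,zero_menu covariate menus to enumerate.
#' @param family model family, see [fit_count_model()].
#' @param alpha significance level of the coefficient filter.
#' @param max_candidates hard cap on the enumeration size.
#' @param ... passed to [fit_count_model()].
#' @return A list: `best` (`pee_fit`), `conforming` (logical), `ledger`
#'   (tibble of every candidate: covariates, AIC, conforming flag,
#'   convergence).
#' @export
select_model <- function(data, count_menu, zero_menu = NULL,
                         family = "poisson", alpha = 0.05,
                         max_candidates = 2^15, ...) {
  subsets <- function(menu) {
    out <- list(character(0))
    for (k in seq_along(menu)) {
      out <- c(out, combn(menu, k, simplify = FALSE))
    }
    out
  }
  cs <- subsets(count_menu)
  zs <- if (family %in% c("zip", "zinb")) subsets(zero_menu %||% character()) else list(NULL)
  if (length(cs) * length(zs) > max_candidates) {
    abort(sprintf("candidate set too large (%d > %d)",
                  length(cs) * length(zs), max_candidates))
  }
  rows <- list()
  fits <- list()
  i <- 0L
  for (cc in cs) {
    for (zz in zs) {
      i <- i + 1L
      fit <- tryCatch(
        fit_count_model(data, count_covariates = cc, zero_covariates = zz,
                        family = family, ...),
        error = function(e) NULL,
        warning = function(w) suppressWarnings(
          fit_count_model(data, count_covariates = cc, zero_covariates = zz,
                          family = family, ...))
      )
      ok <- !is.null(fit) && fit$converged && is.finite(AIC(fit$fit))
      conf <- FALSE
      aic <- NA_real_
      if (ok) {
        aic <- AIC(fit$fit)
        td <- tidy(fit)
        slopes <- td[!grepl("Intercept", td$term), ]
        conf <- nrow(slopes) == 0 || all(slopes$p.value < alpha, na.rm = TRUE)
      }
      rows[[i]] <- tibble(
        count_covariates = paste(cc, collapse = "+"),
        zero_covariates = paste(zz %||% character(), collapse = "+"),
        aic = aic, converged = ok, conforming = conf
      )
      fits[[i]] <- fit
    }
  }
  ledger <- bind_rows(rows) |> mutate(candidate = row_number())
  usable <- ledger |> filter(.data$converged)
  if (nrow(usable) == 0) abort("no candidate model converged")
  conf_ok <- usable |> filter(.data$conforming)
  pick_from <- if (nrow(conf_ok) > 0) conf_ok else usable
  best_row <- pick_from$candidate[which.min(pick_from$aic)]
  list(best = fits[[best_row]],
       conforming = nrow(conf_ok) > 0,
       ledger = arrange(ledger, .data$aic))
}

#' Vuong's closeness test between two non-nested fits
#'
#' For the same response vector, the statistic is
#' `z = sqrt(n) * mean(m) / sd(m)` with `m_i` the pointwise log-likelihood
#' differences; a two-sided normal p-value is reported. Positive `z` favours
#' `fit_a`. Identical likelihood vectors give `z = 0`, `p = 1`.
#'
#' @param fit_a,fit_b `pee_fit` objects fitted to the same response.
#' @return A one-row tibble `z`, `p_value`, `preferred`.
#' @export
vuong_compare <- function(fit_a, fit_b) {
  la <- loglik_pointwise(fit_a)
  lb <- loglik_pointwise(fit_b)
  if (length(la) != length(lb)) abort("fits must share the same response vector")
  m <- la - lb
  s <- sd(m)
  z <- if (!is.finite(s) || s < 1e-12) 0 else sqrt(length(m)) * mean(m) / s
  p <- if (z == 0) 1 else 2 * pnorm(-abs(z))
  tibble(z = z, p_value = p,
         preferred = if (z > 0) fit_a$family else if (z < 0) fit_b$family else "neither")
}

#' Simulate a per-dive table from a zero-inflated count model
#'
#' Generative helper for parameter-recovery tests: standardized normal
#' covariates, log-normal prospected volumes as offset, a logistic
#' structural-zero part and a Poisson or NB(θ) count part.
#'
#' @param n number of dives (rows).
#' @param beta named numeric count-part coefficients; `"(Intercept)"` plus
#'   covariate names (covariates are drawn standard normal).
#' @param gamma named numeric zero-part coefficients on the logit scale
#'   (probability of a structural zero); `NULL` for no zero inflation.
#' @param theta NB size parameter; `Inf` gives Poisson counts.
#' @param mean_log_volume,sd_log_volume log-normal volume distribution.
#' @return A tibble with the covariates, `volume`, `pee_count` and the true
#'   structural-zero indicator `.zero`.
#' @export
simulate_density_data <- function(n, beta, gamma = NULL, theta = Inf,
                                  mean_log_volume = 8, sd_log_volume = 0.5) {
  covs <- setdiff(names(beta), "(Intercept)")
  zcovs <- setdiff(names(gamma %||% numeric()), "(Intercept)")
  allc <- union(covs, zcovs)
  data <- as_tibble(c(
    setNames(lapply(allc, function(.) rnorm(n)), allc),
    list(volume = exp(rnorm(n, mean_log_volume, sd_log_volume)))
  ))
  eta <- rep(beta[["(Intercept)"]], n) + log(data$volume)
  for (cl in covs) eta <- eta + beta[[cl]] * data[[cl]]
  mu <- exp(eta)
  y <- if (is.finite(theta)) rnbinom(n, mu = mu, size = theta) else rpois(n, mu)
  zero <- rep(FALSE, n)
  if (!is.null(gamma)) {
    zeta <- rep(gamma[["(Intercept)"]], n)
    for (cl in zcovs) zeta <- zeta + gamma[[cl]] * data[[cl]]
    zero <- runif(n) < plogis(zeta)
    y[zero] <- 0L
  }
  data$pee_count <- y
  data$.zero <- zero
  data
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
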