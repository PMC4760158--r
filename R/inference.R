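#' Within-group (containment) denominator degrees of freedom
#'
#' The df convention used for all fixed-effect t-tests in this package:
#' \eqn{df = n_{obs} - n_{groups} - n_{slopes}}. With 106 observations
#' over 40 stations and one explanatory variable this gives 65; the
#' ungrouped baseline (one grouping unit, no slopes) gives 105.
#'
#' @param n_obs Number of observations.
#' @param n_groups Number of grouping units (stations).
#' @param n_fixed_slopes Number of non-intercept fixed-effect columns.
#' @return Integer degrees of freedom (> 0).
#' @examples
#' within_group_df(106, 40, 1)  # 65
#' within_group_df(106, 1, 0)   # 105
#' @export
within_group_df <- function(n_obs, n_groups, n_fixed_slopes) {
  df <- n_obs - n_groups - n_fixed_slopes
  if (df <= 0) {
    stop(sprintf(
      "non-positive denominator df (%d obs, %d groups, %d slopes)",
      n_obs, n_groups, n_fixed_slopes), call. = FALSE)
  }
  as.integer(df)
}

#' Akaike information criterion corrected for small samples
#'
#' \eqn{AICc = -2\,\ell + 2k + 2k(k+1)/(n-k-1)}. Converges to AIC as
#' \eqn{n \to \infty}; undefined for \eqn{n \le k+1}.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed effects including the
#'   intercept, plus the random-intercept and residual variances).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop(sprintf("AICc undefined for n = %d <= k + 1 = %d", n, k + 1),
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

build_fixed_formula <- function(response, fixed_terms) {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  as.formula(paste(response, "~", rhs))
}

#' Fit a station random-intercept linear mixed model
#'
#' Fits `response ~ fixed_terms` with a random intercept per grouping
#' unit, by maximum likelihood (the default, so that AICc values are
#' comparable across fixed-effect structures) via [nlme::lme()]. Each
#' fixed term is reported with its estimate, standard error, Wald t
#' statistic and a p-value on the containment denominator df
#' ([within_group_df()]); the same df convention applies to every term.
#'
#' Degenerate designs are handled explicitly: with a single grouping unit,
#' or when the mixed fit fails because a variance component is estimated
#' at an exact zero boundary, the model collapses to ordinary least
#' squares with a warning (random-intercept SD reported as 0). An
#' estimated random-intercept SD numerically at zero is permitted and
#' warned about.
#'
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms; interactions
#'   written `"A:B"` (`"A*B"` / `"A×B"` are normalized). Empty vector =
#'   intercept-only model.
#' @param grouping Grouping (station) column name.
#' @param data Data frame containing all columns.
#' @param method `"ML"` (default) or `"REML"`. Use ML whenever models with
#'   different fixed effects are compared by AICc.
#' @return An object of class `lmm_fit` with elements `coefficients` (a
#'   data frame: term, estimate, se, t, p, df), `loglik`, `aicc`, `k`,
#'   `n_obs`, `n_groups`, `sigma`, `random_intercept_sd`, `response`,
#'   `fixed_terms`, `grouping`, `method`.
#' @export
fit_lmm <- function(response, fixed_terms, grouping, data, method = c("ML", "REML")) {
  method <- match.arg(method)
  fixed_terms <- normalize_terms(fixed_terms)
  need <- unique(c(response, all.vars(build_fixed_formula(response, fixed_terms)),
                   grouping))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dd <- data[, need, drop = FALSE]
  dd[[grouping]] <- factor(dd[[grouping]])
  n_obs <- nrow(dd)
  n_groups <- nlevels(dd[[grouping]])
  fixed <- build_fixed_formula(response, fixed_terms)

  mm <- model.matrix(fixed, dd)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient fixed-effect design; collinear term(s) among: ",
         paste(colnames(mm)[-1], collapse = ", "), call. = FALSE)
  }
  n_slopes <- ncol(mm) - 1L
  df_term <- within_group_df(n_obs, n_groups, n_slopes)

  if (n_groups < 2L) {
    warning("single grouping unit: fitting ordinary least squares", call. = FALSE)
    fit <- lm(fixed, data = dd)
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    ll <- as.numeric(logLik(fit))
    sigma <- summary(fit)$sigma
    ran_sd <- 0
  } else {
    ran_formula <- as.formula(paste("~ 1 |", grouping))
    fit <- tryCatch(
      nlme::lme(fixed = fixed, random = ran_formula, data = dd,
                method = method,
                control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning(sprintf(
        "mixed model failed (%s); falling back to ordinary least squares",
        conditionMessage(fit)), call. = FALSE)
      fit <- lm(fixed, data = dd)
      beta <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      ll <- as.numeric(logLik(fit))
      sigma <- summary(fit)$sigma
      ran_sd <- 0
    } else {
      beta <- nlme::fixef(fit)
      se <- sqrt(diag(vcov(fit)))
      ll <- as.numeric(logLik(fit))
      sigma <- fit$sigma
      vc <- nlme::VarCorr(fit)
      ran_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
      if (is.finite(ran_sd) && sigma > 0 && ran_sd / sigma < 1e-6) {
        warning("random-intercept variance estimated at (near) zero", call. = FALSE)
      }
    }
  }

  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = df_term)
  k <- length(beta) + 2L
  aicc_val <- if (is.finite(ll)) aicc(ll, k, n_obs) else {
    warning("non-finite log-likelihood (degenerate fit); AICc set to NA",
            call. = FALSE)
    NA_real_
  }
  structure(
    list(
      coefficients = data.frame(
        term = names(beta), estimate = unname(beta), se = unname(se),
        t = unname(tval), p = unname(pval), df = df_term,
        stringsAsFactors = FALSE
      ),
      loglik = ll, aicc = aicc_val, k = k,
      n_obs = n_obs, n_groups = n_groups,
      sigma = sigma, random_intercept_sd = ran_sd,
      response = response, fixed_terms = fixed_terms,
      grouping = grouping, method = method,
      model = fit
    ),
    class = "lmm_fit"
  )
}

normalize_terms <- function(fixed_terms) {
  if (is.null(fixed_terms) || !length(fixed_terms)) return(character(0))
  fixed_terms <- gsub("×", ":", fixed_terms)
  fixed_terms <- gsub("\\s*\\*\\s*", ":", fixed_terms)
  gsub("\\s+", "", fixed_terms)
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  rhs <- if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ") else "1"
  cat(sprintf("LMM (%s): %s ~ %s, random intercept by %s\n",
              x$method, x$response, rhs, x$grouping))
  cat(sprintf("  n = %d obs, %d groups; sigma = %.4g; random-intercept sd = %.4g\n",
              x$n_obs, x$n_groups, x$sigma, x$random_intercept_sd))
  cat(sprintf("  logLik = %.3f, k = %d, AICc = %.2f\n", x$loglik, x$k, x$aicc))
  co <- x$coefficients
  co[, 2:5] <- lapply(co[, 2:5], signif, digits)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Rank single explanatory variables by AICc
#'
#' Fits one univariate random-intercept model per candidate term and
#' returns the fits sorted by ascending AICc, with Table-style columns
#' (term, AICc, estimate, se, t, p, df). Ties keep input order.
#'
#' @param response Response column name.
#' @param candidate_terms Character vector of candidate explanatory
#'   variables (each fitted alone).
#' @param grouping Grouping column name.
#' @param data Data frame.
#' @param method Estimation method passed to [fit_lmm()].
#' @return A data frame of class `univariate_ranking`, with the fitted
#'   models in attribute `fits` (in ranked order).
#' @export
rank_univariate <- function(response, candidate_terms, grouping, data,
                            method = "ML") {
  if (!length(candidate_terms)) stop("need at least one candidate", call. = FALSE)
  candidate_terms <- normalize_terms(candidate_terms)
  fits <- lapply(candidate_terms, function(term) {
    fit_lmm(response, term, grouping, data, method = method)
  })
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    slope <- f$coefficients[f$coefficients$term != "(Intercept)", , drop = FALSE]
    data.frame(term = candidate_terms[i], aicc = f$aicc,
               estimate = slope$estimate[1], se = slope$se[1],
               t = slope$t[1], p = slope$p[1], df = slope$df[1],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$aicc, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("univariate_ranking", "data.frame"))
}

# Enumerate admissible fixed-term subsets under marginality: an
# interaction A:B may only appear together with both A and B.
admissible_subsets <- function(terms) {
  p <- length(terms)
  if (p > 20L) {
    stop("refusing all-subsets enumeration over more than 20 terms",
         call. = FALSE)
  }
  parents <- lapply(terms, function(t) {
    if (grepl(":", t, fixed = TRUE)) strsplit(t, ":", fixed = TRUE)[[1]] else NULL
  })
  subsets <- list(character(0))
  if (p > 0) {
    for (mask in seq_len(2^p - 1)) {
      inc <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
      sub <- terms[inc]
      ok <- all(vapply(which(inc), function(i) {
        is.null(parents[[i]]) || all(parents[[i]] %in% sub)
      }, logical(1)))
      if (ok) subsets[[length(subsets) + 1L]] <- sub
    }
  }
  subsets
}

#' Exhaustive all-subsets model selection by AICc
#'
#' Fits every admissible subset of the supplied fixed-effect terms
#' (including the intercept-only model) as a random-intercept model by
#' maximum likelihood, and ranks them by AICc. Marginality is enforced:
#' an interaction term enters a subset only when both of its main effects
#' do. Ties in AICc are broken by fewer parameters, then input order.
#'
#' @param response Response column name.
#' @param full_terms Character vector of candidate terms; interactions as
#'   `"A:B"`.
#' @param grouping Grouping column name.
#' @param data Data frame.
#' @param method Estimation method; `"ML"` (default) is required for AICc
#'   comparability across fixed-effect structures.
#' @return An object of class `dredge_result`: a list with `table` (model
#'   formulas, k, logLik, AICc, delta, ascending), `fits` (ranked) and
#'   `best` (the minimum-AICc [fit_lmm()] object).
#' @export
dredge_all_subsets <- function(response, full_terms, grouping, data,
                               method = "ML") {
  full_terms <- normalize_terms(full_terms)
  subsets <- admissible_subsets(full_terms)
  fits <- lapply(subsets, function(sub) {
    fit_lmm(response, sub, grouping, data, method = method)
  })
  tab <- data.frame(
    model = vapply(subsets, function(s) {
      paste(response, "~", if (length(s)) paste(s, collapse = " + ") else "1")
    }, character(1)),
    n_terms = lengths(subsets),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aicc, tab$k, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$delta <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], best = fits[[ord[1]]]),
            class = "dredge_result")
}

#' @export
print.dredge_result <- function(x, n = 10, ...) {
  cat(sprintf("All-subsets AICc selection: %d admissible models\n",
              nrow(x$table)))
  print(head(x$table, n), row.names = FALSE)
  cat("best model:", x$table$model[1], "\n")
  invisible(x)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y Paired numeric vectors, n >= 3, both with positive variance.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
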