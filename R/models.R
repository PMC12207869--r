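#' Specification of one mixed model
#'
#' The three study models share a fixed-effect menu of treatment, air
#' temperature (active-phase mean for the daytime model, 24-h mean for the
#' night models), wind, body mass and sex. The daytime model carries a
#' random intercept per individual; the two night models carry a random
#' intercept and a random treatment slope, letting both average level and
#' playback response vary among birds. Backward simplification never removes
#' protected terms (treatment by default, so the treatment effect is always
#' reported, significant or not).
#'
#' @param response one of `"median_active_ts"`, `"min_rest_ts"`,
#'   `"torpor_duration_h"`.
#' @param fixed_terms initial fixed-effect terms, a subset of
#'   `c("treatment", "ta", "wind", "mass", "sex")`.
#' @param random `"intercept"` or `"slope"` (intercept + treatment slope).
#' @param protected terms never dropped during simplification.
#' @param alpha_drop p-value threshold for dropping a term (default 0.05).
#' @param df_method `"satterthwaite"` (default) or `"residual"`
#'   (t-tests on `n - p` degrees of freedom).
#' @return a `model_spec` list.
#' @export
model_spec <- function(response,
                       fixed_terms = c("treatment", "ta", "wind", "mass", "sex"),
                       random = c("intercept", "slope"),
                       protected = "treatment",
                       alpha_drop = 0.05,
                       df_method = c("satterthwaite", "residual")) {
  random <- match.arg(random)
  df_method <- match.arg(df_method)
  stopifnot(all(protected %in% fixed_terms))
  structure(list(response = response, fixed_terms = fixed_terms,
                 random = random, protected = protected,
                 alpha_drop = alpha_drop, df_method = df_method),
            class = "model_spec")
}

# spec term name -> data column
term_to_col <- function(term) {
  ifelse(term == "treatment", "condition", term)
}

build_formula <- function(spec, fixed_terms = spec$fixed_terms) {
  rhs <- paste(c(term_to_col(fixed_terms), "1"), collapse = " + ")
  re <- if (spec$random == "slope") "(1 + condition | bird_id)" else "(1 | bird_id)"
  as.formula(paste(spec$response, "~", rhs, "+", re))
}

#' Fit one linear mixed model by REML
#'
#' Fits the model with `lme4`/`lmerTest`, reporting coefficients on their
#' natural scales (C, h, C per C), Satterthwaite (default) or residual-df
#' p-values, random-effect SDs, and variance-partition marginal/conditional
#' R-squared. If a random-slope model fails to converge it is automatically
#' refitted with a random intercept only and flagged (`fallback = TRUE`,
#' with a warning -- never silent). A singular fit (a variance component
#' estimated at zero, common with few individuals) is kept but flagged.
#'
#' @param table model-ready analysis table (rows with `included = FALSE` are
#'   dropped if the column is present).
#' @param spec a [model_spec()].
#' @param fixed_terms fixed terms to use (defaults to the spec's full set).
#' @return an `lmm_fit`: list with `coefficients` (term, estimate, se, df,
#'   t, p), `re_sd`, `resid_sd`, `marginal_r2`, `conditional_r2`,
#'   `n_individuals`, `n_observations`, `converged`, `singular`, `fallback`
#'   and the underlying `fit`.
#' @export
fit_lmm <- function(table, spec, fixed_terms = spec$fixed_terms) {
  dat <- as_tibble(table)
  if ("included" %in% names(dat)) dat <- dat[dat$included, ]
  cols <- unique(c(spec$response, term_to_col(spec$fixed_terms), "bird_id"))
  dat <- dat[stats::complete.cases(dat[, cols]), ]
  if (n_distinct(dat$bird_id) < 2) stop("need >= 2 individuals")
  if (nrow(dat) < 10) stop("need >= 10 observations, got ", nrow(dat))
  for (v in intersect(term_to_col(fixed_terms), names(dat))) {
    if (is.factor(dat[[v]]) && n_distinct(dat[[v]]) < 2) {
      stop("fixed term '", v, "' has a single level in the analysis table ",
           "(degenerate design); cannot estimate its effect")
    }
  }

  fit_one <- function(random) {
    sp <- spec
    sp$random <- random
    f <- build_formula(sp, fixed_terms)
    msgs <- character(0)
    m <- withCallingHandlers(
      lmerTest::lmer(f, data = dat, REML = TRUE),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    conv <- !any(grepl("failed to converge", c(msgs,
                 unlist(m@optinfo$conv$lme4$messages))))
    list(model = m, converged = conv)
  }

  fallback <- FALSE
  res <- tryCatch(fit_one(spec$random), error = function(e) NULL)
  if (spec$random == "slope" && (is.null(res) || !res$converged)) {
    warning("random-slope model for ", spec$response,
            " did not converge; falling back to a random intercept only")
    fallback <- TRUE
    res <- fit_one("intercept")
  }
  if (is.null(res)) stop("mixed model for ", spec$response, " failed to fit")
  m <- res$model

  smry <- summary(m)
  ct <- smry$coefficients
  df_res <- nrow(dat) - nrow(ct)
  if (spec$df_method == "residual") {
    ct[, "df"] <- df_res
    ct[, "Pr(>|t|)"] <- 2 * pt(-abs(ct[, "t value"]), df_res)
  } else {
    # Satterthwaite df can be unavailable on boundary fits; fall back to
    # residual df for those rows so simplification always has a p-value
    bad <- !is.finite(ct[, "Pr(>|t|)"])
    if (any(bad)) {
      ct[bad, "df"] <- df_res
      ct[bad, "Pr(>|t|)"] <- 2 * pt(-abs(ct[bad, "t value"]), df_res)
    }
  }
  # coefficient -> spec term label via the terms() assign attribute
  X <- lme4::getME(m, "X")
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(m), "term.labels")
  term_of <- ifelse(assign == 0, "(Intercept)", labels[pmax(assign, 1)])
  col_to_term <- setNames(spec$fixed_terms, term_to_col(spec$fixed_terms))
  term_of <- ifelse(term_of %in% names(col_to_term),
                    col_to_term[term_of], term_of)

  coefs <- tibble(term = unname(term_of),
                  coefficient = rownames(ct),
                  estimate = unname(ct[, "Estimate"]),
                  se = unname(ct[, "Std. Error"]),
                  df = unname(ct[, "df"]),
                  t = unname(ct[, "t value"]),
                  p = unname(ct[, "Pr(>|t|)"]))

  vc <- lme4::VarCorr(m)
  re_sd <- bind_rows(lapply(names(vc), function(g) {
    tibble(group = g, term = colnames(vc[[g]]),
           sd = attr(vc[[g]], "stddev"))
  }))
  r2 <- r2_mixed(m)
  singular <- lme4::isSingular(m)

  structure(list(response = spec$response,
                 spec = spec,
                 fixed_terms = fixed_terms,
                 coefficients = coefs,
                 re_sd = re_sd,
                 resid_sd = smry$sigma,
                 marginal_r2 = r2[["marginal_r2"]],
                 conditional_r2 = r2[["conditional_r2"]],
                 n_individuals = n_distinct(dat$bird_id),
                 n_observations = nrow(dat),
                 converged = res$converged,
                 singular = singular,
                 fallback = fallback,
                 data = dat,
                 fit = m),
            class = "lmm_fit")
}

#' Variance-partition R-squared for a mixed model
#'
#' Marginal R-squared is the variance of the fixed-effect linear predictor
#' over the total (fixed + random + residual) variance; conditional
#' R-squared adds the random-effect variance to the numerator. The
#' random-effect variance is the mean, over observations, of the per-row
#' quadratic form of the random-effect design with the fitted covariance
#' (so random slopes are handled).
#'
#' @param fit a fitted `merMod` (or an `lmm_fit`).
#' @return named numeric: `marginal_r2`, `conditional_r2`.
#' @export
r2_mixed <- function(fit) {
  m <- if (inherits(fit, "lmm_fit")) fit$fit else fit
  X <- lme4::getME(m, "X")
  var_fix <- var(as.vector(X %*% lme4::fixef(m)))
  vc <- lme4::VarCorr(m)
  mm <- lme4::getME(m, "mmList")
  var_ran_i <- rep(0, nrow(X))
  for (j in seq_along(mm)) {
    Z <- mm[[j]]
    S <- as.matrix(vc[[j]])
    var_ran_i <- var_ran_i + rowSums((Z %*% S) * Z)
  }
  var_ran <- mean(var_ran_i)
  var_res <- stats::sigma(m)^2
  tot <- var_fix + var_ran + var_res
  c(marginal_r2 = var_fix / tot,
    conditional_r2 = (var_fix + var_ran) / tot)
}

#' Backward simplification of a global mixed model
#'
#' Operationalises "sequential removal of least-significant terms": refit
#' after removing the non-protected fixed term with the largest p-value at
#' or above `alpha_drop`, until every remaining non-protected term is
#' significant or only protected terms remain. The treatment term is
#' protected by default and therefore always reported.
#'
#' @param table model-ready analysis table.
#' @param spec a [model_spec()].
#' @return list with `fit` (the final [fit_lmm()]) and `dropped` (tibble
#'   log of removed terms with their p-values).
#' @export
simplify_model <- function(table, spec) {
  terms_now <- spec$fixed_terms
  dropped <- tibble(step = integer(0), term = character(0), p = numeric(0))
  step <- 0L
  repeat {
    fit <- fit_lmm(table, spec, fixed_terms = terms_now)
    cand <- fit$coefficients |>
      filter(.data$term %in% setdiff(terms_now, spec$protected)) |>
      group_by(.data$term) |>
      summarise(p = min(.data$p), .groups = "drop")  # factor terms: best coef
    if (nrow(cand) == 0 || max(cand$p) < spec$alpha_drop) break
    worst <- cand$term[which.max(cand$p)]
    step <- step + 1L
    dropped <- bind_rows(dropped,
                         tibble(step = step, term = worst, p = max(cand$p)))
    terms_now <- setdiff(terms_now, worst)
  }
  list(fit = fit, dropped = dropped)
}

#' Parametric bootstrap prediction intervals
#'
#' Simulates responses from the fitted model, refits, and collects
#' population-level predictions at reference covariate values (each
#' condition, with continuous covariates at their means and sex at its
#' reference level). Percentile intervals are returned per condition plus
#' the treatment-minus-control contrast. Deterministic given `seed`; refit
#' failures are counted and a warning is raised if more than 10% fail.
#'
#' @param fit an `lmm_fit`.
#' @param n_boot number of bootstrap replicates (study analyses used 1000;
#'   tests use fewer).
#' @param seed integer seed.
#' @param level interval coverage (default 0.95).
#' @return tibble with `condition`, `predicted`, `lower`, `upper`;
#'   attribute `n_failed`.
#' @export
bootstrap_prediction_intervals <- function(fit, n_boot = 1000, seed = 1,
                                           level = 0.95) {
  stopifnot(inherits(fit, "lmm_fit"))
  m <- fit$fit
  dat <- fit$data
  newdata <- tibble(condition = factor(c("control", "treatment"),
                                       levels = c("control", "treatment")))
  for (v in c("ta", "wind", "mass")) {
    if (v %in% names(dat)) newdata[[v]] <- mean(dat[[v]])
  }
  if ("sex" %in% names(dat)) {
    newdata$sex <- factor(levels(dat$sex)[1], levels = levels(dat$sex))
  }
  point <- unname(predict(m, newdata = newdata, re.form = NA))

  set.seed(seed)
  sims <- simulate(m, nsim = n_boot)
  preds <- matrix(NA_real_, n_boot, nrow(newdata))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    pb <- tryCatch({
      mb <- suppressWarnings(suppressMessages(lme4::refit(m, sims[[b]])))
      predict(mb, newdata = newdata, re.form = NA)
    }, error = function(e) NULL)
    if (is.null(pb)) failed <- failed + 1L else preds[b, ] <- pb
  }
  if (failed > 0.1 * n_boot) {
    warning(failed, "/", n_boot, " bootstrap refits failed")
  }
  a <- (1 - level) / 2
  qs <- apply(preds, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  contrast <- preds[, 2] - preds[, 1]
  out <- tibble(
    condition = c(as.character(newdata$condition), "treatment - control"),
    predicted = c(point, point[2] - point[1]),
    lower = unname(c(qs[1, ], quantile(contrast, a, na.rm = TRUE))),
    upper = unname(c(qs[2, ], quantile(contrast, 1 - a, na.rm = TRUE)))
  )
  attr(out, "n_failed") <- failed
  out
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model (REML): %s\n", x$response))
  cat(sprintf("  marginal R^2 = %.3f, conditional R^2 = %.3f; N = %d, n = %d\n",
              x$marginal_r2, x$conditional_r2, x$n_individuals, x$n_observations))
  cat("  fixed effects:\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("    %-20s %8.3f  s.e. %6.3f  d.f. %6.1f  t %6.2f  p %s\n",
                cf$coefficient[i], cf$estimate[i], cf$se[i], cf$df[i], cf$t[i],
                format.pval(cf$p[i], digits = 2, eps = 1e-3)))
  }
  cat("  random effects (s.d.):\n")
  for (i in seq_len(nrow(x$re_sd))) {
    cat(sprintf("    %s %s: %.3f\n", x$re_sd$group[i], x$re_sd$term[i],
                x$re_sd$sd[i]))
  }
  cat(sprintf("  residual s.d.: %.3f\n", x$resid_sd))
  if (x$fallback) cat("  NOTE: random-slope fit failed; intercept-only fallback\n")
  if (x$singular) cat("  note: singular fit (a variance component is zero)\n")
  invisible(x)
}
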