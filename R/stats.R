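#' Fit a random-intercept linear mixed model
#'
#' Restricted-maximum-likelihood fit of
#' `response ~ fixed terms + (1 | group)`, the model used both for
#' timepoint effects on single parameters and for GMV-versus-cellular-
#' metric correlations (imaging positions are nested within animals, so the
#' animal gets a random intercept).  Fixed-effect p-values are Wald t tests
#' with residual degrees of freedom `n - rank(X)`.
#'
#' @param table data frame; one row per position and interval.
#' @param response name of the response column.
#' @param fixed_terms character vector of fixed-effect column names (may
#'   include factors).
#' @param group grouping column for the random intercept (default
#'   `"animal_id"`).
#' @return A `mixed_model_result`: `coefficients` data frame (term,
#'   estimate, se, t, df, p), `random_intercept_variance`,
#'   `residual_variance`, `marginal_r2`, `vif` (named vector or `NULL` for
#'   a single term), `n_obs`, `n_groups`, `method` (`"REML"` or
#'   `"OLS-fallback"`), and the underlying `fit`.
#' @export
fit_random_intercept_model <- function(table, response, fixed_terms,
                                       group = "animal_id") {
  stopifnot(is.data.frame(table), response %in% names(table),
            all(fixed_terms %in% names(table)), group %in% names(table))
  dat <- table[complete.cases(table[c(response, fixed_terms, group)]), ]
  n <- nrow(dat)
  fml_fixed <- paste(response, "~", paste(fixed_terms, collapse = " + "))
  X <- model.matrix(as.formula(paste("~", paste(fixed_terms,
                                                collapse = " + "))), dat)
  rk <- qr(X)$rank
  if (rk < ncol(X)) {
    dropped <- colnames(X)[qr(X)$pivot[(rk + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  n_groups <- length(unique(dat[[group]]))
  if (n_groups < 2) {
    warning("single grouping level: falling back to ordinary regression")
    fit <- lm(as.formula(fml_fixed), data = dat)
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     t = sm[, 3], df = n - rk, p = sm[, 4],
                     row.names = NULL, stringsAsFactors = FALSE)
    var_ri <- 0
    var_res <- summary(fit)$sigma^2
    method <- "OLS-fallback"
    pred <- fitted(fit)
  } else {
    fml <- as.formula(paste(fml_fixed, "+ (1 |", group, ")"))
    fit <- lme4::lmer(fml, data = dat, REML = TRUE)
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    df <- n - rk
    tval <- b / se
    co <- data.frame(term = names(b), estimate = as.numeric(b),
                     se = as.numeric(se), t = as.numeric(tval), df = df,
                     p = 2 * pt(-abs(tval), df),
                     row.names = NULL, stringsAsFactors = FALSE)
    vc <- lme4::VarCorr(fit)
    var_ri <- as.numeric(vc[[group]][1, 1])
    var_res <- attr(vc, "sc")^2
    method <- "REML"
    pred <- as.numeric(X %*% b)
  }
  var_fix <- if (n > 1) var(pred) * (n - 1) / n else 0
  r2m <- if (var_fix + var_ri + var_res > 0)
    var_fix / (var_fix + var_ri + var_res) else 0
  vifs <- if (length(fixed_terms) >= 2 &&
              all(vapply(dat[fixed_terms], is.numeric, logical(1))))
    vif(dat, fixed_terms) else NULL
  structure(list(coefficients = co,
                 random_intercept_variance = var_ri,
                 residual_variance = var_res,
                 marginal_r2 = r2m, vif = vifs,
                 n_obs = n, n_groups = n_groups, method = method,
                 response = response, fixed_terms = fixed_terms,
                 group = group, data = dat, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> %s; n = %d in %d groups (%s)\n",
              x$response, x$n_obs, x$n_groups, x$method))
  print(x$coefficients, digits = 4)
  cat(sprintf("random-intercept var %.4g, residual var %.4g, marginal R^2 %.3f\n",
              x$random_intercept_variance, x$residual_variance,
              x$marginal_r2))
  if (!is.null(x$vif)) {
    cat("VIF: ")
    print(round(x$vif, 3))
  }
  invisible(x)
}

#' Marginal R-squared of a mixed model
#'
#' Fraction of total variance explained by the fixed effects:
#' `var(X b) / (var(X b) + var(random intercept) + var(residual))`
#' (the fixed-effects, "marginal" R-squared in the Nakagawa-Schielzeth
#' sense).  With `conditional = TRUE` the random-intercept variance is
#' credited to the model as well.
#'
#' @param model a `mixed_model_result`.
#' @param conditional return the conditional flavor instead.
#' @return R-squared in `[0, 1]`.
#' @export
marginal_r2 <- function(model, conditional = FALSE) {
  stopifnot(inherits(model, "mixed_model_result"))
  if (!conditional) return(model$marginal_r2)
  tot <- model$marginal_r2  # var_fix / denom
  denom_ri <- model$random_intercept_variance /
    (model$random_intercept_variance + model$residual_variance) *
    (1 - 0)  # explicit below
  # recompute from stored variances
  vf <- model$marginal_r2
  # solve var_fix from r2m = vf_frac: easier to recompute directly
  X <- model.matrix(as.formula(paste("~", paste(model$fixed_terms,
                                                collapse = " + "))),
                    model$data)
  b <- model$coefficients$estimate
  pred <- as.numeric(X %*% b)
  n <- length(pred)
  var_fix <- if (n > 1) var(pred) * (n - 1) / n else 0
  (var_fix + model$random_intercept_variance) /
    (var_fix + model$random_intercept_variance + model$residual_variance)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' on the remaining predictors; the standard multicollinearity diagnostic
#' reported with every multivariable model.
#'
#' @param table data frame holding the predictors.
#' @param fixed_terms names of >= 2 numeric predictor columns.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(table, fixed_terms) {
  stopifnot(length(fixed_terms) >= 2,
            all(fixed_terms %in% names(table)))
  dat <- table[fixed_terms]
  stopifnot(all(vapply(dat, is.numeric, logical(1))))
  out <- vapply(fixed_terms, function(tm) {
    others <- setdiff(fixed_terms, tm)
    fml <- as.formula(paste(tm, "~", paste(others, collapse = " + ")))
    r2 <- summary(lm(fml, data = dat))$r.squared
    if (r2 > 1 - 1e-12)
      stop("exact collinearity involving term: ", tm)
    1 / (1 - r2)
  }, numeric(1))
  setNames(out, fixed_terms)
}

#' Pairwise timepoint contrasts from a mixed model
#'
#' Refits the stored model with cell-mean coding of the timepoint factor,
#' forms all pairwise level differences, and adjusts p-values for multiple
#' comparison (Holm by default; Tukey via the studentized range is
#' available for the repeated-measures descriptive analysis).
#'
#' @param model a `mixed_model_result` whose fixed terms include
#'   `factor_term`.
#' @param factor_term name of the factor column (default `"timepoint"`).
#' @param correction `"holm"` or `"tukey"`.
#' @return data frame with `contrast`, `estimate`, `se`, `t`, `df`,
#'   `p_raw`, `p_adj`.
#' @export
pairwise_timepoint_contrasts <- function(model, factor_term = "timepoint",
                                         correction = c("holm", "tukey")) {
  stopifnot(inherits(model, "mixed_model_result"))
  correction <- match.arg(correction)
  dat <- model$data
  if (!factor_term %in% names(dat)) stop("factor term not in model data")
  f <- factor(dat[[factor_term]])
  lev <- levels(f)
  if (length(lev) < 2) stop("timepoint factor needs >= 2 levels")
  dat$.tp <- f
  fml <- as.formula(paste(model$response, "~ 0 + .tp + (1 |", model$group,
                          ")"))
  if (model$n_groups >= 2) {
    fit <- lme4::lmer(fml, data = dat, REML = TRUE)
    b <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    fit <- lm(as.formula(paste(model$response, "~ 0 + .tp")), data = dat)
    b <- coef(fit)
    V <- vcov(fit)
  }
  L <- length(lev)
  df <- nrow(dat) - L
  pairs <- utils::combn(L, 2)
  est <- se <- numeric(ncol(pairs))
  nm <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cvec <- rep(0, L); cvec[j] <- 1; cvec[i] <- -1
    est[k] <- sum(cvec * b)
    se[k] <- sqrt(drop(t(cvec) %*% V %*% cvec))
    nm[k] <- paste(lev[j], "-", lev[i])
  }
  tval <- est / se
  p_raw <- 2 * pt(-abs(tval), df)
  p_adj <- switch(correction,
    holm = p.adjust(p_raw, "holm"),
    tukey = ptukey(sqrt(2) * abs(tval), nmeans = L, df = df,
                   lower.tail = FALSE))
  data.frame(contrast = nm, estimate = est, se = se, t = tval, df = df,
             p_raw = p_raw, p_adj = pmin(p_adj, 1),
             stringsAsFactors = FALSE)
}

#' One-sample test of percent changes against a theoretical mean
#'
#' Tests relative changes (percent of baseline) against the theoretical
#' mean of 100 percent (or another `mu`), two-sided.  `method = "auto"`
#' picks the Wilcoxon signed-rank test when a Shapiro-Wilk normality
#' pre-check fails at `normality_alpha`, and the one-sample t-test
#' otherwise.  The Wilcoxon test is exact for n < 25 (no ties or zeros),
#' with the continuity-corrected normal approximation beyond.
#'
#' @param values numeric vector of percent-of-baseline values.
#' @param mu null value (default 100).
#' @param method `"auto"`, `"t"` or `"wilcoxon"`.
#' @param normality_alpha alpha of the Shapiro-Wilk pre-check.
#' @return list with `method`, `statistic`, `p_value`, `n`, `mu`,
#'   `mean`, `sd`.
#' @export
one_sample_change_test <- function(values, mu = 100,
                                   method = c("auto", "t", "wilcoxon"),
                                   normality_alpha = 0.05) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (method == "auto") {
    method <- "t"
    if (n >= 3 && n <= 5000 && sd(values) > 0) {
      if (shapiro.test(values)$p.value < normality_alpha)
        method <- "wilcoxon"
    }
  }
  if (method == "t") {
    if (n < 2) stop("t-test needs >= 2 values")
    if (sd(values) == 0) stop("zero variance: t-test undefined")
    ht <- t.test(values, mu = mu)
  } else {
    nz <- values[values != mu]
    if (length(nz) < 1) stop("all values tie with mu: Wilcoxon undefined")
    exact <- length(nz) < 25 && !anyDuplicated(abs(nz - mu))
    ht <- suppressWarnings(wilcox.test(values, mu = mu, exact = exact,
                                       correct = TRUE))
  }
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value, n = n, mu = mu, mean = mean(values),
       sd = sd(values))
}

#' Repeated-measures one-way ANOVA with Tukey post-hoc contrasts
#'
#' Descriptive analysis of a parameter across timepoints with subjects as
#' blocks (complete cases only): classical within-subject one-way ANOVA
#' plus Tukey HSD contrasts based on the within-stratum error.
#'
#' @param table data frame.
#' @param value name of the value column.
#' @param timepoint name of the timepoint column.
#' @param subject name of the subject (block) column; only subjects with
#'   all timepoints enter.
#' @return list with `anova` (F, df, p) and `tukey` data frame
#'   (contrast, estimate, p_adj).
#' @export
repeated_measures_anova <- function(table, value, timepoint, subject) {
  stopifnot(all(c(value, timepoint, subject) %in% names(table)))
  d <- data.frame(y = table[[value]], tp = factor(table[[timepoint]]),
                  id = factor(table[[subject]]))
  d <- d[complete.cases(d), ]
  keep <- names(which(tapply(d$tp, d$id,
                             function(x) length(unique(x))) ==
                        nlevels(d$tp)))
  d <- d[d$id %in% keep, ]
  d$id <- droplevels(d$id)
  if (nlevels(d$tp) < 2 || nlevels(d$id) < 2)
    stop("need >= 2 timepoints and >= 2 complete subjects")
  fit <- aov(y ~ tp + Error(id), data = d)
  sm <- summary(fit)
  tab <- sm[["Error: Within"]][[1]]
  Fv <- tab["tp", "F value"]; df1 <- tab["tp", "Df"]
  df2 <- tab["Residuals", "Df"]; p <- tab["tp", "Pr(>F)"]
  mse <- tab["Residuals", "Mean Sq"]
  lev <- levels(d$tp)
  nper <- as.numeric(table(d$tp))
  means <- tapply(d$y, d$tp, mean)
  pairs <- utils::combn(length(lev), 2)
  est <- numeric(ncol(pairs)); padj <- numeric(ncol(pairs))
  nm <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    est[k] <- means[j] - means[i]
    sep <- sqrt(mse / 2 * (1 / nper[i] + 1 / nper[j]))
    padj[k] <- ptukey(abs(est[k]) / sep, nmeans = length(lev), df = df2,
                      lower.tail = FALSE)
    nm[k] <- paste(lev[j], "-", lev[i])
  }
  list(anova = list(F = Fv, df1 = df1, df2 = df2, p = p),
       tukey = data.frame(contrast = nm, estimate = est, p_adj = padj,
                          stringsAsFactors = FALSE))
}

#' Export a mixed-model result as JSON
#'
#' @param model a `mixed_model_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "mixed_model_result"))
  out <- list(response = model$response,
              fixed_terms = model$fixed_terms,
              coefficients = model$coefficients,
              random_intercept_variance = model$random_intercept_variance,
              residual_variance = model$residual_variance,
              marginal_r2 = model$marginal_r2,
              vif = as.list(model$vif),
              n_obs = model$n_obs, n_groups = model$n_groups,
              method = model$method)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
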