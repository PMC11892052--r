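#' Build the person-level analysis frame
#'
#' Joins person-level exposures to the person table (inner join, so only
#' persons with at least one in-scope prescription are analysed) and attaches
#' one 0/1 dummy column per 3-character condition code present in the data
#' (columns \code{cond_<code>}), emulating a comprehensive
#' medical-condition control block.
#'
#' @param ds An \code{rx_survey}.
#' @param exposures Output of \code{\link{person_exposures}}.
#' @param current_only Use only current conditions for the dummy block.
#' @return data.table with outcomes, demographics, exposure fractions and the
#'   condition dummy block; condition column names in attribute
#'   \code{"condition_cols"}.
#' @export
build_analysis_data <- function(ds, exposures, current_only = TRUE) {
  stopifnot(inherits(ds, "rx_survey"))
  af <- merge(as.data.table(exposures), ds$persons, by = c("person_id", "year"))
  cnd <- ds$conditions
  if (current_only) cnd <- cnd[is_current == 1L]
  codes <- sort(unique(cnd$icd10_3))
  cc <- character(0)
  if (length(codes)) {
    wide <- dcast(unique(cnd[, .(person_id, year, icd10_3)]),
                  person_id + year ~ icd10_3, fun.aggregate = length,
                  value.var = "icd10_3")
    setnames(wide, codes, paste0("cond_", codes))
    af <- merge(af, wide, by = c("person_id", "year"), all.x = TRUE)
    cc <- paste0("cond_", codes)
    for (v in cc) set(af, which(is.na(af[[v]])), v, 0L)
  }
  setattr(af, "condition_cols", cc)
  af
}

#' Specify an exposure-outcome regression model
#'
#' Declares the outcome, the exposure fractions of interest and the control
#' set: the condition dummy block, sex, single-year-of-age dummies, education,
#' race, survey-year dummies, prescription-count dummies (one per distinct
#' count up to \code{rx_count_cap}, pooled above) and mean FDA approval year.
#'
#' @param outcome Outcome column name. \code{"total_expenditure"} is modelled
#'   as \code{log(total_expenditure + 1)}.
#' @param exposures Exposure columns (default the contraindicated and
#'   indicated fractions).
#' @param estimator One of \code{"lpm"}, \code{"probit"}, \code{"dml"}.
#' @param rx_count_cap Cap for the prescription-count dummy block (default 30).
#' @param controls \code{NULL} (default) for the standard survey control set
#'   described above, or an explicit character vector of control column names
#'   to use as-is (factors enter as dummy blocks, numeric columns linearly) —
#'   useful for estimator studies on bespoke data.
#' @return An \code{rx_model_spec}.
#' @export
model_spec <- function(outcome,
                       exposures = c("frac_contraindicated", "frac_indicated"),
                       estimator = c("lpm", "probit", "dml"),
                       rx_count_cap = 30L, controls = NULL) {
  estimator <- match.arg(estimator)
  if (outcome %in% exposures) stop("outcome must not be among the exposures")
  if (!is.null(controls) && length(intersect(controls, c(outcome, exposures)))) {
    stop("controls must be disjoint from the outcome and exposures")
  }
  structure(list(outcome = outcome, exposures = exposures,
                 estimator = estimator, rx_count_cap = as.integer(rx_count_cap),
                 controls = controls),
            class = "rx_model_spec")
}

# outcome vector on its analysis scale
.outcome_vector <- function(spec, data) {
  y <- data[[spec$outcome]]
  if (is.null(y)) stop("outcome column not found: ", spec$outcome)
  if (spec$outcome == "total_expenditure") log1p(y) else as.numeric(y)
}

# regression frame: outcome .y plus exposures and the control blocks,
# factors for the dummy blocks, constant columns dropped
.design_frame <- function(spec, data) {
  dt <- as.data.table(data)
  if (!is.null(spec$controls)) {
    miss <- setdiff(c(spec$outcome, spec$exposures, spec$controls), names(dt))
    if (length(miss)) stop("analysis data lacks column(s): ",
                           paste(miss, collapse = ", "))
    df <- data.frame(.y = .outcome_vector(spec, dt))
    for (v in spec$exposures) df[[v]] <- as.numeric(dt[[v]])
    for (v in spec$controls) {
      x <- dt[[v]]
      df[[v]] <- if (is.character(x) || is.factor(x)) factor(x) else
        as.numeric(x)
    }
    return(.finish_design(df, spec))
  }
  cc <- attr(data, "condition_cols")
  if (is.null(cc)) cc <- grep("^cond_", names(dt), value = TRUE)
  need <- c(spec$exposures, "sex", "age", "education", "race", "year",
            "n_rx", "mean_approval_year")
  miss <- setdiff(c(need, spec$outcome), names(dt))
  if (length(miss)) stop("analysis data lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(.y = .outcome_vector(spec, dt))
  for (v in spec$exposures) df[[v]] <- as.numeric(dt[[v]])
  df$mean_approval_year <- as.numeric(dt$mean_approval_year)
  df$sex <- factor(dt$sex)
  df$age <- factor(dt$age)
  df$education <- factor(dt$education)
  df$race <- factor(dt$race)
  df$year <- factor(dt$year)
  df$n_rx <- factor(pmin(as.integer(dt$n_rx), spec$rx_count_cap))
  for (v in cc) df[[v]] <- as.numeric(dt[[v]])
  .finish_design(df, spec)
}

.finish_design <- function(df, spec) {
  # single-level factors and constant dummies carry no information
  keep <- vapply(df, function(x) {
    if (is.factor(x)) nlevels(droplevels(x)) > 1L else sd(x) > 0 || identical(x, df$.y)
  }, logical(1))
  keep[c(".y", spec$exposures)] <- TRUE
  df <- df[, keep, drop = FALSE]
  for (v in names(df)) if (is.factor(df[[v]])) df[[v]] <- droplevels(df[[v]])
  df
}

.check_rank <- function(fit) {
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[aliased], collapse = ", "))
  }
}

.result_row <- function(spec, estimator, exposure, est, se, df_resid, ymean,
                        use_t = TRUE) {
  tval <- est / se
  pval <- if (use_t) 2 * pt(-abs(tval), df_resid) else 2 * pnorm(-abs(tval))
  crit <- if (use_t) qt(0.975, df_resid) else qnorm(0.975)
  data.table(outcome = spec$outcome, estimator = estimator,
             exposure = exposure, estimate = est, std_error = se,
             t_value = tval, p_value = pval,
             ci_low = est - crit * se, ci_high = est + crit * se,
             mean_percentage = 100 * est / ymean)
}

#' Linear probability / linear model with robust standard errors
#'
#' Ordinary least squares of the outcome on the exposure fractions and the
#' full control set, with heteroskedasticity-robust (HC1 sandwich) standard
#' errors. For binary outcomes this is the linear probability model. The
#' "mean percentage" column expresses each coefficient as a percentage of the
#' outcome's sample mean.
#'
#' @param spec An \code{rx_model_spec}.
#' @param data Analysis frame from \code{\link{build_analysis_data}}.
#' @return data.table with one row per exposure: estimate, std_error, t_value,
#'   p_value, 95\% ci_low/ci_high, mean_percentage; attributes \code{n} and
#'   \code{r_squared}.
#' @export
fit_lpm <- function(spec, data) {
  stopifnot(inherits(spec, "rx_model_spec"))
  df <- .design_frame(spec, data)
  fit <- lm(.y ~ ., data = df)
  .check_rank(fit)
  # HC1 does not use hat values; meatHC's near-singularity warning about
  # hat values of 1 (single-observation dummy cells) is not relevant to it
  V <- withCallingHandlers(
    sandwich::vcovHC(fit, type = "HC1"),
    warning = function(w) {
      if (grepl("hat values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ymean <- mean(df$.y)
  out <- rbindlist(lapply(spec$exposures, function(e) {
    .result_row(spec, "lpm", e, coef(fit)[[e]], sqrt(V[e, e]),
                fit$df.residual, ymean)
  }))
  setattr(out, "n", nrow(df))
  setattr(out, "r_squared", summary(fit)$r.squared)
  out[]
}

# ridge-penalised probit Newton fallback for separated fits
.probit_ridge <- function(X, y, lambda = 1e-3, maxit = 50L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- pmin(pmax(pnorm(eta), 1e-10), 1 - 1e-10)
    phi <- dnorm(eta)
    score <- drop(crossprod(X, phi * (y - p) / (p * (1 - p)))) - 2 * lambda * beta
    w <- phi^2 / (p * (1 - p))
    H <- crossprod(X * sqrt(w)) + diag(2 * lambda, ncol(X))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  list(coef = setNames(beta, colnames(X)), vcov = solve(H))
}

#' Probit model with average marginal effects
#'
#' Maximum-likelihood probit of a binary outcome on the exposures and control
#' set. The reported estimate for each exposure is its average marginal
#' effect (the mean of dnorm(x'b) * b_j over the sample), with delta-method
#' standard errors, so results are on the same scale as the linear
#' probability model. Complete or quasi-complete separation triggers a
#' warning and a ridge-penalised refit, flagged in attribute
#' \code{"penalised"}.
#'
#' @inheritParams fit_lpm
#' @return data.table with one row per exposure (average marginal effects).
#' @export
fit_probit <- function(spec, data) {
  stopifnot(inherits(spec, "rx_model_spec"))
  df <- .design_frame(spec, data)
  if (length(unique(df$.y)) < 2L || !all(df$.y %in% c(0, 1))) {
    stop("probit requires a non-degenerate binary outcome; got values: ",
         paste(head(unique(df$.y)), collapse = ", "))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(link = "probit")),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  X <- model.matrix(fit)
  if (separation) {
    warning("separation detected; using ridge-penalised probit fallback")
    pen <- .probit_ridge(X, df$.y)
    b <- pen$coef; V <- pen$vcov
  } else {
    .check_rank(fit)
    b <- coef(fit); V <- vcov(fit)
  }
  eta <- drop(X %*% b)
  phi <- dnorm(eta)
  mean_phi <- mean(phi)
  ymean <- mean(df$.y)
  out <- rbindlist(lapply(spec$exposures, function(e) {
    j <- match(e, names(b))
    ame <- mean_phi * b[[j]]
    # delta method: d(ame)/d(b_k) = mean(-eta phi x_k) b_j + 1{k=j} mean(phi)
    g <- drop(crossprod(X, -eta * phi)) / nrow(X) * b[[j]]
    g[j] <- g[j] + mean_phi
    se <- sqrt(drop(t(g) %*% V %*% g))
    .result_row(spec, "probit", e, ame, se, Inf, ymean, use_t = FALSE)
  }))
  setattr(out, "n", nrow(df))
  setattr(out, "penalised", separation)
  out[]
}

.learner_fit_predict <- function(learner, Xtr, ytr, Xte, seed,
                                 num_trees, max_depth) {
  if (learner == "random_forest") {
    dtr <- data.frame(Xtr); dtr$.y <- ytr
    fit <- ranger::ranger(.y ~ ., data = dtr, num.trees = num_trees,
                          seed = seed, num.threads = 1L,
                          respect.unordered.factors = TRUE)
    predict(fit, data.frame(Xte), num.threads = 1L)$predictions
  } else if (learner == "regression_tree") {
    dtr <- data.frame(Xtr); dtr$.y <- ytr
    fit <- rpart::rpart(.y ~ ., data = dtr, method = "anova",
                        control = rpart::rpart.control(maxdepth = max_depth,
                                                       cp = 1e-4,
                                                       xval = 0L))
    predict(fit, data.frame(Xte))
  } else { # linear
    qr_fit <- qr(cbind(1, Xtr))
    cf <- qr.coef(qr_fit, ytr)
    cf[is.na(cf)] <- 0
    drop(cbind(1, Xte) %*% cf)
  }
}

#' Double machine learning for the partially linear model
#'
#' Estimates the exposure coefficient theta in Y = theta D + g(X) + e by
#' K-fold cross-fitting with the Neyman-orthogonal partialling-out score: the
#' nuisance regressions E[Y|X] and E[D|X] are learned out-of-fold, residuals
#' u = Y - l(X) and v = D - m(X) are formed, and theta = sum(v u) / sum(v^2)
#' with influence-function standard errors. Each exposure is estimated in
#' turn, with the other exposure included among the controls X. With
#' \code{n_folds = 1} the nuisances are fit in-sample (useful for exact
#' comparisons against partialled-out OLS when \code{learner = "linear"}).
#'
#' @inheritParams fit_lpm
#' @param learner Nuisance learner: \code{"random_forest"} (ranger),
#'   \code{"regression_tree"} (rpart, depth-limited) or \code{"linear"}.
#' @param n_folds Number of cross-fitting folds (default 5).
#' @param seed Seed controlling fold assignment and learner randomness
#'   (default 20160101).
#' @param num_trees Trees for the forest learner (default 500).
#' @param max_depth Depth cap for the tree learner (default 8).
#' @return data.table with one row per exposure.
#' @export
fit_dml_plr <- function(spec, data, learner = c("random_forest",
                                                "regression_tree", "linear"),
                        n_folds = 5L, seed = 20160101, num_trees = 500L,
                        max_depth = 8L) {
  stopifnot(inherits(spec, "rx_model_spec"))
  learner <- match.arg(learner)
  df <- .design_frame(spec, data)
  if (nrow(df) < 10L * max(n_folds, 1L)) {
    stop("n must be at least 10 x n_folds")
  }
  y <- df$.y
  n <- length(y)
  X_all <- model.matrix(~ . - 1, data = df[, setdiff(names(df), ".y"),
                                           drop = FALSE])
  set.seed(seed)
  ymean <- mean(y)
  out <- rbindlist(lapply(spec$exposures, function(e) {
    d <- df[[e]]
    Xc <- X_all[, setdiff(colnames(X_all), e), drop = FALSE]
    for (attempt in 1:3) {
      folds <- if (n_folds <= 1L) rep(1L, n) else
        sample(rep(seq_len(n_folds), length.out = n))
      u <- v <- numeric(n)
      ok <- TRUE
      for (k in sort(unique(folds))) {
        te <- folds == k
        tr <- if (n_folds <= 1L) te else !te
        lhat <- .learner_fit_predict(learner, Xc[tr, , drop = FALSE], y[tr],
                                     Xc[te, , drop = FALSE],
                                     seed + k + 100L * attempt,
                                     num_trees, max_depth)
        mhat <- .learner_fit_predict(learner, Xc[tr, , drop = FALSE], d[tr],
                                     Xc[te, , drop = FALSE],
                                     seed + k + 100L * attempt + 7L,
                                     num_trees, max_depth)
        u[te] <- y[te] - lhat
        v[te] <- d[te] - mhat
        if (sd(v[te]) == 0) { ok <- FALSE; break }
      }
      if (ok) break
      if (attempt == 3L) stop("constant residualised exposure '", e,
                              "' in a fold after 3 fold splits")
    }
    theta <- sum(v * u) / sum(v^2)
    psi <- (u - theta * v) * v
    se <- sqrt(mean(psi^2) / n) / mean(v^2)
    .result_row(spec, "dml", e, theta, se, Inf, ymean, use_t = FALSE)
  }))
  setattr(out, "n", n)
  setattr(out, "learner", learner)
  out[]
}

#' Summarise estimation results across outcomes and estimators
#'
#' Stacks estimate tables into one report (estimate, SE, t, p, CI bounds,
#' mean percentage per outcome-exposure pair) with a cross-estimator
#' comparison block of estimates and their signs.
#'
#' @param results A list of estimate tables (from \code{\link{fit_lpm}},
#'   \code{\link{fit_probit}}, \code{\link{fit_dml_plr}}) or a single table.
#' @return An \code{rx_model_summary}: list with \code{table} (stacked rows)
#'   and \code{comparison} (wide by estimator, with a sign-agreement flag).
#' @export
summarize_models <- function(results) {
  if (inherits(results, "data.frame")) results <- list(results)
  if (!length(results)) stop("no estimation results to summarise")
  tab <- rbindlist(results, use.names = TRUE)
  if (!nrow(tab)) stop("no estimation results to summarise")
  cmp <- dcast(tab, outcome + exposure ~ estimator, value.var = "estimate")
  est_cols <- setdiff(names(cmp), c("outcome", "exposure"))
  cmp[, sign_agreement := apply(sign(as.matrix(.SD)), 1L,
                                function(s) length(unique(s[!is.na(s)])) == 1L),
      .SDcols = est_cols]
  structure(list(table = tab[], comparison = cmp[]),
            class = "rx_model_summary")
}

#' @export
print.rx_model_summary <- function(x, ...) {
  cat("Model estimates\n")
  print(x$table, digits = 4)
  cat("\nCross-estimator comparison (estimates)\n")
  print(x$comparison, digits = 4)
  invisible(x)
}
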