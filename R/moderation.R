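## Moderated regression layer: standardization, Cook's-distance screening,
## OLS with an age x segregation interaction, Johnson-Neyman regions of
## significance, and the batch of study models.

#' Standardize a numeric vector
#'
#' `(x - mean) / sd` with the sample SD (n-1 denominator), returning the
#' scaling so values can be mapped back to raw units.
#'
#' @param x numeric vector.
#' @return list with `z` (standardized values), `mean`, `sd`.
#' @export
standardize <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("cannot standardize a constant vector")
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Fit a moderated OLS regression on standardized predictors
#'
#' Standardizes the focal predictor, the moderator and any covariates
#' (sample SD), forms the interaction as the elementwise product of the
#' standardized focal and moderator columns, and fits
#' `y ~ focal + moderator + focal:moderator + covariates` by least squares.
#'
#' @param data data.frame.
#' @param outcome,focal,moderator column names; `focal` is the predictor
#'   whose conditional slope is probed (e.g. network segregation),
#'   `moderator` the variable it is probed along (e.g. age).
#' @param covariates character vector of covariate column names (standardized
#'   too), or `NULL`.
#' @return a [ModerationFit-class].
#' @export
fitModeration <- function(data, outcome, focal, moderator,
                          covariates = NULL) {
  cols <- c(outcome, focal, moderator, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stopf("missing column(s): %s", paste(miss, collapse = ", "))
  keep <- complete.cases(data[, cols, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  preds <- c(focal, moderator, covariates)
  scaling <- data.frame(variable = preds, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  X <- list()
  for (i in seq_along(preds)) {
    st <- standardize(data[[preds[i]]])
    scaling$mean[i] <- st$mean
    scaling$sd[i] <- st$sd
    X[[preds[i]]] <- st$z
  }
  intName <- paste0(focal, ":", moderator)
  df <- as.data.frame(X, check.names = FALSE)
  df[[intName]] <- df[[focal]] * df[[moderator]]
  df[[outcome]] <- data[[outcome]]
  fml <- stats::as.formula(paste0(
    "`", outcome, "` ~ ", paste(sprintf("`%s`", c(preds, intName)),
                                collapse = " + ")))
  fit <- lm(fml, data = df)
  p <- length(coef(fit))
  if (n <= p) stopf("n (%d) must exceed number of parameters (%d)", n, p)
  if (any(is.na(coef(fit)))) stopf("rank-deficient design")
  cf <- coef(fit)
  names(cf) <- sub("^`|`$", "", gsub("`", "", names(cf)))
  V <- vcov(fit)
  dimnames(V) <- list(names(cf), names(cf))
  new("ModerationFit",
      coefficients = cf,
      se = sqrt(diag(V)),
      vcovMat = V,
      df = fit$df.residual,
      sigma2 = sum(fit$residuals^2) / fit$df.residual,
      scaling = scaling,
      terms = list(focal = focal, moderator = moderator,
                   interaction = intName,
                   covariates = if (is.null(covariates)) character()
                                else covariates,
                   modRangeZ = range(df[[moderator]])),
      lmFit = fit)
}

#' Coefficient table of a ModerationFit
#'
#' @param fit a [ModerationFit-class].
#' @return data.frame: term, estimate, se, t, p, df.
#' @export
coefTable <- function(fit) {
  est <- fit@coefficients
  se <- fit@se
  tv <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(tv),
             p = unname(2 * pt(abs(tv), fit@df, lower.tail = FALSE)),
             df = fit@df, stringsAsFactors = FALSE)
}

#' Cook's-distance influence screening
#'
#' Fits the screening regression (by default the simple age-on-composite
#' model), computes each subject's Cook's distance, and flags those exceeding
#' `4 / n`. Screening is applied once — the retained set is then used for all
#' downstream analyses, without iterating.
#'
#' @param data data.frame with a `subject_id` column.
#' @param outcome,predictors column names of the screening model
#'   (`predictors` may list several; default is a single predictor model).
#' @return a [InfluenceReport-class].
#' @export
cooksScreen <- function(data, outcome = "composite", predictors = "age") {
  fml <- stats::as.formula(paste0(
    "`", outcome, "` ~ ", paste(sprintf("`%s`", predictors),
                                collapse = " + ")))
  fit <- lm(fml, data = data)
  d <- cooks.distance(fit)
  # an exact fit has zero residual variance; no point is influential then
  if (sum(fit$residuals^2) <= 1e-12 * max(1, sum(fit$fitted.values^2)))
    d[] <- 0
  ids <- if ("subject_id" %in% names(data)) as.character(data$subject_id)
         else as.character(seq_len(nrow(data)))
  names(d) <- ids
  thr <- 4 / nrow(data)
  new("InfluenceReport", distances = d, threshold = thr,
      removed = ids[d > thr])
}

#' Apply an influence report to a subject table
#'
#' @param data data.frame with `subject_id`.
#' @param report a [InfluenceReport-class].
#' @return `data` without the removed subjects.
#' @export
applyScreen <- function(data, report) {
  data[!(data$subject_id %in% report@removed), , drop = FALSE]
}

#' Johnson-Neyman region of significance
#'
#' For the moderated fit `y = b0 + b1*focal + b2*mod + b3*focal*mod + ...`,
#' the conditional slope of the focal predictor at moderator value `m`
#' (standardized units) is `theta(m) = b1 + b3*m` with variance
#' `V(m) = Var(b1) + 2m*Cov(b1,b3) + m^2*Var(b3)`. Boundaries of the region
#' where `|theta| / sqrt(V)` exceeds the two-sided critical t at the
#' residual df are the real roots of
#' `(b3^2 - t^2 Var(b3)) m^2 + 2 (b1 b3 - t^2 Cov(b1,b3)) m +
#'  (b1^2 - t^2 Var(b1)) = 0`.
#' Boundaries are mapped back to raw moderator units (years) via the stored
#' standardization and intersected with the observed moderator range.
#'
#' @param fit a [ModerationFit-class].
#' @param alpha two-sided significance level (default 0.05).
#' @param observedRange optional raw-unit moderator range; defaults to the
#'   range of the moderator in the fitted data.
#' @return a [JNRegion-class].
#' @export
johnsonNeyman <- function(fit, alpha = 0.05, observedRange = NULL) {
  trm <- fit@terms
  if (is.null(trm$interaction) ||
      !(trm$interaction %in% names(fit@coefficients)))
    stopf("fit has no interaction term; Johnson-Neyman undefined")
  b1 <- fit@coefficients[[trm$focal]]
  b3 <- fit@coefficients[[trm$interaction]]
  V <- fit@vcovMat
  v1 <- V[trm$focal, trm$focal]
  v3 <- V[trm$interaction, trm$interaction]
  c13 <- V[trm$focal, trm$interaction]
  tc <- qt(1 - alpha / 2, fit@df)
  A <- b3^2 - tc^2 * v3
  B <- b1 * b3 - tc^2 * c13
  C <- b1^2 - tc^2 * v1
  sc <- fit@scaling[fit@scaling$variable == trm$moderator, ]
  toRaw <- function(mz) sc$mean + sc$sd * mz
  if (is.null(observedRange))
    observedRange <- toRaw(trm$modRangeZ)
  tstat <- function(mz) (b1 + b3 * mz) / sqrt(v1 + 2 * mz * c13 + mz^2 * v3)
  rootsZ <- numeric(0)
  if (abs(A) < 1e-14) {
    if (abs(B) > 1e-14) rootsZ <- -C / (2 * B)
  } else {
    disc <- B^2 - A * C
    if (disc >= 0) rootsZ <- sort(c((-B - sqrt(disc)) / A,
                                    (-B + sqrt(disc)) / A))
  }
  # classify significance between/around the boundaries at midpoints
  side <- if (length(rootsZ) == 0) {
    if (abs(tstat(0)) > tc) "everywhere" else "nowhere"
  } else if (length(rootsZ) == 1) {
    if (abs(tstat(rootsZ - 1)) > tc) "below" else "above"
  } else {
    mid <- mean(rootsZ)
    if (abs(tstat(mid)) > tc) "between" else "outside"
  }
  new("JNRegion",
      boundaries = toRaw(rootsZ),
      side = side, alpha = alpha,
      observedRange = as.numeric(observedRange),
      boundariesZ = rootsZ)
}

#' Run the study's regression models on a merged subject table
#'
#' The standard battery: simple age effects on the production composite and
#' on language-network and whole-brain segregation, then the two moderated
#' models (composite on age x language segregation and age x whole-brain
#' segregation) with Johnson-Neyman probing of significant interactions,
#' plus optional sensitivity refits adding covariates and per-measure fits.
#'
#' @param data merged data.frame: subject_id, age, composite,
#'   language_segregation, wholebrain_segregation, plus covariate columns.
#' @param covariates covariate names for the moderated models (default
#'   `"motion"` when present in `data`).
#' @param sensitivityCovariates extra covariates for sensitivity refits
#'   (default `"gm_volume"` when present).
#' @param perMeasure optional character vector of single-measure outcome
#'   columns to refit the moderated models on.
#' @param alpha JN significance level.
#' @param screen logical; apply Cook's-distance screening on the
#'   age-on-composite model first.
#' @return list with `results` (tidy coefficient table: model, term,
#'   estimate, se, t, p, df), `jn` (list of [JNRegion-class] by model name),
#'   `screen` (the [InfluenceReport-class] or NULL), `data` (retained rows).
#' @export
runStudyModels <- function(data,
                           covariates = intersect("motion", names(data)),
                           sensitivityCovariates =
                             intersect("gm_volume", names(data)),
                           perMeasure = NULL,
                           alpha = 0.05,
                           screen = TRUE) {
  rep0 <- NULL
  if (screen) {
    rep0 <- cooksScreen(data)
    data <- applyScreen(data, rep0)
  }
  if (length(covariates) == 0) covariates <- NULL
  results <- list()
  jn <- list()
  addFit <- function(name, fit) {
    tab <- coefTable(fit)
    tab$model <- name
    results[[name]] <<- tab[, c("model", setdiff(names(tab), "model"))]
    fit
  }
  simpleFit <- function(outcome, pred) {
    # one-predictor standardized regression via the same machinery: use the
    # predictor as focal with a constant-free design (no interaction)
    st <- standardize(data[[pred]])
    y <- data[[outcome]]
    f <- lm(y ~ st$z)
    V <- vcov(f)
    est <- coef(f)
    tv <- est / sqrt(diag(V))
    data.frame(model = paste0(outcome, " ~ ", pred),
               term = c("(Intercept)", pred),
               estimate = unname(est), se = unname(sqrt(diag(V))),
               t = unname(tv),
               p = unname(2 * pt(abs(tv), f$df.residual, lower.tail = FALSE)),
               df = f$df.residual, stringsAsFactors = FALSE)
  }
  results[["composite ~ age"]] <- simpleFit("composite", "age")
  if ("language_segregation" %in% names(data))
    results[["language_segregation ~ age"]] <-
      simpleFit("language_segregation", "age")
  if ("wholebrain_segregation" %in% names(data))
    results[["wholebrain_segregation ~ age"]] <-
      simpleFit("wholebrain_segregation", "age")
  modFits <- list()
  for (seg in intersect(c("language_segregation", "wholebrain_segregation"),
                        names(data))) {
    nm <- paste0("composite ~ age * ", seg)
    fit <- fitModeration(data, "composite", focal = seg, moderator = "age",
                         covariates = covariates)
    addFit(nm, fit)
    modFits[[nm]] <- fit
    jn[[nm]] <- johnsonNeyman(fit, alpha = alpha)
    if (length(sensitivityCovariates)) {
      nm2 <- paste0(nm, " + ", paste(sensitivityCovariates, collapse = " + "))
      fit2 <- fitModeration(data, "composite", focal = seg, moderator = "age",
                            covariates = c(covariates,
                                           sensitivityCovariates))
      addFit(nm2, fit2)
      jn[[nm2]] <- johnsonNeyman(fit2, alpha = alpha)
    }
    for (pm in perMeasure) {
      nmp <- paste0(pm, " ~ age * ", seg)
      addFit(nmp, fitModeration(data, pm, focal = seg, moderator = "age",
                                covariates = covariates))
    }
  }
  list(results = do.call(rbind, c(results, list(make.row.names = FALSE))),
       jn = jn, fits = modFits, screen = rep0, data = data)
}
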