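## small moderated dataset with known structure
makeModData <- function(n, b = c(b0 = 0, b1 = 0.4, b2 = -0.5, b3 = -0.4),
                        noise = 0.5, seed = 1) {
  set.seed(seed)
  age <- runif(n, 22, 78)
  seg <- runif(n, 0.4, 0.95)
  az <- as.numeric(scale(age)); sz <- as.numeric(scale(seg))
  y <- b[["b0"]] + b[["b1"]] * sz + b[["b2"]] * az + b[["b3"]] * sz * az +
    rnorm(n, 0, noise)
  data.frame(subject_id = paste0("s", seq_len(n)), age = age, seg = seg,
             y = y)
}

test_that("standardization matches the sample-SD convention and inverts", {
  st <- standardize(c(1, 2, 3))
  expect_equal(st$z, c(-1, 0, 1))
  expect_equal(standardize(st$z)$z, st$z) # idempotent on standardized input
  ages <- seq(22, 78, length.out = 30)
  s <- standardize(ages)
  expect_equal(s$mean + s$sd * s$z, ages, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("noiseless designs are interpolated exactly", {
  d <- makeModData(40, noise = 0)
  # lm warns that a perfect fit makes the summary unreliable; exactness is
  # the point here
  fit <- suppressWarnings(
    fitModeration(d, "y", focal = "seg", moderator = "age"))
  expect_equal(unname(coef(fit)[c("seg", "age", "seg:age")]),
               c(0.4, -0.5, -0.4), tolerance = 1e-9)
  expect_lt(fit@sigma2, 1e-20)
  # adding an irrelevant covariate leaves noiseless estimates exact
  d$junk <- rnorm(40)
  fit2 <- suppressWarnings(
    fitModeration(d, "y", focal = "seg", moderator = "age",
                  covariates = "junk"))
  expect_equal(coef(fit2)[c("seg", "age", "seg:age")],
               coef(fit)[c("seg", "age", "seg:age")], tolerance = 1e-9)
})

test_that("OLS matches an independent normal-equations solve", {
  set.seed(5)
  for (rep in 1:5) {
    d <- makeModData(12, noise = 0.8, seed = 100 + rep)
    fit <- fitModeration(d, "y", focal = "seg", moderator = "age")
    sz <- as.numeric(scale(d$seg)); az <- as.numeric(scale(d$age))
    X <- cbind(1, sz, az, sz * az)
    beta <- solve(crossprod(X), crossprod(X, d$y))
    expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-10)
    res <- d$y - X %*% beta
    s2 <- sum(res^2) / (12 - 4)
    V <- s2 * solve(crossprod(X))
    expect_equal(unname(vcov(fit)), unname(V), tolerance = 1e-10)
    expect_equal(fit@df, 8)
  }
})

test_that("fits are invariant to subject order and reject bad designs", {
  d <- makeModData(30, seed = 9)
  f1 <- fitModeration(d, "y", "seg", "age")
  f2 <- fitModeration(d[sample(30), ], "y", "seg", "age")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  d$segcopy <- d$seg
  expect_error(fitModeration(d, "y", "seg", "segcopy"), "rank")
  expect_error(fitModeration(d[1:4, ], "y", "seg", "age"), "exceed")
  expect_error(fitModeration(d, "y", "seg", "nope"), "missing")
})

test_that("Cook's distances match leave-one-out refits", {
  set.seed(77)
  for (rep in 1:6) {
    n <- 25
    d <- makeModData(n, noise = 1, seed = 200 + rep)
    scr <- cooksScreen(d, outcome = "y", predictors = "age")
    X <- cbind(1, d$age)
    expect_equal(unname(scr@distances), looCooks(X, d$y), tolerance = 1e-8)
    expect_equal(scr@threshold, 4 / n)
  }
})

test_that("a gross outlier has maximal Cook's distance and is removed", {
  set.seed(3)
  n <- 50
  age <- runif(n, 22, 78)
  y <- 2 - 0.05 * age + rnorm(n, 0, 0.1)
  y[17] <- y[17] + 8
  d <- data.frame(subject_id = paste0("s", 1:n), age = age, composite = y)
  scr <- cooksScreen(d)
  expect_equal(names(which.max(scr@distances)), "s17")
  expect_true("s17" %in% scr@removed)
  kept <- applyScreen(d, scr)
  expect_false("s17" %in% kept$subject_id)
  # duplicated identical subjects get identical distances
  d2 <- rbind(d[1:10, ], d[1:10, ])
  d2$subject_id <- paste0("r", 1:20)
  scr2 <- cooksScreen(d2)
  expect_equal(unname(scr2@distances[1:10]), unname(scr2@distances[11:20]),
               tolerance = 1e-12)
  # an exact linear relation yields zero influence everywhere
  d3 <- data.frame(subject_id = paste0("c", 1:20), age = 1:20,
                   composite = 3 + 2 * (1:20))
  expect_length(cooksScreen(d3)@removed, 0)
})

test_that("JN boundaries agree with a dense grid scan of the slope t-statistic", {
  set.seed(31)
  nBound <- 0
  for (rep in 1:40) {
    b <- c(b0 = rnorm(1, 0, 0.3), b1 = rnorm(1, 0.3, 0.4),
           b2 = rnorm(1, -0.3, 0.4), b3 = rnorm(1, 0, 0.5))
    d <- makeModData(60, b = b, noise = runif(1, 0.3, 1.2),
                     seed = 300 + rep)
    fit <- fitModeration(d, "y", "seg", "age")
    jn <- johnsonNeyman(fit, alpha = 0.05)
    trm <- fit@terms
    V <- vcov(fit)
    lo <- -6; hi <- 6
    step <- (hi - lo) / (1e5 - 1)
    ref <- gridJN(coef(fit)[[trm$focal]], coef(fit)[[trm$interaction]],
                  V[trm$focal, trm$focal],
                  V[trm$interaction, trm$interaction],
                  V[trm$focal, trm$interaction],
                  qt(0.975, fit@df), lo, hi)
    inRange <- jn@boundariesZ[jn@boundariesZ > lo & jn@boundariesZ < hi]
    expect_equal(length(inRange), length(ref))
    if (length(ref)) {
      nBound <- nBound + length(ref)
      expect_equal(sort(inRange), sort(ref), tolerance = 10 * step)
    }
  }
  expect_gt(nBound, 10) # the sweep actually exercised boundary cases
})

test_that("degenerate JN cases classify whole-range significance", {
  mkFit <- function(b1, b3, v1, v3, c13 = 0, df = 70) {
    V <- diag(c(0.1, v1, 0.1, v3))
    V[2, 4] <- V[4, 2] <- c13
    cf <- c("(Intercept)" = 0, seg = b1, age = -0.1, "seg:age" = b3)
    dimnames(V) <- list(names(cf), names(cf))
    new("ModerationFit", coefficients = cf,
        se = sqrt(diag(V)), vcovMat = V, df = df, sigma2 = 1,
        scaling = data.frame(variable = c("seg", "age"),
                             mean = c(0.7, 50), sd = c(0.1, 16)),
        terms = list(focal = "seg", moderator = "age",
                     interaction = "seg:age", covariates = character(),
                     modRangeZ = c(-1.75, 1.75)),
        lmFit = NULL)
  }
  # b3 = 0 with no interaction uncertainty: constant conditional slope,
  # significant across the whole range
  jn1 <- johnsonNeyman(mkFit(b1 = 1, b3 = 0, v1 = 0.01, v3 = 0))
  expect_length(boundaries(jn1), 0)
  expect_equal(jn1@side, "everywhere")
  # b3 = 0, b1 = 0: nowhere significant
  jn2 <- johnsonNeyman(mkFit(b1 = 0, b3 = 0, v1 = 0.01, v3 = 0))
  expect_equal(jn2@side, "nowhere")
  # boundaries are reported in raw years via the stored scaling
  jn3 <- johnsonNeyman(mkFit(b1 = 0.5, b3 = -0.4, v1 = 0.01, v3 = 0.01))
  expect_true(all(boundaries(jn3) == 50 + 16 * jn3@boundariesZ))
  expect_error(johnsonNeyman(new("ModerationFit",
                                 coefficients = c(a = 1), se = c(a = 1),
                                 vcovMat = matrix(1, 1, 1,
                                                  dimnames = list("a", "a")),
                                 df = 5, sigma2 = 1,
                                 scaling = data.frame(), terms = list(),
                                 lmFit = NULL)),
               "interaction")
})

test_that("the study battery recovers a planted low-age JN region", {
  spec <- cohortSpec(nSubjects = 200L, seed = 11L,
                     networkSizes = c(A = 4L, B = 4L, C = 4L),
                     behavCoefs = c(b_age = -0.5, b_seg = 0.45,
                                    b_int = -0.3, noise_sd = 0.7))
  co <- simulateCohort(spec, transcripts = FALSE)
  d <- co$truth
  d$composite <- d$latent_composite
  d$wholebrain_segregation <- d$true_segregation
  out <- runStudyModels(d, covariates = NULL,
                        sensitivityCovariates = NULL, screen = FALSE)
  jn <- out$jn[["composite ~ age * wholebrain_segregation"]]
  # positive segregation effect confined to the lower end of the age range
  expect_true(jnLowAgeOnly(jn))
  b1 <- boundaries(jn)[1]
  expect_gt(b1, jn@observedRange[1])
  expect_lt(b1, jn@observedRange[2])
  # and the slope at the bottom of the range is significantly positive
  expect_gt(coef(out$fits[["composite ~ age * wholebrain_segregation"]])[[
    "wholebrain_segregation"]], 0)
  # tidy results table covers the simple and moderated models
  expect_true(all(c("composite ~ age",
                    "wholebrain_segregation ~ age") %in%
                    out$results$model))
  ageRow <- subset(out$results, model == "composite ~ age" & term == "age")
  expect_lt(ageRow$estimate, 0)
  expect_lt(ageRow$p, 0.05)
})
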