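## Synthetic cohorts: block-correlated node time series whose segregation
## declines with age, plus behavioral measures tied to age and segregation
## by a planted moderated linear model.

## Default 14-network partition: 231 nodes, left-language network and its
## right-hemisphere homologue carved out of 12 canonical networks.
defaultNetworkSizes <- function() {
  c(left_language = 13L, right_homologue = 9L,
    default = 42L, frontoparietal = 22L, visual = 30L,
    somatomotor_hand = 28L, somatomotor_mouth = 5L, salience = 17L,
    cingulo_opercular = 14L, auditory = 12L, dorsal_attention = 11L,
    ventral_attention = 8L, subcortical = 12L, cerebellar = 8L)
}

#' Construct a CohortSpec
#'
#' Defaults mirror the study conditions the pipeline targets: ages 22-78,
#' 180 resting-state volumes, 231 nodes in 14 networks, and a planted
#' moderated model in which language production declines with age, improves
#' with network segregation, and the segregation benefit fades at older ages
#' (negative interaction).
#'
#' @param nSubjects number of subjects (default 90).
#' @param ageRange numeric(2), years.
#' @param nTimepoints volumes per subject.
#' @param networkSizes named integer vector of nodes per network.
#' @param rWithin baseline within-network correlation.
#' @param rBetween baseline between-network correlation at mean age.
#' @param segAgeSlope change in between-network correlation per SD of age;
#'   positive = dedifferentiation with age.
#' @param rBetweenSd subject-level SD of between-network coupling.
#' @param behavCoefs named numeric `(b_age, b_seg, b_int, noise_sd)`.
#' @param seed master seed.
#' @return a [CohortSpec-class] object.
#' @export
cohortSpec <- function(nSubjects = 90L,
                       ageRange = c(22, 78),
                       nTimepoints = 180L,
                       networkSizes = defaultNetworkSizes(),
                       rWithin = 0.30,
                       rBetween = 0.08,
                       segAgeSlope = 0.03,
                       rBetweenSd = 0.05,
                       behavCoefs = c(b_age = -0.30, b_seg = 0.20,
                                      b_int = -0.40, noise_sd = 0.7),
                       seed = 1L) {
  sizes <- setNames(as.integer(networkSizes), names(networkSizes))
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      ageRange = as.numeric(ageRange), nTimepoints = as.integer(nTimepoints),
      networkSizes = sizes, rWithin = rWithin, rBetween = rBetween,
      segAgeSlope = segAgeSlope, rBetweenSd = rBetweenSd,
      behavCoefs = behavCoefs, seed = as.integer(seed))
}

## standardize an age against the uniform moments of the spec's age range,
## so a single-subject call needs no cohort context
ageZ <- function(spec, age) {
  (age - mean(spec@ageRange)) / (diff(spec@ageRange) / sqrt(12))
}

#' Block correlation matrix for one subject
#'
#' Within-network entries are `rWithin`; between-network entries are the
#' age-shifted coupling `clamp(rBetween + segAgeSlope * age_z, 0, rWithin)`
#' (optionally overridden by `betweenValue`), with unit diagonal. If the
#' resulting matrix is not positive semi-definite it is repaired by clipping
#' negative eigenvalues at zero and re-normalizing to unit diagonal; the
#' repair is reported via a message.
#'
#' @param spec a [CohortSpec-class].
#' @param age subject age in years (standardized internally against the
#'   spec's age range).
#' @param betweenValue optional explicit between-network coupling, bypassing
#'   the age model (used for per-subject jitter).
#' @return correlation matrix with node ids `<network>_<i>` as dimnames.
#' @export
buildBlockCorrelation <- function(spec, age, betweenValue = NULL) {
  validObject(spec)
  sizes <- spec@networkSizes
  n <- sum(sizes)
  b <- if (is.null(betweenValue))
    spec@rBetween + spec@segAgeSlope * ageZ(spec, age)
  else betweenValue
  b <- clamp(b, 0, spec@rWithin)
  labels <- rep(names(sizes), sizes)
  M <- matrix(b, n, n)
  for (nw in names(sizes)) {
    idx <- which(labels == nw)
    M[idx, idx] <- spec@rWithin
  }
  diag(M) <- 1
  ids <- unlist(lapply(names(sizes), function(nw)
    paste0(nw, "_", seq_len(sizes[[nw]]))))
  dimnames(M) <- list(ids, ids)
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    M2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(M2))
    M2 <- M2 / tcrossprod(d)
    diag(M2) <- 1
    dev <- max(abs(M2 - M))
    message(sprintf(
      "block correlation repaired to PSD (eigenvalue clipping); max entry change %.2e",
      dev))
    M <- (M2 + t(M2)) / 2
    dimnames(M) <- list(ids, ids)
    ev2 <- eigen(M, symmetric = TRUE, only.values = TRUE)
    if (min(ev2$values) < -1e-8)
      stopf("correlation matrix not PSD after repair (min eigenvalue %.3e)",
            min(ev2$values))
  }
  M
}

#' Sample node time series from a correlation matrix
#'
#' Multivariate normal draws (zero mean, the given correlation), returned as
#' a nodes x time matrix. Deterministic given `seed`.
#'
#' @param corr PSD correlation matrix (dimnames become node ids).
#' @param nTimepoints number of time points (>= 2).
#' @param seed RNG seed.
#' @return nodes x time numeric matrix.
#' @export
sampleTimeseries <- function(corr, nTimepoints, seed) {
  if (nTimepoints < 2) stopf("nTimepoints must be >= 2")
  ts <- withSeed(seed, t(MASS::mvrnorm(nTimepoints, mu = rep(0, nrow(corr)),
                                       Sigma = corr)))
  rownames(ts) <- rownames(corr)
  colnames(ts) <- paste0("t", seq_len(nTimepoints))
  ts
}

## analytic segregation of the noiseless two-level block matrix: every
## network has within = z(rWithin), between = z(b), so each network's
## segregation (and the whole-brain mean) is (z(rw) - z(b)) / z(rw)
analyticSegregation <- function(rWithin, rBetween) {
  zw <- fisherZ(rWithin)
  zb <- max(fisherZ(rBetween), 0)
  (zw - zb) / zw
}

## Zipf-like token sampler: ranks 1..V with p(r) ~ 1/r
sampleZipfTokens <- function(nTokens, vocabSize) {
  p <- 1 / seq_len(vocabSize)
  ranks <- sample.int(vocabSize, nTokens, replace = TRUE, prob = p)
  paste0("w", ranks)
}

#' Generate behavioral records tied to age and segregation
#'
#' Plants the moderated linear model
#' `latent = b_age*age_z + b_seg*seg_z + b_int*age_z*seg_z + N(0, noise_sd)`
#' and derives the four observed production measures as monotone transforms
#' of the latent score plus independent noise:
#' \itemize{
#'   \item fluency count: linear transform, rounded, floored at 0, emitted as
#'     coded response tokens over the five fluency categories;
#'   \item naming RT: reverse-signed linear transform, floored at 200 ms,
#'     emitted as per-trial correct RTs;
#'   \item a transcript whose utterance lengths (shifted Poisson) and
#'     vocabulary size (Zipf-like sampling) scale with the latent score, so
#'     MLU and MATTR track it.
#' }
#' Calibration constants follow typical adult norms for these tasks
#' (fluency ~88 +/- 15 responses, naming ~1047 +/- 134 ms, MLU ~9.4,
#' MATTR ~0.66 at window 50).
#'
#' @param spec a [CohortSpec-class].
#' @param ages numeric vector of ages (years).
#' @param trueSegregation numeric vector, same length, of noiseless
#'   whole-brain segregation values.
#' @param seed RNG seed (defaults to a fan-out of the spec seed).
#' @param transcripts logical; generate transcripts and coded fluency/naming
#'   records (set `FALSE` for large Monte-Carlo runs that only need the
#'   latent outcome).
#' @return list with `truth` (data.frame: subject_id, age, age_z, seg_z,
#'   true_segregation, latent_composite, motion, gm_volume) and, when
#'   `transcripts = TRUE`, `records`: per-subject lists with `fluency`
#'   (data.frame category/token/flags), `naming` (data.frame rt_ms/correct)
#'   and `transcript` (character vector, one utterance per line).
#' @export
generateBehavior <- function(spec, ages, trueSegregation,
                             seed = fanSeed(spec@seed, 3L),
                             transcripts = TRUE) {
  stopifnot(length(ages) == length(trueSegregation))
  if (spec@behavCoefs[["noise_sd"]] < 0) stopf("noise_sd must be >= 0")
  n <- length(ages)
  b <- spec@behavCoefs
  withSeed(seed, {
    az <- if (sd(ages) > 0) as.numeric(scale(ages)) else rep(0, n)
    sz <- if (sd(trueSegregation) > 0) as.numeric(scale(trueSegregation))
          else rep(0, n)
    latent <- b[["b_age"]] * az + b[["b_seg"]] * sz +
      b[["b_int"]] * az * sz + rnorm(n, 0, b[["noise_sd"]])
    motion <- pmax(0.02, 0.20 + 0.04 * az + rnorm(n, 0, 0.06))
    gm <- 650 + 60 * (-0.8 * az + rnorm(n, 0, 0.6))
    truth <- data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      age = ages, age_z = az, seg_z = sz,
      true_segregation = trueSegregation,
      latent_composite = latent, motion = motion, gm_volume = gm,
      stringsAsFactors = FALSE)
    records <- NULL
    if (transcripts) {
      records <- lapply(seq_len(n), function(i) {
        flTotal <- max(0L, as.integer(round(88 + 10 * latent[i] +
                                              rnorm(1, 0, 6))))
        cats <- c("F", "A", "S", "animals", "supermarkets")
        perCat <- tabulate(sample.int(5L, flTotal, replace = TRUE), 5L)
        fluency <- do.call(rbind, lapply(seq_along(cats), function(k) {
          if (perCat[k] == 0) return(NULL)
          data.frame(category = cats[k],
                     token = paste0(tolower(cats[k]), "_item",
                                    seq_len(perCat[k])),
                     repetition = FALSE, proper_name = FALSE,
                     error = FALSE, mythical_animal = FALSE,
                     stringsAsFactors = FALSE)
        }))
        rtMean <- max(200, 1047 - 90 * latent[i] + rnorm(1, 0, 40))
        nTrial <- 40L
        naming <- data.frame(
          rt_ms = pmax(200, rnorm(nTrial, rtMean, 120)),
          correct = TRUE)
        nUtt <- 30L
        lens <- 1L + rpois(nUtt, pmax(0.3, 8.4 + 1.6 * latent[i]))
        vocab <- max(30L, as.integer(round(180 * (1 + 0.25 * latent[i]))))
        transcript <- vapply(lens, function(L)
          paste(sampleZipfTokens(L, vocab), collapse = " "), character(1))
        list(fluency = fluency, naming = naming, transcript = transcript)
      })
      names(records) <- truth$subject_id
    }
    list(truth = truth, records = records)
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws ages uniformly over the spec's age range, gives each subject a
#' between-network coupling `rBetween + segAgeSlope * age_z + N(0,
#' rBetweenSd)` (clamped to `[0, rWithin]`), records the analytic whole-brain
#' segregation of the noiseless matrix as ground truth, plants the behavioral
#' model on it, and optionally samples node time series from each subject's
#' block correlation matrix.
#'
#' @param spec a [CohortSpec-class].
#' @param timeseries logical; sample per-subject node time series (the
#'   expensive part; skip for behavioral-only Monte-Carlo).
#' @param transcripts logical; passed to [generateBehavior()].
#' @param outDir optional directory; when given, writes per-subject
#'   time-series TSVs, `cohort.csv`, `truth.csv` and transcript files there.
#' @return list with `truth` (ground-truth table including per-subject
#'   between coupling), `records` (behavioral records or NULL), `timeseries`
#'   (named list of nodes x time matrices or NULL), `partition` (named
#'   network label per node id) and `spec`.
#' @export
simulateCohort <- function(spec, timeseries = FALSE, transcripts = TRUE,
                           outDir = NULL) {
  validObject(spec)
  n <- spec@nSubjects
  ages <- withSeed(fanSeed(spec@seed, 1L),
                   runif(n, spec@ageRange[1], spec@ageRange[2]))
  az <- ageZ(spec, ages)
  bSubj <- withSeed(fanSeed(spec@seed, 2L),
                    clamp(spec@rBetween + spec@segAgeSlope * az +
                            rnorm(n, 0, spec@rBetweenSd),
                          0, spec@rWithin))
  trueSeg <- vapply(bSubj, function(b)
    analyticSegregation(spec@rWithin, b), numeric(1))
  beh <- generateBehavior(spec, ages, trueSeg, transcripts = transcripts)
  truth <- beh$truth
  truth$r_between_subj <- bSubj
  labels <- rep(names(spec@networkSizes), spec@networkSizes)
  ids <- unlist(lapply(names(spec@networkSizes), function(nw)
    paste0(nw, "_", seq_len(spec@networkSizes[[nw]]))))
  partition <- setNames(labels, ids)
  tsList <- NULL
  if (timeseries) {
    tsList <- lapply(seq_len(n), function(i) {
      corr <- buildBlockCorrelation(spec, ages[i], betweenValue = bSubj[i])
      sampleTimeseries(corr, spec@nTimepoints, fanSeed(spec@seed, 4L, i))
    })
    names(tsList) <- truth$subject_id
  }
  out <- list(truth = truth, records = beh$records, timeseries = tsList,
              partition = partition, spec = spec)
  if (!is.null(outDir)) writeCohort(out, outDir)
  out
}

#' Write a simulated cohort to disk
#'
#' Lays out the external interface of the generator: per-subject node-by-time
#' TSVs (`ts/<subject>.tsv`), a cohort table (`cohort.csv`), the ground-truth
#' table (`truth.csv`) and one transcript per subject
#' (`transcripts/<subject>.txt`, one utterance per line), plus coded fluency
#' and naming CSVs.
#'
#' @param cohort output of [simulateCohort()].
#' @param outDir output directory (created if missing).
#' @return `outDir`, invisibly.
#' @export
writeCohort <- function(cohort, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohort$truth
  write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
  cohortTab <- truth[, c("subject_id", "age", "motion", "gm_volume")]
  if (!is.null(cohort$records)) {
    tdir <- file.path(outDir, "transcripts")
    dir.create(tdir, showWarnings = FALSE)
    fl <- list(); nm <- list()
    for (sid in names(cohort$records)) {
      rec <- cohort$records[[sid]]
      writeLines(rec$transcript, file.path(tdir, paste0(sid, ".txt")))
      if (!is.null(rec$fluency) && nrow(rec$fluency))
        fl[[sid]] <- cbind(subject_id = sid, rec$fluency)
      nm[[sid]] <- cbind(subject_id = sid, trial = seq_len(nrow(rec$naming)),
                         rec$naming)
    }
    write.csv(do.call(rbind, fl), file.path(outDir, "fluency.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, nm), file.path(outDir, "naming.csv"),
              row.names = FALSE)
    cohortTab$transcript_path <-
      file.path("transcripts", paste0(truth$subject_id, ".txt"))
  }
  write.csv(cohortTab, file.path(outDir, "cohort.csv"), row.names = FALSE)
  if (!is.null(cohort$timeseries)) {
    tsdir <- file.path(outDir, "ts")
    dir.create(tsdir, showWarnings = FALSE)
    for (sid in names(cohort$timeseries))
      writeTimeseriesTSV(cohort$timeseries[[sid]],
                         file.path(tsdir, paste0(sid, ".tsv")))
  }
  invisible(outDir)
}
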