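## Language production measures: verbal fluency scoring, picture-naming RT,
## mean length of utterance, moving-average type-token ratio, and the
## four-measure z-score composite.

fluencyCategories <- c("F", "A", "S", "animals", "supermarkets")

## lowercase + strip leading/trailing punctuation
normalizeToken <- function(tok) {
  tok <- tolower(tok)
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", tok)
}

#' Verbal fluency total score
#'
#' Counts valid responses over the five fluency categories (phonemic F, A, S
#' and categorical animals, supermarkets). Tokens flagged as errors or proper
#' names are excluded; exact repetitions (case-insensitive, after punctuation
#' stripping) after the first occurrence within a category are excluded;
#' mythical animals count as correct in the animals category even when
#' coded as errors.
#'
#' @param responses data.frame with columns `category`, `token` and logical
#'   flag columns `proper_name`, `error`, `mythical_animal` (missing flag
#'   columns are treated as all-FALSE).
#' @return integer total of included responses across categories.
#' @export
fluencyTotal <- function(responses) {
  if (is.null(responses) || nrow(responses) == 0) return(0L)
  for (fl in c("proper_name", "error", "mythical_animal"))
    if (!(fl %in% names(responses))) responses[[fl]] <- FALSE
  bad <- !(responses$category %in% fluencyCategories)
  if (any(bad))
    stopf("unknown fluency category label(s): %s",
          paste(unique(responses$category[bad]), collapse = ", "))
  total <- 0L
  for (cat in unique(responses$category)) {
    sub <- responses[responses$category == cat, , drop = FALSE]
    keep <- !sub$proper_name &
      (!sub$error | (cat == "animals" & sub$mythical_animal))
    sub <- sub[keep, , drop = FALSE]
    norm <- normalizeToken(sub$token)
    total <- total + sum(!duplicated(norm))
  }
  as.integer(total)
}

#' Mean picture-naming reaction time
#'
#' Arithmetic mean RT over trials flagged correct.
#'
#' @param trials data.frame with columns `rt_ms` (> 0) and `correct`
#'   (logical).
#' @return numeric(1), mean RT in ms.
#' @export
namingRT <- function(trials) {
  stopifnot(all(trials$rt_ms > 0))
  ok <- as.logical(trials$correct)
  if (!any(ok)) stopf("no correct naming trials; mean RT undefined")
  mean(trials$rt_ms[ok])
}

#' Mean length of utterance (MLU)
#'
#' Total morphemes divided by the number of utterances. Tokens without a
#' morpheme code count as one morpheme.
#'
#' @param transcript character vector, one utterance per element, tokens
#'   separated by whitespace; or a list of token vectors.
#' @param morphemes optional list (same length) of per-token morpheme
#'   counts; `NULL` entries default to 1 per token.
#' @return numeric(1), morphemes per utterance.
#' @export
mlu <- function(transcript, morphemes = NULL) {
  utts <- if (is.character(transcript))
    strsplit(trimws(transcript), "\\s+") else transcript
  utts <- lapply(utts, function(u) u[nzchar(u)])
  utts <- utts[lengths(utts) > 0]
  if (length(utts) == 0) stopf("empty transcript; MLU undefined")
  total <- 0
  for (i in seq_along(utts)) {
    m <- if (!is.null(morphemes) && !is.null(morphemes[[i]]))
      morphemes[[i]] else rep(1, length(utts[[i]]))
    if (length(m) != length(utts[[i]]))
      stopf("utterance %d: %d morpheme codes for %d tokens",
            i, length(m), length(utts[[i]]))
    total <- total + sum(m)
  }
  total / length(utts)
}

#' Moving-average type-token ratio (MATTR)
#'
#' Slides a fixed window (default 50 tokens, stride 1) over the token
#' sequence, computes each window's type-token ratio (distinct types /
#' window size), and averages over all windows — a length-invariant index of
#' lexical diversity. Tokens are compared case-insensitively after stripping
#' leading/trailing punctuation. For texts shorter than the window the
#' whole-text TTR is returned with a warning.
#'
#' @param tokens character vector of tokens (or a transcript whose elements
#'   are whitespace-split first).
#' @param window window length in tokens (default 50).
#' @return numeric(1) in `(0, 1]`.
#' @export
mattr <- function(tokens, window = 50L) {
  if (window < 1) stopf("window must be >= 1")
  if (length(tokens) && any(grepl("\\s", tokens)))
    tokens <- unlist(strsplit(tokens, "\\s+"))
  tokens <- normalizeToken(tokens)
  tokens <- tokens[tokens != ""]
  L <- length(tokens)
  if (L == 0) stopf("no tokens; MATTR undefined")
  if (L < window) {
    warnf("text length %d < window %d; returning whole-text TTR", L, window)
    return(length(unique(tokens)) / L)
  }
  f <- as.integer(factor(tokens))
  counts <- integer(max(f))
  types <- 0L
  ttrSum <- 0
  for (t in seq_len(L)) {
    ft <- f[t]
    if (counts[ft] == 0L) types <- types + 1L
    counts[ft] <- counts[ft] + 1L
    if (t >= window) {
      ttrSum <- ttrSum + types / window
      fo <- f[t - window + 1L]
      counts[fo] <- counts[fo] - 1L
      if (counts[fo] == 0L) types <- types - 1L
    }
  }
  ttrSum / (L - window + 1)
}

#' Production measures for a cohort
#'
#' Applies the four measures to per-subject behavioral records.
#'
#' @param records named list (by subject id); each element has `fluency`
#'   (data.frame for [fluencyTotal()]), `naming` (data.frame for
#'   [namingRT()]) and `transcript` (character vector of utterances).
#' @param window MATTR window length.
#' @return data.frame: subject_id, fluency_total, naming_rt, mlu, mattr.
#' @export
productionMeasures <- function(records, window = 50L) {
  out <- lapply(names(records), function(sid) {
    r <- records[[sid]]
    data.frame(subject_id = sid,
               fluency_total = fluencyTotal(r$fluency),
               naming_rt = namingRT(r$naming),
               mlu = mlu(r$transcript),
               mattr = mattr(r$transcript, window),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Language production composite score
#'
#' Z-scores each of the four measures across the cohort (sample SD, n-1),
#' reverse-codes naming RT by negating its z-score so that higher always
#' means better, and sums the four z-scores.
#'
#' @param measures data.frame with columns `subject_id`, `fluency_total`,
#'   `naming_rt`, `mlu`, `mattr`.
#' @return the input with added columns `z_fluency`, `z_naming_reversed`,
#'   `z_mlu`, `z_mattr`, `composite`.
#' @export
compositeScores <- function(measures) {
  need <- c("fluency_total", "naming_rt", "mlu", "mattr")
  miss <- setdiff(need, names(measures))
  if (length(miss))
    stopf("measures table missing column(s): %s", paste(miss, collapse = ", "))
  zcol <- function(x, nm) {
    if (sd(x) == 0) stopf("measure %s is constant; z-score undefined", nm)
    as.numeric(scale(x))
  }
  measures$z_fluency <- zcol(measures$fluency_total, "fluency_total")
  measures$z_naming_reversed <- -zcol(measures$naming_rt, "naming_rt")
  measures$z_mlu <- zcol(measures$mlu, "mlu")
  measures$z_mattr <- zcol(measures$mattr, "mattr")
  measures$composite <- measures$z_fluency + measures$z_naming_reversed +
    measures$z_mlu + measures$z_mattr
  measures
}
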