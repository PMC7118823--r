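#' Score a train/validation/test split for confound balance
#'
#' The balance score of a 60/20/20 partition is the sum of five standard
#' deviations taken across the three partitions:
#' \enumerate{
#'   \item the male fraction (males / (males + females); samples of unknown
#'     sex excluded from the denominator),
#'   \item the standard deviation of overall-survival time,
#'   \item the mean of overall-survival time,
#'   \item the deceased fraction,
#'   \item for each tumor-stage level, the SD across partitions of that
#'     level's fraction, summed over levels.
#' }
#' A score of 0 means the three partitions have identical statistics; split
#' selection minimizes this score. Stage or sex levels absent from a
#' partition enter as observed fractions of 0 (never an error).
#'
#' @param split A [CohortSplit-class] (component scores may be unset).
#' @param cohort The [SurvCohort-class] the indices refer to.
#' @return The split with `balanceScore` and `componentScores` filled in.
#' @export
scoreSplit <- function(split, cohort) {
  stopifnot(is(split, "CohortSplit"), is(cohort, "SurvCohort"))
  parts <- list(split@train, split@validation, split@test)
  if (any(lengths(parts) == 0)) stop("empty partition")
  time <- survTime(cohort); event <- survEvent(cohort)
  sex <- sampleSex(cohort); stage <- tumorStage(cohort)

  sdAcross <- function(f) stats::sd(vapply(parts, f, numeric(1)))
  maleFrac <- function(idx) {
    s <- sex[idx]; known <- s %in% c("male", "female")
    if (!any(known)) return(0)
    mean(s[known] == "male")
  }
  comp <- c(
    sex_ratio = sdAcross(maleFrac),
    os_sd = sdAcross(function(idx) stats::sd(time[idx])),
    os_mean = sdAcross(function(idx) mean(time[idx])),
    deceased_fraction = sdAcross(function(idx) mean(event[idx])))
  lvls <- unique(stage[!is.na(stage)])
  stageComp <- if (length(lvls)) {
    sum(vapply(lvls, function(l)
      sdAcross(function(idx) mean(stage[idx] == l, na.rm = TRUE)), numeric(1)))
  } else 0
  comp <- c(comp, stage_composition = stageComp)
  comp[is.na(comp)] <- 0   # single-sample partitions have undefined SDs
  split@componentScores <- comp
  split@balanceScore <- sum(comp)
  split
}

# one random 60/20/20 partition of n samples
.randomSplit <- function(n) {
  perm <- sample.int(n)
  nTrain <- round(0.6 * n); nVal <- round(0.2 * n)
  new("CohortSplit",
      train = sort(perm[seq_len(nTrain)]),
      validation = sort(perm[nTrain + seq_len(nVal)]),
      test = sort(perm[(nTrain + nVal + 1):n]),
      balanceScore = NA_real_, componentScores = numeric())
}

#' Select confound-balanced cohort splits
#'
#' Draws `nShuffles` seeded random 60/20/20 partitions (train =
#' round(0.6 n), validation = round(0.2 n), test = the remainder), scores
#' each with [scoreSplit()], and returns the `nKeep` lowest-scoring splits
#' sorted ascending by score. Repeating the survival experiment on each
#' retained split gives the per-cancer folds.
#'
#' @param cohort A [SurvCohort-class] with at least 10 samples.
#' @param nShuffles Number of random partitions scored (default 1000).
#' @param nKeep Number of lowest-scoring partitions retained (default 5).
#' @param seed Integer seed; the shuffle stream is fully determined by it.
#' @return List of [CohortSplit-class] objects, scores ascending.
#' @export
selectBalancedSplits <- function(cohort, nShuffles = 1000, nKeep = 5, seed = 1) {
  stopifnot(is(cohort, "SurvCohort"))
  n <- ncol(cohort)
  if (n < 10) stop("need at least 10 samples to split 60/20/20")
  if (nKeep > nShuffles) stop("nKeep cannot exceed nShuffles")
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(seed)
  splits <- vector("list", nShuffles)
  scores <- numeric(nShuffles)
  for (i in seq_len(nShuffles)) {
    s <- scoreSplit(.randomSplit(n), cohort)
    splits[[i]] <- s
    scores[i] <- s@balanceScore
  }
  splits[order(scores)[seq_len(nKeep)]]
}

#' Write splits to JSON
#'
#' Serializes a list of [CohortSplit-class] objects as JSON with per-fold
#' sample-id lists and component scores.
#'
#' @param splits List of splits (from [selectBalancedSplits()]).
#' @param cohort The cohort whose sample ids the indices refer to.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeSplitsJSON <- function(splits, cohort, path) {
  ids <- colnames(cohort)
  payload <- lapply(seq_along(splits), function(i) {
    s <- splits[[i]]
    list(fold = i,
         train = ids[s@train], validation = ids[s@validation],
         test = ids[s@test],
         balance_score = s@balanceScore,
         component_scores = as.list(s@componentScores))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read splits from JSON
#'
#' Inverse of [writeSplitsJSON()].
#'
#' @param path JSON file.
#' @param cohort The cohort used to map sample ids back to indices.
#' @return List of [CohortSplit-class] objects.
#' @export
readSplitsJSON <- function(path, cohort) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- colnames(cohort)
  lapply(seq_len(nrow(payload)), function(i) {
    cs <- unlist(payload$component_scores[i, , drop = TRUE])
    new("CohortSplit",
        train = match(unlist(payload$train[i]), ids),
        validation = match(unlist(payload$validation[i]), ids),
        test = match(unlist(payload$test[i]), ids),
        balanceScore = payload$balance_score[i],
        componentScores = cs)
  })
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.seedState <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
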