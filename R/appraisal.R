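# CQS-2B scoring and RoB 2 rating representation.

#' Score a trial with the CQS-2B
#'
#' The Composite Quality Score, version 2B, appraises a prospective
#' controlled therapy trial on four binary criteria:
#' \enumerate{
#'   \item randomisation for allocation to treatment groups is reported;
#'   \item allocation according to the random sequence was applied by an
#'     independent agent (allocation concealment);
#'   \item double-blinding (at least two of participants, personnel, outcome
#'     assessors) is reported;
#'   \item every treatment group has at least N = 100 subjects.
#' }
#' Each criterion scores 0 (no/invalid) or 1 (corroborated). The overall
#' score is the product of the four scores, so a single failed criterion
#' invalidates the trial. The corroboration level (C-level) counts how many
#' *consecutive* criteria are satisfied starting from Criterion I: it is
#' fixed at the first 0-scored criterion and unaffected by any later score,
#' e.g. scores (1,1,0,1) give C-level 2.
#'
#' @param scores numeric or integer vector of exactly four 0/1 criterion
#'   scores, in criterion order I--IV.
#' @param trial_id optional identifier carried through to the result.
#' @return An object of class `"cqs_appraisal"`: a list with elements
#'   `trial_id`, `scores` (integer(4)), `overall` (0 or 1) and `c_level`
#'   (integer 0--4).
#' @examples
#' score_cqs(c(1, 1, 0, 1))  # C-level 2, overall 0
#' score_cqs(c(1, 1, 1, 1))  # C-level 4, overall 1
#' @seealso [failed_criterion()], [parse_rob2()]
#' @export
score_cqs <- function(scores, trial_id = NA_character_) {
  if (length(scores) != 4L) {
    stop("CQS-2B requires exactly four criterion scores, got ",
         length(scores), call. = FALSE)
  }
  bad <- which(is.na(scores) | !(scores %in% c(0, 1)))
  if (length(bad)) {
    stop("CQS-2B criterion ", bad[1L], " score must be 0 or 1 (got '",
         scores[bad[1L]], "')", call. = FALSE)
  }
  scores <- as.integer(scores)
  structure(
    list(
      trial_id = trial_id,
      scores   = scores,
      overall  = as.integer(prod(scores)),
      # leading-ones count: cumprod zeroes out at the first failure
      c_level  = as.integer(sum(cumprod(scores)))
    ),
    class = "cqs_appraisal"
  )
}

#' @export
print.cqs_appraisal <- function(x, ...) {
  cat(sprintf("CQS-2B appraisal%s: scores (%s), overall %d, C-level %d\n",
              if (is.na(x$trial_id)) "" else paste0(" [", x$trial_id, "]"),
              paste(x$scores, collapse = ","), x$overall, x$c_level))
  invisible(x)
}

#' First failed CQS-2B criterion
#'
#' Returns the index (1--4) of the first 0-scored criterion of an appraisal,
#' i.e. the criterion that capped the trial's corroboration level, or `NA`
#' when all four criteria are satisfied. Used by the conclusion mapper to
#' name the bias mechanism that blocks a clinical conclusion.
#'
#' @param appraisal a `"cqs_appraisal"` object from [score_cqs()].
#' @return integer 1--4, or `NA_integer_` for a fully corroborated trial.
#' @export
failed_criterion <- function(appraisal) {
  stopifnot(inherits(appraisal, "cqs_appraisal"))
  if (appraisal$c_level >= 4L) NA_integer_ else appraisal$c_level + 1L
}

#' Bias mechanism associated with a CQS-2B criterion
#'
#' Maps a criterion index to the meta-epidemiological bias mechanism whose
#' absence the criterion guards against: randomization, allocation
#' concealment, double blinding, and minimum per-arm sample size.
#'
#' @param criterion integer 1--4.
#' @return character scalar naming the mechanism.
#' @export
bias_mechanism <- function(criterion) {
  stopifnot(criterion %in% 1:4)
  c("lack of randomization",
    "lack of allocation concealment",
    "lack of double blinding",
    "too low sample size")[criterion]
}

.rob2_levels <- c("low", "some_concerns", "high")

#' Parse an RoB 2 overall rating label
#'
#' Canonicalizes free-text overall ratings from the Cochrane Risk of Bias 2
#' tool. Accepted spellings (case-insensitive, surrounding whitespace
#' ignored): `"low"`, `"low risk"`, `"some concerns"`, `"some_concerns"`,
#' `"high"`, `"high risk"`.
#'
#' @param label character vector of rating labels.
#' @return character vector with values in
#'   `c("low", "some_concerns", "high")`.
#' @examples
#' parse_rob2(c("Low risk", "Some concerns", "HIGH"))
#' @export
parse_rob2 <- function(label) {
  norm <- gsub("[ _]+", " ", trimws(tolower(as.character(label))))
  map <- c("low" = "low", "low risk" = "low",
           "some concerns" = "some_concerns",
           "high" = "high", "high risk" = "high")
  out <- unname(map[norm])
  if (anyNA(out)) {
    bad <- label[is.na(out)][1L]
    stop("unrecognized RoB 2 rating '", bad, "'; accepted spellings: ",
         "'low', 'low risk', 'some concerns', 'high', 'high risk'",
         call. = FALSE)
  }
  out
}

#' Score a table of CQS-2B appraisals
#'
#' Vectorized scorer for an appraisal table with one row per trial.
#'
#' @param appraisals data frame with columns `trial_id`, `cqs_c1` ...
#'   `cqs_c4` (0/1) and `rob2_overall` (text rating).
#' @return the input with added integer columns `overall` and `c_level`
#'   and `rob2_overall` canonicalized.
#' @export
score_cqs_table <- function(appraisals) {
  req <- c("trial_id", paste0("cqs_c", 1:4), "rob2_overall")
  miss <- setdiff(req, names(appraisals))
  if (length(miss)) {
    stop("appraisal table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(appraisals$trial_id)) {
    stop("duplicate trial_id in appraisal table: ",
         appraisals$trial_id[duplicated(appraisals$trial_id)][1L],
         call. = FALSE)
  }
  s <- as.matrix(appraisals[paste0("cqs_c", 1:4)])
  for (j in 1:4) {
    bad <- which(is.na(s[, j]) | !(s[, j] %in% c(0, 1)))
    if (length(bad)) {
      stop("trial '", appraisals$trial_id[bad[1L]], "': criterion ", j,
           " score must be 0 or 1", call. = FALSE)
    }
  }
  appraisals$overall <- as.integer(apply(s, 1L, prod))
  appraisals$c_level <- as.integer(apply(s, 1L, function(r) sum(cumprod(r))))
  appraisals$rob2_overall <- parse_rob2(appraisals$rob2_overall)
  appraisals
}
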