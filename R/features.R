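#' Facial-emotion feature set
#'
#' The encoding models use 48 facial-expression feature timecourses. Eleven
#' of the labels are fixed by the analysis itself: the four complex (social)
#' emotions `guilt`, `embarrassment`, `pride`, `envy`; the six basic emotions
#' `joy`, `sadness`, `fear`, `anger`, `disgust`, `surprise`; and `interest`,
#' which some taxonomies treat as a fifth complex emotion. The remaining 37
#' labels are stable fillers from the same facial-expression taxonomy family.
#'
#' @param interest_complex logical; if `TRUE`, `interest` is added to the
#'   complex-emotion subset (five-feature variant). Default `FALSE` (the
#'   four-feature set guilt/embarrassment/pride/envy).
#' @return A list of class `emotion_feature_set` with elements `names`
#'   (48 unique labels), `complex_set`, and `basic_set`.
#' @export
#' @examples
#' fs <- emotion_feature_set()
#' length(fs$names)      # 48
#' fs$complex_set
emotion_feature_set <- function(interest_complex = FALSE) {
  nm <- c(
    # the eleven analysis-relevant labels
    "guilt", "embarrassment", "pride", "envy", "interest",
    "joy", "sadness", "fear", "anger", "disgust", "surprise",
    # stable fillers
    "admiration", "adoration", "aesthetic_appreciation", "amusement",
    "anxiety", "awe", "awkwardness", "boredom", "calmness",
    "concentration", "confusion", "contemplation", "contempt",
    "contentment", "craving", "desire", "determination",
    "disappointment", "distress", "doubt", "ecstasy", "empathic_pain",
    "entrancement", "excitement", "gratitude", "horror", "love",
    "nostalgia", "pain", "realization", "relief", "romance",
    "satisfaction", "shame", "sympathy", "tiredness", "triumph"
  )
  complex_set <- c("guilt", "embarrassment", "pride", "envy")
  if (isTRUE(interest_complex)) complex_set <- c(complex_set, "interest")
  basic_set <- c("joy", "sadness", "fear", "anger", "disgust", "surprise")
  out <- list(names = nm, complex_set = complex_set, basic_set = basic_set)
  class(out) <- "emotion_feature_set"
  validate_feature_set(out)
  out
}

validate_feature_set <- function(fs) {
  if (length(fs$names) != 48L)
    stop("feature set must contain exactly 48 names, got ", length(fs$names))
  if (anyDuplicated(fs$names))
    stop("feature names must be unique")
  if (length(intersect(fs$complex_set, fs$basic_set)) > 0L)
    stop("complex and basic emotion sets must be disjoint")
  missing <- setdiff(c(fs$complex_set, fs$basic_set), fs$names)
  if (length(missing))
    stop("emotion subsets reference unknown features: ",
         paste(missing, collapse = ", "))
  invisible(fs)
}
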