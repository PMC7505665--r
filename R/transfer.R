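#' Pattern-expression series of a decoder over a dataset
#'
#' One dot-product expression value per image ([pattern_expression()],
#' raw/unscaled by default, the transfer convention), joined to the
#' dataset's design covariates (level, temperature, rating where present).
#'
#' @param model a `pattern_model`.
#' @param dataset a `synth_dataset` (or list with `images` and `design`).
#' @param apply_scaling apply the model's training scaler first.
#' @return An `expression_series` data frame: subject, modality,
#'   condition, covariates, `expression`.
#' @export
expression_series <- function(model, dataset, apply_scaling = FALSE) {
  expr <- pattern_expression(model, dataset$images, apply_scaling)
  out <- cbind(dataset$design, expression = as.numeric(expr))
  class(out) <- c("expression_series", "data.frame")
  out
}

#' Pooled correlation of pattern expression with a covariate
#'
#' Pearson correlation pooled across all subject-by-condition rows (so 33
#' subjects x 6 levels give df = 196), the convention matching a pooled
#' r with df = n - 2. A within-subject variant averages the per-subject
#' correlations (df reported as NA).
#'
#' @param series an [expression_series()] data frame.
#' @param covariate column name, `"level"` or `"rating"` (any numeric
#'   column works).
#' @param within_subject average per-subject correlations instead of
#'   pooling.
#' @return list with `r`, `df`, `p`, `n`.
#' @export
expression_correlation <- function(series, covariate = c("level", "rating"),
                                   within_subject = FALSE) {
  covariate <- if (length(covariate) > 1) match.arg(covariate) else covariate
  if (!covariate %in% names(series))
    stop_invalid("no covariate column `", covariate, "` in the series")
  x <- series[[covariate]]
  y <- series$expression
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_invalid("need >= 3 rows")
  if (stats::sd(x) == 0) stop_invalid("constant covariate")
  if (within_subject) {
    subj <- series$subject[ok]
    rs <- vapply(unique(subj), function(s)
      stats::cor(x[subj == s], y[subj == s]), numeric(1))
    return(list(r = mean(rs), df = NA_integer_, p = NA_real_,
                n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, n = length(x))
}

#' Forced choice between averaged intensity-level sets
#'
#' Per subject, expressions are averaged within a low-level set and a
#' high-level set (e.g. the two lowest vs the two highest temperatures);
#' the subject is scored correct when the high-set average exceeds the
#' low-set average (ties 0.5), with an exact one-tailed binomial p and a
#' paired Cohen's d. Subjects missing any required level are excluded
#' with a warning.
#'
#' @param series an [expression_series()] with a `level` column.
#' @param low_levels,high_levels disjoint non-empty level sets.
#' @return An `eval_result` (as [forced_choice()]; `accuracy_single` is
#'   NA, there is no decision threshold on transfer data).
#' @export
level_contrast_2afc <- function(series, low_levels, high_levels) {
  if (!length(low_levels) || !length(high_levels) ||
      length(intersect(low_levels, high_levels)))
    stop_invalid("level sets must be non-empty and disjoint")
  if (!"level" %in% names(series)) stop_invalid("series has no `level` column")
  subjects <- unique(series$subject)
  diffs <- vapply(subjects, function(s) {
    rows <- series[series$subject == s, ]
    lo <- rows$expression[rows$level %in% low_levels]
    hi <- rows$expression[rows$level %in% high_levels]
    if (length(lo) < length(low_levels) || length(hi) < length(high_levels))
      return(NA_real_)
    mean(hi) - mean(lo)
  }, numeric(1))
  if (anyNA(diffs)) {
    warning(sum(is.na(diffs)), " subject(s) missing a level; excluded")
    diffs <- diffs[!is.na(diffs)]
  }
  n <- length(diffs)
  if (!n) stop_invalid("no complete subjects")
  correct <- ifelse(diffs > 0, 1, ifelse(diffs < 0, 0, 0.5))
  p <- stats::binom.test(sum(diffs > 0), n, 0.5,
                         alternative = "greater")$p.value
  sdd <- stats::sd(diffs)
  d <- if (n < 2 || (sdd == 0 && mean(diffs) == 0)) 0
  else if (sdd == 0) sign(mean(diffs)) * Inf
  else mean(diffs) / sdd
  structure(list(accuracy_2afc = mean(correct), accuracy_single = NA_real_,
                 p_value = p, cohens_d = d, per_subject_correct = correct,
                 diffs = diffs, n_pairs = n),
            class = "eval_result")
}

#' Specificity of a pain decoder for non-painful negative affect
#'
#' Applies the vicarious-pain decoder, under the same repeated
#' cross-validation fold structure used to train it, to the
#' negative-versus-neutral emotion contrast of the held-out subjects
#' (forced choice on raw dot products). Accuracy near chance indicates
#' the decoder does not merely track arousal or negative affect.
#'
#' @param dataset a `synth_dataset` containing the training modality and
#'   an `"IAPS"` modality with `negative`/`neutral` conditions.
#' @param train_modality modality the decoder is trained on.
#' @param scheme a `cv_scheme`.
#' @param C margin penalty.
#' @param emotion_modality modality label of the emotion paradigm.
#' @param emotion_conditions condition pair scored at test time.
#' @return A `cv_result`, as [cross_modality_eval()].
#' @export
specificity_eval <- function(dataset, train_modality, scheme, C = 1,
                             emotion_modality = "IAPS",
                             emotion_conditions = c("negative", "neutral")) {
  cross_modality_eval(dataset, train_modality, emotion_modality, scheme,
                      C = C, test_conditions = emotion_conditions,
                      apply_scaling = FALSE)
}
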