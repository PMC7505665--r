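#' Fit per-voxel [-1, 1] range scaling on a training set
#'
#' Records the per-voxel training minimum and maximum; [apply_scaler()]
#' maps min to -1 and max to +1 (test values may fall outside). Constant
#' voxels are mapped to 0 everywhere.
#'
#' @param train numeric matrix, training images x voxels.
#' @return A `range_scaler` with `min` and `max` vectors.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop_invalid("need >= 2 training rows")
  structure(list(min = apply(train, 2, min), max = apply(train, 2, max)),
            class = "range_scaler")
}

#' Apply a fitted range scaler
#' @param scaler a [fit_scaler()] `range_scaler`.
#' @param x numeric matrix (images x voxels) or single image vector.
#' @return scaled matrix/vector; constant training voxels give 0.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "range_scaler"))
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != length(scaler$min))
    stop_invalid("image length does not match scaler")
  rng <- scaler$max - scaler$min
  ok <- rng > 0
  out <- matrix(0, nrow(x), ncol(x))
  if (any(ok)) {
    out[, ok] <- 2 * sweep(x[, ok, drop = FALSE], 2, scaler$min[ok]) /
      rep(rng[ok], each = nrow(x)) - 1
  }
  if (vec) drop(out) else out
}

#' Train a whole-brain linear support-vector decoder
#'
#' Soft-margin linear SVM (hinge loss, penalty `C`, default 1) via
#' \pkg{e1071}/libsvm. The returned weight vector is oriented so that the
#' decision value `w . x + offset` is positive on the positive-label side.
#'
#' @param x numeric matrix, images x voxels (typically already scaled with
#'   [apply_scaler()]).
#' @param labels vector of +1 / -1 (or a 2-level factor whose first level
#'   is the positive class).
#' @param C margin penalty.
#' @param scaler optional `range_scaler` stored with the model.
#' @param meta optional list of training metadata.
#' @param tolerance optimizer KKT termination tolerance; the default is
#'   tight enough that decision values are reproducible to ~1e-5.
#' @return A `pattern_model`: `weights`, `offset`, `scaler`, `C`, `meta`.
#' @export
train_decoder <- function(x, labels, C = 1, scaler = NULL, meta = list(),
                          tolerance = 1e-6) {
  x <- as.matrix(x)
  if (is.factor(labels) || is.character(labels)) {
    lv <- if (is.factor(labels)) levels(labels) else unique(labels)
    labels <- ifelse(as.character(labels) == lv[1], 1, -1)
  }
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop_invalid("both classes must be present")
  if (!all(labels %in% c(-1, 1))) stop_invalid("labels must be +1/-1")
  yf <- factor(labels, levels = c(1, -1))
  fit <- e1071::svm(x = x, y = yf, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's decision value is positive for the class listed first in
  # fit$labels; orient so the +1 class is positive.
  if (fit$levels[fit$labels[1]] != "1") {
    w <- -w
    b <- -b
  }
  structure(list(weights = unname(w), offset = unname(b), scaler = scaler,
                 C = C, meta = meta),
            class = "pattern_model")
}

#' Pattern expression of an image under a trained decoder
#'
#' The scalar dot product between the decoder's voxel weights and the
#' image (the decoder offset is excluded). With `apply_scaling = TRUE` the
#' model's stored training scaler is applied to the image first; transfer
#' to data from a different acquisition should use the raw dot product
#' (the default).
#'
#' @param model a `pattern_model`.
#' @param image image vector or matrix (images x voxels) in the model's
#'   mask space.
#' @param apply_scaling logical.
#' @return numeric expression value(s).
#' @export
pattern_expression <- function(model, image, apply_scaling = FALSE) {
  stopifnot(inherits(model, "pattern_model"))
  vec <- is.null(dim(image))
  x <- if (vec) matrix(image, 1) else as.matrix(image)
  if (ncol(x) != length(model$weights))
    stop_invalid("image length (", ncol(x), ") != weight length (",
                 length(model$weights), ")")
  if (apply_scaling) {
    if (is.null(model$scaler)) stop_invalid("model carries no scaler")
    x <- apply_scaler(model$scaler, x)
    if (is.null(dim(x))) x <- matrix(x, 1)
  }
  drop(x %*% model$weights)
}

#' Two-alternative forced-choice evaluation of a decoder
#'
#' For each subject's (positive, control) image pair the image with the
#' higher pattern expression is called positive; ties score 0.5. Also
#' reports single-interval accuracy (sign of the decision value
#' `w . x + offset` against the label), a one-tailed exact binomial p
#' against chance 0.5 (strict wins only; ties are not counted as wins),
#' and a paired Cohen's d (mean / sd of the per-subject expression
#' differences).
#'
#' @param model a `pattern_model`.
#' @param pos_images matrix of positive-condition images (one row per
#'   subject).
#' @param neg_images matrix of matched control images, same subject order.
#' @param apply_scaling apply the model's training scaler first (the
#'   within-paradigm cross-validation convention).
#' @return An `eval_result`: `accuracy_2afc`, `accuracy_single`,
#'   `p_value`, `cohens_d`, `per_subject_correct`, `diffs`, `n_pairs`.
#' @export
forced_choice <- function(model, pos_images, neg_images,
                          apply_scaling = FALSE) {
  pos_images <- as.matrix(pos_images)
  neg_images <- as.matrix(neg_images)
  if (nrow(pos_images) != nrow(neg_images) || nrow(pos_images) < 1)
    stop_invalid("need >= 1 matched image pair")
  ep <- pattern_expression(model, pos_images, apply_scaling)
  en <- pattern_expression(model, neg_images, apply_scaling)
  diffs <- ep - en
  correct <- ifelse(diffs > 0, 1, ifelse(diffs < 0, 0, 0.5))
  n <- length(diffs)
  wins <- sum(diffs > 0)
  p <- stats::binom.test(wins, n, p = 0.5, alternative = "greater")$p.value
  sdd <- stats::sd(diffs)
  d <- if (n < 2 || (sdd == 0 && mean(diffs) == 0)) 0
  else if (sdd == 0) sign(mean(diffs)) * Inf
  else mean(diffs) / sdd
  # single-interval: signed decision value vs label over all images
  xs <- rbind(pos_images, neg_images)
  if (apply_scaling && !is.null(model$scaler))
    xs <- apply_scaler(model$scaler, xs)
  dec <- drop(as.matrix(xs) %*% model$weights) + model$offset
  lab <- rep(c(1, -1), each = n)
  single <- mean(ifelse(dec * lab > 0, 1, ifelse(dec == 0, 0.5, 0)))
  structure(list(accuracy_2afc = mean(correct), accuracy_single = single,
                 p_value = p, cohens_d = d, per_subject_correct = correct,
                 diffs = diffs, n_pairs = n),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result: 2AFC accuracy %.3f (single %.3f), p = %.3g, d = %.2f, n = %d\n",
    x$accuracy_2afc, x$accuracy_single, x$p_value, x$cohens_d, x$n_pairs))
  invisible(x)
}

#' Repeated k-fold cross-validation scheme over subjects
#'
#' Subjects are randomly partitioned into `n_folds` subsamples whose sizes
#' differ by at most one; the partition is re-drawn `n_repeats` times.
#' Fold membership is per subject, so a subject's paired condition images
#' always share a fold.
#'
#' @param subjects vector of subject ids.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats number of repeats (default 10).
#' @param seed integer seed.
#' @return A `cv_scheme`: list with `subjects`, `n_folds`, `n_repeats`,
#'   `assignment` (list of per-repeat fold vectors), `seed`.
#' @export
make_cv_scheme <- function(subjects, n_folds = 10, n_repeats = 10, seed = 1) {
  subjects <- unique(subjects)
  n <- length(subjects)
  if (n < n_folds) stop_invalid("fewer subjects (", n, ") than folds (",
                                n_folds, ")")
  assignment <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) sample(rep_len(seq_len(n_folds), n)))
  })
  structure(list(subjects = subjects, n_folds = n_folds,
                 n_repeats = n_repeats, assignment = assignment,
                 seed = seed),
            class = "cv_scheme")
}

# Train a scaled decoder on the given subjects' images for one pair of
# conditions of one modality set; internal workhorse for the CV drivers.
train_fold_model <- function(dataset, modality, conditions, subjects,
                             C = 1, meta = list()) {
  d <- dataset$design
  pos_rows <- which(d$modality %in% modality & d$condition == conditions[1] &
                      d$subject %in% subjects)
  neg_rows <- which(d$modality %in% modality & d$condition == conditions[2] &
                      d$subject %in% subjects)
  if (!length(pos_rows) || !length(neg_rows))
    stop_invalid("a training fold lacks one class")
  X <- dataset$images[c(pos_rows, neg_rows), , drop = FALSE]
  y <- rep(c(1, -1), c(length(pos_rows), length(neg_rows)))
  scaler <- fit_scaler(X)
  train_decoder(apply_scaler(scaler, X), y, C = C, scaler = scaler,
                meta = meta)
}

# Paired test images of held-out subjects for a modality/condition pair.
test_pairs <- function(dataset, modality, conditions, subjects) {
  d <- dataset$design
  subjects <- sort(subjects)
  sel <- function(cond) {
    rows <- which(d$modality %in% modality & d$condition == cond &
                    d$subject %in% subjects)
    rows[order(d$subject[rows])]
  }
  pr <- sel(conditions[1]); nr <- sel(conditions[2])
  if (length(pr) != length(nr))
    stop_invalid("unpaired test images for conditions ",
                 paste(conditions, collapse = "/"))
  list(pos = dataset$images[pr, , drop = FALSE],
       neg = dataset$images[nr, , drop = FALSE],
       subjects = d$subject[pr])
}

# Shared driver for within- and between-modality repeated CV.
repeated_cv_engine <- function(dataset, train_modality, test_modality,
                               scheme, C = 1,
                               train_conditions = c("pain", "control"),
                               test_conditions = train_conditions,
                               apply_scaling = TRUE,
                               voxels = NULL) {
  stopifnot(inherits(scheme, "cv_scheme"))
  ds <- if (is.null(voxels)) dataset else {
    dataset$images <- dataset$images[, voxels, drop = FALSE]
    dataset
  }
  subjects <- scheme$subjects
  per_repeat <- vector("list", scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    fold_of <- scheme$assignment[[r]]
    correct <- numeric(0); diffs <- numeric(0); fold_acc <- numeric(scheme$n_folds)
    singles <- numeric(scheme$n_folds)
    for (f in seq_len(scheme$n_folds)) {
      train_subj <- subjects[fold_of != f]
      test_subj <- subjects[fold_of == f]
      model <- train_fold_model(ds, train_modality, train_conditions,
                                train_subj, C = C)
      pairs <- test_pairs(ds, test_modality, test_conditions, test_subj)
      ev <- forced_choice(model, pairs$pos, pairs$neg,
                          apply_scaling = apply_scaling)
      correct <- c(correct, ev$per_subject_correct)
      diffs <- c(diffs, ev$diffs)
      fold_acc[f] <- ev$accuracy_2afc
      singles[f] <- ev$accuracy_single
    }
    n <- length(correct)
    wins <- sum(correct == 1)
    sdd <- stats::sd(diffs)
    per_repeat[[r]] <- list(
      accuracy_2afc = mean(correct),
      accuracy_single = sum(singles * tabulate(fold_of, scheme$n_folds)) /
        length(subjects),
      p_value = stats::binom.test(wins, n, 0.5,
                                  alternative = "greater")$p.value,
      cohens_d = if (sdd > 0) mean(diffs) / sdd else 0,
      per_fold_accuracy = fold_acc
    )
  }
  agg <- function(field) mean(vapply(per_repeat, `[[`, numeric(1), field))
  structure(list(
    accuracy_2afc = agg("accuracy_2afc"),
    accuracy_single = agg("accuracy_single"),
    p_value = agg("p_value"),
    cohens_d = agg("cohens_d"),
    per_fold_accuracy = do.call(rbind, lapply(per_repeat, `[[`,
                                              "per_fold_accuracy")),
    per_repeat = per_repeat,
    n_pairs = length(subjects),
    train_modality = train_modality, test_modality = test_modality
  ), class = c("cv_result", "eval_result"))
}

#' Repeated k-fold cross-validated decoding of one modality
#'
#' For every repeat and fold, a scaler and linear SVM are fit on the
#' training-fold subjects' condition images and evaluated by forced choice
#' on the held-out subjects. Accuracy, binomial p and Cohen's d are
#' computed per repeat and averaged across repeats.
#'
#' @param dataset a `synth_dataset` (or compatible `images` + `design`).
#' @param modality modality to decode (e.g. `"NS"`).
#' @param scheme a [make_cv_scheme()] `cv_scheme`.
#' @param C margin penalty.
#' @param conditions length-2 condition pair (positive first).
#' @param voxels optional column subset (e.g. a searchlight sphere).
#' @return A `cv_result` (also `eval_result`) with repeat-averaged
#'   `accuracy_2afc`, `accuracy_single`, `p_value`, `cohens_d`, plus
#'   per-fold and per-repeat detail.
#' @export
repeated_cv <- function(dataset, modality, scheme, C = 1,
                        conditions = c("pain", "control"), voxels = NULL) {
  repeated_cv_engine(dataset, modality, modality, scheme, C = C,
                     train_conditions = conditions, voxels = voxels)
}

#' Between-modality cross-prediction under a shared fold partition
#'
#' Within each repeat and fold the decoder is trained on the training-fold
#' subjects' `train_modality` images and tested, by forced choice, on the
#' held-out subjects' `test_modality` images (scaled with the training
#' scaler). With `train_modality == test_modality` this reduces to
#' [repeated_cv()].
#'
#' @inheritParams repeated_cv
#' @param train_modality,test_modality modality labels.
#' @param test_conditions condition pair scored at test time (positive
#'   first); defaults to the training pair.
#' @param apply_scaling apply the training scaler to test images.
#' @return A `cv_result`, as [repeated_cv()].
#' @export
cross_modality_eval <- function(dataset, train_modality, test_modality,
                                scheme, C = 1,
                                conditions = c("pain", "control"),
                                test_conditions = conditions,
                                apply_scaling = TRUE, voxels = NULL) {
  repeated_cv_engine(dataset, train_modality, test_modality, scheme, C = C,
                     train_conditions = conditions,
                     test_conditions = test_conditions,
                     apply_scaling = apply_scaling, voxels = voxels)
}

#' Train a final decoder on the full sample
#'
#' Fits the scaler and linear SVM on all subjects' images (optionally
#' pooling several modalities, e.g. for a modality-general pattern).
#' Intended for transfer analyses on independent data, never for
#' within-sample accuracy claims.
#'
#' @inheritParams repeated_cv
#' @param modalities modalities pooled into training (default both
#'   vicarious-pain modalities).
#' @param subjects optional subject subset.
#' @return A `pattern_model`.
#' @export
train_final <- function(dataset, modalities = c("NS", "FE"),
                        conditions = c("pain", "control"), C = 1,
                        subjects = NULL) {
  subj <- subjects %||% unique(dataset$design$subject)
  train_fold_model(dataset, modalities, conditions, subj, C = C,
                   meta = list(modalities = modalities,
                               conditions = conditions,
                               n_subjects = length(subj)))
}

#' Learning curve over training-set size
#'
#' For each size, `n_draws` random subject subsets are drawn, a final
#' decoder is trained on each subset and scored with `eval_fn`; scores are
#' averaged per size.
#'
#' @inheritParams train_final
#' @param train_sizes integer vector of subject counts.
#' @param eval_fn function(`pattern_model`) -> scalar score (e.g. a
#'   prediction-outcome correlation on an independent dataset).
#' @param n_draws random draws per size.
#' @param seed integer seed.
#' @return data frame with `size`, `mean_score`, `sd_score`.
#' @export
learning_curve <- function(dataset, train_sizes, eval_fn, n_draws = 5,
                           seed = 1, modalities = c("NS", "FE"),
                           conditions = c("pain", "control"), C = 1) {
  subj <- unique(dataset$design$subject)
  if (max(train_sizes) > length(subj))
    stop_invalid("train size exceeds number of subjects")
  if (any(train_sizes < 2)) stop_invalid("train sizes must be >= 2")
  rows <- with_seed(seed, {
    lapply(train_sizes, function(sz) {
      scores <- vapply(seq_len(n_draws), function(d) {
        pick <- if (sz == length(subj)) subj else sample(subj, sz)
        m <- train_final(dataset, modalities, conditions, C = C,
                         subjects = pick)
        eval_fn(m)
      }, numeric(1))
      data.frame(size = sz, mean_score = mean(scores),
                 sd_score = stats::sd(scores))
    })
  })
  do.call(rbind, rows)
}
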