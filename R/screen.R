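#' Train/test split sizes for two labelled image classes
#'
#' The held-out test set takes `ceiling(test_fraction * n)` images from
#' each class; the rest train. With the standard 15% fraction, classes
#' of 742 and 735 images give test sets of 112 and 111.
#'
#' @param n_class_a,n_class_b Image counts per class.
#' @param test_fraction Held-out fraction in (0, 1), default 0.15.
#' @return One-row tibble: `test_a`, `test_b`, `train_a`, `train_b`.
#' @examples
#' split_counts(742, 735)
#' @export
split_counts <- function(n_class_a, n_class_b, test_fraction = 0.15) {
  stopifnot(n_class_a >= 1, n_class_b >= 1,
            test_fraction > 0, test_fraction < 1)
  ta <- as.integer(ceiling(test_fraction * n_class_a))
  tb <- as.integer(ceiling(test_fraction * n_class_b))
  if (ta == n_class_a || tb == n_class_b)
    abort("Test split consumes an entire class; reduce `test_fraction`.")
  tibble(test_a = ta, test_b = tb,
         train_a = n_class_a - ta, train_b = n_class_b - tb)
}

#' Morphometry feature vector of one image
#'
#' Summarizes a single lysosome image into the handcrafted feature
#' vector used by the baseline screen classifier: particle count and
#' density, tubular count and density, and robust summaries of the
#' per-particle shape metrics. Optionally augments by horizontal and
#' vertical flips (each flip contributes its own feature row; shape
#' features are flip-invariant up to rasterization, which makes the
#' augmentation a mild regularizer).
#'
#' @param image Numeric matrix (one frame, lysosome channel).
#' @param pixel_size_nm Pixel pitch (nm).
#' @param scale_px,k,min_area_px Detection settings, see
#'   [binarize_spots()].
#' @param augment_flips Add flipped copies of the image (default FALSE).
#' @return Tibble with one row per (possibly flipped) image.
#' @export
image_features <- function(image, pixel_size_nm, scale_px = 2, k = 3,
                           min_area_px = 4, augment_flips = FALSE) {
  imgs <- list(image)
  if (augment_flips)
    imgs <- c(imgs, list(image[nrow(image):1, ], image[, ncol(image):1]))
  map(imgs, function(im) {
    mask <- binarize_spots(im, scale_px = scale_px, k = k,
                           min_area_px = min_area_px)
    area_um2 <- prod(dim(im)) * (pixel_size_nm / 1000)^2
    reg <- label_regions(mask, pixel_size_nm)
    v <- classify_tubular(reg)
    fin_ratio <- v$axis_ratio[is.finite(v$axis_ratio)]
    tibble(
      n_particles = nrow(reg),
      particle_density = nrow(reg) / area_um2,
      n_tubular = sum(v$tubular),
      tubule_density = sum(v$tubular) / area_um2,
      tubular_fraction = ifelse(nrow(reg) > 0, mean(v$tubular), 0),
      mean_area_um2 = ifelse(nrow(reg) > 0, mean(reg$area_um2), 0),
      mean_circularity = ifelse(nrow(reg) > 0, mean(reg$circularity), 1),
      mean_eccentricity = ifelse(nrow(reg) > 0, mean(reg$eccentricity), 0),
      mean_axis_ratio = ifelse(length(fin_ratio) > 0, mean(fin_ratio), 1),
      max_major_axis_um = ifelse(nrow(reg) > 0, max(reg$major_axis_um), 0)
    )
  }) |> list_rbind()
}

#' Train the baseline knockout-phenotype classifier
#'
#' Trains a ridge-regularized logistic regression (the
#' `baseline_features` backend) on per-image morphometry feature rows to
#' discriminate wild-type-like from knockout-like lysosomal phenotypes.
#' A per-class `ceiling(test_fraction * n)` held-out split measures test
#' accuracy. The deep transfer-learning backend used for full-scale
#' screens is intentionally pluggable and not part of this package; the
#' screen logic consumes only predicted probabilities.
#'
#' @param features Tibble of per-image feature rows (e.g. from
#'   [image_features()]) plus a label column.
#' @param label Name of the label column (exactly two classes).
#' @param ko_label Which label value is the knockout-like positive
#'   class; defaults to the second factor level with a message.
#' @param test_fraction Held-out fraction (default 0.15).
#' @param lambda Ridge penalty (default 0.01).
#' @param seed Seed for the split.
#' @return A `lyso_classifier` object; see [predict.lyso_classifier()],
#'   [tidy.lyso_classifier()], [glance.lyso_classifier()].
#' @export
train_classifier <- function(features, label = "label", ko_label = NULL,
                             test_fraction = 0.15, lambda = 0.01, seed = 1) {
  stopifnot(label %in% names(features))
  y <- factor(features[[label]])
  if (nlevels(y) != 2)
    abort("Exactly two classes are required to train the classifier.")
  if (is.null(ko_label)) {
    ko_label <- levels(y)[2]
    inform(paste0("Treating `", ko_label, "` as the knockout-like class."))
  }
  if (!ko_label %in% levels(y))
    abort("`ko_label` must be one of the two label values.")
  # put the knockout-like class second: glmnet models P(second level)
  y <- factor(y, levels = c(setdiff(levels(y), ko_label), ko_label))
  feat_cols <- setdiff(names(features), label)
  x <- as.matrix(features[feat_cols])
  if (!is.numeric(x)) abort("All feature columns must be numeric.")
  one_feature <- ncol(x) == 1L  # glmnet needs >= 2 columns
  with_seed(seed, {
    test_idx <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, ceiling(test_fraction * length(idx)))
    }))
    train_idx <- setdiff(seq_along(y), test_idx)
    if (nlevels(droplevels(y[train_idx])) != 2)
      abort("Training split lost a class; supply more images.")
    ctr <- colMeans(x[train_idx, , drop = FALSE])
    scl <- apply(x[train_idx, , drop = FALSE], 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    if (one_feature) xs <- cbind(xs, `.zero` = 0)
    fit <- glmnet::glmnet(xs[train_idx, , drop = FALSE], y[train_idx],
                          family = "binomial", alpha = 0,
                          lambda = c(10 * lambda, lambda), standardize = FALSE)
    prob_test <- as.numeric(predict(fit, xs[test_idx, , drop = FALSE],
                                    s = lambda, type = "response"))
    acc <- mean((prob_test > 0.5) == (y[test_idx] == levels(y)[2]))
    structure(list(fit = fit, lambda = lambda, feature_names = feat_cols,
                   center = ctr, scale = scl, levels = levels(y),
                   ko_label = ko_label, test_accuracy = acc,
                   n_train = length(train_idx), n_test = length(test_idx)),
              class = "lyso_classifier")
  })
}

#' Predict knockout probability for new images
#'
#' @param object A `lyso_classifier`.
#' @param newdata Tibble of feature rows with the training feature
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the knockout-like class.
#' @export
predict.lyso_classifier <- function(object, newdata, ...) {
  x <- as.matrix(as_tibble(newdata)[object$feature_names])
  xs <- scale(x, center = object$center, scale = object$scale)
  if (length(object$feature_names) == 1L) xs <- cbind(xs, `.zero` = 0)
  as.numeric(predict(object$fit, xs, s = object$lambda, type = "response"))
}

#' @export
print.lyso_classifier <- function(x, ...) {
  cat("<lyso_classifier> ridge logistic on", length(x$feature_names),
      "morphometry features\n")
  cat("  classes:", paste(x$levels, collapse = " vs "),
      sprintf("(P = knockout-like = %s)\n", x$ko_label))
  cat(sprintf("  held-out accuracy: %.3f (train %d / test %d)\n",
              x$test_accuracy, x$n_train, x$n_test))
  invisible(x)
}

#' Tidy a fitted screen classifier
#'
#' @param x A `lyso_classifier`.
#' @param ... Unused.
#' @return Tibble of `term` and `estimate` (standardized coefficients).
#' @method tidy lyso_classifier
#' @export
tidy.lyso_classifier <- function(x, ...) {
  co <- as.matrix(stats::coef(x$fit, s = x$lambda))
  tibble(term = rownames(co), estimate = as.numeric(co))
}

#' One-row summary of a fitted screen classifier
#'
#' @param x A `lyso_classifier`.
#' @param ... Unused.
#' @return Tibble: `accuracy`, `n_train`, `n_test`, `n_features`,
#'   `lambda`.
#' @method glance lyso_classifier
#' @export
glance.lyso_classifier <- function(x, ...) {
  tibble(accuracy = x$test_accuracy, n_train = x$n_train, n_test = x$n_test,
         n_features = length(x$feature_names), lambda = x$lambda)
}

#' Score one screen condition
#'
#' Combines the two screen readouts for one siRNA condition: the
#' arithmetic mean of the per-image predicted knockout probability, and
#' the tubulation index of the condition's mean tubule density relative
#' to the same-experiment control means.
#'
#' @param features Tibble of per-image feature rows for this condition
#'   (must contain `tubule_density` and the classifier's feature
#'   columns).
#' @param classifier A `lyso_classifier`.
#' @param wt_mean,ko_mean Control mean tubule densities (per um^2).
#' @param condition_id Condition label stored in the record.
#' @return One-row tibble: `condition_id`, `n_images`,
#'   `mean_ko_probability`, `tubulation_index`.
#' @export
score_condition <- function(features, classifier, wt_mean, ko_mean,
                            condition_id = "condition") {
  if (nrow(features) == 0L) abort("At least one image is required.")
  prob <- predict(classifier, features)
  dens <- mean(features$tubule_density)
  tibble(condition_id = condition_id, n_images = nrow(features),
         mean_ko_probability = mean(prob),
         tubulation_index = tubulation_index(dens, wt_mean, ko_mean))
}

#' Derive screen gates from positive-control conditions
#'
#' Sets the two hit thresholds from the scored positive-control (gene of
#' interest) siRNAs. Under the default `minimal_effect` rule a candidate
#' must do at least as well as the *weakest* positive control: the
#' classifier gate is the minimum control knockout probability and the
#' tubulation gate is the maximum control index. The stricter
#' `all_controls` rule requires beating every control (maximum control
#' probability, minimum control index).
#'
#' @param controls Tibble of scored positive-control records (needs
#'   `mean_ko_probability`, `tubulation_index`).
#' @param rule `"minimal_effect"` (default) or `"all_controls"`.
#' @return One-row tibble: `nn_min_probability`, `tub_max_index`,
#'   `rule`.
#' @examples
#' ctl <- tibble::tibble(mean_ko_probability = c(0.36, 0.21, 0.26),
#'                       tubulation_index = c(0.55, 0.43, 0.50))
#' derive_gates(ctl)
#' @export
derive_gates <- function(controls, rule = c("minimal_effect", "all_controls")) {
  rule <- match.arg(rule)
  if (nrow(controls) == 0L)
    abort("At least one positive-control record is required.")
  if (rule == "minimal_effect") {
    tibble(nn_min_probability = min(controls$mean_ko_probability),
           tub_max_index = max(controls$tubulation_index), rule = rule)
  } else {
    tibble(nn_min_probability = max(controls$mean_ko_probability),
           tub_max_index = min(controls$tubulation_index), rule = rule)
  }
}

#' Apply screen gates and call hits
#'
#' A condition passes the classifier gate when its mean knockout
#' probability is at least the gate, passes the tubulation gate when its
#' index is at most the gate (stronger tubule loss), and is a hit when
#' it passes both - the intersection of the two single-readout pass
#' sets.
#'
#' @param records Tibble of scored conditions (needs `condition_id`,
#'   `mean_ko_probability`, `tubulation_index`).
#' @param gates Output of [derive_gates()].
#' @return `records` with `passes_nn_gate`, `passes_tub_gate`, `is_hit`
#'   appended, sorted by `condition_id`.
#' @export
call_hits <- function(records, gates) {
  stopifnot(all(c("nn_min_probability", "tub_max_index") %in% names(gates)))
  records |>
    as_tibble() |>
    mutate(
      passes_nn_gate = .data$mean_ko_probability >= gates$nn_min_probability,
      passes_tub_gate = .data$tubulation_index <= gates$tub_max_index,
      is_hit = .data$passes_nn_gate & .data$passes_tub_gate
    ) |>
    arrange(.data$condition_id)
}
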