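# 0-1-loss linear discrimination of cells from multi-frequency Re[CM]
# features. The 0-1 loss is minimized directly by deterministic exhaustive
# search: unit directions on an angular grid (k <= 3), thresholds at the
# midpoints of consecutive sorted projections.

#' Unit direction search grid
#'
#' Deterministic grid of unit directions covering a hemisphere (orientation
#' is handled separately by the threshold search).
#'
#' @param k Feature dimension (1, 2 or 3).
#' @param res_deg Angular resolution in degrees (default 1).
#' @return Matrix of unit row vectors.
#' @export
direction_grid <- function(k, res_deg = 1) {
  stopifnot(k >= 1, k <= 3, res_deg > 0)
  if (k == 1) return(matrix(1, 1, 1))
  ang <- seq(0, 180 - res_deg, by = res_deg) * pi / 180
  if (k == 2) return(cbind(cos(ang), sin(ang)))
  pol <- seq(0, 180, by = res_deg) * pi / 180
  g <- expand.grid(azimuth = ang, polar = pol)
  d <- cbind(sin(g$polar) * cos(g$azimuth),
             sin(g$polar) * sin(g$azimuth),
             cos(g$polar))
  unique(round(d, 12))
}

# Best threshold for 1-D projections z under 0-1 loss, both orientations.
# Returns list(threshold, sign, correct, margin).
best_split <- function(z, y01) {
  n <- length(z)
  o <- order(z)
  zs <- z[o]
  ys <- y01[o]
  cum1 <- cumsum(ys)            # positives among first i
  n1 <- cum1[n]
  i <- 0:n                      # split after the i-th sorted point
  below1 <- c(0, cum1)          # positives among the first i
  # orientation +1 (predict positive when z > t):
  # correct = negatives below the split + positives above it
  corr_pos <- (i - below1) + (n1 - below1)
  corr_neg <- n - corr_pos      # flipped orientation
  gaps <- c(0, diff(zs), 0)     # margin at each split
  best <- function(corr, sgn) {
    top <- max(corr)
    cand <- which(corr == top)
    j <- cand[which.max(gaps[cand])]
    thr <- if (j == 1) zs[1] - 1 else if (j == n + 1) zs[n] + 1
           else (zs[j - 1] + zs[j]) / 2
    list(threshold = thr, sign = sgn, correct = top, margin = gaps[j])
  }
  a <- best(corr_pos, 1)
  b <- best(corr_neg, -1)
  if (b$correct > a$correct ||
      (b$correct == a$correct && b$margin > a$margin)) b else a
}

#' Fit a 0-1-loss linear rule
#'
#' Exhaustive deterministic search over the direction grid and all
#' inter-point thresholds for the unit-norm weight vector and threshold
#' minimizing training 0-1 loss. Ties are broken toward the larger margin
#' (gap between the projections adjacent to the threshold), then toward the
#' earlier direction in the grid's lexicographic order.
#'
#' @param x Numeric feature matrix, n x k (k <= 3), or vector.
#' @param labels Binary labels (factor, character or logical); both classes
#'   must be present.
#' @param res_deg Direction-grid resolution in degrees (default 1).
#' @return An object of class `linear_rule`: list with unit `weights`,
#'   `threshold`, `positive_class`, `classes`, training `accuracy`,
#'   `margin`. Predict positive when `x %*% weights > threshold`.
#' @export
fit_01_linear <- function(x, labels, res_deg = 1) {
  x <- as.matrix(x)
  if (ncol(x) > 3)
    stop("exhaustive search supports at most 3 features", call. = FALSE)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    stop("both (and only) two classes must be present", call. = FALSE)
  labels <- droplevels(labels)
  classes <- levels(labels)
  y01 <- as.integer(labels == classes[2])
  dirs <- direction_grid(ncol(x), res_deg)
  best <- NULL
  for (i in seq_len(nrow(dirs))) {
    z <- drop(x %*% dirs[i, ])
    s <- best_split(z, y01)
    if (is.null(best) || s$correct > best$correct ||
        (s$correct == best$correct && s$margin > best$margin)) {
      best <- s
      best$dir <- dirs[i, ]
    }
  }
  w <- best$dir * best$sign
  thr <- best$threshold * best$sign
  structure(list(weights = w, threshold = thr,
                 positive_class = classes[2], classes = classes,
                 accuracy = best$correct / length(y01),
                 margin = best$margin),
            class = "linear_rule")
}

#' @export
predict.linear_rule <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  pos <- drop(newdata %*% object$weights) > object$threshold
  factor(ifelse(pos, object$positive_class,
                setdiff(object$classes, object$positive_class)),
         levels = object$classes)
}

#' Multiclass 0-1-loss classification
#'
#' All pairwise [fit_01_linear()] rules combined by majority vote; vote ties
#' go to the tied class whose training centroid is nearest the cell in
#' feature space.
#'
#' @inheritParams fit_01_linear
#' @param labels Labels among >= 2 classes.
#' @return List with `predicted` (factor), training `accuracy`, `rules`
#'   (named list of pairwise rules), `centroids`.
#' @export
classify_multiclass <- function(x, labels, res_deg = 1) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  cl <- levels(labels)
  if (length(cl) < 2) stop("at least two classes required", call. = FALSE)
  pairs <- utils::combn(cl, 2, simplify = FALSE)
  rules <- lapply(pairs, function(p) {
    sel <- labels %in% p
    fit_01_linear(x[sel, , drop = FALSE], labels[sel], res_deg)
  })
  names(rules) <- vapply(pairs, paste, collapse = "|", FUN.VALUE = "")
  votes <- matrix(0L, nrow(x), length(cl), dimnames = list(NULL, cl))
  for (r in rules) {
    pred <- as.character(predict(r, x))
    for (k in cl) votes[, k] <- votes[, k] + (pred == k)
  }
  centroids <- t(vapply(cl, function(k)
    colMeans(x[labels == k, , drop = FALSE]), numeric(ncol(x))))
  predicted <- vapply(seq_len(nrow(x)), function(i) {
    v <- votes[i, ]
    tied <- names(v)[v == max(v)]
    if (length(tied) == 1) return(tied)
    d2 <- rowSums(sweep(centroids[tied, , drop = FALSE], 2, x[i, ])^2)
    tied[which.min(d2)]
  }, "")
  predicted <- factor(predicted, levels = cl)
  list(predicted = predicted,
       accuracy = mean(predicted == labels),
       rules = rules, centroids = centroids)
}

#' Discrimination accuracy
#'
#' (cells tested - errors made) / cells tested.
#'
#' @param n_tested Number of cells tested (> 0).
#' @param n_errors Number of classification errors (0 <= n_errors <=
#'   n_tested).
#' @return Fraction in `[0, 1]`.
#' @export
discrimination_accuracy <- function(n_tested, n_errors) {
  if (!is.numeric(n_tested) || n_tested <= 0)
    stop("n_tested must be > 0", call. = FALSE)
  if (n_errors < 0 || n_errors > n_tested)
    stop("n_errors must lie in [0, n_tested]", call. = FALSE)
  (n_tested - n_errors) / n_tested
}

#' Permutation significance of a classification accuracy
#'
#' Label-permutation test: p = (1 + #\{permuted accuracy >= observed\}) /
#' (1 + n_permutations).
#'
#' @inheritParams fit_01_linear
#' @param fit Fitting procedure, a `function(x, labels)` returning a list
#'   with an `accuracy` element (default: [fit_01_linear()] at `res_deg`).
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `p_value`, `observed`, `permuted` (vector of permuted
#'   accuracies).
#' @export
accuracy_significance <- function(x, labels, fit = NULL,
                                  n_permutations = 999, seed = 1L,
                                  res_deg = 1) {
  if (n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  fit <- fit %||% function(x, labels) fit_01_linear(x, labels, res_deg)
  observed <- fit(x, labels)$accuracy
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  permuted <- vapply(seq_len(n_permutations), function(i)
    fit(x, sample(labels))$accuracy, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(p_value = (1 + sum(permuted >= observed)) / (1 + n_permutations),
       observed = observed, permuted = permuted)
}

#' Write / read a feature table
#'
#' Columns `cell_id`, `re_cm_f1..fk`, optional `radius_m`, `label`.
#'
#' @param features Data frame feature table.
#' @param path File path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) utils::read.csv(path)
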