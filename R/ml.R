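#' Sample distance correlation
#'
#' V-statistic distance correlation (double-centered Euclidean distance
#' matrices): 0 iff (in the population) the variables are independent, 1 for
#' exact linear dependence, and sensitive to nonlinear association where
#' Pearson correlation is not.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return scalar in `[0, 1]` (0 with a warning for zero-variance input).
#' @export
distance_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("lengths differ")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: distance correlation set to 0")
    return(0)
  }
  dc <- function(v) {
    D <- abs(outer(v, v, `-`))
    D - outer(rowMeans(D), rep(1, n)) - outer(rep(1, n), colMeans(D)) + mean(D)
  }
  A <- dc(x); B <- dc(y)
  dcov2 <- mean(A * B)
  dvar <- sqrt(mean(A * A) * mean(B * B))
  if (dvar <= 0) return(0)
  sqrt(max(dcov2, 0) / dvar)
}

# pairwise distance-correlation matrix over the columns of F
dcor_matrix <- function(F) {
  n <- nrow(F); p <- ncol(F)
  cent <- vector("list", p)
  for (j in seq_len(p)) {
    v <- F[, j]
    if (stats::sd(v) == 0) { cent[[j]] <- NULL; next }
    D <- abs(outer(v, v, `-`))
    cent[[j]] <- D - outer(rowMeans(D), rep(1, n)) -
      outer(rep(1, n), colMeans(D)) + mean(D)
  }
  dv <- vapply(cent, function(A) if (is.null(A)) 0 else mean(A * A), 0)
  S <- matrix(0, p, p)
  for (j in seq_len(p - 1)) for (l in (j + 1):p) {
    if (dv[j] > 0 && dv[l] > 0) {
      S[j, l] <- S[l, j] <-
        sqrt(max(mean(cent[[j]] * cent[[l]]), 0) / sqrt(dv[j] * dv[l]))
    }
  }
  S
}

#' Dominant-set clustering of a similarity matrix
#'
#' Iteratively extracts dominant sets by replicator dynamics: starting from
#' the uniform profile on the remaining items, iterate
#' `x <- x * (S x) / (x' S x)` to convergence and take the support of the
#' fixed point as one cluster, peel it off, and repeat.  Items left when no
#' coherent set remains become singletons.  Deterministic (uniform
#' initialization).
#'
#' @param S symmetric similarity matrix, entries in `[0, 1]`, zero diagonal.
#' @param support_tol relative support threshold on the converged profile.
#' @param max_iter,tol replicator iteration controls.
#' @return integer vector of cluster labels (1-based).
#' @export
dominant_set_clusters <- function(S, support_tol = 1e-2,
                                  max_iter = 2000, tol = 1e-10) {
  p <- nrow(S)
  if (p == 0) stop("empty similarity matrix")
  labels <- integer(p)
  remaining <- seq_len(p)
  cl <- 0L
  while (length(remaining) > 0) {
    if (length(remaining) == 1 || max(S[remaining, remaining]) <= 1e-12) {
      for (i in remaining) { cl <- cl + 1L; labels[i] <- cl }
      break
    }
    Sr <- S[remaining, remaining, drop = FALSE]
    # near-uniform start with a tiny deterministic index tilt so that
    # exactly symmetric similarity blocks cannot pin the dynamics on an
    # unstable mixed fixed point
    m <- length(remaining)
    x <- 1 + 1e-6 * (seq_len(m) / m)
    x <- x / sum(x)
    for (it in seq_len(max_iter)) {
      Sx <- as.vector(Sr %*% x)
      denom <- sum(x * Sx)
      if (denom <= 1e-300) break
      x_new <- x * Sx / denom
      if (sum(abs(x_new - x)) < tol) { x <- x_new; break }
      x <- x_new
    }
    members <- remaining[x > support_tol * max(x)]
    if (length(members) == 0) members <- remaining[which.max(x)]
    cl <- cl + 1L
    labels[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  labels
}

#' Select one representative feature per cluster
#'
#' Within each cluster, the member with the highest absolute distance
#' correlation with the target (age); ties go to the lowest feature index.
#'
#' @param partition integer cluster labels per feature.
#' @param features subjects x features matrix.
#' @param age target vector.
#' @return logical mask over features.
#' @export
select_representatives <- function(partition, features, age) {
  mask <- rep(FALSE, ncol(features))
  for (cl in sort(unique(partition))) {
    members <- which(partition == cl)
    sc <- vapply(members, function(j)
      suppressWarnings(distance_correlation(features[, j], age)), 0)
    mask[members[which.max(sc)]] <- TRUE
  }
  mask
}

#' Laplacian score of features for a two-group labelling
#'
#' Locality score on the label-informed neighbourhood graph (same-label
#' subjects connected).  Reported so that larger values mean more
#' discriminative: `score = 1 - (f' L f) / (f' D f)` on the centred feature.
#' Constant features score 0.
#'
#' @param F subjects x features matrix.
#' @param labels two-level factor (or coercible).
#' @return numeric vector of per-feature scores.
#' @export
laplacian_score <- function(F, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  F <- as.matrix(F)
  W <- outer(labels, labels, `==`) * 1
  diag(W) <- 0
  d <- rowSums(W)
  Dsum <- sum(d)
  Ft <- F - matrix(colSums(F * d) / Dsum, nrow(F), ncol(F), byrow = TRUE)
  denom <- colSums(d * Ft^2)
  num <- colSums(Ft * (d * Ft - W %*% Ft))            # f' L f per feature
  out <- ifelse(denom < 1e-24, 0, 1 - num / denom)
  as.vector(out)
}

#' Permutation threshold on Laplacian scores
#'
#' Recomputes the scores under random label shuffles and keeps features
#' whose true score exceeds `mean + c * sd` of their permuted scores.
#'
#' @param F subjects x features matrix.
#' @param labels two-level labels.
#' @param n_perm number of shuffles (>= 50; default 200).
#' @param c_sd standard-deviation multiplier (default 2.5).
#' @param seed RNG seed.
#' @return list with `mask` (logical), `scores`, `perm_mean`, `perm_sd`.
#' @export
permutation_threshold <- function(F, labels, n_perm = 200, c_sd = 2.5,
                                  seed = 1L) {
  if (n_perm < 50) stop("n_perm must be >= 50")
  scores <- laplacian_score(F, labels)
  set.seed(as.integer(seed %% .Machine$integer.max))
  perm <- matrix(0, n_perm, ncol(F))
  for (b in seq_len(n_perm))
    perm[b, ] <- laplacian_score(F, sample(labels))
  pm <- colMeans(perm)
  ps <- apply(perm, 2, stats::sd)
  list(mask = scores > pm + c_sd * ps, scores = scores,
       perm_mean = pm, perm_sd = ps)
}

standardize_cols <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  te <- if (is.null(test)) NULL else sweep(sweep(test, 2, mu, ), 2, sdv, "/")
  list(train = tr, test = te)
}

#' Leave-one-out SVR age prediction
#'
#' Per fold: standardize on the training subjects, fit a linear-kernel
#' support vector regressor, predict the held-out subject.  Reports the
#' squared correlation between predicted and true ages and the least-squares
#' line of predicted on true.
#'
#' @param F subjects x (selected) features matrix.
#' @param age true ages.
#' @param cost,epsilon SVR hyperparameters (defaults 1.0, 0.1).
#' @return list of class `age_regression`: `predictions`, `r2`, `slope`,
#'   `intercept`.
#' @export
svr_loocv <- function(F, age, cost = 1, epsilon = 0.1) {
  n <- nrow(F)
  if (n < 10) stop("need at least 10 subjects")
  if (stats::sd(age) == 0) stop("degenerate constant target")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    st <- standardize_cols(F[-i, , drop = FALSE], F[i, , drop = FALSE])
    fit <- e1071::svm(x = st$train, y = age[-i], type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    preds[i] <- stats::predict(fit, st$test)
  }
  line <- stats::lm(preds ~ age)
  structure(list(predictions = preds, r2 = stats::cor(preds, age)^2,
                 slope = unname(stats::coef(line)[2]),
                 intercept = unname(stats::coef(line)[1])),
            class = "age_regression")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

elm_fit <- function(X, y, n_hidden, ridge, seed) {
  p <- ncol(X)
  set.seed(as.integer(seed %% .Machine$integer.max))
  Win <- matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden)
  b <- stats::runif(n_hidden, -1, 1)
  H <- sigmoid(X %*% Win + matrix(b, nrow(X), n_hidden, byrow = TRUE))
  beta <- solve(crossprod(H) + ridge * diag(n_hidden), crossprod(H, y))
  list(Win = Win, b = b, beta = beta)
}

elm_predict <- function(model, X) {
  H <- sigmoid(X %*% model$Win +
                 matrix(model$b, nrow(X), length(model$b), byrow = TRUE))
  as.vector(H %*% model$beta)
}

#' Leave-one-out ELM classification
#'
#' Extreme learning machine: a single hidden layer of sigmoid units with
#' random fixed input weights (seeded), output weights by ridge-regularized
#' least squares on +/-1 targets; per-fold standardization.  The first
#' factor level is the positive class for sensitivity.
#'
#' @param F subjects x (selected) features matrix.
#' @param labels two-level labels.
#' @param n_hidden hidden units (default 100).
#' @param ridge ridge penalty (default 1e-6).
#' @param seed RNG seed (same random hidden layer in every fold).
#' @return list of class `group_classification`: `accuracy`, `sensitivity`,
#'   `specificity` (percent), `predictions`.
#' @export
elm_classify_loocv <- function(F, labels, n_hidden = 100, ridge = 1e-6,
                               seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (min(table(labels)) < 5) stop("need at least 5 subjects per class")
  y <- ifelse(labels == levels(labels)[1], 1, -1)
  n <- nrow(F)
  preds <- character(n)
  for (i in seq_len(n)) {
    st <- standardize_cols(F[-i, , drop = FALSE], F[i, , drop = FALSE])
    model <- elm_fit(st$train, y[-i], n_hidden, ridge, seed)
    preds[i] <- if (elm_predict(model, st$test) >= 0)
      levels(labels)[1] else levels(labels)[2]
  }
  pos <- labels == levels(labels)[1]
  structure(list(
    accuracy = 100 * mean(preds == as.character(labels)),
    sensitivity = 100 * mean(preds[pos] == levels(labels)[1]),
    specificity = 100 * mean(preds[!pos] == levels(labels)[2]),
    predictions = factor(preds, levels = levels(labels))),
    class = "group_classification")
}

#' Age-prediction pipeline with LOOCV
#'
#' Distance-correlation feature clustering (dominant sets), one
#' representative per cluster by correlation with age, then linear SVR.
#' With `nested = TRUE` (default) the selection is re-run inside every
#' leave-one-out fold, guarding against selection leakage; `nested = FALSE`
#' reproduces cohort-level selection before cross-validation.
#'
#' @param F subjects x features matrix.
#' @param age true ages.
#' @param nested re-select features within each fold.
#' @param cost,epsilon SVR hyperparameters.
#' @return an `age_regression` list with an added `n_selected` field.
#' @export
age_pipeline_loocv <- function(F, age, nested = TRUE, cost = 1,
                               epsilon = 0.1) {
  n <- nrow(F)
  if (n < 10) stop("need at least 10 subjects")
  select_on <- function(Ftr, agetr) {
    S <- dcor_matrix(Ftr)
    diag(S) <- 0
    part <- dominant_set_clusters(S)
    select_representatives(part, Ftr, agetr)
  }
  if (!nested) {
    mask <- select_on(F, age)
    res <- svr_loocv(F[, mask, drop = FALSE], age, cost, epsilon)
    res$n_selected <- sum(mask)
    return(res)
  }
  preds <- numeric(n)
  nsel <- integer(n)
  for (i in seq_len(n)) {
    mask <- select_on(F[-i, , drop = FALSE], age[-i])
    nsel[i] <- sum(mask)
    st <- standardize_cols(F[-i, mask, drop = FALSE],
                           F[i, mask, drop = FALSE])
    fit <- e1071::svm(x = st$train, y = age[-i], type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    preds[i] <- stats::predict(fit, st$test)
  }
  line <- stats::lm(preds ~ age)
  structure(list(predictions = preds, r2 = stats::cor(preds, age)^2,
                 slope = unname(stats::coef(line)[2]),
                 intercept = unname(stats::coef(line)[1]),
                 n_selected = round(mean(nsel))),
            class = "age_regression")
}

#' Group-classification pipeline with LOOCV
#'
#' Laplacian-score feature weights with a permutation threshold
#' (`mean + 2.5 sd` of shuffled-label scores), then ELM classification.
#' With `nested = TRUE` the selection is re-run inside every fold.
#'
#' @param F subjects x features matrix.
#' @param labels two-level labels.
#' @param nested re-select features within each fold.
#' @param n_perm permutations for the threshold (default 200).
#' @param n_hidden,ridge ELM hyperparameters.
#' @param seed RNG seed.
#' @return a `group_classification` list with an added `n_selected` field.
#' @export
classify_pipeline_loocv <- function(F, labels, nested = TRUE, n_perm = 200,
                                    n_hidden = 100, ridge = 1e-6, seed = 1L) {
  labels <- as.factor(labels)
  select_on <- function(Ftr, labtr, s) {
    m <- permutation_threshold(Ftr, labtr, n_perm, seed = s)$mask
    if (!any(m)) m[which.max(laplacian_score(Ftr, labtr))] <- TRUE
    m
  }
  if (!nested) {
    mask <- select_on(F, labels, seed)
    res <- elm_classify_loocv(F[, mask, drop = FALSE], labels,
                              n_hidden, ridge, seed)
    res$n_selected <- sum(mask)
    return(res)
  }
  n <- nrow(F)
  preds <- character(n)
  nsel <- integer(n)
  for (i in seq_len(n)) {
    mask <- select_on(F[-i, , drop = FALSE], labels[-i], seed + i)
    nsel[i] <- sum(mask)
    st <- standardize_cols(F[-i, mask, drop = FALSE],
                           F[i, mask, drop = FALSE])
    y <- ifelse(labels[-i] == levels(labels)[1], 1, -1)
    model <- elm_fit(st$train, y, n_hidden, ridge, seed)
    preds[i] <- if (elm_predict(model, st$test) >= 0)
      levels(labels)[1] else levels(labels)[2]
  }
  pos <- labels == levels(labels)[1]
  structure(list(
    accuracy = 100 * mean(preds == as.character(labels)),
    sensitivity = 100 * mean(preds[pos] == levels(labels)[1]),
    specificity = 100 * mean(preds[!pos] == levels(labels)[2]),
    predictions = factor(preds, levels = levels(labels)),
    n_selected = round(mean(nsel))),
    class = "group_classification")
}
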