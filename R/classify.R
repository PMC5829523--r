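#' Train/test split protocol
#'
#' The repeated random-split evaluation used for the identification
#' experiments: stratified splits (the same fraction of every class goes to
#' training), a fixed number of repeats, and a seed making the whole report
#' reproducible bit-for-bit.
#'
#' @param train_fraction fraction of each class used for training, in (0, 1).
#' @param n_repeats number of independent random splits.
#' @param stratified draw the split per class? (Unstratified splits can lose
#'   a class from the training set entirely.)
#' @param seed RNG seed for the split sequence.
#' @return A list of class `split_protocol`.
#' @export
split_protocol <- function(train_fraction = 0.5, n_repeats = 10,
                           stratified = TRUE, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  structure(list(train_fraction = train_fraction, n_repeats = n_repeats,
                 stratified = stratified, seed = seed),
            class = "split_protocol")
}

#' The supported classifier set
#'
#' Seven classifiers chosen for being realisable on embedded real-time
#' hardware: linear Gaussian Bayes (shared covariance), Fisher's
#' least-squares linear discriminant, multinomial logistic regression,
#' Gaussian naive Bayes, a linear support vector machine, a Parzen
#' (Gaussian-kernel density) classifier, and 1-nearest-neighbour.
#'
#' @return Character vector of classifier names accepted by [run_protocol()].
#' @export
wheelfeat_classifiers <- function() {
  c("linear_bayes", "fisher", "logistic", "naive_bayes",
    "svm_linear", "parzen", "knn1")
}

# classifiers operating on raw feature scales vs standardised ones: the
# distance-based rules (nearest neighbour, kernel density, margin) are not
# scale-invariant, so they see train-standardised features.
scaled_classifiers <- c("knn1", "parzen", "svm_linear")

#' Run the identification protocol
#'
#' For each repeat a fresh stratified split is drawn; every classifier is fit
#' on the training rows and scored (percent correct) on the held-out rows.
#' Features are standardised with training-set mean/variance before the
#' distance-based classifiers (1-NN, Parzen, linear SVM), whose decision
#' rules are not scale-invariant across features measured in counts, hertz
#' and seconds; the density/discriminant classifiers see raw scales.
#'
#' @param x data.frame or matrix of numeric features (rows = samples).
#' @param y class labels (factor or coercible).
#' @param protocol a [split_protocol].
#' @param classifiers character subset of [wheelfeat_classifiers()].
#' @param standardize standardise features for the distance-based rules?
#' @return An object of class `classifier_report`: list with `accuracy`
#'   (matrix, classifiers x repeats, percent), `mean` (named numeric) and the
#'   protocol.
#' @examples
#' d <- fixed_course_features()
#' rep <- run_protocol(d[, -(1:2)], d$id, split_protocol(seed = 1),
#'                     classifiers = "linear_bayes")
#' rep$mean
#' @export
run_protocol <- function(x, y, protocol = split_protocol(),
                         classifiers = wheelfeat_classifiers(),
                         standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (protocol$stratified && any(tab < 2L)) {
    stop("stratified splitting requires every class to have at least 2 samples")
  }
  classifiers <- match.arg(classifiers, wheelfeat_classifiers(),
                           several.ok = TRUE)
  acc <- matrix(NA_real_, nrow = length(classifiers),
                ncol = protocol$n_repeats,
                dimnames = list(classifiers,
                                paste0("test_", seq_len(protocol$n_repeats))))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(protocol$seed)
  for (r in seq_len(protocol$n_repeats)) {
    tr <- draw_split(y, protocol)
    x_tr <- x[tr, , drop = FALSE]
    x_te <- x[-tr, , drop = FALSE]
    y_tr <- droplevels(y[tr])
    y_te <- y[-tr]
    mu <- colMeans(x_tr)
    sd_ <- apply(x_tr, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    xs_tr <- scale(x_tr, mu, sd_)
    xs_te <- scale(x_te, mu, sd_)
    for (cl in classifiers) {
      use_scaled <- standardize && cl %in% scaled_classifiers
      pred <- fit_predict(cl,
                          if (use_scaled) xs_tr else x_tr, y_tr,
                          if (use_scaled) xs_te else x_te)
      acc[cl, r] <- 100 * mean(as.character(pred) == as.character(y_te))
    }
  }
  structure(list(accuracy = acc, mean = rowMeans(acc), protocol = protocol),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d repeats, %.0f:%.0f split\n",
              x$protocol$n_repeats, 100 * x$protocol$train_fraction,
              100 * (1 - x$protocol$train_fraction)))
  m <- cbind(round(x$accuracy, 1), Ave = round(x$mean, 1))
  print(m)
  invisible(x)
}

draw_split <- function(y, protocol) {
  if (protocol$stratified) {
    unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      n_tr <- max(1L, min(length(idx) - 1L,
                          round(protocol$train_fraction * length(idx))))
      sample(idx, n_tr)
    }))
  } else {
    n_tr <- max(2L, round(protocol$train_fraction * length(y)))
    sample(seq_along(y), n_tr)
  }
}

fit_predict <- function(name, x_tr, y_tr, x_te) {
  switch(name,
    linear_bayes = predict_linear_bayes(x_tr, y_tr, x_te),
    fisher = predict_fisher_lsq(x_tr, y_tr, x_te),
    logistic = predict_logistic(x_tr, y_tr, x_te),
    naive_bayes = predict_naive_bayes(x_tr, y_tr, x_te),
    svm_linear = {
      fit <- e1071::svm(x = x_tr, y = y_tr, kernel = "linear", scale = FALSE)
      stats::predict(fit, x_te)
    },
    parzen = predict_parzen(x_tr, y_tr, x_te),
    knn1 = class::knn(x_tr, x_te, y_tr, k = 1)
  )
}

# Linear Gaussian Bayes: one Gaussian per class with a shared (pooled)
# covariance and empirical priors. With fewer training rows than features the
# pooled covariance is singular; the Moore-Penrose pseudo-inverse restricts
# the discriminant to the spanned subspace.
predict_linear_bayes <- function(x_tr, y_tr, x_te) {
  lv <- levels(y_tr)
  p <- ncol(x_tr)
  means <- t(vapply(lv, function(l) colMeans(x_tr[y_tr == l, , drop = FALSE]),
                    numeric(p)))
  centred <- x_tr - means[as.integer(y_tr), , drop = FALSE]
  pooled <- crossprod(centred) / max(1L, nrow(x_tr) - length(lv))
  s_inv <- MASS::ginv(pooled)
  priors <- as.numeric(table(y_tr)) / length(y_tr)
  disc <- x_te %*% s_inv %*% t(means) -
    matrix(0.5 * diag(means %*% s_inv %*% t(means)), nrow(x_te), length(lv),
           byrow = TRUE) +
    matrix(log(priors), nrow(x_te), length(lv), byrow = TRUE)
  factor(lv[max.col(disc, ties.method = "first")], levels = lv)
}

# Fisher least-squares linear discriminant: regress the one-hot class
# indicator matrix on the (augmented) features, classify by the largest
# fitted indicator.
predict_fisher_lsq <- function(x_tr, y_tr, x_te) {
  lv <- levels(y_tr)
  xa_tr <- cbind(1, x_tr)
  target <- outer(y_tr, lv, "==") * 1
  beta <- MASS::ginv(xa_tr) %*% target
  scores <- cbind(1, x_te) %*% beta
  factor(lv[max.col(scores, ties.method = "first")], levels = lv)
}

predict_logistic <- function(x_tr, y_tr, x_te) {
  d_tr <- data.frame(x_tr)
  d_tr$.y <- y_tr
  fit <- nnet::multinom(.y ~ ., data = d_tr, trace = FALSE, decay = 1e-2,
                        maxit = 300, MaxNWts = 10000)
  stats::predict(fit, newdata = data.frame(x_te))
}

# Gaussian naive Bayes with a variance floor: with two training samples per
# class, integer-valued features can have zero within-class variance, which
# would make the Gaussian density degenerate.
predict_naive_bayes <- function(x_tr, y_tr, x_te) {
  lv <- levels(y_tr)
  p <- ncol(x_tr)
  eps <- 1e-9 * max(apply(x_tr, 2, stats::var), 1e-12)
  log_post <- vapply(lv, function(l) {
    rows <- x_tr[y_tr == l, , drop = FALSE]
    mu <- colMeans(rows)
    v <- pmax(apply(rows, 2, stats::var), eps)
    v[!is.finite(v)] <- eps
    ll <- rowSums(vapply(seq_len(p), function(j) {
      stats::dnorm(x_te[, j], mu[j], sqrt(v[j]), log = TRUE)
    }, numeric(nrow(x_te))))
    ll + log(sum(y_tr == l) / length(y_tr))
  }, numeric(nrow(x_te)))
  log_post <- matrix(log_post, nrow = nrow(x_te))
  factor(lv[max.col(log_post, ties.method = "first")], levels = lv)
}

# Parzen classifier: class-conditional Gaussian kernel densities with one
# shared bandwidth chosen by maximising the pooled leave-one-out likelihood
# of the training set.
predict_parzen <- function(x_tr, y_tr, x_te) {
  lv <- levels(y_tr)
  d_tr <- as.matrix(stats::dist(x_tr))^2
  med <- stats::median(d_tr[upper.tri(d_tr)])
  if (!is.finite(med) || med <= 0) med <- 1
  grid <- sqrt(med) * 2^seq(-4, 2, length.out = 15)
  p <- ncol(x_tr)
  loo <- vapply(grid, function(h) {
    k <- exp(-d_tr / (2 * h^2))
    diag(k) <- 0
    dens <- rowSums(k) / ((nrow(x_tr) - 1) * (2 * pi * h^2)^(p / 2))
    sum(log(pmax(dens, 1e-300)))
  }, numeric(1))
  h <- grid[which.max(loo)]
  cross <- outer(rowSums(x_te^2), rowSums(x_tr^2), "+") -
    2 * x_te %*% t(x_tr)
  k_te <- exp(-pmax(cross, 0) / (2 * h^2))
  post <- vapply(lv, function(l) rowSums(k_te[, y_tr == l, drop = FALSE]),
                 numeric(nrow(x_te)))
  post <- matrix(post, nrow = nrow(x_te))
  factor(lv[max.col(post, ties.method = "first")], levels = lv)
}
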