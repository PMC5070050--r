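#' Spearman rank correlation with small-sample exact p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (tied observations
#' receive average ranks). The two-sided p-value comes from the exact
#' permutation distribution of the statistic for n <= 10 (all n! assignments,
#' valid with or without ties) and from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list with `rho`, `p`, `n` and `method`.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("spearman_rho: x and y must have equal length")
  if (n < 3L) stop("spearman_rho: need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("spearman_rho: missing values")
  if (var(x) == 0 || var(y) == 0)
    stop("spearman_rho: rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 10L) {
    # exact permutation null: the cross-product sum is a monotone affine
    # image of rho, so compare on that scale
    s_obs <- sum(rx * ry)
    centre <- n * mean(rx) * mean(ry)
    s_perm <- perm_cross_sums(rx, ry)
    p <- mean(abs(s_perm - centre) >= abs(s_obs - centre) - 1e-9)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all permutations of seq_len(n) as an n! x n integer matrix (n <= 9)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# sum_i rx[i] * ry[perm(i)] over all n! permutations; n = 10 is split on the
# first position to keep the permutation matrix at 9! rows
perm_cross_sums <- function(rx, ry) {
  n <- length(rx)
  if (n <= 9L) {
    P <- all_perms(n)
    as.numeric(matrix(ry[P], nrow(P), n) %*% rx)
  } else {
    P <- all_perms(n - 1L)
    unlist(lapply(seq_len(n), function(k) {
      rest <- ry[-k]
      rx[1L] * ry[k] +
        as.numeric(matrix(rest[P], nrow(P), n - 1L) %*% rx[-1L])
    }), use.names = FALSE)
  }
}

#' Holm step-down multiple-testing adjustment
#'
#' Standard step-down procedure controlling the family-wise error rate:
#' ascending p-values are multiplied by `m, m-1, ..., 1`, a running maximum
#' enforces monotonicity, values are capped at 1 and returned in the original
#' order. Uniformly no more conservative than Bonferroni.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("holm_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Spearman correlation report: motion features vs CIB composites
#'
#' Correlates each of the 17 motion features with each of the 8 CIB composite
#' scores across sessions and applies the Holm correction. The correction
#' family is either each composite's column of 17 tests (default, matching
#' how one corrected p-value is quoted per feature-composite pair within a
#' composite) or the global set of all cells.
#'
#' Cells whose feature (or composite) is constant across sessions, or
#' contains missing values, are reported as NA and excluded from the
#' correction family.
#'
#' @param features data.frame with `session_id` and the 17 canonical feature
#'   columns (see [read_feature_table()]).
#' @param cib data.frame with `session_id` and the eight composite columns
#'   (`maternal_sensitivity`, `mother_intrusiveness`, `mother_limit_setting`,
#'   `dyadic_reciprocity`, `negative_dyadic_status`, `infant_avoidance`,
#'   `infant_engagement`, `infant_compliance`), each scored in `[1, 5]`.
#' @param family `"per_composite"` or `"global"`.
#' @return list of class `correlation_report` with matrices `rho`, `p_raw`,
#'   `p_holm` (features x composites), the `family` mode and `family_size`.
#' @export
correlate_features_with_cib <- function(features, cib,
                                        family = c("per_composite", "global")) {
  family <- match.arg(family)
  fn <- feature_names()
  comp <- cib_composite_names()
  if (!"session_id" %in% names(features) || !"session_id" %in% names(cib))
    stop("correlate_features_with_cib: both tables need a session_id column")
  extra <- setdiff(features$session_id, cib$session_id)
  miss <- setdiff(cib$session_id, features$session_id)
  if (length(extra) || length(miss))
    stop("correlate_features_with_cib: session ids do not match; ",
         "only in features: [", paste(extra, collapse = ", "),
         "], only in cib: [", paste(miss, collapse = ", "), "]")
  cib <- cib[match(features$session_id, cib$session_id), , drop = FALSE]
  n <- nrow(features)
  if (n < 5L) stop("correlate_features_with_cib: need n >= 5 sessions")
  badf <- setdiff(fn, names(features)); badc <- setdiff(comp, names(cib))
  if (length(badf) || length(badc))
    stop("correlate_features_with_cib: missing columns: ",
         paste(c(badf, badc), collapse = ", "))
  rng <- range(as.matrix(cib[, comp]), na.rm = TRUE)
  if (rng[1L] < 1 - 1e-9 || rng[2L] > 5 + 1e-9)
    stop("correlate_features_with_cib: composite scores outside [1, 5]")
  rho <- p_raw <- matrix(NA_real_, length(fn), length(comp),
                         dimnames = list(fn, comp))
  for (i in seq_along(fn)) for (j in seq_along(comp)) {
    xv <- features[[fn[i]]]; yv <- cib[[comp[j]]]
    if (anyNA(xv) || anyNA(yv) || var(xv) == 0 || var(yv) == 0) next
    r <- spearman_rho(xv, yv)
    rho[i, j] <- r$rho; p_raw[i, j] <- r$p
  }
  p_holm <- p_raw
  if (family == "global") {
    ok <- !is.na(p_raw)
    p_holm[ok] <- holm_adjust(p_raw[ok])
    family_size <- sum(ok)
  } else {
    family_size <- integer(length(comp))
    for (j in seq_along(comp)) {
      ok <- !is.na(p_raw[, j])
      p_holm[ok, j] <- holm_adjust(p_raw[ok, j])
      family_size[j] <- sum(ok)
    }
    names(family_size) <- comp
  }
  structure(list(rho = rho, p_raw = p_raw, p_holm = p_holm,
                 family = family, family_size = family_size, n = n),
            class = "correlation_report")
}

#' Names of the eight CIB composite scores
#' @return Character vector of length 8.
#' @export
cib_composite_names <- function() {
  c("maternal_sensitivity", "mother_intrusiveness", "mother_limit_setting",
    "dyadic_reciprocity", "negative_dyadic_status", "infant_avoidance",
    "infant_engagement", "infant_compliance")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d features x %d composites, n = %d, Holm family: %s\n",
              nrow(x$rho), ncol(x$rho), x$n, x$family))
  sig <- which(x$p_holm < 0.05, arr.ind = TRUE)
  cat(sprintf("  Holm-significant cells (p < 0.05): %d\n", nrow(sig)))
  if (nrow(sig)) {
    for (k in seq_len(min(nrow(sig), 12L)))
      cat(sprintf("    %s ~ %s: rho = %+.2f, p_holm = %.3f\n",
                  rownames(x$rho)[sig[k, 1L]], colnames(x$rho)[sig[k, 2L]],
                  x$rho[sig[k, 1L], sig[k, 2L]],
                  x$p_holm[sig[k, 1L], sig[k, 2L]]))
  }
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test in the Mann-Whitney U convention: the statistic is
#' the rank sum of `x` minus `n_x(n_x+1)/2`. Exact for combined samples up to
#' 20 without ties, normal approximation with tie correction otherwise.
#'
#' @param x,y numeric group vectors.
#' @return list with `W`, `p` and the method used.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("rank_sum_test: empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of tables no
#' more probable than the observed one (margins fixed); the odds ratio is the
#' conditional maximum-likelihood estimate.
#'
#' @param table 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("fisher_exact: need a 2 x 2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_exact: counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("fisher_exact: zero margin")
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Linear SVM group classification with stratified cross-validation
#'
#' Fits a linear maximum-margin classifier to the session feature vectors and
#' estimates held-out accuracy by stratified k-fold cross-validation. Rows
#' are shuffled with the given seed before the stratified split; features are
#' standardized using each training fold's statistics only. Also reports the
#' whole-data training accuracy (fit and evaluated on all sessions).
#'
#' @param features numeric matrix or data.frame (sessions x features), no
#'   missing values.
#' @param labels binary group labels (factor, character or 0/1), length
#'   `nrow(features)`.
#' @param k number of folds (default 15).
#' @param seed integer seed driving the shuffle; the result is bit
#'   reproducible given `(features, labels, k, seed)`.
#' @param cost SVM cost parameter.
#' @return list of class `classification_result`: `fold_accuracies`,
#'   `total_accuracy` (pooled held-out), `training_accuracy`, `confusion`
#'   (2 x 2, truth x prediction), `k`, `seed`.
#' @export
classify_dyads <- function(features, labels, k = 15, seed = 1, cost = 1) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- factor(labels)
  n <- nrow(X)
  if (length(y) != n) stop("classify_dyads: labels length must match rows")
  if (nlevels(y) != 2L) stop("classify_dyads: exactly two classes required")
  if (anyNA(X)) {
    bad <- colnames(X)[apply(is.na(X), 2L, any)]
    stop("classify_dyads: missing values in feature column(s): ",
         paste(bad, collapse = ", "))
  }
  k <- as.integer(k)
  if (k < 2L || k > n) stop("classify_dyads: need 2 <= k <= n")
  # constant columns carry no information and break standardization
  keep <- apply(X, 2L, function(col) var(col) > 0)
  if (!any(keep)) stop("classify_dyads: all feature columns are constant")
  X <- X[, keep, drop = FALSE]
  folds <- with_seed(seed, {
    idx <- sample.int(n)                       # randomize before splitting
    fold <- integer(n)
    nxt <- 0L                                  # rotate start so folds fill evenly
    for (lv in levels(y)) {
      members <- idx[y[idx] == lv]             # shuffled within class
      fold[members] <- ((nxt + seq_along(members) - 1L) %% k) + 1L
      nxt <- nxt + length(members)
    }
    fold
  })
  for (f in seq_len(k)) {
    train_y <- y[folds != f]
    if (length(unique(train_y)) < 2L)
      stop("classify_dyads: a training split lost a class; use a smaller k")
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(!tr)) { fold_acc[f] <- NA_real_; next }
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = TRUE)
    ph <- predict(fit, X[!tr, , drop = FALSE])
    pred[!tr] <- ph
    fold_acc[f] <- mean(ph == y[!tr])
  }
  fit_all <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = TRUE)
  train_acc <- mean(predict(fit_all, X) == y)
  confusion <- table(truth = y, prediction = pred)
  structure(list(fold_accuracies = fold_acc,
                 total_accuracy = mean(pred == y),
                 training_accuracy = train_acc,
                 confusion = confusion,
                 k = k, seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %d-fold CV (seed %d)\n", x$k, x$seed))
  cat(sprintf("  held-out total accuracy: %.3f\n", x$total_accuracy))
  cat(sprintf("  training accuracy:       %.3f\n", x$training_accuracy))
  print(x$confusion)
  invisible(x)
}
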