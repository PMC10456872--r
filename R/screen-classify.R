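#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration p-value when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.  Missing values are dropped.
#'
#' @param x,y numeric samples from the two groups.
#' @return the two-sided p-value; 1 when every value is identical across
#'   both groups, `NA` when either group has no finite values.
#' @export
mw_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  exact <- (length(pooled) <= 12) && !any(duplicated(pooled))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Screen indices for group differences
#'
#' Applies [mw_test()] to every feature column and reports group means and
#' standard deviations.  A feature is testable only when both groups have
#' at least 2 finite values; untestable features receive `NA` p-values and
#' never pass.
#'
#' @param features numeric matrix or data frame (subjects x indices) with
#'   column names.
#' @param groups factor or character vector of group labels, length
#'   `nrow(features)`, exactly two levels present.
#' @param p_max significance cut (default 0.05; `p <= p_max` passes).
#' @return data frame of class `screen_result` with columns `index`, `p`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `pass`; groups `a`/`b` follow the
#'   factor level order, recorded in attribute `"groups"`.
#' @export
screen_indices <- function(features, groups, p_max = 0.05) {
  features <- as.matrix(features)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (length(groups) != nrow(features))
    stop("groups length must match the number of subjects")
  ga <- levels(groups)[1]; gb <- levels(groups)[2]
  res <- lapply(colnames(features), function(nm) {
    xa <- features[groups == ga, nm]
    xb <- features[groups == gb, nm]
    p <- if (sum(is.finite(xa)) >= 2 && sum(is.finite(xb)) >= 2)
      mw_test(xa, xb) else NA_real_
    data.frame(index = nm, p = p,
               mean_a = mean(xa, na.rm = TRUE), sd_a = sd(xa[is.finite(xa)]),
               mean_b = mean(xb, na.rm = TRUE), sd_b = sd(xb[is.finite(xb)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pass <- !is.na(out$p) & out$p <= p_max
  attr(out, "groups") <- c(ga, gb)
  class(out) <- c("screen_result", class(out))
  out
}

#' Admissible low-correlation index pairs
#'
#' All unordered pairs of significant indices whose absolute Spearman rank
#' correlation stays below `rho_max`; highly collinear indices would carry
#' redundant information into a two-feature classifier.
#'
#' @param features subject x index matrix or data frame.
#' @param significant character vector of significant index names (at
#'   least 2).
#' @param rho_max correlation cap (default 0.7).
#' @return two-column character matrix of admissible pairs; the Spearman
#'   matrix is attached as attribute `"rho"`.  Errors (with the
#'   correlation matrix in the message) when no pair is admissible.
#' @export
correlation_filter <- function(features, significant, rho_max = 0.7) {
  if (length(significant) < 2)
    stop("need at least 2 significant indices to form pairs")
  m <- as.matrix(features)[, significant, drop = FALSE]
  rho <- suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs"))
  pairs <- t(combn(significant, 2))
  ok <- abs(rho[pairs]) < rho_max
  ok[is.na(ok)] <- FALSE
  out <- pairs[ok, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no admissible pair below |rho| = ", rho_max, "; correlations:\n",
         paste(utils::capture.output(print(round(rho, 2))), collapse = "\n"))
  colnames(out) <- c("index1", "index2")
  attr(out, "rho") <- rho
  out
}

#' Kernel matrix between two sets of feature vectors
#'
#' Gaussian `K = exp(-||x-y||^2 / (2 sigma^2))`, Laplace
#' `K = exp(-||x-y|| / sigma)` and ANOVA
#' `K = (sum_k exp(-sigma (x_k - y_k)^2))^d` kernels on standardized
#' features.
#'
#' @param X,Y numeric matrices with observations in rows and the same
#'   number of columns (`Y` defaults to `X`).
#' @param kernel `"gaussian"`, `"laplace"` or `"anova"`.
#' @param sigma positive kernel width/scale.
#' @param d polynomial degree of the ANOVA kernel.
#' @return `nrow(X) x nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(X, Y = X, kernel = c("gaussian", "laplace", "anova"),
                          sigma = 1, d = 2) {
  kernel <- match.arg(kernel)
  if (sigma <= 0) stop("sigma must be positive")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of columns")
  if (kernel == "anova") {
    K <- matrix(0, nrow(X), nrow(Y))
    for (k in seq_len(ncol(X))) {
      dk <- outer(X[, k], Y[, k], "-")
      K <- K + exp(-sigma * dk^2)
    }
    return(K^d)
  }
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  if (kernel == "gaussian") exp(-d2 / (2 * sigma^2))
  else exp(-sqrt(d2) / sigma)
}

#' Train a soft-margin SVM on a precomputed kernel matrix
#'
#' Solves the C-SVC dual by sequential minimal optimization, yielding the
#' decision function `f(x) = sum_i alpha_i y_i K(x_i, x) + b`; `sign(f)`
#' gives the class.
#'
#' @param gram symmetric kernel matrix of the training points.
#' @param labels vector coercible to two classes; the `positive` class is
#'   mapped to +1.
#' @param C positive box constraint; larger values penalize margin
#'   violations more strongly.
#' @param positive the label treated as the positive (sensitivity) class;
#'   defaults to the first factor level.
#' @return object of class `baro_svm` with `alpha`, `b`, `y`, `support`,
#'   `levels` (`c(positive, negative)`) and `C`.
#' @export
train_svm <- function(gram, labels, C = 1, positive = NULL) {
  gram <- as.matrix(gram)
  f <- as.factor(labels)
  f <- droplevels(f)
  if (nlevels(f) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(f)[1]
  if (!positive %in% levels(f)) stop("positive class not present in labels")
  negative <- setdiff(levels(f), positive)
  y <- ifelse(as.character(f) == positive, 1L, -1L)
  fit <- .smo_train(gram, as.integer(y), C)
  structure(list(alpha = fit$alpha, b = fit$b, y = y,
                 support = fit$support, iterations = fit$iterations,
                 levels = c(positive = positive, negative = negative),
                 C = C),
            class = "baro_svm")
}

#' Decision values and class predictions of a trained SVM
#'
#' @param object a [train_svm()] fit.
#' @param ktest kernel matrix between test points (rows) and the training
#'   points (columns) used for the fit.
#' @param type `"class"` for labels, `"decision"` for raw `f(x)`.
#' @param ... unused.
#' @export
predict.baro_svm <- function(object, ktest, type = c("class", "decision"),
                             ...) {
  type <- match.arg(type)
  f <- .smo_decision(as.matrix(ktest), object$alpha, as.integer(object$y),
                     object$b)
  if (type == "decision") return(f)
  ifelse(f >= 0, object$levels[["positive"]], object$levels[["negative"]])
}

#' Classification metrics from confusion counts
#'
#' @param tp,fn,tn,fp confusion counts with the sensitivity class as
#'   positive.
#' @return named vector with `acc`, `sn`, `sp` in percent.
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  c(acc = 100 * (tp + tn) / n,
    sn = 100 * tp / (tp + fn),
    sp = 100 * tn / (tn + fp))
}

# numeric feature matrix with column names preserved verbatim
.feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    nm <- names(features)
    features <- do.call(cbind, lapply(features, as.numeric))
    colnames(features) <- nm
  }
  m <- as.matrix(features)
  if (is.null(colnames(m))) stop("features must have column names")
  m
}

# per-fold column standardization using training statistics only
.standardize_fold <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sg <- apply(X[train_idx, , drop = FALSE], 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
}

#' Leave-one-out cross-validation of one feature pair
#'
#' For each of the n folds the held-out subject is predicted by an SVM
#' trained on the remaining subjects; feature standardization statistics
#' are computed from the training fold only.  Subjects missing either
#' feature are excluded (count reported).
#'
#' @param features subject x index matrix or data frame with named
#'   columns.
#' @param groups two-class label vector.
#' @param pair character vector of two index names.
#' @param kernel,sigma,d kernel specification, see [kernel_matrix()].
#' @param C box constraint; may be a vector, in which case the per-fold
#'   kernel matrices are shared across the values and a list of results
#'   (one per C) is returned.
#' @param positive positive (sensitivity) class label.
#' @param admissible_folds optional logical vector (length n): folds where
#'   the pair failed in-fold screening predict the training majority class
#'   instead of an SVM decision (honest screening mode).
#' @return list with `acc`, `sn`, `sp` (percent), `counts`
#'   (tp/fn/tn/fp), `predictions`, `truth` and `n_excluded`.
#' @export
loocv_evaluate <- function(features, groups, pair, kernel = "gaussian",
                           C = 1, sigma = 1, d = 2, positive = NULL,
                           admissible_folds = NULL) {
  X <- .feature_matrix(features)[, pair, drop = FALSE]
  g <- as.factor(groups)
  ok <- stats::complete.cases(X)
  n_excluded <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  g <- droplevels(g[ok])
  if (!is.null(admissible_folds)) admissible_folds <- admissible_folds[ok]
  if (nlevels(g) != 2) stop("two classes required after exclusions")
  n <- nrow(X)
  if (n < 4 || min(table(g)) < 2)
    stop("need at least 4 subjects and 2 per class")
  if (is.null(positive)) positive <- levels(g)[1]
  negative <- setdiff(levels(g), positive)
  nC <- length(C)
  preds <- matrix(NA_character_, n, nC)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(g[tr])) < 2) stop("single-class training fold")
    if (!is.null(admissible_folds) && !admissible_folds[i]) {
      tab <- table(g[tr])
      preds[i, ] <- names(tab)[which.max(tab)]
      next
    }
    Z <- .standardize_fold(X, tr)
    Ktr <- kernel_matrix(Z[tr, , drop = FALSE], kernel = kernel,
                         sigma = sigma, d = d)
    Kte <- kernel_matrix(Z[i, , drop = FALSE], Z[tr, , drop = FALSE],
                         kernel = kernel, sigma = sigma, d = d)
    for (ci in seq_len(nC)) {
      fit <- train_svm(Ktr, g[tr], C = C[ci], positive = positive)
      preds[i, ci] <- predict(fit, Kte)
    }
  }
  truth <- as.character(g)
  one <- function(pr) {
    tp <- sum(pr == positive & truth == positive)
    fn <- sum(pr == negative & truth == positive)
    tn <- sum(pr == negative & truth == negative)
    fp <- sum(pr == positive & truth == negative)
    met <- metrics_from_counts(tp, fn, tn, fp)
    list(acc = unname(met["acc"]), sn = unname(met["sn"]),
         sp = unname(met["sp"]),
         counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
         predictions = pr, truth = truth, n_excluded = n_excluded)
  }
  if (nC == 1) one(preds[, 1])
  else lapply(seq_len(nC), function(ci) one(preds[, ci]))
}

# per-fold screening: which pairs remain admissible when screening uses the
# training subjects only
.fold_admissibility <- function(features, groups, pairs, p_max, rho_max) {
  n <- nrow(features)
  adm <- matrix(FALSE, n, nrow(pairs))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sc <- screen_indices(features[tr, , drop = FALSE], groups[tr],
                         p_max = p_max)
    sig <- sc$index[sc$pass]
    if (length(sig) < 2) next
    rho <- suppressWarnings(
      cor(as.matrix(features)[tr, sig, drop = FALSE], method = "spearman",
          use = "pairwise.complete.obs"))
    for (j in seq_len(nrow(pairs))) {
      a <- pairs[j, 1]; b <- pairs[j, 2]
      if (a %in% sig && b %in% sig && isTRUE(abs(rho[a, b]) < rho_max))
        adm[i, j] <- TRUE
    }
  }
  adm
}

#' Exhaustive pairwise SVM model search for one group comparison
#'
#' Screens indices by Mann-Whitney test, forms low-correlation pairs,
#' and evaluates every (pair, kernel, C, sigma, d) candidate by
#' leave-one-out cross-validation, returning the candidate with the best
#' accuracy (ties broken by higher sensitivity, then fewer support
#' vectors, then lexicographic pair name).  In the default honest mode
#' screening is recomputed inside every training fold and folds where a
#' pair fails in-fold screening fall back to majority-class prediction;
#' `full_sample_screen = TRUE` screens once on the full dataset, reproducing the
#' optimistic full-sample protocol.
#'
#' @param features subject x index matrix or data frame.
#' @param groups two-class label vector.
#' @param positive the sensitivity class; defaults to the first factor
#'   level.
#' @param kernels kernels to search (default all three).
#' @param C_grid,sigma_grid,d_grid hyperparameter grids; the defaults
#'   bracket typical optima for standardized two-feature problems.
#' @param p_max screening significance cut (default 0.05).
#' @param rho_max Spearman correlation cap for pairs (default 0.7).
#' @param top_k at most this many indices (smallest screening p-values)
#'   enter the pairing stage, bounding the search (default 10).
#' @param full_sample_screen if `TRUE`, screening is performed once on the full
#'   sample (no per-fold re-screening).
#' @return object of class `baro_model`: the selected `pair`, `kernel`,
#'   `C`, `sigma`, `d`, metrics `acc`/`sn`/`sp`, confusion `counts`,
#'   per-fold `predictions`, the `screening` table, the full search
#'   `trace`, and a final SVM trained on all subjects (for [predict()]).
#' @export
model_search <- function(features, groups,
                         positive = NULL,
                         kernels = c("gaussian", "laplace", "anova"),
                         C_grid = c(0.5, 1, 2.2, 5, 10),
                         sigma_grid = c(0.5, 0.8, 1, 1.5, 2, 3),
                         d_grid = c(1, 2, 3),
                         p_max = 0.05, rho_max = 0.7, top_k = 10,
                         full_sample_screen = FALSE) {
  features <- .feature_matrix(features)
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (is.null(positive)) positive <- levels(g)[1]
  kernels <- match.arg(kernels, several.ok = TRUE)
  screening <- screen_indices(features, g, p_max = p_max)
  sig <- screening$index[screening$pass]
  if (length(sig) < 2)
    stop("fewer than 2 indices passed screening (p <= ", p_max, ")")
  if (length(sig) > top_k) {
    ord <- order(screening$p[match(sig, screening$index)])
    sig <- sig[ord][seq_len(top_k)]
  }
  pairs <- correlation_filter(features, sig, rho_max = rho_max)
  adm <- NULL
  if (!full_sample_screen)
    adm <- .fold_admissibility(features, g, pairs, p_max, rho_max)
  trace <- list()
  best <- NULL
  for (j in seq_len(nrow(pairs))) {
    pair <- pairs[j, ]
    Xp <- features[, pair, drop = FALSE]
    ok <- stats::complete.cases(Xp)
    Zfull <- .standardize_fold(Xp[ok, , drop = FALSE], seq_len(sum(ok)))
    adm_j <- if (is.null(adm)) NULL else adm[, j]
    for (kern in kernels) {
      dg <- if (kern == "anova") d_grid else NA
      for (sg in sigma_grid) for (dd in dg) {
        Kfull <- kernel_matrix(Zfull, kernel = kern, sigma = sg,
                               d = if (is.na(dd)) 2 else dd)
        evs <- loocv_evaluate(features, g, pair, kernel = kern, C = C_grid,
                              sigma = sg, d = if (is.na(dd)) 2 else dd,
                              positive = positive, admissible_folds = adm_j)
        if (length(C_grid) == 1) evs <- list(evs)
        for (ci in seq_along(C_grid)) {
          Cv <- C_grid[ci]
          ev <- evs[[ci]]
          # support count of a full-data fit, used only for tie-breaking
          nsv <- tryCatch(length(train_svm(Kfull, g[ok], C = Cv,
                                           positive = positive)$support),
            error = function(e) NA_integer_)
          cand <- list(pair = unname(pair), kernel = kern, C = Cv,
                       sigma = sg, d = if (is.na(dd)) NA_real_ else dd,
                       acc = ev$acc, sn = ev$sn, sp = ev$sp,
                       counts = ev$counts, predictions = ev$predictions,
                       truth = ev$truth, n_sv = nsv,
                       n_excluded = ev$n_excluded)
          trace[[length(trace) + 1L]] <- cand
          if (is.null(best) || .better_candidate(cand, best)) best <- cand
        }
      }
    }
  }
  if (is.null(best)) stop("empty search grid")
  # final model on all (complete) subjects with the selected configuration
  Xp <- features[, best$pair, drop = FALSE]
  ok <- stats::complete.cases(Xp)
  mu <- colMeans(Xp[ok, , drop = FALSE])
  sdv <- apply(Xp[ok, , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(Xp[ok, , drop = FALSE], 2, mu, "-"), 2, sdv, "/")
  dfin <- if (is.na(best$d)) 2 else best$d
  fit <- train_svm(kernel_matrix(Z, kernel = best$kernel,
                                 sigma = best$sigma, d = dfin),
                   g[ok], C = best$C, positive = positive)
  structure(c(best,
              list(positive = positive,
                   negative = setdiff(levels(g), positive),
                   screening = screening,
                   trace = .trace_frame(trace),
                   fit = fit, train_Z = Z, train_center = mu,
                   train_scale = sdv, full_sample_screen = full_sample_screen)),
            class = "baro_model")
}

.better_candidate <- function(a, b) {
  if (a$acc != b$acc) return(a$acc > b$acc)
  if (a$sn != b$sn) return(a$sn > b$sn)
  na <- if (is.na(a$n_sv)) Inf else a$n_sv
  nb <- if (is.na(b$n_sv)) Inf else b$n_sv
  if (na != nb) return(na < nb)
  paste(a$pair, collapse = "|") < paste(b$pair, collapse = "|")
}

.trace_frame <- function(trace) {
  do.call(rbind, lapply(trace, function(t)
    data.frame(index1 = t$pair[1], index2 = t$pair[2], kernel = t$kernel,
               C = t$C, sigma = t$sigma, d = t$d, acc = t$acc, sn = t$sn,
               sp = t$sp, n_sv = t$n_sv, stringsAsFactors = FALSE)))
}

#' @export
print.baro_model <- function(x, ...) {
  cat(sprintf("<baro_model %s vs %s>\n", x$positive, x$negative))
  cat(sprintf("  pair:   %s + %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  kernel: %s (C = %g, sigma = %g%s)\n", x$kernel, x$C,
              x$sigma, if (is.na(x$d)) "" else sprintf(", d = %g", x$d)))
  cat(sprintf("  LOOCV:  Acc %.1f%% | Sn %.1f%% | Sp %.1f%%\n",
              x$acc, x$sn, x$sp))
  cat(sprintf("  counts: TP %d, FN %d, TN %d, FP %d\n",
              x$counts["tp"], x$counts["fn"], x$counts["tn"],
              x$counts["fp"]))
  invisible(x)
}

#' @export
summary.baro_model <- function(object, n_trace = 5, ...) {
  print(object)
  cat(sprintf("\nScreening: %d/%d indices significant (p <= 0.05)\n",
              sum(object$screening$pass), nrow(object$screening)))
  tr <- object$trace
  tr <- tr[order(-tr$acc, -tr$sn), ]
  cat(sprintf("Search: %d candidates; top %d:\n", nrow(tr),
              min(n_trace, nrow(tr))))
  print(head(tr, n_trace), row.names = FALSE)
  invisible(object)
}

#' Predict group membership for new subjects
#'
#' @param object a [model_search()] result.
#' @param newdata data frame or matrix containing the model's two feature
#'   columns.
#' @param type `"class"` or `"decision"`.
#' @param ... unused.
#' @export
predict.baro_model <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  X <- .feature_matrix(newdata)[, object$pair, drop = FALSE]
  Z <- sweep(sweep(X, 2, object$train_center, "-"), 2,
             object$train_scale, "/")
  dfin <- if (is.na(object$d)) 2 else object$d
  K <- kernel_matrix(Z, object$train_Z, kernel = object$kernel,
                     sigma = object$sigma, d = dfin)
  predict(object$fit, K, type = type)
}
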