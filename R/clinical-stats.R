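#' Pearson association between editing levels and a clinical feature
#'
#' Complete-case Pearson correlation with two-sided t-test p-value
#' (n - 2 df). Pairs with fewer than 3 complete observations or a constant
#' vector are untestable.
#'
#' @param x,y Numeric vectors over matched samples.
#' @return data.frame row: r, p, n.
#' @keywords internal
pearson_assoc <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  n <- sum(cc)
  if (n < 3 || stats::var(x[cc]) == 0 || stats::var(y[cc]) == 0)
    return(data.frame(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x[cc], y[cc], method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlation of hub editing events with clinical hormone features
#'
#' Emits the full hub x feature grid of Pearson r and p over complete
#' cases; constant editing vectors are skipped (logged as untestable rows).
#'
#' @param em An `EditingMatrix` (or events x samples level matrix).
#' @param hub_ids Event keys (`contig:pos`) or row names to test.
#' @param metadata `SampleMetadata`; features from [hormone_features()].
#' @return data.frame of class `AssociationResult`: event, feature, r, p, n.
#' @export
hub_clinical_correlation <- function(em, hub_ids, metadata) {
  lev <- if (inherits(em, "EditingMatrix")) em$levels else em
  ord <- match(colnames(lev), metadata$sample_id)
  if (anyNA(ord)) stop_edscan("samples missing from metadata")
  md <- metadata[ord, ]
  out <- list()
  for (ev in hub_ids) {
    if (!ev %in% rownames(lev)) stop_edscan("unknown event %s", ev)
    for (f in hormone_features()) {
      a <- pearson_assoc(lev[ev, ], md[[f]])
      out[[paste(ev, f)]] <- cbind(data.frame(event = ev, feature = f), a)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("AssociationResult", "data.frame")
  res
}

#' Cis correlation between an event's editing level and host-gene expression
#'
#' @param event_levels Editing levels over samples.
#' @param gene_expression Expression of the host gene over the same samples.
#' @return data.frame: r, p, n (untestable rows carry NA).
#' @export
cis_correlation <- function(event_levels, gene_expression) {
  if (length(event_levels) != length(gene_expression))
    stop_edscan("sample mismatch")
  pearson_assoc(event_levels, gene_expression)
}

#' Empirical ROC curve and AUC for a single marker
#'
#' Higher scores are treated as case-like. The curve is evaluated at every
#' distinct score threshold; the AUC is the Mann-Whitney U statistic over
#' case/control pairs with half credit for ties, which equals the
#' trapezoidal integral of the curve.
#'
#' @param levels Numeric marker values (NA excluded with their labels).
#' @param labels Group labels (`"case"`/`"control"`) or logical/0-1 with
#'   `TRUE`/1 = case.
#' @return Object of class `ROCResult`: `points` (threshold, fpr, tpr),
#'   `auc`, `n_case`, `n_control`.
#' @export
roc_single <- function(levels, labels) {
  lab <- normalize_labels(labels)
  keep <- !is.na(levels) & !is.na(lab)
  x <- levels[keep]; y <- lab[keep]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop_edscan("both classes must be present")
  thr <- sort(unique(x), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(x[!y] >= t), numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  # Mann-Whitney with tie correction via midranks
  r <- rank(x)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = points, auc = auc, n_case = n1, n_control = n0),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d case / %d control)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    bad <- !l %in% c("case", "control") & !is.na(l)
    if (any(bad)) stop_edscan("unknown label: %s", l[bad][1])
    l == "case"
  } else as.logical(labels)
}

#' Trapezoidal area under an ROC point set
#' @param points data.frame with `fpr`, `tpr` (any order).
#' @export
auc_trapezoid <- function(points) {
  p <- points[order(points$fpr, points$tpr), ]
  p <- rbind(p[, c("fpr", "tpr")], data.frame(fpr = 1, tpr = 1))
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' ROC for a combined multi-marker panel via logistic regression
#'
#' Markers are combined by unpenalized logistic regression of the label on
#' the marker levels (intercept included); the score is the fitted linear
#' predictor, and the ROC/AUC is computed in-sample on these scores.
#' Duplicate marker columns are dropped before fitting; if the fit is
#' separated (fitted probabilities at 0/1), a ridge-stabilized fit with a
#' small fixed penalty is used and flagged in the result.
#'
#' @param level_matrix Samples x markers numeric matrix (>= 2 markers).
#' @param labels As in [roc_single()].
#' @return `ROCResult` with extra fields `coefficients`, `ridge`
#'   (logical), `markers_used`.
#' @export
roc_combined <- function(level_matrix, labels) {
  x <- as.matrix(level_matrix)
  if (ncol(x) < 2) stop_edscan("need >= 2 markers")
  lab <- normalize_labels(labels)
  cc <- stats::complete.cases(x) & !is.na(lab)
  if (sum(cc) < 6) stop_edscan("need >= 6 complete-case samples")
  x <- x[cc, , drop = FALSE]; y <- lab[cc]
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  # drop exact duplicate columns (collinearity contract)
  dup <- duplicated(lapply(seq_len(ncol(x)), function(j) unname(x[, j])))
  x <- x[, !dup, drop = FALSE]
  ridge <- FALSE
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)))
  prob <- stats::fitted(fit)
  if (!fit$converged || any(prob < 1e-8) || any(prob > 1 - 1e-8)) {
    ridge <- TRUE
    fit <- ridge_logistic(x, y, lambda = 1e-6 * length(y))
    score <- drop(cbind(1, x) %*% fit$coef)
    coefs <- fit$coef
  } else {
    score <- drop(cbind(1, x) %*% stats::coef(fit))
    coefs <- stats::coef(fit)
  }
  roc <- roc_single(score, y)
  roc$coefficients <- coefs
  roc$ridge <- ridge
  roc$markers_used <- colnames(x)
  roc
}

# Newton-Raphson logistic regression with an L2 penalty on the non-intercept
# coefficients; used only when the unpenalized fit separates.
ridge_logistic <- function(x, y, lambda, maxit = 200, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(x))), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(X, y - p) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = drop(beta))
}
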