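#' Differential editing between groups by binomial GLM likelihood-ratio test
#'
#' Per event, the (edited, unedited) read counts of each usable sample
#' (depth >= `min_depth`) are modelled with a binomial-family GLM with logit
#' link and group as the sole covariate, and compared against the
#' intercept-only model by likelihood-ratio test (chi-square, 1 df). With a
#' single binary covariate the binomial GLM is saturated in the two group
#' means, so the maximum-likelihood fit is computed analytically (pooled
#' proportion under the null, per-group proportions under the alternative);
#' boundary cases (a group entirely unedited) are handled exactly by the
#' binomial likelihood. Events with fewer than two usable samples in either
#' group are flagged untestable. Significance is raw p < 0.05 (no
#' multiplicity correction), with a Benjamini-Hochberg column reported
#' alongside.
#'
#' @param em An `EditingMatrix` from [call_editing()]/[high_confidence()].
#' @param counts The `SiteCountTable` (source of read counts).
#' @param metadata `SampleMetadata` with group labels.
#' @param min_depth Depth floor for a sample to be usable.
#' @param family `"binomial"` (default) for the count-based GLM or
#'   `"gaussian"` for a sensitivity-analysis fit on the levels themselves.
#' @param alpha Significance cutoff on the raw p-value.
#' @return data.frame of class `DREResult`: one row per event with LRT
#'   statistic, `p_glm`, `p_bh`, group means, `delta`, per-group n and
#'   testability flag.
#' @export
dre_test <- function(em, counts, metadata, min_depth = 10L,
                     family = c("binomial", "gaussian"), alpha = 0.05) {
  family <- match.arg(family)
  check_samples(counts, metadata)
  grp <- metadata$group[match(counts$samples, metadata$sample_id)]
  depth <- count_depth(counts)
  ck <- rownames(counts$nA)
  ev <- em$events
  n_ev <- nrow(ev)
  out <- data.frame(
    event_id = ev$event_id, gene_id = ev$gene_id, contig = ev$contig,
    pos = ev$pos, strand = ev$strand, consequence = ev$consequence,
    whitelisted = ev$whitelisted,
    n_case = 0L, n_control = 0L, mean_case = NA_real_,
    mean_control = NA_real_, delta = NA_real_, lrt_stat = NA_real_,
    p_glm = NA_real_, testable = FALSE)
  for (i in seq_len(n_ev)) {
    ci <- match(site_key(ev$contig[i], ev$pos[i]), ck)
    if (ev$strand[i] == "+") {
      edited <- counts$nG[ci, ]; unedited <- counts$nA[ci, ]
    } else {
      edited <- counts$nC[ci, ]; unedited <- counts$nT[ci, ]
    }
    usable <- depth[ci, ] >= min_depth & (edited + unedited) > 0
    g <- grp[usable]
    e <- edited[usable]; u <- unedited[usable]
    out$n_case[i] <- sum(g == "case"); out$n_control[i] <- sum(g == "control")
    lv <- e / (e + u)
    out$mean_case[i] <- mean(lv[g == "case"])
    out$mean_control[i] <- mean(lv[g == "control"])
    out$delta[i] <- out$mean_case[i] - out$mean_control[i]
    if (out$n_case[i] < 2 || out$n_control[i] < 2) next
    out$testable[i] <- TRUE
    if (family == "binomial") {
      fit <- binom_lrt(e, u, g == "case")
      out$lrt_stat[i] <- fit$stat
      out$p_glm[i] <- fit$p
    } else {
      m1 <- stats::lm(lv ~ g)
      m0 <- stats::lm(lv ~ 1)
      stat <- as.numeric(2 * (stats::logLik(m1) - stats::logLik(m0)))
      out$lrt_stat[i] <- max(stat, 0)
      out$p_glm[i] <- stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
    }
  }
  out$p_bh <- NA_real_
  tst <- out$testable
  out$p_bh[tst] <- stats::p.adjust(out$p_glm[tst], method = "BH")
  out$significant <- tst & out$p_glm < alpha
  class(out) <- c("DREResult", "data.frame")
  out
}

# Exact LRT for a binomial GLM with one binary covariate: the MLE is the
# per-group (alternative) / pooled (null) proportion, and the deviance
# difference equals twice the log-likelihood difference.
binom_lrt <- function(edited, unedited, is_case) {
  e1 <- sum(edited[is_case]); u1 <- sum(unedited[is_case])
  e0 <- sum(edited[!is_case]); u0 <- sum(unedited[!is_case])
  ll <- function(e, u, p) xlogy(e, p) + xlogy(u, 1 - p)
  p1 <- e1 / (e1 + u1); p0 <- e0 / (e0 + u0)
  pp <- (e1 + e0) / (e1 + u1 + e0 + u0)
  stat <- 2 * (ll(e1, u1, p1) + ll(e0, u0, p0) - ll(e1 + e0, u1 + u0, pp))
  stat <- max(stat, 0)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cross-dataset consensus of differential editing
#'
#' An event (or gene) is in the consensus set when it is significant
#' (p < `alpha`) in at least `k` of the supplied per-dataset results,
#' optionally also requiring a consistent sign of the editing-level
#' difference.
#'
#' @param dre_by_dataset Named list of `DREResult` data.frames.
#' @param k Minimum number of supporting datasets (>= 1).
#' @param by `"event"` (match on contig:pos) or `"gene"`.
#' @param require_direction If `TRUE`, only count datasets sharing the
#'   majority sign of delta.
#' @param alpha Significance cutoff.
#' @return data.frame: id, `n_datasets`, comma-separated dataset list.
#' @export
consensus <- function(dre_by_dataset, k = 3L, by = c("event", "gene"),
                      require_direction = FALSE, alpha = 0.05) {
  by <- match.arg(by)
  if (k < 1) stop_edscan("k must be >= 1")
  if (is.null(names(dre_by_dataset)))
    names(dre_by_dataset) <- paste0("dataset", seq_along(dre_by_dataset))
  hits <- do.call(rbind, lapply(names(dre_by_dataset), function(ds) {
    d <- dre_by_dataset[[ds]]
    d <- d[d$testable & d$p_glm < alpha, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    id <- if (by == "event") site_key(d$contig, d$pos) else d$gene_id
    data.frame(id = id, dataset = ds, sign = sign(d$delta))
  }))
  if (is.null(hits))
    return(data.frame(id = character(0), n_datasets = integer(0),
                      datasets = character(0)))
  res <- do.call(rbind, lapply(split(hits, hits$id), function(h) {
    h <- h[!duplicated(h$dataset), ]
    if (require_direction) {
      maj <- sign(sum(h$sign))
      if (maj == 0) maj <- 1
      h <- h[h$sign == maj, ]
    }
    data.frame(id = h$id[1], n_datasets = nrow(h),
               datasets = paste(sort(h$dataset), collapse = ","))
  }))
  res <- res[res$n_datasets >= k, , drop = FALSE]
  res <- res[order(-res$n_datasets, res$id), ]
  rownames(res) <- NULL
  res
}

#' Genes containing at least one differential editing event
#'
#' @param dre A `DREResult` data.frame.
#' @param alpha Significance cutoff on the raw GLM p-value.
#' @return Sorted character vector of gene ids.
#' @export
differentially_edited_genes <- function(dre, alpha = 0.05) {
  sort(unique(dre$gene_id[dre$testable & !is.na(dre$p_glm) &
                            dre$p_glm < alpha]))
}

#' Two-group differential expression screen
#'
#' Per gene: Welch two-sample t-test on log2(x + 1), log fold change as the
#' difference of group means on that scale, Benjamini-Hochberg FDR, and a
#' hit flag at FDR <= `fdr_cut` and |logFC| >= `lfc_cut`. Genes with zero
#' variance in both groups get p = 1 by convention.
#'
#' @param expr Numeric matrix genes x samples (non-negative, linear scale).
#' @param metadata `SampleMetadata` covering the matrix columns.
#' @param fdr_cut,lfc_cut Hit thresholds.
#' @return data.frame: gene, logFC, p, FDR, flag.
#' @export
de_expression_screen <- function(expr, metadata, fdr_cut = 0.05,
                                 lfc_cut = 1) {
  grp <- metadata$group[match(colnames(expr), metadata$sample_id)]
  if (anyNA(grp)) stop_edscan("expression samples missing from metadata")
  if (sum(grp == "case") < 2 || sum(grp == "control") < 2)
    stop_edscan("need >= 2 samples per group")
  lx <- log2(expr + 1)
  res <- data.frame(gene = rownames(expr), logFC = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(lx))) {
    a <- lx[i, grp == "case"]; b <- lx[i, grp == "control"]
    res$logFC[i] <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      res$p[i] <- 1
    } else {
      res$p[i] <- stats::t.test(a, b)$p.value
    }
  }
  res$FDR <- stats::p.adjust(res$p, method = "BH")
  res$flag <- res$FDR <= fdr_cut & abs(res$logFC) >= lfc_cut
  res
}

#' PCA of the editing matrix
#'
#' Missing cells are mean-imputed per event, then samples are projected by
#' column-centred SVD (prcomp). Scores are deterministic up to sign.
#'
#' @param em An `EditingMatrix`, or a numeric events x samples matrix.
#' @param n_pc Number of components to return.
#' @return List: `scores` (samples x PCs), `var_frac`.
#' @export
pca_editing <- function(em, n_pc = 2L) {
  lev <- if (inherits(em, "EditingMatrix")) em$levels else em
  if (nrow(lev) < 2) stop_edscan("need >= 2 events for PCA")
  for (i in seq_len(nrow(lev))) {
    m <- mean(lev[i, ], na.rm = TRUE)
    lev[i, is.na(lev[i, ])] <- if (is.nan(m)) 0 else m
  }
  x <- t(lev)
  if (all(apply(x, 2, stats::var) < .Machine$double.eps))
    stop_edscan("degenerate PCA: all events constant")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       var_frac = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)])
}
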