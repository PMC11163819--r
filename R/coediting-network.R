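#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power beta, builds the unsigned adjacency
#' `|cor|^beta`, computes the connectivity distribution and the scale-free
#' topology fit index: the R-squared of the regression of log10 p(k) on
#' log10 k over connectivity bins, sign-adjusted by the slope (positive when
#' the slope is negative, as in scale-free networks). Returns the smallest
#' beta whose signed fit reaches `r2_target`, otherwise the argmax with a
#' warning.
#'
#' @param lev Numeric events x samples matrix (missing allowed; pairwise
#'   complete correlations).
#' @param powers Candidate integer powers.
#' @param r2_target Fit threshold (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return List: `power`, `fit_table` (power, r2_signed, mean_k), `reached`.
#' @export
pick_soft_threshold <- function(lev, powers = 1:20, r2_target = 0.8,
                                n_bins = 10L) {
  if (nrow(lev) < 20) stop_edscan("need >= 20 events")
  if (ncol(lev) < 8) stop_edscan("need >= 8 samples")
  cr <- abs(stats::cor(t(lev), use = "pairwise.complete.obs"))
  diag(cr) <- 0
  tab <- data.frame(power = powers, r2_signed = NA_real_, mean_k = NA_real_)
  for (j in seq_along(powers)) {
    a <- cr^powers[j]
    k <- rowSums(a)
    tab$mean_k[j] <- mean(k)
    if (max(k) - min(k) < .Machine$double.eps)
      stop_edscan("degenerate connectivity: all nodes identical")
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, brk, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    keep <- !is.na(pk) & pk > 0 & km > 0
    if (sum(keep) < 3) next
    fit <- stats::lm(log10(pk[keep]) ~ log10(km[keep]))
    r2 <- summary(fit)$r.squared
    tab$r2_signed[j] <- -sign(stats::coef(fit)[2]) * r2
  }
  ok <- which(!is.na(tab$r2_signed) & tab$r2_signed >= r2_target)
  if (length(ok)) {
    power <- powers[ok[1]]; reached <- TRUE
  } else {
    power <- powers[which.max(tab$r2_signed)]; reached <- FALSE
    warning("no power reached the scale-free fit target; returning argmax")
  }
  list(power = power, fit_table = tab, reached = reached)
}

#' Build the weighted co-editing network (adjacency and TOM)
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` on pairwise-complete
#' Pearson correlations, with unit diagonal. The topological overlap matrix
#' is `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`. Events with more than `max_missing` missing
#' cells or constant profiles are excluded (logged in `excluded`).
#'
#' @param lev Events x samples level matrix.
#' @param beta Soft-threshold power.
#' @param max_missing Maximum tolerated fraction of missing cells per event.
#' @return Object of class `CoEditingNetwork`: `adjacency`, `tom`, `beta`,
#'   `nodes`, `excluded`.
#' @export
build_network <- function(lev, beta, max_missing = 0.5) {
  miss <- rowMeans(is.na(lev))
  const <- apply(lev, 1, function(x) stats::var(x, na.rm = TRUE)) == 0
  const[is.na(const)] <- TRUE
  drop <- miss > max_missing | const
  excluded <- data.frame(node = rownames(lev)[drop],
                         reason = ifelse(const[drop], "constant",
                                         "too_many_missing"))
  lev <- lev[!drop, , drop = FALSE]
  if (nrow(lev) < 2) stop_edscan("fewer than 2 usable events")
  a <- abs(stats::cor(t(lev), use = "pairwise.complete.obs"))^beta
  a[is.na(a)] <- 0
  diag(a) <- 1
  n <- nrow(a)
  k <- rowSums(a) - 1
  aa <- a %*% a
  # l_ij = sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
  l <- aa - 2 * a          # subtracts u = i and u = j terms (diag = 1)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  structure(list(adjacency = a, tom = tom, beta = beta,
                 nodes = rownames(a), excluded = excluded),
            class = "CoEditingNetwork")
}

#' Detect co-editing modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage clustering on the TOM dissimilarity, cut statically at
#' `cut_frac` of the maximum merge height. Clusters smaller than `min_size`
#' are unassigned (grey); surviving modules are labelled in decreasing size
#' order with the conventional WGCNA colour sequence, so the largest module
#' is always turquoise. The default cut (0.95 of the top merge) sits just
#' below the final merges where distinct co-editing blocks join the
#' unclustered background: TOM dissimilarities between unrelated events
#' concentrate near 1, so genuine modules attach far below the top of the
#' dendrogram.
#'
#' @param network A `CoEditingNetwork`.
#' @param min_size Minimum module size (default 10).
#' @param cut_frac Static cut height as a fraction of the maximum merge
#'   height (default 0.95).
#' @return Named character vector: node -> colour label.
#' @export
detect_modules <- function(network, min_size = 10L, cut_frac = 0.95) {
  d <- stats::as.dist(1 - network$tom)
  tree <- stats::hclust(d, method = "average")
  h <- cut_frac * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  labels <- rep("grey", length(cl))
  names(labels) <- network$nodes
  if (length(keep) == 0) {
    warning("no module reached min_size; all nodes grey")
    return(labels)
  }
  # order surviving clusters by size (ties: by smallest member id for
  # determinism under input reordering)
  keep_sizes <- sizes[keep]
  anchor <- vapply(keep, function(g)
    min(network$nodes[cl == as.integer(g)]), character(1))
  ord <- keep[order(-as.integer(keep_sizes), anchor)]
  cols <- wgcna_colors(length(ord))
  for (i in seq_along(ord))
    labels[cl == as.integer(ord[i])] <- cols[i]
  labels
}

#' Conventional WGCNA module colour sequence
#' @param n Number of colours needed.
#' @export
wgcna_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

#' Module eigengene
#'
#' First principal component of the samples x module-events matrix after
#' per-event standardization, unit norm, sign-oriented so its correlation
#' with the module's mean standardized profile is non-negative. Missing
#' cells are mean-imputed (logged via attribute `imputed`).
#'
#' @param lev Events x samples level matrix.
#' @param module_nodes Event ids forming the module (length >= 2).
#' @return Numeric vector over samples (unit norm).
#' @export
module_eigengene <- function(lev, module_nodes) {
  if (length(module_nodes) < 2) stop_edscan("module size must be >= 2")
  x <- lev[module_nodes, , drop = FALSE]
  n_imp <- 0L
  for (i in seq_len(nrow(x))) {
    na <- is.na(x[i, ])
    if (any(na)) { x[i, na] <- mean(x[i, ], na.rm = TRUE); n_imp <- n_imp + sum(na) }
  }
  xs <- t(scale(t(x)))              # standardize each event profile
  xs[is.na(xs)] <- 0
  sv <- svd(t(xs))                  # samples x events
  e <- sv$u[, 1]
  ref <- rowMeans(t(xs))
  if (stats::cor(e, ref) < 0) e <- -e
  names(e) <- colnames(lev)
  attr(e, "imputed") <- n_imp
  e
}

#' Module-trait correlations
#'
#' Pearson correlation and two-sided t-test p-value between each module
#' eigengene and each trait (group coded control = 0 / case = 1, plus
#' hormones). Constant traits are skipped.
#'
#' @param eigengenes Named list of eigengene vectors (module -> vector).
#' @param metadata `SampleMetadata` in the same sample order as the
#'   eigengenes.
#' @return data.frame: module, trait, R, p, n.
#' @export
module_trait_correlation <- function(eigengenes, metadata) {
  traits <- data.frame(group = as.numeric(metadata$group == "case"))
  for (h in hormone_features()) traits[[h]] <- metadata[[h]]
  out <- list()
  for (m in names(eigengenes)) {
    e <- eigengenes[[m]]
    for (tr in names(traits)) {
      v <- traits[[tr]]
      cc <- stats::complete.cases(e, v)
      if (sum(cc) < 3 || stats::var(v[cc]) == 0) next
      ct <- stats::cor.test(e[cc], v[cc], method = "pearson")
      out[[paste(m, tr)]] <- data.frame(
        module = m, trait = tr, R = unname(ct$estimate),
        p = ct$p.value, n = sum(cc))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Identify the key module (most significant association with group)
#' @param module_trait Result of [module_trait_correlation()].
#' @return Module name.
#' @export
key_module <- function(module_trait) {
  g <- module_trait[module_trait$trait == "group", ]
  g$module[which.min(g$p)]
}

#' Extract hub events by degree centrality
#'
#' Binarizes the intramodular edge weights at `edge_threshold` (strictly
#' greater), computes each node's within-module degree, and returns the top
#' `n` by degree; ties are broken by smaller differential-editing p-value
#' (when supplied) then lexicographic event id.
#'
#' By default edges are defined on the unpowered correlation strength
#' `|cor(x_i, x_j)|` rather than the soft-thresholded adjacency: after
#' raising to a typical power beta the adjacency of even strongly
#' co-edited pairs falls far below any fixed cutoff, so a 0.4 threshold on
#' the powered adjacency empties the graph. Thresholding `|r|` at 0.4
#' keeps the cutoff on the scale the threshold was designed for.
#' `edge_on = "adjacency"` restores thresholding of `a_ij = |r|^beta`.
#'
#' @param network A `CoEditingNetwork`.
#' @param module_nodes Event ids of the module.
#' @param n Number of hubs (default 10).
#' @param edge_threshold Edge-weight cutoff defining an edge (default 0.4).
#' @param dre Optional `DREResult` for tie-breaking.
#' @param edge_on `"correlation"` (default) or `"adjacency"`.
#' @return data.frame of class `HubList`: event, degree, rank.
#' @export
hub_events <- function(network, module_nodes, n = 10L, edge_threshold = 0.4,
                       dre = NULL, edge_on = c("correlation", "adjacency")) {
  edge_on <- match.arg(edge_on)
  a <- network$adjacency[module_nodes, module_nodes, drop = FALSE]
  if (edge_on == "correlation") a <- a^(1 / network$beta)
  edges <- a > edge_threshold
  diag(edges) <- FALSE
  if (!any(edges))
    stop_edscan("edge threshold %.2f yields an empty edge set; lower it",
                edge_threshold)
  degree <- rowSums(edges)
  p <- rep(NA_real_, length(module_nodes))
  if (!is.null(dre)) {
    dk <- site_key(dre$contig, dre$pos)
    p <- dre$p_glm[match(module_nodes, dk)]
  }
  ord <- order(-degree, p, module_nodes, na.last = TRUE)
  top <- ord[seq_len(min(n, length(module_nodes)))]
  out <- data.frame(event = module_nodes[top], degree = degree[top],
                    rank = seq_along(top))
  class(out) <- c("HubList", "data.frame")
  out
}

#' Edge list of a module at a given edge-weight threshold
#' @inheritParams hub_events
#' @return data.frame node1, node2, weight, sorted.
#' @export
module_edges <- function(network, module_nodes, edge_threshold = 0.4,
                         edge_on = c("correlation", "adjacency")) {
  edge_on <- match.arg(edge_on)
  a <- network$adjacency[module_nodes, module_nodes, drop = FALSE]
  if (edge_on == "correlation") a <- a^(1 / network$beta)
  idx <- which(upper.tri(a) & a > edge_threshold, arr.ind = TRUE)
  out <- data.frame(node1 = module_nodes[idx[, 1]],
                    node2 = module_nodes[idx[, 2]],
                    weight = a[idx])
  out <- out[order(out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
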