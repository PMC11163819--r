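#' Per-site editing level
#'
#' The editing level at a site is the fraction of edited over
#' (reference + edited) reads: G/(A+G) on the coding (plus) strand, C/(T+C)
#' on the non-coding (minus) strand. Reads on other bases are excluded from
#' the denominator. Returns `NA` when the denominator is zero.
#'
#' @param n_ref Reference-base read count(s).
#' @param n_edited Edited-base read count(s).
#' @return Numeric vector of levels in `[0,1]` with `NA` for empty cells.
#' @export
editing_level <- function(n_ref, n_edited) {
  if (any(n_ref < 0 | n_edited < 0, na.rm = TRUE))
    stop_edscan("negative counts")
  tot <- n_ref + n_edited
  out <- n_edited / tot
  out[tot == 0] <- NA_real_
  out
}

#' Default SNV calling thresholds
#'
#' Minimum sequencing depth 10, minimum alternative allele depth 2 and
#' minimum alternative allele frequency 1% (all inclusive); base quality
#' >= 25 is an upstream contract of the count table.
#' @export
call_thresholds <- function(min_depth = 10L, min_alt = 2L, min_aaf = 0.01) {
  list(min_depth = as.integer(min_depth), min_alt = as.integer(min_alt),
       min_aaf = min_aaf)
}

#' Call candidate SNVs from a site count table
#'
#' A site is called in a sample iff depth >= `min_depth`, alt depth >=
#' `min_alt` and AAF = alt/(ref+alt) >= `min_aaf`; it enters the candidate
#' set iff called in at least one sample. The alternative base at a site is
#' the non-reference base with the largest total count over samples (ties
#' broken in A,C,G,T order).
#'
#' @param counts A `SiteCountTable`.
#' @param thresholds See [call_thresholds()].
#' @return Object of class `SNVCalls`: candidate site table with per-sample
#'   depth, alt-depth, AAF and call mask matrices.
#' @export
call_snvs <- function(counts, thresholds = call_thresholds()) {
  th <- thresholds
  depth <- count_depth(counts)
  base_mats <- list(A = counts$nA, C = counts$nC, G = counts$nG, T = counts$nT)
  ns <- nrow(counts$sites)
  alt_base <- character(ns)
  alt_mat <- matrix(0L, ns, length(counts$samples))
  ref_mat <- alt_mat
  for (i in seq_len(ns)) {
    ref <- counts$sites$ref[i]
    others <- setdiff(c("A", "C", "G", "T"), ref)
    tot <- vapply(others, function(b) sum(base_mats[[b]][i, ]), numeric(1))
    ab <- others[which.max(tot)]
    alt_base[i] <- ab
    alt_mat[i, ] <- base_mats[[ab]][i, ]
    ref_mat[i, ] <- base_mats[[ref]][i, ]
  }
  aaf <- alt_mat / (ref_mat + alt_mat)
  aaf[ref_mat + alt_mat == 0] <- NA_real_
  called <- depth >= th$min_depth & alt_mat >= th$min_alt &
    !is.na(aaf) & aaf >= th$min_aaf
  cand <- rowSums(called) >= 1
  keys <- site_key(counts$sites$contig, counts$sites$pos)
  dimnames(alt_mat) <- dimnames(ref_mat) <- dimnames(aaf) <-
    dimnames(called) <- list(keys, counts$samples)
  structure(list(
    sites = cbind(counts$sites, data.frame(alt = alt_base,
                                           candidate = cand)),
    depth = depth, alt_depth = alt_mat, ref_depth = ref_mat,
    aaf = aaf, called = called, thresholds = th),
    class = "SNVCalls")
}

#' Keep strand-consistent A-to-I candidates
#'
#' A-to-I editing reads as A-to-G on the coding strand and T-to-C on the
#' non-coding strand, so only A>G candidates inside a plus-strand gene and
#' T>C candidates inside a minus-strand gene are kept. All other candidates
#' are dropped with a reason: `non_AG` (wrong substitution type),
#' `strand_mismatch` (right substitution, wrong gene strand), `intergenic`
#' (no overlapping gene), `ambiguous_strand` (genes on both strands).
#'
#' @param snvs An `SNVCalls` object.
#' @param genome A `GenomeContext` with gene models.
#' @return List with `candidates` (contig, pos, ref, alt, gene_id, strand)
#'   and `dropped` (site, reason) data.frames.
#' @export
select_strand_consistent <- function(snvs, genome) {
  s <- snvs$sites[snvs$sites$candidate, , drop = FALSE]
  genes <- genome$genes
  gspan <- data.frame(
    gene_id = names(genes),
    contig = vapply(genes, `[[`, character(1), "contig"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, `[[`, numeric(1), "end"))
  keep <- list(); drop <- list()
  for (i in seq_len(nrow(s))) {
    key <- site_key(s$contig[i], s$pos[i])
    ov <- gspan[gspan$contig == s$contig[i] & gspan$start <= s$pos[i] &
                  gspan$end >= s$pos[i], ]
    sub <- paste0(s$ref[i], ">", s$alt[i])
    if (!sub %in% c("A>G", "T>C")) {
      drop[[key]] <- "non_AG"
    } else if (nrow(ov) == 0) {
      drop[[key]] <- "intergenic"
    } else if (length(unique(ov$strand)) > 1) {
      drop[[key]] <- "ambiguous_strand"
    } else {
      want <- if (sub == "A>G") "+" else "-"
      if (ov$strand[1] != want) {
        drop[[key]] <- "strand_mismatch"
      } else {
        g <- ov[order(ov$gene_id), ][1, ]
        keep[[key]] <- data.frame(
          contig = s$contig[i], pos = s$pos[i], ref = s$ref[i],
          alt = s$alt[i], gene_id = g$gene_id, strand = g$strand)
      }
    }
  }
  candidates <- if (length(keep)) do.call(rbind, keep) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene_id = character(0),
               strand = character(0))
  rownames(candidates) <- NULL
  dropped <- data.frame(site = names(drop),
                        reason = unlist(drop, use.names = FALSE))
  list(candidates = candidates, dropped = dropped)
}

#' Apply the four-rule artifact filter cascade
#'
#' Non-whitelisted candidates are removed if any rule fires; candidates on
#' the editing whitelist (known sites) bypass all rules. Rules, with the
#' reason recorded for the first that fires:
#' 1. `homopolymer` (site inside a maximal single-base run >= 5 nt),
#'    `simple_repeat` (inside a simple-repeat interval), `mitochondrial`
#'    (on the mitochondrial contig);
#' 2. `splice_junction` (genomic distance <= 6 nt from a junction-adjacent
#'    base), `near_indel` (site flagged within 1 nt of an indel),
#'    `read_end` (cross-sample median relative alt-read position <= 0.04 or
#'    >= 0.96);
#' 3. `known_snp` (on the SNP blacklist);
#' 4. `germline_pattern` (AAF equal to 100% or between 40% and 60% in more
#'    than 90% of the callable samples).
#'
#' @param candidates Candidate table from [select_strand_consistent()].
#' @param genome A `GenomeContext`.
#' @param counts The `SiteCountTable`.
#' @param snvs The `SNVCalls` (for per-sample AAF and depth).
#' @param rescue_whitelist If `TRUE` (default), whitelisted candidates
#'   bypass all rules.
#' @return List with `kept` (candidates + `whitelisted` flag) and `dropped`
#'   (site, reason).
#' @export
apply_filter_cascade <- function(candidates, genome, counts, snvs,
                                 rescue_whitelist = TRUE) {
  if (nrow(candidates) == 0)
    return(list(kept = cbind(candidates, whitelisted = logical(0)),
                dropped = data.frame(site = character(0),
                                     reason = character(0))))
  keys <- site_key(candidates$contig, candidates$pos)
  wl_keys <- site_key(genome$whitelist$contig, genome$whitelist$pos)
  bl_keys <- site_key(genome$blacklist$contig, genome$blacklist$pos)
  simple_rep <- genome$repeats[genome$repeats$class == "simple_repeat", ]
  ck <- rownames(counts$nA)
  depth <- count_depth(counts)

  reason <- rep(NA_character_, nrow(candidates))
  whitelisted <- keys %in% wl_keys
  for (i in seq_len(nrow(candidates))) {
    if (rescue_whitelist && whitelisted[i]) next
    ctg <- candidates$contig[i]; pos <- candidates$pos[i]
    # rule 1
    if (homopolymer_run_length(genome$contigs[[ctg]], pos) >= 5) {
      reason[i] <- "homopolymer"; next
    }
    if (in_intervals(ctg, pos, simple_rep)) { reason[i] <- "simple_repeat"; next }
    if (!is.na(genome$mito_name) && ctg == genome$mito_name) {
      reason[i] <- "mitochondrial"; next
    }
    # rule 2
    jn <- genome$junctions[genome$junctions$contig == ctg, "pos"]
    if (length(jn) && min(abs(jn - pos)) <= 6) {
      reason[i] <- "splice_junction"; next
    }
    ci <- match(keys[i], ck)
    if (isTRUE(counts$sites$near_indel[ci])) { reason[i] <- "near_indel"; next }
    med_pos <- stats::median(counts$alt_read_pos[ci, ], na.rm = TRUE)
    if (!is.na(med_pos) && (med_pos <= 0.04 || med_pos >= 0.96)) {
      reason[i] <- "read_end"; next
    }
    # rule 3
    if (keys[i] %in% bl_keys) { reason[i] <- "known_snp"; next }
    # rule 4: over callable samples, AAF == 1 or in [0.40, 0.60] in > 90%
    callable <- depth[ci, ] >= snvs$thresholds$min_depth
    if (any(callable)) {
      aaf <- snvs$aaf[keys[i], callable]
      aaf <- aaf[!is.na(aaf)]
      if (length(aaf)) {
        frac <- mean(aaf == 1 | (aaf >= 0.40 & aaf <= 0.60))
        if (frac > 0.90) { reason[i] <- "germline_pattern"; next }
      }
    }
  }
  kept <- cbind(candidates[is.na(reason), , drop = FALSE],
                whitelisted = whitelisted[is.na(reason)])
  rownames(kept) <- NULL
  list(kept = kept,
       dropped = data.frame(site = keys[!is.na(reason)],
                            reason = reason[!is.na(reason)]))
}

#' Build the high-confidence editing matrix
#'
#' Per-sample editing levels are G/(A+G) at plus-strand events and C/(T+C)
#' at minus-strand events, set missing where total depth < `min_depth`.
#' Events are retained when the level is >= 1% in at least two samples, or
#' when the site is whitelisted (known editing site).
#'
#' @param filtered `kept` table from [apply_filter_cascade()].
#' @param counts The `SiteCountTable`.
#' @param genome The `GenomeContext` (for consequence annotation).
#' @param min_level,min_samples High-confidence rule parameters.
#' @param min_depth Depth floor below which level cells are missing.
#' @return Object of class `EditingMatrix`: `events` data.frame and `levels`
#'   matrix (events x samples), plus `dropped` (site, reason
#'   `low_confidence`).
#' @export
high_confidence <- function(filtered, counts, genome, min_level = 0.01,
                            min_samples = 2L, min_depth = 10L) {
  ck <- rownames(counts$nA)
  depth <- count_depth(counts)
  n <- nrow(filtered)
  lev <- matrix(NA_real_, n, length(counts$samples),
                dimnames = list(site_key(filtered$contig, filtered$pos),
                                counts$samples))
  for (i in seq_len(n)) {
    ci <- match(rownames(lev)[i], ck)
    l <- if (filtered$strand[i] == "+")
      editing_level(counts$nA[ci, ], counts$nG[ci, ])
    else
      editing_level(counts$nT[ci, ], counts$nC[ci, ])
    l[depth[ci, ] < min_depth] <- NA_real_
    lev[i, ] <- l
  }
  ok <- rowSums(lev >= min_level, na.rm = TRUE) >= min_samples |
    filtered$whitelisted
  if (!any(ok)) warning("no high-confidence editing events retained")
  events <- filtered[ok, , drop = FALSE]
  lev <- lev[ok, , drop = FALSE]
  cons <- vapply(seq_len(nrow(events)), function(i)
    annotate_consequence(genome$genes[[events$gene_id[i]]], events$pos[i],
                         genome, events$ref[i], events$alt[i]),
    character(1))
  events$consequence <- if (nrow(events)) cons else character(0)
  events$event_id <- if (nrow(events))
    sprintf("%s:%s:%d", events$gene_id, events$contig, events$pos)
  else character(0)
  rownames(events) <- NULL
  structure(list(events = events, levels = lev,
                 dropped = data.frame(
                   site = site_key(filtered$contig, filtered$pos)[!ok],
                   reason = rep("low_confidence", sum(!ok)))),
            class = "EditingMatrix")
}

#' @export
print.EditingMatrix <- function(x, ...) {
  cat(sprintf("EditingMatrix: %d events x %d samples\n",
              nrow(x$events), ncol(x$levels)))
  invisible(x)
}

#' Annotate the functional consequence of an editing event
#'
#' CDS events are translated on the coding strand with the standard codon
#' table (`missense`, `synonymous`, `stop_gained`); exonic non-CDS events
#' are `5_prime_UTR`/`3_prime_UTR` by strand-aware position; intra-gene
#' non-exonic events are `intron`; events in genes without a CDS are
#' `non_coding`.
#'
#' @param gene A `GeneModel` containing the position.
#' @param pos Genomic position of the event.
#' @param genome The `GenomeContext` (for the reference sequence).
#' @param ref,alt Reference and alternative base on the genome's plus strand.
#' @return Consequence string.
#' @export
annotate_consequence <- function(gene, pos, genome, ref, alt) {
  if (is.null(gene)) stop_edscan("event at %d lies outside all genes", pos)
  cls <- classify_gene_position(gene, pos)
  if (cls == "outside") stop_edscan("event at %d outside gene %s", pos,
                                    gene$gene_id)
  if (cls == "intron") return("intron")
  if (cls == "non_coding") return("non_coding")
  if (cls == "utr5") return("5_prime_UTR")
  if (cls == "utr3") return("3_prime_UTR")
  # CDS: translate the affected codon on the coding strand
  seqstr <- genome$contigs[[gene$contig]]
  cds_iv <- lapply(seq_len(nrow(gene$exons)), function(i) {
    s <- max(gene$exons[i, 1], gene$cds[1])
    e <- min(gene$exons[i, 2], gene$cds[2])
    if (s <= e) c(s, e) else NULL
  })
  cds_iv <- Filter(Negate(is.null), cds_iv)
  cds_pos <- unlist(lapply(cds_iv, function(iv) iv[1]:iv[2]))
  cds_seq <- strsplit(substr(seqstr, 1, nchar(seqstr)), "")[[1]][cds_pos]
  if (gene$strand == "-") {
    cds_pos <- rev(cds_pos)
    cds_seq <- rev(chartr("ACGT", "TGCA", cds_seq))
  }
  idx <- match(pos, cds_pos)
  ref_tx <- if (gene$strand == "+") ref else dna_complement(ref)
  alt_tx <- if (gene$strand == "+") alt else dna_complement(alt)
  if (cds_seq[idx] != ref_tx)
    stop_edscan("reference mismatch at %s:%d", gene$contig, pos)
  codon_i <- (idx - 1) %/% 3
  cpos <- codon_i * 3 + 1:3
  codon_ref <- paste(cds_seq[cpos], collapse = "")
  codon_alt_v <- cds_seq[cpos]
  codon_alt_v[idx - codon_i * 3] <- alt_tx
  codon_alt <- paste(codon_alt_v, collapse = "")
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  if (is.na(aa_ref) || is.na(aa_alt)) return("non_coding")
  if (aa_alt == "*" && aa_ref != "*") return("stop_gained")
  if (aa_alt == aa_ref) return("synonymous")
  "missense"
}

#' Run the full editing-calling stage
#'
#' Orchestrates [call_snvs()], [select_strand_consistent()],
#' [apply_filter_cascade()] and [high_confidence()], and assembles a filter
#' log that accounts for every candidate exactly once (reason `retained` for
#' events entering the editing matrix).
#'
#' @inheritParams call_snvs
#' @param genome A `GenomeContext`.
#' @param rescue_whitelist Passed to [apply_filter_cascade()].
#' @param min_level,min_samples Passed to [high_confidence()].
#' @return List: `matrix` (an `EditingMatrix`), `filter_log` (site, reason),
#'   `snvs`.
#' @export
call_editing <- function(counts, genome, thresholds = call_thresholds(),
                         rescue_whitelist = TRUE, min_level = 0.01,
                         min_samples = 2L) {
  snvs <- call_snvs(counts, thresholds)
  sel <- select_strand_consistent(snvs, genome)
  fc <- apply_filter_cascade(sel$candidates, genome, counts, snvs,
                             rescue_whitelist = rescue_whitelist)
  em <- suppressWarnings(
    high_confidence(fc$kept, counts, genome, min_level = min_level,
                    min_samples = min_samples,
                    min_depth = thresholds$min_depth))
  log <- rbind(sel$dropped, fc$dropped, em$dropped,
               data.frame(site = rownames(em$levels),
                          reason = rep("retained", nrow(em$events))))
  log <- log[order(log$site), ]
  rownames(log) <- NULL
  n_cand <- sum(snvs$sites$candidate)
  if (nrow(log) != n_cand || anyDuplicated(log$site))
    stop_edscan("filter log does not account for every candidate exactly once")
  list(matrix = em, filter_log = log, snvs = snvs)
}

#' Compare called events against a planted truth table
#'
#' Precision is the fraction of retained events whose planted kind is
#' `edit`; recall is the fraction of clean planted editing sites (no
#' artifact context, i.e. decoy-free) that are retained; `snp_removal` is
#' the fraction of planted germline SNPs absent from the retained set.
#'
#' @param em An `EditingMatrix`.
#' @param truth A `TruthTable`.
#' @return List with `precision`, `recall`, `snp_removal` and the joined
#'   per-site table.
#' @export
truth_eval <- function(em, truth) {
  called <- rownames(em$levels)
  tt <- truth$sites
  tkey <- site_key(tt$contig, tt$pos)
  clean_edit <- tt$kind == "edit" & is.na(tt$decoy_class)
  snp <- tt$kind %in% c("het_snp", "hom_snp")
  tp <- called %in% tkey[tt$kind == "edit"]
  precision <- if (length(called)) mean(tp) else NA_real_
  recall <- mean(tkey[clean_edit] %in% called)
  snp_removal <- 1 - mean(tkey[snp] %in% called)
  list(precision = precision, recall = recall, snp_removal = snp_removal,
       joined = data.frame(site = tkey, kind = tt$kind,
                           decoy_class = tt$decoy_class,
                           called = tkey %in% called))
}
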