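#' Gene model with exon/CDS structure and derived UTRs
#'
#' Builds a validated gene model on 1-based closed genomic coordinates.
#' Exons must be sorted and non-overlapping; the optional CDS span must lie
#' within the exonic footprint. 5' and 3' UTR intervals are derived
#' strand-aware: on the plus strand exonic bases left of the CDS are 5' UTR,
#' on the minus strand they are 3' UTR.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon start/end
#'   (1-based closed), sorted, non-overlapping.
#' @param cds Optional length-2 vector, the genomic CDS span (closed).
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = NULL) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "start"] > exons[, "end"]))
    stop_edscan("gene %s: exon start > end", gene_id)
  if (nrow(exons) > 1) {
    if (any(diff(exons[, "start"]) <= 0))
      stop_edscan("gene %s: exons must be sorted", gene_id)
    if (any(exons[-1, "start"] <= exons[-nrow(exons), "end"]))
      stop_edscan("gene %s: exons overlap", gene_id)
  }
  if (!strand %in% c("+", "-")) stop_edscan("gene %s: bad strand", gene_id)
  utr5 <- utr3 <- NULL
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    exonic <- unlist(lapply(seq_len(nrow(exons)),
                            function(i) exons[i, 1]:exons[i, 2]))
    if (!all(c(cds[1], cds[2]) %in% exonic))
      stop_edscan("gene %s: CDS boundaries not exonic", gene_id)
    left  <- exonic[exonic < cds[1]]
    right <- exonic[exonic > cds[2]]
    if (strand == "+") { u5 <- left; u3 <- right } else { u5 <- right; u3 <- left }
    utr5 <- positions_to_intervals(u5)
    utr3 <- positions_to_intervals(u3)
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                 start = min(exons[, 1]), end = max(exons[, 2])),
            class = "GeneModel")
}

# Collapse a sorted vector of positions into closed intervals.
positions_to_intervals <- function(pos) {
  if (length(pos) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  pos <- sort(unique(as.integer(pos)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1L]])
}

#' Classify a genomic position within a gene model
#'
#' Returns one of `"utr5"`, `"cds"`, `"utr3"`, `"intron"`, `"non_coding"`
#' (exonic position in a gene without CDS) or `"outside"`.
#'
#' @param gene A `GeneModel`.
#' @param pos 1-based genomic position.
#' @export
classify_gene_position <- function(gene, pos) {
  if (pos < gene$start || pos > gene$end) return("outside")
  exonic <- any(gene$exons[, 1] <= pos & gene$exons[, 2] >= pos)
  if (!exonic) return("intron")
  if (is.null(gene$cds)) return("non_coding")
  if (pos >= gene$cds[1] && pos <= gene$cds[2]) return("cds")
  if (nrow(gene$utr5) && any(gene$utr5$start <= pos & gene$utr5$end >= pos))
    return("utr5")
  "utr3"
}

#' Assemble a genome context from sequences and annotations
#'
#' The container every other stage consumes: contig sequences, repeat and
#' splice-junction annotations, gene models, a known-editing-site whitelist
#' (REDIportal-style) and a known-SNP blacklist (dbSNP-style). All
#' coordinates are 1-based closed internally.
#'
#' @param contigs Named character vector of uppercase DNA sequences.
#' @param genes List of `GeneModel` objects.
#' @param repeats data.frame `contig,start,end,class` with class in
#'   `{"alu","simple_repeat"}` (1-based closed).
#' @param junctions data.frame `contig,pos`: the exonic base adjacent to each
#'   splice boundary.
#' @param whitelist,blacklist data.frame `contig,pos` of known editing sites
#'   / known SNPs.
#' @param mito_name Contig name treated as mitochondrial, or `NA`.
#' @return An object of class `GenomeContext`.
#' @export
genome_context <- function(contigs, genes = list(), repeats = NULL,
                           junctions = NULL, whitelist = NULL,
                           blacklist = NULL, mito_name = NA_character_) {
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop_edscan("contigs must be named")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop_edscan("contig %s contains non-ACGTN characters",
                names(contigs)[bad][1])
  empty_iv <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0), class = character(0))
  empty_pt <- data.frame(contig = character(0), pos = integer(0))
  repeats   <- repeats   %||% empty_iv
  junctions <- junctions %||% empty_pt
  whitelist <- whitelist %||% empty_pt
  blacklist <- blacklist %||% empty_pt
  clens <- nchar(contigs)
  check_within <- function(df, what, endcol) {
    if (nrow(df) == 0) return(invisible())
    if (!all(df$contig %in% names(contigs)))
      stop_edscan("%s: unknown contig '%s'", what,
                  setdiff(df$contig, names(contigs))[1])
    if (any(df[[endcol]] > clens[df$contig] | df[[if (endcol == "end") "start" else endcol]] < 1))
      stop_edscan("%s: coordinate beyond contig end", what)
  }
  check_within(repeats, "repeats", "end")
  check_within(junctions, "junctions", "pos")
  check_within(whitelist, "whitelist", "pos")
  check_within(blacklist, "blacklist", "pos")
  for (g in genes) {
    if (!g$contig %in% names(contigs))
      stop_edscan("gene %s: unknown contig", g$gene_id)
    if (g$end > clens[g$contig])
      stop_edscan("gene %s: coordinate beyond contig end", g$gene_id)
  }
  if (!is.na(mito_name) && !mito_name %in% names(contigs))
    stop_edscan("mito_name '%s' is not a contig", mito_name)
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(list(contigs = contigs, mito_name = mito_name, repeats = repeats,
                 junctions = junctions, genes = genes,
                 whitelist = whitelist, blacklist = blacklist),
            class = "GenomeContext")
}

#' @export
print.GenomeContext <- function(x, ...) {
  cat(sprintf("GenomeContext: %d contig(s), %d gene(s), %d repeat interval(s),\n",
              length(x$contigs), length(x$genes), nrow(x$repeats)))
  cat(sprintf("  %d junction base(s), whitelist %d, blacklist %d, mito = %s\n",
              nrow(x$junctions), nrow(x$whitelist), nrow(x$blacklist),
              x$mito_name))
  invisible(x)
}

## ---- coordinate conversion -------------------------------------------------

#' Convert BED (0-based half-open) intervals to 1-based closed and back
#'
#' @param start0,end0 BED start/end.
#' @name bed_coords
#' @export
bed_to_closed <- function(start0, end0) {
  data.frame(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' @param start1,end1 1-based closed start/end.
#' @rdname bed_coords
#' @export
closed_to_bed <- function(start1, end1) {
  data.frame(start0 = as.integer(start1) - 1L, end0 = as.integer(end1))
}

## ---- file readers ----------------------------------------------------------

read_bed <- function(path, with_name = FALSE) {
  if (!file.exists(path)) stop_edscan("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0))
    if (with_name) out$class <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (with_name) 4L else 3L
  nlen <- lengths(fields)
  if (any(nlen < need))
    stop_edscan("malformed BED line %d in %s", which(nlen < need)[1], path)
  contig <- vapply(fields, `[[`, character(1), 1)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(s0) || anyNA(e0) || any(s0 < 0) || any(e0 <= s0))
    stop_edscan("malformed BED coordinates in %s (line %d)",
                path, which(is.na(s0) | is.na(e0) | s0 < 0 | e0 <= s0)[1])
  cl <- bed_to_closed(s0, e0)
  out <- data.frame(contig = contig, start = cl$start, end = cl$end,
                    stringsAsFactors = FALSE)
  if (with_name) out$class <- vapply(fields, `[[`, character(1), 4)
  out
}

# BED3 of single bases -> data.frame(contig, pos)
read_bed_points <- function(path) {
  iv <- read_bed(path)
  if (nrow(iv) == 0) return(data.frame(contig = character(0), pos = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    data.frame(contig = iv$contig[i], pos = iv$start[i]:iv$end[i])
  }))
  rownames(out) <- NULL
  out
}

# GTF-lite: tab-separated GTF lines restricted to exon/CDS features with a
# gene_id attribute; 1-based closed like real GTF.
read_gtf_lite <- function(path) {
  if (!file.exists(path)) stop_edscan("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nlen <- lengths(fields)
  if (any(nlen < 9))
    stop_edscan("malformed GTF line %d in %s", which(nlen < 9)[1], path)
  rec <- data.frame(
    contig  = vapply(fields, `[[`, character(1), 1),
    feature = vapply(fields, `[[`, character(1), 3),
    start   = as.integer(vapply(fields, `[[`, character(1), 4)),
    end     = as.integer(vapply(fields, `[[`, character(1), 5)),
    strand  = vapply(fields, `[[`, character(1), 7),
    attr    = vapply(fields, `[[`, character(1), 9),
    stringsAsFactors = FALSE)
  m <- regmatches(rec$attr, regexpr('gene_id "[^"]+"', rec$attr))
  if (length(m) != nrow(rec))
    stop_edscan("GTF line without gene_id attribute in %s", path)
  rec$gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  genes <- lapply(split(rec, rec$gene_id), function(d) {
    ex <- d[d$feature == "exon", c("start", "end")]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds_rows <- d[d$feature == "CDS", ]
    cds <- if (nrow(cds_rows)) c(min(cds_rows$start), max(cds_rows$end)) else NULL
    gene_model(d$gene_id[1], d$contig[1], d$strand[1], as.matrix(ex), cds)
  })
  genes[order(names(genes))]
}

#' Read a genome context from FASTA plus annotation files
#'
#' @param fasta_path FASTA of contig sequences.
#' @param annotation_paths Named list of paths: `repeats` (BED4, name column
#'   = repeat class), `junctions`, `whitelist`, `blacklist` (BED3 of single
#'   bases) and `genes` (GTF-lite). Any entry may be omitted.
#' @param mito_name Mitochondrial contig name, or `NA`.
#' @return A [genome_context()].
#' @export
read_genome <- function(fasta_path, annotation_paths = list(),
                        mito_name = NA_character_) {
  if (!file.exists(fasta_path)) stop_edscan("file not found: %s", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- stats::setNames(toupper(as.character(seqs)),
                             sub("\\s.*$", "", names(seqs)))
  ap <- annotation_paths
  genome_context(
    contigs,
    genes     = if (!is.null(ap$genes)) read_gtf_lite(ap$genes) else list(),
    repeats   = if (!is.null(ap$repeats)) read_bed(ap$repeats, with_name = TRUE) else NULL,
    junctions = if (!is.null(ap$junctions)) read_bed_points(ap$junctions) else NULL,
    whitelist = if (!is.null(ap$whitelist)) read_bed_points(ap$whitelist) else NULL,
    blacklist = if (!is.null(ap$blacklist)) read_bed_points(ap$blacklist) else NULL,
    mito_name = mito_name)
}

## ---- file writers (deterministic order) ------------------------------------

#' Write genome context components to files
#'
#' Writers emit a fixed column order and rows sorted by (contig, pos/start)
#' so outputs are byte-reproducible.
#'
#' @param genome A `GenomeContext`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             repeats = file.path(dir, "repeats.bed"),
             junctions = file.path(dir, "junctions.bed"),
             whitelist = file.path(dir, "whitelist.bed"),
             blacklist = file.path(dir, "blacklist.bed"),
             genes = file.path(dir, "genes.gtf"))
  dss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dss, paths["fasta"], width = 70L)
  write_bed4(genome$repeats, paths["repeats"])
  write_bed_points(genome$junctions, paths["junctions"])
  write_bed_points(genome$whitelist, paths["whitelist"])
  write_bed_points(genome$blacklist, paths["blacklist"])
  write_gtf_lite(genome$genes, paths["genes"])
  invisible(paths)
}

write_bed4 <- function(iv, path) {
  iv <- iv[order(iv$contig, iv$start), , drop = FALSE]
  b <- closed_to_bed(iv$start, iv$end)
  writeLines(if (nrow(iv)) paste(iv$contig, b$start0, b$end0, iv$class,
                                 sep = "\t") else character(0), path)
  invisible(path)
}

write_bed_points <- function(pt, path) {
  pt <- pt[order(pt$contig, pt$pos), , drop = FALSE]
  b <- closed_to_bed(pt$pos, pt$pos)
  writeLines(if (nrow(pt)) paste(pt$contig, b$start0, b$end0, sep = "\t")
             else character(0), path)
  invisible(path)
}

write_gtf_lite <- function(genes, path) {
  lines <- character(0)
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    att <- sprintf('gene_id "%s";', g$gene_id)
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines, paste(g$contig, "edscan", "exon", g$exons[i, 1],
                              g$exons[i, 2], ".", g$strand, ".", att,
                              sep = "\t"))
    if (!is.null(g$cds))
      lines <- c(lines, paste(g$contig, "edscan", "CDS", g$cds[1], g$cds[2],
                              ".", g$strand, ".", att, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- site count table ------------------------------------------------------

#' Construct a per-sample, per-site base count table
#'
#' The pipeline's universal currency: base-quality-filtered (by upstream
#' contract, BQ >= 25) A/C/G/T read counts for every sample at every site,
#' plus the median relative read position of alt-supporting reads and a
#' near-indel flag per site.
#'
#' @param samples Ordered character vector of sample ids.
#' @param sites data.frame `contig,pos,ref,near_indel` (ref one of ACGT).
#' @param nA,nC,nG,nT Integer matrices, sites x samples.
#' @param alt_read_pos Numeric matrix in `[0,1]`, `NA` where no alt reads.
#' @return Object of class `SiteCountTable`.
#' @export
site_count_table <- function(samples, sites, nA, nC, nG, nT, alt_read_pos) {
  ns <- nrow(sites); np <- length(samples)
  for (m in list(nA, nC, nG, nT, alt_read_pos))
    if (!all(dim(m) == c(ns, np))) stop_edscan("count matrix dimension mismatch")
  if (any(nA < 0 | nC < 0 | nG < 0 | nT < 0)) stop_edscan("negative counts")
  if (any(sites$pos < 1)) stop_edscan("pos < 1")
  keys <- site_key(sites$contig, sites$pos)
  if (anyDuplicated(keys)) stop_edscan("duplicate record: %s",
                                       keys[duplicated(keys)][1])
  dn <- list(keys, samples)
  dimnames(nA) <- dimnames(nC) <- dimnames(nG) <- dimnames(nT) <-
    dimnames(alt_read_pos) <- dn
  structure(list(samples = samples, sites = sites, nA = nA, nC = nC,
                 nG = nG, nT = nT, alt_read_pos = alt_read_pos),
            class = "SiteCountTable")
}

#' @export
print.SiteCountTable <- function(x, ...) {
  cat(sprintf("SiteCountTable: %d sites x %d samples (mean depth %.1f)\n",
              nrow(x$sites), length(x$samples), mean(count_depth(x))))
  invisible(x)
}

#' Total sequencing depth per site and sample
#' @param counts A `SiteCountTable`.
#' @return Integer matrix sites x samples.
#' @export
count_depth <- function(counts) counts$nA + counts$nC + counts$nG + counts$nT

#' Read a site count table from long-format TSV
#'
#' Expected header: `sample contig pos ref nA nC nG nT alt_read_pos
#' near_indel`. Absent (sample, site) pairs get depth 0.
#'
#' @param tsv_path Path to the TSV.
#' @return A `SiteCountTable`.
#' @export
read_counts <- function(tsv_path) {
  d <- read_tsv_strict(tsv_path)
  need <- c("sample", "contig", "pos", "ref", "nA", "nC", "nG", "nT",
            "alt_read_pos", "near_indel")
  if (!all(need %in% names(d)))
    stop_edscan("counts TSV %s missing columns: %s", tsv_path,
                paste(setdiff(need, names(d)), collapse = ","))
  if (any(d$pos < 1)) stop_edscan("pos < 1 in %s", tsv_path)
  if (any(d$nA < 0 | d$nC < 0 | d$nG < 0 | d$nT < 0))
    stop_edscan("negative counts in %s", tsv_path)
  key <- paste(d$sample, d$contig, d$pos)
  if (anyDuplicated(key))
    stop_edscan("duplicate record in %s: %s", tsv_path, key[duplicated(key)][1])
  samples <- sort(unique(d$sample))
  sk <- site_key(d$contig, d$pos)
  ord <- order(d$contig, d$pos)
  usite <- !duplicated(sk)
  sites <- d[usite, c("contig", "pos", "ref", "near_indel")][
    order(d$contig[usite], d$pos[usite]), ]
  rownames(sites) <- NULL
  keys <- site_key(sites$contig, sites$pos)
  zero <- matrix(0L, nrow(sites), length(samples),
                 dimnames = list(keys, samples))
  nA <- nC <- nG <- nT <- zero
  arp <- matrix(NA_real_, nrow(sites), length(samples),
                dimnames = list(keys, samples))
  idx <- cbind(match(sk, keys), match(d$sample, samples))
  nA[idx] <- as.integer(d$nA); nC[idx] <- as.integer(d$nC)
  nG[idx] <- as.integer(d$nG); nT[idx] <- as.integer(d$nT)
  arp[idx] <- d$alt_read_pos
  site_count_table(samples, sites, nA, nC, nG, nT, arp)
}

#' Write a site count table as long-format TSV
#'
#' Rows sorted by (contig, pos, sample); cells with zero depth and no
#' annotation are still written so the round trip is exact.
#'
#' @param counts A `SiteCountTable`.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  ns <- nrow(counts$sites); np <- length(counts$samples)
  d <- data.frame(
    sample = rep(counts$samples, each = ns),
    contig = rep(counts$sites$contig, np),
    pos = rep(counts$sites$pos, np),
    ref = rep(counts$sites$ref, np),
    nA = as.vector(counts$nA), nC = as.vector(counts$nC),
    nG = as.vector(counts$nG), nT = as.vector(counts$nT),
    alt_read_pos = round(as.vector(counts$alt_read_pos), 6),
    near_indel = rep(counts$sites$near_indel, np))
  d <- d[order(d$contig, d$pos, d$sample), ]
  write_tsv_strict(d, path)
}

## ---- sample metadata -------------------------------------------------------

#' Hormone feature names used throughout the package
#' @export
hormone_features <- function() c("LH", "FSH", "LH_FSH", "T", "DHEAS", "E2")

#' Read sample metadata (group labels and hormone features)
#'
#' @param tsv_path TSV with columns `sample_id`, `group` and optionally the
#'   hormone columns of [hormone_features()]; blanks allowed in hormones.
#' @param group_aliases Named character vector mapping raw labels to
#'   `"case"`/`"control"`.
#' @return data.frame of class `SampleMetadata`.
#' @export
read_metadata <- function(tsv_path,
                          group_aliases = c(PCOS = "case", Con = "control",
                                            Control = "control")) {
  d <- read_tsv_strict(tsv_path)
  if (!all(c("sample_id", "group") %in% names(d)))
    stop_edscan("metadata %s must have sample_id and group columns", tsv_path)
  sample_metadata(d, group_aliases = group_aliases)
}

#' Validate a metadata data.frame
#'
#' Applies group-label aliases, recomputes the LH/FSH ratio where missing,
#' and checks sample uniqueness.
#'
#' @param d data.frame with `sample_id`, `group` and hormone columns.
#' @inheritParams read_metadata
#' @export
sample_metadata <- function(d, group_aliases = c(PCOS = "case",
                                                 Con = "control",
                                                 Control = "control")) {
  if (anyDuplicated(d$sample_id))
    stop_edscan("duplicate sample_id: %s",
                d$sample_id[duplicated(d$sample_id)][1])
  g <- as.character(d$group)
  hit <- g %in% names(group_aliases)
  g[hit] <- unname(group_aliases[g[hit]])
  if (!all(g %in% c("case", "control")))
    stop_edscan("unknown group label: %s",
                setdiff(g, c("case", "control"))[1])
  d$group <- g
  for (h in hormone_features()) if (!h %in% names(d)) d[[h]] <- NA_real_
  fix <- is.na(d$LH_FSH) & !is.na(d$LH) & !is.na(d$FSH) & d$FSH != 0
  d$LH_FSH[fix] <- d$LH[fix] / d$FSH[fix]
  d <- d[, c("sample_id", "group", hormone_features())]
  class(d) <- c("SampleMetadata", "data.frame")
  d
}

#' Check that all count-table samples are described in the metadata
#' @param counts A `SiteCountTable`.
#' @param metadata A `SampleMetadata`.
#' @export
check_samples <- function(counts, metadata) {
  missing <- setdiff(counts$samples, metadata$sample_id)
  if (length(missing))
    stop_edscan("samples missing from metadata: %s",
                paste(missing, collapse = ", "))
  invisible(TRUE)
}
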