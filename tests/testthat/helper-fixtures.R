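# Hand-built miniature genome and count-table builders shared across tests.
# All fixtures are constructed in code; nothing is read from disk.

# chrT (200 bp): plus-strand gene GP with two exons and no CDS, minus-strand
# single-exon gene GM; chrM (60 bp) with one plus-strand gene. Designed
# bases: a 5-nt A homopolymer at 20-24, a simple-repeat interval at 95-106,
# junction-adjacent bases at 60 and 81, and clean A/T sites at known
# positions.
fixture_genome <- function(whitelist = NULL, blacklist = NULL) {
  set.seed(4242)
  s <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  s[19] <- "C"; s[20:24] <- "A"; s[25] <- "C"     # homopolymer run of 5
  put_isolated <- function(p, base) {
    s[p] <<- base
    for (q in c(p - 1, p + 1)) if (s[q] == base) s[q] <<- "C"
  }
  put_isolated(35, "A")
  put_isolated(45, "A"); put_isolated(50, "A"); put_isolated(55, "A")
  put_isolated(90, "A"); put_isolated(100, "A"); put_isolated(63, "A")
  put_isolated(110, "A")
  put_isolated(165, "T"); put_isolated(170, "T")
  m <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  m[29] <- "C"; m[30] <- "A"; m[31] <- "C"
  genome_context(
    contigs = c(chrT = paste(s, collapse = ""), chrM = paste(m, collapse = "")),
    genes = list(
      gene_model("GP", "chrT", "+", rbind(c(11L, 60L), c(81L, 130L))),
      gene_model("GM", "chrT", "-", rbind(c(141L, 190L))),
      gene_model("MTG", "chrM", "+", rbind(c(11L, 50L)))),
    repeats = data.frame(contig = "chrT", start = 95L, end = 106L,
                         class = "simple_repeat"),
    junctions = data.frame(contig = "chrT", pos = c(60L, 81L)),
    whitelist = whitelist, blacklist = blacklist,
    mito_name = "chrM")
}

# Build a SiteCountTable from per-site strand, depth and editing levels.
# `levels` and `depth` are sites x samples; edited counts are rounded
# level * depth on the strand-appropriate base.
build_counts <- function(sites, samples, depth, levels,
                         arp = NULL, near_indel = NULL) {
  ns <- nrow(sites); np <- length(samples)
  depth <- matrix(depth, ns, np)
  levels <- matrix(levels, ns, np)
  edited <- round(levels * depth)
  ref_n <- depth - edited
  zero <- matrix(0L, ns, np)
  nA <- nC <- nG <- nT <- zero
  plus <- sites$strand == "+"
  nA[plus, ] <- ref_n[plus, ]; nG[plus, ] <- edited[plus, ]
  nT[!plus, ] <- ref_n[!plus, ]; nC[!plus, ] <- edited[!plus, ]
  if (is.null(arp)) arp <- matrix(ifelse(edited > 0, 0.5, NA_real_), ns, np)
  st <- data.frame(contig = sites$contig, pos = sites$pos,
                   ref = ifelse(plus, "A", "T"),
                   near_indel = near_indel %||% rep(FALSE, ns))
  site_count_table(samples, st, nA, nC, nG, nT, matrix(arp, ns, np))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

site_key <- function(contig, pos) paste(contig, pos, sep = ":")

# Plain Rand index between two labelings.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Independent consequence oracle: rebuild the coding sequence with
# Biostrings, apply the substitution, translate both proteins, compare.
consequence_oracle <- function(gene, pos, genome, ref, alt) {
  pieces <- lapply(seq_len(nrow(gene$exons)), function(i) {
    s <- max(gene$exons[i, 1], gene$cds[1]); e <- min(gene$exons[i, 2], gene$cds[2])
    if (s <= e) c(s, e) else NULL
  })
  pieces <- Filter(Negate(is.null), pieces)
  cds_pos <- unlist(lapply(pieces, function(p) p[1]:p[2]))
  chars <- strsplit(genome$contigs[[gene$contig]], "")[[1]]
  stopifnot(chars[pos] == ref)
  mut <- chars; mut[pos] <- alt
  get_prot <- function(v) {
    d <- Biostrings::DNAString(paste(v[cds_pos], collapse = ""))
    if (gene$strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d, if.fuzzy.codon = "X"))
  }
  p0 <- get_prot(chars); p1 <- get_prot(mut)
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  if (length(d) == 0) return("synonymous")
  aa1 <- substr(p1, d[1], d[1])
  if (aa1 == "*") "stop_gained" else "missense"
}
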