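test_that("editing level is edited/(ref+edited) with other bases excluded", {
  expect_equal(editing_level(90, 10), 0.10)
  expect_equal(editing_level(0, 50), 1.0)
  expect_equal(editing_level(97, 2), 2 / 99)   # C reads excluded upstream
  expect_true(is.na(editing_level(0, 0)))
  expect_error(editing_level(-1, 5), "negative")
})

test_that("SNV calling applies inclusive depth/alt/AAF thresholds", {
  gen <- fixture_genome()
  sites <- data.frame(contig = "chrT", pos = c(45L, 50L, 55L, 110L),
                      strand = "+")
  # depths 9, 100, 200, 30 with alt counts 3, 1, 2, 3
  depth <- matrix(c(9, 100, 200, 30), 4, 1)
  lev <- matrix(c(3 / 9, 1 / 100, 2 / 200, 3 / 30), 4, 1)
  counts <- build_counts(sites, "s1", depth, lev)
  snvs <- call_snvs(counts)
  called <- snvs$sites$candidate
  names(called) <- paste0("p", sites$pos)
  expect_false(called[["p45"]])   # depth 9 < 10
  expect_false(called[["p50"]])   # alt 1 < 2
  expect_true(called[["p55"]])    # AAF exactly 1% is included
  expect_true(called[["p110"]])
  # threshold monotonicity: raising any threshold never enlarges the set
  base_n <- sum(call_snvs(counts)$sites$candidate)
  for (th in list(call_thresholds(min_depth = 40),
                  call_thresholds(min_alt = 3),
                  call_thresholds(min_aaf = 0.05))) {
    expect_lte(sum(call_snvs(counts, th)$sites$candidate), base_n)
  }
})

test_that("strand rule keeps only A>G in + genes and T>C in - genes", {
  gen <- fixture_genome()
  # 45: A in + gene; 165: T in - gene; 170: T in - gene but alt will be G
  # (non_AG); 5: A outside genes
  sites <- data.frame(contig = c("chrT", "chrT", "chrT", "chrT"),
                      pos = c(45L, 165L, 170L, 5L),
                      strand = c("+", "-", "-", "+"))
  counts <- build_counts(sites, c("s1", "s2"), depth = 50, levels = 0.2)
  # make site 170 a T>G substitution instead of T>C
  i <- match("chrT:170", rownames(counts$nC))
  counts$nG[i, ] <- counts$nC[i, ]; counts$nC[i, ] <- 0L
  counts$sites$ref[counts$sites$pos == 5] <- "A"
  snvs <- call_snvs(counts)
  sel <- select_strand_consistent(snvs, gen)
  expect_setequal(sel$candidates$pos, c(45L, 165L))
  reasons <- setNames(sel$dropped$reason, sel$dropped$site)
  expect_identical(unname(reasons["chrT:170"]), "non_AG")
  expect_identical(unname(reasons["chrT:5"]), "intergenic")
  # A>G inside a minus-strand gene is a strand mismatch (U>C on transcript)
  sites2 <- data.frame(contig = "chrT", pos = 150L, strand = "+")
  counts2 <- build_counts(sites2, "s1", 50, 0.2)
  counts2$sites$ref <- "A"  # genomic A at a minus-gene position
  # place inside GM (141-190)
  sel2 <- select_strand_consistent(call_snvs(counts2), gen)
  expect_identical(sel2$dropped$reason, "strand_mismatch")
})

test_that("filter cascade fires the documented rules and whitelist rescues", {
  gen <- fixture_genome()
  sam <- paste0("s", 1:10)
  sites <- data.frame(
    contig = c("chrT", "chrT", "chrT", "chrT", "chrT", "chrM", "chrT", "chrT"),
    pos    = c(22L,    100L,   63L,    90L,    45L,    30L,    50L,   35L),
    strand = c("+",    "+",    "+",    "+",    "+",    "+",    "+",   "+"))
  # 22 homopolymer centre; 100 simple repeat; 63 within 6 of junction 60;
  # 90 near-indel flag; 45 read-end; chrM:30 mitochondrial; 50 germline
  # pattern (AAF ~0.5 everywhere); 35 clean control site
  lev <- matrix(0.2, 8, 10)
  lev[7, ] <- 0.5
  arp <- matrix(0.5, 8, 10); arp[5, ] <- 0.03
  ni <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  counts <- build_counts(sites, sam, depth = 60, levels = lev, arp = arp,
                         near_indel = ni)
  snvs <- call_snvs(counts)
  sel <- select_strand_consistent(snvs, gen)
  fc <- apply_filter_cascade(sel$candidates, gen, counts, snvs)
  reasons <- setNames(fc$dropped$reason, fc$dropped$site)
  expect_identical(unname(reasons["chrT:22"]), "homopolymer")
  expect_identical(unname(reasons["chrT:100"]), "simple_repeat")
  expect_identical(unname(reasons["chrT:63"]), "splice_junction")
  expect_identical(unname(reasons["chrT:90"]), "near_indel")
  expect_identical(unname(reasons["chrT:45"]), "read_end")
  expect_identical(unname(reasons["chrM:30"]), "mitochondrial")
  expect_identical(unname(reasons["chrT:50"]), "germline_pattern")
  expect_identical(fc$kept$pos, 35L)
  # whitelist rescues every class
  gen_wl <- fixture_genome(whitelist = data.frame(
    contig = sites$contig, pos = sites$pos))
  fc2 <- apply_filter_cascade(sel$candidates, gen_wl, counts, snvs)
  expect_equal(nrow(fc2$kept), 8)
  expect_true(all(fc2$kept$whitelisted))
  # whitelist monotonicity: enlarging the whitelist never shrinks the kept set
  for (k in seq_len(nrow(sites))) {
    gen_k <- fixture_genome(whitelist = data.frame(
      contig = sites$contig[seq_len(k)], pos = sites$pos[seq_len(k)]))
    kept_k <- apply_filter_cascade(sel$candidates, gen_k, counts, snvs)$kept
    expect_true(all(fc$kept$pos %in% kept_k$pos))
    if (k > 1) expect_gte(nrow(kept_k), nrow(prev_kept))
    prev_kept <- kept_k
  }
  # blacklist drops as known_snp
  gen_bl <- fixture_genome(blacklist = data.frame(contig = "chrT", pos = 35L))
  fc3 <- apply_filter_cascade(sel$candidates, gen_bl, counts, snvs)
  expect_identical(setNames(fc3$dropped$reason, fc3$dropped$site)[["chrT:35"]],
                   "known_snp")
})

test_that("germline AAF pattern counts both the 40-60% band and AAF = 1", {
  gen <- fixture_genome()
  sam <- paste0("s", 1:10)
  # hom-like: AAF 1.0 in all samples
  sites <- data.frame(contig = "chrT", pos = 35L, strand = "+")
  counts <- build_counts(sites, sam, depth = 50, levels = 1)
  snvs <- call_snvs(counts)
  sel <- select_strand_consistent(snvs, gen)
  fc <- apply_filter_cascade(sel$candidates, gen, counts, snvs)
  expect_identical(fc$dropped$reason, "germline_pattern")
  # 9/10 in band is not > 90%: retained
  lev <- matrix(0.5, 1, 10); lev[1, 1] <- 0.2
  counts2 <- build_counts(sites, sam, depth = 50, levels = lev)
  snvs2 <- call_snvs(counts2)
  fc2 <- apply_filter_cascade(select_strand_consistent(snvs2, gen)$candidates,
                              gen, counts2, snvs2)
  expect_equal(nrow(fc2$kept), 1)
})

test_that("high-confidence rule needs >= 1% in >= 2 samples unless whitelisted", {
  gen <- fixture_genome()
  sam <- paste0("s", 1:6)
  sites <- data.frame(contig = "chrT", pos = c(45L, 50L, 55L), strand = "+")
  lev <- rbind(c(0.02, 0.015, 0, 0, 0, 0),    # two samples >= 1%: retained
               c(0.02, 0, 0, 0, 0, 0),        # one sample: dropped
               c(0, 0, 0, 0, 0, 0))           # zero but whitelisted below
  counts <- build_counts(sites, sam, depth = 200, levels = lev)
  filtered <- data.frame(contig = "chrT", pos = c(45L, 50L, 55L), ref = "A",
                         alt = "G", gene_id = "GP", strand = "+",
                         whitelisted = c(FALSE, FALSE, TRUE))
  em <- suppressWarnings(high_confidence(filtered, counts, gen))
  expect_setequal(em$events$pos, c(45L, 55L))
  expect_identical(em$dropped$site, "chrT:50")
  # cells below depth 10 are missing
  counts2 <- build_counts(sites, sam, depth = 9, levels = lev)
  em2 <- suppressWarnings(high_confidence(filtered[3, ], counts2, gen))
  expect_true(all(is.na(em2$levels)))
})

test_that("consequence annotation matches an independent translation oracle", {
  # simulated genome gives CDS genes on both strands
  gen <- simulate_genome(sim_config(), seed = 11)
  set.seed(11)
  checked <- 0
  for (gid in names(gen$genes)) {
    g <- gen$genes[[gid]]
    if (is.null(g$cds)) next
    want_ref <- if (g$strand == "+") "A" else "T"
    alt <- if (g$strand == "+") "G" else "C"
    chars <- strsplit(gen$contigs[[g$contig]], "")[[1]]
    cds_pos <- unlist(lapply(seq_len(nrow(g$exons)), function(i) {
      s <- max(g$exons[i, 1], g$cds[1]); e <- min(g$exons[i, 2], g$cds[2])
      if (s <= e) s:e else integer(0)
    }))
    hits <- cds_pos[chars[cds_pos] == want_ref]
    for (p in sample(hits, min(8, length(hits)))) {
      expect_identical(annotate_consequence(g, p, gen, want_ref, alt),
                       consequence_oracle(g, p, gen, want_ref, alt),
                       info = sprintf("%s:%d", gid, p))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 50)
  # hand example: A>G at codon position 1 of ATG -> GTG (M -> V), missense
  gsim <- genome_context(
    c(c1 = "AAAAAAAAAAATGGCTTAAAAAAAAA"),
    genes = list(gene_model("gx", "c1", "+", rbind(c(5L, 22L)),
                            cds = c(11L, 19L))))
  expect_identical(annotate_consequence(gsim$genes[["gx"]], 11L, gsim,
                                        "A", "G"), "missense")
  # UTR and intron categories
  gen2 <- fixture_genome()
  expect_identical(annotate_consequence(gen2$genes[["GP"]], 63L, gen2,
                                        "A", "G"), "intron")
  expect_identical(annotate_consequence(gen2$genes[["GP"]], 45L, gen2,
                                        "A", "G"), "non_coding")
})

test_that("filter log accounts for every candidate exactly once", {
  ds <- simulate_dataset(sim_config(n_edit = 40L, n_diff = 10L, n_hub = 5L,
                                    n_het = 20L, n_hom = 10L, n_null = 30L,
                                    n_decoy = c(homopolymer = 5L,
                                                simple_repeat = 5L,
                                                mitochondrial = 5L,
                                                splice_junction = 5L,
                                                near_indel = 5L,
                                                read_end = 5L)),
                         seed = 3)
  called <- call_editing(ds$counts, ds$genome)
  n_cand <- sum(called$snvs$sites$candidate)
  expect_equal(nrow(called$filter_log), n_cand)
  expect_false(anyDuplicated(called$filter_log$site) > 0)
  expect_equal(sum(called$filter_log$reason == "retained"),
               nrow(called$matrix$events))
})

test_that("event set is invariant under reverse-complementing the genome", {
  # mirror the fixture genome: reverse-complement contigs, flip all
  # annotations and counts to mirrored coordinates and swapped strands
  gen <- fixture_genome()
  sam <- paste0("s", 1:4)
  sites <- data.frame(contig = "chrT", pos = c(45L, 165L), strand = c("+", "-"))
  counts <- build_counts(sites, sam, depth = 50, levels = 0.2)
  em1 <- call_editing(counts, gen)$matrix

  L <- nchar(gen$contigs)
  flip <- function(contig, pos) L[[contig]] - pos + 1L
  contigs_rc <- vapply(gen$contigs, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  genes_rc <- lapply(gen$genes, function(g) {
    ex <- cbind(flip(g$contig, g$exons[, 2]), flip(g$contig, g$exons[, 1]))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    gene_model(g$gene_id, g$contig, if (g$strand == "+") "-" else "+", ex)
  })
  rep_rc <- within(gen$repeats, {
    s2 <- flip(contig, end); end <- flip(contig, start); start <- s2
    rm(s2)
  })[, c("contig", "start", "end", "class")]
  jn_rc <- data.frame(contig = gen$junctions$contig,
                      pos = flip("chrT", gen$junctions$pos))
  gen_rc <- genome_context(contigs_rc, genes = genes_rc, repeats = rep_rc,
                           junctions = jn_rc, mito_name = "chrM")
  counts_rc <- counts
  counts_rc$sites$pos <- flip("chrT", counts$sites$pos)
  counts_rc$sites$ref <- chartr("ACGT", "TGCA", counts$sites$ref)
  swap <- function(a, b) list(a = b, b = a)
  tmp <- counts_rc$nA; counts_rc$nA <- counts_rc$nT; counts_rc$nT <- tmp
  tmp <- counts_rc$nC; counts_rc$nC <- counts_rc$nG; counts_rc$nG <- tmp
  counts_rc$alt_read_pos <- 1 - counts$alt_read_pos
  keys_rc <- site_key(counts_rc$sites$contig, counts_rc$sites$pos)
  for (f in c("nA", "nC", "nG", "nT", "alt_read_pos"))
    rownames(counts_rc[[f]]) <- keys_rc
  em2 <- call_editing(counts_rc, gen_rc)$matrix
  expect_equal(nrow(em2$events), nrow(em1$events))
  expect_setequal(flip("chrT", em2$events$pos), em1$events$pos)
  m1 <- em1$levels[order(em1$events$pos), , drop = FALSE]
  m2 <- em2$levels[order(flip("chrT", em2$events$pos)), , drop = FALSE]
  expect_equal(unname(m1), unname(m2))
})
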