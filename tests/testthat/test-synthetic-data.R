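small_cfg <- function(...) {
  sim_config(n_edit = 40L, n_diff = 10L, n_hub = 5L, n_het = 20L,
             n_hom = 10L, n_null = 20L,
             n_decoy = c(homopolymer = 4L, simple_repeat = 4L,
                         mitochondrial = 4L, splice_junction = 4L,
                         near_indel = 4L, read_end = 4L), ...)
}

test_that("simulated genome contains the requested context features", {
  cfg <- sim_config(n_homopolymer = 3L)
  gen <- simulate_genome(cfg, seed = 5)
  expect_identical(gen$mito_name, "chrM")
  # at least the 3 requested homopolymer runs of length >= 5 exist
  hp <- edscan:::find_homopolymers(gen$contigs[["chr1"]])
  expect_gte(nrow(hp), 3)
  expect_true(all(hp$end - hp$start + 1 >= 5))
  expect_equal(sum(gen$repeats$class == "simple_repeat"),
               cfg$n_simple_repeat)
  expect_equal(sum(gen$repeats$class == "alu"), cfg$n_alu)
  strands <- vapply(gen$genes, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
  expect_gt(nrow(gen$junctions), 0)
  # determinism: identical FASTA bytes
  gen2 <- simulate_genome(cfg, seed = 5)
  expect_identical(gen$contigs, gen2$contigs)
  expect_error(sim_config(bogus = 1), "unknown config field")
})

test_that("planted truth respects site classes and strand placement", {
  cfg <- small_cfg()
  gen <- simulate_genome(cfg, seed = 7)
  truth <- plant_truth(gen, cfg, seed = 8)
  st <- truth$sites
  expect_equal(sum(st$kind == "edit" & is.na(st$decoy_class)), cfg$n_edit)
  expect_equal(sum(st$kind == "het_snp"), cfg$n_het)
  expect_equal(sum(st$kind == "hom_snp"), cfg$n_hom)
  expect_equal(as.vector(table(st$decoy_class)[names(cfg$n_decoy)]),
               as.vector(cfg$n_decoy))
  # edit sites only at A on + genes, T on - genes
  expect_true(all(st$ref[st$strand == "+"] == "A"))
  expect_true(all(st$ref[st$strand == "-"] == "T"))
  # decoy context flags match their class
  expect_true(all(st$in_homopolymer[st$decoy_class %in% "homopolymer"]))
  expect_true(all(st$in_simple_repeat[st$decoy_class %in% "simple_repeat"]))
  expect_true(all(st$on_mito[st$decoy_class %in% "mitochondrial"]))
  expect_true(all(st$near_junction[st$decoy_class %in% "splice_junction"]))
  clean <- st$kind == "edit" & is.na(st$decoy_class)
  expect_false(any(st$in_homopolymer[clean] | st$in_simple_repeat[clean] |
                     st$near_junction[clean] | st$on_mito[clean]))
  # SNP invariants
  expect_true(all(truth$levels[st$kind == "het_snp", ] == 0.5))
  expect_true(all(truth$levels[st$kind == "hom_snp", ] == 1))
  expect_true(all(truth$levels[st$kind == "null", ] == 0))
  ed <- st$kind == "edit"
  expect_true(all(truth$levels[ed, ] >= 0.005 & truth$levels[ed, ] <= 0.99))
  # whitelisted/blacklisted sites landed in the genome annotations
  expect_equal(nrow(truth$genome$whitelist), sum(st$whitelisted))
  expect_equal(nrow(truth$genome$blacklist), sum(st$blacklisted))
})

test_that("zero effect size gives equal group means everywhere", {
  cfg <- small_cfg(delta = 0, n_hub = 0L)
  gen <- simulate_genome(cfg, seed = 2)
  truth <- plant_truth(gen, cfg, seed = 2)
  expect_equal(truth$sites$mu_case, truth$sites$mu_control)
})

test_that("hub sites share a latent factor producing strong correlations", {
  cfg <- sim_config(n_edit = 40L, n_diff = 20L, n_hub = 20L, n_het = 0L,
                    n_hom = 0L, n_null = 0L,
                    n_decoy = c(homopolymer = 0L, simple_repeat = 0L,
                                mitochondrial = 0L, splice_junction = 0L,
                                near_indel = 0L, read_end = 0L))
  gen <- simulate_genome(cfg, seed = 9)
  truth <- plant_truth(gen, cfg, seed = 9)
  hub_lv <- truth$levels[truth$sites$hub, ]
  cr <- cor(t(hub_lv))
  expect_gt(mean(cr[upper.tri(cr)]), 0.6)
})

test_that("simulated counts reflect binomial editing and are deterministic", {
  cfg <- small_cfg(error_rate = 0)
  gen <- simulate_genome(cfg, seed = 4)
  truth <- plant_truth(gen, cfg, seed = 5)
  counts <- simulate_counts(truth, truth$genome, cfg, seed = 6)
  counts2 <- simulate_counts(truth, truth$genome, cfg, seed = 6)
  expect_identical(counts, counts2)
  # byte-identical TSV under a fixed seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_counts(counts, p1); write_counts(counts2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # strand representation: G at + edit sites, C at - edit sites, and the
  # observed level tracks the planted mean
  st <- truth$sites[order(truth$sites$contig, truth$sites$pos), ]
  keys <- paste(st$contig, st$pos, sep = ":")
  ed_p <- keys[st$kind == "edit" & st$strand == "+"]
  ed_m <- keys[st$kind == "edit" & st$strand == "-"]
  expect_true(all(counts$nC[ed_p, ] == 0) && all(counts$nT[ed_p, ] == 0))
  expect_true(all(counts$nA[ed_m, ] == 0) && all(counts$nG[ed_m, ] == 0))
  # read-end decoys carry low alt read positions; genuine sites do not
  re <- keys[st$read_end]
  ok <- !is.na(counts$alt_read_pos[re, ])
  expect_true(all(counts$alt_read_pos[re, ][ok] <= 0.04))
  gm <- keys[st$kind == "edit" & !st$read_end]
  okg <- !is.na(counts$alt_read_pos[gm, ])
  expect_true(all(counts$alt_read_pos[gm, ][okg] >= 0.05))
})

test_that("het SNPs show the germline AAF pattern at high depth", {
  # at depth 500 the binomial(depth, 0.5) AAF lies in [0.40, 0.60] with
  # probability ~1, so the rule-4 fraction criterion is met in all samples
  cfg <- small_cfg(depth_mean = 500, depth_dispersion = 50, error_rate = 0)
  gen <- simulate_genome(cfg, seed = 1)
  truth <- plant_truth(gen, cfg, seed = 1)
  counts <- simulate_counts(truth, truth$genome, cfg, seed = 1)
  st <- truth$sites[order(truth$sites$contig, truth$sites$pos), ]
  keys <- paste(st$contig, st$pos, sep = ":")
  het <- keys[st$kind == "het_snp"]
  for (k in het) {
    plus <- st$strand[match(k, keys)] == "+"
    aaf <- if (plus) counts$nG[k, ] / (counts$nA[k, ] + counts$nG[k, ])
           else counts$nC[k, ] / (counts$nT[k, ] + counts$nC[k, ])
    expect_gt(mean(aaf >= 0.40 & aaf <= 0.60, na.rm = TRUE), 0.90)
  }
})

test_that("observed editing level is consistent for the planted mean at extreme depth", {
  cfg <- small_cfg(depth_mean = 1e4, depth_dispersion = 100, kappa = Inf,
                   error_rate = 0, n_het = 0L, n_hom = 0L, n_null = 0L,
                   n_hub = 0L)
  gen <- simulate_genome(cfg, seed = 3)
  truth <- plant_truth(gen, cfg, seed = 3)
  counts <- simulate_counts(truth, truth$genome, cfg, seed = 3)
  st <- truth$sites[order(truth$sites$contig, truth$sites$pos), ]
  keys <- paste(st$contig, st$pos, sep = ":")
  grp <- truth$samples$group[match(counts$samples, truth$samples$sample_id)]
  for (i in which(st$kind == "edit" & is.na(st$decoy_class))[1:20]) {
    k <- keys[i]
    lev <- if (st$strand[i] == "+")
      counts$nG[k, ] / (counts$nA[k, ] + counts$nG[k, ])
    else counts$nC[k, ] / (counts$nT[k, ] + counts$nC[k, ])
    expect_lt(abs(mean(lev[grp == "case"]) - st$mu_case[i]), 0.005)
    expect_lt(abs(mean(lev[grp == "control"]) - st$mu_control[i]), 0.005)
  }
})

test_that("clinical simulation follows the linear hormone model", {
  cfg <- small_cfg()
  gen <- simulate_genome(cfg, seed = 12)
  truth <- plant_truth(gen, cfg, seed = 12)
  md <- simulate_clinical(truth, cfg, seed = 12)
  md2 <- simulate_clinical(truth, cfg, seed = 12)
  expect_identical(md, md2)
  expect_equal(md$LH_FSH, md$LH / md$FSH)
  # gamma_LH > 0: case mean LH exceeds control mean in expectation; average
  # over seeds to beat noise
  lh_gap <- vapply(1:20, function(s) {
    m <- simulate_clinical(truth, cfg, seed = 100 + s)
    mean(m$LH[m$group == "case"]) - mean(m$LH[m$group == "control"])
  }, numeric(1))
  expect_gt(mean(lh_gap), 0)
  # beta = gamma = 0 decouples hormones from the hub factor
  cfg0 <- small_cfg()
  cfg0$hormones$beta[] <- 0; cfg0$hormones$gamma[] <- 0
  rs <- vapply(1:30, function(s) {
    m <- simulate_clinical(truth, cfg0, seed = 200 + s)
    cor(m$LH, truth$samples$latent)
  }, numeric(1))
  expect_lt(quantile(abs(rs), 0.95), 0.55)
  expect_lt(mean(abs(rs) >= 0.3), 0.4)
})

test_that("expression matrix carries the planted cis coupling", {
  cfg <- small_cfg()
  gen <- simulate_genome(cfg, seed = 21)
  truth <- plant_truth(gen, cfg, seed = 21)
  expr <- simulate_expression(truth, truth$genome, cfg, seed = 21)
  expect_identical(colnames(expr), truth$samples$sample_id)
  hub <- which(truth$sites$hub)
  j <- hub[1]
  g <- truth$sites$gene_id[j]
  key <- paste(truth$sites$contig[j], truth$sites$pos[j], sep = ":")
  expect_gt(cor(log2(expr[g, ]), truth$levels[key, ]), 0.5)
})
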