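#' Simulation configuration
#'
#' Default settings describe the discovery-cohort-style study the package is
#' validated against: 12 case vs 10 control samples, mean sequencing depth 50
#' (negative binomial, dispersion 5, so a realistic fraction of cells drops
#' below the depth-10 callability floor), per-base sequencing error 0.1%,
#' 200 planted editing sites of which 100 are differential at an editing
#' level shift of 0.15 (20 of those form a correlated hub block driven by a
#' shared latent factor), 100 heterozygous and 50 homozygous germline SNPs,
#' 200 context decoys split across the six artifact classes the filter
#' cascade targets, and 300 unedited null sites. Hormone means and standard
#' deviations default to values typical of a PCOS discovery cohort (LH
#' elevated in cases, FSH unchanged), with LH additionally loaded on the hub
#' latent factor.
#'
#' @param ... Overrides for any default field.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_case = 12L, n_control = 10L,
    # genome geometry
    n_genes = 20L, mito = TRUE,
    n_homopolymer = 12L, n_simple_repeat = 8L, n_alu = 10L,
    # sequencing model
    depth_mean = 50, depth_dispersion = 5, error_rate = 0.001,
    # planted sites
    n_edit = 200L, n_diff = 100L, delta = 0.15,
    n_het = 100L, n_hom = 50L, n_null = 300L,
    n_decoy = c(homopolymer = 34L, simple_repeat = 34L, mitochondrial = 33L,
                splice_junction = 33L, near_indel = 33L, read_end = 33L),
    mu_range = c(0.05, 0.35), kappa = 30,
    whitelist_frac = 0.3, snp_blacklist_frac = 0.95,
    # hub block
    n_hub = 20L, hub_loading = 0.9, hub_sd = 0.12, hub_group_shift = 2,
    hub_mu_control = 0.25,
    # hormone model: value = alpha + beta * latent + gamma * I(case) + noise
    hormones = data.frame(
      feature = c("LH", "FSH", "T", "DHEAS", "E2"),
      alpha = c(7.34, 8.10, 0.76, 344.23, 36.09),
      beta  = c(2.5, 0, 0, 0, 0),
      gamma = c(13.16, -0.34, 0.40, 90.58, 64.15),
      sd    = c(3.5, 4.9, 0.45, 200, 25)),
    # expression model for the cis-correlation analysis
    expr_base_mean = 8, expr_base_sd = 1, expr_noise_sd = 0.5, cis_beta = 3
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop_edscan("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  with(cfg, {
    stopifnot(n_case >= 0, n_control >= 0, all(n_decoy >= 0),
              n_edit >= 0, n_diff <= n_edit, n_hub <= n_diff,
              error_rate >= 0, error_rate <= 0.05,
              kappa > 0, depth_mean > 0)
  })
  structure(cfg, class = "SimulationConfig")
}

## ---- genome ----------------------------------------------------------------

#' Simulate a toy genome with the contexts the filter cascade targets
#'
#' Builds one main contig carrying `n_genes` alternating-strand gene models
#' (three exons, an internal CDS, hence genuine 5'/3' UTRs, introns and four
#' splice-junction-adjacent bases per gene), an optional mitochondrial contig
#' with a single-exon gene, and plants homopolymer runs (>= 6 nt),
#' simple-repeat tracts and Alu-like intervals inside exons. Repeat
#' annotations, junction bases and gene models are recorded in the returned
#' context; homopolymers are sequence-intrinsic and rediscovered by scanning.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; fully determines the genome.
#' @return A `GenomeContext` with empty whitelist/blacklist (filled by
#'   [plant_truth()]).
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  ng <- config$n_genes
  gene_len <- 1800L; spacing <- 700L
  starts <- 1000L + (seq_len(ng) - 1L) * (gene_len + spacing)
  chr1_len <- 1000L + ng * (gene_len + spacing) + 500L
  chr1 <- sample(c("A", "C", "G", "T"), chr1_len, replace = TRUE)

  genes <- list()
  for (i in seq_len(ng)) {
    g0 <- starts[i]
    ex <- cbind(start = g0 + c(0L, 700L, 1400L),
                end   = g0 + c(399L, 1099L, 1799L))
    strand <- if (i %% 2L == 1L) "+" else "-"
    cds <- if (i %% 7L == 0L) NULL else c(g0 + 200L, g0 + 1600L)
    genes[[i]] <- gene_model(sprintf("G%03d", i), "chr1", strand, ex, cds)
  }

  # feature placement inside exons, non-overlapping, away from junctions
  occupied <- data.frame(start = integer(0), end = integer(0))
  place <- function(width) {
    for (try in 1:200) {
      g <- genes[[sample.int(ng, 1)]]
      ex <- g$exons[2, ]                      # middle exon: far from gene ends
      lo <- ex[1] + 30L; hi <- ex[2] - 30L - width
      if (hi <= lo) next
      s <- sample(lo:hi, 1)
      if (any(occupied$start <= s + width + 10L & occupied$end >= s - 10L)) next
      occupied <<- rbind(occupied, data.frame(start = s, end = s + width - 1L))
      return(list(gene = g, start = s))
    }
    stop_edscan("could not place feature of width %d: contig too crowded", width)
  }

  for (k in seq_len(config$n_homopolymer)) {
    p <- place(6L)
    base <- if (p$gene$strand == "+") "A" else "T"
    chr1[p$start:(p$start + 5L)] <- base
  }
  repeats <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), class = character(0))
  for (k in seq_len(config$n_simple_repeat)) {
    p <- place(24L)
    chr1[p$start:(p$start + 23L)] <- rep(c("A", "T"), 12L)
    repeats <- rbind(repeats, data.frame(contig = "chr1", start = p$start,
                                         end = p$start + 23L,
                                         class = "simple_repeat"))
  }
  for (k in seq_len(config$n_alu)) {
    g <- genes[[sample.int(ng, 1)]]
    s <- sample(g$start:(g$end - 300L), 1)
    repeats <- rbind(repeats, data.frame(contig = "chr1", start = s,
                                         end = s + 299L, class = "alu"))
  }

  # break accidental homopolymer runs over CDS starts? not needed: planting
  # avoids them by scanning the final sequence.

  contigs <- c(chr1 = paste(chr1, collapse = ""))
  mito_name <- NA_character_
  if (isTRUE(config$mito)) {
    chrM <- sample(c("A", "C", "G", "T"), 2000L, replace = TRUE)
    contigs <- c(contigs, chrM = paste(chrM, collapse = ""))
    genes <- c(genes, list(gene_model("MT-G1", "chrM", "+",
                                      cbind(201L, 1400L), c(401L, 1201L))))
    mito_name <- "chrM"
  }

  junctions <- do.call(rbind, lapply(genes, function(g) {
    if (nrow(g$exons) < 2) return(NULL)
    n <- nrow(g$exons)
    data.frame(contig = g$contig,
               pos = c(g$exons[-n, "end"], g$exons[-1, "start"]))
  }))
  genome_context(contigs, genes = genes, repeats = repeats,
                 junctions = junctions, mito_name = mito_name)
}

# Scan a contig for maximal single-base runs of length >= min_len.
find_homopolymers <- function(seqstr, min_len = 5L) {
  r <- rle(strsplit(seqstr, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  data.frame(start = (ends - r$lengths + 1L)[keep], end = ends[keep],
             base = r$values[keep])
}

## ---- truth -----------------------------------------------------------------

#' Plant ground-truth sites into a simulated genome
#'
#' Places clean editing sites (a subset differential, a subset forming a
#' latent-factor hub block), heterozygous/homozygous germline SNPs, null
#' sites and context decoys (homopolymer, simple repeat, mitochondrial,
#' splice-junction, near-indel, read-end). Editing sites sit at genomic A in
#' plus-strand genes and genomic T in minus-strand genes. Whitelisted sites
#' are added to the genome's editing whitelist, blacklisted SNPs to its SNP
#' blacklist; the updated genome travels in the returned object.
#'
#' @inheritParams simulate_genome
#' @param genome Result of [simulate_genome()].
#' @return An object of class `TruthTable`: `samples` (with group and latent
#'   factor), `sites`, per-sample true `levels` matrix, and the updated
#'   `genome`.
#' @export
plant_truth <- function(genome, config = sim_config(), seed = 1) {
  set.seed(seed)
  seqs <- lapply(genome$contigs, identity)
  hp <- lapply(genome$contigs, find_homopolymers)
  simple_rep <- genome$repeats[genome$repeats$class == "simple_repeat", ]

  # eligibility table over all genic positions
  elig <- do.call(rbind, lapply(genome$genes, function(g) {
    pos <- g$start:g$end
    refs <- strsplit(substr(genome$contigs[[g$contig]], g$start, g$end), "")[[1]]
    want <- if (g$strand == "+") "A" else "T"
    d <- data.frame(contig = g$contig, pos = pos, ref = refs,
                    gene_id = g$gene_id, strand = g$strand)
    d <- d[d$ref == want, ]
    h <- hp[[g$contig]]
    d$in_homopolymer <- vapply(d$pos, function(p)
      any(h$start <= p & h$end >= p), logical(1))
    d$in_simple_repeat <- in_intervals(d$contig, d$pos, simple_rep)
    jn <- genome$junctions[genome$junctions$contig == g$contig, "pos"]
    d$near_junction <- vapply(d$pos, function(p)
      length(jn) > 0 && min(abs(jn - p)) <= 6, logical(1))
    d$on_mito <- !is.na(genome$mito_name) & g$contig == genome$mito_name
    d
  }))
  rownames(elig) <- NULL
  clean <- !elig$in_homopolymer & !elig$in_simple_repeat &
    !elig$near_junction & !elig$on_mito

  take <- function(mask, n, what) {
    avail <- which(mask & !elig$used)
    if (length(avail) < n)
      stop_edscan("infeasible placement: need %d %s sites, only %d eligible",
                  n, what, length(avail))
    idx <- sample(avail, n)
    elig$used[idx] <<- TRUE
    idx
  }
  elig$used <- FALSE

  cfg <- config
  i_edit <- take(clean, cfg$n_edit, "clean edit")
  i_het  <- take(clean, cfg$n_het, "het SNP")
  i_hom  <- take(clean, cfg$n_hom, "hom SNP")
  i_null <- take(clean, cfg$n_null, "null")
  nd <- cfg$n_decoy
  i_dec <- list(
    homopolymer = take(elig$in_homopolymer & !elig$near_junction &
                         !elig$on_mito, nd[["homopolymer"]], "homopolymer decoy"),
    simple_repeat = take(elig$in_simple_repeat & !elig$in_homopolymer &
                           !elig$near_junction & !elig$on_mito,
                         nd[["simple_repeat"]], "simple-repeat decoy"),
    mitochondrial = take(elig$on_mito & !elig$in_homopolymer &
                           !elig$in_simple_repeat & !elig$near_junction,
                         nd[["mitochondrial"]], "mitochondrial decoy"),
    splice_junction = take(elig$near_junction & !elig$in_homopolymer &
                             !elig$in_simple_repeat & !elig$on_mito,
                           nd[["splice_junction"]], "splice-junction decoy"),
    near_indel = take(clean, nd[["near_indel"]], "near-indel decoy"),
    read_end = take(clean, nd[["read_end"]], "read-end decoy"))

  mk <- function(idx, kind, decoy_class = NA_character_) {
    if (length(idx) == 0) return(NULL)
    cbind(elig[idx, c("contig", "pos", "ref", "gene_id", "strand",
                      "in_homopolymer", "in_simple_repeat", "near_junction",
                      "on_mito")],
          data.frame(kind = kind, decoy_class = decoy_class))
  }
  sites <- rbind(
    mk(i_edit, "edit"), mk(i_het, "het_snp"), mk(i_hom, "hom_snp"),
    mk(i_null, "null"),
    do.call(rbind, lapply(names(i_dec), function(cl)
      mk(i_dec[[cl]], "edit", cl))))
  rownames(sites) <- NULL

  n_sites <- nrow(sites)
  sites$near_indel <- !is.na(sites$decoy_class) & sites$decoy_class == "near_indel"
  sites$read_end   <- !is.na(sites$decoy_class) & sites$decoy_class == "read_end"
  sites$differential <- FALSE
  sites$hub <- FALSE
  is_clean_edit <- sites$kind == "edit" & is.na(sites$decoy_class)
  clean_idx <- which(is_clean_edit)
  diff_idx <- clean_idx[seq_len(cfg$n_diff)]
  hub_idx <- diff_idx[seq_len(cfg$n_hub)]
  sites$differential[diff_idx] <- TRUE
  sites$hub[hub_idx] <- TRUE

  # group means
  sites$mu_control <- 0
  sites$mu_case <- 0
  mu0 <- stats::runif(length(clean_idx), cfg$mu_range[1], cfg$mu_range[2])
  sites$mu_control[clean_idx] <- mu0
  sites$mu_case[clean_idx] <- mu0
  sites$mu_case[diff_idx] <- pmin(0.99, sites$mu_control[diff_idx] + cfg$delta)
  sites$mu_control[hub_idx] <- cfg$hub_mu_control
  sites$mu_case[hub_idx] <- min(0.99, cfg$hub_mu_control + cfg$delta)
  dec_all <- which(!is.na(sites$decoy_class))
  mud <- stats::runif(length(dec_all), 0.10, 0.30)
  sites$mu_control[dec_all] <- mud
  sites$mu_case[dec_all] <- mud
  sites$mu_control[sites$kind == "het_snp"] <- 0.5
  sites$mu_case[sites$kind == "het_snp"] <- 0.5
  sites$mu_control[sites$kind == "hom_snp"] <- 1
  sites$mu_case[sites$kind == "hom_snp"] <- 1

  # whitelist / blacklist membership
  sites$whitelisted <- FALSE
  sites$whitelisted[clean_idx] <-
    stats::runif(length(clean_idx)) < cfg$whitelist_frac
  sites$whitelisted[hub_idx] <- TRUE       # hub events are known sites
  sites$blacklisted <- FALSE
  snp_idx <- which(sites$kind %in% c("het_snp", "hom_snp"))
  sites$blacklisted[snp_idx] <-
    stats::runif(length(snp_idx)) < cfg$snp_blacklist_frac

  # samples and latent hub factor
  n <- cfg$n_case + cfg$n_control
  samples <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(cfg$n_case)),
                  sprintf("control_%02d", seq_len(cfg$n_control))),
    group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control)))
  samples$latent <- stats::rnorm(n) +
    cfg$hub_group_shift * ifelse(samples$group == "case", 0.5, -0.5)

  # per-sample true levels
  levels <- matrix(0, n_sites, n,
                   dimnames = list(site_key(sites$contig, sites$pos),
                                   samples$sample_id))
  mu_s <- ifelse(rep(samples$group, each = n_sites) == "case",
                 rep(sites$mu_case, n), rep(sites$mu_control, n))
  mu_s <- matrix(mu_s, n_sites, n)
  ed <- which(sites$kind == "edit")
  if (is.finite(cfg$kappa)) {
    m <- mu_s[ed, , drop = FALSE]
    levels[ed, ] <- stats::rbeta(length(m), m * cfg$kappa, (1 - m) * cfg$kappa)
  } else {
    levels[ed, ] <- mu_s[ed, , drop = FALSE]
  }
  if (length(hub_idx)) {
    lam <- cfg$hub_loading
    f <- samples$latent
    for (j in hub_idx) {
      base <- ifelse(samples$group == "case", sites$mu_case[j],
                     sites$mu_control[j])
      levels[j, ] <- base + lam * cfg$hub_sd * f +
        sqrt(1 - lam^2) * cfg$hub_sd * stats::rnorm(n)
    }
  }
  levels[sites$kind == "het_snp", ] <- 0.5
  levels[sites$kind == "hom_snp", ] <- 1
  levels[sites$kind == "edit", ] <-
    pmin(0.99, pmax(0.005, levels[sites$kind == "edit", ]))

  # fold whitelist/blacklist into the genome annotations
  wl <- sites[sites$whitelisted, c("contig", "pos")]
  bl <- sites[sites$blacklisted, c("contig", "pos")]
  genome$whitelist <- rbind(genome$whitelist, wl)
  genome$blacklist <- rbind(genome$blacklist, bl)
  genome$whitelist <- genome$whitelist[order(genome$whitelist$contig,
                                             genome$whitelist$pos), ]
  genome$blacklist <- genome$blacklist[order(genome$blacklist$contig,
                                             genome$blacklist$pos), ]
  rownames(genome$whitelist) <- rownames(genome$blacklist) <- NULL

  structure(list(samples = samples, sites = sites, levels = levels,
                 genome = genome, config = cfg),
            class = "TruthTable")
}

## ---- counts ----------------------------------------------------------------

#' Simulate pileup counts from planted truth
#'
#' Depth per cell is negative binomial; edited (alt) reads are binomial at
#' the site's true per-sample level; sequencing errors scatter reads
#' uniformly to the other three bases. Plus-strand editing appears as G
#' counts at A reference sites, minus-strand editing as C counts at T
#' reference sites. The median relative read position of alt reads is drawn
#' in (0.05, 0.95) for genuine sites and at or below 0.04 for read-end
#' decoys.
#'
#' @inheritParams plant_truth
#' @param truth Result of [plant_truth()].
#' @return A `SiteCountTable`.
#' @export
simulate_counts <- function(truth, genome = truth$genome,
                            config = truth$config, seed = 1) {
  set.seed(seed)
  st <- truth$sites
  ord <- order(st$contig, st$pos)
  st <- st[ord, ]
  lv <- truth$levels[ord, , drop = FALSE]
  n_sites <- nrow(st); n_samp <- nrow(truth$samples)
  depth <- matrix(stats::rnbinom(n_sites * n_samp, size = config$depth_dispersion,
                                 mu = config$depth_mean), n_sites, n_samp)
  alt <- matrix(stats::rbinom(n_sites * n_samp, as.vector(depth),
                              as.vector(lv)), n_sites, n_samp)
  ref <- depth - alt
  zero <- matrix(0L, n_sites, n_samp)
  nA <- nC <- nG <- nT <- zero
  plus <- st$strand == "+"
  nA[plus, ] <- ref[plus, ]; nG[plus, ] <- alt[plus, ]
  nT[!plus, ] <- ref[!plus, ]; nC[!plus, ] <- alt[!plus, ]

  # sequencing errors: each read miscalls with prob error_rate, uniformly to
  # the other three bases
  if (config$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    mats <- list(A = nA, C = nC, G = nG, T = nT)
    err_add <- lapply(mats, function(m) matrix(0L, n_sites, n_samp))
    for (b in bases) {
      m <- mats[[b]]
      k <- matrix(stats::rbinom(length(m), as.vector(m), config$error_rate),
                  n_sites, n_samp)
      mats[[b]] <- m - k
      hot <- which(k > 0)
      others <- setdiff(bases, b)
      for (cell in hot) {
        spread <- stats::rmultinom(1, k[cell], rep(1 / 3, 3))[, 1]
        for (j in 1:3)
          err_add[[others[j]]][cell] <- err_add[[others[j]]][cell] + spread[j]
      }
    }
    nA <- mats$A + err_add$A; nC <- mats$C + err_add$C
    nG <- mats$G + err_add$G; nT <- mats$T + err_add$T
  }

  alt_count <- matrix(0L, n_sites, n_samp)
  alt_count[plus, ] <- nG[plus, , drop = FALSE]
  alt_count[!plus, ] <- nC[!plus, , drop = FALSE]
  arp <- matrix(NA_real_, n_sites, n_samp)
  has_alt <- alt_count > 0
  low <- matrix(rep(st$read_end, n_samp), n_sites, n_samp)
  n_hi <- sum(has_alt & !low); n_lo <- sum(has_alt & low)
  arp[has_alt & !low] <- stats::runif(n_hi, 0.05, 0.95)
  arp[has_alt & low] <- stats::runif(n_lo, 0.005, 0.035)

  sites <- data.frame(contig = st$contig, pos = st$pos, ref = st$ref,
                      near_indel = st$near_indel)
  site_count_table(truth$samples$sample_id, sites,
                   nA, nC, nG, nT, round(arp, 6))
}

## ---- clinical covariates ---------------------------------------------------

#' Simulate hormone metadata coupled to group and the hub latent factor
#'
#' Each hormone is `alpha + beta * latent + gamma * I(case) + noise`; the
#' LH/FSH ratio is computed from the simulated LH and FSH.
#'
#' @inheritParams simulate_counts
#' @return A `SampleMetadata` data.frame.
#' @export
simulate_clinical <- function(truth, config = truth$config, seed = 1) {
  set.seed(seed)
  s <- truth$samples
  d <- data.frame(sample_id = s$sample_id, group = s$group)
  hm <- config$hormones
  for (i in seq_len(nrow(hm))) {
    v <- hm$alpha[i] + hm$beta[i] * s$latent +
      hm$gamma[i] * (s$group == "case") +
      stats::rnorm(nrow(s), 0, hm$sd[i])
    d[[hm$feature[i]]] <- pmax(v, 0.01)
  }
  d$LH_FSH <- d$LH / d$FSH
  sample_metadata(d)
}

#' Simulate a per-gene expression matrix with cis coupling at hub genes
#'
#' Gene expression is log-normal around a per-gene baseline; genes hosting a
#' planted hub editing site get an additive log2 term `cis_beta * level` of
#' their first hub site, creating the editing-expression cis correlation the
#' clinical module tests for.
#'
#' @inheritParams simulate_counts
#' @return Numeric matrix genes x samples (linear scale).
#' @export
simulate_expression <- function(truth, genome = truth$genome,
                                config = truth$config, seed = 1) {
  set.seed(seed)
  gids <- sort(names(genome$genes))
  n <- nrow(truth$samples)
  base <- stats::rnorm(length(gids), config$expr_base_mean, config$expr_base_sd)
  log2x <- matrix(rep(base, n), length(gids), n) +
    stats::rnorm(length(gids) * n, 0, config$expr_noise_sd)
  rownames(log2x) <- gids
  colnames(log2x) <- truth$samples$sample_id
  hub_sites <- which(truth$sites$hub)
  if (length(hub_sites)) {
    first_per_gene <- hub_sites[!duplicated(truth$sites$gene_id[hub_sites])]
    for (j in first_per_gene) {
      g <- truth$sites$gene_id[j]
      key <- site_key(truth$sites$contig[j], truth$sites$pos[j])
      log2x[g, ] <- log2x[g, ] + config$cis_beta * truth$levels[key, ]
    }
  }
  2^log2x
}

## ---- orchestration & I/O ---------------------------------------------------

#' Simulate a complete dataset (genome, truth, counts, metadata, expression)
#'
#' Stage seeds are derived from `seed` by fixed small offsets, so one seed
#' fully determines every artifact.
#'
#' @inheritParams simulate_genome
#' @return List with elements `genome`, `truth`, `counts`, `metadata`,
#'   `expression`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  genome0 <- simulate_genome(config, seed)
  truth <- plant_truth(genome0, config, seed + 1L)
  counts <- simulate_counts(truth, truth$genome, config, seed + 2L)
  metadata <- simulate_clinical(truth, config, seed + 3L)
  expression <- simulate_expression(truth, truth$genome, config, seed + 4L)
  list(genome = truth$genome, truth = truth, counts = counts,
       metadata = metadata, expression = expression)
}

#' Write a simulated dataset to a directory
#'
#' Emits `genome.fa`, annotation BEDs, `genes.gtf`, `counts.tsv`,
#' `metadata.tsv`, `expression.tsv` and `truth.tsv`, all with deterministic
#' ordering.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_genome(dataset$genome, dir)
  p2 <- c(counts = file.path(dir, "counts.tsv"),
          metadata = file.path(dir, "metadata.tsv"),
          expression = file.path(dir, "expression.tsv"),
          truth = file.path(dir, "truth.tsv"))
  write_counts(dataset$counts, p2["counts"])
  md <- as.data.frame(dataset$metadata)
  num <- vapply(md, is.numeric, logical(1))
  md[num] <- lapply(md[num], round, 6)
  write_tsv_strict(md, p2["metadata"])
  ex <- data.frame(gene_id = rownames(dataset$expression),
                   round(dataset$expression, 4), check.names = FALSE)
  write_tsv_strict(ex, p2["expression"])
  tt <- dataset$truth$sites
  tt <- tt[order(tt$contig, tt$pos), ]
  tt$mu_case <- round(tt$mu_case, 6); tt$mu_control <- round(tt$mu_control, 6)
  write_tsv_strict(tt, p2["truth"])
  invisible(c(paths, p2))
}

#' Read an expression matrix written by [write_dataset()]
#' @param path TSV with `gene_id` column then one column per sample.
#' @return Numeric matrix genes x samples.
#' @export
read_expression <- function(path) {
  d <- read_tsv_strict(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  m
}
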