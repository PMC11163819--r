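#' Run the full editing-analysis pipeline on a simulated dataset
#'
#' Executes simulate -> call -> differential editing -> co-editing network
#' -> clinical association as one reproducible run. Every stage writes its
#' outputs under `out_dir` with deterministic formatting, and a manifest of
#' md5 checksums over all outputs is written last, so two runs with the same
#' seed produce byte-identical trees.
#'
#' @param out_dir Run directory (created; existing files overwritten).
#' @param config A [sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @param dre_alpha Significance cutoff for differential editing.
#' @param edge_threshold Adjacency cutoff for hub-degree edges.
#' @param n_hubs Number of hub events to extract.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1,
                         dre_alpha = 0.05, edge_threshold = 0.4,
                         n_hubs = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage: simulate
  dataset <- simulate_dataset(config, seed)
  sim_dir <- file.path(out_dir, "sim")
  write_dataset(dataset, sim_dir)
  cfg_json <- file.path(out_dir, "config.json")
  cfg <- unclass(config)
  cfg$seed <- seed
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)

  ## stage: read back through the file interfaces (round-trip contract)
  genome <- read_genome(file.path(sim_dir, "genome.fa"),
                        list(repeats = file.path(sim_dir, "repeats.bed"),
                             junctions = file.path(sim_dir, "junctions.bed"),
                             whitelist = file.path(sim_dir, "whitelist.bed"),
                             blacklist = file.path(sim_dir, "blacklist.bed"),
                             genes = file.path(sim_dir, "genes.gtf")),
                        mito_name = dataset$genome$mito_name)
  counts <- read_counts(file.path(sim_dir, "counts.tsv"))
  metadata <- read_metadata(file.path(sim_dir, "metadata.tsv"))
  check_samples(counts, metadata)
  expr <- read_expression(file.path(sim_dir, "expression.tsv"))

  ## stage: call
  call_dir <- file.path(out_dir, "call")
  dir.create(call_dir, showWarnings = FALSE)
  called <- call_editing(counts, genome)
  em <- called$matrix
  ev_out <- em$events[, c("contig", "pos", "ref", "alt", "gene_id", "strand",
                          "consequence", "whitelisted", "event_id")]
  write_tsv_strict(ev_out[order(ev_out$contig, ev_out$pos), ],
                   file.path(call_dir, "events.tsv"))
  lv <- data.frame(event = rownames(em$levels),
                   round(em$levels, 6), check.names = FALSE)
  write_tsv_strict(lv[order(lv$event), ], file.path(call_dir, "matrix.tsv"))
  write_tsv_strict(called$filter_log, file.path(call_dir, "filter_log.tsv"))

  ## stage: differential editing
  dre <- dre_test(em, counts, metadata, alpha = dre_alpha)
  dre_dir <- file.path(out_dir, "dre")
  dir.create(dre_dir, showWarnings = FALSE)
  dre_out <- dre
  num <- vapply(dre_out, is.numeric, logical(1))
  dre_out[num] <- lapply(dre_out[num], function(x) round(x, 8))
  write_tsv_strict(as.data.frame(dre_out), file.path(dre_dir, "dre.tsv"))

  ## stage: co-editing network on differential events
  net_dir <- file.path(out_dir, "network")
  dir.create(net_dir, showWarnings = FALSE)
  sig <- dre$testable & !is.na(dre$p_glm) & dre$p_glm < dre_alpha
  sig_keys <- site_key(dre$contig[sig], dre$pos[sig])
  network <- NULL; hubs <- NULL; modules <- NULL; mt <- NULL
  if (sum(sig) >= 20) {
    lev_sig <- em$levels[sig_keys, , drop = FALSE]
    pst <- pick_soft_threshold(lev_sig)
    write_tsv_strict(within(pst$fit_table, {
      r2_signed <- round(r2_signed, 6); mean_k <- round(mean_k, 6)
    }), file.path(net_dir, "power_table.tsv"))
    network <- build_network(lev_sig, pst$power)
    modules <- detect_modules(network)
    write_tsv_strict(data.frame(event = names(modules), module = modules),
                     file.path(net_dir, "modules.tsv"))
    mods <- setdiff(unique(modules), "grey")
    eig <- lapply(stats::setNames(mods, mods), function(m)
      module_eigengene(em$levels, names(modules)[modules == m]))
    if (length(eig)) {
      eg <- data.frame(sample = colnames(em$levels),
                       do.call(cbind, lapply(eig, round, 6)),
                       check.names = FALSE)
      write_tsv_strict(eg, file.path(net_dir, "eigengenes.tsv"))
      md_ord <- metadata[match(colnames(em$levels), metadata$sample_id), ]
      mt <- module_trait_correlation(eig, md_ord)
      mt_out <- within(mt, { R <- round(R, 6); p <- signif(p, 6) })
      write_tsv_strict(mt_out, file.path(net_dir, "module_trait.tsv"))
      km <- key_module(mt)
      km_nodes <- names(modules)[modules == km]
      hubs <- hub_events(network, km_nodes, n = n_hubs,
                         edge_threshold = edge_threshold, dre = dre)
      hubs$module <- km
      write_tsv_strict(as.data.frame(hubs), file.path(net_dir, "hubs.tsv"))
      write_tsv_strict(within(module_edges(network, km_nodes,
                                           edge_threshold),
                              weight <- round(weight, 6)),
                       file.path(net_dir, "edges.tsv"))
    }
  }

  ## stage: clinical association & ROC
  clin_dir <- file.path(out_dir, "clinical")
  dir.create(clin_dir, showWarnings = FALSE)
  roc_rows <- list(); cors <- NULL
  if (!is.null(hubs) && nrow(hubs) > 0) {
    md_ord <- metadata[match(colnames(em$levels), metadata$sample_id), ]
    cors <- hub_clinical_correlation(em, hubs$event, md_ord)
    # cis correlation with host-gene expression
    cis <- do.call(rbind, lapply(hubs$event, function(evk) {
      g <- em$events$gene_id[match(evk, rownames(em$levels))]
      if (!g %in% rownames(expr)) return(NULL)
      a <- cis_correlation(em$levels[evk, ],
                           expr[g, colnames(em$levels)])
      cbind(data.frame(event = evk, feature = paste0("expr:", g)), a)
    }))
    cors <- rbind(cors, cis)
    cors$r <- round(cors$r, 6); cors$p <- signif(cors$p, 6)
    write_tsv_strict(cors, file.path(clin_dir, "correlations.tsv"))
    labels <- md_ord$group
    top <- hubs$event[1]
    r1 <- roc_single(em$levels[top, ], labels)
    roc_rows[[1]] <- data.frame(marker = top, auc = round(r1$auc, 6),
                                n = r1$n_case + r1$n_control)
    pts <- cbind(marker = top, r1$points)
    if (nrow(hubs) >= 2) {
      panel <- t(em$levels[hubs$event[seq_len(min(5, nrow(hubs)))], ,
                           drop = FALSE])
      rc <- roc_combined(panel, labels)
      roc_rows[[2]] <- data.frame(marker = "combined_panel",
                                  auc = round(rc$auc, 6),
                                  n = rc$n_case + rc$n_control)
      pts <- rbind(pts, cbind(marker = "combined_panel", rc$points))
    }
    pts$fpr <- round(pts$fpr, 6); pts$tpr <- round(pts$tpr, 6)
    pts$threshold <- round(pts$threshold, 6)
    write_tsv_strict(pts, file.path(clin_dir, "roc_points.tsv"))
    write_tsv_strict(do.call(rbind, roc_rows),
                     file.path(clin_dir, "auc.tsv"))
  }

  ## manifest
  manifest <- run_manifest(out_dir)
  write_tsv_strict(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(dataset = dataset, matrix = em, filter_log = called$filter_log,
                 dre = dre, network = network, modules = modules,
                 module_trait = mt, hubs = hubs, correlations = cors,
                 manifest = manifest))
}

# md5 checksums over all regular files in the run directory (manifest
# excluded), with stable relative paths.
run_manifest <- function(out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.tsv")
  files <- sort(files)
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(out_dir, files))))
}

#' Summary report over a completed pipeline run directory
#'
#' Re-reads the run outputs and tabulates: consequence-category proportions
#' of retained events, per-rule filter attrition, the number of significant
#' differential events, module sizes, the hub table and the AUC table.
#' Re-running the report does not modify the run directory.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List of summary data.frames.
#' @export
pipeline_report <- function(run_dir) {
  ev_path <- file.path(run_dir, "call", "events.tsv")
  if (!file.exists(ev_path))
    stop_edscan("run directory %s has no call stage output", run_dir)
  events <- read_tsv_strict(ev_path)
  cons <- table(events$consequence)
  consequence <- data.frame(consequence = names(cons),
                            n = as.integer(cons),
                            proportion = as.numeric(cons) / sum(cons))
  flog <- read_tsv_strict(file.path(run_dir, "call", "filter_log.tsv"))
  att <- table(flog$reason)
  attrition <- data.frame(reason = names(att), n = as.integer(att))
  out <- list(consequence = consequence, attrition = attrition)
  dre_path <- file.path(run_dir, "dre", "dre.tsv")
  if (file.exists(dre_path)) {
    dre <- read_tsv_strict(dre_path)
    out$dre_summary <- data.frame(
      n_events = nrow(dre), n_testable = sum(dre$testable),
      n_significant = sum(dre$significant))
  }
  mod_path <- file.path(run_dir, "network", "modules.tsv")
  if (file.exists(mod_path)) {
    mod <- read_tsv_strict(mod_path)
    ms <- table(mod$module)
    out$module_sizes <- data.frame(module = names(ms), n = as.integer(ms))
  }
  hub_path <- file.path(run_dir, "network", "hubs.tsv")
  if (file.exists(hub_path)) out$hubs <- read_tsv_strict(hub_path)
  auc_path <- file.path(run_dir, "clinical", "auc.tsv")
  if (file.exists(auc_path)) out$auc <- read_tsv_strict(auc_path)
  out
}
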