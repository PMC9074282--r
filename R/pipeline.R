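#' Default pipeline configuration
#'
#' Desk-scale study conditions for the end-to-end synthetic run: a balanced
#' panel of 20 lines x 2 sexes x 2 treatments x 2 replicates over 500
#' transcripts, 800 biallelic variants, three planted 10-transcript
#' co-regulation modules, 10 planted response eQTLs, and a 6-line activity
#' monitor experiment. All stage parameters mirror the analysis defaults
#' (FDR 0.05, top 10 percent |r| edges, MCODE vwp 0.2 with fluff 0.1 and
#' score > 4, 100 permutations, conditional p <= 1e-5, 1 kb cis window,
#' >= 5 interaction links, 5-minute sleep bouts, survival days 2-9).
#'
#' @param outdir output directory (NULL to skip writing).
#' @param seed global seed; per-stage seeds derive from it via [stage_seed()].
#' @return nested configuration list.
#' @export
default_config <- function(outdir = NULL, seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(
      n_lines = 30, n_transcripts = 500, n_replicates = 2,
      sd_line = 0.5, sd_sexline = 0.25, sd_treatline = 1,
      sd_sextreatline = 0, sd_resid = 0.5,
      sex_effect = 1, treatment_effect = 0.5, frac_lxt = 0.1,
      wolbachia_frac = 0.5, wolbachia_effect = 0.2,
      n_variants = 800, maf_range = c(0.2, 0.5),
      genome = data.frame(chrom = c("2L", "2R"), length = c(2.5e6, 2.5e6)),
      modules = list(n = 3, size = 10, loading = 2),
      eqtls = list(n = 10, beta = 4),
      interactions = list(n_edges = 300, n_hubs = 3, hub_links = 6),
      go = list(n_terms = 25, terms_per_gene = 2),
      dam = list(n_flies = 4, n_days = 4, p_active_day = 0.4,
                 p_active_night = 0.1, mean_bout_minutes = 20,
                 death_frac = 0, n_replicates = 2, n_lines = 6)),
    fit = list(fdr = 0.05),
    network = list(fdr = 0.05, top_frac = 0.10, vwp = 0.2, fluff = TRUE,
                   fluff_density = 0.1, haircut = FALSE, score_min = 4),
    eqtl = list(n_perm = 100, fdr = 0.05, conditional_p_max = 1e-5,
                window = 1000, min_class = 3, n_pcs = 5),
    integrate = list(min_links = 5, go_fdr = 0.05),
    sleep = list(min_bout = 5, window_days = c(2, 9),
                 death_zeros_hours = 24))
}

validate_config <- function(config) {
  for (f in c(config$fit$fdr, config$network$fdr, config$eqtl$fdr,
              config$integrate$go_fdr))
    if (!is.numeric(f) || f <= 0 || f > 1)
      stop("validation error: fdr parameters must lie in (0, 1]")
  if (config$network$top_frac <= 0 || config$network$top_frac > 1)
    stop("validation error: top_frac must lie in (0, 1]")
  if (config$eqtl$n_perm < 1)
    stop("validation error: n_perm must be >= 1")
  if (config$integrate$min_links < 1)
    stop("validation error: min_links must be >= 1")
  invisible(config)
}

## fingerprint covers the analysis parameters, not the output location
config_fingerprint <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "outdir")]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, fit, delta/network, eQTL, integrate and sleep stages
#' in dependency order under a single global seed, returns the full artifact
#' bundle, and (when `outdir` is set) writes every table as TSV with a
#' provenance header. Identical config + seed yields identical output.
#'
#' @param config a configuration list from [default_config()], or the path
#'   of a YAML file holding one.
#' @return (invisibly) list with the per-stage results, ground truth and a
#'   recovery report comparing planted with detected effects.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  sc <- config$simulate
  fp <- config_fingerprint(config)

  ## --- simulate -----------------------------------------------------------
  design <- sim_design(
    n_lines = sc$n_lines, n_transcripts = sc$n_transcripts,
    n_replicates = sc$n_replicates, sd_line = sc$sd_line,
    sd_sexline = sc$sd_sexline, sd_treatline = sc$sd_treatline,
    sd_sextreatline = sc$sd_sextreatline, sd_resid = sc$sd_resid,
    sex_effect = sc$sex_effect, treatment_effect = sc$treatment_effect,
    frac_lxt = sc$frac_lxt, wolbachia_frac = sc$wolbachia_frac,
    wolbachia_effect = sc$wolbachia_effect,
    seed = stage_seed(config$seed, "simulate"))
  sim <- simulate_expression(design)
  study <- sim$study; truth <- sim$truth
  transcripts <- rownames(study$values)

  genome <- as.data.frame(sc$genome)
  geno <- simulate_genotypes(sc$n_lines, sc$n_variants,
                             maf_range = sc$maf_range, genome = genome,
                             seed = stage_seed(config$seed, "genotypes"))
  annotation <- simulate_gene_annotation(
    transcripts, genome = genome,
    seed = stage_seed(config$seed, "annotation"))

  ## planted co-regulation modules on non-LxT transcripts
  set.seed(stage_seed(config$seed, "modules"))
  free <- setdiff(transcripts, truth$lxt_transcripts)
  msize <- sc$modules$size
  module_tx <- split(sample(free, sc$modules$n * msize),
                     rep(seq_len(sc$modules$n), each = msize))
  modules <- lapply(module_tx, function(tx)
    list(transcripts = tx, loading = sc$modules$loading))
  study <- plant_modules(study, modules,
                         seed = stage_seed(config$seed, "modulefactors"))
  truth$planted_modules <- module_tx

  ## planted response eQTLs on LxT transcripts
  set.seed(stage_seed(config$seed, "eqtlplant"))
  etx <- truth$lxt_transcripts[seq_len(min(sc$eqtls$n,
                                           length(truth$lxt_transcripts)))]
  effects <- data.frame(transcript = etx,
                        variant = sample(colnames(geno$geno), length(etx)),
                        beta = sc$eqtls$beta)
  study <- plant_eqtls(study, geno, effects)
  truth$planted_eqtls <- effects

  ## known-interaction database + GO annotation (hubs exercise the filter)
  hubs <- sprintf("HUB%02d", seq_len(sc$interactions$n_hubs))
  cis_candidates <- unique(unlist(lapply(effects$variant, function(v) {
    vr <- geno$variants[geno$variants$variant == v, ]
    annotate_cis_genes(vr$chrom, vr$pos, annotation, config$eqtl$window)
  })))
  anchors <- unique(c(etx, cis_candidates))
  db <- simulate_interactions(c(transcripts, hubs),
                              n_edges = sc$interactions$n_edges,
                              anchors = anchors, hubs = hubs,
                              hub_links = sc$interactions$hub_links,
                              seed = stage_seed(config$seed, "interactions"))
  go <- simulate_go_annotation(c(transcripts, hubs),
                               n_terms = sc$go$n_terms,
                               terms_per_gene = sc$go$terms_per_gene,
                               planted = list(term = "GO:PLANTED",
                                              genes = module_tx[[1]]),
                               seed = stage_seed(config$seed, "go"))

  ## --- fit ----------------------------------------------------------------
  full <- fit_full_model(study, fdr = config$fit$fdr)
  sex_fits <- lapply(c(F = "F", M = "M"), function(sx)
    fit_sex_model(study, sx, fdr = config$fit$fdr))
  lxt_hits <- lapply(sex_fits, function(fit) {
    a <- fit$anova
    sort(a$transcript[a$term == "LxT" & a$q < config$fit$fdr])
  })

  ## --- delta + correlation networks ---------------------------------------
  nets <- list(); dendros <- list(); net_modules <- list(); deltas <- list()
  for (sx in c("F", "M")) {
    if (length(lxt_hits[[sx]]) < 2) next
    delta <- delta_expression(study, lxt_hits[[sx]], sx)
    net <- correlation_network(delta)
    fnet <- filter_edges(net, fdr = config$network$fdr,
                         top_frac = config$network$top_frac)
    deltas[[sx]] <- delta
    nets[[sx]] <- fnet
    dendros[[sx]] <- bicluster(net)
    net_modules[[sx]] <- mcode_modules(
      network_graph(fnet), vwp = config$network$vwp,
      fluff = config$network$fluff,
      fluff_density = config$network$fluff_density,
      haircut = config$network$haircut,
      score_min = config$network$score_min)
  }

  ## --- eQTL mapping --------------------------------------------------------
  n_pcs <- min(config$eqtl$n_pcs, sc$n_lines - 2)
  pcs <- genotype_pca(geno, k = n_pcs)
  lines <- rownames(geno$geno)
  wolb <- as.integer(lines %in% truth$wolbachia_lines)
  covariates <- cbind(wolbachia = wolb, pcs)
  rownames(covariates) <- lines
  eqtls <- list()
  for (sx in names(deltas))
    eqtls[[sx]] <- map_eqtls(
      deltas[[sx]], geno, covariates, annotation,
      n_perm = config$eqtl$n_perm, fdr = config$eqtl$fdr,
      conditional_p_max = config$eqtl$conditional_p_max,
      window = config$eqtl$window, min_class = config$eqtl$min_class,
      seed = stage_seed(config$seed, paste0("eqtl", sx)))

  ## --- integrate -----------------------------------------------------------
  integrated <- list()
  for (sx in names(eqtls)) {
    tab <- eqtls[[sx]]
    tab <- tab[tab$cis_genes != "intergenic", , drop = FALSE]
    if (!nrow(tab)) next
    pairs <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
      data.frame(lxt_gene = tab$transcript[i],
                 cis_gene = strsplit(tab$cis_genes[i], ",")[[1]])))
    net <- filter_network(build_network(pairs, db),
                          min_links = config$integrate$min_links)
    mods <- modularize(net, vwp = config$network$vwp,
                       fluff = config$network$fluff,
                       fluff_density = config$network$fluff_density,
                       haircut = config$network$haircut,
                       score_min = config$network$score_min)
    background <- unique(c(transcripts, hubs))
    enrich <- lapply(mods$modules, function(m)
      go_enrichment(intersect(m$nodes, background), go, background))
    integrated[[sx]] <- list(network = net, modules = mods,
                             enrichment = enrich)
  }

  ## --- sleep ----------------------------------------------------------------
  dam_par <- dam_sim_params(
    n_flies = sc$dam$n_flies, n_days = sc$dam$n_days,
    p_active_day = sc$dam$p_active_day,
    p_active_night = sc$dam$p_active_night,
    mean_bout_minutes = sc$dam$mean_bout_minutes,
    death_frac = sc$dam$death_frac, n_replicates = sc$dam$n_replicates,
    seed = stage_seed(config$seed, "dam"))
  dam <- simulate_dam(dam_par,
                      lines = sprintf("line_%03d", seq_len(sc$dam$n_lines)))
  n_rec_days <- sc$dam$n_days
  window <- c(2, min(config$sleep$window_days[2], n_rec_days + 1))
  dam_f <- survival_filter(dam, window_days = window,
                           death_zeros_hours = config$sleep$death_zeros_hours)
  phen <- day_night_phenotypes(dam_f, min_bout = config$sleep$min_bout)
  phen <- rebalance_phenotypes(phen)
  sleep_tab <- sleep_anova(phen)

  ## --- recovery report ------------------------------------------------------
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  module_recovery <- lapply(names(net_modules), function(sx) {
    found <- lapply(net_modules[[sx]]$modules, `[[`, "nodes")
    vapply(truth$planted_modules, function(tx)
      if (length(found)) max(vapply(found, jaccard, numeric(1), b = tx))
      else 0, numeric(1))
  })
  names(module_recovery) <- names(net_modules)
  sel_pairs <- unlist(lapply(eqtls, function(tab)
    paste(tab$transcript, tab$variant)))
  planted_pairs <- paste(effects$transcript, effects$variant)
  recovery <- list(
    lxt = lapply(names(lxt_hits), function(sx) {
      hits <- lxt_hits[[sx]]
      c(sensitivity = mean(truth$lxt_transcripts %in% hits),
        fdp = if (length(hits))
          mean(!hits %in% c(truth$lxt_transcripts,
                            unlist(truth$planted_modules),
                            effects$transcript)) else 0)
    }),
    module_jaccard = module_recovery,
    eqtl_recovery = mean(planted_pairs %in% sel_pairs))
  names(recovery$lxt) <- names(lxt_hits)

  bundle <- list(config = config, fingerprint = fp, design = design,
                 study = study, truth = truth, geno = geno,
                 annotation = annotation, interactions = db, go = go,
                 full_fit = full, sex_fits = sex_fits, lxt_hits = lxt_hits,
                 deltas = deltas, networks = nets, dendrograms = dendros,
                 network_modules = net_modules, eqtls = eqtls,
                 integrated = integrated, dam = dam_f, phenotypes = phen,
                 sleep_anova = sleep_tab, recovery = recovery)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  invisible(bundle)
}

## write the artifact bundle as provenance-stamped TSVs
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- paste0("gxetrans fingerprint=", bundle$fingerprint,
                 " seed=", bundle$config$seed)
  p <- function(...) file.path(outdir, paste0(...))
  write_expression_study(bundle$study, p("expression_log2.tsv"),
                         p("sample_sheet.tsv"), prov)
  write_genotypes(bundle$geno, p("genotypes.tsv"), p("variants.tsv"))
  write_tsv_prov(bundle$annotation, p("gene_annotation.tsv"), prov)
  write_tsv_prov(bundle$interactions, p("interaction_db.tsv"), prov)
  write_tsv_prov(bundle$go, p("go_annotation.tsv"), prov)
  write_tsv_prov(bundle$full_fit$anova, p("anova_full.tsv"), prov)
  write_tsv_prov(bundle$full_fit$vc, p("variance_components.tsv"), prov)
  for (sx in names(bundle$sex_fits)) {
    write_tsv_prov(bundle$sex_fits[[sx]]$anova,
                   p("anova_sex_", sx, ".tsv"), prov)
    write_tsv_prov(bundle$sex_fits[[sx]]$vc,
                   p("variance_components_", sx, ".tsv"), prov)
  }
  for (sx in names(bundle$deltas)) {
    d <- bundle$deltas[[sx]]
    write_tsv_prov(data.frame(line = rownames(d), d, check.names = FALSE),
                   p("delta_expression_", sx, ".tsv"), prov)
    write_tsv_prov(bundle$networks[[sx]]$edges,
                   p("network_edges_", sx, ".tsv"), prov)
    write_dendrogram_newick(bundle$dendrograms[[sx]],
                            p("dendrogram_", sx, ".nwk"))
    mods <- bundle$network_modules[[sx]]$modules
    if (length(mods)) {
      mt <- do.call(rbind, lapply(seq_along(mods), function(i)
        data.frame(module = i, node = mods[[i]]$nodes,
                   weight = unname(mods[[i]]$weights),
                   score = mods[[i]]$score)))
      write_tsv_prov(mt, p("network_modules_", sx, ".tsv"), prov)
    }
    if (!is.null(bundle$eqtls[[sx]]))
      write_tsv_prov(bundle$eqtls[[sx]], p("eqtls_", sx, ".tsv"), prov)
  }
  write_tsv_prov(bundle$phenotypes, p("sleep_phenotypes.tsv"), prov)
  write_tsv_prov(bundle$sleep_anova, p("sleep_anova.tsv"), prov)
  rec <- c(unlist(bundle$recovery$lxt),
           unlist(bundle$recovery$module_jaccard),
           eqtl_recovery = bundle$recovery$eqtl_recovery)
  write_tsv_prov(data.frame(metric = names(rec), value = unname(rec)),
                 p("recovery_report.tsv"), prov)
  invisible(outdir)
}
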