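# End-to-end orchestration of the synthetic-data landscape-genomics
# pipeline with a single validated config, per-stage seeds derived from a
# master seed, TSV outputs and a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    stages = c("popstats", "ibd", "dstat", "outliers", "gea", "ewas",
               "annotate", "offset"),
    # landscape / genotype generator
    n_pops = 13, n_per_pop = 12, fst_target = 0.193,
    n_neutral = 3000, n_adaptive = 50, cline_strength = 2,
    driver = "BIO16", missing_rate = 0.02,
    # stage parameters
    n_perm = 9999, trio = NULL, block_size = NULL,
    confidence = 0.99, n_null = 200000, n_bins_null = 20,
    q_cutoff = 0.05,
    meth_sites = 1500, meth_assoc = 15, meth_effect = 1.5,
    meth_noise_sd = 0.4,
    ewas_repeats = 50, ewas_subset = 1000, ewas_alpha = 0.05,
    window = 10000,
    ntree = 500, gf_bins = 201)
}

stage_seed <- function(master, k) {
  as.integer((as.numeric(master) * 10007 + k * 101) %% 2147483647)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the requested stages in dependency order (simulate ->
#' popstats -> ibd -> dstat -> outliers -> gea/ewas -> annotate ->
#' offset) on a generated landscape, writes per-stage TSVs under
#' `config$out_dir`, and returns (and writes) a manifest of versions,
#' seeds, parameters and per-stage row counts. Identical configs give
#' identical outputs. Unknown config keys are rejected before any
#' computation.
#'
#' @param config named list overriding the pipeline defaults; `out_dir`
#'   is required. Per-stage seeds are derived from `seed` by a fixed
#'   splitting rule (`seed * 10007 + stage_index * 101` mod 2^31 - 1).
#' @return manifest list, invisibly writes `manifest.json` when
#'   jsonlite is available.
#' @export
run_pipeline <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("climadapt")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  emit <- function(df, name) {
    write_table(df, file.path(cfg$out_dir, name))
    nrow(df)
  }

  spec <- landscape_spec(n_pops = cfg$n_pops, n_per_pop = cfg$n_per_pop,
                         fst_target = cfg$fst_target,
                         n_neutral = cfg$n_neutral,
                         n_adaptive = cfg$n_adaptive,
                         cline_strength = cfg$cline_strength,
                         driver = cfg$driver,
                         missing_rate = cfg$missing_rate,
                         seed = stage_seed(cfg$seed, 1))
  land <- simulate_landscape(spec)
  sim <- simulate_genotypes(spec, land$popmap, land$current)
  G <- sim$genotypes
  note("simulate", seed = spec$seed, n_samples = length(G$samples),
       n_loci = nrow(G$loci))

  fst <- NULL
  if (any(c("popstats", "ibd", "outliers") %in% cfg$stages))
    fst <- wc_fst(G, land$popmap)

  if ("popstats" %in% cfg$stages) {
    div <- diversity_stats(G, land$popmap)
    pc <- pcoa(linearize_fst(fst$theta), k = 2)
    n1 <- emit(div, "diversity.tsv")
    n2 <- emit(data.frame(population = rownames(pc$coords), pc$coords),
               "pcoa.tsv")
    emit(data.frame(population = rep(fst$populations,
                                     length(fst$populations)),
                    population2 = rep(fst$populations,
                                      each = length(fst$populations)),
                    theta = as.vector(fst$theta)), "fst_pairwise.tsv")
    note("popstats", global_fst = fst$global_theta, rows = n1 + n2)
  }

  if ("ibd" %in% cfg$stages) {
    geo <- geographic_distance(land$popmap, log_transform = TRUE)
    gen <- linearize_fst(fst$theta)
    ibd <- mantel(gen, geo, n_perm = cfg$n_perm,
                  seed = stage_seed(cfg$seed, 2))
    env <- environmental_distance(land$current, n_pc = 3)
    ibe <- partial_mantel(gen, env, geo, n_perm = cfg$n_perm,
                          seed = stage_seed(cfg$seed, 2))
    emit(data.frame(test = c("IBD", "IBE_partial"),
                    r = c(ibd$r, ibe$r), p = c(ibd$p, ibe$p),
                    n_perm = cfg$n_perm), "mantel.tsv")
    note("ibd", r_ibd = ibd$r, p_ibd = ibd$p, r_ibe = ibe$r, p_ibe = ibe$p)
  }

  if ("dstat" %in% cfg$stages) {
    trio <- cfg$trio
    if (is.null(trio)) trio <- land$popmap$sites$population[1:3]
    fr <- derived_freqs(G, land$popmap)
    d1 <- abba_baba(fr, trio, cfg$block_size)
    dm <- dmin(fr, trio, cfg$block_size)
    emit(data.frame(statistic = c("D", "Dmin"),
                    trio = paste(trio, collapse = ","),
                    d = c(d1$d, dm$d), se = c(d1$se, dm$se),
                    z = c(d1$z, dm$z)), "dstat.tsv")
    note("dstat", d = d1$d, z = d1$z, dmin = dm$d)
  }

  outlier_ids <- NULL
  if ("outliers" %in% cfg$stages) {
    cal <- calibrate_null(G, land$popmap, seed = stage_seed(cfg$seed, 3))
    sizes <- as.integer(table(land$popmap$assignments[G$samples]))
    cloud <- simulate_null(cal$F, sizes, cfg$n_null,
                           seed = stage_seed(cfg$seed, 4))
    rep_out <- fdist_outliers(fst$per_locus, cloud,
                              confidence = cfg$confidence,
                              n_bins = cfg$n_bins_null)
    emit(rep_out, "outliers.tsv")
    outlier_ids <- rep_out$locus[rep_out$flagged]
    note("outliers", F_calibrated = cal$F, n_flagged = sum(rep_out$flagged))
  }

  gea <- NULL
  if ("gea" %in% cfg$stages) {
    gea <- gea_scan(G, land$current, land$popmap,
                    q_cutoff = cfg$q_cutoff)
    emit(gea$hits, "gea_hits.tsv")
    note("gea", per_variable = as.list(gea$per_variable),
         n_hits = nrow(gea$hits))
  }

  if ("ewas" %in% cfg$stages) {
    me <- simulate_methylation(spec, land$popmap, land$current,
                               n_sites = cfg$meth_sites,
                               n_assoc = cfg$meth_assoc,
                               effect = cfg$meth_effect,
                               noise_sd = cfg$meth_noise_sd)
    smv <- call_smvs(me$methylation)
    K <- kinship(smv$level, "methylation")
    spp <- me$truth$sample_population
    thr <- lapply(land$current$variables, function(v) {
      y <- climate_response(land$current, v, spp[smv$samples])
      permutation_threshold(y, smv$level, K,
                            n_repeats = cfg$ewas_repeats,
                            subset_size = cfg$ewas_subset,
                            alpha = cfg$ewas_alpha,
                            seed = stage_seed(cfg$seed, 5))$threshold
    })
    names(thr) <- land$current$variables
    ew <- ewas_scan(smv, land$current, spp, thresholds = thr, K = K)
    emit(ew$hits, "ewas_hits.tsv")
    note("ewas", thresholds = thr, n_hits = nrow(ew$hits),
         n_smvs = ncol(smv$level))
  }

  if ("annotate" %in% cfg$stages && !is.null(gea) && nrow(gea$hits)) {
    # synthetic exon model: 2-kb exons every 20 kb along each chromosome
    chroms <- unique(G$loci$chrom)
    feats <- do.call(rbind, lapply(chroms, function(ch) {
      starts <- seq(0L, max(G$loci$pos0[G$loci$chrom == ch]), by = 20000L)
      data.frame(chrom = ch, start0 = starts, end0 = starts + 2000L)
    }))
    ft <- feature_table(feats$chrom, feats$start0, feats$end0,
                        sprintf("exon_%05d", seq_len(nrow(feats))))
    hit_loci <- unique(gea$hits$marker)
    li <- match(hit_loci, colnames(G$dosage))
    ann <- annotate_proximal(data.frame(marker = hit_loci,
                                        chrom = G$loci$chrom[li],
                                        pos0 = G$loci$pos0[li]),
                             ft, window = cfg$window)
    emit(ann$annotated, "annotation.tsv")
    note("annotate", n_annotated = nrow(ann$annotated))
  }

  if ("offset" %in% cfg$stages) {
    fr <- population_freqs(G, land$popmap)
    model <- fit_gradient_forest(fr, land$current, ntree = cfg$ntree,
                                 n_bins = cfg$gf_bins,
                                 seed = stage_seed(cfg$seed, 6))
    rep_all <- offset_report(model, land$current, land$futures)
    emit(rep_all$offsets, "offsets.tsv")
    emit(data.frame(predictor = names(model$importance),
                    importance = unname(model$importance)),
         "importance.tsv")
    if (!is.null(outlier_ids) && length(outlier_ids) >= 5) {
      model_out <- fit_gradient_forest(fr[, outlier_ids, drop = FALSE],
                                       land$current, ntree = cfg$ntree,
                                       n_bins = cfg$gf_bins,
                                       seed = stage_seed(cfg$seed, 6))
      rep_out2 <- offset_report(model_out, land$current, land$futures)
      emit(rep_out2$offsets, "offsets_outliers.tsv")
    }
    note("offset", importance = as.list(model$importance),
         monotone_fraction = mean(rep_all$monotone))
  }

  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
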