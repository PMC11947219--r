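# Staged pipeline driver: simulate -> quantify -> phenotype -> spatial ->
# neighbourhoods -> lr -> stats -> report. Each stage writes versioned CSV /
# JSON / TIFF artefacts into `outdir` and appends to a manifest with
# parameter echo and file checksums; a fixed config + seed gives
# byte-identical CSV outputs.

PIPELINE_KEYS <- c("seed", "region_mode", "exclude_mixed",
                   "n_cases", "rois_a", "rois_b", "n_cases_b", "scale",
                   "n_perm", "contact_radius", "r_max", "dr",
                   "k_per_batch", "coarse_resolution", "fine_resolution",
                   "pcf_pairs",
                   "cn_k_range", "cn_repeats", "cn_hop_depth", "cn_max_edge",
                   "cn_pca_dims",
                   "lr_fold", "lr_cells_per_pop", "lr_n_perm", "lr_top_n",
                   "lr_min_frac")

PIPELINE_STAGES <- c("simulate", "quantify", "phenotype", "spatial",
                     "neighbourhoods", "lr", "stats", "report")

#' Default pipeline configuration (small demo scale)
#'
#' @return a named list understood by \code{\link{run_pipeline}}.
#' @export
demo_config <- function() {
  list(seed = 1L, region_mode = "separate", exclude_mixed = TRUE,
       n_cases = 3, rois_a = 2, rois_b = 1, n_cases_b = 3, scale = 0.15,
       n_perm = 199, contact_radius = 10, r_max = 20, dr = 1,
       k_per_batch = 3, coarse_resolution = 1, fine_resolution = 1.5,
       pcf_pairs = list(c("TAM_classical", "CD8_TEMRA"),
                        c("CD8_TEMRA", "Schwann_PDL1"),
                        c("Schwann_S100B", "Schwann_S100B"),
                        c("CD4_TEMRA", "Endothelium")),
       cn_k_range = 2:5, cn_repeats = 3, cn_hop_depth = 2, cn_max_edge = 30,
       cn_pca_dims = 10,
       lr_fold = 8, lr_cells_per_pop = 150, lr_n_perm = 199, lr_top_n = 20,
       lr_min_frac = 0.05)
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; missing keys are filled from
#' \code{\link{demo_config}}.
#'
#' @param config named list or path to a YAML file.
#' @return the completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- demo_config()
  base[names(config)] <- config
  stopifnot(base$region_mode %in% c("separate", "combined"))
  base
}

pipeline_need <- function(state, what, stage_needed) {
  if (is.null(state[[what]]))
    stop(sprintf("missing '%s': run stage '%s' first", what, stage_needed),
         call. = FALSE)
  state[[what]]
}

#' Run the analysis pipeline
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{validate_config}}).
#' @param outdir output directory (created if absent).
#' @param stages stages to run, in order; "all" runs every stage.
#' @param seed overrides \code{config$seed} when given.
#' @return invisibly, the final state list (cells, labels, results, paths).
#' @export
run_pipeline <- function(config = demo_config(), outdir = tempfile("imcniche"),
                         stages = "all", seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list())
  state <- list()
  log_stage <- function(name, files) {
    files <- files[file.exists(files)]
    manifest$stages[[name]] <<- list(
      files = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("[%s] wrote %d artefact(s)", name, length(files)))
  }

  for (stage in stages) state <- switch(
    stage,
    simulate = {
      ds <- simulate_dataset(n_cases = cfg$n_cases, rois_a = cfg$rois_a,
                             rois_b = cfg$rois_b, n_cases_b = cfg$n_cases_b,
                             scale = cfg$scale, seed = cfg$seed)
      write_cell_table(ds$cells, file.path(outdir, "cells.csv"))
      utils::write.csv(ds$cases, file.path(outdir, "cases.csv"), row.names = FALSE)
      log_stage("simulate", file.path(outdir, c("cells.csv", "cases.csv")))
      c(state, list(cells = ds$cells, cases = ds$cases))
    },
    quantify = {
      cells <- pipeline_need(state, "cells", "simulate")
      roi1 <- cells[cells$roi_id == cells$roi_id[1], , drop = FALSE]
      rend <- generate_channel_stack(roi1, 1000, 1000)
      f_stack <- file.path(outdir, "roi1_stack.tif")
      f_mask <- file.path(outdir, "roi1_mask.tif")
      if (!all(dim(rend$mask) > 0) || max(rend$mask) == 0)
        stop("quantify: corrupted or empty mask for roi1", call. = FALSE)
      write_channel_stack(rend, f_stack)
      write_label_mask(rend$mask, f_mask)
      quant <- extract_cells(rend$mask, rend$stack, expansion_px = 1,
                             roi_id = roi1$roi_id[1], case_id = roi1$case_id[1])
      write_cell_table(quant, file.path(outdir, "quantified.csv"))
      qc <- jaccard_qc(rend$mask, generate_mask_pair(rend$mask, 2, cfg$seed),
                       seed = cfg$seed)
      jsonlite::write_json(list(mean_jaccard = qc$mean_jaccard,
                                n_sampled = qc$n_sampled,
                                frac_above = qc$frac_above),
                           file.path(outdir, "jaccard_qc.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage("quantify", c(f_stack, f_mask,
                              file.path(outdir, c("quantified.csv", "jaccard_qc.json"))))
      c(state, list(quantified = quant))
    },
    phenotype = {
      cells <- pipeline_need(state, "cells", "simulate")
      cells <- normalize_percentile(cells)
      g <- build_bbknn_graph(cells, k_per_batch = cfg$k_per_batch)
      coarse <- cluster_cells(g, resolution = cfg$coarse_resolution,
                              seed = cfg$seed)
      rec <- recluster_hierarchical(cells, coarse, vs_group_rules(),
                                    fine_resolution = cfg$fine_resolution,
                                    k_per_batch = cfg$k_per_batch,
                                    seed = cfg$seed)
      cells$cluster_population <- rec$population
      cells$cluster_group <- rec$parent_group
      write_cell_table(cells, file.path(outdir, "cells_labelled.csv"))
      excl <- if (cfg$exclude_mixed) "Mixed" else character()
      ab_roi <- abundance_table(cells, "roi", exclude_regions = excl)
      ab_case <- abundance_table(cells, "case", exclude_regions = excl)
      utils::write.csv(ab_roi, file.path(outdir, "abundance_roi.csv"), row.names = FALSE)
      utils::write.csv(ab_case, file.path(outdir, "abundance_case.csv"), row.names = FALSE)
      log_stage("phenotype", file.path(outdir, c("cells_labelled.csv",
                                                 "abundance_roi.csv",
                                                 "abundance_case.csv")))
      c(state, list(cells = cells, abundance_roi = ab_roi,
                    abundance_case = ab_case))
    },
    spatial = {
      cells <- pipeline_need(state, "cells", "simulate")
      pairs <- cfg$pcf_pairs
      res_pcf <- list(); res_acn <- list()
      for (roi in unique(cells$roi_id)) {
        rc <- cells[cells$roi_id == roi, , drop = FALSE]
        win <- c(1000, 1000)
        for (pr in pairs) {
          ps <- pcf_significance(rc, pr[1], pr[2], n_perm = cfg$n_perm,
                                 seed = cfg$seed, r_max = cfg$r_max,
                                 dr = cfg$dr, window = win)
          res_pcf[[length(res_pcf) + 1]] <- data.frame(
            roi_id = roi, region = rc$region[1], type_a = pr[1], type_b = pr[2],
            gr20 = ps$gr20, p_value = ps$p_value, direction = ps$direction)
        }
        acn_df <- acn_significance(
          rc, pairs = data.frame(type_a = vapply(pairs, `[`, "", 1),
                                 type_b = vapply(pairs, `[`, "", 2)),
          contact_radius = cfg$contact_radius, n_perm = cfg$n_perm,
          seed = cfg$seed)
        acn_df$region <- rc$region[1]
        res_acn[[length(res_acn) + 1]] <- acn_df
      }
      pcf_df <- do.call(rbind, res_pcf)
      acn_df <- do.call(rbind, res_acn)
      utils::write.csv(pcf_df, file.path(outdir, "pcf_results.csv"), row.names = FALSE)
      utils::write.csv(acn_df, file.path(outdir, "acn_results.csv"), row.names = FALSE)
      files <- file.path(outdir, c("pcf_results.csv", "acn_results.csv"))
      for (reg in setdiff(unique(pcf_df$region), if (cfg$exclude_mixed) "Mixed")) {
        hm <- pcf_heatmap(pcf_df[pcf_df$region == reg, , drop = FALSE])
        f_hm <- file.path(outdir, sprintf("pcf_heatmap_%s.csv", reg))
        utils::write.csv(hm$matrix, f_hm)
        net <- acn_network(acn_df[acn_df$region == reg, , drop = FALSE],
                           pcf_df[pcf_df$region == reg, , drop = FALSE],
                           state$abundance_roi)
        f_ed <- file.path(outdir, sprintf("network_%s_edges.csv", reg))
        f_gm <- file.path(outdir, sprintf("network_%s.graphml", reg))
        write_network(net, f_gm, f_ed)
        files <- c(files, f_hm, f_ed, f_gm)
      }
      log_stage("spatial", files)
      c(state, list(pcf = pcf_df, acn = acn_df))
    },
    neighbourhoods = {
      cells <- pipeline_need(state, "cells", "simulate")
      regions <- if (cfg$region_mode == "separate")
        setdiff(unique(cells$region), if (cfg$exclude_mixed) "Mixed")
      else "combined"
      files <- character()
      cells$cn <- NA_character_
      cn_models <- list()
      for (reg in regions) {
        sel <- if (reg == "combined") rep(TRUE, nrow(cells)) else cells$region == reg
        sub <- cells[sel, , drop = FALSE]
        rois <- unique(sub$roi_id)
        graphs <- lapply(rois, function(r)
          build_spatial_graph(sub[sub$roi_id == r, , drop = FALSE],
                              cfg$cn_max_edge))
        feats <- do.call(rbind, lapply(seq_along(rois), function(i)
          aggregate_features(sub[sub$roi_id == rois[i], , drop = FALSE],
                             graphs[[i]], L = cfg$cn_hop_depth)))
        pc <- stats::prcomp(feats, rank. = min(cfg$cn_pca_dims, ncol(feats)))
        sc <- select_k(pc$x, cfg$cn_k_range, R = cfg$cn_repeats,
                       seed = substream_seed(cfg$seed, paste0("cn:", reg)))
        ord <- unlist(lapply(rois, function(r) which(sub$roi_id == r)))
        cn_lab <- character(nrow(sub))
        cn_lab[ord] <- paste0(substr(reg, nchar(reg), nchar(reg)), sc$labels)
        cells$cn[sel] <- cn_lab
        f_st <- file.path(outdir, sprintf("cn_stability_%s.csv", reg))
        utils::write.csv(data.frame(K = sc$k_range, stability = sc$stability),
                         f_st, row.names = FALSE)
        jsonlite::write_json(list(region = reg, best_k = sc$best_k,
                                  repeats = sc$repeats, mode = sc$mode),
                             file.path(outdir, sprintf("cn_stability_%s.json", reg)),
                             auto_unbox = TRUE, digits = NA)
        enr <- cn_enrichment(cn_lab, sub$population)
        f_en <- file.path(outdir, sprintf("cn_enrichment_%s.csv", reg))
        utils::write.csv(as.data.frame.matrix(enr), f_en)
        labs_by_roi <- lapply(rois, function(r) cn_lab[sub$roi_id == r])
        prox <- cn_proximity(labs_by_roi, graphs, n_perm = cfg$n_perm,
                             seed = cfg$seed)
        f_px <- file.path(outdir, sprintf("cn_proximity_%s.csv", reg))
        utils::write.csv(as.data.frame(prox$score), f_px)
        files <- c(files, f_st, file.path(outdir, sprintf("cn_stability_%s.json", reg)),
                   f_en, f_px)
        cn_models[[reg]] <- sc
      }
      write_cell_table(cells, file.path(outdir, "cells_cn.csv"))
      files <- c(files, file.path(outdir, "cells_cn.csv"))
      log_stage("neighbourhoods", files)
      c(state, list(cells = cells, cn_models = cn_models))
    },
    lr = {
      pairs <- vs_lr_pairs(cfg$lr_fold)
      pops <- unique(c(pairs$sender, pairs$receiver, "TAM_alternative",
                       "Monocyte_transitioning"))
      gen <- generate_expression_counts(pops, pairs,
                                        n_cells_per_pop = cfg$lr_cells_per_pop,
                                        seed = cfg$seed)
      expr <- normalize_counts(gen$counts)
      res <- do.call(rbind, lapply(unique(pairs$sender), function(s)
        lr_permutation_test(expr, gen$labels, pairs, s, "CD8_TEMRA",
                            n_perm = cfg$lr_n_perm, seed = cfg$seed)))
      ranked <- filter_and_rank(res, min_frac = cfg$lr_min_frac,
                                top_n = cfg$lr_top_n, lymphocyte = "CD8_TEMRA")
      utils::write.csv(res, file.path(outdir, "lr_scores.csv"), row.names = FALSE)
      utils::write.csv(ranked, file.path(outdir, "lr_significant.csv"), row.names = FALSE)
      log_stage("lr", file.path(outdir, c("lr_scores.csv", "lr_significant.csv")))
      c(state, list(lr = ranked))
    },
    stats = {
      ab_case <- pipeline_need(state, "abundance_roi", "phenotype")
      cells <- state$cells
      cases <- pipeline_need(state, "cases", "simulate")
      ab_roi <- state$abundance_roi
      comp_rows <- list()
      for (pop in c("TAM_classical", "CD8_TEMRA", "Schwann_PDL1")) {
        if (!pop %in% colnames(ab_roi)) next
        byc <- function(reg) {
          d <- ab_roi[ab_roi$region == reg, , drop = FALSE]
          tapply(d[[pop]], d$case_id, mean)
        }
        a <- byc("AntoniA"); b <- byc("AntoniB")
        if (length(a) >= 3 && length(b) >= 3) {
          cr <- compare_two_groups(as.numeric(a), as.numeric(b))
          comp_rows[[length(comp_rows) + 1]] <- data.frame(
            contrast = paste0(pop, ": AntoniA vs AntoniB"), test = cr$test,
            statistic = cr$statistic, p_value = cr$p_value)
        }
      }
      comps <- do.call(rbind, comp_rows) %||%
        data.frame(contrast = character(), test = character(),
                   statistic = numeric(), p_value = numeric())
      utils::write.csv(comps, file.path(outdir, "comparisons.csv"), row.names = FALSE)
      cors <- data.frame()
      if (!is.null(cells$cn) && !all(is.na(cells$cn))) {
        cn_ab <- abundance_table(cells[!is.na(cells$cn), , drop = FALSE],
                                 "case", exclude_regions = character(),
                                 label_col = "cn")
        gr <- cases$growth_rate[match(cn_ab$case_id, cases$case_id)]
        cn_cols <- setdiff(colnames(cn_ab), "case_id")
        cors <- do.call(rbind, lapply(cn_cols, function(cn) {
          ct <- tryCatch(correlate_with_covariate(cn_ab[[cn]], gr),
                         error = function(e) NULL)
          if (is.null(ct)) return(NULL)
          data.frame(cn = cn, method = ct$method, estimate = ct$estimate,
                     p_value = ct$p_value)
        })) %||% data.frame()
      }
      utils::write.csv(cors, file.path(outdir, "cn_growth_correlations.csv"),
                       row.names = FALSE)
      log_stage("stats", file.path(outdir, c("comparisons.csv",
                                             "cn_growth_correlations.csv")))
      c(state, list(comparisons = comps, correlations = cors))
    },
    report = {
      acc <- match_accounting(731237, 659880, 548455)
      jsonlite::write_json(
        list(integration_accounting = acc,
             n_cells = if (!is.null(state$cells)) nrow(state$cells) else NA,
             stages_run = names(manifest$stages)),
        file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
      log_stage("report", file.path(outdir, "report.json"))
      state
    })

  invisible(c(state, list(outdir = outdir, config = cfg)))
}
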