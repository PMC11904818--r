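# Full-pipeline orchestration: one config + one seed determine every output.

config_schema <- function() {
  take <- function(fn, drop = c("seed", "sample_id", "planted_pairs")) {
    f <- formals(fn)
    f <- f[setdiff(names(f), drop)]
    lapply(f, function(v) if (is.call(v) || is.name(v)) eval(v) else v)
  }
  list(
    seed = 1,
    out_dir = "results/pipeline",
    log_level = "info",
    reference = take(reference_spec),
    samples = list(TB = list(condition = "obese"),
                   Duroc = list(condition = "lean")),
    planted_pairs = NULL,
    locations = list(secreted_fraction = 0.1),
    genesets = list(n_sets = 20, set_size = 25),
    qc = take(qc_params),
    de = take(de_params),
    signatures = list(top_k_markers = 50),
    region = take(region_params),
    correlation = take(correlation_params),
    target_genes = NULL
  )
}

# allowed per-sample keys = spatial_spec knobs + condition
sample_allowed_keys <- function()
  c(setdiff(names(formals(spatial_spec)),
            c("seed", "sample_id", "planted_pairs", "fap_celltype")),
    "condition")

merge_section <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stopf("config section '%s' must be a mapping", path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s) under '%s': %s", path,
          paste(unknown, collapse = ", "))
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

#' Validate and fully default a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list. Unknown keys anywhere are an
#' error (no silent typo tolerance); scalar options are type-checked by
#' the parameter constructors when the pipeline runs. The first two
#' option levels are defaulted from the documented parameter defaults
#' (500 detected genes, 0.25 mito fraction, 0.26 log2FC, 0.05 alpha,
#' 25-spot regions, 200 regions/sample, r threshold 0.4).
#'
#' @param x path to a YAML or JSON config, or a config list
#' @return a fully-defaulted list of class `pipeline_config`
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("config file not found: %s", x)
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  if (inherits(x, "pipeline_config")) x <- unclass(x)
  if (!is.list(x)) stopf("config must be a file path or a list")
  schema <- config_schema()
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- schema
  for (k in c("seed", "out_dir", "log_level", "planted_pairs", "target_genes"))
    if (!is.null(x[[k]])) cfg[[k]] <- x[[k]]
  for (k in c("reference", "locations", "genesets", "qc", "de",
              "signatures", "region", "correlation"))
    cfg[[k]] <- merge_section(schema[[k]], x[[k]], k)
  if (!is.null(x$samples)) {
    if (!is.list(x$samples) || is.null(names(x$samples)))
      stopf("samples must be a named mapping")
    cfg$samples <- lapply(seq_along(x$samples), function(i) {
      s <- x$samples[[i]]
      unknown <- setdiff(names(s), sample_allowed_keys())
      if (length(unknown))
        stopf("unknown config key(s) under 'samples.%s': %s",
              names(x$samples)[i], paste(unknown, collapse = ", "))
      if (is.null(s$condition)) s$condition <- names(x$samples)[i]
      s
    })
    names(cfg$samples) <- names(x$samples)
  }
  if (!num1(cfg$seed)) stopf("seed must be a single integer")
  cfg$seed <- as.numeric(cfg$seed)
  if (!is.null(cfg$planted_pairs)) {
    pp <- cfg$planted_pairs
    if (is.list(pp) && !is.data.frame(pp)) {
      # YAML gives either column lists or a list of row mappings
      pp <- if (all(c("gene_a", "gene_b", "rho") %in% names(pp)))
        as.data.frame(pp, stringsAsFactors = FALSE)
      else do.call(rbind, lapply(pp, as.data.frame, stringsAsFactors = FALSE))
    }
    if (!all(c("gene_a", "gene_b", "rho") %in% names(pp)))
      stopf("planted_pairs needs gene_a, gene_b, rho")
    pp$gene_a <- as.character(pp$gene_a); pp$gene_b <- as.character(pp$gene_b)
    pp$rho <- as.numeric(pp$rho)
    rownames(pp) <- NULL
    cfg$planted_pairs <- pp
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a config echo next to the pipeline outputs
#' @param cfg a `pipeline_config`
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_config_echo <- function(cfg, path) {
  x <- unclass(cfg)
  if (is.data.frame(x$planted_pairs)) x$planted_pairs <- as.list(x$planted_pairs)
  yaml::write_yaml(x, path)
  invisible(path)
}

plog <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[muscleniche] ", fmt), ...))
}

# row-bind two spot count matrices over their shared genes
bind_counts <- function(a, b) {
  genes <- intersect(a$gene_ids, b$gene_ids)
  if (!length(genes)) stopf("no shared genes between samples")
  ai <- match(genes, a$gene_ids)
  count_matrix(rbind(a$counts[, genes, drop = FALSE],
                     b$counts[, genes, drop = FALSE]),
               c(a$obs_ids, b$obs_ids), genes, a$gene_names[ai],
               obs_kind = a$obs_kind,
               sample_id = paste(a$sample_id, b$sample_id, sep = "+"))
}

#' Run the full analysis pipeline from one validated config
#'
#' Stages, in dependency order: synthetic data generation (reference,
#' spatial samples, location table, gene sets; all written as standard
#' fixtures and read back through the IO layer), nucleus/spot QC,
#' marker detection, signature building and NNLS deconvolution,
#' FAPs-high/low region delineation, the three-way secretory DEG screen,
#' hypergeometric enrichment, random-region correlation, and the spatial
#' co-aggregation table. Every stage seeds its own RNG stream derived
#' from the global seed, so reruns are byte-identical. A manifest of
#' produced artifacts (with md5 checksums) is written after every stage,
#' so a failed run documents how far it got.
#'
#' @param cfg a `pipeline_config` from [validate_config()] (or anything it
#'   accepts)
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  manifest_path <- file.path(out, "manifest.json")
  note <- function(stage, files, extra = NULL) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- c(list(
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      sub(paste0("^", out, "/?"), "", files))),
      seed = derive_seed(cfg$seed, stage)), extra)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s (outputs so far listed in %s)",
            stage, conditionMessage(e), manifest_path))
  }
  write_config_echo(cfg, file.path(out, "config_echo.yaml"))

  ## stage: synth ------------------------------------------------------
  fixdir <- file.path(out, "fixtures")
  ref <- run_stage("synth", {
    plog(cfg, "synth: simulating reference + %d spatial samples",
         length(cfg$samples))
    spec <- do.call(reference_spec,
                    c(cfg$reference, list(seed = derive_seed(cfg$seed, "reference"))))
    ref <- simulate_reference(spec)
    d <- file.path(fixdir, "reference")
    write_counts_10x(ref$counts, d)
    write_records(data.frame(barcode = names(ref$labels),
                             celltype = unname(ref$labels)),
                  file.path(d, "labels.tsv"))
    ref
  })
  genes <- ref$counts$gene_ids
  vis <- run_stage("synth", {
    vis <- lapply(names(cfg$samples), function(sid) {
      s <- cfg$samples[[sid]]
      spec <- do.call(spatial_spec, c(
        s[setdiff(names(s), "condition")],
        list(planted_pairs = cfg$planted_pairs, sample_id = sid,
             seed = derive_seed(cfg$seed, paste0("visium_", sid)))))
      v <- simulate_visium(spec, ref$truth)
      d <- file.path(fixdir, sid)
      write_counts_10x(v$counts, d)
      write_tissue_positions(v$geometry, file.path(d, "tissue_positions.csv"))
      v
    })
    names(vis) <- names(cfg$samples)
    vis
  })
  run_stage("synth", {
    loc <- do.call(simulate_location_table, c(
      list(genes = genes,
           planted_secreted = unique(cfg$planted_pairs$gene_a),
           seed = derive_seed(cfg$seed, "locations")),
      cfg$locations))
    write_records(loc, file.path(fixdir, "locations.tsv"))
    gs <- do.call(simulate_genesets, c(
      list(genes = genes, seed = derive_seed(cfg$seed, "genesets")),
      cfg$genesets))
    write_gmt(gs, file.path(fixdir, "genesets.gmt"))
    truth <- list(
      true_signatures = ref$truth$true_signatures,
      marker_sets = ref$truth$marker_sets,
      true_proportions = lapply(vis, function(v) v$truth$true_proportions),
      true_rho = cfg$planted_pairs)
    jsonlite::write_json(truth, file.path(fixdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         matrix = "columnmajor", dataframe = "columns")
  })
  note("synth", list.files(fixdir, recursive = TRUE, full.names = TRUE))

  ## stage: qc ---------------------------------------------------------
  qcd <- run_stage("qc", {
    plog(cfg, "qc: reading fixtures back and filtering")
    ref_cm <- read_counts_10x(file.path(fixdir, "reference"),
                              obs_kind = "nucleus", sample_id = "reference")
    lab <- read_records(file.path(fixdir, "reference/labels.tsv"))
    labels <- stats::setNames(lab$celltype, lab$barcode)
    qp <- do.call(qc_params, cfg$qc)
    fq <- filter_matrix(ref_cm, qp)
    spots <- lapply(names(vis), function(sid) {
      cm <- read_counts_10x(file.path(fixdir, sid), obs_kind = "spot",
                            sample_id = sid)
      geom <- read_tissue_positions(
        file.path(fixdir, sid, "tissue_positions.csv"), sample_id = sid)
      tis <- filter_spots_tissue(cm, geom)
      gs <- filter_matrix(tis, qc_params(min_genes_per_nucleus = 0,
                                         min_cells_per_gene = qp$min_cells_per_gene),
                          apply_mito = FALSE)
      list(counts = gs$filtered, geometry = geom, report = gs$report)
    })
    names(spots) <- names(vis)
    jsonlite::write_json(
      c(list(reference = unclass(fq$report)),
        lapply(spots, function(s) unclass(s$report))),
      file.path(out, "qc_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    list(ref = fq$filtered, labels = labels, spots = spots)
  })
  note("qc", file.path(out, "qc_report.json"),
       list(n_kept_nuclei = nrow(qcd$ref$counts)))

  ## stage: markers ----------------------------------------------------
  dp <- do.call(de_params, cfg$de)
  markers <- run_stage("markers", {
    plog(cfg, "markers: one-vs-rest Wilcoxon scan")
    mk <- find_markers(normalize_log_cpm(qcd$ref),
                       qcd$labels[qcd$ref$obs_ids], dp)
    write_records(mk, file.path(out, "markers.tsv"), key = c("cluster", "gene_id"))
    mk
  })
  note("markers", file.path(out, "markers.tsv"),
       list(n_marker_records = nrow(markers)))

  ## stage: deconv -----------------------------------------------------
  dec <- run_stage("deconv", {
    plog(cfg, "deconv: NNLS deconvolution + region delineation")
    sig <- build_signatures(qcd$ref, qcd$labels[qcd$ref$obs_ids],
                            top_k_markers = cfg$signatures$top_k_markers, dp)
    rp <- do.call(region_params,
                  c(cfg$region, list(seed = derive_seed(cfg$seed, "regions"))))
    lapply(names(qcd$spots), function(sid) {
      s <- qcd$spots[[sid]]
      pm <- deconvolve_spots(s$counts, sig)
      regions <- classify_regions(pm, s$geometry, rp)
      pt <- data.frame(barcode = rownames(pm$proportions),
                       pm$proportions, residual = pm$residual,
                       check.names = FALSE)
      write_records(pt, file.path(out, paste0("proportions_", sid, ".tsv")))
      write_records(data.frame(barcode = names(regions), region = unname(regions)),
                    file.path(out, paste0("regions_", sid, ".tsv")))
      list(pm = pm, regions = regions)
    }) -> per_sample
    names(per_sample) <- names(qcd$spots)
    list(sig = sig, per_sample = per_sample)
  })
  note("deconv", file.path(out, c(paste0("proportions_", names(qcd$spots), ".tsv"),
                                  paste0("regions_", names(qcd$spots), ".tsv"))))

  ## stage: de_screen --------------------------------------------------
  screen <- run_stage("de_screen", {
    plog(cfg, "de_screen: region DE + condition DE + secretory screen")
    loc <- read_location_table(file.path(fixdir, "locations.tsv"))
    comps <- list(); de_tables <- list()
    for (sid in names(qcd$spots)) {
      de <- region_de(qcd$spots[[sid]]$counts, dec$per_sample[[sid]]$regions, dp)
      de <- annotate_secretory(de, loc)
      de_tables[[paste0("high_vs_low_", sid)]] <- de
      hit <- de[de$passes_filter & de$secreted, ]
      comps[[paste0("high_vs_low_", sid)]] <-
        list(up = hit$gene_id[hit$direction == "up"],
             down = hit$gene_id[hit$direction == "down"])
    }
    conds <- vapply(cfg$samples, `[[`, "", "condition")
    if (length(unique(conds)) >= 2 && length(qcd$spots) >= 2) {
      cond_of <- function(i) names(qcd$spots)[i]
      a <- qcd$spots[[1]]; b <- qcd$spots[[2]]
      ha <- names(dec$per_sample[[1]]$regions)[dec$per_sample[[1]]$regions == "high"]
      hb <- names(dec$per_sample[[2]]$regions)[dec$per_sample[[2]]$regions == "high"]
      high_cm <- bind_counts(subset_counts(a$counts, obs = ha),
                             subset_counts(b$counts, obs = hb))
      gl <- stats::setNames(c(rep(conds[[1]], length(ha)),
                              rep(conds[[2]], length(hb))), c(ha, hb))
      de <- de_between_groups(high_cm, gl, dp,
                              contrast = unname(conds[1:2]))
      de <- annotate_secretory(de, loc)
      de_tables[["condition_in_high"]] <- de
      hit <- de[de$passes_filter & de$secreted, ]
      comps[["condition_in_high"]] <-
        list(up = hit$gene_id[hit$direction == "up"],
             down = hit$gene_id[hit$direction == "down"])
    }
    for (nm in names(de_tables))
      write_records(de_tables[[nm]], file.path(out, paste0("de_", nm, ".tsv")))
    scr <- if (length(comps) >= 2) screen_comparisons(comps) else NULL
    if (!is.null(scr))
      jsonlite::write_json(
        list(common = scr$common, common_consistent = scr$common_consistent,
             unique = scr$unique, counts = scr$counts),
        file.path(out, "secretory_screen.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    list(comparisons = comps, screen = scr, de_tables = de_tables,
         locations = loc)
  })
  note("de_screen", c(file.path(out, paste0("de_", names(screen$de_tables), ".tsv")),
                      file.path(out, "secretory_screen.json")))

  ## stage: enrichment -------------------------------------------------
  run_stage("enrichment", {
    plog(cfg, "enrichment: hypergeometric gene-set tests")
    gs <- read_gmt(file.path(fixdir, "genesets.gmt"))
    de1 <- screen$de_tables[[1]]
    universe <- de1$gene_id
    query <- de1$gene_id[de1$passes_filter & de1$direction == "up"]
    enr <- hypergeom_enrich(query, universe, gs)
    write_records(enr, file.path(out, "enrichment.tsv"), key = "set")
    enr
  })
  note("enrichment", file.path(out, "enrichment.tsv"))

  ## stage: niche ------------------------------------------------------
  corr <- run_stage("niche", {
    plog(cfg, "niche: random-region correlation")
    rsets <- lapply(names(qcd$spots), function(sid) {
      cp <- do.call(correlation_params, c(
        cfg$correlation,
        list(seed = derive_seed(cfg$seed, paste0("niche_", sid)))))
      sample_regions(qcd$spots[[sid]]$geometry, qcd$spots[[sid]]$counts, cp)
    })
    pooled <- if (length(rsets) > 1) pool_region_sets(rsets) else rsets[[1]]
    write_records(pooled$regions, file.path(out, "regions_sampled.tsv"))
    set_a <- unique(c(unlist(lapply(screen$comparisons, unlist),
                             use.names = FALSE),
                      cfg$planted_pairs$gene_a))
    set_b <- unique(cfg$target_genes %||% cfg$planted_pairs$gene_b)
    if (is.null(set_b)) {
      mk <- markers[markers$cluster == "Myofibers" & markers$direction == "up", ]
      set_b <- utils::head(mk$gene_id[order(mk$p_value)], 5)
    }
    cp <- do.call(correlation_params,
                  c(cfg$correlation, list(seed = derive_seed(cfg$seed, "niche"))))
    conds <- vapply(cfg$samples, `[[`, "", "condition")
    cr <- correlate_gene_sets(pooled, set_a, set_b, cp, sample_groups = conds)
    write_records(as.data.frame(cr), file.path(out, "correlations.tsv"),
                  key = c("gene_a", "gene_b"))
    list(records = cr, pooled = pooled)
  })
  note("niche", file.path(out, c("regions_sampled.tsv", "correlations.tsv")),
       list(n_regions = nrow(corr$pooled$profiles)))

  ## stage: aggregation ------------------------------------------------
  run_stage("aggregation", {
    cr <- corr$records[!corr$records$undefined & corr$records$gene_a !=
                         corr$records$gene_b, ]
    if (nrow(cr)) {
      top <- cr[order(-abs(cr$r)), ][1, ]
      sid <- names(qcd$spots)[1]
      agg <- spatial_aggregation_map(qcd$spots[[sid]]$counts,
                                     qcd$spots[[sid]]$geometry,
                                     c(top$gene_a, top$gene_b))
      write_records(agg, file.path(out, "spatial_aggregation.tsv"))
    }
  })
  note("aggregation", file.path(out, "spatial_aggregation.tsv"))

  plog(cfg, "done: manifest at %s", manifest_path)
  invisible(manifest)
}
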