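#!/usr/bin/env Rscript
# Stage 5: secretory DEG screen.
# Three comparisons, mirroring the study design: FAPs-high vs FAPs-low
# regions within each breed, and obese vs lean within the FAPs-high
# region; DEGs are annotated against the subcellular-location table and
# intersected direction-aware. Upregulated DEGs go into hypergeometric
# gene-set enrichment.

suppressPackageStartupMessages(library(muscleniche))
cfg <- validate_config("analysis/config.yaml")
qcd <- file.path(cfg$out_dir, "qc")
dp <- do.call(de_params, cfg$de)
loc <- read_location_table(file.path(cfg$out_dir, "fixtures", "locations.tsv"))

spots <- list(); regions <- list()
for (sid in names(cfg$samples)) {
  spots[[sid]] <- read_counts_10x(file.path(qcd, sid), obs_kind = "spot",
                                  sample_id = sid)
  rg <- read_records(file.path(cfg$out_dir, paste0("regions_", sid, ".tsv")))
  regions[[sid]] <- stats::setNames(rg$region, rg$barcode)
}

comps <- list()
for (sid in names(spots)) {
  de <- annotate_secretory(region_de(spots[[sid]], regions[[sid]], dp), loc)
  write_records(de, file.path(cfg$out_dir, paste0("de_high_vs_low_", sid, ".tsv")))
  hit <- de[de$passes_filter & de$secreted, ]
  comps[[paste0("high_vs_low_", sid)]] <-
    list(up = hit$gene_id[hit$direction == "up"],
         down = hit$gene_id[hit$direction == "down"])
  message(sprintf("%s high-vs-low: %d DEGs, %d secretory", sid,
                  sum(de$passes_filter), nrow(hit)))
}

conds <- vapply(cfg$samples, `[[`, "", "condition")
hi <- lapply(names(spots), function(sid)
  names(regions[[sid]])[regions[[sid]] == "high"])
high_cm <- subset_counts(spots[[1]], obs = hi[[1]])
high_cm2 <- subset_counts(spots[[2]], obs = hi[[2]])
pooled <- muscleniche:::bind_counts(high_cm, high_cm2)
gl <- stats::setNames(c(rep(conds[[1]], length(hi[[1]])),
                        rep(conds[[2]], length(hi[[2]]))),
                      c(hi[[1]], hi[[2]]))
de <- annotate_secretory(
  de_between_groups(pooled, gl, dp, contrast = unname(conds[1:2])), loc)
write_records(de, file.path(cfg$out_dir, "de_condition_in_high.tsv"))
hit <- de[de$passes_filter & de$secreted, ]
comps$condition_in_high <- list(up = hit$gene_id[hit$direction == "up"],
                                down = hit$gene_id[hit$direction == "down"])
message(sprintf("%s vs %s in FAPs-high: %d DEGs, %d secretory",
                conds[[1]], conds[[2]], sum(de$passes_filter), nrow(hit)))

scr <- screen_comparisons(comps)
print(scr)
jsonlite::write_json(list(common = scr$common,
                          common_consistent = scr$common_consistent,
                          counts = scr$counts),
                     file.path(cfg$out_dir, "secretory_screen.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

gs <- read_gmt(file.path(cfg$out_dir, "fixtures", "genesets.gmt"))
de1 <- read_records(file.path(cfg$out_dir,
                              paste0("de_high_vs_low_", names(spots)[1], ".tsv")))
enr <- hypergeom_enrich(de1$gene_id[de1$passes_filter & de1$direction == "up"],
                        de1$gene_id, gs)
write_records(enr, file.path(cfg$out_dir, "enrichment.tsv"), key = "set")
message(sprintf("enrichment: %d/%d sets significant at Q < 0.05",
                sum(enr$significant), nrow(enr)))
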