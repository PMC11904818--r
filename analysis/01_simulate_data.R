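#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known ground truth.
# Writes standard 10x/Visium-style fixtures so the rest of the analysis is
# indistinguishable from one that starts from real exports.

suppressPackageStartupMessages(library(muscleniche))
cfg <- validate_config("analysis/config.yaml")
fix <- file.path(cfg$out_dir, "fixtures")

ref <- simulate_reference(do.call(reference_spec, c(
  cfg$reference, list(seed = derive_seed(cfg$seed, "reference")))))
write_counts_10x(ref$counts, file.path(fix, "reference"))
write_records(data.frame(barcode = names(ref$labels),
                         celltype = unname(ref$labels)),
              file.path(fix, "reference", "labels.tsv"))
message(sprintf("reference: %d nuclei x %d genes over %d populations",
                nrow(ref$counts$counts), ncol(ref$counts$counts),
                length(ref$truth$celltypes)))

for (sid in names(cfg$samples)) {
  s <- cfg$samples[[sid]]
  v <- simulate_visium(do.call(spatial_spec, c(
    s[setdiff(names(s), "condition")],
    list(planted_pairs = cfg$planted_pairs, sample_id = sid,
         seed = derive_seed(cfg$seed, paste0("visium_", sid))))), ref$truth)
  write_counts_10x(v$counts, file.path(fix, sid))
  write_tissue_positions(v$geometry, file.path(fix, sid, "tissue_positions.csv"))
  # ground truth ships beside the fixture: this is a synthetic study
  utils::write.csv(data.frame(barcode = rownames(v$truth$true_proportions),
                              v$truth$true_proportions, check.names = FALSE),
                   file.path(fix, sid, "true_proportions.csv"),
                   row.names = FALSE, quote = FALSE)
  message(sprintf("%s (%s): %d spots (%d in tissue), median %d genes/spot",
                  sid, s$condition, nrow(v$counts$counts),
                  sum(v$geometry$in_tissue),
                  stats::median(Matrix::rowSums(v$counts$counts > 0))))
}

loc <- simulate_location_table(ref$counts$gene_ids, secreted_fraction = 0.1,
                               planted_secreted = cfg$planted_pairs$gene_a,
                               seed = derive_seed(cfg$seed, "locations"))
write_records(loc, file.path(fix, "locations.tsv"))
gs <- simulate_genesets(ref$counts$gene_ids, n_sets = 20, set_size = 25,
                        seed = derive_seed(cfg$seed, "genesets"))
write_gmt(gs, file.path(fix, "genesets.gmt"))
jsonlite::write_json(list(true_rho = cfg$planted_pairs,
                          marker_sets = ref$truth$marker_sets),
                     file.path(fix, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("secretome table: %d/%d genes secreted; %d gene sets",
                sum(grepl("Secreted", loc$location)), nrow(loc), length(gs)))
message("fixtures written under ", fix)
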