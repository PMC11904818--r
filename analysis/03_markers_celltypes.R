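#!/usr/bin/env Rscript
# Stage 3: marker detection per cell population.
# One-vs-rest Wilcoxon on log-CPM; a marker must be expressed in > 10% of
# its population and carry |log2FC| > 0.26. Checks recovery of the
# generator's planted marker blocks.

suppressPackageStartupMessages(library(muscleniche))
cfg <- validate_config("analysis/config.yaml")
qcd <- file.path(cfg$out_dir, "qc")

ref <- read_counts_10x(file.path(qcd, "reference"), obs_kind = "nucleus",
                       sample_id = "reference")
lab <- read_records(file.path(qcd, "reference", "labels.tsv"))
labels <- stats::setNames(lab$celltype, lab$barcode)

mk <- find_markers(normalize_log_cpm(ref), labels[ref$obs_ids],
                   do.call(de_params, cfg$de))
write_records(mk, file.path(cfg$out_dir, "markers.tsv"),
              key = c("cluster", "gene_id"))

truth <- jsonlite::read_json(file.path(cfg$out_dir, "fixtures", "truth.json"),
                             simplifyVector = TRUE)
sig_mk <- mk[mk$passes_filter & mk$direction == "up", ]
for (ct in sort(unique(sig_mk$cluster))) {
  found <- sig_mk$gene_id[sig_mk$cluster == ct]
  planted <- truth$marker_sets[[ct]]
  message(sprintf("%-12s %3d significant up-markers; %d/%d planted recovered",
                  ct, length(found), length(intersect(found, planted)),
                  length(planted)))
}
message("marker table: ", nrow(mk), " records -> ",
        file.path(cfg$out_dir, "markers.tsv"))
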