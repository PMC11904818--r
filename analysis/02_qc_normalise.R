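#!/usr/bin/env Rscript
# Stage 2: nucleus and spot quality control.
# Nuclei: keep > 500 detected genes and < 25% mitochondrial counts, then
# drop genes detected in no kept nucleus. Spots: keep in-tissue positions.

suppressPackageStartupMessages(library(muscleniche))
cfg <- validate_config("analysis/config.yaml")
fix <- file.path(cfg$out_dir, "fixtures")
qcd <- file.path(cfg$out_dir, "qc")

ref <- read_counts_10x(file.path(fix, "reference"), obs_kind = "nucleus",
                       sample_id = "reference")
fq <- filter_matrix(ref, do.call(qc_params, cfg$qc))
print(fq$report)
write_counts_10x(fq$filtered, file.path(qcd, "reference"))
file.copy(file.path(fix, "reference", "labels.tsv"),
          file.path(qcd, "reference", "labels.tsv"), overwrite = TRUE)

reports <- list(reference = unclass(fq$report))
for (sid in names(cfg$samples)) {
  cm <- read_counts_10x(file.path(fix, sid), obs_kind = "spot", sample_id = sid)
  geom <- read_tissue_positions(file.path(fix, sid, "tissue_positions.csv"),
                                sample_id = sid)
  tis <- filter_spots_tissue(cm, geom)
  gs <- filter_matrix(tis, qc_params(min_genes_per_nucleus = 0),
                      apply_mito = FALSE)
  write_counts_10x(gs$filtered, file.path(qcd, sid))
  file.copy(file.path(fix, sid, "tissue_positions.csv"),
            file.path(qcd, sid, "tissue_positions.csv"), overwrite = TRUE)
  reports[[sid]] <- unclass(gs$report)
  message(sprintf("%s: %d/%d spots in tissue kept, %d genes detected",
                  sid, gs$report$n_kept_obs, nrow(cm$counts),
                  gs$report$n_kept_genes))
}
jsonlite::write_json(reports, file.path(cfg$out_dir, "qc_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("nuclei kept: %.1f%% — filtered matrices under %s",
                100 * fq$report$n_kept_obs / fq$report$n_input_obs, qcd))
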