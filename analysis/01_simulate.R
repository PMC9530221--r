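#!/usr/bin/env Rscript
# Generate the synthetic study: a two-condition cohort (15 subjects,
# placebo vs. amplitude-attenuated "drug" scans), a modular structural
# connectome, spherical parcel coordinates, a spatially autocorrelated
# receptor density map, and binary RSN masks. Everything downstream reads
# these files.

suppressPackageStartupMessages(library(ctrlstates))

seed <- 1
out <- "results/synth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synth_cohort_spec(n_subjects = 15, n_regions = 200, k_states = 4,
                          frames_per_scan = 150, tr_seconds = 2,
                          noise_sd = 1.0, drug_amplitude_factor = 0.7,
                          seed = seed)
cohort <- gen_two_condition_cohort(spec)
write_cohort(cohort, file.path(out, "cohort"))
cat(sprintf("cohort: %d scans of %d frames x %d regions (TR %g s)\n",
            length(cohort$scans), spec$frames_per_scan, spec$n_regions,
            spec$tr_seconds))

conn <- gen_connectome(spec$n_regions, n_modules = 4, density = 0.3,
                       seed = seed + 1)
write_matrix_tsv(conn, file.path(out, "connectome.tsv"), rownames = TRUE)
cat(sprintf("connectome: density %.2f, mean weight %.2f\n",
            mean(conn[upper.tri(conn)] > 0), mean(conn[conn > 0])))

coords <- gen_parcel_coords(spec$n_regions, seed = seed + 2)
write.table(coords, file.path(out, "coords.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

rmap <- gen_receptor_map(coords, autocorr_scale = 0.5, seed = seed + 3)
write.table(data.frame(region_id = names(rmap), value = rmap),
            file.path(out, "receptor_5ht2a_synthetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("receptor map Moran's I: %.3f (spatially smooth)\n",
            morans_i(rmap, coords)))

masks <- gen_rsn_masks(spec$n_regions, n_networks = 7, seed = seed + 4)
write_matrix_tsv(masks, file.path(out, "rsn_masks.tsv"), rownames = TRUE)

# planted truth, kept for validation in later steps
write_matrix_tsv(cohort$centroids, file.path(out, "planted_centroids.tsv"),
                 rownames = TRUE)
cat("wrote", out, "\n")
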