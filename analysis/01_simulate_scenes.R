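#!/usr/bin/env Rscript
# Generates one representative scene of every class the metrics consume and
# writes them as TIFF stacks with SceneTruth JSON sidecars. The later
# analysis scripts regenerate their own scenes in memory; these files exist
# so the imaging inputs can be inspected with any TIFF viewer.

suppressPackageStartupMessages(library(mitoquant))
out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

save_scene <- function(name, scene) {
  write_stack(scene$stack, file.path(out, paste0(name, ".tif")))
  write_scene_truth(scene$truth, file.path(out, paste0(name, "_truth.json")))
  cat(sprintf("  %s: %s\n", name, scene$truth$scene_id))
}

cat("simulating representative scenes...\n")
save_scene("bipolar_f060",
           make_cell_scene("bipolar", list(central_fraction = 0.6,
                                           n_spots_inside = 6L,
                                           n_spots_outside = 4L), seed = 1))
save_scene("monopolar_displaced", make_cell_scene("monopolar", list(), seed = 2))
save_scene("droplets_p5",
           make_droplet_field(list(partition_ratio = 5), seed = 3))
save_scene("filaments_excluded",
           make_filament_field(list(exclusion = TRUE), seed = 4))
save_scene("frap_m09_tau2",
           make_frap_series(list(mobile_fraction = 0.9, half_time_s = 2),
                            seed = 5))
save_scene("fret_r07", make_fret_pair(list(fret_ratio = 0.7), seed = 6))

fx <- make_tomogram_fixture(list(), seed = 7)
jsonlite::write_json(lapply(fx$polylines, function(m)
  as.data.frame(m)), file.path(out, "tomogram_polylines.json"),
  digits = NA)
write_stack(calibrated_stack(list(chromatin = array(fx$mask * 1,
                                                    dim(fx$mask))),
                             calibration(fx$voxel_um[1],
                                         z_step = fx$voxel_um[3])),
            file.path(out, "tomogram_mask.tif"))
write_scene_truth(fx$truth, file.path(out, "tomogram_truth.json"))
cat("  tomogram fixture with", length(fx$polylines), "polylines\n")
cat("done; scenes under", out, "\n")
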