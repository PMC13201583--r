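#!/usr/bin/env Rscript
# Six-setting permuted hexamer-core RMSD comparison.  A 152-residue AAA+
# core template (chain F of the 3-tight analog) is rigid-fit onto every
# chain to build idealized core hexamers; a target is scored against the
# reference in all six cyclic settings by one global 912-point
# superposition.  The binned/sorted survey table mirrors the procedure
# used for the PDB-wide census (the census itself needs bulk downloads and
# is a user batch run).

library(ringmetrics)

dir.create("results", showWarnings = FALSE)
anchors <- builtin_anchor_set("archaeal_chimera")
ring <- ring_map(LETTERS[1:6])
models_dir <- file.path("results", "models")

m2b <- read_structure(file.path(models_dir, "class2b_analog.cif"))
tpl <- core_template(m2b, "F", anchors)
ref <- build_core_hexamer(m2b, ring, tpl)

ids <- c("class1a_analog", "class2a_analog", "class2b_analog")
rows <- list()
for (id in ids) {
  model <- read_structure(file.path(models_dir, paste0(id, ".cif")))
  hex <- build_core_hexamer(model, ring, tpl)
  tab <- setting_rmsd_table(ref, hex)
  print(tab)
  rows[[id]] <- data.frame(target = id,
                           t(round(tab$rmsd_by_setting, 3)),
                           best_setting = tab$best_setting,
                           best_rmsd = round(tab$best_rmsd, 3))
}
out <- do.call(rbind, rows)
names(out)[2:7] <- paste0("setting", 1:6)
write.table(out, "results/setting_rmsd.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

models <- lapply(ids, function(id)
  read_structure(file.path(models_dir, paste0(id, ".cif"))))
survey <- survey_models(models, list(ring), anchors, ref, tpl)
write.table(survey, "results/survey.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nSurvey (binned eclipsed/staggered, sub-binned by best setting,\n",
    "reverse-sorted by best RMSD):\n", sep = "")
print(survey, row.names = FALSE)
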