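# Regenerates the bundled core and R-group library under inst/extdata/.
# Open Babel's 3D builder is stochastic, so these structures were generated
# once and frozen; rerunning this script produces equivalent but not
# byte-identical geometries. Run from the package root.

suppressMessages({library(ChemmineOB)})

gen3d <- function(smiles, name) {
  txt <- convertFormat("SMI", "SDF", source = paste(smiles, name),
                       options = data.frame(names = "gen3d", args = ""))
  # normalise the program line so no timestamp is embedded
  lines <- strsplit(txt, "\n")[[1]]
  lines[2] <- "  growkit          3D"
  lines
}

writeLines(gen3d("c1ccccc1", "benzene"), "inst/extdata/core_benzene.sdf")

lib <- rbind(
  c("H",               "[H][H]"),
  c("methyl",          "C"),
  c("ethyl",           "CC"),
  c("propyl",          "CCC"),
  c("isopropyl",       "C(C)C"),
  c("tert-butyl",      "C(C)(C)C"),
  c("cyclopropyl",     "C1CC1"),
  c("cyclohexyl",      "C1CCCCC1"),
  c("phenyl",          "c1ccccc1"),
  c("benzyl",          "Cc1ccccc1"),
  c("hydroxy",         "O"),
  c("methoxy",         "OC"),
  c("ethoxy",          "OCC"),
  c("propoxy",         "OCCC"),
  c("amino",           "N"),
  c("methylamino",     "NC"),
  c("dimethylamino",   "N(C)C"),
  c("fluoro",          "F"),
  c("chloro",          "Cl"),
  c("bromo",           "Br"),
  c("cyano",           "C#N"),
  c("trifluoromethyl", "C(F)(F)F"),
  c("acetyl",          "C(C)=O"),
  c("carbamoyl",       "C(N)=O"),
  c("methylsulfonyl",  "S(C)(=O)=O"),
  c("pyridin-4-yl",    "c1ccncc1"),
  c("uracil-1-yl",     "N1C=CC(=O)NC1=O"))

idx <- data.frame(label = lib[, 1],
                  filename = paste0(gsub("[^A-Za-z0-9]", "_", lib[, 1]), ".sdf"),
                  attachment_atom = 1L, smiles = lib[, 2])
for (k in seq_len(nrow(idx))) {
  writeLines(gen3d(idx$smiles[k], idx$label[k]),
             file.path("inst/extdata/rgroups", idx$filename[k]))
}
write.table(idx, "inst/extdata/rgroups/index.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote", nrow(idx), "fragments\n")
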