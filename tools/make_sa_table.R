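# Builds the bundled synthetic-accessibility fragment-frequency snapshot
# (inst/extdata/sa_fragments.tsv) from a hand-curated list of common
# drug-like and fragment-like molecules. Run from the package root after
# loading the package (pkgload::load_all()).

suppressMessages(pkgload::load_all(".", quiet = TRUE))

smiles <- c(
  # simple scaffolds and solvents/fragments
  "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "c1ccc(cc1)c1ccccc1",
  "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "C1CCNC1", "C1CN(CCO1)C", "C1COCCN1",
  "CC(C)C", "CCO", "CCN", "CCOC", "CC(C)=O", "CC(N)=O", "CCC(=O)O",
  "c1ccc(O)cc1", "c1ccc(N)cc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1",
  "c1ccc(C)cc1", "c1ccc(OC)cc1", "c1ccc(C#N)cc1", "c1ccc(C(F)(F)F)cc1",
  "c1ccc(cc1)S(=O)(=O)N", "c1ccc(cc1)C(=O)N", "c1ccc(cc1)C(=O)O",
  "c1ccc(cc1)C(=O)OC", "c1ccc(cc1)NC(C)=O", "c1ccc(cc1)CN",
  # heteroaromatics
  "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1", "c1ccc2sccc2c1", "c1cnc2[nH]ccc2c1",
  "c1cc2ccccc2[nH]1", "c1csc(n1)C", "c1coc(n1)C", "c1cnn(c1)C",
  "c1cnc[nH]1", "c1ncncn1", "c1ccnnc1", "c1ccc(nc1)N", "c1ccc(nc1)C",
  "c1cc(ncn1)N", "c1nc2ccccc2[nH]1", "c1nc2ccccc2o1", "c1nc2ccccc2s1",
  "Cn1cnc2ccccc21", "c1ccc2ncccc2c1", "c1cnc2ccccc2n1",
  # common drugs
  "CC(=O)Oc1ccccc1C(=O)O",                       # aspirin
  "CC(=O)Nc1ccc(O)cc1",                          # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                  # ibuprofen
  "COc1ccc2cc(ccc2c1)C(C)C(=O)O",                # naproxen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                  # caffeine
  "NC(=O)c1ccc(N)cc1",
  "Clc1ccccc1C(=O)Nc1ccccc1",
  "CCN(CC)CC(=O)Nc1c(C)cccc1C",                  # lidocaine
  "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",          # hydrochlorothiazide
  "CC(N)Cc1ccccc1",                              # amphetamine
  "OC(=O)c1ccccc1O",                             # salicylic acid
  "NCCc1ccc(O)c(O)c1",                           # dopamine
  "OCC(O)CO", "OCCO", "NCCO", "NCCN", "OC(=O)CCC(=O)O",
  "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",               # salbutamol
  "CN1CCC[C@H]1c1cccnc1",                        # nicotine
  "COc1cc2c(cc1OC)C(=O)C(CC2)Cc1ccn(C)c1",
  "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",               # melatonin
  "Oc1ccc2[nH]cc(CCN)c2c1",                      # serotonin
  "Clc1ccc(cc1)C(c1ccccc1)N1CCN(CCOCCO)CC1",
  "CC(C)NCC(O)COc1ccc(COC)cc1",
  "CCOC(=O)c1ccccc1N", "CN(C)CCOC(c1ccccc1)c1ccccc1",
  "OC(=O)c1cc(O)c(O)c(O)c1", "COc1ccccc1OC",
  "NC1CCCCC1", "OC1CCCCC1", "O=C1CCCCC1", "O=C1CCCN1", "O=C1CCCCN1",
  "O=c1cc[nH]c(=O)[nH]1",                        # uracil
  "Cc1c[nH]c(=O)[nH]c1=O",                       # thymine
  "Nc1nc2[nH]cnc2c(=O)[nH]1",                    # guanine
  "Nc1ccn(c(=O)n1)C",                            # cytosine-like
  "c1ccc(cc1)n1cccn1", "c1ccc(cc1)N1CCNCC1", "c1ccc(cc1)N1CCOCC1",
  "O=S(=O)(N)c1ccc(N)cc1",                       # sulfanilamide
  "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O",  # penicillin G
  "CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1",          # atropine
  "CCC(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C21",
  "COc1ccc(CCN(C)CCCC(C#N)(C(C)C)c2ccc(OC)c(OC)c2)cc1OC",  # verapamil
  "NC(Cc1ccccc1)C(=O)O", "NC(Cc1ccc(O)cc1)C(=O)O", "NC(CO)C(=O)O",
  "NC(CC(C)C)C(=O)O", "NC(CCCNC(N)=N)C(=O)O", "NC(Cc1c[nH]cn1)C(=O)O",
  "CSCCC(N)C(=O)O", "NC(CS)C(=O)O",
  "OCC1OC(O)C(O)C(O)C1O",                        # glucose
  "CC(=O)OCC1OC(OC)C(OC(C)=O)C1OC(C)=O",
  "CN(C)c1ccc(cc1)C(=O)O", "COC(=O)c1ccc(O)cc1",
  "Fc1ccc(cc1)C(=O)CCCN1CCC(O)(CC1)c1ccc(Cl)cc1",  # haloperidol
  "CC(C)(C)c1ccc(O)cc1", "Cc1ccc(C)cc1", "Cc1ccccc1C",
  "CCc1ccccc1", "CCCc1ccccc1", "CCCCc1ccccc1",
  "ClCc1ccccc1", "OCc1ccccc1", "NCc1ccccc1", "O=Cc1ccccc1",
  "CC(=O)c1ccccc1", "CCOC(=O)c1ccccc1", "CNC(=O)c1ccccc1",
  "c1ccc(cc1)C(=O)Nc1ccccc1", "c1ccc(cc1)NC(=O)Nc1ccccc1",
  "c1ccc(cc1)S(=O)(=O)Nc1ccccc1", "c1ccc(cc1)Cc1ccccc1",
  "c1ccc(cc1)Oc1ccccc1", "c1ccc(cc1)Sc1ccccc1", "c1ccc(cc1)CCc1ccccc1",
  "c1ccc(cc1)C(=O)c1ccccc1", "C(c1ccccc1)N1CCNCC1",
  "O=C(N1CCOCC1)c1ccccc1", "O=C(N1CCNCC1)c1ccccc1",
  "CN1CCN(CC1)c1ccccc1", "c1ccc(cc1)C1CCNCC1",
  "CC1COc2ccccc2O1", "c1ccc2OCOc2c1", "c1ccc2OCCOc2c1",
  "CC(C)Oc1ccccc1", "CCOc1ccccc1", "COc1ccc(Cl)cc1", "COc1ccc(N)cc1",
  "CCN(CC)c1ccccc1", "CN(C)c1ccccc1", "CNc1ccccc1", "COc1cccc(OC)c1",
  "OC(=O)c1cccnc1", "NC(=O)c1cccnc1", "OC(=O)c1ccncc1",
  "Cc1nccn1C", "CCn1ccnc1", "Cc1ncc([N+](=O)[O-])n1C",
  "OCCN1CCNCC1", "OCCN1CCOCC1", "CC(O)c1ccccc1", "CC(N)c1ccccc1")

counts <- new.env(parent = emptyenv())
n_ok <- 0
for (smi in smiles) {
  m <- tryCatch(mol_from_smiles(smi, gen3d = FALSE), error = function(e) NULL)
  if (is.null(m)) { message("skipping ", smi); next }
  n_ok <- n_ok + 1
  for (f in sa_fragments(m)[, "r2"]) {
    counts[[f]] <- (if (is.null(counts[[f]])) 0 else counts[[f]]) + 1
  }
}
tab <- data.frame(fragment = ls(counts),
                  count = vapply(ls(counts), function(k) counts[[k]],
                                 numeric(1)))
tab <- tab[order(-tab$count, tab$fragment), ]
con <- file("inst/extdata/sa_fragments.tsv", "w")
writeLines(c("# Circular-fragment (radius 2) frequency snapshot used by sa_score().",
             sprintf("# Built from %d hand-curated common drug-like molecules;", n_ok),
             "# approximate by design. Regenerate with tools/make_sa_table.R.",
             "fragment\tcount"), con)
utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE,
                   col.names = FALSE)
close(con)
cat("wrote", nrow(tab), "fragments from", n_ok, "molecules\n")
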