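# Receptor tests run against the lysozyme structure shipped with bio3d
# (offline) plus synthetic edits of it.

hel_file <- system.file("examples", "1hel.pdb", package = "bio3d")

# lysozyme copy with three water molecules appended
hel_with_waters <- function() {
  f <- tempfile(fileext = ".pdb")
  lines <- readLines(hel_file, warn = FALSE)
  lines <- lines[!grepl("^END", lines)]
  wat <- c(
    "HETATM 9001  O   HOH A 301      30.000  30.000  30.000  1.00  0.00           O",
    "HETATM 9002  O   HOH A 305       2.000   2.000   2.000  1.00  0.00           O",
    "HETATM 9003  O   HOH A 306      31.000  31.000  31.000  1.00  0.00           O")
  writeLines(c(lines, wat, "END"), f)
  f
}

# an extracted residue range, zwitterion-completed with an OXT atom
residue_fragment_pdb <- function(resno_range) {
  p <- bio3d::read.pdb(hel_file, verbose = FALSE)
  a <- p$atom[p$atom$resno %in% resno_range, , drop = FALSE]
  last <- a[a$resno == max(resno_range), ]
  cpos <- unlist(last[last$elety == "C", c("x", "y", "z")])
  capos <- unlist(last[last$elety == "CA", c("x", "y", "z")])
  opos <- unlist(last[last$elety == "O", c("x", "y", "z")])
  dir <- -((capos - cpos) / sqrt(sum((capos - cpos)^2)) +
             (opos - cpos) / sqrt(sum((opos - cpos)^2)))
  oxt <- cpos + 1.25 * dir / sqrt(sum(dir^2))
  f <- tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a) + 1),
    c(ifelse(nchar(a$elety) <= 3, sprintf(" %-3s", a$elety),
             sprintf("%-4s", a$elety)), " OXT"),
    c(a$resid, a$resid[nrow(a)]), "A", c(a$resno, max(resno_range)),
    c(a$x, oxt[1]), c(a$y, oxt[2]), c(a$z, oxt[3]),
    c(a$elesy, "O"))
  writeLines(c(lines, "END"), f)
  f
}

test_that("loading strips waters by default and honours keep selectors", {
  f <- hel_with_waters()
  rec <- load_receptor(f)
  expect_false(any(rec$atoms$resid == "HOH"))
  expect_equal(nrow(rec$atoms), 1001)

  kept <- load_receptor(f, keep_residues = "HOH 305")
  expect_equal(sum(kept$atoms$resid == "HOH"), 1)
  expect_equal(kept$atoms$resno[kept$atoms$resid == "HOH"], 305)
  expect_true("HOH 305" %in% kept$retained_waters)
  expect_true(kept$all_fixed)

  expect_error(load_receptor(f, keep_residues = "XYZ 1"), "unknown residue")
})

test_that("loading rejects empty structures", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(load_receptor(f), "unparseable|no atom")
})

test_that("fixing adds hydrogens and leaves heavy atoms untouched", {
  rec <- load_receptor(hel_file)
  fx <- fix_receptor(rec)
  expect_gt(sum(fx$atoms$elem == "H"), 0)
  expect_gte(nrow(fx$atoms), nrow(rec$atoms))
  # every standard residue picked up at least one hydrogen
  res_h <- tapply(fx$atoms$elem == "H",
                  paste(fx$atoms$chain, fx$atoms$resno), any)
  expect_true(all(res_h))
  # heavy records byte-identical (same names, same coordinates)
  a <- rec$atoms
  b <- fx$atoms[fx$atoms$elem != "H", ]
  key <- function(d) d[order(d$resno, d$name), c("name", "x", "y", "z")]
  expect_equal(key(b[b$name != "OXT", ]), key(a[a$name != "OXT", ]),
               ignore_attr = TRUE)

  # idempotence: fixing a complete receptor changes nothing
  fx2 <- fix_receptor(fx)
  expect_equal(nrow(fx2$atoms), nrow(fx$atoms))
})

test_that("a missing backbone oxygen is reconstructed at sane geometry", {
  rec <- load_receptor(hel_file)
  broken <- rec
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 5 &
                                   broken$atoms$name == "O"), ]
  fx <- fix_receptor(broken)
  o <- fx$atoms[fx$atoms$resno == 5 & fx$atoms$name == "O", ]
  expect_equal(nrow(o), 1)
  cpos <- fx$atoms[fx$atoms$resno == 5 & fx$atoms$name == "C", c("x", "y", "z")]
  d <- sqrt(sum((unlist(o[, c("x", "y", "z")]) - unlist(cpos))^2))
  expect_equal(d, 1.23, tolerance = 0.01)
})

test_that("parameterisation assigns charges summing to an integer total", {
  rec <- parameterise_receptor(fix_receptor(load_receptor(hel_file)))
  expect_true(rec$parameterised)
  expect_false(anyNA(rec$atoms$pcharge))
  expect_false(anyNA(rec$atoms$rmin))
  expect_lt(abs(sum(rec$atoms$pcharge) - round(sum(rec$atoms$pcharge))), 1e-6)
  # lysozyme is a basic protein: clearly positive at pH 7
  expect_gt(sum(rec$atoms$pcharge), 5)
  expect_error(parameterise_receptor(rec, ff_name = "nope"), "unknown")
})

test_that("neutral and acidic residue fragments get the expected net charge", {
  # VAL-PHE-GLY stretch, zwitterion-completed: net 0
  neutral <- parameterise_receptor(fix_receptor(
    load_receptor(residue_fragment_pdb(2:4))))
  expect_equal(round(sum(neutral$atoms$pcharge)), 0)

  # single aspartate: deprotonated side chain at pH 7 -> net -1
  asp_no <- {
    p <- bio3d::read.pdb(hel_file, verbose = FALSE)
    min(p$atom$resno[p$atom$resid == "ASP"])
  }
  asp <- parameterise_receptor(fix_receptor(
    load_receptor(residue_fragment_pdb(asp_no))))
  expect_equal(round(sum(asp$atoms$pcharge)), -1)
})

test_that("receptors round-trip through PDB within format precision", {
  rec <- fx_pocket()$receptor
  f <- tempfile(fileext = ".pdb")
  receptor_write_pdb(rec, f)
  back <- growkit:::load_receptor_raw(f)
  expect_equal(receptor_coords(back), receptor_coords(rec), tolerance = 1e-3)
  expect_equal(back$atoms$elem, rec$atoms$elem)
})
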