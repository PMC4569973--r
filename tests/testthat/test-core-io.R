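# Structure and compound ingestion.

write_mini_pdb <- function(path, resolution = "2.00", with_remark = TRUE) {
  lines <- "HEADER    TEST"
  if (with_remark)
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %s ANGSTROMS.",
                              resolution))
  atom <- function(rec, serial, name, res, ch, no, x, y, z, el)
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, res, ch, no, x, y, z, 1.0, 0.0, el)
  lines <- c(lines,
             atom("ATOM", 1, " CA ", "ALA", "A", 1, 0, 0, 0, "C"),
             atom("ATOM", 2, " CA ", "HIS", "A", 2, 3, 0, 0, "C"),
             atom("ATOM", 3, " CA ", "GLY", "B", 1, 20, 0, 0, "C"),
             atom("HETATM", 4, " C1 ", "XYZ", "A", 90, 1, 1, 1, "C"),
             atom("HETATM", 5, " O1 ", "XYZ", "A", 90, 1, 2, 1, "O"),
             "END")
  writeLines(lines, path)
  path
}

test_that("a two-chain structure with one ligand round-trips", {
  path <- write_mini_pdb(file.path(tempdir(), "mini.pdb"))
  m <- read_structure(path)
  expect_s3_class(m, "bind_structure")
  expect_length(m$chains, 2)
  expect_length(m$ligands, 1)
  expect_equal(m$resolution, 2.0)
  expect_equal(m$chains[["A"]]$sequence, "AH")
  expect_equal(nrow(m$chains[["A"]]$residues), 2)
  lig <- m$ligands[[1]]
  expect_equal(lig$compound_id, "XYZ")
  expect_equal(lig$molecular_weight, 12.011 + 15.999, tolerance = 1e-6)
})

test_that("missing resolution records parse as NA and are filtered out", {
  p <- write_mini_pdb(file.path(tempdir(), "nores.pdb"), with_remark = FALSE)
  m <- read_structure(p)
  expect_true(is.na(m$resolution))
  expect_length(filter_structures(list(m)), 0)
})

test_that("resolution filter is inclusive at the cutoff and idempotent", {
  mk <- function(res) fix_model(list(fix_chain("A", c(0, 0, 0))), list(),
                                resolution = res)
  models <- list(mk(1.5), mk(2.0), mk(2.5), mk(NA_real_))
  kept <- filter_structures(models, 2.0)
  expect_equal(vapply(kept, `[[`, numeric(1), "resolution"), c(1.5, 2.0))
  expect_identical(filter_structures(kept, 2.0), kept)
})

test_that("ligand admission applies weight window, exclusions, covalency", {
  chain <- fix_chain(c("A", "H", "G"), rbind(c(0, 0, 0), c(4, 0, 0),
                                             c(8, 0, 0)))
  far <- c(0, 0, 3)
  ligs <- list(
    fix_ligand(far, "AAA", mw = 29),      # below window
    fix_ligand(far, "BBB", mw = 1001),    # above window
    fix_ligand(far, "HOH", mw = 18),      # solvent code
    fix_ligand(far, "SO4", mw = 96),      # ion code
    fix_ligand(far, "CCC", mw = 30),      # inclusive lower bound
    fix_ligand(far, "DDD", mw = 1000),    # inclusive upper bound
    fix_ligand(far, "EEE", mw = 300))
  model <- fix_model(list(chain), ligs)
  kept <- identify_ligands(model)
  expect_setequal(vapply(kept, `[[`, "", "compound_id"),
                  c("CCC", "DDD", "EEE"))
  # every survivor is from the model and satisfies the predicates
  expect_true(all(vapply(kept, function(l)
    l$molecular_weight >= 30 && l$molecular_weight <= 1000 &&
      !(l$compound_id %in% default_ligand_exclusions) &&
      !l$covalent_flag, logical(1))))
  # covalent flag removes a ligand
  cov <- fix_ligand(far, "FFF", mw = 300)
  cov$covalent_flag <- TRUE
  expect_length(identify_ligands(fix_model(list(chain), list(cov))), 0)
})

test_that("covalency heuristic fires below 1.9 Angstrom on parsed files", {
  path <- file.path(tempdir(), "cov.pdb")
  atom <- function(rec, serial, name, res, ch, no, x, el)
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, res, ch, no, x, 0, 0, 1.0, 0.0, el)
  writeLines(c("REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
               atom("ATOM", 1, " CA ", "ALA", "A", 1, 0, "C"),
               atom("HETATM", 2, " C1 ", "LIG", "A", 90, 1.5, "C"),
               "END"), path)
  m <- read_structure(path)
  expect_true(m$ligands[[1]]$covalent_flag)
})

test_that("SDF libraries parse with computed weights; R-groups dropped", {
  benzene <- make_compound("BNZ", rep("C", 6),
                           data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                      order = c(2, 1, 2, 1, 2, 1)))
  ethanol <- make_compound("EOH", c("C", "C", "O"),
                           data.frame(a1 = c(1, 2), a2 = c(2, 3),
                                      order = 1))
  path <- file.path(tempdir(), "lib.sdf")
  write_sdf(list(benzene, ethanol), path)
  # append an R-group record manually
  con <- file(path, "a")
  writeLines(c("RGRP", "  test", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, 0, "C"),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, 0, "R#"),
               "  1  2  1  0  0  0  0", "M  END", "$$$$"), con)
  close(con)
  expect_message(lib <- read_compound_library(path), "dropped")
  expect_length(lib, 2)
  expect_equal(lib[[1]]$molecular_weight, 78.11, tolerance = 0.01)
  expect_equal(lib[[2]]$molecular_weight, 46.07, tolerance = 0.01)
  # cross-check against an established SDF routine: ChemmineR sums the
  # explicit atom block, so add our implicit-hydrogen mass on top
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  expect_equal(unname(ChemmineR::MW(sdfset[1])) +
                 1.008 * sum(lib[[1]]$implicit_h),
               lib[[1]]$molecular_weight, tolerance = 0.05)
})

test_that("an SDF with no parsable molecule is an error", {
  empty <- file.path(tempdir(), "empty.sdf")
  writeLines("", empty)
  expect_error(read_compound_library(empty))
})

test_that("salts reduce to the largest covalent fragment", {
  frag <- make_compound("SALT", c("C", "C", "C", "O", "NA"),
                        data.frame(a1 = c(1, 2, 3), a2 = c(2, 3, 4),
                                   order = 1))
  expect_length(frag$elements, 4)
  expect_false("NA" %in% frag$elements)
})
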