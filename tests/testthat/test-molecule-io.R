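test_that("a minimal XYZ file parses to a one-carbon molecule", {
  f <- write_lines_tmp(c("1", "lone carbon", "C 0.0 0.0 0.0"), ".xyz")
  m <- read_molecule(f)
  expect_s3_class(m, "hsr_molecule")
  expect_equal(n_atoms(m), 1L)
  expect_equal(m$atoms$atomic_number, 6L)
  expect_equal(m$atoms$formal_charge, 0L)
  expect_true(is.na(m$atoms$mass_number))
  expect_identical(m$source_format, "XYZ")
})

test_that("SDF property lines set formal charge and isotope", {
  f <- sdf_fixture(c("M  CHG  1   1   1"))
  m <- read_molecule(f)
  expect_equal(m$atoms$formal_charge, c(1L, 0L))

  f <- sdf_fixture(c("M  ISO  1   1  13"))
  m <- read_molecule(f)
  expect_equal(m$atoms$mass_number, c(13L, NA))
  # neutron count n = mass - Z = 13 - 6
  expect_equal(neutron_count(m)[1], 7)

  # M CHG supersedes any old-style atom-block charge code
  f <- write_lines_tmp(c("chg", "", "",
    "  2  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  3  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  CHG  1   2  -1", "M  END"), ".sdf")
  m <- read_molecule(f)
  expect_equal(m$atoms$formal_charge, c(0L, -1L))
})

test_that("malformed structure files give named errors", {
  f <- write_lines_tmp(c("v3", "", "",
    "  0  0  0     0  0            999 V3000", "M  END"), ".sdf")
  expect_error(read_molecule(f), "V3000")

  f <- write_lines_tmp(c("0", "empty"), ".xyz")
  expect_error(read_molecule(f), "zero atoms")

  f <- write_lines_tmp(c("1", "bad", "Xx 0 0 0"), ".xyz")
  expect_error(read_molecule(f), "unknown element")

  f <- write_lines_tmp(c("1", "bad", "C 0 zero 0"), ".xyz")
  expect_error(read_molecule(f), "line 3")
})

test_that("PDB ATOM/HETATM records parse with elements and charges", {
  f <- write_lines_tmp(c(
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N1  LIG A   1       1.400   0.000   0.000  1.00  0.00           N1+",
    "HETATM    3 CL1  LIG A   1       0.000   1.300   0.200  1.00  0.00          CL",
    "END"), ".pdb")
  m <- read_molecule(f)
  expect_equal(m$atoms$element, c("C", "N", "Cl"))
  expect_equal(m$atoms$formal_charge, c(0L, 1L, 0L))
  expect_equal(coords(m)[3, ], c(0, 1.3, 0.2), ignore_attr = TRUE)
})

test_that("SDF round trip preserves coordinates, elements, charges, isotopes", {
  mols <- c(list(generate_fixture("chiral_tetrahedron", seed = 3)),
            unlist(generate_fixture("protonation_series",
                                    chain_lengths = c(3, 4)),
                   recursive = FALSE),
            unlist(generate_fixture("isotopologue_series",
                                    chain_lengths = 5),
                   recursive = FALSE))
  for (m in mols) {
    f <- tempfile(fileext = ".sdf")
    write_molecule(m, f)
    back <- read_molecule(f)
    expect_equal(back$atoms$element, m$atoms$element)
    expect_equal(back$atoms$formal_charge, m$atoms$formal_charge)
    expect_equal(back$atoms$mass_number, m$atoms$mass_number)
    expect_equal(coords(back), coords(m), tolerance = 1e-4)
  }
  # XYZ round trip keeps coordinates and elements
  m <- mols[[1]]
  f <- tempfile(fileext = ".xyz")
  write_molecule(m, f)
  back <- read_molecule(f)
  expect_equal(back$atoms$element, m$atoms$element)
  expect_equal(coords(back), coords(m), tolerance = 1e-6)
})

test_that("written SDF fixtures agree with independent parsers", {
  dir <- tempfile("fixtures")
  fx <- c(list(generate_fixture("chiral_tetrahedron", seed = 1),
               generate_fixture("random_cloud", n_atoms = 9, seed = 2),
               generate_fixture("linear_symmetric"),
               generate_fixture("planar", n_atoms = 6, seed = 3)),
          unlist(generate_fixture("protonation_series",
                                  chain_lengths = c(3, 5)),
                 recursive = FALSE),
          unlist(generate_fixture("isotopologue_series",
                                  chain_lengths = c(3, 5)),
                 recursive = FALSE))
  paths <- write_fixture_set(fx, dir, format = "sdf")
  expect_gte(length(paths), 10L)

  # ChemmineR: atom counts, elements, coordinates
  for (i in seq_along(paths)) {
    m <- read_molecule(paths[i])
    sdf <- suppressWarnings(ChemmineR::read.SDFset(paths[i]))
    ab <- ChemmineR::atomblock(sdf[[1]])
    expect_equal(nrow(ab), n_atoms(m))
    expect_equal(sub("_.*", "", rownames(ab)), m$atoms$element)
    expect_equal(unname(ab[, 1:3]), unname(coords(m)), tolerance = 1e-4)
  }

  # RDKit (python): charges and isotopes, which ChemmineR does not expose
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "out = {}",
    "for p in sys.argv[1:]:",
    "    mol = Chem.MolFromMolFile(p, sanitize=False, removeHs=False)",
    "    out[p] = [[a.GetSymbol(), a.GetFormalCharge(), a.GetIsotope()]",
    "              for a in mol.GetAtoms()]",
    "print(json.dumps(out))"), script)
  res <- system2("python", c(script, paths), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""),
                               simplifyVector = FALSE)
  for (p in paths) {
    m <- read_molecule(p)
    ref <- do.call(rbind, lapply(parsed[[p]], function(a)
      data.frame(el = a[[1]], chg = a[[2]], iso = a[[3]])))
    expect_equal(ref$el, m$atoms$element)
    expect_equal(ref$chg, m$atoms$formal_charge)
    iso <- m$atoms$mass_number
    iso[is.na(iso)] <- 0L  # rdkit reports 0 for unlabelled atoms
    expect_equal(ref$iso, iso)
  }
})

test_that("feature tables validate row counts and numeric cells", {
  m <- hsr_molecule(c("C", "N"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  f <- write_lines_tmp(c("partial_charge", "0.5", "-0.5"), ".csv")
  tab <- read_feature_table(f, m)
  expect_named(tab, "partial_charge")
  m2 <- add_features(m, tab)
  expect_equal(m2$features$partial_charge, c(0.5, -0.5))
  # dimension name propagates into downstream metadata
  fp <- electroshape_fingerprint(m2)
  expect_identical(attr(fp, "scheme_name"), "electroshape4d")

  f3 <- write_lines_tmp(c("q", "0.5", "-0.5", "0.1"), ".csv")
  expect_error(read_feature_table(f3, m), "3 rows")
  fbad <- write_lines_tmp(c("q", "0.5", "high"), ".csv")
  expect_error(read_feature_table(fbad, m), "row 2, column 'q'")
})

test_that("multi-record SDF files expose every record", {
  m1 <- generate_fixture("random_cloud", n_atoms = 4, seed = 1)
  m2 <- generate_fixture("random_cloud", n_atoms = 5, seed = 2)
  f <- tempfile(fileext = ".sdf")
  write_molecule(m1, f)
  lines <- readLines(f)
  f2 <- tempfile(fileext = ".sdf")
  write_molecule(m2, f2)
  writeLines(c(lines, readLines(f2)), f)
  mols <- read_sdf(f)
  expect_length(mols, 2L)
  expect_equal(vapply(mols, n_atoms, 1L), c(4L, 5L))
  expect_warning(first <- read_molecule(f), "2 records")
  expect_equal(n_atoms(first), 4L)
})
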