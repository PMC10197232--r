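test_that("per-residue means are the arithmetic mean over a residue's atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "MET", 1, 1.0, 2.0, 3.0, 50.0),
    pdb_atom_line(2, "N",  "ALA", 2, 0.0, 0.0, 0.0, 70.0),
    pdb_atom_line(3, "CA", "ALA", 2, 2.0, 0.0, 0.0, 70.0),
    pdb_atom_line(4, "CB", "ALA", 2, 1.0, 3.0, 0.0, 70.0),
    "TER", "END"
  ), path)
  p <- read_structure(path, gene_id = "G1")
  expect_s3_class(p, "StructureProfile")
  expect_equal(p$residues$position, c(1L, 2L))
  expect_equal(p$residues$aa, c("M", "A"))
  # single-atom residue: mean is the atom itself
  expect_equal(unlist(p$residues[1, c("x", "y", "z", "plddt")]),
               c(x = 1, y = 2, z = 3, plddt = 50))
  # three atoms at (0,0,0), (2,0,0), (1,3,0), B 70 -> mean (1,1,0), 70
  expect_equal(unlist(p$residues[2, c("x", "y", "z", "plddt")]),
               c(x = 1, y = 1, z = 0, plddt = 70))
  expect_equal(p$residues$n_atoms, c(1L, 3L))
})

test_that("pLDDT of a residue with one shared B-factor equals that B-factor", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(vapply(1:4, function(i) {
    pdb_atom_line(i, "CA", "GLY", 1, i * 0.1, 0, 0, 83.17)
  }, ""), path)
  p <- read_structure(path)
  expect_identical(p$residues$plddt, 83.17)
})

test_that("read/write round trip preserves profiles at formatting precision", {
  set.seed(11)
  for (trial in 1:5) {
    n_res <- sample(3:10, 1)
    atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
      n_at <- sample(1:4, 1)
      data.frame(position = i, aa = sample(AA_CODES, 1),
                 atom = c("N", "CA", "C", "O")[seq_len(n_at)],
                 x = round(runif(n_at, -99, 99), 3),
                 y = round(runif(n_at, -99, 99), 3),
                 z = round(runif(n_at, -99, 99), 3),
                 plddt = round(runif(n_at, 0, 100), 2))
    }))
    path <- withr::local_tempfile(fileext = ".pdb")
    write_structure(atoms, path)
    p <- read_structure(path, gene_id = "RT")

    # independent oracle: naive per-atom accumulation from the written text
    lines <- grep("^ATOM", readLines(path), value = TRUE)
    oracle <- aggregate(
      cbind(x = as.numeric(substr(lines, 31, 38)),
            y = as.numeric(substr(lines, 39, 46)),
            z = as.numeric(substr(lines, 47, 54)),
            plddt = as.numeric(substr(lines, 61, 66))),
      by = list(position = as.integer(substr(lines, 23, 26))), FUN = mean)
    expect_equal(p$residues[, c("position", "x", "y", "z", "plddt")],
                 oracle[order(oracle$position), ],
                 ignore_attr = TRUE, tolerance = 1e-12)
    # and against the pre-write atom table directly
    manual <- aggregate(atoms[, c("x", "y", "z", "plddt")],
                        by = list(position = atoms$position), FUN = mean)
    expect_equal(p$residues$x, manual$x, tolerance = 1e-9)
    expect_equal(p$residues$plddt, manual$plddt, tolerance = 1e-9)
    expect_equal(p$residues$aa,
                 atoms$aa[!duplicated(atoms$position)])
  }
})

test_that("a long synthetic chain is parseable by an independent PDB reader", {
  spec <- synthetic_spec(length = 400L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".pdb")
  p <- generate_structure(spec, path = path)
  expect_equal(nrow(p$residues), 400L)
  expect_equal(anyDuplicated(p$residues$position), 0L)

  b3d <- bio3d::read.pdb(path)
  ca <- b3d$atom[b3d$atom$elety == "CA", ]
  expect_equal(nrow(ca), 400L)
  expect_equal(ca$resno, p$residues$position)
  expect_equal(ca$x, p$residues$x, tolerance = 1e-9)
  expect_equal(ca$y, p$residues$y, tolerance = 1e-9)
  expect_equal(ca$z, p$residues$z, tolerance = 1e-9)
  expect_equal(ca$b, p$residues$plddt, tolerance = 1e-9)
  expect_equal(unname(bio3d::aa321(ca$resid)), p$residues$aa)
})

test_that("malformed or unsupported structures are rejected with clear errors", {
  expect_error(read_structure(file.path(tempdir(), "no-such-file.pdb")),
               "not found")

  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER", "TER", "END"), path)
  expect_error(read_structure(path), "no ATOM records")

  writeLines(pdb_atom_line(1, "CA", "XYZ", 1, 0, 0, 0, 50), path)
  expect_error(read_structure(path), "unknown residue name.*XYZ")

  writeLines(c(pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0, 50, chain = "A"),
               pdb_atom_line(2, "CA", "GLY", 1, 3, 0, 0, 50, chain = "B")),
             path)
  expect_error(read_structure(path), "2 chains: A, B")

  ins <- pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0, 50)
  substr(ins, 27, 27) <- "A"  # insertion code
  writeLines(ins, path)
  expect_error(read_structure(path), "insertion codes")

  writeLines(pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0, 250), path)
  expect_error(read_structure(path), "outside \\[0, 100\\]")

  expect_error(write_structure(data.frame(), tempfile()), "non-empty")
})

test_that("HETATM records are ignored", {
  path <- withr::local_tempfile(fileext = ".pdb")
  het <- pdb_atom_line(9, "O", "HOH", 99, 5, 5, 5, 0)
  substr(het, 1, 6) <- "HETATM"
  writeLines(c(pdb_atom_line(1, "CA", "TRP", 7, 1, 2, 3, 60), het), path)
  p <- read_structure(path)
  expect_equal(p$residues$position, 7L)
  expect_equal(p$residues$aa, "W")
})
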