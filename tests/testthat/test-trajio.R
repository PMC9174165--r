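test_that("a minimal single-model PDB is read as one frame", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "END"), f)
  tr <- read_multi_model_pdb(f)
  expect_equal(n_frames(tr), 1L)
  expect_equal(n_atoms(tr), 3L)
  expect_equal(unname(frame_coords(tr)[2, 1]), 1.458)
  expect_equal(tr$topology$atom_name, c("N", "CA", "C"))
})

test_that("write -> read round-trips coordinates to PDB precision", {
  pep <- build_ideal_peptide(5, "H")
  tr <- gen_gaussian_ensemble(frame_coords(pep), 0.04, 4, seed = 11,
                              topology = pep$topology)
  f <- tempfile(fileext = ".pdb")
  write_multi_model_pdb(tr, f)
  tr2 <- read_multi_model_pdb(f)
  expect_equal(n_frames(tr2), 4L)
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-3)
  expect_identical(tr2$topology, tr$topology)
  # independent reader agrees frame by frame
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(as.vector(pdb$xyz[3, ]), as.vector(t(frame_coords(tr2, 3))))
})

test_that("structural and format errors are detected with context", {
  pep <- build_ideal_peptide(5, "H")
  tr <- gen_gaussian_ensemble(frame_coords(pep), 0.04, 5, seed = 3,
                              topology = pep$topology)
  f <- tempfile(fileext = ".pdb")
  write_multi_model_pdb(tr, f)
  lines <- readLines(f)
  atom_lines <- which(substr(lines, 1, 4) == "ATOM")
  # drop one atom from the third model
  drop <- atom_lines[2 * n_atoms(tr) + 1L]
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines[-drop], f2)
  expect_error(read_multi_model_pdb(f2),
               class = "vardyn_structural_mismatch")
  # corrupt a coordinate field in an otherwise valid file
  bad_line <- lines[atom_lines[1]]
  substr(bad_line, 31, 38) <- "  xx.yyy"
  lines[atom_lines[1]] <- bad_line
  f3 <- tempfile(fileext = ".pdb")
  writeLines(lines, f3)
  err <- tryCatch(read_multi_model_pdb(f3), error = identity)
  expect_s3_class(err, "vardyn_format_error")
  expect_match(conditionMessage(err), "line [0-9]+")
})

test_that("writer refuses what the fixed-width format cannot hold", {
  tr <- trajectory(ca_topology(3), matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0),
                                          3, 3, byrow = TRUE))
  bad <- tr
  bad$coords[1, 1, 1] <- 12345.0
  expect_error(write_multi_model_pdb(bad, tempfile()),
               class = "vardyn_value_error")
  bad$coords[1, 1, 1] <- NaN
  expect_error(write_multi_model_pdb(bad, tempfile()),
               class = "vardyn_value_error")
  # zero-frame trajectories cannot even be constructed
  expect_error(trajectory(ca_topology(3),
                          array(0, dim = c(0, 3, 3))),
               class = "vardyn_value_error")
})

test_that("selection grammar resolves names, backbone, ranges and lists", {
  pep <- build_ideal_peptide(10, "H", first_resid = 40L)
  expect_length(select_atoms(pep, "name CA"), 10L)
  expect_length(select_atoms(pep, "backbone"), 40L)
  expect_length(select_atoms(pep, "resid 40-47 and name CA"), 8L)
  expect_length(select_atoms(pep, "resid 40,42,49"), 12L)
  expect_length(select_atoms(pep, "name N or name O"), 20L)
  expect_error(select_atoms(pep, "name XX"),
               class = "vardyn_empty_selection")
  expect_error(select_atoms(pep, "within 5 of resid 40"),
               class = "vardyn_parse_error")
})

test_that("selection is idempotent and independent of frame content", {
  pep <- build_ideal_peptide(6, "H")
  tr <- gen_gaussian_ensemble(frame_coords(pep), 0.5, 3, seed = 8,
                              topology = pep$topology)
  s1 <- select_atoms(pep, "name CA")
  s2 <- select_atoms(tr, "name CA")
  expect_identical(as.integer(s1), as.integer(s2))
  expect_identical(as.integer(select_atoms(tr, "name CA")),
                   as.integer(s2))
})

test_that("time slicing keeps the requested window", {
  tr <- trajectory(ca_topology(2), array(rnorm(2 * 501 * 3),
                                         dim = c(501, 2, 3)),
                   times = seq(0, 500, by = 1))
  sl <- slice_time(tr, 200, 500)
  expect_equal(n_frames(sl), 301L)
  expect_equal(n_frames(sl) / n_frames(tr), 0.6, tolerance = 0.01)
  expect_equal(range(sl$times), c(200, 500))
  all_sl <- slice_time(tr, 0, 500)
  expect_equal(all_sl$coords, tr$coords)
  expect_error(slice_time(tr, 600, 700), class = "vardyn_empty_slice")
  expect_error(slice_time(tr, 10, 10), class = "vardyn_value_error")
})

test_that("concatenation preserves frames and builds one time axis", {
  tr <- trajectory(ca_topology(2), array(rnorm(2 * 100 * 3),
                                         dim = c(100, 2, 3)),
                   times = seq(0.1, 10, by = 0.1))
  pieces <- list(slice_time(tr, 0, 3.05), slice_time(tr, 3.05, 6.55),
                 slice_time(tr, 6.55, 10.05))
  cc <- concat_trajectories(pieces)
  expect_equal(n_frames(cc), 100L)
  expect_true(all(diff(cc$times) > 0))
  expect_identical(cc$coords[100, , ], tr$coords[100, , ])
  prov <- attr(cc, "provenance")
  expect_equal(unique(prov$replica), 1:3)
  # single-trajectory concat is the identity on coordinates
  one <- concat_trajectories(list(tr))
  expect_identical(one$coords, tr$coords)
  # mismatched topologies are rejected
  other <- trajectory(ca_topology(3), array(0, dim = c(2, 3, 3)))
  expect_error(concat_trajectories(list(tr, other)),
               class = "vardyn_structural_mismatch")
})
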