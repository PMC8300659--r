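zn_ions <- function(rules, cd = 2.5) {
  tibble::tibble(element = "ZN", rule = rules, contact_distance = cd)
}

test_that("fixtures realise the requested SG-SG separations exactly", {
  near <- make_structure_fixture(structure_arrangement("nearby"))
  d_near <- cys_sg_distances(near)
  expect_equal(nrow(d_near), 1)
  expect_equal(d_near$distance, 4.0, tolerance = 1e-9)
  expect_equal(sort(c(d_near$chain_a, d_near$chain_b)), c("A", "B"))
  far <- make_structure_fixture(structure_arrangement("distant"))
  expect_equal(cys_sg_distances(far)$distance, 22.0, tolerance = 1e-9)
  # intra-chain pairs excluded by default; single-chain models are empty
  solo <- structure_model(near$atoms[near$atoms$chain_id == "A", ],
                          list(near$coords[[1]][near$atoms$chain_id == "A", ]))
  expect_equal(nrow(cys_sg_distances(solo)), 0)
})

test_that("hand-placed SG atoms give the expected pair distance", {
  atoms <- tibble::tibble(
    serial = 1:2, record = "ATOM", atom_name = "SG", residue_name = "CYS",
    chain_id = c("A", "B"), residue_number = 328L, insert = "",
    element = "S")
  m <- structure_model(atoms, list(rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_equal(cys_sg_distances(m)$distance, 4)
})

test_that("distances are invariant under rigid-body motion", {
  arr <- structure_arrangement("nearby", n_frames = 3, seed = 5,
                               ions = zn_ions(c("pinned", "walk")))
  model <- make_structure_fixture(arr)
  d0 <- cys_sg_distances(model, frame = 2)$distance
  p0 <- ion_contact_persistence(model)$contact_fraction
  set.seed(99)
  for (i in 1:5) {
    moved <- apply_rigid(model, random_rigid_motion())
    expect_equal(cys_sg_distances(moved, frame = 2)$distance, d0,
                 tolerance = 1e-9)
    expect_equal(ion_contact_persistence(moved)$contact_fraction, p0,
                 tolerance = 1e-12)
  }
})

test_that("PDB writing and reading round-trip to coordinate precision", {
  arr <- structure_arrangement("nearby", n_frames = 7, seed = 2,
                               ions = zn_ions(c("pinned", "walk")))
  model <- make_structure_fixture(arr)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(model, path)
  back <- read_pdb(path)
  expect_equal(n_frames(back), 7)
  expect_equal(back$atoms$atom_name, model$atoms$atom_name)
  expect_equal(back$atoms$chain_id, model$atoms$chain_id)
  expect_equal(back$atoms$element, model$atoms$element)
  for (f in c(1, 4, 7)) {
    expect_lt(max(abs(back$coords[[f]] - model$coords[[f]])), 5.1e-4)
  }
  # single-frame files parse as one frame without MODEL records
  single <- make_structure_fixture(structure_arrangement("distant"))
  lines <- write_pdb(single)
  expect_false(any(grepl("^MODEL", lines)))
  expect_equal(n_frames(read_pdb(lines)), 1)
})

test_that("the parser matches an independent PDB reader", {
  skip_if_not_installed("bio3d")
  model <- make_structure_fixture(structure_arrangement(
    "nearby", n_frames = 3, seed = 4, ions = zn_ions("pinned")))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(model, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$atom_name, ref$atom$elety)
  expect_equal(ours$atoms$residue_number, ref$atom$resno)
  expect_equal(toupper(ours$atoms$element), toupper(ref$atom$elesy))
  xyz1 <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(unname(ours$coords[[1]]), unname(xyz1), tolerance = 1e-9)
})

test_that("PDB error contracts: malformed input and dialect limits", {
  expect_error(read_pdb(c("HEADER foo", "END")), "no ATOM")
  good <- write_pdb(make_structure_fixture(
    structure_arrangement("nearby", n_frames = 2)))
  # drop one atom from the second MODEL block
  drop_at <- max(which(grepl("^ATOM", good)))
  expect_error(read_pdb(good[-drop_at]), "frame 2")
  m <- make_structure_fixture(structure_arrangement("nearby"))
  m$atoms$chain_id[1] <- "AB"
  expect_error(write_pdb(m), "single characters")
  m2 <- make_structure_fixture(structure_arrangement("nearby"))
  m2$coords[[1]][1, 1] <- 1e5
  expect_error(write_pdb(m2), "field width")
  expect_error(structure_model(m2$atoms, list()), "non-empty")
})

test_that("element inference falls back to atom-name heuristics", {
  lines <- c(
    "ATOM      1  SG  CYS A 328       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  CYS A 328       1.000   0.000   0.000  1.00  0.00",
    "HETATM    3 ZN    ZN Z 901       2.500   0.000   0.000  1.00  0.00")
  m <- read_pdb(lines)
  expect_equal(m$atoms$element, c("S", "C", "ZN"))
})

test_that("crosslink feasibility reproduces the published geometry rules", {
  # 4 A pair: short-spacer crosslinker and disulfide both feasible
  f4 <- classify_crosslink_feasibility(4)
  expect_true(f4$feasible[f4$name == "DBB"])
  expect_true(all(f4$feasible[f4$chemistry == "oxidant"]))
  expect_true(is.na(f4$feasible[f4$name == "DST"]))
  expect_false(f4$applicable[f4$name == "DST"])
  # 22 A pair: no thiol crosslinker can bridge (max 13.0 + 1.12)
  f22 <- classify_crosslink_feasibility(22)
  expect_false(any(f22$feasible[f22$chemistry == "thiol"]))
  expect_false(any(f22$feasible[f22$chemistry == "oxidant"]))
  # contact: everything thiol-reactive is feasible
  f0 <- classify_crosslink_feasibility(0)
  expect_true(all(f0$feasible[f0$chemistry %in% c("thiol", "oxidant")]))
  # monotone in distance for every reagent
  grid <- seq(0, 20, by = 0.25)
  feas <- vapply(grid, function(d) {
    classify_crosslink_feasibility(d)$feasible[1:3]
  }, logical(3))
  for (r in 1:3) expect_true(all(diff(as.integer(feas[r, ])) <= 0))
  expect_error(
    classify_crosslink_feasibility(4, registry = tibble::tibble(
      name = "X", chemistry = "photo", spacer_arm_a = 5)),
    "unknown chemistry")
})

test_that("ion persistence matches the brute-force oracle", {
  arr <- structure_arrangement("nearby", n_frames = 8, seed = 6,
                               ions = zn_ions(c("pinned", "pinned", "walk",
                                                "walk", "walk")))
  model <- make_structure_fixture(arr)
  res <- ion_contact_persistence(model)
  expect_equal(nrow(res), 5)
  expect_equal(sum(res$persistent), 2)
  ion_rows <- which(model$atoms$record == "HETATM")
  for (i in seq_along(ion_rows)) {
    expect_equal(res$contact_fraction[i],
                 oracle_contact_fraction(model, ion_rows[i], 3.0),
                 tolerance = 1e-12)
  }
  # pinned zinc at the coordination-bond distance is always in contact
  sg_idx <- which(model$atoms$atom_name == "SG" &
                    model$atoms$chain_id == "A")
  for (f in seq_len(n_frames(model))) {
    d <- sqrt(sum((model$coords[[f]][ion_rows[1], ] -
                     model$coords[[f]][sg_idx, ])^2))
    expect_equal(d, 2.5, tolerance = 1e-9)
  }
  expect_equal(res$contact_fraction[1], 1)
  # partner ranking names the cysteine sulfur's residue
  expect_equal(res$partner_residues[[1]]$residue_name[1], "CYS")
  expect_equal(nrow(ion_contact_persistence(model, ion_elements = "MG")), 0)
})

test_that("persistence threshold is strictly greater-than", {
  atoms <- tibble::tibble(
    serial = 1:2, record = c("ATOM", "HETATM"),
    atom_name = c("SG", "ZN"), residue_name = c("CYS", "ZN"),
    chain_id = c("A", "Z"), residue_number = c(328L, 901L), insert = "",
    element = c("S", "ZN"))
  # in contact for exactly 9 of 10 frames
  coords <- lapply(1:10, function(f) {
    rbind(c(0, 0, 0), if (f <= 9) c(2.5, 0, 0) else c(50, 0, 0))
  })
  m <- structure_model(atoms, coords)
  res <- ion_contact_persistence(m, threshold = 0.9)
  expect_equal(res$contact_fraction, 0.9)
  # exactly at the threshold is NOT persistent (strict inequality) ...
  expect_false(res$persistent)
  # ... but any lower threshold qualifies
  expect_true(ion_contact_persistence(m, threshold = 0.85)$persistent)
})
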