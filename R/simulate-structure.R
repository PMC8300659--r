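#' Build a toy two-chain cysteine-pair structure (optionally a trajectory)
#'
#' Constructs a minimal two-chain model for geometry analyses: chains A
#' and B each carry a three-residue ALA-CYS-ALA stub (residues 327-329,
#' mirroring the numbering around vimentin Cys328) with backbone, CB and
#' SG atoms; the chains are placed so that the inter-chain SG-SG
#' separation in frame 1 equals `sg_distance` exactly (4 Angstrom for the
#' `"nearby"` arrangement, 22 for `"distant"`).
#'
#' With `n_frames > 1`, later frames add Gaussian jitter
#' (`frame_jitter_sd`) to every protein atom. Ions are appended as
#' HETATM records: `"pinned"` ions sit at exactly `contact_distance` from
#' the chain-A SG in *every* frame (the 2.5 Angstrom default is the Zn-S
#' coordination bond length), while `"walk"` ions start ~20 Angstrom away
#' from the protein and diffuse with 1 Angstrom steps, staying far from
#' any contact cutoff.
#'
#' @param arr A [structure_arrangement()].
#' @return A [structure_model()]; write it to disk with [write_pdb()].
#' @export
#' @examples
#' fx <- make_structure_fixture(structure_arrangement("distant"))
#' cys_sg_distances(fx)$distance # 22
make_structure_fixture <- function(arr) {
  stopifnot(inherits(arr, "structure_arrangement"))
  # one chain's atoms: idealised-ish local geometry, 1.5 A bond steps;
  # stereochemistry is irrelevant here, distances are what matter
  chain_template <- function() {
    res <- list(
      list(num = 327L, name = "ALA",
           atoms = c("N", "CA", "C", "O", "CB")),
      list(num = 328L, name = "CYS",
           atoms = c("N", "CA", "C", "O", "CB", "SG")),
      list(num = 329L, name = "ALA",
           atoms = c("N", "CA", "C", "O", "CB"))
    )
    rows <- list(); xyz <- list()
    for (i in seq_along(res)) {
      base <- c(0, (i - 2) * 3.8, 0) # residues strung along y
      offs <- list(N = c(-0.8, -0.6, 0), CA = c(0, 0, 0),
                   C = c(0.9, 0.6, 0), O = c(1.9, 0.4, 0.6),
                   CB = c(-0.6, 0.8, 1.2), SG = c(-0.9, 1.2, 2.8))
      for (at in res[[i]]$atoms) {
        rows[[length(rows) + 1]] <- tibble(
          record = "ATOM", atom_name = at,
          residue_name = res[[i]]$name,
          residue_number = res[[i]]$num,
          element = if (at == "SG") "S" else substr(at, 1, 1)
        )
        xyz[[length(xyz) + 1]] <- base + offs[[at]]
      }
    }
    list(atoms = bind_rows(rows), xyz = do.call(rbind, xyz))
  }
  tpl <- chain_template()
  sg_row <- which(tpl$atoms$atom_name == "SG")
  # chain B: mirror through the SG plane, then translate so that the
  # SG-SG vector is sg_distance along x
  xyz_a <- tpl$xyz
  xyz_b <- tpl$xyz
  xyz_b[, 1] <- -xyz_b[, 1]
  shift <- c(arr$sg_distance + xyz_a[sg_row, 1] - xyz_b[sg_row, 1], 0, 0)
  xyz_b <- sweep(xyz_b, 2, shift, `+`)
  atoms <- bind_rows(
    mutate(tpl$atoms, chain_id = "A"),
    mutate(tpl$atoms, chain_id = "B")
  )
  prot_xyz <- rbind(xyz_a, xyz_b)
  n_prot <- nrow(prot_xyz)
  sg_a <- sg_row # index of chain A SG in the combined table

  ions <- arr$ions
  n_ions <- if (is.null(ions)) 0L else nrow(ions)
  if (n_ions > 0) {
    atoms <- bind_rows(atoms, purrr::map_dfr(seq_len(n_ions), function(i) {
      tibble(record = "HETATM", atom_name = toupper(ions$element[i]),
             residue_name = toupper(ions$element[i]),
             residue_number = 900L + i, element = toupper(ions$element[i]),
             chain_id = "Z")
    }))
  }
  atoms <- mutate(atoms, serial = row_number(), insert = "")
  atoms <- select(atoms, "serial", "record", "atom_name", "residue_name",
                  "chain_id", "residue_number", "insert", "element")

  withr::with_seed(arr$seed, {
    # random-walk ion tracks, far (>= ~15 A) from every protein atom
    walk_tracks <- lapply(seq_len(n_ions), function(i) {
      if (is.null(ions) || ions$rule[i] != "walk") return(NULL)
      pos <- matrix(NA_real_, arr$n_frames, 3)
      pos[1, ] <- colMeans(prot_xyz) + c(0, 0, 20 + 2 * i)
      if (arr$n_frames > 1) {
        for (f in 2:arr$n_frames) {
          pos[f, ] <- pos[f - 1, ] + rnorm(3, 0, 1)
        }
      }
      pos
    })
    coords <- lapply(seq_len(arr$n_frames), function(f) {
      p <- prot_xyz
      if (f > 1 && arr$frame_jitter_sd > 0) {
        p <- p + matrix(rnorm(length(p), 0, arr$frame_jitter_sd),
                        nrow = n_prot)
      }
      if (n_ions == 0) return(p)
      ion_xyz <- t(vapply(seq_len(n_ions), function(i) {
        if (ions$rule[i] == "pinned") {
          # exactly contact_distance from the (jittered) chain-A SG
          p[sg_a, ] + c(0, 0, ions$contact_distance[i])
        } else {
          walk_tracks[[i]][f, ]
        }
      }, numeric(3)))
      rbind(p, ion_xyz)
    })
    structure_model(atoms, coords)
  })
}
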