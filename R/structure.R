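#' Structure models
#'
#' A `structure_model` holds one set of atoms plus one or more coordinate
#' frames (a trajectory when read from a multi-MODEL PDB). Atom metadata
#' live in a tibble (`serial`, `record`, `atom_name`, `residue_name`,
#' `chain_id`, `residue_number`, `insert`, `element`); coordinates are a
#' list of `n_atoms x 3` matrices in Angstrom, one per frame, all frames
#' sharing the same atom ordering.
#'
#' @param atoms Atom metadata tibble.
#' @param coords List of `n_atoms x 3` numeric matrices.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, coords) {
  atoms <- as_tibble(atoms)
  check_columns(atoms, c("serial", "record", "atom_name", "residue_name",
                         "chain_id", "residue_number", "element"), "atoms")
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!is.list(coords) || length(coords) < 1) {
    abort("`coords` must be a non-empty list of coordinate matrices.")
  }
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3 || nrow(m) != nrow(atoms)) {
      abort("each frame must be an n_atoms x 3 matrix.")
    }
    if (!all(is.finite(m))) abort("coordinates must be finite.")
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  structure(list(atoms = atoms, coords = coords), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d frame(s), chains %s\n",
              nrow(x$atoms), length(x$coords),
              paste(unique(x$atoms$chain_id), collapse = "/")))
  invisible(x)
}

#' Number of frames in a structure model
#' @param model A `structure_model`.
#' @return Integer frame count.
#' @export
n_frames <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  length(model$coords)
}

#' @method as_tibble structure_model
#' @export
as_tibble.structure_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$coords), function(i) {
    dplyr::bind_cols(tibble(frame = i), x$atoms,
                     as_tibble(x$coords[[i]]))
  })
}

# element from a PDB atom name when columns 77-78 are blank: strip digits
# and primes; HETATM names matching a common metal/halogen keep both
# letters (ZN, MG, ...), while ATOM names take the first letter only
# (protein "CA" is an alpha carbon, not calcium)
element_from_name <- function(name, is_het = FALSE) {
  metals <- c("ZN", "MG", "FE", "CA", "NA", "CL", "MN", "CU", "BR", "SE")
  vapply(seq_along(name), function(i) {
    clean <- gsub("[0-9']", "", trimws(name[i]))
    two <- toupper(substr(clean, 1, 2))
    het <- if (length(is_het) == 1) is_het else is_het[i]
    if (het && two %in% metals) return(two)
    toupper(substr(clean, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a (possibly multi-MODEL) PDB file
#'
#' Fixed-column parser for the PDB dialect used by the package: ATOM and
#' HETATM records, with MODEL/ENDMDL blocks interpreted as trajectory
#' frames. Elements are taken from columns 77-78, falling back to an
#' atom-name heuristic when blank; insertion codes are preserved. All
#' frames must contain the same atoms in the same order.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @return A [structure_model()].
#' @export
#' @examples
#' fx <- make_structure_fixture(structure_arrangement("nearby"))
#' path <- tempfile(fileext = ".pdb")
#' write_pdb(fx, path)
#' read_pdb(path)
read_pdb <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  is_end <- rec == "ENDMDL"
  if (!any(is_atom)) abort("no ATOM/HETATM records found.")
  # frame index per line: 1 when no MODEL records are present
  frame_id <- cumsum(is_model)
  if (max(frame_id) == 0) frame_id <- frame_id + 1L
  frame_of_atom <- frame_id[is_atom]
  al <- lines[is_atom]
  parse_frame <- function(fl) {
    el <- trimws(substr(fl, 77, 78))
    blank <- el == ""
    if (any(blank)) {
      el[blank] <- element_from_name(substr(fl[blank], 13, 16),
                                     is_het = substr(fl[blank], 1, 6) ==
                                       "HETATM")
    }
    list(
      atoms = tibble(
        serial = as.integer(substr(fl, 7, 11)),
        record = trimws(substr(fl, 1, 6)),
        atom_name = trimws(substr(fl, 13, 16)),
        residue_name = trimws(substr(fl, 18, 20)),
        chain_id = substr(fl, 22, 22),
        residue_number = as.integer(substr(fl, 23, 26)),
        insert = trimws(substr(fl, 27, 27)),
        element = toupper(el)
      ),
      xyz = cbind(x = as.numeric(substr(fl, 31, 38)),
                  y = as.numeric(substr(fl, 39, 46)),
                  z = as.numeric(substr(fl, 47, 54)))
    )
  }
  frames <- lapply(split(al, frame_of_atom), parse_frame)
  n0 <- nrow(frames[[1]]$atoms)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$atoms) != n0) {
      abort(sprintf(
        "frame %d has %d atoms, expected %d (inconsistent MODEL blocks).",
        i, nrow(frames[[i]]$atoms), n0))
    }
  }
  structure_model(frames[[1]]$atoms, lapply(frames, `[[`, "xyz"))
}

#' Write a structure model as PDB
#'
#' Fixed-column PDB writer; multi-frame models are written as
#' MODEL/ENDMDL blocks. Coordinates round-trip through [read_pdb()] at
#' PDB precision (3 decimals). Chain identifiers must be single
#' characters and coordinates must fit the 8-column field.
#'
#' @param model A [structure_model()].
#' @param path Output path; if `NULL` the PDB lines are returned instead.
#' @return `path` invisibly, or the character vector of lines when
#'   `path = NULL`.
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0) abort("cannot write an empty frame.")
  if (any(nchar(a$chain_id) != 1)) {
    abort("chain identifiers must be single characters in the PDB dialect.")
  }
  rng <- range(unlist(lapply(model$coords, range)))
  if (rng[1] <= -1000 || rng[2] >= 10000) {
    abort("coordinates exceed the fixed PDB field width (%8.3f).")
  }
  fmt_frame <- function(xyz) {
    name4 <- ifelse(nchar(a$atom_name) >= 4, substr(a$atom_name, 1, 4),
                    paste0(" ", formatC(a$atom_name, width = -3)))
    sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, a$serial, name4, "", a$residue_name, a$chain_id,
            a$residue_number, ifelse(a$insert == "", " ", a$insert),
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
            formatC(a$element, width = 2))
  }
  nf <- length(model$coords)
  lines <- if (nf == 1) {
    c(fmt_frame(model$coords[[1]]), "END")
  } else {
    c(unlist(lapply(seq_len(nf), function(i) {
      c(sprintf("MODEL %8d", i), fmt_frame(model$coords[[i]]), "ENDMDL")
    })), "END")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Inter-cysteine SG-SG distances
#'
#' Euclidean distances between the sulfur (SG) atoms of cysteine residues
#' in one frame, each unordered pair reported once (ordered by chain and
#' residue number). With `inter_chain_only = TRUE` (the default) only
#' pairs on different chains are reported, the geometry relevant to
#' crosslinking between subunits.
#'
#' @param model A [structure_model()].
#' @param frame Frame index (default 1).
#' @param inter_chain_only Restrict to inter-chain pairs.
#' @return A tibble with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `distance` (Angstrom); zero rows when fewer than two CYS SG atoms
#'   are present.
#' @export
#' @examples
#' fx <- make_structure_fixture(structure_arrangement("nearby"))
#' cys_sg_distances(fx)
cys_sg_distances <- function(model, frame = 1, inter_chain_only = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  if (frame < 1 || frame > n_frames(model)) {
    abort(sprintf("frame %d does not exist (model has %d frame(s)).",
                  frame, n_frames(model)))
  }
  sel <- which(model$atoms$record == "ATOM" &
                 model$atoms$residue_name == "CYS" &
                 model$atoms$atom_name == "SG")
  if (length(sel) < 2) {
    return(tibble(chain_a = character(0), res_a = integer(0),
                  chain_b = character(0), res_b = integer(0),
                  distance = numeric(0)))
  }
  a <- model$atoms[sel, ]
  xyz <- model$coords[[frame]][sel, , drop = FALSE]
  ord <- order(a$chain_id, a$residue_number)
  a <- a[ord, ]; xyz <- xyz[ord, , drop = FALSE]
  idx <- utils::combn(length(sel), 2)
  out <- tibble(
    chain_a = a$chain_id[idx[1, ]], res_a = a$residue_number[idx[1, ]],
    chain_b = a$chain_id[idx[2, ]], res_b = a$residue_number[idx[2, ]],
    distance = sqrt(rowSums((xyz[idx[1, ], , drop = FALSE] -
                               xyz[idx[2, ], , drop = FALSE])^2))
  )
  if (inter_chain_only) out <- filter(out, .data$chain_a != .data$chain_b)
  out
}

#' Crosslink feasibility of a cysteine pair
#'
#' Classifies which reagents of the registry could bridge two cysteine
#' sulfurs separated by `distance`. A thiol crosslinker is feasible when
#' `distance <= spacer_arm + slack`; the default slack of 1.12 Angstrom is
#' chosen so that the short crosslinker DBB (spacer 4.88) reproduces the
#' 6 Angstrom feasibility cutoff used for oxidative or chemical
#' crosslinking of the nearby-CYS arrangement. Oxidants (disulfide
#' formation) are feasible when `distance < disulfide_cutoff` (6 by
#' default). Amine-reactive crosslinkers are reported as not applicable
#' to a cysteine pair.
#'
#' Feasibility is monotone: a reagent feasible at some distance is
#' feasible at any shorter distance.
#'
#' @param distance SG-SG separation (Angstrom, >= 0).
#' @param registry A crosslinker registry tibble.
#' @param slack Geometric slack added to spacer arms (Angstrom, >= 0).
#' @param disulfide_cutoff Distance below which disulfide formation is
#'   considered possible (Angstrom).
#' @return A tibble with one row per registry entry: `name`, `chemistry`,
#'   `spacer_arm_a`, `threshold_a` (`NA` where not applicable),
#'   `applicable`, `feasible`.
#' @export
#' @examples
#' classify_crosslink_feasibility(4)
classify_crosslink_feasibility <- function(distance,
                                           registry = crosslinker_registry(),
                                           slack = 1.12,
                                           disulfide_cutoff = 6) {
  check_scalar(distance, "distance", positive = FALSE)
  if (distance < 0) abort("`distance` must be non-negative.")
  if (slack < 0) abort("`slack` must be non-negative.")
  check_columns(registry, c("name", "chemistry", "spacer_arm_a"), "registry")
  if (anyDuplicated(registry$name)) abort("registry names must be unique.")
  unknown <- setdiff(unique(registry$chemistry),
                     c("thiol", "amine", "oxidant"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown chemistry label(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  registry %>%
    mutate(
      threshold_a = dplyr::case_when(
        .data$chemistry == "thiol" ~ .data$spacer_arm_a + slack,
        .data$chemistry == "oxidant" ~ disulfide_cutoff,
        TRUE ~ NA_real_
      ),
      applicable = .data$chemistry != "amine",
      feasible = dplyr::case_when(
        .data$chemistry == "thiol" ~ distance <= .data$threshold_a,
        .data$chemistry == "oxidant" ~ distance < disulfide_cutoff,
        TRUE ~ NA
      )
    ) %>%
    select("name", "chemistry", "spacer_arm_a", "threshold_a",
           "applicable", "feasible")
}

#' Metal-ion contact persistence across trajectory frames
#'
#' For every HETATM ion of the requested elements, computes the fraction
#' of frames in which its minimum distance to any protein (ATOM-record)
#' atom is within `cutoff`, flags the ion persistent when that fraction
#' exceeds `threshold` (strictly; the conventional criterion is "more
#' than 90% of the simulation time"), and ranks the protein residues most
#' frequently found in contact. The default 3.0 Angstrom cutoff covers
#' the 2.5 Angstrom Zn-S coordination bond with a vibration margin.
#'
#' @param model A [structure_model()] with >= 1 frame.
#' @param ion_elements Element symbols to analyse (default `"ZN"`).
#' @param cutoff Contact distance cutoff (Angstrom, > 0).
#' @param threshold Persistence threshold on the contact fraction, in
#'   (0, 1].
#' @return A tibble with one row per ion: `ion_serial`, `element`,
#'   `contact_fraction`, `persistent`, `partner_residues` (list column of
#'   tibbles `chain_id`, `residue_number`, `residue_name`, `n_frames`).
#'   Zero rows when no matching ion exists.
#' @export
#' @examples
#' arr <- structure_arrangement("nearby", n_frames = 5,
#'   ions = tibble::tibble(element = "ZN", rule = "pinned",
#'                         contact_distance = 2.5))
#' ion_contact_persistence(make_structure_fixture(arr))
ion_contact_persistence <- function(model, ion_elements = "ZN",
                                    cutoff = 3.0, threshold = 0.9) {
  stopifnot(inherits(model, "structure_model"))
  check_scalar(cutoff, "cutoff")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1].")
  }
  ions <- which(model$atoms$record == "HETATM" &
                  model$atoms$element %in% toupper(ion_elements))
  prot <- which(model$atoms$record == "ATOM")
  if (length(ions) == 0) {
    return(tibble(ion_serial = integer(0), element = character(0),
                  contact_fraction = numeric(0), persistent = logical(0),
                  partner_residues = list()))
  }
  if (length(prot) == 0) abort("model has no protein (ATOM) atoms.")
  nf <- n_frames(model)
  pa <- model$atoms[prot, ]
  purrr::map_dfr(ions, function(ii) {
    contact <- logical(nf)
    partners <- list()
    for (f in seq_len(nf)) {
      d2 <- colSums((t(model$coords[[f]][prot, , drop = FALSE]) -
                       model$coords[[f]][ii, ])^2)
      hit <- d2 <= cutoff^2
      contact[f] <- any(hit)
      if (any(hit)) {
        partners[[length(partners) + 1]] <-
          distinct(pa[hit, c("chain_id", "residue_number", "residue_name")])
      }
    }
    ranked <- if (length(partners) > 0) {
      bind_rows(partners) %>%
        dplyr::count(.data$chain_id, .data$residue_number,
                     .data$residue_name, name = "n_frames") %>%
        arrange(dplyr::desc(.data$n_frames))
    } else {
      tibble(chain_id = character(0), residue_number = integer(0),
             residue_name = character(0), n_frames = integer(0))
    }
    tibble(
      ion_serial = model$atoms$serial[ii],
      element = model$atoms$element[ii],
      contact_fraction = mean(contact),
      persistent = mean(contact) > threshold,
      partner_residues = list(ranked)
    )
  })
}
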