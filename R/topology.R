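#' Build and validate a topology table
#'
#' A topology is a tibble with one row per atom and columns `atom_id`
#' (unique, dense integers), `element` (symbol, e.g. "O", "H", "C"),
#' `mass` (amu), `charge` (elementary charges; these are the partial
#' charges entering the dipole-moment derivative), `molecule_id`
#' (integer grouping) and `role` (one of `"protein"`, `"water"`,
#' `"ion"`). Validation enforces the water chemistry the spectral
#' analysis relies on: every water molecule has exactly one oxygen and
#' two hydrogens, and each water molecule is electroneutral to 1e-9 e.
#'
#' @param atoms A data frame with the columns listed above.
#' @return A validated topology tibble (class `hydro_topology`).
#' @export
#' @examples
#' topology(data.frame(
#'   atom_id = 1:3, element = c("O", "H", "H"),
#'   mass = c(15.999, 1.008, 1.008), charge = c(-0.82, 0.41, 0.41),
#'   molecule_id = 1L, role = "water"
#' ))
topology <- function(atoms) {
  required <- c("atom_id", "element", "mass", "charge", "molecule_id", "role")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("topology is missing column(s): ", paste(missing, collapse = ", ")))
  }
  topo <- as_tibble(atoms)[required]
  topo$atom_id <- as.integer(topo$atom_id)
  topo$molecule_id <- as.integer(topo$molecule_id)
  topo$element <- as.character(topo$element)
  topo$role <- as.character(topo$role)
  validate_topology(topo)
  class(topo) <- c("hydro_topology", class(topo))
  topo
}

validate_topology <- function(topo) {
  if (anyDuplicated(topo$atom_id)) {
    dup <- topo$atom_id[duplicated(topo$atom_id)][1]
    abort(paste0("duplicate atom_id: ", dup))
  }
  bad_role <- setdiff(unique(topo$role), c("protein", "water", "ion"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (any(!is.finite(topo$mass)) || any(topo$mass <= 0)) {
    abort("masses must be finite and positive")
  }
  water <- topo[topo$role == "water", ]
  if (nrow(water) > 0) {
    per_mol <- split(water, water$molecule_id)
    for (mol in per_mol) {
      if (nrow(mol) != 3L ||
          sum(mol$element == "O") != 1L || sum(mol$element == "H") != 2L) {
        abort(paste0(
          "water molecule ", mol$molecule_id[1],
          " must have exactly 1 O and 2 H atoms (found ",
          paste(sort(mol$element), collapse = ""), ")"
        ))
      }
      q <- sum(mol$charge)
      if (abs(q) > 1e-9) {
        abort(paste0(
          "water molecule ", mol$molecule_id[1],
          " carries net charge ", format(q), " e (must be 0 within 1e-9)"
        ))
      }
    }
  }
  invisible(topo)
}

#' Read a topology from a columnar text file
#'
#' The file is comma- or whitespace-separated with a header naming the
#' six topology columns (`atom_id,element,mass,charge,molecule_id,role`).
#' Water is detected by the `role` column, never by residue-name
#' heuristics.
#'
#' @param path Path to the file.
#' @return A topology tibble.
#' @seealso [topology()] for the validation rules, [write_topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          strip.white = TRUE)
  topology(df)
}

#' @rdname read_topology
#' @param topo A topology tibble.
#' @export
write_topology <- function(topo, path) {
  utils::write.csv(as.data.frame(topo), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# atom ids of water oxygens / hydrogens / solute heavy atoms
water_oxygen_ids <- function(topo) {
  topo$atom_id[topo$role == "water" & topo$element == "O"]
}

water_hydrogen_ids <- function(topo) {
  topo$atom_id[topo$role == "water" & topo$element == "H"]
}

solute_ids <- function(topo, heavy_only = TRUE) {
  sel <- topo$role == "protein"
  if (heavy_only) sel <- sel & topo$element != "H"
  topo$atom_id[sel]
}

# mass of each water molecule, named by molecule_id
water_molecule_masses <- function(topo) {
  water <- topo[topo$role == "water", ]
  vapply(split(water$mass, water$molecule_id), sum, numeric(1))
}
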