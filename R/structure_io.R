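#' hbq: hydrogen-bond distance QSAR and docking pose analysis
#'
#' Tools that connect minimized ligand-protein-water complexes to percent
#' channel inhibition: fixed-column structure parsing, polar-contact
#' detection at a distance cutoff, residue-keyed feature matrices, genetic
#' algorithm subset selection with OLS fitness, docking pose clustering,
#' and one-parameter dose-response fitting.
#'
#' @keywords internal
"_PACKAGE"

# Default residue-name dialects. Ligand names are always caller-supplied;
# HETATM flags are unreliable after minimization round-trips.
WATER_RESIDUES <- c("HOH", "WAT", "SOL")
POLAR_ELEMENTS <- c("N", "O", "S")

title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

#' Chain-agnostic residue key
#'
#' Renders `"TRP" + 74` as `"Trp74"`. Keys intentionally carry no chain
#' identifier: the heptameric channel's seven protomers are identical and
#' contacts are pooled across chains.
#'
#' @param residue_name three-letter residue name (any case).
#' @param residue_number integer residue number.
#' @return character vector of keys such as `"Trp74"`.
#' @export
residue_key <- function(residue_name, residue_number) {
  paste0(title_case(residue_name), residue_number)
}

new_complex_structure <- function(ligand_id, atoms, protonation_tag, pose_index) {
  stopifnot(is.data.frame(atoms), all(is.finite(atoms$x)),
            all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  structure(
    list(ligand_id = ligand_id, atoms = atoms,
         protonation_tag = protonation_tag, pose_index = as.integer(pose_index)),
    class = "ComplexStructure"
  )
}

#' @export
print.ComplexStructure <- function(x, ...) {
  tab <- table(factor(x$atoms$role, levels = c("protein", "ligand", "water")))
  cat(sprintf("ComplexStructure '%s' (%s, pose %d): %d atoms (%d protein, %d ligand, %d water)\n",
              x$ligand_id, x$protonation_tag, x$pose_index, nrow(x$atoms),
              tab[["protein"]], tab[["ligand"]], tab[["water"]]))
  invisible(x)
}

infer_element <- function(element_field, atom_name) {
  el <- trimws(element_field)
  need <- el == "" | is.na(el)
  if (any(need)) {
    # first alphabetic character of the atom name ("1HG1" -> "H", "OD1" -> "O")
    first_alpha <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name[need])
    el[need] <- first_alpha
  }
  # normalize: "FE" stays two letters, "o" -> "O"
  ifelse(nchar(el) > 1,
         paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2))),
         toupper(el))
}

#' Read a minimized complex from a fixed-column atom-record file
#'
#' Parses `ATOM`/`HETATM` records (PDB fixed columns) and partitions atoms
#' into protein, ligand, and water roles. Role assignment is by residue
#' name: names in `water_res` become water, names in `ligand_res` become
#' ligand, everything else is protein.
#'
#' @param path path to the structure file.
#' @param ligand_res character vector of residue names identifying the
#'   ligand; must be disjoint from `water_res`.
#' @param water_res water residue names (default `HOH`, `WAT`, `SOL`).
#' @param ligand_id label for this conformation (default: file name without
#'   extension). A trailing `-` marks the deprotonated form, e.g. `"12b-"`.
#' @param protonation `"neutral"` or `"deprotonated"`; inferred from a
#'   trailing `-` in `ligand_id` when missing.
#' @param pose_index 1-based index of the docking pose this complex came
#'   from (`"12e_2"` style labels).
#' @return a `ComplexStructure`: ligand id, atom table (serial, atom_name,
#'   element, residue_name, residue_number, chain_id, x, y, z, role),
#'   protonation tag and pose index.
#' @export
read_structure <- function(path, ligand_res,
                           water_res = WATER_RESIDUES,
                           ligand_id = NULL,
                           protonation = NULL,
                           pose_index = 1L) {
  if (length(ligand_res) == 0) stop("at least one ligand residue name is required")
  if (any(ligand_res %in% water_res))
    stop("ligand residue names must be disjoint from water residue names")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(keep) == 0) stop("no atom records found in '", path, "'")
  ln <- lines[keep]

  bad <- which(nchar(ln) < 54)
  if (length(bad))
    stop("malformed atom record at line ", keep[bad[1]], " of '", path,
         "': fewer than 54 columns")

  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (anyNA(v))
      stop("malformed atom record at line ", keep[which(is.na(v))[1]],
           " of '", path, "': unparseable ", what)
    v
  }
  serial <- as.integer(num(7, 11, "serial"))
  atom_name <- trimws(substr(ln, 13, 16))
  res_name <- toupper(trimws(substr(ln, 18, 20)))
  chain_id <- trimws(substr(ln, 22, 22))
  res_num <- as.integer(num(23, 26, "residue number"))
  x <- num(31, 38, "x coordinate")
  y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  element <- infer_element(substr(ln, 77, 78), atom_name)

  role <- rep("protein", length(ln))
  role[res_name %in% toupper(water_res)] <- "water"
  role[res_name %in% toupper(ligand_res)] <- "ligand"
  if (!any(role == "ligand"))
    stop("no ligand: no atom with residue name in {",
         paste(ligand_res, collapse = ", "), "} found in '", path, "'")

  atoms <- data.frame(
    serial = serial, atom_name = atom_name, element = element,
    residue_name = res_name, residue_number = res_num, chain_id = chain_id,
    x = x, y = y, z = z, role = role, stringsAsFactors = FALSE
  )
  if (is.null(ligand_id))
    ligand_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(protonation))
    protonation <- if (grepl("[-−]$", ligand_id)) "deprotonated" else "neutral"
  protonation <- match.arg(protonation, c("neutral", "deprotonated"))
  new_complex_structure(ligand_id, atoms, protonation, pose_index)
}

#' Write a complex back to fixed-column atom records
#'
#' Inverse of [read_structure()]: coordinates are printed at 3 decimals,
#' so a read/write round trip preserves records to the dialect's printed
#' precision. Protein atoms are written as `ATOM`, ligand and water as
#' `HETATM`.
#'
#' @param structure a `ComplexStructure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  rec <- ifelse(a$role == "protein", "ATOM  ", "HETATM")
  # atom names of <4 chars start in column 14, PDB convention
  name_fmt <- ifelse(nchar(a$atom_name) >= 4, a$atom_name,
                     sprintf(" %-3s", a$atom_name))
  lines <- sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   rec, a$serial, name_fmt, a$residue_name,
                   ifelse(a$chain_id == "", " ", a$chain_id),
                   a$residue_number, a$x, a$y, a$z, 1, 0)
  # element right-justified in columns 77-78
  lines <- paste0(formatC(lines, width = -76), formatC(toupper(a$element), width = 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Polar heavy atoms of one role
#'
#' Returns the atoms of the requested role whose element belongs to the
#' polar set (default N, O, S). Hydrogens and carbons are excluded; only a
#' distance criterion is applied downstream, with no donor/acceptor or
#' angle distinction.
#'
#' @param structure a `ComplexStructure`.
#' @param role `"protein"`, `"ligand"` or `"water"`.
#' @param polar elements counted as hydrogen-bond capable.
#' @return the subset of the atom table with polar elements.
#' @export
polar_atoms <- function(structure, role, polar = POLAR_ELEMENTS) {
  role <- match.arg(role, c("protein", "ligand", "water"))
  a <- structure$atoms
  a[a$role == role & a$element %in% polar, , drop = FALSE]
}
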