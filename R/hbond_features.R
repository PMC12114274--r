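cross_dist <- function(A, B) {
  # |A_i - B_j| for row-coordinate matrices; guards tiny negative rounding
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}

coord_mat <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

empty_hbonds <- function() {
  data.frame(residue_key = character(), bridged = logical(), length = numeric(),
             ligand_atom_serial = integer(), protein_atom_serial = integer(),
             water_serial = integer(), stringsAsFactors = FALSE)
}

#' Detect direct ligand-protein hydrogen bonds
#'
#' A hydrogen bond is a ligand polar heavy atom and a protein polar heavy
#' atom within `cutoff` of each other (Euclidean distance; no angle or
#' donor/acceptor criterion). One bond is reported per qualifying pair,
#' keyed by the protein residue without chain id.
#'
#' @param structure a `ComplexStructure`.
#' @param cutoff distance ceiling in Angstrom (default 3.0).
#' @param polar polar element set (default N, O, S).
#' @return data frame with one row per bond: `residue_key`, `bridged`
#'   (always `FALSE` here), `length` (Angstrom), `ligand_atom_serial`,
#'   `protein_atom_serial`, `water_serial` (`NA`).
#' @export
detect_direct_hbonds <- function(structure, cutoff = 3.0, polar = POLAR_ELEMENTS) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("cutoff must be a single positive number")
  lig <- polar_atoms(structure, "ligand", polar)
  prot <- polar_atoms(structure, "protein", polar)
  if (nrow(lig) == 0 || nrow(prot) == 0) return(empty_hbonds())
  D <- cross_dist(coord_mat(lig), coord_mat(prot))
  hit <- which(D > 0 & D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_hbonds())
  out <- data.frame(
    residue_key = residue_key(prot$residue_name[hit[, 2]],
                              prot$residue_number[hit[, 2]]),
    bridged = FALSE,
    length = D[hit],
    ligand_atom_serial = lig$serial[hit[, 1]],
    protein_atom_serial = prot$serial[hit[, 2]],
    water_serial = NA_integer_,
    stringsAsFactors = FALSE
  )
  out[order(out$ligand_atom_serial, out$protein_atom_serial), , drop = FALSE]
}

#' Detect water-bridged ligand-protein hydrogen bonds
#'
#' A bridge is a (ligand polar atom, water oxygen, protein polar atom)
#' triple in which the water is within `cutoff` of both partners
#' simultaneously. The recorded length is, by default, the ligand-water
#' leg (the ligand-dependent quantity); `length_mode = "sum"` records the
#' sum of both legs instead.
#'
#' @inheritParams detect_direct_hbonds
#' @param length_mode `"ligand_water"` (default) or `"sum"`.
#' @return data frame as in [detect_direct_hbonds()] with `bridged = TRUE`
#'   and the bridging `water_serial` set; one row per qualifying triple.
#' @export
detect_water_bridges <- function(structure, cutoff = 3.0,
                                 length_mode = c("ligand_water", "sum"),
                                 polar = POLAR_ELEMENTS) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("cutoff must be a single positive number")
  length_mode <- match.arg(length_mode)
  lig <- polar_atoms(structure, "ligand", polar)
  prot <- polar_atoms(structure, "protein", polar)
  wat <- structure$atoms[structure$atoms$role == "water" &
                           structure$atoms$element == "O", , drop = FALSE]
  if (nrow(lig) == 0 || nrow(prot) == 0 || nrow(wat) == 0) return(empty_hbonds())
  DL <- cross_dist(coord_mat(wat), coord_mat(lig))    # water x ligand
  DP <- cross_dist(coord_mat(wat), coord_mat(prot))   # water x protein
  res <- vector("list", nrow(wat))
  for (w in seq_len(nrow(wat))) {
    li <- which(DL[w, ] > 0 & DL[w, ] <= cutoff)
    pj <- which(DP[w, ] > 0 & DP[w, ] <= cutoff)
    if (length(li) == 0 || length(pj) == 0) next
    g <- expand.grid(l = li, p = pj, KEEP.OUT.ATTRS = FALSE)
    len <- DL[w, g$l]
    if (length_mode == "sum") len <- len + DP[w, g$p]
    res[[w]] <- data.frame(
      residue_key = residue_key(prot$residue_name[g$p], prot$residue_number[g$p]),
      bridged = TRUE,
      length = len,
      ligand_atom_serial = lig$serial[g$l],
      protein_atom_serial = prot$serial[g$p],
      water_serial = wat$serial[w],
      stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(empty_hbonds())
  out <- do.call(rbind, res)
  out <- out[order(out$water_serial, out$ligand_atom_serial,
                   out$protein_atom_serial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

variable_label <- function(residue_key, bridged) {
  ifelse(bridged, paste0("W", residue_key), residue_key)
}

new_feature_matrix <- function(values, response, catalog) {
  stopifnot(nrow(values) == length(response), ncol(values) == nrow(catalog))
  colnames(values) <- catalog$index
  structure(list(values = values, response = response, catalog = catalog,
                 row_ids = rownames(values)),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d conformations x %d variables (%d bridged), I%% in [%g, %g]\n",
              nrow(x$values), ncol(x$values), sum(x$catalog$bridged),
              min(x$response), max(x$response)))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

#' Assemble the residue-keyed bond-length feature matrix
#'
#' Runs both hydrogen-bond detectors on every complex and builds the
#' QSAR design: one row per ligand conformation (protonation variants are
#' distinct rows), one column per distinct `(residue key, bridged)` pair
#' observed anywhere in the study set, ordered by first appearance and
#' indexed `V1...Vp`. A cell holds the minimum bond length among that
#' row's bonds matching the column (the strongest contact, reading
#' strength as inversely proportional to length), or `fill` when the
#' conformation makes no such contact. Residue keys carry no chain id, so
#' contacts with any of the seven identical protomers pool into one
#' variable. The response is the percent inhibition of the parent
#' compound, shared across its conformations.
#'
#' @param structures list of `ComplexStructure` objects with unique
#'   `ligand_id`s.
#' @param inhibition numeric percent-inhibition responses in `[0, 100]`,
#'   one per structure (recycled by `ligand_id` if named).
#' @param cutoff hydrogen-bond distance ceiling in Angstrom.
#' @param fill value for absent bonds, default `cutoff` ("no interaction
#'   within reach", the weakest possible contact).
#' @param length_mode bridged-bond length convention, see
#'   [detect_water_bridges()].
#' @param polar polar element set.
#' @return a `FeatureMatrix`: `values` (rows x `V1...Vp`, Angstrom),
#'   `response` (I%), and `catalog` (data frame `index`, `residue_key`,
#'   `bridged`, `label`; bridged labels get the `W` prefix).
#' @export
build_feature_matrix <- function(structures, inhibition, cutoff = 3.0,
                                 fill = cutoff,
                                 length_mode = c("ligand_water", "sum"),
                                 polar = POLAR_ELEMENTS) {
  length_mode <- match.arg(length_mode)
  if (length(structures) == 0) stop("empty record list")
  ids <- vapply(structures, function(s) s$ligand_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate row_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(names(inhibition))) inhibition <- inhibition[ids]
  if (length(inhibition) != length(structures) || anyNA(inhibition))
    stop("need one inhibition value per structure")
  if (any(inhibition < 0 | inhibition > 100))
    stop("inhibition must lie in [0, 100]")

  bonds <- lapply(structures, function(s) {
    rbind(detect_direct_hbonds(s, cutoff, polar),
          detect_water_bridges(s, cutoff, length_mode, polar))
  })

  # catalog: (residue_key, bridged) pairs by first appearance
  all_b <- do.call(rbind, bonds)
  keys <- unique(paste(all_b$residue_key, all_b$bridged, sep = "\r"))
  if (length(keys) == 0)
    stop("no hydrogen bonds detected in any structure; cannot build a matrix")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  catalog <- data.frame(
    index = paste0("V", seq_along(keys)),
    residue_key = vapply(parts, `[`, character(1), 1),
    bridged = vapply(parts, `[`, character(1), 2) == "TRUE",
    stringsAsFactors = FALSE
  )
  catalog$label <- variable_label(catalog$residue_key, catalog$bridged)

  values <- matrix(fill, nrow = length(structures), ncol = length(keys),
                   dimnames = list(ids, catalog$index))
  for (i in seq_along(bonds)) {
    b <- bonds[[i]]
    if (nrow(b) == 0) next
    col <- match(paste(b$residue_key, b$bridged, sep = "\r"), keys)
    m <- tapply(b$length, col, min)
    values[i, as.integer(names(m))] <- pmin(m, fill)
  }
  new_feature_matrix(values, as.numeric(inhibition), catalog)
}
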