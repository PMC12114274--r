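# Generators for every input the pipeline consumes, each a pure function
# of its spec + seed, with the planted truth returned alongside so the
# corresponding stage can be validated against construction.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

split_residue_key <- function(key) {
  name <- sub("[0-9]+$", "", key)
  num <- as.integer(sub("^[A-Za-z]+", "", key))
  if (any(is.na(num)) || any(nchar(name) == 0))
    stop("residue keys must look like 'Trp74'")
  list(name = toupper(name), number = num)
}

#' Specification of a planted sparse linear model
#'
#' The statistical world the regression stage assumes: percent inhibition
#' is linear in a small subset of bond-length variables plus Gaussian
#' noise. Defaults mirror the study scale: 40 conformations, 31
#' variables, 8 true variables, noise sd 2 I% units, bond lengths uniform
#' in 2.4-3.0 Angstrom. Default coefficients alternate between +60 and
#' -60 (response spread of roughly sd 29 I%, matching an observed
#' inhibition range of about 10-100%) around an intercept of 55.
#'
#' @param n_rows number of conformations (rows).
#' @param p_variables number of catalog variables.
#' @param true_subset indices of the truly active variables; default: a
#'   seed-determined random draw of `k` of them.
#' @param k size of the default `true_subset` (ignored when `true_subset`
#'   is given).
#' @param betas named or positional coefficients for `true_subset`;
#'   default alternates +60/-60.
#' @param intercept response intercept in I% units.
#' @param noise_sd Gaussian noise sd in I% units.
#' @param distance_range uniform bond-length range in Angstrom, within
#'   `[2, 3]` (the detector ceiling).
#' @param missing_rate probability a cell is "no bond" and takes the fill
#'   value.
#' @param fill fill value for missing cells (the 3 Angstrom cutoff).
#' @param seed RNG seed.
#' @return a `PlantedModelSpec` list.
#' @export
planted_model_spec <- function(n_rows = 40, p_variables = 31,
                               true_subset = NULL, k = 8, betas = NULL,
                               intercept = 55, noise_sd = 2,
                               distance_range = c(2.4, 3.0),
                               missing_rate = 0.2, fill = 3.0, seed = 1) {
  stopifnot(n_rows >= 1, p_variables >= 1, noise_sd >= 0,
            missing_rate >= 0, missing_rate <= 1)
  if (distance_range[1] < 2.0 || distance_range[2] > 3.0 ||
      distance_range[1] >= distance_range[2])
    stop("distance_range must be increasing and lie within [2, 3] Angstrom")
  if (!is.null(true_subset)) {
    true_subset <- sort(as.integer(true_subset))
    if (length(true_subset) > p_variables || any(true_subset < 1) ||
        any(true_subset > p_variables))
      stop("true_subset must be distinct indices within 1..p_variables")
    k <- length(true_subset)
  }
  if (k > p_variables) stop("k must not exceed p_variables")
  if (!is.null(betas) && length(betas) != k)
    stop("betas must have one value per true variable")
  structure(list(n_rows = as.integer(n_rows),
                 p_variables = as.integer(p_variables),
                 true_subset = true_subset, k = as.integer(k), betas = betas,
                 intercept = intercept, noise_sd = noise_sd,
                 distance_range = distance_range,
                 missing_rate = missing_rate, fill = fill,
                 seed = as.integer(seed)),
            class = "PlantedModelSpec")
}

#' Generate a feature matrix with planted linear structure
#'
#' Draws bond lengths uniformly in `distance_range`, sets cells flagged
#' missing to the fill value, and computes the response from the final
#' cell values: `I% = intercept + sum_j beta_j V_j + N(0, noise_sd)`.
#' Fully reproducible from the spec seed.
#'
#' @param spec a `PlantedModelSpec`.
#' @return list with `matrix` (a `FeatureMatrix`) and `truth`
#'   (`subset`, `betas` named by variable index, `intercept`, `noise_sd`).
#' @export
synth_feature_table <- function(spec) {
  stopifnot(inherits(spec, "PlantedModelSpec"))
  n <- spec$n_rows; p <- spec$p_variables
  out <- withr::with_seed(spec$seed, {
    subset <- spec$true_subset
    if (is.null(subset)) subset <- sort(sample.int(p, spec$k))
    betas <- spec$betas
    if (is.null(betas)) betas <- 60 * (-1)^(seq_along(subset) - 1)
    values <- matrix(stats::runif(n * p, spec$distance_range[1],
                                  spec$distance_range[2]), n, p)
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      values[miss] <- spec$fill
    }
    response <- spec$intercept +
      drop(values[, subset, drop = FALSE] %*% betas) +
      stats::rnorm(n, 0, spec$noise_sd)
    bridged <- stats::runif(p) < 0.3
    catalog <- data.frame(
      index = paste0("V", seq_len(p)),
      residue_key = paste0(title_case(AA3[(seq_len(p) - 1) %% 20 + 1]),
                           10 + seq_len(p)),
      bridged = bridged, stringsAsFactors = FALSE
    )
    catalog$label <- variable_label(catalog$residue_key, catalog$bridged)
    rownames(values) <- sprintf("cmp%02d", seq_len(n))
    list(matrix = new_feature_matrix(values, response, catalog),
         truth = list(subset = subset,
                      betas = stats::setNames(betas, paste0("V", subset)),
                      intercept = spec$intercept, noise_sd = spec$noise_sd))
  })
  out
}

#' Specification of a toy complex with planted contacts
#'
#' @param contacts data frame (or list coercible to one) with columns
#'   `residue_key` (e.g. `"Trp74"`) and `distance` (Angstrom): direct
#'   ligand-protein contacts, one ligand polar atom each.
#' @param bridges data frame with columns `residue_key`, `d_ligand_water`
#'   and `d_water_protein`: water-mediated contacts.
#' @param decoy_carbons number of protein-role carbon atoms placed 2
#'   Angstrom from ligand atoms; polar detectors must ignore them.
#' @param chains chain ids to replicate each planted protein atom across
#'   (e.g. `LETTERS[1:7]` emulates the heptamer; keys are chain-agnostic
#'   so replicas merge into one variable).
#' @return a `ComplexSpec` list.
#' @export
complex_spec <- function(contacts = NULL, bridges = NULL, decoy_carbons = 0,
                         chains = "A") {
  if (!is.null(contacts)) {
    contacts <- as.data.frame(contacts)
    stopifnot(all(c("residue_key", "distance") %in% names(contacts)),
              all(contacts$distance > 0))
  }
  if (!is.null(bridges)) {
    bridges <- as.data.frame(bridges)
    stopifnot(all(c("residue_key", "d_ligand_water", "d_water_protein")
                  %in% names(bridges)),
              all(bridges$d_ligand_water > 0), all(bridges$d_water_protein > 0))
  }
  if ((is.null(contacts) || nrow(contacts) == 0) &&
      (is.null(bridges) || nrow(bridges) == 0))
    stop("at least one contact or bridge must be planted")
  structure(list(contacts = contacts, bridges = bridges,
                 decoy_carbons = as.integer(decoy_carbons), chains = chains),
            class = "ComplexSpec")
}

#' Build a toy complex realizing a planted bond set exactly
#'
#' Each planted contact lives in its own spatial pocket 25 Angstrom from
#' the next, so the detectors applied to the result return exactly the
#' planted bonds: the ligand polar atom sits at the pocket center, its
#' partner at the prescribed distance in a random direction. For bridges
#' the protein partner is re-drawn (at most 100 attempts) until it is
#' farther than 3 Angstrom from the ligand atom, so no spurious direct
#' bond appears. Decoy carbons at 2 Angstrom probe the polar filter.
#'
#' @param spec a `ComplexSpec`.
#' @param seed RNG seed for the random directions.
#' @param ligand_id label for the generated conformation.
#' @return a `ComplexStructure` (write it with [write_structure()] for a
#'   file-based round trip).
#' @export
synth_complex <- function(spec, seed = 1, ligand_id = "SYN1") {
  stopifnot(inherits(spec, "ComplexSpec"))
  rows <- list()
  serial <- 0L
  add <- function(atom_name, element, residue_name, residue_number, chain_id,
                  pos, role) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, atom_name = atom_name, element = element,
      residue_name = residue_name, residue_number = as.integer(residue_number),
      chain_id = chain_id, x = pos[1], y = pos[2], z = pos[3],
      role = role, stringsAsFactors = FALSE)
  }
  withr::with_seed(seed, {
    pocket <- 0
    lig_atoms <- list()   # pocket centers, for decoy placement
    n_lig <- 0L
    if (!is.null(spec$contacts)) for (i in seq_len(nrow(spec$contacts))) {
      pocket <- pocket + 1
      center <- c(25 * pocket, 0, 0)
      n_lig <- n_lig + 1L
      add(paste0("O", n_lig), "O", "LIG", 1, "", center, "ligand")
      lig_atoms[[length(lig_atoms) + 1L]] <- center
      rk <- split_residue_key(spec$contacts$residue_key[i])
      for (ch in spec$chains)
        add("N", "N", rk$name, rk$number, ch,
            center + spec$contacts$distance[i] * runit(), "protein")
    }
    if (!is.null(spec$bridges)) for (i in seq_len(nrow(spec$bridges))) {
      pocket <- pocket + 1
      center <- c(25 * pocket, 0, 0)
      n_lig <- n_lig + 1L
      add(paste0("O", n_lig), "O", "LIG", 1, "", center, "ligand")
      lig_atoms[[length(lig_atoms) + 1L]] <- center
      wpos <- center + spec$bridges$d_ligand_water[i] * runit()
      add("O", "O", "HOH", 9000 + i, "", wpos, "water")
      rk <- split_residue_key(spec$bridges$residue_key[i])
      for (ch in spec$chains) {
        ok <- FALSE
        for (try in seq_len(100)) {
          ppos <- wpos + spec$bridges$d_water_protein[i] * runit()
          if (sqrt(sum((ppos - center)^2)) > 3.0 &&
              sqrt(sum((ppos - wpos)^2)) > 0.5) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place bridge partner for ",
                      spec$bridges$residue_key[i],
                      " without a spurious contact (100 attempts)")
        add("O", "O", rk$name, rk$number, ch, ppos, "protein")
      }
    }
    if (spec$decoy_carbons > 0) for (d in seq_len(spec$decoy_carbons)) {
      base <- lig_atoms[[(d - 1L) %% length(lig_atoms) + 1L]]
      add("C", "C", "GLY", 500 + d, "A", base + 2.0 * runit(), "protein")
    }
  })
  atoms <- do.call(rbind, rows)
  new_complex_structure(ligand_id, atoms, "neutral", 1L)
}

#' Random complex for brute-force oracle sweeps
#'
#' Scatters polar (and some carbon) atoms uniformly in a cube so the
#' vectorized detectors can be compared against all-pairs / all-triples
#' enumeration on unstructured input.
#'
#' @param n_protein,n_ligand,n_water atom counts per role.
#' @param box cube edge in Angstrom (default 12; small enough that many
#'   contacts fall under the 3 Angstrom cutoff).
#' @param carbon_frac fraction of protein/ligand atoms that are carbon.
#' @param seed RNG seed.
#' @return a `ComplexStructure`.
#' @export
synth_random_complex <- function(n_protein = 60, n_ligand = 6, n_water = 20,
                                 box = 12, carbon_frac = 0.2, seed = 1) {
  withr::with_seed(seed, {
    n <- n_protein + n_ligand + n_water
    pos <- matrix(stats::runif(n * 3, 0, box), n, 3)
    el_pool <- c("N", "O", "S")
    pel <- ifelse(stats::runif(n_protein) < carbon_frac, "C",
                  sample(el_pool, n_protein, replace = TRUE))
    lel <- ifelse(stats::runif(n_ligand) < carbon_frac, "C",
                  sample(el_pool, n_ligand, replace = TRUE))
    atoms <- data.frame(
      serial = seq_len(n),
      atom_name = c(pel, paste0(lel, seq_len(n_ligand)), rep("O", n_water)),
      element = c(pel, lel, rep("O", n_water)),
      residue_name = c(sample(AA3, n_protein, replace = TRUE),
                       rep("LIG", n_ligand), rep("HOH", n_water)),
      residue_number = c(seq_len(n_protein), rep(1L, n_ligand),
                         9000L + seq_len(n_water)),
      chain_id = c(sample(LETTERS[1:7], n_protein, replace = TRUE),
                   rep("", n_ligand), rep("", n_water)),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      role = c(rep("protein", n_protein), rep("ligand", n_ligand),
               rep("water", n_water)),
      stringsAsFactors = FALSE
    )
    new_complex_structure(sprintf("RND%d", seed), atoms, "neutral", 1L)
  })
}

#' Generate a docking pose set from jittered cluster centers
#'
#' Poses are drawn as `center + N(0, jitter_sd)` per coordinate; energies
#' per cluster as `N(energy_mean, energy_sd)`. With centers separated by
#' much more than the clustering threshold, [cluster_poses()] must
#' recover exactly the planted cluster count and sizes.
#'
#' @param centers list of n_atoms x 3 matrices, one per planted cluster.
#' @param sizes poses per cluster.
#' @param jitter_sd isotropic positional noise sd in Angstrom.
#' @param energy_means per-cluster mean binding energy (kcal/mol);
#'   default `-10, -9, ...`.
#' @param energy_sd energy spread within a cluster.
#' @param min_separation if positive, error when any two centers are
#'   closer (RMSD) than this.
#' @param seed RNG seed.
#' @return list of `Pose` objects (pose ids 1..sum(sizes), cluster by
#'   cluster), with the planted cluster id attached as attribute
#'   `"truth"`.
#' @export
synth_pose_set <- function(centers, sizes, jitter_sd = 1.0,
                           energy_means = NULL, energy_sd = 1.0,
                           min_separation = 0, seed = 1) {
  stopifnot(length(centers) == length(sizes), all(sizes >= 1))
  centers <- lapply(centers, as.matrix)
  if (min_separation > 0 && length(centers) > 1) {
    for (i in seq_along(centers)) for (j in seq_len(i - 1)) {
      d <- sqrt(mean(rowSums((centers[[i]] - centers[[j]])^2)))
      if (d < min_separation)
        stop("centers ", j, " and ", i, " are only ", round(d, 2),
             " Angstrom apart (< min_separation = ", min_separation, ")")
    }
  }
  if (is.null(energy_means)) energy_means <- -10 + seq_along(centers) - 1
  withr::with_seed(seed, {
    poses <- list(); truth <- integer()
    id <- 0L
    for (c_i in seq_along(centers)) {
      n_at <- nrow(centers[[c_i]])
      for (s in seq_len(sizes[c_i])) {
        id <- id + 1L
        jitter <- matrix(stats::rnorm(n_at * 3, 0, jitter_sd), n_at, 3)
        poses[[id]] <- pose(id, stats::rnorm(1, energy_means[c_i], energy_sd),
                            centers[[c_i]] + jitter)
        truth[id] <- c_i
      }
    }
    attr(poses, "truth") <- truth
    poses
  })
}

#' Simulate a dose-response table from the one-parameter model
#'
#' @param ic50 generating IC50 in uM.
#' @param doses concentrations in uM.
#' @param noise_sd Gaussian response noise sd in percent units (responses
#'   are not clipped to `[0, 100]`).
#' @param seed RNG seed; pass one whenever `noise_sd > 0` for
#'   reproducibility (`NULL` uses the current RNG state).
#' @return data frame with columns `dose` and `response`.
#' @export
synth_dose_response <- function(ic50, doses, noise_sd = 0, seed = NULL) {
  gen <- function() {
    data.frame(dose = doses,
               response = predict_response(doses, ic50) +
                 stats::rnorm(length(doses), 0, noise_sd))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
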