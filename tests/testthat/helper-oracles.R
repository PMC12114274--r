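# Independent brute-force oracles. Deliberately naive (explicit loops,
# scalar arithmetic) so they share no code path with the vectorized
# implementations they check.

dist3 <- function(a, b) sqrt(sum((a - b)^2))

atom_xyz <- function(atoms, i) c(atoms$x[i], atoms$y[i], atoms$z[i])

oracle_direct_hbonds <- function(structure, cutoff = 3, polar = c("N", "O", "S")) {
  a <- structure$atoms
  lig <- which(a$role == "ligand" & a$element %in% polar)
  prot <- which(a$role == "protein" & a$element %in% polar)
  rows <- list()
  for (i in lig) for (j in prot) {
    d <- dist3(atom_xyz(a, i), atom_xyz(a, j))
    if (d > 0 && d <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        residue_key = residue_key(a$residue_name[j], a$residue_number[j]),
        bridged = FALSE, length = d,
        ligand_atom_serial = a$serial[i], protein_atom_serial = a$serial[j],
        water_serial = NA_integer_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

oracle_water_bridges <- function(structure, cutoff = 3, polar = c("N", "O", "S")) {
  a <- structure$atoms
  lig <- which(a$role == "ligand" & a$element %in% polar)
  prot <- which(a$role == "protein" & a$element %in% polar)
  wat <- which(a$role == "water" & a$element == "O")
  rows <- list()
  for (w in wat) for (i in lig) for (j in prot) {
    dl <- dist3(atom_xyz(a, w), atom_xyz(a, i))
    dp <- dist3(atom_xyz(a, w), atom_xyz(a, j))
    if (dl > 0 && dl <= cutoff && dp > 0 && dp <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        residue_key = residue_key(a$residue_name[j], a$residue_number[j]),
        bridged = TRUE, length = dl,
        ligand_atom_serial = a$serial[i], protein_atom_serial = a$serial[j],
        water_serial = a$serial[w], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# canonical ordering so bond tables from different code paths compare
normalize_bonds <- function(b) {
  if (is.null(b) || nrow(b) == 0)
    return(data.frame(residue_key = character(), length = numeric()))
  b <- b[order(b$bridged, b$ligand_atom_serial, b$protein_atom_serial,
               b$water_serial, na.last = FALSE), , drop = FALSE]
  rownames(b) <- NULL
  b
}

expect_same_bonds <- function(got, want, tol = 1e-9) {
  g <- normalize_bonds(got); w <- normalize_bonds(want)
  expect_equal(nrow(g), nrow(w))
  if (nrow(g) == 0) return(invisible())
  expect_identical(g$residue_key, w$residue_key)
  expect_identical(g$bridged, w$bridged)
  expect_identical(g$ligand_atom_serial, w$ligand_atom_serial)
  expect_identical(g$protein_atom_serial, w$protein_atom_serial)
  expect_equal(g$water_serial, w$water_serial)
  expect_equal(g$length, w$length, tolerance = tol)
}

# hand solver of the normal equations, the OLS cross-check
oracle_ols <- function(X, y) {
  Z <- cbind(1, X)
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  pred <- drop(Z %*% beta)
  res <- y - pred
  sstot <- sum((y - mean(y))^2)
  list(beta = drop(beta),
       r2 = if (sstot == 0) 0 else 1 - sum(res^2) / sstot,
       rmse = sqrt(mean(res^2)))
}

# exhaustive minimal-cover: fewest clusters whose sizes reach min_coverage
minimal_cover_size <- function(sizes, n_total, min_coverage) {
  for (m in seq_along(sizes)) {
    combos <- utils::combn(length(sizes), m, simplify = FALSE)
    for (idx in combos)
      if (sum(sizes[idx]) / n_total >= min_coverage) return(m)
  }
  length(sizes)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# rigid motion applied to every atom of a complex
transform_structure <- function(structure, R, t) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}
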