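## Bondi van der Waals radii (angstrom); unknown elements fall back to C.
BONDI_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

vdw_radius <- function(element) {
  r <- BONDI_RADII[element]
  r[is.na(r)] <- BONDI_RADII[["C"]]
  unname(r)
}

# Orthonormal frame for atom i from its neighbor geometry: first axis to
# the nearest neighbor, second from the nearest non-collinear neighbor.
# When all neighbors are collinear the occlusion pattern is azimuthally
# symmetric, so any deterministic completion preserves invariance.
local_frame <- function(xyz, i, neigh_ordered) {
  e1 <- xyz[neigh_ordered[1], ] - xyz[i, ]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- NULL
  for (j in neigh_ordered[-1]) {
    v <- xyz[j, ] - xyz[i, ]
    v <- v - sum(v * e1) * e1
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) {
      e2 <- v / nv
      break
    }
  }
  if (is.null(e2)) {
    a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- a - sum(a * e1) * e1
    e2 <- v / sqrt(sum(v^2))
  }
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

# Quasi-uniform unit-sphere point set (Fibonacci lattice); deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible surface area by probe-sphere point sampling: each
#' atom's van der Waals sphere is expanded by the probe radius and covered
#' with a deterministic quasi-uniform (Fibonacci lattice) point set; the
#' accessible area is the sphere area times the fraction of points not
#' inside any other atom's expanded sphere.
#'
#' The lattice is oriented per atom in a local frame built from the
#' nearest-neighbor geometry (pole toward the nearest neighbor, azimuth
#' fixed by the nearest non-collinear neighbor), so the computed areas are
#' exactly invariant under rigid motions of the structure while remaining
#' fully deterministic.
#'
#' @param xyz Numeric matrix (n x 3) of atom coordinates in angstrom.
#' @param radii Numeric vector of van der Waals radii (angstrom).
#' @param probe_radius Probe (solvent) radius, default 1.4 A.
#' @param n_points Sphere sample points per atom (default 960).
#' @param indices Optional integer vector: compute ASA only for these atoms
#'   (all atoms still occlude).
#' @return Numeric vector of per-atom ASA in square angstrom (length
#'   `length(indices)` if given, else n).
#' @export
shrake_rupley_asa <- function(xyz, radii, probe_radius = 1.4, n_points = 960L,
                              indices = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(radii),
            probe_radius >= 0, n_points >= 100L)
  n <- nrow(xyz)
  if (is.null(indices)) indices <- seq_len(n)
  sphere <- fibonacci_sphere(n_points)
  expanded <- radii + probe_radius
  out <- numeric(length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    ri <- expanded[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    neigh <- which(d2 < (ri + expanded)^2 & seq_len(n) != i)
    if (any(d2[neigh] == 0)) {
      stop("coincident atoms with identical centers (atom ", i, ")")
    }
    if (length(neigh) == 0L) {
      out[k] <- 4 * pi * ri^2
      next
    }
    frame <- local_frame(xyz, i, neigh[order(d2[neigh], neigh)])
    pts <- sweep((sphere %*% t(frame)) * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in neigh) {
      if (!any(free)) break
      dj2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      keep <- dj2 >= expanded[j]^2
      free[free] <- keep
    }
    out[k] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  out
}

## Tyrosine side-chain atom subsets: the hydroxyl; hydroxyl plus ipso (CZ)
## and ortho (CE1/CE2) carbons; the full aromatic ring.
TYROSINE_SUBSETS <- list(
  OH_ONLY = "OH",
  OH_IPSO_ORTHO = c("OH", "CZ", "CE1", "CE2"),
  FULL_RING = c("OH", "CZ", "CE1", "CE2", "CD1", "CD2", "CG")
)

#' Surface exposure of one tyrosine's side-chain atom subset
#'
#' Sums per-atom Shrake-Rupley ASA over a chosen subset of one tyrosine's
#' side-chain atoms, computed in the context of all atoms of the structure.
#' Labeling chemistry acts on the tyrosine ring/hydroxyl, so exposure of
#' the hydroxyl (and the ipso/ortho carbons) is usually the relevant
#' measure rather than the whole ring.
#'
#' @param structure Atom table: data.frame with columns `resno`, `resid`,
#'   `elety` (atom name), `x`, `y`, `z`, and `element` (or derivable from
#'   `elety`). [read_structure_pdb()] produces this from a PDB file.
#' @param position Residue number of the tyrosine.
#' @param subset One of `"OH_ONLY"`, `"OH_IPSO_ORTHO"`, `"FULL_RING"`.
#' @param probe_radius,n_points Passed to [shrake_rupley_asa()].
#' @return ASA in square angstrom.
#' @export
tyrosine_subset_asa <- function(structure, position,
                                subset = c("OH_IPSO_ORTHO", "OH_ONLY", "FULL_RING"),
                                probe_radius = 1.4, n_points = 960L) {
  subset <- match.arg(subset)
  require_columns(structure, c("resno", "resid", "elety", "x", "y", "z"),
                  "structure atom table")
  res <- structure[structure$resno == position, , drop = FALSE]
  if (nrow(res) == 0L) stop("no residue at position ", position)
  if (!all(res$resid == "TYR")) stop("residue at position ", position, " is not tyrosine")
  wanted <- TYROSINE_SUBSETS[[subset]]
  sel <- which(structure$resno == position & structure$elety %in% wanted)
  missing <- setdiff(wanted, structure$elety[sel])
  if (length(missing) > 0L) {
    stop("tyrosine ", position, " is missing atom(s): ",
         paste(missing, collapse = ", "))
  }
  element <- if ("element" %in% names(structure)) structure$element else
    substr(structure$elety, 1L, 1L)
  asa <- shrake_rupley_asa(as.matrix(structure[, c("x", "y", "z")]),
                           vdw_radius(element),
                           probe_radius = probe_radius, n_points = n_points,
                           indices = sel)
  sum(asa)
}

#' Aggregate per-structure exposures by maximum
#'
#' Crystal packing can artificially bury a residue that is exposed in
#' solution, so when several structures cover the same site the maximum
#' exposure over structures is taken. Sites resolved in no structure are
#' reported as unresolved.
#'
#' @param per_structure_asa Named list (one element per structure) of named
#'   numeric vectors: site identifier -> ASA. A site absent from a
#'   structure's vector did not resolve in it.
#' @param all_sites Optional character vector of site identifiers to
#'   report; defaults to the union over structures.
#' @return A list with `asa` (named numeric vector, max over structures)
#'   and `unresolved` (character vector of sites seen in no structure).
#' @export
aggregate_max_asa <- function(per_structure_asa, all_sites = NULL) {
  stopifnot(length(per_structure_asa) >= 1L)
  seen <- unique(unlist(lapply(per_structure_asa, names)))
  if (is.null(all_sites)) all_sites <- seen
  resolved <- intersect(all_sites, seen)
  asa <- vapply(resolved, function(s) {
    max(vapply(per_structure_asa, function(v) {
      if (s %in% names(v)) v[[s]] else -Inf
    }, numeric(1)))
  }, numeric(1))
  list(asa = asa, unresolved = setdiff(all_sites, resolved))
}

#' Composite false-positive / false-negative exposure scoring
#'
#' Scores the agreement between observed tagging and computed surface
#' exposure for the tyrosines of one protein. Each tagged tyrosine with
#' ASA below the threshold contributes 10; each tagged tyrosine at or
#' above the threshold but below the smallest untagged tyrosine's ASA
#' contributes 1 (skipped when there are no untagged tyrosines). A
#' protein with fp_score > 10 belongs to the final false-positive set.
#' Untagged tyrosines whose ASA exceeds `fn_margin` times the largest
#' tagged ASA are flagged as false negatives.
#'
#' @param tagged_positions Positions (names of `asa_by_position`) that were
#'   experimentally tagged.
#' @param asa_by_position Named numeric vector: tyrosine position -> ASA
#'   (square angstrom) for every scoreable tyrosine of the protein.
#' @param threshold Burial threshold in square angstrom (default 5).
#' @param fn_margin Multiplier formalizing "significantly greater" for the
#'   false-negative flag (default 3).
#' @return A list with `fp_score`, `is_false_positive` (fp_score > 10),
#'   `fn_flags` (positions), and the per-category counts
#'   `n_below_threshold`, `n_below_min_untagged`.
#' @export
score_exposure <- function(tagged_positions, asa_by_position,
                           threshold = 5, fn_margin = 3) {
  stopifnot(threshold > 0, length(asa_by_position) >= 1L,
            !is.null(names(asa_by_position)))
  tagged_positions <- as.character(tagged_positions)
  bad <- setdiff(tagged_positions, names(asa_by_position))
  if (length(bad) > 0L) {
    stop("tagged position(s) absent from ASA table: ", paste(bad, collapse = ", "))
  }
  tagged_asa <- asa_by_position[tagged_positions]
  untagged_asa <- asa_by_position[setdiff(names(asa_by_position), tagged_positions)]
  n_buried <- sum(tagged_asa < threshold)
  n_low <- if (length(untagged_asa) > 0L) {
    sum(tagged_asa >= threshold & tagged_asa < min(untagged_asa))
  } else 0L
  fn_flags <- character(0)
  if (length(tagged_asa) > 0L && length(untagged_asa) > 0L) {
    fn_flags <- names(untagged_asa)[untagged_asa > fn_margin * max(tagged_asa)]
  }
  list(
    fp_score = 10L * as.integer(n_buried) + 1L * as.integer(n_low),
    is_false_positive = (10L * n_buried + n_low) > 10L,
    fn_flags = fn_flags,
    n_below_threshold = as.integer(n_buried),
    n_below_min_untagged = as.integer(n_low)
  )
}

#' Read an atom table from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()` returning the flat atom
#' data.frame this package's exposure functions consume.
#'
#' @param path PDB file path.
#' @return data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`, `element`.
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(at$elety, 1L, 1L), at$elesy),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_structure_pdb
#' @param structure Atom table (as above).
#' @export
write_structure_pdb <- function(structure, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(structure[, c("x", "y", "z")]))),
    resno = structure$resno,
    resid = structure$resid,
    eleno = structure$eleno,
    elety = structure$elety,
    chain = structure$chain,
    elesy = structure$element
  )
  invisible(path)
}
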