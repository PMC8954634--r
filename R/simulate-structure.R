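## Idealized tyrosine side-chain atom coordinates (angstrom): aromatic ring
## as a regular hexagon (C-C 1.39 A) in the xy plane with the hydroxyl
## oxygen bonded to CZ (C-O 1.36 A).
TYROSINE_TEMPLATE <- local({
  ring_r <- 1.39
  ang <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
  rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  oh <- c((ring_r + 1.36) * cos(pi), 0, 0)
  rbind(ring, OH = oh)
})

#' Simulate a toy structure with tyrosines of controlled burial
#'
#' Places idealized tyrosine side chains far apart along the x axis.
#' Exposed tyrosines stand free in solvent; buried tyrosines are enclosed
#' in two concentric shells of carbon blocker atoms dense enough that no
#' probe can reach the side chain.
#'
#' @param n_tyrosines Number of tyrosines (>= 1).
#' @param buried_fraction Probability each tyrosine is buried.
#' @param seed RNG seed.
#' @return A list with `atoms` (atom table usable by
#'   [tyrosine_subset_asa()] and [write_structure_pdb()]), and
#'   `ground_truth`: data.frame of `position` (residue number) and
#'   `buried`.
#' @export
simulate_structure <- function(n_tyrosines, buried_fraction = 0.5, seed = 1L) {
  stopifnot(n_tyrosines >= 1L, buried_fraction >= 0, buried_fraction <= 1)
  with_seed(seed, {
    buried <- stats::runif(n_tyrosines) < buried_fraction
    centroid <- colMeans(TYROSINE_TEMPLATE)
    shells <- rbind(
      sweep(fibonacci_sphere(160L) * 4.3, 2, centroid, "+"),
      sweep(fibonacci_sphere(340L) * 6.5, 2, centroid, "+")
    )
    rows <- list()
    eleno <- 0L
    for (t in seq_len(n_tyrosines)) {
      offset <- c((t - 1L) * 60, 0, 0)
      coords <- sweep(TYROSINE_TEMPLATE, 2, offset, "+")
      for (a in rownames(coords)) {
        eleno <- eleno + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          eleno = eleno, elety = a, resid = "TYR", chain = "A", resno = t,
          x = coords[a, 1], y = coords[a, 2], z = coords[a, 3],
          element = substr(a, 1L, 1L), stringsAsFactors = FALSE
        )
      }
      if (buried[t]) {
        cage <- sweep(shells, 2, offset, "+")
        for (b in seq_len(nrow(cage))) {
          eleno <- eleno + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            eleno = eleno, elety = "C", resid = "BLK", chain = "B",
            resno = 1000L + t,
            x = cage[b, 1], y = cage[b, 2], z = cage[b, 3],
            element = "C", stringsAsFactors = FALSE
          )
        }
      }
    }
    list(
      atoms = do.call(rbind, rows),
      ground_truth = data.frame(position = seq_len(n_tyrosines),
                                buried = buried)
    )
  })
}
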