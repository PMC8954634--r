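## Monoisotopic masses of the most abundant isotope of each element
## (CODATA/NIST). Extensible: add entries here if new compositions need them.
ELEMENT_MASSES <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376200
)

#' Physical constants used in peptide mass arithmetic
#'
#' Monoisotopic mass of a proton and of water, in daltons. A peptide's
#' neutral monoisotopic mass is the sum of its residue masses plus
#' `WATER_MASS`; the singly protonated ion \[M+H\]+ adds `PROTON_MASS`.
#'
#' @format Length-one numeric values (Da).
#' @export
PROTON_MASS <- 1.00727646

#' @rdname PROTON_MASS
#' @export
WATER_MASS <- 2 * 1.00782503 + 15.99491462

#' Parse an elemental composition string
#'
#' Accepts both spaced (`"C10 H14 O2 N2 S1"`) and compact (`"C10H14O2N2S1"`)
#' forms. Element symbols are case-sensitive; a bare symbol means count 1;
#' a leading `+` or `-` sign and surrounding whitespace are tolerated (the
#' sign is ignored -- direction of a gain/loss is carried by the operation,
#' not the composition).
#'
#' @param text Composition string. The empty string parses to the empty
#'   composition (mass 0).
#' @return A named integer vector of element counts (class
#'   `elemental_composition`), one entry per element present.
#' @examples
#' parse_composition("C10 H14 O2 N2 S1")
#' parse_composition("C O N1 H3")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  body <- sub("^\\s*[+-]?\\s*", "", text)
  chunks <- strsplit(trimws(body), "\\s+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) {
    return(as_composition(integer(0)))
  }
  if (!all(grepl("^([A-Z][a-z]?[0-9]*)+$", chunks))) {
    stop("malformed composition string: '", text, "'")
  }
  tokens <- unlist(regmatches(chunks, gregexpr("[A-Z][a-z]?[0-9]*", chunks)))
  syms <- sub("[0-9]*$", "", tokens)
  unknown <- setdiff(syms, names(ELEMENT_MASSES))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- suppressWarnings(as.integer(sub("^[A-Z][a-z]?", "", tokens)))
  counts[is.na(counts)] <- 1L
  out <- tapply(counts, syms, sum)
  as_composition(stats::setNames(as.integer(out), names(out)))
}

as_composition <- function(x) {
  x <- x[x != 0L]
  if (any(x < 0L)) stop("negative element count in composition")
  # canonical element order: Hill-ish (C, H, then alphabetical)
  ord <- c(intersect(c("C", "H"), names(x)),
           sort(setdiff(names(x), c("C", "H"))))
  x <- x[ord]
  class(x) <- "elemental_composition"
  x
}

#' Format an elemental composition as a canonical string
#'
#' Inverse of [parse_composition()]: `parse_composition(format(x))` recovers
#' `x` for any composition.
#'
#' @param x An `elemental_composition`.
#' @param ... Unused.
#' @return A single string such as `"C10 H14 N2 O2 S1"`.
#' @method format elemental_composition
#' @export
format.elemental_composition <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), unclass(x), collapse = " ")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition> ", format(x), "  (", signif(monoisotopic_mass(x), 9),
      " Da)\n", sep = "")
  invisible(x)
}

#' Add or subtract elemental compositions
#'
#' Element-wise arithmetic on compositions. Subtraction errors if any
#' element count would go negative (the loss exceeds what is available).
#'
#' @param a,b `elemental_composition` objects (or parseable strings).
#' @return An `elemental_composition`.
#' @export
comp_add <- function(a, b) {
  a <- as_comp_arg(a); b <- as_comp_arg(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  as_composition(out)
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  a <- as_comp_arg(a); b <- as_comp_arg(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] - unclass(b)
  if (any(out < 0L)) {
    stop("composition subtraction yields negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  }
  as_composition(out)
}

as_comp_arg <- function(x) {
  if (inherits(x, "elemental_composition")) x else parse_composition(x)
}

#' Monoisotopic mass of an elemental composition
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#' Additive: `monoisotopic_mass(comp_add(a, b))` equals
#' `monoisotopic_mass(a) + monoisotopic_mass(b)`.
#'
#' @param comp An `elemental_composition` or composition string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C10 H14 O2 N2 S1")  # biotin delta mass, 226.0776
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_comp_arg(comp)
  if (length(comp) == 0L) return(0)
  missing <- setdiff(names(comp), names(ELEMENT_MASSES))
  if (length(missing) > 0L) {
    stop("element(s) missing from mass table: ", paste(missing, collapse = ", "))
  }
  sum(ELEMENT_MASSES[names(comp)] * unclass(comp))
}

## Residue elemental compositions (the residue, i.e. amino acid minus water).
## Masses are always derived from these so that peptide arithmetic is
## self-consistent with composition arithmetic.
RESIDUE_COMPOSITIONS <- list(
  G = "C2 H3 N1 O1",  A = "C3 H5 N1 O1",  S = "C3 H5 N1 O2",
  P = "C5 H7 N1 O1",  V = "C5 H9 N1 O1",  T = "C4 H7 N1 O2",
  C = "C3 H5 N1 O1 S1", L = "C6 H11 N1 O1", I = "C6 H11 N1 O1",
  N = "C4 H6 N2 O2",  D = "C4 H5 N1 O3",  Q = "C5 H8 N2 O2",
  K = "C6 H12 N2 O1", E = "C5 H7 N1 O3",  M = "C5 H9 N1 O1 S1",
  H = "C6 H7 N3 O1",  F = "C9 H9 N1 O1",  R = "C6 H12 N4 O1",
  Y = "C9 H9 N1 O2",  W = "C11 H10 N2 O1"
)

#' Monoisotopic residue masses
#'
#' Named vector of residue (amino acid minus water) monoisotopic masses in
#' Da, derived from elemental compositions and the element mass table.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
residue_masses <- function() {
  vapply(RESIDUE_COMPOSITIONS, monoisotopic_mass, numeric(1))
}

#' Monoisotopic peptide mass
#'
#' @param sequence Peptide string of standard one-letter residue codes.
#' @param charge 0 for the neutral mass M; 1 for \[M+H\]+.
#' @return Mass (Da) or m/z for the singly protonated ion.
#' @export
peptide_mass <- function(sequence, charge = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_COMPOSITIONS))
  if (length(bad) > 0L) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  m <- sum(residue_masses()[aa]) + WATER_MASS
  if (charge == 1L) m <- m + PROTON_MASS
  m
}

#' Define a peptide modification
#'
#' A modification is a named elemental-composition gain on specific target
#' residues, optionally with diagnostic marker-ion neutral losses (losses
#' from the fully modified residue that produce low-mass diagnostic
#' fragment ions).
#'
#' @param name Modification name.
#' @param composition Composition string or `elemental_composition` added to
#'   the residue.
#' @param target_residues Character vector of one-letter residue codes (the
#'   sentinel `"n"` denotes the peptide N terminus).
#' @param marker_losses Named list of compositions lost from the fully
#'   modified residue to form each marker ion; names label the losses.
#' @param delta_mass Optional printed delta mass (Da) to validate against the
#'   composition; must agree within 5e-4 Da.
#' @return A `modification_spec` list.
#' @export
modification_spec <- function(name, composition, target_residues,
                              marker_losses = list(), delta_mass = NULL) {
  comp <- as_comp_arg(composition)
  mass <- monoisotopic_mass(comp)
  if (!is.null(delta_mass) && abs(mass - delta_mass) > 5e-4) {
    stop(sprintf("declared delta mass %.5f disagrees with composition mass %.5f",
                 delta_mass, mass))
  }
  valid_targets <- c(names(RESIDUE_COMPOSITIONS), "n")
  bad <- setdiff(target_residues, valid_targets)
  if (length(bad) > 0L) stop("invalid target residue(s): ", paste(bad, collapse = ", "))
  structure(list(
    name = name,
    composition = comp,
    delta_mass = mass,
    target_residues = target_residues,
    marker_losses = lapply(marker_losses, as_comp_arg)
  ), class = "modification_spec")
}

#' @export
print.modification_spec <- function(x, ...) {
  cat(sprintf("<modification> %s: +%.5f Da (+%s) on %s\n", x$name, x$delta_mass,
              format(x$composition), paste(x$target_residues, collapse = ",")))
  for (nm in names(x$marker_losses)) {
    cat(sprintf("  marker loss %s: -%s\n", nm, format(x$marker_losses[[nm]])))
  }
  invisible(x)
}

#' Built-in modification definitions
#'
#' `biotin_mod()`: biotinylation (+C10 H14 O2 N2 S1, +226.0776 Da) on lysine
#' and peptide N termini. `biotin_phenol_mod()`: biotin-phenol adduct
#' (+C18 H23 N3 O3 S1, +361.14601 Da) on tyrosine, with the three diagnostic
#' marker-ion neutral losses (-CO; -CONH3; -C17H18N2O3).
#'
#' @return A `modification_spec`.
#' @export
biotin_mod <- function() {
  modification_spec("biotin", "C10 H14 O2 N2 S1",
                    target_residues = c("K", "n"),
                    marker_losses = list(immonium_CO = "C1 O1"))
}

#' @rdname biotin_mod
#' @export
biotin_phenol_mod <- function() {
  modification_spec("biotin-phenol", "C18 H23 N3 O3 S1",
                    target_residues = "Y",
                    marker_losses = list(
                      minus_CO      = "C1 O1",
                      minus_CONH3   = "C1 O1 N1 H3",
                      minus_C17H18N2O3 = "C17 H18 N2 O3"
                    ))
}

## The biotin-on-lysine marker ion is conventionally quoted as 329.1 m/z
## with a -CO loss; the immonium-style formula used for the tyrosine marker
## ions gives 327.185 m/z for K + biotin - CO + proton. The arithmetic
## behind 329.1 is not recoverable; the quoted value is kept as a constant
## for reference and is not derived from marker_ion_mz().
BIOTIN_K_MARKER_MZ <- 329.1

#' Diagnostic marker-ion m/z
#'
#' m/z (singly protonated) of the marker ion formed by a neutral loss from a
#' fully modified residue: residue mass + modification delta mass - loss
#' mass + proton mass.
#'
#' @param residue One-letter residue code; must be in `mod$target_residues`.
#' @param mod A `modification_spec`.
#' @param loss Composition string or `elemental_composition` lost; the empty
#'   composition gives the protonated fully modified residue. The loss must
#'   be subtractable from the residue-plus-modification composition.
#' @return m/z in Th (singly charged).
#' @examples
#' marker_ion_mz("Y", biotin_phenol_mod(), "C1 O1")  # 497.2217
#' @export
marker_ion_mz <- function(residue, mod, loss = "") {
  stopifnot(inherits(mod, "modification_spec"))
  if (!(residue %in% mod$target_residues)) {
    stop("residue '", residue, "' is not a target of modification '", mod$name, "'")
  }
  loss <- as_comp_arg(loss)
  full <- comp_add(parse_composition(RESIDUE_COMPOSITIONS[[residue]]), mod$composition)
  remaining <- comp_subtract(full, loss)  # errors if loss exceeds composition
  monoisotopic_mass(remaining) + PROTON_MASS
}

#' Predicted marker-ion m/z values for a modification
#'
#' Applies [marker_ion_mz()] to every declared marker loss of a modification
#' on one residue.
#'
#' @param mod A `modification_spec`.
#' @param residue One-letter residue code (default: first target residue).
#' @return Named numeric vector of m/z values.
#' @export
predicted_marker_ions <- function(mod, residue = mod$target_residues[[1]]) {
  vapply(mod$marker_losses, function(l) marker_ion_mz(residue, mod, l), numeric(1))
}

#' Load modification definitions from a YAML config
#'
#' Each entry needs `name`, `composition` and `targets`; optional `losses`
#' (name -> composition) and `delta_mass` (validated against the
#' composition). The package ships its built-in definitions at
#' `system.file("extdata", "modifications.yml", package = "biotinsites")`.
#'
#' @param path Path to a YAML file.
#' @return Named list of `modification_spec` objects.
#' @export
load_modifications <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg, function(entry) {
    modification_spec(
      name = entry$name,
      composition = entry$composition,
      target_residues = unlist(entry$targets),
      marker_losses = if (is.null(entry$losses)) list() else entry$losses,
      delta_mass = entry$delta_mass
    )
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
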