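#' Monoisotopic residue mass table
#'
#' Glycosyl residue (anhydro) and substituent-group monoisotopic masses in
#' daltons, plus the terminal water and the sodium cation of the [M+Na]+
#' adduct. Values are sums of atomic monoisotopic masses:
#' hexose C6H10O5 162.0528, pentose C5H8O4 132.0423, deoxyhexose C6H10O4
#' 146.0579, hexuronic acid C6H8O6 176.0321, acetyl +C2H2O 42.0106, methyl
#' +CH2 14.0157, water 18.0106, Na 22.9898.
#'
#' @param override_file Optional path to a two-column TSV
#'   (\code{residue<TAB>mass}) overriding individual entries; residue names
#'   must be a subset of the default names.
#' @return Named numeric vector with elements \code{hexose},
#'   \code{pentose}, \code{deoxyhexose}, \code{hexuronic_acid},
#'   \code{acetyl}, \code{methyl}, \code{water}, \code{sodium}.
#' @export
residue_masses <- function(override_file = NULL) {
  masses <- c(hexose = 162.0528, pentose = 132.0423, deoxyhexose = 146.0579,
              hexuronic_acid = 176.0321, acetyl = 42.0106, methyl = 14.0157,
              water = 18.0106, sodium = 22.9898)
  if (!is.null(override_file)) {
    tab <- utils::read.delim(override_file, header = FALSE,
                             col.names = c("residue", "mass"),
                             comment.char = "#",
                             stringsAsFactors = FALSE)
    unknown <- setdiff(tab$residue, names(masses))
    if (length(unknown))
      stop("unknown residue in mass override: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    masses[tab$residue] <- tab$mass
  }
  if (any(masses <= 0)) stop("residue masses must be positive", call. = FALSE)
  # sanity: hexose and pentose differ by one CH2O (table rounding leaves
  # the difference within ~1e-4 of 30.0106)
  if (abs((masses[["hexose"]] - masses[["pentose"]]) - 30.0106) > 2e-4)
    stop("hexose - pentose mass difference must equal CH2O (30.0106 Da)",
         call. = FALSE)
  masses
}

#' Sodiated monoisotopic mass of an oligosaccharide composition
#'
#' Mass of the [M+Na]+ ion of the unreduced oligomer: the sum of anhydro
#' residue masses and ester-group masses, plus one terminal water and one
#' sodium. Positive-mode MALDI of neutral glycans from a DHB-type matrix
#' is dominated by sodium adducts, and this model reproduces the nominal
#' m/z of every annotated digest ion in the apple fingerprinting study.
#'
#' @param comp An \code{\link{oligo_composition}} or a code string parsed
#'   with \code{\link{parse_oligo_code}}.
#' @param masses A mass table from \code{\link{residue_masses}}.
#' @return Mass in Da (numeric scalar).
#' @examples
#' sodiated_mass("Hex4a1")  # 731.22
#' sodiated_mass("XXXG")    # 1085.34
#' @export
sodiated_mass <- function(comp, masses = residue_masses()) {
  if (is.character(comp)) comp <- parse_oligo_code(comp)
  stopifnot(inherits(comp, "oligo_composition"))
  sum(unclass(comp) * masses[c("hexose", "pentose", "deoxyhexose",
                               "hexuronic_acid", "methyl", "acetyl")]) +
    masses[["water"]] + masses[["sodium"]]
}

#' Nominal (integer) m/z
#'
#' Truncates the monoisotopic m/z toward zero, matching how annotated
#' ions are reported (1085 for the XXXG sodium adduct at 1085.34, and
#' 1597 for XLFGa1 at 1597.51 — the reported integers drop the decimal
#' part rather than rounding it).
#'
#' @param mz Numeric m/z value(s).
#' @return Integer vector.
#' @export
nominal_mz <- function(mz) {
  as.integer(trunc(mz))
}

#' Enumerate compositions matching an observed m/z
#'
#' Inverse of \code{\link{sodiated_mass}}: exhaustively lists the
#' compositions in each requested search family whose sodiated mass lies
#' within \code{tol} of \code{mz}. Families:
#' \describe{
#'   \item{\code{"hexose-series"}}{Hex oligomers with 0..acetyl-ceiling
#'     acetyl groups (galactoglucomannan fragments).}
#'   \item{\code{"pentose-series"}}{Pen oligomers with optional uronic
#'     acid, methyl and acetyl substituents (glucuronoarabinoxylan
#'     fragments).}
#'   \item{\code{"xygo-grammar"}}{Compositions reachable from some
#'     xyloglucan letter code (so n_hex = n_backbone + branch hexoses with
#'     the grammar's structural constraints).}
#'   \item{\code{"unconstrained"}}{Any mixed composition under the
#'     modifier ceilings.}
#' }
#' Modifier ceilings bound the search: total residues <= \code{max_residues},
#' acetyl <= backbone (hexose + pentose) residues, methyl <= uronic acids,
#' and uronic acids <= backbone residues (in this annotation space uronic
#' acids occur as glucuronoxylan-type substituents on a neutral backbone,
#' never as a free uronic-acid homo-oligomer).
#'
#' @param mz Observed m/z (Da), must exceed the water+sodium floor.
#' @param tol Absolute tolerance (Da).
#' @param families Character vector of family names (see above).
#' @param masses Mass table.
#' @param max_residues Residue-count ceiling (default 12).
#' @param max_acetyl Optional cap on acetyl count, tightening the
#'   acetyl <= backbone ceiling (the annotated digest ions carry at most
#'   2 acetyl groups; the digest-default annotation libraries use that
#'   cap).
#' @return List of \code{\link{oligo_composition}} objects sorted by
#'   absolute mass error; attribute \code{"error"} on each element carries
#'   the signed error (computed - observed).
#' @export
enumerate_compositions <- function(mz, tol,
                                   families = c("hexose-series",
                                                "pentose-series"),
                                   masses = residue_masses(),
                                   max_residues = 12L,
                                   max_acetyl = Inf) {
  known <- c("hexose-series", "pentose-series", "xygo-grammar",
             "unconstrained")
  if (length(families) == 0)
    stop("at least one search family is required", call. = FALSE)
  families <- match.arg(families, known, several.ok = TRUE)
  floor_mass <- masses[["water"]] + masses[["sodium"]]
  if (!is.finite(mz) || mz <= floor_mass)
    stop("mz must exceed the water + sodium mass (", round(floor_mass, 2),
         " Da)", call. = FALSE)
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)

  hits <- list()
  add <- function(comp) {
    m <- sodiated_mass(comp, masses)
    if (abs(m - mz) <= tol) {
      attr(comp, "error") <- m - mz
      hits[[length(hits) + 1L]] <<- comp
    }
  }

  if ("hexose-series" %in% families) {
    for (h in 1:max_residues) for (a in 0:min(h, max_acetyl))
      add(oligo_composition(n_hex = h, n_acetyl = a))
  }
  if ("pentose-series" %in% families) {
    for (p in 1:max_residues) for (u in 0:min(p, max_residues - p))
      for (m in 0:u) for (a in 0:min(p, max_acetyl))
        add(oligo_composition(n_pen = p, n_hexa = u, n_methyl = m,
                              n_acetyl = a))
  }
  if ("xygo-grammar" %in% families) {
    # a code with g G's, x X's, l L's, f F's gives
    # hex = g + x + 2l + 2f, pen = x + l + f, dhex = f; backbone <= 8
    for (g in 0:8) for (x in 0:(8 - g)) for (l in 0:(8 - g - x))
      for (f in 0:(8 - g - x - l)) {
        nb <- g + x + l + f
        if (nb < 1) next
        nh <- g + x + 2L * l + 2L * f
        for (a in 0:min(nb, max_acetyl))
          add(oligo_composition(n_hex = nh, n_pen = x + l + f, n_dhex = f,
                                n_acetyl = a))
      }
  }
  if ("unconstrained" %in% families) {
    mr <- max_residues
    for (h in 0:mr) for (p in 0:(mr - h)) for (d in 0:(mr - h - p))
      for (u in 0:min(h + p, mr - h - p - d)) {
        nres <- h + p + d + u
        if (nres < 1) next
        for (m in 0:u) for (a in 0:min(h + p, max_acetyl)) {
          add(oligo_composition(n_hex = h, n_pen = p, n_dhex = d, n_hexa = u,
                                n_methyl = m, n_acetyl = a))
        }
      }
  }

  # drop duplicates found via multiple families, keep smallest |error| first
  if (length(hits) > 1) {
    key <- vapply(hits, function(cc) paste(unclass(cc), collapse = ","), "")
    hits <- hits[!duplicated(key)]
  }
  hits[order(vapply(hits, function(cc) abs(attr(cc, "error")), 0))]
}
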