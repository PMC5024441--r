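#' Oligosaccharide composition
#'
#' Constructs a glycosyl-residue composition: counts of hexose, pentose,
#' deoxyhexose (fucose), hexuronic acid residues, plus methyl- and
#' acetyl-ester substituents. This is the common currency of the package:
#' both the xyloglucan letter nomenclature (\code{\link{parse_xygo_code}})
#' and the Hex/Pen composition nomenclature
#' (\code{\link{parse_composition_code}}) reduce to it, and
#' \code{\link{sodiated_mass}} consumes it.
#'
#' @param n_hex,n_pen,n_dhex,n_hexa Non-negative residue counts (hexose,
#'   pentose, deoxyhexose, hexuronic acid).
#' @param n_methyl,n_acetyl Non-negative ester substituent counts.
#' @return An object of class \code{"oligo_composition"}: a named integer
#'   vector with elements \code{n_hex}, \code{n_pen}, \code{n_dhex},
#'   \code{n_hexa}, \code{n_methyl}, \code{n_acetyl}.
#' @examples
#' oligo_composition(n_hex = 4, n_acetyl = 1)  # Hex4a1
#' @export
oligo_composition <- function(n_hex = 0, n_pen = 0, n_dhex = 0, n_hexa = 0,
                              n_methyl = 0, n_acetyl = 0) {
  counts <- c(n_hex = n_hex, n_pen = n_pen, n_dhex = n_dhex, n_hexa = n_hexa,
              n_methyl = n_methyl, n_acetyl = n_acetyl)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers", call. = FALSE)
  structure(as.integer(round(counts)),
            names = names(counts), class = "oligo_composition")
}

#' @export
print.oligo_composition <- function(x, ...) {
  lab <- tryCatch(format_code(x), error = function(e) NULL)
  parts <- paste0(names(x), "=", unclass(x))[x > 0]
  if (length(parts) == 0) parts <- "empty"
  cat("<oligo_composition", if (!is.null(lab)) paste0(" ", lab), "> ",
      paste(parts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`==.oligo_composition` <- function(e1, e2) {
  all(unclass(e1) == unclass(e2))
}

n_residues <- function(comp) {
  sum(comp[c("n_hex", "n_pen", "n_dhex", "n_hexa")])
}

#' Parse a xyloglucan letter code
#'
#' The xyloglucan oligosaccharide nomenclature encodes each backbone
#' beta-1,4-glucose residue with one uppercase letter describing its side
#' chain: \code{G} bare glucose; \code{X} glucose carrying an alpha-xylosyl
#' residue; \code{L} the X structure extended by a beta-galactosyl residue;
#' \code{F} the L structure further extended by an alpha-fucose. An
#' optional trailing \code{a<count>} suffix gives the number of acetyl
#' ester groups (e.g. \code{"XXFGa1"}).
#'
#' Residue expansions: G -> 1 Hex; X -> 1 Hex + 1 Pen; L -> 2 Hex + 1 Pen;
#' F -> 2 Hex + 1 Pen + 1 dHex.
#'
#' @param code Character scalar such as \code{"XXXG"} or \code{"XLFGa1"}.
#' @return An \code{\link{oligo_composition}}.
#' @examples
#' parse_xygo_code("XXFGa1")
#' @export
parse_xygo_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code))
    stop("xyloglucan code must be a non-empty character scalar", call. = FALSE)
  m <- regmatches(code, regexec("^([GXLF]+)(a([0-9]+))?$", code))[[1]]
  if (length(m) == 0) {
    bad <- regmatches(code, regexpr("[^GXLFa0-9]", code))
    if (length(bad) == 1 && nzchar(bad))
      stop(sprintf("malformed xyloglucan code '%s': unexpected character '%s'",
                   code, bad), call. = FALSE)
    stop(sprintf(paste0("malformed xyloglucan code '%s': expected letters ",
                        "G/X/L/F with optional trailing a<count>"), code),
         call. = FALSE)
  }
  letters <- strsplit(m[2], "")[[1]]
  n_ac <- if (nzchar(m[3])) as.integer(m[4]) else 0L
  # per-letter (hex, pen, dhex) expansion
  expand <- list(G = c(1L, 0L, 0L), X = c(1L, 1L, 0L),
                 L = c(2L, 1L, 0L), F = c(2L, 1L, 1L))
  tot <- Reduce(`+`, expand[letters])
  oligo_composition(n_hex = tot[1], n_pen = tot[2], n_dhex = tot[3],
                    n_acetyl = n_ac)
}

#' Parse a Hex/Pen composition code
#'
#' Composition codes name an oligomer by its residue family and counts:
#' \code{Hex} (hexose) or \code{Pen} (pentose) followed by the residue
#' count, then optional \code{U} (hexuronic acid), \code{m} (methyl ester)
#' and \code{a} (acetyl ester) counts, in that order. \code{"Pen5U1m1a1"}
#' is 5 pentoses, 1 uronic acid, 1 methyl and 1 acetyl group.
#'
#' @param code Character scalar such as \code{"Hex4a1"}.
#' @return An \code{\link{oligo_composition}}.
#' @examples
#' parse_composition_code("Pen5U1m1a1")
#' @export
parse_composition_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code))
    stop("composition code must be a non-empty character scalar", call. = FALSE)
  m <- regmatches(code,
                  regexec("^(Hex|Pen)([0-9]+)(U([0-9]+))?(m([0-9]+))?(a([0-9]+))?$",
                          code))[[1]]
  if (length(m) == 0)
    stop(sprintf(paste0("malformed composition code '%s': expected ",
                        "(Hex|Pen)<n> with optional U<n>, m<n>, a<n>"), code),
         call. = FALSE)
  n_fam <- as.integer(m[3])
  cnt <- function(i) if (nzchar(m[i])) as.integer(m[i + 1L]) else 0L
  oligo_composition(
    n_hex = if (m[2] == "Hex") n_fam else 0L,
    n_pen = if (m[2] == "Pen") n_fam else 0L,
    n_hexa = cnt(4L), n_methyl = cnt(6L), n_acetyl = cnt(8L))
}

#' Parse either nomenclature
#'
#' Dispatches to \code{\link{parse_composition_code}} for codes starting
#' with \code{Hex}/\code{Pen} and to \code{\link{parse_xygo_code}}
#' otherwise. Also accepts the generalized mixed labels the annotator
#' emits for compositions outside either canonical nomenclature
#' (e.g. \code{"Hex5Pen3dHex1a1"} for the XXFGa1 composition).
#'
#' @param code Character scalar.
#' @return An \code{\link{oligo_composition}}.
#' @export
parse_oligo_code <- function(code) {
  if (!grepl("^(Hex|Pen)", code)) return(parse_xygo_code(code))
  m <- regmatches(code, regexec(paste0(
    "^(Hex([0-9]+))?(Pen([0-9]+))?(dHex([0-9]+))?",
    "(U([0-9]+))?(m([0-9]+))?(a([0-9]+))?$"), code))[[1]]
  if (length(m) == 0 || !nzchar(paste0(m[2], m[4], m[6])))
    stop(sprintf(paste0("malformed composition code '%s': expected ",
                        "(Hex|Pen)<n> with optional U<n>, m<n>, a<n>"), code),
         call. = FALSE)
  cnt <- function(i) if (nzchar(m[i])) as.integer(m[i + 1L]) else 0L
  oligo_composition(n_hex = cnt(2L), n_pen = cnt(4L), n_dhex = cnt(6L),
                    n_hexa = cnt(8L), n_methyl = cnt(10L),
                    n_acetyl = cnt(12L))
}

#' Format a composition as a Hex/Pen code
#'
#' Canonical inverse of \code{\link{parse_composition_code}} on the
#' Hex/Pen family: \code{parse_composition_code(format_code(x))} recovers
#' \code{x} whenever \code{x} carries no deoxyhexose. Compositions with
#' deoxyhexose (fucosylated xyloglucan fragments) have no Hex/Pen code and
#' raise an error directing the caller to the letter nomenclature. Mixed
#' hexose + pentose compositions are likewise rejected.
#'
#' @param comp An \code{\link{oligo_composition}}.
#' @return Character scalar, e.g. \code{"Pen4U1m1"}.
#' @export
format_code <- function(comp) {
  stopifnot(inherits(comp, "oligo_composition"))
  if (comp[["n_dhex"]] > 0)
    stop(paste("compositions containing deoxyhexose have no Hex/Pen code;",
               "use the xyloglucan letter nomenclature (XygoCode)"),
         call. = FALSE)
  if (comp[["n_hex"]] > 0 && comp[["n_pen"]] > 0)
    stop("mixed hexose/pentose compositions have no canonical Hex/Pen code",
         call. = FALSE)
  fam <- if (comp[["n_pen"]] > 0) c("Pen", comp[["n_pen"]])
         else c("Hex", comp[["n_hex"]])
  if (as.integer(fam[2]) == 0L && comp[["n_hexa"]] == 0L)
    stop("empty composition has no code", call. = FALSE)
  paste0(fam[1], fam[2],
         if (comp[["n_hexa"]] > 0) paste0("U", comp[["n_hexa"]]) else "",
         if (comp[["n_methyl"]] > 0) paste0("m", comp[["n_methyl"]]) else "",
         if (comp[["n_acetyl"]] > 0) paste0("a", comp[["n_acetyl"]]) else "")
}
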