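DIGESTS <- c("mannanase", "xylanase", "glucanase")
STAGES <- c("60DAF", "110DAF", "H", "1M", "2M")
GENOTYPES <- c("H074", "H097", "I016", "I062", "I095", "V034", "V083", "W029")
PLOTS <- c("PH", "P12")

#' Digest-specific reference ions
#'
#' Nominal m/z of the ion on which each digest's intensities are
#' normalized: 1085 (XXXG) for glucanase, 731 (Hex4a1) for mannanase and
#' 655 (Pen3U1a1) for xylanase hydrolysates.
#'
#' @return Named numeric vector keyed by digest.
#' @export
digest_reference_mz <- function() {
  c(glucanase = 1085, mannanase = 731, xylanase = 655)
}

#' Construct a digest mass spectrum
#'
#' A centroided peak list tagged with its digest enzyme and sample
#' metadata. Peaks are stored sorted by m/z; duplicate m/z values (within
#' 1e-6 Da) are rejected.
#'
#' @param mz,intensity Numeric vectors of equal length; intensities >= 0.
#' @param digest One of \code{"mannanase"}, \code{"xylanase"},
#'   \code{"glucanase"}.
#' @param sample_id Sample identifier.
#' @param stage Developmental stage, one of 60DAF, 110DAF, H, 1M, 2M (or
#'   NA).
#' @param replicate Replicate index.
#' @return Object of class \code{"digest_spectrum"}: a list with elements
#'   \code{peaks} (data.frame mz, intensity), \code{digest},
#'   \code{sample_id}, \code{stage}, \code{replicate}, \code{normalized}.
#' @export
digest_spectrum <- function(mz, intensity, digest, sample_id = "sample",
                            stage = NA_character_, replicate = 1L) {
  digest <- match.arg(digest, DIGESTS)
  if (!is.na(stage)) stage <- match.arg(stage, STAGES)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite peak values", call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (length(mz) > 1 && any(diff(mz) < 1e-6))
    stop("duplicate m/z values within 1e-6 Da", call. = FALSE)
  structure(list(peaks = data.frame(mz = mz, intensity = intensity),
                 digest = digest, sample_id = sample_id, stage = stage,
                 replicate = as.integer(replicate), normalized = FALSE),
            class = "digest_spectrum")
}

#' @export
print.digest_spectrum <- function(x, ...) {
  cat(sprintf("<digest_spectrum> %s | %s | stage %s | rep %d | %d peaks%s\n",
              x$sample_id, x$digest, x$stage, x$replicate, nrow(x$peaks),
              if (x$normalized) " (reference-normalized)" else ""))
  invisible(x)
}

#' Read a two-column peak list
#'
#' Reads a tab- or whitespace-delimited file of (m/z, intensity) rows;
#' lines starting with \code{#} are comments. With
#' \code{enforce_window = TRUE}, peaks outside the acquisition window
#' (default m/z 500-3000, closed interval) are dropped and the dropped
#' count is reported via \code{message()} and the \code{"n_dropped"}
#' attribute.
#'
#' @param path File path.
#' @param digest Digest enzyme of the hydrolysate.
#' @param sample_id,stage,replicate Sample metadata (see
#'   \code{\link{digest_spectrum}}).
#' @param enforce_window Drop peaks outside \code{window}?
#' @param window Length-2 numeric acquisition window in Da.
#' @return A \code{\link{digest_spectrum}}.
#' @export
read_peaklist <- function(path, digest, sample_id = basename(path),
                          stage = NA_character_, replicate = 1L,
                          enforce_window = TRUE, window = c(500, 3000)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty peak list: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  lineno <- which(keep)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 2 ||
        anyNA(suppressWarnings(as.numeric(fields[[i]][1:2]))))
      stop(sprintf("non-numeric peak fields at line %d of %s", lineno[i],
                   path), call. = FALSE)
  }
  mz <- vapply(fields, function(f) as.numeric(f[1]), 0)
  intensity <- vapply(fields, function(f) as.numeric(f[2]), 0)
  n_dropped <- 0L
  if (enforce_window) {
    inside <- mz >= window[1] & mz <= window[2]
    n_dropped <- sum(!inside)
    if (n_dropped > 0)
      message(n_dropped, " peak(s) outside the m/z window [", window[1], ", ",
              window[2], "] dropped from ", path)
    mz <- mz[inside]; intensity <- intensity[inside]
  }
  spec <- digest_spectrum(mz, intensity, digest, sample_id, stage, replicate)
  attr(spec, "n_dropped") <- n_dropped
  spec
}

#' Default annotation library of a digest
#'
#' The composition search space used by \code{\link{annotate_spectrum}} in
#' \code{"digest-default"} mode: mannanase digests are searched against the
#' hexose series (galactoglucomannan fragments, DP 1-8, 0-2 acetyl) plus
#' the pentose series (xylanase carry-over); xylanase digests against the
#' pentose series; glucanase digests against xyloglucan letter-code
#' compositions plus both series (all three families are observed in
#' glucanase hydrolysates).
#'
#' @param digest Digest enzyme.
#' @return Character vector of search family names understood by
#'   \code{\link{enumerate_compositions}}.
#' @export
digest_library_families <- function(digest) {
  digest <- match.arg(digest, DIGESTS)
  switch(digest,
         mannanase = c("hexose-series", "pentose-series"),
         xylanase = "pentose-series",
         glucanase = c("xygo-grammar", "hexose-series", "pentose-series"))
}

#' Annotate a digest spectrum
#'
#' Assigns each peak every library composition whose sodiated monoisotopic
#' mass lies within \code{tol} of the observed m/z. A peak with more than
#' one assignment is flagged ambiguous; unassigned peaks carry empty
#' assignment lists.
#'
#' @param spec A \code{\link{digest_spectrum}}.
#' @param tol Mass tolerance in Da (default 0.3).
#' @param library_mode \code{"digest-default"} (search families chosen by
#'   the digest, see \code{\link{digest_library_families}}), an explicit
#'   character vector of composition codes, or \code{"unconstrained"}.
#' @param masses Mass table.
#' @param max_residues Enumeration ceiling (see
#'   \code{\link{enumerate_compositions}}).
#' @return Object of class \code{"annotated_spectrum"}: the spectrum plus
#'   \code{annotations}, a list (one element per peak) of data.frames with
#'   columns \code{code}, \code{mass}, \code{error}, and a logical
#'   \code{ambiguous} vector.
#' @export
annotate_spectrum <- function(spec, tol = 0.3, library_mode = "digest-default",
                              masses = residue_masses(), max_residues = 12L) {
  stopifnot(inherits(spec, "digest_spectrum"))
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)

  explicit <- length(library_mode) > 1 ||
    !library_mode %in% c("digest-default", "unconstrained")
  if (explicit) {
    lib <- lapply(library_mode, parse_oligo_code)
    lib_mass <- vapply(lib, sodiated_mass, 0, masses = masses)
    lib_code <- library_mode
    lookup <- function(mz) {
      hit <- which(abs(lib_mass - mz) <= tol)
      data.frame(code = lib_code[hit], mass = lib_mass[hit],
                 error = lib_mass[hit] - mz, stringsAsFactors = FALSE)
    }
  } else {
    fams <- if (identical(library_mode, "unconstrained")) "unconstrained"
            else digest_library_families(spec$digest)
    # digest libraries cap acetylation at 2 (the observed annotation space)
    acetyl_cap <- if (identical(library_mode, "unconstrained")) Inf else 2L
    lookup <- function(mz) {
      hits <- enumerate_compositions(mz, tol, families = fams,
                                     masses = masses,
                                     max_residues = max_residues,
                                     max_acetyl = acetyl_cap)
      data.frame(
        code = vapply(hits, composition_label, ""),
        mass = vapply(hits, function(h) mz + attr(h, "error"), 0),
        error = vapply(hits, function(h) attr(h, "error"), 0),
        stringsAsFactors = FALSE)
    }
  }

  ann <- lapply(spec$peaks$mz, lookup)
  out <- spec
  out$annotations <- ann
  out$ambiguous <- vapply(ann, nrow, 0L) > 1L
  class(out) <- c("annotated_spectrum", "digest_spectrum")
  out
}

# Hex/Pen code where one exists, xyloglucan-style composition label otherwise
composition_label <- function(comp) {
  tryCatch(format_code(comp), error = function(e) {
    parts <- c(Hex = comp[["n_hex"]], Pen = comp[["n_pen"]],
               dHex = comp[["n_dhex"]], U = comp[["n_hexa"]],
               m = comp[["n_methyl"]], a = comp[["n_acetyl"]])
    paste0(names(parts)[parts > 0], parts[parts > 0], collapse = "")
  })
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  NextMethod()
  n_ass <- sum(vapply(x$annotations, nrow, 0L) > 0)
  cat(sprintf("  %d/%d peaks assigned, %d ambiguous\n", n_ass, nrow(x$peaks),
              sum(x$ambiguous)))
  invisible(x)
}

#' Normalize spectrum intensities to the digest reference ion
#'
#' Divides every intensity by the intensity of the digest's reference peak
#' (1085/731/655 for glucanase/mannanase/xylanase), so the reference maps
#' to 1.0 and all other peaks become relative intensities. If several
#' peaks fall within \code{tol} of the reference m/z, the most intense one
#' is used (reference ions are major fragments). Idempotent.
#'
#' @param spec A \code{\link{digest_spectrum}}.
#' @param tol Matching tolerance around the reference m/z (Da).
#' @return The spectrum with relative intensities and
#'   \code{normalized = TRUE}.
#' @export
normalize_to_reference <- function(spec, tol = 0.5) {
  stopifnot(inherits(spec, "digest_spectrum"))
  ref <- digest_reference_mz()[[spec$digest]]
  near <- which(abs(spec$peaks$mz - ref) <= tol)
  if (length(near) == 0)
    stop(sprintf(
      "no reference peak for %s digest: expected an ion near m/z %g",
      spec$digest, ref), call. = FALSE)
  ref_int <- max(spec$peaks$intensity[near])
  if (ref_int <= 0)
    stop("reference peak has zero intensity", call. = FALSE)
  spec$peaks$intensity <- spec$peaks$intensity / ref_int
  spec$normalized <- TRUE
  spec
}

#' Assemble a samples x ions intensity matrix
#'
#' Collects normalized intensities for a fixed roster of ions across
#' spectra. Replicate spectra are kept as separate rows; averaging across
#' replicates is an explicit downstream choice. An ion absent from a
#' spectrum contributes 0; a roster ion observed in no spectrum triggers a
#' warning but its all-zero column is retained.
#'
#' @param spectra List of \code{\link{digest_spectrum}} objects (normally
#'   reference-normalized).
#' @param roster Character vector of composition codes defining the
#'   columns.
#' @param tol Peak-matching tolerance (Da).
#' @param masses Mass table.
#' @return Numeric matrix (spectra x roster codes) with a \code{meta}
#'   attribute data.frame (sample_id, digest, stage, replicate).
#' @export
build_intensity_matrix <- function(spectra, roster, tol = 0.3,
                                   masses = residue_masses()) {
  stopifnot(length(spectra) > 0, length(roster) > 0)
  roster_mass <- vapply(roster, function(code)
    sodiated_mass(parse_oligo_code(code), masses), 0)
  mat <- t(vapply(spectra, function(sp) {
    vapply(roster_mass, function(m) {
      hit <- which(abs(sp$peaks$mz - m) <= tol)
      if (length(hit) == 0) 0 else max(sp$peaks$intensity[hit])
    }, 0)
  }, numeric(length(roster))))
  colnames(mat) <- roster
  rownames(mat) <- vapply(spectra, function(sp)
    paste(sp$sample_id, sp$replicate, sep = "_"), "")
  if (any(colSums(mat != 0) == 0))
    warning("roster ion(s) never observed: ",
            paste(roster[colSums(mat != 0) == 0], collapse = ", "),
            call. = FALSE)
  attr(mat, "meta") <- data.frame(
    sample_id = vapply(spectra, `[[`, "", "sample_id"),
    digest = vapply(spectra, `[[`, "", "digest"),
    stage = vapply(spectra, `[[`, "", "stage"),
    replicate = vapply(spectra, function(sp) sp$replicate, 0L),
    stringsAsFactors = FALSE)
  mat
}
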