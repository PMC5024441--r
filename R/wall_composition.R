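#' Starch-corrected non-starch polysaccharide content
#'
#' NSP (% of AIM dry weight) is the total cell-wall sugar content minus
#' the starch-derived glucose, floored at zero. AIM = alcohol insoluble
#' material, the crude cell-wall preparation.
#'
#' @param total_sugars_pct_aim Total sugars, \% AIM.
#' @param starch_pct_aim Starch, \% AIM.
#' @return NSP in \% AIM.
#' @examples
#' compute_nsp(98.5, 47.1)  # 51.4
#' @export
compute_nsp <- function(total_sugars_pct_aim, starch_pct_aim) {
  if (any(starch_pct_aim < 0) || any(total_sugars_pct_aim < 0))
    stop("percentages must be non-negative", call. = FALSE)
  if (any(total_sugars_pct_aim > 110))
    stop("total sugars exceed the 110% analytical tolerance", call. = FALSE)
  if (any(starch_pct_aim > total_sugars_pct_aim))
    stop("starch content exceeds total sugars", call. = FALSE)
  pmax(total_sugars_pct_aim - starch_pct_aim, 0)
}

#' Express an analyte as a percentage of NSP
#'
#' @param analyte_pct_aim Analyte content, \% AIM.
#' @param nsp_pct_aim NSP content, \% AIM (> 0).
#' @param stage Optional stage label used in error messages.
#' @return Analyte content, \% NSP.
#' @export
pct_of_nsp <- function(analyte_pct_aim, nsp_pct_aim, stage = NULL) {
  if (any(nsp_pct_aim <= 0))
    stop("NSP must be positive",
         if (!is.null(stage)) paste0(" (stage ", stage, ")"), call. = FALSE)
  analyte_pct_aim / nsp_pct_aim * 100
}

#' Degree of methylesterification of pectin
#'
#' DM = moles of methanol released on saponification per 100 moles of
#' galacturonic acid. Both inputs are \% NSP by weight; the molar
#' conversion uses methanol 32.042 g/mol and the anhydro-galacturonic-acid
#' residue 176.126 g/mol (the residue mass, not the 194 free acid, is what
#' the colorimetric uronic-acid assay quantifies in the polymer).
#'
#' @param methanol_pct_nsp Methanol (methyl ester) content, \% NSP.
#' @param gala_pct_nsp Galacturonic acid (uronic acid) content, \% NSP.
#' @return DM, mol methanol / 100 mol GalA.
#' @examples
#' degree_methylesterification(2.8, 22.4)  # ~68.7
#' @export
degree_methylesterification <- function(methanol_pct_nsp, gala_pct_nsp) {
  if (any(gala_pct_nsp <= 0))
    stop("galacturonic acid content must be positive", call. = FALSE)
  if (any(methanol_pct_nsp < 0))
    stop("methanol content must be non-negative", call. = FALSE)
  (methanol_pct_nsp / 32.042) / (gala_pct_nsp / 176.126) * 100
}

#' Fraction of a sugar released by a digest step
#'
#' Expresses the amount of a sugar solubilized by one sequential
#' treatment as a percentage of that sugar's initial content in the NSP
#' fraction.
#'
#' @param released_pct_nsp Released amount, \% NSP.
#' @param initial_pct_nsp Initial content, \% NSP (> 0; a zero initial
#'   content makes the fraction undefined and raises an error rather than
#'   reporting 0).
#' @return Release fraction, \% of initial content.
#' @examples
#' release_fraction(5.1, 31.0)  # 16.45
#' @export
release_fraction <- function(released_pct_nsp, initial_pct_nsp) {
  if (any(initial_pct_nsp <= 0))
    stop("initial sugar content is zero: release fraction undefined",
         call. = FALSE)
  if (any(released_pct_nsp < 0))
    stop("released amount must be non-negative", call. = FALSE)
  released_pct_nsp / initial_pct_nsp * 100
}

#' Stage-wise one-way ANOVA with the study's significance gate
#'
#' Classical fixed-effects one-way ANOVA across developmental stages,
#' flagged significant at p < 1e-4 (the study's gate for chemical data).
#' Optionally computes the three named pairwise stage contrasts reported
#' as letters in the release tables (a: 60DAF vs H, b: H vs 2M, c: 60DAF
#' vs 2M), each as a two-group ANOVA at the same gate.
#'
#' @param values Numeric vector of observations.
#' @param stage Factor/character vector of stage labels, same length.
#' @param alpha Significance gate (default 1e-4).
#' @param contrasts Compute the pairwise letter contrasts?
#' @return List with \code{f}, \code{p}, \code{significant}, and (when
#'   requested and the stages are present) \code{contrasts}, a data.frame
#'   with columns letter, stage1, stage2, f, p, significant.
#' @export
stage_anova <- function(values, stage, alpha = 1e-4, contrasts = TRUE) {
  stage <- as.character(stage)
  if (length(values) != length(stage))
    stop("values and stage must have equal length", call. = FALSE)
  tab <- table(stage)
  if (length(tab) < 2) stop("need at least 2 stage groups", call. = FALSE)
  if (any(tab < 2))
    stop("each stage group needs >= 2 observations (violated by: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")", call. = FALSE)
  one_way <- function(v, g) {
    if (stats::var(v) == 0) return(list(f = 0, p = 1))
    a <- stats::anova(stats::aov(v ~ factor(g)))
    list(f = a[["F value"]][1], p = a[["Pr(>F)"]][1])
  }
  overall <- one_way(values, stage)
  out <- list(f = overall$f, p = overall$p,
              significant = overall$p < alpha)
  if (contrasts) {
    pairs <- list(a = c("60DAF", "H"), b = c("H", "2M"), c = c("60DAF", "2M"))
    pairs <- Filter(function(p) all(p %in% stage), pairs)
    if (length(pairs)) {
      out$contrasts <- do.call(rbind, lapply(names(pairs), function(nm) {
        sel <- stage %in% pairs[[nm]]
        cw <- one_way(values[sel], stage[sel])
        data.frame(letter = nm, stage1 = pairs[[nm]][1],
                   stage2 = pairs[[nm]][2], f = cw$f, p = cw$p,
                   significant = cw$p < alpha, stringsAsFactors = FALSE)
      }))
    }
  }
  out
}

#' Unit-tagged composition table
#'
#' Wraps a stage x analyte data.frame with an explicit unit tag per
#' analyte column (\code{"%AIM"} for starch/NSP, \code{"%NSP"} for sugars
#' and esters, \code{"DM"} for the dimensionless per-100 ratio). The tags
#' enforce unit discipline: \code{\link{check_same_unit}} rejects
#' arithmetic that silently mixes \%AIM and \%NSP quantities.
#'
#' @param df data.frame with a \code{stage} column and numeric analyte
#'   columns.
#' @param units Named character vector mapping every analyte column to its
#'   unit tag.
#' @return The data.frame with class \code{"composition_table"} and a
#'   \code{"units"} attribute.
#' @export
composition_table <- function(df, units) {
  analytes <- setdiff(names(df), c("stage", "replicate"))
  if (!all(analytes %in% names(units)))
    stop("missing unit tag for: ",
         paste(setdiff(analytes, names(units)), collapse = ", "),
         call. = FALSE)
  if (!all(units %in% c("%AIM", "%NSP", "DM")))
    stop("unit tags must be %AIM, %NSP or DM", call. = FALSE)
  structure(df, units = units[analytes], class = c("composition_table",
                                                   "data.frame"))
}

#' Units of a composition table column
#' @param tab A \code{\link{composition_table}}.
#' @param column Analyte column name.
#' @return Unit tag string.
#' @export
column_unit <- function(tab, column) {
  u <- attr(tab, "units")
  if (is.null(u) || !column %in% names(u))
    stop("no unit tag for column '", column, "'", call. = FALSE)
  u[[column]]
}

#' Assert two columns share a unit before combining them
#'
#' @param tab A \code{\link{composition_table}}.
#' @param col1,col2 Analyte column names.
#' @return Invisibly, the shared unit tag; error if the tags differ.
#' @export
check_same_unit <- function(tab, col1, col2) {
  u1 <- column_unit(tab, col1); u2 <- column_unit(tab, col2)
  if (u1 != u2)
    stop(sprintf(
      "unit mismatch: '%s' is %s but '%s' is %s; convert explicitly first",
      col1, u1, col2, u2), call. = FALSE)
  invisible(u1)
}
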