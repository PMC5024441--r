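# Bundled reference datasets: printed cell-wall composition of 'HIVW' apple
# fruit across five developmental/storage stages, used as pipeline inputs and
# as the ground truth the accounting functions are checked against.

#' Apple cell-wall composition across development and storage
#'
#' Published composition of apple fruit alcohol-insoluble material at five
#' stages (60DAF, 110DAF, harvest, 1 and 2 months cold storage): starch
#' and NSP as \% of AIM dry weight, individual sugars / uronic acids /
#' ester contents as \% of NSP, and the degree of methylesterification
#' (DM). Values are the printed means; \code{apple_wall_composition_sd()}
#' returns the matching standard deviations.
#'
#' @return A \code{\link{composition_table}} (5 stages x 13 analytes).
#' @export
apple_wall_composition <- function() {
  df <- data.frame(
    stage = c("60DAF", "110DAF", "H", "1M", "2M"),
    starch = c(18.0, 47.1, 13.4, 3.8, 1.3),
    nsp    = c(69.2, 51.5, 82.3, 87.4, 90.2),
    rha    = c(1.3, 1.3, 1.4, 1.3, 1.2),
    fuc    = c(0.8, 0.8, 1.2, 1.2, 1.2),
    ara    = c(16.7, 13.6, 14.6, 14.7, 14.9),
    xyl    = c(4.8, 5.2, 6.9, 7.2, 7.6),
    man    = c(4.4, 3.8, 3.3, 3.3, 3.1),
    gal    = c(18.7, 17.2, 11.3, 8.8, 7.2),
    glc    = c(31.0, 34.1, 35.3, 35.7, 35.8),
    ua     = c(22.4, 23.9, 26.1, 27.8, 29.0),
    acetyl = c(1.5, 1.8, 1.4, 1.3, 1.2),
    methyl = c(2.8, 3.1, 2.8, 3.4, 2.7),
    dm     = c(69.2, 70.7, 59.4, 67.0, 52.2),
    stringsAsFactors = FALSE)
  units <- c(starch = "%AIM", nsp = "%AIM", rha = "%NSP", fuc = "%NSP",
             ara = "%NSP", xyl = "%NSP", man = "%NSP", gal = "%NSP",
             glc = "%NSP", ua = "%NSP", acetyl = "%NSP", methyl = "%NSP",
             dm = "DM")
  composition_table(df, units)
}

#' @rdname apple_wall_composition
#' @export
apple_wall_composition_sd <- function() {
  data.frame(
    stage = c("60DAF", "110DAF", "H", "1M", "2M"),
    starch = c(2.7, 2.2, 2.4, 0.9, 0.8),
    nsp    = c(4.0, 2.4, 3.3, 1.9, 1.8),
    rha    = c(0.1, 0.1, 0.1, 0.0, 0.0),
    fuc    = c(0.1, 0.1, 0.1, 0.0, 0.0),
    ara    = c(1.6, 1.3, 0.9, 0.3, 0.2),
    xyl    = c(0.4, 0.4, 0.4, 0.2, 0.2),
    man    = c(0.4, 0.3, 0.2, 0.1, 0.1),
    gal    = c(1.6, 1.7, 0.8, 0.7, 0.4),
    glc    = c(5.4, 5.6, 3.9, 1.1, 0.7),
    ua     = c(1.3, 1.7, 1.7, 0.7, 0.7),
    acetyl = c(0.1, 0.3, 0.1, 0.1, 0.0),
    methyl = c(0.3, 0.2, 0.4, 0.1, 0.2),
    dm     = c(17.5, 10.4, 16.6, 4.8, 8.2),
    stringsAsFactors = FALSE)
}

#' Sugars released by sequential enzymatic treatment of apple AIM
#'
#' Published neutral-sugar and uronic-acid release at 60DAF and 2M for the
#' five sequential treatments (water-soluble WS, pectinase-soluble PS,
#' mannanase, xylanase, glucanase), in two unit systems: panel
#' \code{"released"} gives the released amount as \% of initial NSP dry
#' weight, panel \code{"fraction"} as \% of each sugar's initial content
#' in the NSP fraction.
#'
#' @param panel \code{"released"} (\% NSP) or \code{"fraction"} (\% of
#'   initial content).
#' @return data.frame with columns stage, treatment, rha, fuc, ara, xyl,
#'   man, gal, glc, ua; treatments in protocol order.
#' @export
apple_digest_release <- function(panel = c("released", "fraction")) {
  panel <- match.arg(panel)
  treatments <- c("WS", "PS", "mannanase", "xylanase", "glucanase")
  released <- rbind(
    # 60DAF: rha fuc ara xyl man gal glc ua
    c(0.0, 0.0, 0.2, 0.0, 0.1, 0.2, 0.2, 0.5),
    c(0.2, 0.0, 1.9, 0.1, 1.0, 2.1, 1.1, 5.0),
    c(0.0, 0.0, 0.3, 0.0, 0.3, 0.3, 0.4, 0.0),
    c(0.0, 0.0, 0.2, 0.0, 0.0, 0.1, 0.1, 0.0),
    c(0.1, 0.2, 0.4, 0.6, 0.3, 0.3, 5.1, 0.0),
    # 2M
    c(0.0, 0.0, 0.2, 0.0, 0.0, 0.1, 0.1, 1.3),
    c(0.3, 0.0, 2.3, 0.1, 0.9, 0.6, 0.2, 4.3),
    c(0.0, 0.0, 0.2, 0.1, 0.2, 0.1, 0.1, 0.2),
    c(0.1, 0.0, 0.9, 0.5, 0.0, 0.3, 0.2, 0.0),
    c(0.1, 0.2, 0.4, 1.0, 0.3, 0.5, 5.7, 0.2))
  fraction <- rbind(
    c(1.3, 0.8, 1.1, 0.4, 1.9, 1.1, 0.7, 2.2),
    c(15.2, 2.1, 11.2, 1.1, 22.7, 11.2, 3.7, 22.3),
    c(2.6, 0.0, 1.8, 0.9, 6.2, 1.3, 1.2, 0.0),
    c(1.3, 0.0, 1.0, 0.9, 0.1, 0.6, 0.3, 0.0),
    c(5.7, 18.4, 2.1, 13.1, 7.5, 1.8, 16.4, 0.0),
    c(1.9, 0.0, 1.6, 0.4, 1.4, 2.0, 0.2, 4.5),
    c(21.1, 1.5, 15.3, 1.4, 27.8, 8.8, 0.5, 14.8),
    c(2.0, 1.4, 1.1, 0.8, 5.4, 1.2, 0.3, 0.7),
    c(5.4, 0.0, 6.2, 6.0, 0.0, 3.6, 0.6, 0.0),
    c(9.1, 19.8, 2.7, 12.9, 8.2, 6.6, 15.8, 0.7))
  vals <- if (panel == "released") released else fraction
  out <- data.frame(stage = rep(c("60DAF", "2M"), each = 5),
                    treatment = rep(treatments, 2),
                    vals, stringsAsFactors = FALSE)
  names(out)[3:10] <- c("rha", "fuc", "ara", "xyl", "man", "gal", "glc", "ua")
  out$treatment <- factor(out$treatment, levels = treatments)
  out
}

#' Annotated digest ion rosters
#'
#' Composition codes of the ions annotated in the mean MALDI-TOF spectra
#' of each apple AIM digest, with the digest's reference ion first.
#'
#' @param digest Digest enzyme.
#' @return Character vector of composition codes.
#' @export
apple_ion_roster <- function(digest) {
  digest <- match.arg(digest, DIGESTS)
  switch(digest,
    mannanase = c("Hex4a1", "Hex4a2", "Hex5a1", "Hex5a2", "Hex6a1", "Hex4",
                  "Hex5", "Hex3a1", "Hex7a1", "Hex7a2", "Hex8a1", "Hex8a2",
                  "Pen3U1", "Pen3U1a1", "Pen4a1", "Pen4a2", "Pen4U1m1",
                  "Pen4U1m1a1", "Pen5a1"),
    xylanase = c("Pen3U1a1", "Pen3U1", "Pen4a1", "Pen4U1m1", "Pen4U1m1a1",
                 "Pen5a1", "Pen5U1m1a1"),
    glucanase = c("XXXG", "XXFGa1", "XLFGa1", "XXG", "XLG", "GFG", "XFG",
                  "XLXG", "XLXGa1", "XXFG", "XXFGa2", "XLFGa2", "Hex4",
                  "Hex4a1", "Hex4a2", "Hex5", "Hex5a1", "Hex5a2", "Hex6a1",
                  "Hex7a1", "Hex8a1", "Pen3U1", "Pen3U1a1", "Pen4a1",
                  "Pen4U1m1", "Pen4U1m1a1", "Pen5a1", "Pen5U1m1a1"))
}
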