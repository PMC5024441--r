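# Seeded generators emulating the study design: digest spectra built from
# known compositions, five-stage expression matrices with planted early/late
# clusters, and composition tables with the published monotone stage trends.
# Every generator is a pure function of (scenario, seed): the global RNG
# state is saved and restored around each call.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Spectrum simulation scenario
#'
#' Describes one synthetic digest spectrum: the planted compositions with
#' their relative abundances, the m/z jitter, multiplicative intensity
#' noise and the number of decoy peaks. The digest's reference ion is
#' always part of the roster so reference normalization is possible.
#'
#' @param digest Digest enzyme.
#' @param abundances Named numeric vector: composition code ->
#'   relative abundance (> 0). Default: the digest's annotated ion roster
#'   with geometrically decaying abundances, reference ion first at 100.
#' @param jitter_sd m/z jitter standard deviation in Da (default 0.05,
#'   sub-tolerance reflectron-TOF scatter).
#' @param n_decoys Number of unrelated decoy peaks drawn uniformly over
#'   the acquisition window (default 0).
#' @param noise_cv Coefficient of variation of the lognormal intensity
#'   noise (default 0.2).
#' @param window Acquisition window (default m/z 500-3000).
#' @return List of class \code{"spectrum_scenario"}.
#' @export
spectrum_scenario <- function(digest, abundances = NULL, jitter_sd = 0.05,
                              n_decoys = 0L, noise_cv = 0.2,
                              window = c(500, 3000)) {
  digest <- match.arg(digest, DIGESTS)
  if (is.null(abundances)) {
    roster <- apple_ion_roster(digest)
    abundances <- stats::setNames(100 * 0.85^(seq_along(roster) - 1), roster)
  }
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stop("abundances must be named by composition code", call. = FALSE)
  if (any(abundances <= 0)) stop("abundances must be positive", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  # validate codes now, and check the reference ion is reachable
  masses <- vapply(names(abundances), function(code)
    sodiated_mass(parse_oligo_code(code)), 0)
  ref <- digest_reference_mz()[[digest]]
  if (!any(abs(masses - ref) <= 0.5))
    stop("scenario must include the ", digest, " reference ion (m/z ", ref,
         ")", call. = FALSE)
  structure(list(digest = digest, abundances = abundances,
                 masses = masses, jitter_sd = jitter_sd,
                 n_decoys = as.integer(n_decoys), noise_cv = noise_cv,
                 window = window),
            class = "spectrum_scenario")
}

#' Generate a synthetic digest spectrum
#'
#' Plants one peak per scenario composition at its sodiated monoisotopic
#' mass plus Gaussian jitter, with intensity = abundance times lognormal
#' noise (unit mean), and adds uniform decoy peaks kept at least 1 Da
#' away from every planted mass. The returned spectrum carries a
#' \code{"truth"} attribute mapping each peak to its true code (NA for
#' decoys).
#'
#' @param scenario A \code{\link{spectrum_scenario}}.
#' @param seed Integer seed.
#' @param sample_id,stage,replicate Sample metadata.
#' @return A \code{\link{digest_spectrum}} with attribute \code{"truth"}
#'   (data.frame mz, code).
#' @export
gen_spectrum <- function(scenario, seed, sample_id = "synthetic",
                         stage = NA_character_, replicate = 1L) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  with_seed(seed, {
    n <- length(scenario$abundances)
    mz <- scenario$masses + stats::rnorm(n, 0, scenario$jitter_sd)
    sdlog <- sqrt(log(1 + scenario$noise_cv^2))
    intensity <- scenario$abundances *
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    code <- names(scenario$abundances)
    if (scenario$n_decoys > 0) {
      decoys <- numeric(0)
      while (length(decoys) < scenario$n_decoys) {
        cand <- stats::runif(scenario$n_decoys - length(decoys),
                             scenario$window[1], scenario$window[2])
        far <- vapply(cand, function(m)
          all(abs(scenario$masses - m) > 1), TRUE)
        decoys <- c(decoys, cand[far])
      }
      dec_int <- stats::runif(scenario$n_decoys, 0.01, 0.3) *
        max(scenario$abundances)
      mz <- c(mz, decoys)
      intensity <- c(intensity, dec_int)
      code <- c(code, rep(NA_character_, scenario$n_decoys))
    }
    ord <- order(mz)
    spec <- digest_spectrum(mz[ord], intensity[ord], scenario$digest,
                            sample_id, stage, replicate)
    attr(spec, "truth") <- data.frame(mz = mz[ord], code = code[ord],
                                      stringsAsFactors = FALSE)
    spec
  })
}

#' Expression simulation scenario
#'
#' A five-stage, eight-genotype, two-plot expression design with planted
#' early/late co-expression structure: a fraction of genes belongs to
#' cluster A (elevated at 60DAF and 110DAF) and a fraction to cluster B
#' (elevated at H, 1M and 2M); the rest are flat. Values are log2 scale,
#' baseline plus cluster shift plus Gaussian residual noise.
#'
#' @param n_genes Number of genes (default 1000).
#' @param frac_a,frac_b Fractions of genes in clusters A and B
#'   (default 0.1 each; must sum to <= 1).
#' @param effect Cluster shift in log2 units (default 2).
#' @param residual_sd Residual standard deviation (default 0.5).
#' @param genotypes,plots,stages Design vocabulary (defaults: the eight
#'   study hybrids, plots PH and P12, five stages).
#' @return List of class \code{"expression_scenario"}.
#' @export
expression_scenario <- function(n_genes = 1000, frac_a = 0.1, frac_b = 0.1,
                                effect = 2, residual_sd = 0.5,
                                genotypes = GENOTYPES, plots = PLOTS,
                                stages = STAGES) {
  if (frac_a < 0 || frac_b < 0 || frac_a + frac_b > 1)
    stop("cluster fractions must be >= 0 and sum to <= 1", call. = FALSE)
  if (effect < 0) stop("effect size must be >= 0", call. = FALSE)
  if (!all(genotypes %in% GENOTYPES))
    stop("unknown genotype(s): ",
         paste(setdiff(genotypes, GENOTYPES), collapse = ", "),
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), frac_a = frac_a,
                 frac_b = frac_b, effect = effect,
                 residual_sd = residual_sd, genotypes = genotypes,
                 plots = plots, stages = stages, baseline = 8),
            class = "expression_scenario")
}

#' Generate a synthetic expression matrix
#'
#' @param scenario An \code{\link{expression_scenario}}.
#' @param seed Integer seed.
#' @return List with \code{values} (genes x samples log2 matrix),
#'   \code{meta} (sample, stage, genotype, plot) and \code{labels} (true
#'   cluster per gene: "A", "B" or "null").
#' @export
gen_expression <- function(scenario, seed) {
  stopifnot(inherits(scenario, "expression_scenario"))
  with_seed(seed, {
    meta <- expand.grid(plot = scenario$plots, genotype = scenario$genotypes,
                        stage = scenario$stages, stringsAsFactors = FALSE)
    meta <- meta[, c("stage", "genotype", "plot")]
    meta$sample <- paste(meta$stage, meta$genotype, meta$plot, sep = "_")
    n_a <- round(scenario$n_genes * scenario$frac_a)
    n_b <- round(scenario$n_genes * scenario$frac_b)
    labels <- rep(c("A", "B", "null"),
                  c(n_a, n_b, scenario$n_genes - n_a - n_b))
    early <- meta$stage %in% c("60DAF", "110DAF")
    shift <- matrix(0, scenario$n_genes, nrow(meta))
    shift[labels == "A", early] <- scenario$effect
    shift[labels == "B", !early] <- scenario$effect
    values <- scenario$baseline + shift +
      matrix(stats::rnorm(scenario$n_genes * nrow(meta), 0,
                          scenario$residual_sd),
             scenario$n_genes, nrow(meta))
    dimnames(values) <- list(sprintf("gene%04d", seq_len(scenario$n_genes)),
                             meta$sample)
    list(values = values, meta = meta,
         labels = stats::setNames(labels, rownames(values)))
  })
}

#' Biochemical composition simulation scenario
#'
#' Linear-in-stage analyte templates with Gaussian noise and three
#' replicates per stage. Default endpoints are the published apple
#' cell-wall stage trends (\% NSP): galactose declining 18.7 to 7.2,
#' uronic acids rising 22.4 to 29.0, xylose 4.8 to 7.6, mannose declining
#' 4.4 to 3.1 and fucose 0.8 to 1.2; default noise scales are of the
#' order of the published replicate standard deviations.
#'
#' @param analytes data.frame with columns \code{analyte}, \code{start},
#'   \code{end}, \code{noise_sd}.
#' @param n_replicates Replicates per stage (default 3).
#' @param stages Stage vector (default the five study stages).
#' @return List of class \code{"biochem_scenario"}.
#' @export
biochem_scenario <- function(analytes = NULL, n_replicates = 3,
                             stages = STAGES) {
  if (is.null(analytes)) {
    analytes <- data.frame(
      analyte = c("gal", "ua", "xyl", "man", "fuc"),
      start = c(18.7, 22.4, 4.8, 4.4, 0.8),
      end = c(7.2, 29.0, 7.6, 3.1, 1.2),
      noise_sd = c(1.0, 1.0, 0.3, 0.2, 0.08),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("analyte", "start", "end", "noise_sd") %in%
                  names(analytes)))
  if (any(analytes$start < 0) || any(analytes$end < 0) ||
      any(analytes$noise_sd < 0))
    stop("scenario values must be non-negative", call. = FALSE)
  structure(list(analytes = analytes, n_replicates = as.integer(n_replicates),
                 stages = stages),
            class = "biochem_scenario")
}

#' Generate a synthetic composition table
#'
#' Each analyte follows a linear template between its start and end
#' values across the stage axis, with Gaussian replicate noise. A draw
#' that comes out negative is resampled (never clipped, which would bias
#' the mean of near-zero analytes).
#'
#' @param scenario A \code{\link{biochem_scenario}}.
#' @param seed Integer seed.
#' @return A \code{\link{composition_table}} with columns stage,
#'   replicate and one \%NSP-tagged column per analyte; attribute
#'   \code{"templates"} carries the noise-free stage templates.
#' @export
gen_biochem <- function(scenario, seed) {
  stopifnot(inherits(scenario, "biochem_scenario"))
  with_seed(seed, {
    n_st <- length(scenario$stages)
    frac <- if (n_st == 1) 0 else (seq_len(n_st) - 1) / (n_st - 1)
    df <- expand.grid(replicate = seq_len(scenario$n_replicates),
                      stage = scenario$stages,
                      stringsAsFactors = FALSE)[, c("stage", "replicate")]
    templates <- list()
    for (i in seq_len(nrow(scenario$analytes))) {
      a <- scenario$analytes[i, ]
      template <- a$start + (a$end - a$start) * frac
      templates[[a$analyte]] <- stats::setNames(template, scenario$stages)
      vals <- template[match(df$stage, scenario$stages)] +
        stats::rnorm(nrow(df), 0, a$noise_sd)
      while (any(vals < 0)) {
        bad <- which(vals < 0)
        vals[bad] <- templates[[a$analyte]][match(df$stage[bad],
                                                  scenario$stages)] +
          stats::rnorm(length(bad), 0, a$noise_sd)
      }
      df[[a$analyte]] <- vals
    }
    tab <- composition_table(
      df, stats::setNames(rep("%NSP", nrow(scenario$analytes)),
                          scenario$analytes$analyte))
    attr(tab, "templates") <- templates
    tab
  })
}
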