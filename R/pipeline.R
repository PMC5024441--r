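#' Pipeline configuration
#'
#' Declarative configuration for \code{\link{run_pipeline}}. Defaults are
#' the study's stated analysis settings: annotation tolerance 0.3 Da,
#' differential gate p < 0.01, network thresholds r > 0.7 / p < 0.01,
#' chemical ANOVA gate p < 1e-4, the three-pool genotype scheme and the
#' digest reference ions.
#'
#' @param tolerance Annotation mass tolerance (Da).
#' @param alpha_differential Differential-expression p gate.
#' @param network_r,network_p Correlation-network thresholds.
#' @param anova_alpha Chemical ANOVA gate.
#' @param pooling Genotype pooling scheme (named list).
#' @param reference_ions Named digest -> reference m/z vector.
#' @param seed Master seed; all stage seeds derive from it.
#' @param expression,biochem,spectra Scenario objects for the simulation
#'   stage (defaults: study-design scenarios; spectra is a list of
#'   \code{\link{spectrum_scenario}}, one per digest).
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(tolerance = 0.3, alpha_differential = 0.01,
                            network_r = 0.7, network_p = 0.01,
                            anova_alpha = 1e-4,
                            pooling = default_pooling_scheme(),
                            reference_ions = digest_reference_mz(),
                            seed = 1L,
                            expression = expression_scenario(),
                            biochem = biochem_scenario(),
                            spectra = lapply(stats::setNames(DIGESTS,
                                                             DIGESTS),
                                             spectrum_scenario)) {
  stopifnot(tolerance > 0, alpha_differential > 0, alpha_differential < 1,
            network_r >= -1, network_r <= 1.01, network_p > 0,
            network_p <= 1, anova_alpha > 0, anova_alpha < 1)
  if (!all(DIGESTS %in% names(reference_ions)))
    stop("reference_ions must cover all three digests", call. = FALSE)
  structure(list(tolerance = tolerance,
                 alpha_differential = alpha_differential,
                 network_r = network_r, network_p = network_p,
                 anova_alpha = anova_alpha, pooling = pooling,
                 reference_ions = reference_ions, seed = as.integer(seed),
                 expression = expression, biochem = biochem,
                 spectra = spectra),
            class = "pipeline_config")
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  path
}

#' Run the full synthetic-study pipeline
#'
#' Executes the stages in fixed order — simulate, annotate, composition,
#' transcriptome, integration — writing every stage output as TSV into
#' \code{out_dir} together with a provenance manifest (JSON: config hash,
#' seeds, package version, per-stage settings). Deterministic given the
#' config: a rerun with the same config writes identical stage outputs.
#' A stage failure aborts with the stage name and leaves a
#' \code{PARTIAL_RESULTS} marker file.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage_now <- "setup"
  marker <- file.path(out_dir, "PARTIAL_RESULTS")
  file.create(marker)
  results <- tryCatch({
    # ---- simulate ------------------------------------------------------
    stage_now <- "simulate"
    say("[simulate] seed ", config$seed)
    expr <- gen_expression(config$expression, seed = config$seed)
    bio <- gen_biochem(config$biochem, seed = config$seed + 1L)
    spectra <- list()
    for (i in seq_along(config$spectra)) {
      sc <- config$spectra[[i]]
      for (s in seq_along(STAGES)) for (r in 1:3) {
        spectra[[length(spectra) + 1L]] <-
          gen_spectrum(sc, seed = config$seed + 100L * i + 10L * s + r,
                       sample_id = paste0(STAGES[s], "_", sc$digest),
                       stage = STAGES[s], replicate = r)
      }
    }
    write_tsv(cbind(gene = rownames(expr$values), as.data.frame(expr$values)),
              file.path(out_dir, "expression_matrix.tsv"))
    write_tsv(expr$meta, file.path(out_dir, "sample_sheet.tsv"))
    write_tsv(as.data.frame(bio), file.path(out_dir, "biochem_table.tsv"))

    # ---- annotate ------------------------------------------------------
    stage_now <- "annotate"
    say("[annotate] tolerance ", config$tolerance,
        " Da; replicates kept as separate rows")
    matrices <- list()
    for (dg in DIGESTS) {
      sub <- Filter(function(sp) sp$digest == dg, spectra)
      sub <- lapply(sub, normalize_to_reference)
      roster <- apple_ion_roster(dg)
      mat <- build_intensity_matrix(sub, roster, tol = config$tolerance)
      matrices[[dg]] <- mat
      write_tsv(cbind(attr(mat, "meta"), as.data.frame(mat)),
                file.path(out_dir, paste0("intensity_", dg, ".tsv")))
    }

    # ---- composition ---------------------------------------------------
    stage_now <- "composition"
    say("[composition] ANOVA gate p < ", config$anova_alpha)
    analytes <- setdiff(names(bio), c("stage", "replicate"))
    anova_tab <- do.call(rbind, lapply(analytes, function(a) {
      res <- stage_anova(bio[[a]], bio$stage, alpha = config$anova_alpha)
      data.frame(analyte = a, f = res$f, p = res$p,
                 significant = res$significant, stringsAsFactors = FALSE)
    }))
    write_tsv(anova_tab, file.path(out_dir, "composition_anova.tsv"))

    # ---- transcriptome -------------------------------------------------
    stage_now <- "transcriptome"
    say("[transcriptome] differential gate p < ", config$alpha_differential,
        " (60DAF vs 2M)")
    qn <- quantile_normalize(expr$values)
    sel_cols <- expr$meta$stage %in% c("60DAF", "2M")
    tt <- moderated_ttest(qn[, sel_cols],
                          expr$meta$stage[sel_cols])
    diff <- select_differential(tt, alpha = config$alpha_differential)
    write_tsv(cbind(gene = rownames(tt), as.data.frame(tt)),
              file.path(out_dir, "differential.tsv"))
    stage_means <- vapply(STAGES, function(s)
      rowMeans(qn[, expr$meta$stage == s, drop = FALSE]),
      numeric(nrow(qn)))
    clus <- if (length(diff$selected) >= 2)
      hierarchical_cluster(stage_means[diff$selected, , drop = FALSE], k = 2)
    else NULL
    if (!is.null(clus))
      write_tsv(data.frame(gene = names(clus$clusters),
                           cluster = clus$clusters),
                file.path(out_dir, "clusters.tsv"))

    # ---- integration ---------------------------------------------------
    stage_now <- "integration"
    say("[integration] network r > ", config$network_r, ", p < ",
        config$network_p, "; gene mode positive, biochem mode absolute")
    pca <- fingerprint_pca(matrices$glucanase)
    write_tsv(cbind(sample = rownames(pca$scores),
                    as.data.frame(pca$scores)),
              file.path(out_dir, "pca_scores.tsv"))
    pooled <- pool_genotypes(qn, expr$meta, scheme = config$pooling)
    net_genes <- utils::head(diff$selected, 100)
    net <- if (length(net_genes) >= 2)
      build_network(qn[net_genes, , drop = FALSE], r_min = config$network_r,
                    p_max = config$network_p, signed_mode = "positive")
    else NULL
    if (!is.null(net))
      write_network(net, file.path(out_dir, "gene_network.tsv"))
    bio_mat <- t(as.matrix(bio[, analytes]))
    colnames(bio_mat) <- paste(bio$stage, bio$replicate, sep = ".")
    bt <- correlate_biochem_transcript(
      bio_mat, bio[, c("stage", "replicate")],
      pooled[utils::head(diff$selected, 50), , drop = FALSE],
      p_max = config$network_p)
    write_tsv(bt, file.path(out_dir, "biochem_transcript_correlations.tsv"))

    list(expression = expr, biochem = bio, matrices = matrices,
         anova = anova_tab, test = tt, differential = diff,
         clusters = clus, pca = pca, network = net,
         biochem_transcript = bt)
  }, error = function(e) {
    stop("pipeline stage '", stage_now, "' failed: ", conditionMessage(e),
         " (partial results in ", out_dir, ")", call. = FALSE)
  })

  # ---- manifest --------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(
    tolerance = config$tolerance,
    alpha_differential = config$alpha_differential,
    network_r = config$network_r, network_p = config$network_p,
    anova_alpha = config$anova_alpha, seed = config$seed,
    pooling = config$pooling), cfg_file)
  manifest <- list(
    package = "glycowall",
    version = as.character(utils::packageVersion("glycowall")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages = c("simulate", "annotate", "composition", "transcriptome",
               "integration"),
    settings = list(tolerance_da = config$tolerance,
                    replicate_handling = "separate rows",
                    gene_network_mode = "positive",
                    biochem_network_mode = "absolute"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  file.remove(marker)
  invisible(c(results, list(manifest = manifest)))
}

#' Validate pipeline input files
#'
#' Schema report for the TSV formats the pipeline reads. Never mutates
#' inputs; returns one row per finding (violations and warnings).
#' Checks: peak lists are two numeric columns; sample sheets use the
#' closed stage/genotype vocabularies; composition tables have numeric
#' analyte columns, and a \%NSP sugar panel summing far above 105 (the
#' analytical tolerance) is warned about.
#'
#' @param paths Character vector of file paths.
#' @param types Matching character vector of schema names:
#'   \code{"peaklist"}, \code{"sample_sheet"} or \code{"composition"}.
#' @return data.frame with columns file, level ("violation"/"warning"),
#'   message; zero rows if everything conforms.
#' @export
validate_inputs <- function(paths, types) {
  stopifnot(length(paths) == length(types))
  findings <- list()
  note <- function(file, level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      file = file, level = level, message = msg, stringsAsFactors = FALSE)
  for (i in seq_along(paths)) {
    path <- paths[i]
    type <- match.arg(types[i], c("peaklist", "sample_sheet", "composition"))
    if (!file.exists(path)) {
      note(path, "violation", "file does not exist")
      next
    }
    if (type == "peaklist") {
      lines <- readLines(path)
      keep <- which(!grepl("^\\s*(#|$)", lines))
      if (!length(keep)) {
        note(path, "violation", "empty peak list")
        next
      }
      for (j in keep) {
        f <- strsplit(trimws(lines[j]), "[\t ]+")[[1]]
        if (length(f) < 2 || anyNA(suppressWarnings(as.numeric(f[1:2]))))
          note(path, "violation",
               paste0("non-numeric peak fields at line ", j))
      }
    } else {
      df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                     error = function(e) NULL)
      if (is.null(df)) {
        note(path, "violation", "unreadable TSV")
        next
      }
      if (type == "sample_sheet") {
        if (!"stage" %in% names(df)) {
          note(path, "violation", "missing 'stage' column")
        } else {
          bad <- setdiff(unique(df$stage), STAGES)
          if (length(bad))
            note(path, "violation",
                 paste0("unknown stage label(s): ",
                        paste(bad, collapse = ", ")))
        }
        if ("genotype" %in% names(df)) {
          bad <- setdiff(unique(df$genotype), GENOTYPES)
          if (length(bad))
            note(path, "violation",
                 paste0("unknown genotype(s): ",
                        paste(bad, collapse = ", ")))
        }
      } else { # composition
        analytes <- setdiff(names(df), c("stage", "replicate"))
        non_num <- analytes[!vapply(df[analytes], is.numeric, TRUE)]
        if (length(non_num))
          note(path, "violation",
               paste0("non-numeric analyte column(s): ",
                      paste(non_num, collapse = ", ")))
        num <- setdiff(analytes, non_num)
        if (length(num) && "stage" %in% names(df)) {
          sums <- tapply(rowSums(df[, num, drop = FALSE]), df$stage, mean)
          over <- sums[sums > 105]
          if (length(over))
            note(path, "warning",
                 paste0("analyte sum exceeds 105% at stage(s): ",
                        paste(names(over), collapse = ", ")))
        }
      }
    }
  }
  if (!length(findings))
    return(data.frame(file = character(), level = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}
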