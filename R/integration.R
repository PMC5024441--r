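#' Principal component analysis of a fingerprint matrix
#'
#' Centred (optionally unit-variance-scaled) PCA of a samples x variables
#' matrix, as used to summarize digest ion-intensity fingerprints across
#' developmental stages. Scores are the data projected on the orthonormal
#' loadings; explained-variance fractions are non-increasing and sum to
#' at most 1.
#'
#' @param x Numeric matrix, samples x variables (>= 2 of each).
#' @param center,scale Centre / unit-variance-scale the columns.
#' @return Object of class \code{"fingerprint_pca"}: list with
#'   \code{scores}, \code{loadings}, \code{explained} (variance
#'   fractions), \code{sdev}, \code{center}, \code{scale}.
#' @export
fingerprint_pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  if (scale) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      nm <- colnames(x)
      if (is.null(nm)) nm <- as.character(seq_len(ncol(x)))
      stop("zero-variance column(s) with scaling on: ",
           paste(nm[v == 0], collapse = ", "), call. = FALSE)
    }
  }
  fit <- stats::prcomp(x, center = center, scale. = scale)
  structure(list(scores = fit$x, loadings = fit$rotation,
                 explained = fit$sdev^2 / sum(fit$sdev^2), sdev = fit$sdev,
                 center = fit$center, scale = fit$scale),
            class = "fingerprint_pca")
}

#' @export
print.fingerprint_pca <- function(x, ...) {
  cat("<fingerprint_pca> ", nrow(x$scores), " samples, ",
      nrow(x$loadings), " variables\n", sep = "")
  ev <- round(100 * x$explained[seq_len(min(3, length(x$explained)))], 1)
  cat("  explained variance: ",
      paste0("PC", seq_along(ev), " ", ev, "%", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Default genotype pooling scheme
#'
#' The three pools used to align the eight genotypes' expression profiles
#' with the three biochemical replicates.
#'
#' @return Named list of genotype character vectors.
#' @export
default_pooling_scheme <- function() {
  list(Pool1 = c("V034", "I062", "V083"),
       Pool2 = c("W029", "I095", "H097"),
       Pool3 = c("H074", "I016"))
}

#' Pool expression columns across genotypes
#'
#' Averages sample columns genotype-wise within each (stage, pool) cell:
#' output columns are \code{<stage>.<pool>}, the arithmetic mean over the
#' pool's member genotypes (all plots/replicates of a member included).
#'
#' @param x Numeric matrix, genes x samples.
#' @param meta data.frame with \code{stage} and \code{genotype} columns
#'   describing the samples (rows aligned with \code{ncol(x)}).
#' @param scheme Named list of genotype vectors (default
#'   \code{\link{default_pooling_scheme}}).
#' @param stages Stage order for the output columns.
#' @return Genes x (stage x pool) matrix with a \code{"pool_meta"}
#'   attribute data.frame (stage, pool).
#' @export
pool_genotypes <- function(x, meta, scheme = default_pooling_scheme(),
                           stages = intersect(STAGES, unique(meta$stage))) {
  x <- as.matrix(x)
  if (nrow(meta) != ncol(x))
    stop("meta rows must match matrix columns", call. = FALSE)
  unknown <- setdiff(unlist(scheme), unique(meta$genotype))
  if (length(unknown))
    stop("pooling scheme names genotype(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cells <- expand.grid(pool = names(scheme), stage = stages,
                       stringsAsFactors = FALSE)[, c("stage", "pool")]
  out <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- meta$stage == cells$stage[i] &
      meta$genotype %in% scheme[[cells$pool[i]]]
    if (!any(sel))
      stop("no samples for stage ", cells$stage[i], " in ",
           cells$pool[i], call. = FALSE)
    rowMeans(x[, sel, drop = FALSE])
  }, numeric(nrow(x)))
  colnames(out) <- paste(cells$stage, cells$pool, sep = ".")
  rownames(out) <- rownames(x)
  attr(out, "pool_meta") <- cells
  out
}

#' Pearson correlation with a closed-form p-value
#'
#' Pearson's r together with the two-sided p-value from the exact t
#' transform t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3, both non-constant.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @examples
#' # an r of 0.7 over 16 points clears the study's p < 0.01 gate:
#' # t = 3.67, p ~ 0.0025
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Thresholded Pearson correlation network
#'
#' All-pairs correlation of profile rows; an edge is admitted when it
#' passes the network's thresholds: p < \code{p_max} and r > \code{r_min}
#' in \code{"positive"} mode (the gene-network default, matching the
#' study's r > 0.7 rule) or |r| > \code{r_min} in \code{"absolute"} mode
#' (the integration default, where negative biochemistry correlations are
#' meaningful). Connected components are computed on the admitted edges.
#'
#' @param profiles Numeric matrix, nodes x observations.
#' @param r_min Correlation threshold (default 0.7).
#' @param p_max p-value threshold (default 0.01).
#' @param signed_mode \code{"positive"} or \code{"absolute"}.
#' @param adjust Optional multiple-testing adjustment for edge p-values
#'   (\code{"none"}, the study's choice, or \code{"BH"}).
#' @return Object of class \code{"correlation_network"}: list with
#'   \code{nodes}, \code{edges} (data.frame node1, node2, r, p, n),
#'   \code{components} (membership vector), \code{component_sizes} and
#'   \code{thresholds}.
#' @export
build_network <- function(profiles, r_min = 0.7, p_max = 0.01,
                          signed_mode = c("positive", "absolute"),
                          adjust = c("none", "BH")) {
  signed_mode <- match.arg(signed_mode)
  adjust <- match.arg(adjust)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need >= 2 profiles", call. = FALSE)
  nodes <- rownames(profiles)
  if (is.null(nodes)) nodes <- paste0("node", seq_len(nrow(profiles)))
  n_obs <- ncol(profiles)
  cmat <- stats::cor(t(profiles))
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  r <- cmat[idx]
  r_clip <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r_clip * sqrt(n_obs - 2) / sqrt(1 - r_clip^2)
  p <- 2 * stats::pt(-abs(tt), n_obs - 2)
  p[abs(r) >= 1] <- 0
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  pass <- p < p_max &
    (if (signed_mode == "positive") r > r_min else abs(r) > r_min)
  edges <- data.frame(node1 = nodes[idx[pass, 1]],
                      node2 = nodes[idx[pass, 2]],
                      r = r[pass], p = p[pass],
                      n = rep(n_obs, sum(pass)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("node1", "node2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  structure(list(nodes = nodes, edges = edges,
                 components = stats::setNames(comp$membership, nodes),
                 component_sizes = sort(as.integer(comp$csize),
                                        decreasing = TRUE),
                 thresholds = list(r_min = r_min, p_max = p_max,
                                   signed_mode = signed_mode,
                                   adjust = adjust)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network> %d nodes, %d edges (r %s %.2g, p < %.2g)\n",
    length(x$nodes), nrow(x$edges),
    if (x$thresholds$signed_mode == "positive") ">" else "|.| >",
    x$thresholds$r_min, x$thresholds$p_max))
  nontrivial <- x$component_sizes[x$component_sizes > 1]
  cat("  component sizes > 1: ",
      if (length(nontrivial)) paste(nontrivial, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Export a network as an edge-list TSV or GraphML
#'
#' @param net A \code{\link{build_network}} result.
#' @param path Output file; format picked by extension (\code{.graphml}
#'   for GraphML, anything else edge-list TSV with columns node1, node2,
#'   r, p).
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges[, c("node1", "node2", "r", "p")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Correlate biochemical trajectories with pooled expression
#'
#' Pairs each biochemical analyte series (stages x replicates) with each
#' gene's pooled expression series (stages x pools) by stage and
#' replicate/pool index, and reports the signed Pearson correlation with
#' its closed-form p-value and a significance flag at \code{p_max}.
#'
#' @param biochem Numeric matrix, analytes x (stage x replicate) columns.
#' @param biochem_meta data.frame (stage, replicate) describing
#'   \code{biochem} columns.
#' @param expression Numeric matrix, genes x (stage x pool) columns, e.g.
#'   from \code{\link{pool_genotypes}}.
#' @param expr_meta data.frame (stage, pool) describing
#'   \code{expression} columns; defaults to the matrix's
#'   \code{"pool_meta"} attribute.
#' @param p_max Significance gate (default 0.01).
#' @return data.frame with columns gene, analyte, r, p, n, significant.
#' @export
correlate_biochem_transcript <- function(biochem, biochem_meta, expression,
                                         expr_meta = attr(expression,
                                                          "pool_meta"),
                                         p_max = 0.01) {
  biochem <- as.matrix(biochem); expression <- as.matrix(expression)
  if (is.null(expr_meta)) {
    # subsetted pooled matrices lose the attribute; recover the axis from
    # the "<stage>.<pool>" column names
    cn <- colnames(expression)
    if (is.null(cn) || !all(grepl(".", cn, fixed = TRUE)))
      stop("expr_meta is required (or pass a pooled matrix)", call. = FALSE)
    expr_meta <- data.frame(stage = sub("\\.[^.]*$", "", cn),
                            pool = sub("^.*\\.", "", cn),
                            stringsAsFactors = FALSE)
  }
  if (nrow(biochem_meta) != ncol(biochem) ||
      nrow(expr_meta) != ncol(expression))
    stop("metadata rows must match matrix columns", call. = FALSE)
  # align by stage and within-stage index
  key_b <- paste(biochem_meta$stage,
                 stats::ave(seq_len(nrow(biochem_meta)), biochem_meta$stage,
                            FUN = seq_along))
  rep_idx <- if ("pool" %in% names(expr_meta))
    as.integer(factor(expr_meta$pool)) else expr_meta$replicate
  key_e <- paste(expr_meta$stage, rep_idx)
  if (!setequal(key_b, key_e) || anyDuplicated(key_b) || anyDuplicated(key_e))
    stop("stage/replicate axes of the two data sets do not match",
         call. = FALSE)
  expression <- expression[, match(key_b, key_e), drop = FALSE]
  genes <- rownames(expression)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(expression)))
  analytes <- rownames(biochem)
  if (is.null(analytes)) analytes <- paste0("analyte", seq_len(nrow(biochem)))
  grid <- expand.grid(gene = genes, analyte = analytes,
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, a) {
    unlist(pearson_with_p(expression[g, ], biochem[a, ]))
  }, match(grid$gene, genes), match(grid$analyte, analytes))
  out <- cbind(grid, t(res))
  out$significant <- out$p < p_max
  out
}
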