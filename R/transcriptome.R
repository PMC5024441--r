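#' Lowess normalization of two-channel array intensities
#'
#' Removes intensity-dependent dye bias from a two-colour hybridization:
#' the log-ratio M = log2(ch1/ch2) is detrended against the mean
#' log-intensity A = (log2 ch1 + log2 ch2)/2 by locally weighted
#' regression, and the fitted trend is subtracted.
#'
#' @param ch1,ch2 Positive intensity vectors (the two channels).
#' @param f Lowess smoother span (default 0.15: narrow enough to track
#'   bias that varies over a fraction of the A range, wide enough to
#'   average hundreds of probes on a full-size array).
#' @return data.frame with columns \code{A}, \code{M} (raw) and
#'   \code{M_corrected}.
#' @export
lowess_normalize <- function(ch1, ch2, f = 0.15) {
  if (length(ch1) != length(ch2))
    stop("channels must have equal length", call. = FALSE)
  bad <- which(!(is.finite(ch1) & is.finite(ch2) & ch1 > 0 & ch2 > 0))
  if (length(bad))
    stop("non-positive intensity at probe(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  A <- (log2(ch1) + log2(ch2)) / 2
  M <- log2(ch1) - log2(ch2)
  fit <- stats::lowess(A, M, f = f)
  trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  data.frame(A = A, M = M, M_corrected = M - trend)
}

#' Quantile normalization
#'
#' Forces every column of a matrix onto the same empirical distribution:
#' each rank is mapped to the cross-column mean of the values at that
#' rank, and tied values within a column share the average of the
#' reference values their ranks span. Idempotent, and preserves each
#' column's rank order.
#'
#' @param x Numeric matrix (genes x samples), no missing values.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  if (!is.numeric(x)) stop("matrix must be numeric", call. = FALSE)
  if (ncol(x) == 1) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # tied values share the mean of the reference values their ranks span
    stats::ave(res, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  out
}

# Inverse of the trigamma function by Newton iteration on 1/x scale
# (monotone and nearly linear there), as used for empirical-Bayes moment
# matching of the scaled inverse-chi-square prior.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, 0)
}

#' Empirical-Bayes moderated t-test for a two-group design
#'
#' Gene-wise two-group comparison in which the residual variance of each
#' gene is shrunk toward a common prior before forming the t-statistic.
#' The prior (d0 degrees of freedom, s0^2 scale) is estimated from the
#' ensemble of gene-wise variances by moment matching on the log scale:
#' under the scaled inverse-chi-square model, log s_g^2 follows a shifted
#' log-F distribution whose mean and variance involve digamma/trigamma
#' functions of d_g/2 and d0/2; equating observed moments and inverting
#' the trigamma function yields (d0, s0). The posterior variance
#' s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g) replaces s_g^2 in an
#' ordinary t-statistic, referred to a t distribution on d0 + d_g degrees
#' of freedom.
#'
#' Limiting cases: \code{d0 = 0} (forced with \code{moderation = FALSE})
#' reproduces the ordinary two-sample pooled-variance t-test; d0 = Inf
#' (estimated when the gene variances are exchangeable) uses the common
#' s0 for every gene.
#'
#' @param x Numeric matrix, genes x samples (log2 scale).
#' @param group Two-level factor/vector of length \code{ncol(x)}.
#' @param moderation If \code{FALSE}, skip shrinkage (d0 = 0).
#' @return Object of class \code{"moderated_ttest"}: data.frame with per
#'   gene \code{effect} (group2 - group1 mean difference), \code{s} (gene
#'   sd), \code{df} (residual df), \code{s_post} (posterior sd), \code{t},
#'   \code{p}; attributes \code{d0} and \code{s0}.
#' @export
moderated_ttest <- function(x, group, moderation = TRUE) {
  x <- as.matrix(x)
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly 2 levels", call. = FALSE)
  if (length(group) != ncol(x))
    stop("group length must match ncol(x)", call. = FALSE)
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  d_g <- n1 + n2 - 2L
  if (d_g == 0) stop("zero residual degrees of freedom", call. = FALSE)

  m1 <- rowMeans(x[, group == levels(group)[1], drop = FALSE])
  m2 <- rowMeans(x[, group == levels(group)[2], drop = FALSE])
  effect <- m2 - m1
  ss <- rowSums((x[, group == levels(group)[1], drop = FALSE] - m1)^2) +
        rowSums((x[, group == levels(group)[2], drop = FALSE] - m2)^2)
  s2 <- ss / d_g
  design_factor <- sqrt(1 / n1 + 1 / n2)

  if (!moderation) {
    d0 <- 0; s0 <- NA_real_
    s2_post <- s2
  } else {
    # moment matching on e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)
    ok <- s2 > 0
    e <- log(s2[ok]) - digamma(d_g / 2) + log(d_g / 2)
    emean <- mean(e)
    excess <- stats::var(e) - trigamma(d_g / 2)
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
      s0 <- sqrt(exp(emean))
      s2_post <- rep(s0^2, length(s2))
    } else {
      d0 <- 2 * trigamma_inverse(excess)
      s0 <- sqrt(exp(emean + digamma(d0 / 2) - log(d0 / 2)))
      s2_post <- (d0 * s0^2 + d_g * s2) / (d0 + d_g)
    }
  }

  tstat <- effect / (sqrt(s2_post) * design_factor)
  df_total <- d_g + d0
  p <- 2 * stats::pt(-abs(tstat), df_total)
  res <- data.frame(effect = effect, s = sqrt(s2), df = d_g,
                    s_post = sqrt(s2_post), t = tstat, p = p)
  rownames(res) <- rownames(x)
  structure(res, d0 = d0, s0 = s0, class = c("moderated_ttest",
                                             "data.frame"))
}

#' Select differentially expressed genes
#'
#' Genes with moderated-test p-value below \code{alpha} (default 0.01,
#' the study's differential gate between 60DAF and 2M), partitioned by
#' the sign of the effect into down- and up-regulated sets.
#'
#' @param results A \code{\link{moderated_ttest}} result (or any
#'   data.frame with \code{p} and \code{effect}).
#' @param alpha Significance threshold in (0, 1).
#' @return List with \code{selected}, \code{up}, \code{down} (character
#'   vectors of gene ids) and \code{n_selected}.
#' @export
select_differential <- function(results, alpha = 0.01) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  genes <- rownames(results)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(results)))
  sel <- results$p < alpha
  list(selected = genes[sel],
       up = genes[sel & results$effect > 0],
       down = genes[sel & results$effect < 0],
       n_selected = sum(sel))
}

#' Correlation-distance hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of gene expression profiles with distance
#' 1 - Pearson correlation and average (UPGMA) linkage, the combination
#' used to group co-expressed genes in the study. The Pearson distance
#' makes the result invariant to per-gene scaling and shifting. Merge
#' order is deterministic given the input order (ties resolved by
#' lowest-index pair first, the \code{\link[stats]{hclust}} convention).
#'
#' @param profiles Numeric matrix, genes x conditions (>= 3 conditions).
#' @param k Optional number of flat clusters to cut.
#' @return List with \code{tree} (an \code{hclust}), \code{dist} and,
#'   when \code{k} is given, \code{clusters} (named integer vector).
#' @export
hierarchical_cluster <- function(profiles, k = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need >= 2 profiles", call. = FALSE)
  if (ncol(profiles) < 3) stop("need >= 3 points per profile", call. = FALSE)
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0)) {
    nm <- rownames(profiles)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(profiles)))
    stop("zero-variance profile(s): ",
         paste(nm[v == 0], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  tree <- stats::hclust(d, method = "average")
  out <- list(tree = tree, dist = d)
  if (!is.null(k)) out$clusters <- stats::cutree(tree, k = k)
  out
}

#' qPCR relative expression by the 2^-dCt method
#'
#' Computes the relative expression of a target gene against the
#' geometric centre of a reference panel: the reference Ct is the
#' arithmetic mean of the three reference-gene Cts (the normalization
#' factor), dCt = Ct_target - Ct_ref, and relative expression = 2^-dCt.
#' \code{fold_change_ddct()} compares two conditions via
#' ddCt = dCt_1 - dCt_2 and fold change 2^-ddCt.
#'
#' @param ct_target Target-gene threshold cycle, in (0, 45).
#' @param ct_refs Numeric vector of three reference-gene Cts.
#' @return List with \code{ct_ref}, \code{delta_ct},
#'   \code{relative_expression}.
#' @export
relative_expression <- function(ct_target, ct_refs) {
  cts <- c(ct_target, ct_refs)
  if (length(ct_refs) != 3)
    stop("three reference-gene Ct values are required", call. = FALSE)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts >= 45))
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  ct_ref <- mean(ct_refs)
  dct <- ct_target - ct_ref
  list(ct_ref = ct_ref, delta_ct = dct, relative_expression = 2^(-dct))
}

#' @rdname relative_expression
#' @param delta_ct_1,delta_ct_2 dCt of the two conditions being compared.
#' @return \code{fold_change_ddct}: list with \code{delta_delta_ct} and
#'   \code{fold_change}.
#' @export
fold_change_ddct <- function(delta_ct_1, delta_ct_2) {
  ddct <- delta_ct_1 - delta_ct_2
  list(delta_delta_ct = ddct, fold_change = 2^(-ddct))
}
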