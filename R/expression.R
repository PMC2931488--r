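#' Quantile normalize and log2 transform an intensity matrix
#'
#' Maps every column onto the common distribution of across-column mean
#' quantiles (ranks preserved within columns), then log2 transforms.
#'
#' @param mat Probe x sample matrix of positive raw intensities.
#' @param log2 Apply the log2 transform after normalization.
#' @return Matrix of the same dimensions.
#' @export
quantile_normalize <- function(mat, log2 = TRUE) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("'mat' must be numeric", call. = FALSE)
  if (any(mat <= 0, na.rm = TRUE))
    stop("raw intensities must be positive", call. = FALSE)
  out <- limma::normalizeQuantiles(mat)
  if (log2) {
    if (any(out <= 0, na.rm = TRUE))
      stop("non-positive intensity after normalization", call. = FALSE)
    out <- base::log2(out)
  }
  out
}

#' Remove flagged-outlier and low-presence probes
#'
#' Cells flagged as outliers are set to missing.  A probe is removed
#' entirely if it is flagged in more than `probe_flag_threshold` of the
#' samples, or if it is present (unflagged) in strictly less than
#' `presence_threshold` of the samples.
#'
#' @param mat Probe x sample matrix.
#' @param flags 0/1 (or logical) matrix of the same dimensions marking
#'   outlier cells.
#' @param presence_threshold Minimum fraction of present samples (default
#'   0.30; probes below it are removed).
#' @param probe_flag_threshold Fraction of flagged samples above which the
#'   whole probe is dropped.
#' @return The filtered matrix (flagged cells of retained probes are `NA`).
#' @export
filter_probes <- function(mat, flags, presence_threshold = 0.30,
                          probe_flag_threshold = 0.5) {
  mat <- as.matrix(mat)
  if (is.null(flags)) flags <- matrix(0, nrow(mat), ncol(mat))
  flags <- as.matrix(flags) != 0
  if (!all(dim(flags) == dim(mat)))
    stop("'flags' must align with 'mat'", call. = FALSE)
  mat[flags] <- NA
  flag_frac <- rowMeans(flags)
  presence <- rowMeans(!is.na(mat))
  keep <- flag_frac <= probe_flag_threshold & presence >= presence_threshold
  if (!any(keep)) warning("all probes removed by filtering")
  mat[keep, , drop = FALSE]
}

#' Collapse probes to one row per transcript
#'
#' Rows with identical probe ids are averaged; among distinct probes
#' annotated to the same gene, the probe with the largest interquartile
#' range across samples is retained to represent the transcript.  Probes
#' without a gene annotation are dropped.
#'
#' @param mat Probe x sample matrix (rownames are probe ids), log2 scale.
#' @param annotation data.frame with columns `probe_id` and `gene`.
#' @return Gene x sample matrix; the representing probe ids are attached as
#'   attribute `"probe_id"`.
#' @export
collapse_probes <- function(mat, annotation) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    stop("'mat' must have probe ids as rownames", call. = FALSE)
  if (!all(c("probe_id", "gene") %in% names(annotation)))
    stop("'annotation' needs columns probe_id and gene", call. = FALSE)
  mat <- limma::avereps(mat, ID = rownames(mat))
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "", ]
  ann <- ann[!duplicated(ann$probe_id), ]
  ann <- ann[ann$probe_id %in% rownames(mat), ]
  if (!nrow(ann)) stop("no annotated probes in the matrix", call. = FALSE)
  genes <- sort(unique(ann$gene))
  picked <- vapply(genes, function(g) {
    probes <- sort(ann$probe_id[ann$gene == g])
    if (length(probes) == 1L) return(probes)
    iqr <- vapply(probes, function(p)
      stats::IQR(mat[p, ], na.rm = TRUE), numeric(1))
    probes[which.max(iqr)]          # ties: first probe id in sorted order
  }, character(1))
  out <- mat[picked, , drop = FALSE]
  rownames(out) <- genes
  attr(out, "probe_id") <- stats::setNames(picked, genes)
  out
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)), used by the moment-matching hyperparameter estimator.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated t statistics for two-group expression data
#'
#' Per gene, the log2-fold difference is the difference of group means and
#' the residual variance the pooled within-group variance with
#' `d = n1 + n2 - 2` degrees of freedom.  The gene-wise variances are
#' modelled as scaled F draws around a common prior variance `s0^2` with
#' `d0` prior degrees of freedom; `(d0, s0^2)` are estimated by closed-form
#' moment matching of the log variances (mean and variance of
#' `log s^2`, using digamma/trigamma moments of log chi-square, with the
#' trigamma equation inverted by Newton iteration).  Each gene's variance is
#' shrunk to the posterior `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated
#' t referred to a t distribution with `d + d0` degrees of freedom.
#' Benjamini-Hochberg adjusted p-values are attached.
#'
#' @param mat Gene x sample matrix on the log2 scale.
#' @param groups Character/factor of length `ncol(mat)` with exactly two
#'   levels; the fold difference is first level minus second (order of
#'   first appearance for character input).
#' @param prior_df,prior_var Optional overrides of the estimated
#'   hyperparameters (`prior_df = 0` turns shrinkage off, recovering the
#'   ordinary pooled t; `prior_df = Inf` gives every gene the common
#'   variance `prior_var`).
#' @param alpha FDR threshold for the significance flag.
#' @return Object of class `moderated_fit`: `results` data.frame (gene,
#'   log2fc, s2, moderated_t, df_total, p_value, adj_p, significant),
#'   `prior_df`, `prior_var`, `groups`.
#' @export
fit_moderated_t <- function(mat, groups, prior_df = NULL, prior_var = NULL,
                            alpha = 0.05) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat))
    stop("'groups' must have one entry per column", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  i1 <- groups == lev[1]; i2 <- groups == lev[2]
  if (sum(i1) < 2 || sum(i2) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (nrow(mat) < 10L && is.null(prior_df))
    stop("hyperparameter estimation needs at least 10 genes", call. = FALSE)

  n1 <- rowSums(!is.na(mat[, i1, drop = FALSE]))
  n2 <- rowSums(!is.na(mat[, i2, drop = FALSE]))
  m1 <- rowMeans(mat[, i1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(mat[, i2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(mat[, i1, drop = FALSE], 1, stats::var, na.rm = TRUE)
  v2 <- apply(mat[, i2, drop = FALSE], 1, stats::var, na.rm = TRUE)
  v1[n1 < 2] <- NA; v2[n2 < 2] <- NA
  df <- n1 + n2 - 2
  s2 <- (ifelse(n1 > 1, (n1 - 1) * v1, 0) +
           ifelse(n2 > 1, (n2 - 1) * v2, 0)) / df
  fold <- m1 - m2

  if (is.null(prior_df)) {
    ok <- is.finite(s2) & s2 > 0 & df > 0
    if (sum(ok) < 10L)
      stop("hyperparameter estimation needs at least 10 genes with positive variance",
           call. = FALSE)
    z <- log(s2[ok]); d <- df[ok]
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - mean(trigamma(d / 2))
    if (is.finite(evar) && evar > 0) {
      prior_df <- 2 * trigamma_inverse(evar)
      prior_var <- exp(mean(e) + digamma(prior_df / 2) - log(prior_df / 2))
    } else {
      prior_df <- Inf
      prior_var <- exp(mean(e))
    }
  } else if (is.null(prior_var)) {
    if (is.infinite(prior_df))
      stop("'prior_var' must be supplied with infinite 'prior_df'",
           call. = FALSE)
    prior_var <- if (prior_df == 0) 0 else stats::median(s2, na.rm = TRUE)
  }

  s2_post <- if (is.infinite(prior_df)) rep(prior_var, length(s2)) else
    (prior_df * prior_var + df * s2) / (prior_df + df)
  df_total <- df + prior_df
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, fold / se, ifelse(fold == 0, 0, sign(fold) * Inf))
  p <- 2 * stats::pt(-abs(tt), df_total)
  p[!is.finite(tt) & !is.na(tt)] <- 0
  adj <- rep(NA_real_, length(p))
  good <- is.finite(p)
  p_for_adjust <- pmax(p[good], .Machine$double.xmin)  # BH needs p in (0, 1]
  adj[good] <- bh_adjust(p_for_adjust)
  genes <- rownames(mat)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(mat)))
  res <- data.frame(
    gene = genes, log2fc = fold, s2 = s2, moderated_t = tt,
    df_total = df_total, p_value = p, adj_p = adj,
    significant = !is.na(adj) & adj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(results = res, prior_df = prior_df, prior_var = prior_var,
         groups = lev, alpha = alpha),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated t fit: %d genes, %s vs %s\n", nrow(x$results),
              x$groups[1], x$groups[2]))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.4g\n",
              x$prior_df, x$prior_var))
  cat(sprintf("  %d genes significant at adjusted p < %.2f\n",
              sum(x$results$significant, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' @export
summary.moderated_fit <- function(object, ...) {
  r <- object$results[order(object$results$adj_p), ]
  print(object)
  cat("Top genes:\n")
  print(utils::head(r[, c("gene", "log2fc", "moderated_t", "adj_p")], 10),
        digits = 3, row.names = FALSE)
  invisible(r)
}

#' @export
coef.moderated_fit <- function(object, ...) {
  stats::setNames(object$results$log2fc, object$results$gene)
}

#' @export
plot.moderated_fit <- function(x, ...) {
  r <- x$results
  graphics::plot(r$log2fc, -log10(pmax(r$adj_p, 1e-300)),
                 pch = ifelse(r$significant, 19, 1),
                 xlab = "log2-fold difference",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Restrict results to a curated gene panel
#'
#' @param fit A `moderated_fit` (or its `results` data.frame).
#' @param panel Character vector of panel gene symbols.
#' @return The fit restricted to panel genes found in the results; the
#'   number found is attached as attribute `"n_found"`.
#' @export
select_panel <- function(fit, panel) {
  res <- if (inherits(fit, "moderated_fit")) fit$results else fit
  found <- intersect(panel, res$gene)
  if (!length(found))
    stop("no panel genes present in the results", call. = FALSE)
  res <- res[res$gene %in% found, , drop = FALSE]
  if (inherits(fit, "moderated_fit")) {
    fit$results <- res
    attr(fit, "n_found") <- length(found)
    fit
  } else {
    attr(res, "n_found") <- length(found)
    res
  }
}

#' Hierarchically cluster a gene expression matrix for heatmap display
#'
#' Rows (genes) are mean-centered, then genes and samples are clustered by
#' agglomerative hierarchical clustering with Euclidean distance and
#' complete linkage.  Rows and columns are sorted by label before
#' clustering so the output is deterministic and invariant to input order.
#'
#' @param mat Gene x sample matrix (>= 2 rows and >= 2 columns) with
#'   dimnames.
#' @param center Mean-center each row first (default `TRUE`).
#' @return Object of class `expr_clust`: `matrix` (centered, reordered to
#'   dendrogram leaf order), `row_hclust`, `col_hclust`, and Newick strings
#'   `row_newick`, `col_newick`.
#' @export
cluster_heatmap <- function(mat, center = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("clustering needs at least 2 genes and 2 samples", call. = FALSE)
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("gene_%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  if (center) mat <- mat - rowMeans(mat, na.rm = TRUE)
  mat[is.na(mat)] <- 0    # missing cells sit at the row mean after centering
  hr <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  hc <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                      method = "complete")
  structure(
    list(matrix = mat[hr$order, hc$order, drop = FALSE],
         row_hclust = hr, col_hclust = hc,
         row_newick = hclust_newick(hr), col_newick = hclust_newick(hc)),
    class = "expr_clust"
  )
}

# Newick serialization of an hclust dendrogram.
hclust_newick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}

#' @export
print.expr_clust <- function(x, ...) {
  cat(sprintf("<expr_clust> %d genes x %d samples (Euclidean, complete linkage)\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
plot.expr_clust <- function(x, ...) {
  stats::heatmap(x$matrix, Rowv = stats::as.dendrogram(x$row_hclust),
                 Colv = stats::as.dendrogram(x$col_hclust), scale = "none",
                 ...)
  invisible(x)
}
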