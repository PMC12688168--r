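# project points onto the polyline through `nodes` (rows ordered along the
# curve); returns arc-length positions and squared residuals
project_polyline <- function(nodes, x) {
  m <- nrow(nodes)
  seg <- diff(nodes)                       # (m-1) x d
  seglen2 <- rowSums(seg^2)
  seglen <- sqrt(seglen2)
  cum <- c(0, cumsum(seglen))
  lambda <- numeric(nrow(x))
  dist2 <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    p <- x[i, ]
    best_d2 <- Inf; best_l <- 0
    for (s in seq_len(m - 1)) {
      if (seglen2[s] == 0) {
        t <- 0
      } else {
        t <- sum((p - nodes[s, ]) * seg[s, ]) / seglen2[s]
        t <- min(1, max(0, t))
      }
      proj <- nodes[s, ] + t * seg[s, ]
      d2 <- sum((p - proj)^2)
      if (d2 < best_d2) {
        best_d2 <- d2
        best_l <- cum[s] + t * seglen[s]
      }
    }
    lambda[i] <- best_l
    dist2[i] <- best_d2
  }
  list(lambda = lambda, dist2 = dist2)
}

#' Fit a principal curve through a point cloud
#'
#' Simplified Hastie-Stuetzle iteration: the curve is initialized at the
#' first principal component, then projection onto the current curve and
#' span-smoothing of each coordinate against arc length alternate until the
#' mean squared projection distance changes by less than `tol` (or
#' `max_iter` iterations). Smoothing uses locally weighted regression
#' ([stats::lowess()]) with span `span`; for data lying exactly on a line the
#' fit coincides with the line and projection residuals vanish.
#'
#' @param x numeric matrix, samples x dimensions.
#' @param span lowess smoother span (default 0.5).
#' @param max_iter maximal iterations (default 100).
#' @param tol convergence tolerance on the mean squared projection distance
#'   (default 1e-6).
#' @return List with `nodes` (curve nodes ordered along the curve, one per
#'   sample), `lambda` (arc-length position of each sample's projection),
#'   `mse` (mean squared projection distance), `n_iter`, `converged`.
#' @export
fit_principal_curve <- function(x, span = 0.5, max_iter = 100, tol = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("at least 3 samples are required")
  if (max(apply(x, 2, function(v) diff(range(v)))) < 1e-12) {
    stop("degenerate input: all points identical")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  lambda <- pc$x[, 1]
  mse_prev <- Inf
  nodes <- NULL
  n_iter <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    ord <- order(lambda)
    fitted <- matrix(0, nrow(x), ncol(x))
    for (j in seq_len(ncol(x))) {
      if (diff(range(lambda)) < 1e-12) {
        fitted[ord, j] <- mean(x[, j])
      } else {
        lw <- stats::lowess(lambda[ord], x[ord, j], f = span)
        fitted[ord, j] <- lw$y
      }
    }
    nodes <- fitted[ord, , drop = FALSE]
    pr <- project_polyline(nodes, x)
    lambda <- pr$lambda
    mse <- mean(pr$dist2)
    if (abs(mse_prev - mse) < tol) {
      converged <- TRUE
      break
    }
    mse_prev <- mse
  }
  pr <- project_polyline(nodes, x)
  list(nodes = nodes, lambda = pr$lambda, mse = mean(pr$dist2),
       n_iter = n_iter, converged = converged)
}

#' Pathway deregulation score along a principal curve
#'
#' Simplified pathway-deregulation scoring: the pathway's genes are
#' standardized by the normal samples' mean and SD, the samples are reduced
#' by PCA to the components explaining at least `var_explained` of the
#' variance (capped at `max_dims`), and a principal curve is fitted through
#' all samples. Each sample's deviation is the absolute arc-length distance
#' of its projection from the median projection of the normal samples; the
#' normal samples' own median deviation (their typical spread along the
#' curve) is subtracted, negatives are clipped to zero, and the result is
#' divided by its maximum, so scores lie in `[0, 1]` per pathway and the
#' median normal sample scores exactly 0.
#'
#' This is a deliberate simplification of the published principal-curve
#' deregulation algorithm: its gene-filtering and curve-stability heuristics
#' are omitted, and deviation is measured along the curve rather than by the
#' full pipeline. Outputs are labelled accordingly.
#'
#' @param expr normalized expression matrix (genes x samples), e.g. VST.
#' @param pathway_genes character vector of the pathway's genes.
#' @param normal_ids sample ids of the normal reference samples (>= 2).
#' @param var_explained PCA variance target (default 0.9).
#' @param max_dims PCA dimension cap (default 5).
#' @param span,max_iter,tol passed to [fit_principal_curve()].
#' @return Data frame with one row per sample: `sample`, `pds`,
#'   `curve_position`; or `NULL` (with a warning) when fewer than 3 pathway
#'   genes are usable.
#' @export
compute_pds <- function(expr, pathway_genes, normal_ids, var_explained = 0.9,
                        max_dims = 5, span = 0.5, max_iter = 100,
                        tol = 1e-6) {
  genes <- intersect(pathway_genes, rownames(expr))
  if (length(normal_ids) < 2 || !all(normal_ids %in% colnames(expr))) {
    stop("at least 2 normal sample ids present in `expr` are required")
  }
  sub <- expr[genes, , drop = FALSE]
  nmean <- rowMeans(sub[, normal_ids, drop = FALSE])
  nsd <- apply(sub[, normal_ids, drop = FALSE], 1, stats::sd)
  osd <- apply(sub, 1, stats::sd)
  nsd[nsd < 1e-12] <- osd[nsd < 1e-12]   # flat in normals: fall back
  usable <- nsd > 1e-12
  if (sum(usable) < 3) {
    warning("pathway skipped: fewer than 3 usable genes")
    return(NULL)
  }
  z <- (sub[usable, , drop = FALSE] - nmean[usable]) / nsd[usable]
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  ndim <- min(max_dims, which(ve >= var_explained)[1], length(pca$sdev))
  scores <- pca$x[, seq_len(ndim), drop = FALSE]
  curve <- fit_principal_curve(scores, span = span, max_iter = max_iter,
                               tol = tol)
  lambda <- curve$lambda
  names(lambda) <- colnames(expr)
  dev <- abs(lambda - stats::median(lambda[normal_ids]))
  # subtract the normals' typical spread along the curve (their upper
  # median, so that at least half the normals land exactly at zero and the
  # median normal PDS is 0 by construction), clipping negatives
  nd <- sort(dev[normal_ids])
  dev <- pmax(0, dev - nd[ceiling((length(nd) + 1) / 2)])
  pds <- if (max(dev) > 0) dev / max(dev) else dev
  data.frame(sample = colnames(expr), pds = unname(pds),
             curve_position = unname(lambda), stringsAsFactors = FALSE)
}

#' PDS matrix over a gene-set collection
#'
#' Applies [compute_pds()] to every pathway of a collection and assembles
#' the wide pathways x samples score matrix (the data behind the cohort-level
#' deregulation heatmap). Pathways with fewer than 3 usable genes are
#' dropped.
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param collection named list of pathway gene vectors.
#' @param normal_ids normal reference sample ids.
#' @param ... passed to [compute_pds()].
#' @return Numeric matrix, pathways x samples.
#' @export
pds_matrix <- function(expr, collection, normal_ids, ...) {
  rows <- lapply(names(collection), function(pw) {
    r <- suppressWarnings(compute_pds(expr, collection[[pw]], normal_ids, ...))
    if (is.null(r)) return(NULL)
    stats::setNames(r$pds, r$sample)
  })
  names(rows) <- names(collection)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no pathway had >= 3 usable genes")
  do.call(rbind, rows)
}
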