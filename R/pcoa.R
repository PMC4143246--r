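#' Principal coordinate analysis of a distance matrix
#'
#' Classic metric PCoA: the squared distance matrix is double-centered
#' (Gower), eigendecomposed, and coordinates are formed from the positive
#' eigenvalues as `v_c * sqrt(lambda_c)`. Negative eigenvalues (which arise
#' when the distance is not Euclidean-embeddable, as DA need not be) are
#' reported but excluded from the percent-variance denominator; no
#' Cailliez/Lingoes correction is applied by default. Axis signs are fixed by
#' making the largest-magnitude coordinate on each axis positive.
#'
#' @param D a `da_matrix`, `dist` or symmetric matrix with zero diagonal.
#' @param k number of axes to return (default 3; capped at the number of
#'   positive eigenvalues).
#' @param cailliez add the Cailliez constant to off-diagonal distances to
#'   remove negative eigenvalues before decomposing.
#' @return a `pcoa_result`: list with `coordinates` (n x k, rownames =
#'   labels), `eigenvalues` (all, descending), `percent_variance` (per
#'   positive eigenvalue, summing to 100) and `labels`.
#' @export
pcoa <- function(D, k = 3, cailliez = FALSE) {
  if (inherits(D, "da_matrix")) D <- D$d
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("u", seq_len(nrow(D)))
  n <- nrow(D)
  if (k > n - 1) stop("k must be at most n - 1")
  gower <- function(Dm) {
    A <- -0.5 * Dm^2
    Ac <- sweep(A, 1, rowMeans(A))
    Ac <- sweep(Ac, 2, colMeans(A))
    Ac + mean(A)
  }
  if (cailliez) {
    # smallest constant c so that D + c (off-diagonal) is Euclidean
    B1 <- gower(D)
    A <- -0.5 * D
    J <- diag(n) - matrix(1 / n, n, n)
    B2 <- J %*% A %*% J
    M <- rbind(cbind(matrix(0, n, n), 2 * B1),
               cbind(-diag(n), -4 * B2))
    cc <- max(Re(eigen(M, only.values = TRUE)$values))
    D <- D + cc * (1 - diag(n))
  }
  e <- eigen(gower(D), symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev) * 1e-9
  pct <- 100 * ev[pos] / sum(ev[pos])
  k_eff <- min(k, sum(pos))
  coords <- e$vectors[, which(pos)[seq_len(k_eff)], drop = FALSE] %*%
    diag(sqrt(ev[which(pos)[seq_len(k_eff)]]), k_eff)
  for (c in seq_len(ncol(coords))) {
    s <- sign(coords[which.max(abs(coords[, c])), c])
    if (s < 0) coords[, c] <- -coords[, c]
  }
  dimnames(coords) <- list(labels, paste0("Axis", seq_len(k_eff)))
  structure(list(coordinates = coords, eigenvalues = ev,
                 percent_variance = pct, labels = labels),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat("PCoA over", length(x$labels), "units;",
      "first", k, "axes explain",
      sprintf("%.1f%%", sum(x$percent_variance[seq_len(k)])), "\n")
  cat("percent variance:",
      paste(sprintf("%.1f", utils::head(x$percent_variance, 5)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Write PCoA coordinates and eigenvalue table to TSV
#'
#' @param res a `pcoa_result`.
#' @param path coordinates path; the eigenvalue/percent table goes to
#'   `<path>.eig`.
#' @return `path`, invisibly.
#' @export
write_pcoa <- function(res, path) {
  utils::write.table(cbind(label = rownames(res$coordinates),
                           as.data.frame(res$coordinates)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  eig <- data.frame(axis = seq_along(res$eigenvalues),
                    eigenvalue = res$eigenvalues)
  eig$percent_variance <- NA_real_
  eig$percent_variance[seq_along(res$percent_variance)] <- res$percent_variance
  utils::write.table(eig, paste0(path, ".eig"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
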