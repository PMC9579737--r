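#' Principal-coordinates embedding of a trait dissimilarity matrix
#'
#' Classical metric multidimensional scaling of a Gower matrix, giving each
#' species Euclidean coordinates whose pairwise distances reproduce the
#' (corrected) dissimilarities. The embedding realizes the "centroid in
#' trait space" needed by functional dispersion for mixed-type traits, whose
#' Gower matrices are generally non-Euclidean.
#'
#' If the double-centred matrix has negative eigenvalues, the requested
#' correction is applied and the decomposition re-run: `"cailliez"` adds the
#' smallest constant to all off-diagonal dissimilarities that makes the
#' matrix Euclidean (the default, matching the standard realization of
#' centroid-based functional diversity metrics); `"sqrt"` takes the
#' element-wise square root (Gower matrices are metric, and their square
#' root is very often Euclidean); `"none"` keeps only the non-negative part
#' of the spectrum and records a warning on the object.
#'
#' @param d an `fd_dissim` matrix (see [gower_distance()]).
#' @param correction `"cailliez"`, `"sqrt"` or `"none"`.
#' @param tol relative eigenvalue tolerance: axes with eigenvalue greater
#'   than `tol * max(eigenvalue)` are retained.
#' @return an `fd_embedding` list: `points` (species x axes coordinate
#'   matrix), `eigenvalues`, `correction`, `negative_eigenvalues` flag, and
#'   `cailliez_constant` when applicable.
#' @export
trait_embedding <- function(d, correction = c("cailliez", "sqrt", "none"),
                            tol = 1e-10) {
  correction <- match.arg(correction)
  d <- as_dissim(d)
  n <- nrow(d)
  sp <- rownames(d)

  decompose <- function(dm) {
    b <- double_centre(-0.5 * dm^2)
    e <- eigen(b, symmetric = TRUE)
    e
  }

  e <- decompose(d)
  neg <- any(e$values < -tol * max(abs(e$values)))
  ccst <- NA_real_
  used <- unclass(d)

  if (neg && correction == "cailliez") {
    ccst <- cailliez_constant(unclass(d))
    used <- unclass(d) + ccst
    diag(used) <- 0
    e <- decompose(used)
  } else if (neg && correction == "sqrt") {
    used <- sqrt(unclass(d))
    e <- decompose(used)
  } else if (neg && correction == "none") {
    warning("negative eigenvalues retained uncorrected; ",
            "embedding distances only approximate the input", call. = FALSE)
  }

  keep <- e$values > tol * max(e$values)
  if (any(keep)) {
    pts <- e$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(e$values[keep]), sum(keep))
    dimnames(pts) <- list(sp, paste0("axis", seq_len(ncol(pts))))
  } else {
    # fully degenerate input (all species coincide): zero-dimensional space
    pts <- matrix(0, n, 1, dimnames = list(sp, "axis1"))
  }

  structure(
    list(
      points = pts,
      eigenvalues = e$values,
      correction = correction,
      negative_eigenvalues = neg,
      cailliez_constant = ccst,
      species = sp
    ),
    class = "fd_embedding"
  )
}

double_centre <- function(a) {
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# Smallest additive constant c such that d_ij + c (i != j) is Euclidean:
# the largest real eigenvalue of the 2n x 2n block matrix
#   [ 0        2*D1 ]
#   [ -I   -4*D2  ]
# with D1 the double-centred -1/2 d^2 and D2 the double-centred -1/2 d.
cailliez_constant <- function(d) {
  n <- nrow(d)
  d1 <- double_centre(-0.5 * d^2)
  d2 <- double_centre(-0.5 * d)
  m <- rbind(
    cbind(matrix(0, n, n), 2 * d1),
    cbind(-diag(n), -4 * d2)
  )
  ev <- eigen(m, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' @export
print.fd_embedding <- function(x, ...) {
  cat("<trait-space embedding: ", length(x$species), " species, ",
      ncol(x$points), " axes, correction = ", x$correction, ">\n", sep = "")
  invisible(x)
}

#' Euclidean distances reproduced by an embedding
#'
#' @param embedding an `fd_embedding`.
#' @return species-by-species Euclidean distance matrix of the coordinates.
#' @export
embedding_distances <- function(embedding) {
  as.matrix(stats::dist(embedding$points))
}
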