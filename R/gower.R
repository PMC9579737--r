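#' Mixed-type Gower dissimilarity between species
#'
#' Pairwise Gower distance over the traits of a table, honouring trait kinds:
#' numeric and ordinal traits contribute `|x_i - x_j| / range`, with the
#' range taken over the whole table; categorical traits contribute 0 on a
#' match and 1 otherwise; binary traits contribute the symmetric 0/1
#' mismatch. The pairwise distance is the weighted mean of the contributions
#' over the traits where *both* species are non-missing, with weights
#' renormalized per pair (Gower's original missing-data rule). Distances are
#' therefore bounded in \[0, 1\].
#'
#' A numeric trait with zero range over the table carries no information;
#' its contribution is defined as 0 and a warning is raised. A species pair
#' sharing no non-missing trait is an error.
#'
#' @param traits a `fd_traits` table (usually after [prepare_traits()]).
#' @param weights optional non-negative per-trait weights, named or in
#'   schema order; default equal.
#' @return a symmetric species-by-species matrix of class `fd_dissim` with
#'   zero diagonal and species ids as dimnames.
#' @examples
#' tt <- trait_table(
#'   data.frame(species = c("a", "b", "c"),
#'              size = c(0, 5, 10), color = c("red", "red", "blue")),
#'   trait_schema(c("size", "color"), c("numeric", "categorical"))
#' )
#' gower_distance(tt)
#' @export
gower_distance <- function(traits, weights = NULL) {
  sch <- trait_schema_of(traits)
  n <- nrow(traits)
  if (n < 2) stop("need at least 2 species", call. = FALSE)
  sp <- traits$species

  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, nrow(sch)), sch$trait)
  } else if (!is.null(names(weights))) {
    if (!all(sch$trait %in% names(weights))) {
      stop("weights must name every trait", call. = FALSE)
    }
    weights <- weights[sch$trait]
  } else {
    stopifnot(length(weights) == nrow(sch))
    weights <- stats::setNames(weights, sch$trait)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (i in seq_len(nrow(sch))) {
    tr <- sch$trait[i]
    w <- weights[[tr]]
    if (w == 0) next
    v <- traits[[tr]]
    present <- !is.na(v)
    if (!any(present)) next
    pair_ok <- outer(present, present, `&`)
    if (sch$kind[i] %in% c("numeric", "ordinal")) {
      rng <- diff(range(v, na.rm = TRUE))
      if (rng == 0) {
        warning("trait '", tr, "' has zero range; contribution set to 0",
                call. = FALSE)
        contrib <- matrix(0, n, n)
      } else {
        vv <- v
        vv[!present] <- 0  # masked by pair_ok below
        contrib <- abs(outer(vv, vv, `-`)) / rng
      }
    } else {  # categorical or binary: 0/1 mismatch
      idx <- match(v, unique(v[present]))
      idx[!present] <- 0L
      contrib <- (outer(idx, idx, `!=`)) * 1
    }
    num <- num + ifelse(pair_ok, contrib, 0) * w
    den <- den + pair_ok * w
  }

  no_info <- den == 0
  diag(no_info) <- FALSE
  if (any(no_info)) {
    ij <- which(no_info, arr.ind = TRUE)[1, ]
    stop("species pair with no shared non-missing trait: ",
         sp[ij[1]], " / ", sp[ij[2]], call. = FALSE)
  }
  d <- num / den
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against float noise
  dimnames(d) <- list(sp, sp)
  class(d) <- c("fd_dissim", "matrix", "array")
  d
}

#' @export
print.fd_dissim <- function(x, ...) {
  cat("<Gower dissimilarity:", nrow(x), "species>\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Write / read a dissimilarity matrix as square CSV
#'
#' @param d an `fd_dissim` matrix.
#' @param path file path; species ids form the header row and first column.
#' @export
write_dissim <- function(d, path) {
  df <- tibble::as_tibble(unclass(d), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(species = rownames(d)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_dissim
#' @export
read_dissim <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$species
  as_dissim(m)
}

#' Validate a plain matrix as a dissimilarity matrix
#'
#' @param m square numeric matrix with matching dimnames.
#' @export
as_dissim <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix not square", call. = FALSE)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("dimnames must be identical species ids", call. = FALSE)
  }
  if (any(is.na(m))) stop("missing entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix not symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(m < 0) || any(m > 1 + 1e-12)) {
    stop("entries must lie in [0, 1]", call. = FALSE)
  }
  class(m) <- c("fd_dissim", "matrix", "array")
  m
}
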