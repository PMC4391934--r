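# Per-pixel non-negative least-squares spectral unmixing.
#
# Each pixel spectrum y is decomposed as y ~ E a with a >= 0, where E is the
# bands x 3 endmember matrix (CK, Ki67, AF). For a full-column-rank E the
# NNLS optimum restricted to its active support equals the unconstrained LS
# solution on that support, so with few endmembers the exact optimum can be
# found by enumerating all column subsets, keeping the feasible solutions and
# taking the one with the smallest residual. This enumeration is done in
# vectorised form across all pixels of a cube.

subset_masks <- function(p) {
  lapply(seq_len(2^p) - 1L, function(k) as.logical(bitwAnd(k, 2^(seq_len(p) - 1L)) > 0))
}

#' Unmix a single pixel spectrum
#'
#' Solves `argmin_{a >= 0} || E a - y ||_2` exactly (active-set enumeration)
#' and returns the abundance triple and the residual norm.
#'
#' @param y Numeric pixel spectrum, one value per band. Negative entries
#'   (possible in background-subtracted real data) are clipped to 0.
#' @param E Bands x components endmember matrix with full column rank, e.g.
#'   `as.matrix(build_default_library())`.
#' @return A list with `abundance` (named numeric vector) and `residual`
#'   (Euclidean norm of `E a - y`).
#' @examples
#' E <- as.matrix(build_default_library())
#' unmix_pixel(E %*% c(0.3, 0.5, 0.2), E)$abundance
#' @export
unmix_pixel <- function(y, E) {
  y <- as.numeric(y)
  E <- as.matrix(E)
  if (length(y) != nrow(E))
    stop("pixel spectrum length does not match the endmember matrix", call. = FALSE)
  sv <- svd(E, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-10 * max(sv))
    stop("ill-conditioned library: endmember matrix is rank deficient", call. = FALSE)
  y <- pmax(y, 0)
  res <- unmix_matrix(matrix(y, ncol = 1), E)
  a <- res$abundance[, 1]
  names(a) <- colnames(E)
  list(abundance = a, residual = res$residual[1])
}

# Exact NNLS for all columns of Y (bands x pixels) at once.
# Returns abundance (p x pixels) and residual (pixels).
unmix_matrix <- function(Y, E) {
  p <- ncol(E)
  npix <- ncol(Y)
  yty <- colSums(Y^2)
  best_res2 <- yty                      # empty support: a = 0
  best_a <- matrix(0, p, npix)
  for (S in subset_masks(p)) {
    k <- sum(S)
    if (k == 0) next
    Es <- E[, S, drop = FALSE]
    M <- crossprod(Es)                  # k x k
    EtY <- crossprod(Es, Y)             # k x pixels
    A <- solve(M, EtY)
    feas <- colSums(A < -1e-10) == 0
    if (!any(feas)) next
    A[A < 0] <- 0
    res2 <- yty - colSums(A * EtY) * 2 + colSums(A * (M %*% A))
    better <- feas & (res2 < best_res2 - 1e-12 * pmax(yty, 1))
    if (any(better)) {
      best_res2[better] <- res2[better]
      best_a[, better] <- 0
      best_a[S, better] <- A[, better]
    }
  }
  # recompute the residual directly; the expanded quadratic form used for
  # subset selection loses precision to cancellation near zero
  list(abundance = best_a, residual = sqrt(colSums((E %*% best_a - Y)^2)))
}

#' Abundance maps from unmixing a spectral cube
#'
#' Applies [unmix_pixel()] to every pixel of a cube (vectorised), producing
#' per-pixel CK, Ki67 and autofluorescence abundance maps plus a residual
#' map, all aligned pixel-for-pixel with the cube.
#'
#' @param cube A [spectral_cube()].
#' @param library An [endmember_library()] on the same wavelength grid.
#' @return An object of class `abundance_maps`: a list with matrices
#'   `ck_map`, `ki67_map`, `af_map`, `residual_map` and the logical flag
#'   `af_dropped`.
#' @export
unmix_cube <- function(cube, library) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(library, "endmember_library"))
  if (!same_grid(cube$grid, library$grid))
    stop("cube and library are on different wavelength grids", call. = FALSE)
  E <- library$matrix
  d <- dim(cube$intensities)
  Y <- t(matrix(cube$intensities, nrow = d[1] * d[2], ncol = d[3]))  # bands x pixels
  nneg <- sum(Y < 0)
  if (nneg > 0) {
    message(sprintf("clipped %d negative intensities to 0 before unmixing", nneg))
    Y[Y < 0] <- 0
  }
  res <- unmix_matrix(Y, E)
  structure(list(
    ck_map  = matrix(res$abundance[1, ], d[1], d[2]),
    ki67_map = matrix(res$abundance[2, ], d[1], d[2]),
    af_map  = matrix(res$abundance[3, ], d[1], d[2]),
    residual_map = matrix(res$residual, d[1], d[2]),
    af_dropped = FALSE), class = "abundance_maps")
}

#' @export
print.abundance_maps <- function(x, ...) {
  cat(sprintf("abundance maps %d x %d (CK, Ki67, AF%s); total CK %.4g, Ki67 %.4g\n",
              nrow(x$ck_map), ncol(x$ck_map),
              if (x$af_dropped) " dropped" else "",
              sum(x$ck_map), sum(x$ki67_map)))
  invisible(x)
}

#' Delete the autofluorescence component
#'
#' Zeroes the autofluorescence map so that it is excluded from all downstream
#' quantification (the background is removed at the last step before
#' quantification). CK and Ki67 maps are untouched; the operation is
#' idempotent.
#'
#' @param maps An `abundance_maps` object from [unmix_cube()].
#' @return The maps with `af_map` zeroed and `af_dropped = TRUE`.
#' @export
drop_autofluorescence <- function(maps) {
  stopifnot(inherits(maps, "abundance_maps"))
  maps$af_map[] <- 0
  maps$af_dropped <- TRUE
  maps
}
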