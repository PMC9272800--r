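#' Neighbourhood lattice over bin pairs
#'
#' Hi-C bin pairs live on a two-dimensional grid: the pair \eqn{s = (i, j)}
#' has the four neighbours \eqn{(i+1, j)}, \eqn{(i-1, j)}, \eqn{(i, j+1)} and
#' \eqn{(i, j-1)} that exist on the grid. `pair_lattice()` builds this
#' structure either for a full `rows x cols` rectangle (the layout used by
#' the synthetic-data generator) or for an arbitrary set of `(i, j)` sites
#' such as the upper triangle of a binned region.
#'
#' @param rows,cols Dimensions of a rectangular grid. Ignored when `sites`
#'   is supplied.
#' @param sites Optional data frame with integer columns `i` and `j`, one row
#'   per lattice site. Row order defines the site index.
#' @param n_keep Optionally keep only the first `n_keep` sites in row-major
#'   order (the generator draws labels on the full rectangle and keeps the
#'   first `n_pairs` sites).
#'
#' @return An object of class `pair_lattice`: a list with `n_sites`, a
#'   `sites` tibble (`site`, `i`, `j`) and an `n_sites x 4` integer neighbour
#'   matrix `nbr` (0 marks a missing neighbour).
#' @examples
#' lat <- pair_lattice(3, 3)
#' lat$n_sites
#' @export
pair_lattice <- function(rows = NULL, cols = NULL, sites = NULL,
                         n_keep = NULL) {
  if (is.null(sites)) {
    rows <- check_count(rows, "rows")
    cols <- check_count(cols, "cols")
    sites <- tibble(
      i = rep(seq_len(rows), each = cols),
      j = rep(seq_len(cols), times = rows)
    )
  } else {
    if (!all(c("i", "j") %in% names(sites))) {
      abort("`sites` must have integer columns `i` and `j`")
    }
    sites <- tibble(i = as.integer(sites$i), j = as.integer(sites$j))
    if (anyDuplicated(paste(sites$i, sites$j))) {
      abort("duplicated (i, j) sites in lattice")
    }
  }
  if (!is.null(n_keep)) {
    n_keep <- check_count(n_keep, "n_keep")
    if (n_keep > nrow(sites)) abort("lattice too small for `n_keep` sites")
    sites <- sites[seq_len(n_keep), ]
  }
  n <- nrow(sites)
  key <- paste(sites$i, sites$j)
  idx <- setNames(seq_len(n), key)
  nbr <- matrix(0L, n, 4)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (a in seq_along(shifts)) {
    k <- paste(sites$i + shifts[[a]][1], sites$j + shifts[[a]][2])
    hit <- idx[k]
    nbr[, a] <- ifelse(is.na(hit), 0L, as.integer(hit))
  }
  structure(
    list(
      n_sites = n,
      sites = mutate(sites, site = dplyr::row_number(), .before = 1),
      nbr = nbr,
      shape = if (!is.null(rows)) c(rows, cols) else NULL
    ),
    class = "pair_lattice"
  )
}

#' @export
print.pair_lattice <- function(x, ...) {
  cat("<pair_lattice> ", x$n_sites, " sites",
      if (!is.null(x$shape)) sprintf(" (%d x %d grid)", x$shape[1], x$shape[2]),
      "\n", sep = "")
  invisible(x)
}

#' Number of unordered neighbour pairs with equal labels
#'
#' The sufficient statistic of the Potts model: each unordered neighbour pair
#' \eqn{(s \sim t)} is counted once.
#'
#' @param z Integer label vector over lattice sites.
#' @param lattice A [pair_lattice()].
#' @return Integer count.
#' @export
concordant_pairs <- function(z, lattice) {
  stopifnot(inherits(lattice, "pair_lattice"))
  if (length(z) != lattice$n_sites) abort("label vector length != lattice size")
  cpp_concordant_pairs(lattice$nbr, as.integer(z))
}
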