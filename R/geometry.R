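## Surface lattice geometry: site addressing and neighbourhoods.

.GEOMETRIES <- c(hex6 = 0L, square4 = 1L, moore8 = 2L, tri3 = 3L)
.BOUNDARIES <- c(periodic = 0L, bounded = 1L)

#' Define a surface lattice
#'
#' The surface is a rectangular array of `height * width` sites, each holding
#' at most one cell. Four neighbourhood structures are supported: `hex6`
#' (hexagonal, the default; six neighbours), `square4` (von Neumann, four),
#' `moore8` (eight) and `tri3` (honeycomb / triangular coordination, three).
#' Hexagonal sites use axial (rhombic) addressing on the rectangular array:
#' the neighbours of site (r, c) are at offsets (0,+1), (0,-1), (+1,0),
#' (-1,0), (-1,+1) and (+1,-1). This offset set is closed under negation, so
#' the neighbour relation is symmetric on a torus of any size. `tri3` uses
#' the two horizontal offsets plus (+1,0) when r + c is even and (-1,0) when
#' odd, which requires an even `height` under periodic boundaries.
#'
#' The boundary defaults to periodic (toroidal) to avoid edge artefacts in
#' spatial pattern statistics; `bounded` drops out-of-range neighbours.
#'
#' @param width,height positive integers; number of sites per row / number
#'   of rows. The default 100 x 100 gives a surface carrying capacity of
#'   10,000 cells.
#' @param neighbourhood one of `"hex6"`, `"square4"`, `"moore8"`, `"tri3"`.
#' @param boundary `"periodic"` (default) or `"bounded"`.
#' @return An object of class `lattice_spec`.
#' @examples
#' sp <- lattice_spec(5, 5)
#' neighbours(sp, 1, 1)
#' @export
lattice_spec <- function(width = 100L, height = 100L,
                         neighbourhood = c("hex6", "square4", "moore8",
                                           "tri3"),
                         boundary = c("periodic", "bounded")) {
  neighbourhood <- match.arg(neighbourhood)
  boundary <- match.arg(boundary)
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || width < 1L) stop("'width' must be a positive integer")
  if (is.na(height) || height < 1L) stop("'height' must be a positive integer")
  if (neighbourhood == "tri3" && boundary == "periodic" && height %% 2L != 0L)
    stop("tri3 geometry requires an even 'height' under periodic boundaries")
  structure(list(width = width, height = height,
                 neighbourhood = neighbourhood, boundary = boundary),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d sites, %s neighbourhood, %s boundary\n",
              x$height, x$width, x$neighbourhood, x$boundary))
  invisible(x)
}

#' Neighbourhood size of a lattice geometry
#'
#' Number of neighbours of an interior site: 6 for `hex6`, 4 for `square4`,
#' 8 for `moore8`, 3 for `tri3`.
#'
#' @param spec a [lattice_spec()].
#' @return integer.
#' @export
neighbourhood_size <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  c(hex6 = 6L, square4 = 4L, moore8 = 8L, tri3 = 3L)[[spec$neighbourhood]]
}

#' Neighbouring sites of a lattice position
#'
#' Returns the distinct neighbouring sites of `(row, col)` under the lattice
#' geometry. Under periodic boundaries every site has exactly
#' [neighbourhood_size()] neighbours; under `bounded` boundaries edge sites
#' have fewer. The relation is symmetric: `q` is a neighbour of `p` if and
#' only if `p` is a neighbour of `q`.
#'
#' @param spec a [lattice_spec()].
#' @param row,col 1-based position, `1 <= row <= height`,
#'   `1 <= col <= width`.
#' @return an integer matrix with columns `row`, `col`, one row per
#'   neighbour.
#' @export
neighbours <- function(spec, row, col) {
  stopifnot(inherits(spec, "lattice_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (is.na(row) || row < 1L || row > spec$height ||
      is.na(col) || col < 1L || col > spec$width)
    stop("position out of range for this lattice")
  m <- cpp_neighbours(spec$height, spec$width,
                      .GEOMETRIES[[spec$neighbourhood]],
                      .BOUNDARIES[[spec$boundary]],
                      row - 1L, col - 1L)
  m <- m + 1L
  colnames(m) <- c("row", "col")
  m
}

#' Draw a uniformly random site
#'
#' Uniform draw over *all* sites of the lattice, vacant or not: the model's
#' migration event first picks any site and then fails if that site is
#' occupied, so the draw itself is unconditional. Uses R's RNG.
#'
#' @param spec a [lattice_spec()].
#' @return a named integer vector `c(row =, col =)` (1-based).
#' @export
random_site <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  s <- sample.int(spec$width * spec$height, 1L) - 1L
  c(row = s %/% spec$width + 1L, col = s %% spec$width + 1L)
}

#' Is a neighbourhood continuous?
#'
#' A geometry is *continuous* when each site's neighbours include pairs that
#' are themselves neighbours of each other (true for `hex6` and `moore8`),
#' and *discontinuous* when a site's neighbours never neighbour each other
#' (`square4`, `tri3`). Discontinuous neighbourhoods matter because a dying
#' sticky cell then leaves no adjacent pair that could reconnect a colony.
#'
#' @param spec a [lattice_spec()].
#' @param row,col site at which to evaluate the predicate (defaults to an
#'   interior-ish site).
#' @return `TRUE` if at least one pair of the site's neighbours are mutual
#'   neighbours.
#' @export
neighbourhood_continuous <- function(spec, row = 2L, col = 2L) {
  nb <- neighbours(spec, row, col)
  n <- nrow(nb)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    nbi <- neighbours(spec, nb[i, "row"], nb[i, "col"])
    for (j in seq(i + 1L, n)) {
      if (any(nbi[, "row"] == nb[j, "row"] & nbi[, "col"] == nb[j, "col"]))
        return(TRUE)
    }
  }
  FALSE
}
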