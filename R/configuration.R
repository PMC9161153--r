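#' Built-in element masses
#'
#' Average atomic masses (amu) for the elements the built-in model
#' systems use.  Toy species (e.g. \code{"X"}) have no default mass and
#' must be supplied explicitly wherever a configuration is built.
#'
#' @return named numeric vector of masses in amu.
#' @export
element_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
}

.lookup_masses <- function(elements, masses = NULL) {
  if (!is.null(masses)) {
    if (is.null(names(masses)) && length(masses) == length(elements))
      return(as.numeric(masses))
    if (!is.null(names(masses))) {
      # per-element override, falling back to the built-in table
      tab <- c(masses, element_masses()[setdiff(names(element_masses()),
                                                names(masses))])
      out <- unname(tab[elements])
      if (anyNA(out)) stop("no mass supplied for element(s): ",
                           paste(unique(elements[is.na(out)]), collapse = ", "))
      return(as.numeric(out))
    }
    stop("masses must be per-atom or a named per-element vector")
  }
  tab <- element_masses()
  out <- unname(tab[elements])
  if (anyNA(out))
    stop("unknown element(s) with no built-in mass: ",
         paste(unique(elements[is.na(out)]), collapse = ", "),
         " (supply masses explicitly)")
  as.numeric(out)
}

#' Molecular configuration
#'
#' A single frame of a molecular system: species labels, Cartesian
#' positions (Angstrom), per-atom masses (amu) and, for periodic
#' systems, an orthorhombic box.
#'
#' @param elements character vector of species labels.
#' @param positions N x 3 numeric matrix of positions (Angstrom).  1D
#'   model systems live on the x coordinate of a single atom.
#' @param masses per-atom masses in amu, or a named per-element vector;
#'   defaults to the built-in element table.
#' @param cell optional length-3 numeric of orthorhombic box edges
#'   (Angstrom); supplying it marks the configuration periodic.
#' @return object of class \code{molecular_configuration}.
#' @examples
#' cfg <- molecular_configuration("H", matrix(c(0.5, 0, 0), 1))
#' cfg$masses
#' @export
molecular_configuration <- function(elements, positions, masses = NULL,
                                    cell = NULL) {
  positions <- as.matrix(positions)
  if (is.vector(positions)) positions <- matrix(positions, ncol = 3)
  if (ncol(positions) != 3) stop("positions must be N x 3")
  if (nrow(positions) != length(elements))
    stop("elements and positions disagree on atom count")
  if (!all(is.finite(positions))) stop("positions must be finite")
  m <- .lookup_masses(elements, masses)
  if (any(m <= 0)) stop("masses must be positive")
  periodic <- !is.null(cell)
  if (periodic) {
    cell <- as.numeric(cell)
    if (length(cell) != 3 || any(cell <= 0))
      stop("cell must be 3 positive orthorhombic box lengths")
  }
  structure(list(elements = as.character(elements), positions = positions,
                 masses = m, cell = cell, periodic = periodic),
            class = "molecular_configuration")
}

#' @export
print.molecular_configuration <- function(x, ...) {
  cat(sprintf("<molecular_configuration: %d atoms (%s)%s>\n",
              nrow(x$positions),
              paste(names(table(x$elements)), table(x$elements),
                    sep = ":", collapse = " "),
              if (x$periodic)
                sprintf(", box %s Angstrom",
                        paste(signif(x$cell, 6), collapse = " x "))
              else ""))
  invisible(x)
}

n_atoms <- function(config) nrow(config$positions)

# minimum-image displacement for orthorhombic cells
min_image <- function(d, cell) {
  if (is.null(cell)) return(d)
  d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
}
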