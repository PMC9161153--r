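#' Read an extended-XYZ trajectory
#'
#' Reads one or more frames in the extended-XYZ dialect: an atom-count
#' line, a comment line carrying \code{key=value} pairs (including an
#' optional \code{Lattice="ax ... cz"} entry and a \code{Properties}
#' column descriptor), then one line per atom.  Only orthorhombic
#' lattices are supported; a non-orthorhombic \code{Lattice} is an
#' error.  Masses are filled from the built-in element table unless
#' overridden.
#'
#' @param path file to read.
#' @param masses optional named per-element mass override (amu), needed
#'   for toy species such as \code{"X"}.
#' @return list of [molecular_configuration()] objects, one per frame,
#'   each carrying the parsed comment fields in attribute
#'   \code{"comment_fields"}.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path, masses = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("line %d: truncated frame (%d atoms declared)", i, nat))
    fields <- .parse_xyz_comment(lines[i + 1L], i + 1L)
    cell <- NULL
    if (!is.null(fields$Lattice)) {
      lat <- suppressWarnings(as.numeric(strsplit(trimws(fields$Lattice),
                                                  "\\s+")[[1]]))
      if (length(lat) != 9 || anyNA(lat))
        stop(sprintf("line %d: Lattice must contain 9 numbers", i + 1L))
      M <- matrix(lat, 3, 3, byrow = TRUE)
      if (max(abs(M - diag(diag(M)))) > 1e-10)
        stop(sprintf("line %d: only orthorhombic lattices are supported",
                     i + 1L))
      cell <- diag(M)
    }
    spec_col <- 1L; pos_col <- 2L
    if (!is.null(fields$Properties)) {
      cols <- .properties_columns(fields$Properties, i + 1L)
      spec_col <- cols$species; pos_col <- cols$pos
    }
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    elements <- character(nat); pos <- matrix(NA_real_, nat, 3)
    for (a in seq_len(nat)) {
      tk <- toks[[a]]
      if (length(tk) < pos_col + 2L)
        stop(sprintf("line %d: too few columns in atom line", i + 1L + a))
      elements[a] <- tk[spec_col]
      xyz <- suppressWarnings(as.numeric(tk[pos_col:(pos_col + 2L)]))
      if (anyNA(xyz))
        stop(sprintf("line %d: non-numeric coordinates", i + 1L + a))
      pos[a, ] <- xyz
    }
    cfg <- molecular_configuration(elements, pos, masses = masses, cell = cell)
    attr(cfg, "comment_fields") <- fields
    frames[[length(frames) + 1L]] <- cfg
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

.parse_xyz_comment <- function(line, lineno) {
  out <- list()
  rest <- trimws(line)
  pat <- '^([A-Za-z_][A-Za-z0-9_]*)=("(?:[^"]*)"|[^\\s]+)\\s*'
  while (nzchar(rest)) {
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1) break  # free-text comment remainder; keep going gracefully
    tok <- regmatches(rest, m)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- trimws(substr(tok, eq + 1, nchar(tok)))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
    rest <- substr(rest, attr(m, "match.length") + 1, nchar(rest))
  }
  out
}

.properties_columns <- function(props, lineno) {
  parts <- strsplit(props, ":")[[1]]
  if (length(parts) %% 3 != 0)
    stop(sprintf("line %d: malformed Properties descriptor '%s'",
                 lineno, props))
  col <- 1L; species <- NA_integer_; pos <- NA_integer_
  for (j in seq(1, length(parts), by = 3)) {
    name <- parts[j]; width <- as.integer(parts[j + 2])
    if (name == "species") species <- col
    if (name == "pos") pos <- col
    col <- col + width
  }
  if (is.na(species) || is.na(pos))
    stop(sprintf("line %d: Properties must declare species and pos", lineno))
  list(species = species, pos = pos)
}

#' Write configurations as extended XYZ
#'
#' @param configs a [molecular_configuration()] or list of them.
#' @param path output file.
#' @param comment_fields optional named list of extra \code{key=value}
#'   entries for the comment line (recycled across frames, or a list of
#'   per-frame lists).
#' @param digits coordinate precision.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(configs, path, comment_fields = NULL, digits = 10) {
  if (inherits(configs, "molecular_configuration")) configs <- list(configs)
  per_frame <- !is.null(comment_fields) && length(comment_fields) &&
    is.list(comment_fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_along(configs)) {
    cfg <- configs[[f]]
    hdr <- 'Properties=species:S:1:pos:R:3'
    if (cfg$periodic) {
      c3 <- sprintf("%.8f", cfg$cell)
      hdr <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s" %s',
                     c3[1], c3[2], c3[3], hdr)
    }
    extra <- if (per_frame) comment_fields[[f]] else comment_fields
    for (k in names(extra)) {
      v <- as.character(extra[[k]])
      if (grepl("\\s", v)) v <- sprintf('"%s"', v)
      hdr <- paste0(hdr, " ", k, "=", v)
    }
    writeLines(as.character(nrow(cfg$positions)), con)
    writeLines(hdr, con)
    for (a in seq_len(nrow(cfg$positions)))
      writeLines(sprintf(fmt, cfg$elements[a], cfg$positions[a, 1],
                         cfg$positions[a, 2], cfg$positions[a, 3]), con)
  }
  invisible(path)
}
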