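#' Annual ring-width series for one disc radius
#'
#' A `ring_series` holds the annual ring widths measured along one radius of
#' a stem disc, ordered from the pith (innermost ring) to the bark, together
#' with the calendar year of the outermost ring.  A width of exactly 0
#' encodes a locally missing (wedge or discontinuous) ring: the ring exists
#' on the disc but is absent on this radius.
#'
#' The first calendar year is always derivable as
#' `last_year - length(widths) + 1` and is never stored separately.  When no
#' felling year is known, `last_year` may simply equal the cambial age so
#' that years run 1..n.
#'
#' @param tree_id Character scalar identifying the tree.
#' @param radius_id Character scalar identifying the radius within the tree.
#' @param widths Numeric vector of ring widths in mm, pith to bark.  All
#'   values must be finite and non-negative; 0 marks a wedge ring.
#' @param last_year Calendar year of the outermost ring (defaults to the
#'   cambial age, i.e. years 1..n).
#' @param species Species code (free-form character scalar).
#' @param resolution_mm Measurement resolution in mm (default 0.01, the
#'   resolution of stage-micrometer ring measurement).
#'
#' @return An object of class `ring_series`.
#' @examples
#' ring_series("T1", "r1", c(1.2, 1.5, 0, 1.4), last_year = 2000)
#' @export
ring_series <- function(tree_id, radius_id, widths, last_year = length(widths),
                        species = NA_character_, resolution_mm = 0.01) {
  widths <- as.numeric(widths)
  if (length(widths) < 1L)
    stop("ring_series: 'widths' must contain at least one ring")
  if (any(!is.finite(widths)))
    stop("ring_series: widths must all be finite")
  if (any(widths < 0))
    stop("ring_series: widths must be non-negative (0 encodes a wedge ring)")
  if (!is.numeric(last_year) || length(last_year) != 1L || !is.finite(last_year))
    stop("ring_series: 'last_year' must be a single finite year")
  structure(
    list(tree_id = as.character(tree_id),
         radius_id = as.character(radius_id),
         species = as.character(species),
         last_year = as.integer(last_year),
         widths = widths,
         resolution_mm = resolution_mm),
    class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> tree %s radius %s: %d rings, years %d-%d\n",
              x$tree_id, x$radius_id, length(x$widths),
              first_year(x), x$last_year))
  invisible(x)
}

#' @export
length.ring_series <- function(x) length(x$widths)

#' First calendar year of a ring series
#'
#' @param x A [ring_series()].
#' @return `last_year - n + 1`, the year of the innermost ring.
#' @export
first_year <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  x$last_year - length(x$widths) + 1L
}

#' Species, site and radius bundle for one tree
#'
#' Collects everything needed to take one tree through the carbon pipeline:
#' its species, wood density, the site environmental stress factor of the
#' pantropical allometry, the biomass-to-carbon fraction, and all measured
#' radii.  All radii must belong to the same tree and, once cross-dated,
#' share the same outermost calendar year.
#'
#' Default wood densities by species code follow published species-level
#' values for the three Suriname species: Cedrela odorata 0.38,
#' Hymenaea courbaril 0.77, Goupia glabra 0.72 g cm^-3.
#'
#' @param tree_id Character scalar.
#' @param species Species code; the codes `"C.odorata"`, `"H.courbaril"`
#'   and `"G.glabra"` have built-in default wood densities.
#' @param radii List of [ring_series()] objects (at least one).
#' @param wood_density Wood density rho in g cm^-3 (> 0).  If `NULL`, looked
#'   up from the species defaults.
#' @param stress_E Environmental stress factor E of the allometric model
#'   (dimensionless, site-level; default 0).
#' @param carbon_fraction Fraction of dry biomass that is carbon, in (0,1).
#'   Default 0.471, a published mean for tropical angiosperm wood.
#'
#' @return An object of class `tree_record`.
#' @export
tree_record <- function(tree_id, species, radii, wood_density = NULL,
                        stress_E = 0, carbon_fraction = 0.471) {
  if (is.null(wood_density)) {
    wood_density <- default_wood_density(species)
    if (is.na(wood_density))
      stop(sprintf("tree_record: no default wood density for species '%s'; supply wood_density", species))
  }
  if (!is.numeric(wood_density) || wood_density <= 0)
    stop("tree_record: wood_density must be > 0")
  if (!is.numeric(carbon_fraction) || carbon_fraction <= 0 || carbon_fraction >= 1)
    stop("tree_record: carbon_fraction must lie in (0, 1)")
  if (!is.list(radii) || length(radii) < 1L ||
      !all(vapply(radii, inherits, logical(1), "ring_series")))
    stop("tree_record: 'radii' must be a non-empty list of ring_series")
  ids <- vapply(radii, `[[`, character(1), "tree_id")
  if (!all(ids == as.character(tree_id)))
    stop("tree_record: all radii must carry the tree's id")
  structure(
    list(tree_id = as.character(tree_id),
         species = as.character(species),
         wood_density = wood_density,
         stress_E = stress_E,
         carbon_fraction = carbon_fraction,
         radii = radii),
    class = "tree_record")
}

#' @export
print.tree_record <- function(x, ...) {
  cat(sprintf("<tree_record> %s (%s): %d radii, rho = %.2f g/cm3, E = %.3g\n",
              x$tree_id, x$species, length(x$radii), x$wood_density, x$stress_E))
  invisible(x)
}

#' Default species wood densities (g cm^-3)
#'
#' @param species Character vector of species codes.
#' @return Numeric vector of densities; `NA` for unknown codes.
#' @export
default_wood_density <- function(species) {
  lut <- c("C.odorata" = 0.38, "H.courbaril" = 0.77, "G.glabra" = 0.72)
  unname(lut[as.character(species)])
}

## ---------------------------------------------------------------------------
## Tucson / RWL decadal format
##
## Layout per line: series id in columns 1-8, decade start year right-
## adjusted in columns 9-12, then up to 10 integer fields of width 6.  The
## first line of a series starts at the series' first year and runs to the
## end of that calendar decade; later lines start at multiples of 10.  Data
## values are widths in units of 0.01 mm (terminator 999) or 0.001 mm
## (terminator -9999).  A value of 0 encodes a locally absent ring.

#' Read ring-width series from a Tucson/RWL file
#'
#' Parses the decadal Tucson dialect used by ring-measurement software.
#' Both the 999 terminator (0.01 mm units) and the -9999 terminator
#' (0.001 mm units) are accepted; widths are returned in mm.
#'
#' Because series ids carry no tree structure, every series in the file
#' becomes one [ring_series()] whose `tree_id` and `radius_id` are both the
#' 8-character series id; use [read_series_table()] for data with explicit
#' tree/radius structure, or regroup by id downstream.
#'
#' @param path Path to an RWL file.
#' @return A list of [ring_series()] objects, one per series in the file.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  open <- NULL  # state for the series currently being read

  flush_series <- function(st) {
    if (is.null(st)) return(invisible(NULL))
    stop(sprintf("read_rwl: series '%s' not terminated (missing 999/-9999)", st$id))
  }

  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    id <- trimws(substr(ln, 1L, 8L))
    restr <- substr(ln, 9L, nchar(ln))
    fields <- strsplit(trimws(restr), "\\s+")[[1]]
    if (length(fields) < 2L)
      stop(sprintf("read_rwl: line %d: expected a year and at least one value", k))
    year <- suppressWarnings(as.integer(fields[[1]]))
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (is.na(year) || any(is.na(vals)))
      stop(sprintf("read_rwl: line %d: non-numeric year or value", k))

    if (is.null(open) || open$id != id) {
      flush_series(open)
      open <- list(id = id, first_year = year, next_year = year, values = numeric(0))
    } else {
      if (year != open$next_year)
        stop(sprintf(
          "read_rwl: line %d: malformed decade sequence for series '%s' (expected year %d, found %d)",
          k, id, open$next_year, year))
    }

    term <- which(vals == 999 | vals == -9999)
    done <- length(term) > 0L
    if (done) {
      tval <- vals[term[1L]]
      if (term[1L] < length(vals))
        stop(sprintf("read_rwl: line %d: data after terminator in series '%s'", k, id))
      vals <- vals[seq_len(term[1L] - 1L)]
    }
    if (any(vals < 0))
      stop(sprintf("read_rwl: line %d: negative width (only -9999 terminator may be negative)", k))
    if (length(vals) > 10L)
      stop(sprintf("read_rwl: line %d: more than 10 values on a decadal line", k))
    open$values <- c(open$values, vals)
    open$next_year <- open$next_year + length(vals)

    if (done) {
      divisor <- if (tval == 999) 100 else 1000
      res <- if (tval == 999) 0.01 else 0.001
      if (length(open$values) < 1L)
        stop(sprintf("read_rwl: series '%s' has no data values", id))
      out[[length(out) + 1L]] <- ring_series(
        tree_id = open$id, radius_id = open$id,
        widths = open$values / divisor,
        last_year = open$next_year - 1L,
        resolution_mm = res)
      open <- NULL
    }
  }
  flush_series(open)
  out
}

#' Write ring-width series to a Tucson/RWL file
#'
#' Writes the decadal Tucson dialect re-readable by [read_rwl()] with exact
#' width recovery at the declared resolution.  With `resolution_mm = 0.01`
#' values are stored in 0.01 mm units and the series is terminated by 999;
#' with `resolution_mm = 0.001` units are 0.001 mm and the terminator is
#' -9999.  A width that would collide with the 999 terminator or overflow
#' the fixed-width field raises an error (switch to 0.001 mm resolution).
#'
#' @param series A [ring_series()] or list of them.
#' @param path Output file path.
#' @param resolution_mm Storage resolution, 0.01 (default) or 0.001 mm.
#' @return Invisibly, `path`.
#' @export
write_rwl <- function(series, path, resolution_mm = 0.01) {
  if (inherits(series, "ring_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "ring_series")))
  if (!resolution_mm %in% c(0.01, 0.001))
    stop("write_rwl: resolution_mm must be 0.01 or 0.001")
  divisor <- if (resolution_mm == 0.01) 0.01 else 0.001
  term <- if (resolution_mm == 0.01) 999 else -9999

  lines <- character(0)
  for (s in series) {
    vals <- round(s$widths / divisor)
    if (max(abs(vals - s$widths / divisor)) > 1e-6)
      stop(sprintf("write_rwl: series '%s' has widths not representable at %.3f mm resolution",
                   s$radius_id, resolution_mm))
    if (any(vals > 99999))
      stop(sprintf("write_rwl: series '%s' overflows the 6-character field", s$radius_id))
    if (term == 999 && any(vals == 999))
      stop(sprintf("write_rwl: series '%s' contains a width equal to the 999 terminator; write at resolution_mm = 0.001", s$radius_id))
    id <- sprintf("%-8s", substr(s$radius_id, 1L, 8L))
    fy <- first_year(s)
    vals <- c(vals, term)
    years <- seq(fy, length.out = length(vals))
    yr <- fy
    i <- 1L
    while (i <= length(vals)) {
      dec_end <- (yr %/% 10L) * 10L + 9L
      j <- min(length(vals), i + (dec_end - yr))
      lines <- c(lines, paste0(id, sprintf("%4d", yr),
                               paste(sprintf("%6d", vals[i:j]), collapse = "")))
      i <- j + 1L
      yr <- dec_end + 1L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Long-form table format

#' Read ring-width series from a long-form table
#'
#' Expects a delimited text file with columns `tree_id`, `species`,
#' `radius_id`, `year`, `width_mm`; one row per ring per radius.  Rows may
#' appear in any order, but the years of each radius must be contiguous once
#' sorted and must not repeat.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default `","`).
#' @return A list of [ring_series()], one per (tree_id, radius_id), sorted
#'   by tree then radius id.
#' @seealso [write_series_table()]
#' @export
read_series_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  need <- c("tree_id", "species", "radius_id", "year", "width_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_series_table: missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(df$tree_id, df$radius_id, drop = TRUE, sep = "\r")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    if (anyDuplicated(d$year))
      stop(sprintf("read_series_table: duplicate year(s) %s in tree %s radius %s",
                   paste(unique(d$year[duplicated(d$year)]), collapse = ", "),
                   d$tree_id[1], d$radius_id[1]))
    full <- seq(min(d$year), max(d$year))
    gap <- setdiff(full, d$year)
    if (length(gap))
      stop(sprintf("read_series_table: missing year(s) %s in tree %s radius %s",
                   paste(gap, collapse = ", "), d$tree_id[1], d$radius_id[1]))
    ring_series(d$tree_id[1], d$radius_id[1], d$width_mm,
                last_year = max(d$year), species = d$species[1])
  })
  names(out) <- NULL
  ord <- order(vapply(out, `[[`, character(1), "tree_id"),
               vapply(out, `[[`, character(1), "radius_id"))
  out[ord]
}

#' Write ring-width series to a long-form table
#'
#' @param series A [ring_series()] or list of them.
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return Invisibly, `path`.
#' @export
write_series_table <- function(series, path, sep = ",") {
  if (inherits(series, "ring_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "ring_series")))
  rows <- lapply(series, function(s)
    data.frame(tree_id = s$tree_id, species = s$species,
               radius_id = s$radius_id,
               year = seq(first_year(s), s$last_year),
               width_mm = s$widths, stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(tree_id = character(0), species = character(0),
                     radius_id = character(0), year = integer(0),
                     width_mm = numeric(0))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
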