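#' Hard-sphere radius tables
#'
#' A radius table maps chemical element symbols (optionally overridden per
#' atom name) to the hard-sphere radii used by the probe-sphere algorithm.
#' The default set (C 1.85, N 1.75, O 1.65, S 2.00, H 1.00, P 2.10 Angstrom)
#' follows the simple element-based convention used by pore-profiling tools;
#' all values can be overridden because crystallographic models rarely state
#' them.
#'
#' @param radii named numeric vector, element symbol -> radius in Angstrom.
#' @param overrides named numeric vector keyed by exact atom name, applied
#'   before element lookup (e.g. `c(OXT = 1.60)`).
#' @param default radius assigned to elements absent from `radii`.
#' @return an object of class `radius_table`.
#' @examples
#' tab <- default_radius_table()
#' tab$radii[["O"]]
#' @export
radius_table <- function(radii, overrides = numeric(0), default = 2.0) {
  if (length(radii) == 0L || is.null(names(radii)) || any(names(radii) == "")) {
    stop("radii must be a non-empty named numeric vector", call. = FALSE)
  }
  all_r <- c(radii, overrides, default)
  if (any(!is.finite(all_r)) || any(all_r <= 0.5) || any(all_r >= 3.0)) {
    stop("all radii must lie in (0.5, 3.0) Angstrom", call. = FALSE)
  }
  structure(
    list(radii = radii, overrides = overrides, default = default),
    class = "radius_table"
  )
}

#' @rdname radius_table
#' @export
default_radius_table <- function() {
  radius_table(c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, H = 1.00, P = 2.10))
}

#' Read a radius table from a key=value text file
#'
#' Lines are `ELEMENT=radius`; the key `default` sets the fallback radius;
#' keys containing a digit or longer than 2 characters are treated as
#' atom-name overrides. Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return a `radius_table`.
#' @export
read_radius_table <- function(path) {
  if (!file.exists(path)) stop("radius table not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed radius-table line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  if (anyNA(vals)) stop("non-numeric radius in table: ", path, call. = FALSE)
  is_default <- keys == "default"
  is_override <- !is_default & (grepl("[0-9]", keys) | nchar(keys) > 2L)
  radius_table(
    radii = setNames(vals[!is_default & !is_override], keys[!is_default & !is_override]),
    overrides = setNames(vals[is_override], keys[is_override]),
    default = if (any(is_default)) vals[is_default][1] else 2.0
  )
}

# Infer an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, keep leading letters; a full match against the
# table's elements (e.g. "CL") wins over the one-letter fallback.
infer_element <- function(name, known = c("C", "N", "O", "S", "H", "P")) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  out <- character(length(name))
  for (i in seq_along(stripped)) {
    s <- stripped[i]
    if (!nzchar(s)) {
      out[i] <- ""
    } else if (s %in% known) {
      out[i] <- s
    } else if (substr(s, 1, 2) %in% known) {
      out[i] <- substr(s, 1, 2)
    } else {
      out[i] <- substr(s, 1, 1)
    }
  }
  out
}

#' Assign hard-sphere radii to a structure
#'
#' Fills the `radius` column of a structure's atom table by atom-name
#' override, then element, then the table default. Elements are inferred
#' from atom names where the element column is blank. Idempotent.
#'
#' @param structure a `pore_structure`.
#' @param table a `radius_table` (default [default_radius_table()]).
#' @return the structure with radii assigned.
#' @export
assign_radii <- function(structure, table = default_radius_table()) {
  stopifnot(inherits(structure, "pore_structure"))
  if (!inherits(table, "radius_table")) stop("table must be a radius_table", call. = FALSE)
  at <- structure$atoms
  elem <- at$element
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) {
    elem[blank] <- infer_element(at$name[blank], known = names(table$radii))
  }
  elem <- toupper(trimws(elem))
  r <- rep(NA_real_, nrow(at))
  if (length(table$overrides)) {
    hit <- match(at$name, names(table$overrides))
    r[!is.na(hit)] <- table$overrides[hit[!is.na(hit)]]
  }
  need <- is.na(r)
  hit <- match(elem[need], names(table$radii))
  r[need][!is.na(hit)] <- table$radii[hit[!is.na(hit)]]
  unknown <- is.na(r)
  if (any(unknown)) {
    message("assign_radii: ", sum(unknown), " atom(s) with unknown element (",
            paste(unique(elem[unknown]), collapse = ", "),
            ") assigned default radius ", table$default, " A")
    r[unknown] <- table$default
  }
  at$element <- elem
  at$radius <- r
  structure$atoms <- at
  structure
}
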