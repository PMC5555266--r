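#' Construct a pore structure object
#'
#' A `pore_structure` holds an ordered atom table (element, atom name,
#' residue, chain, coordinates in Angstrom, and an assigned hard-sphere
#' radius) plus a free-text label. Coordinates are Angstrom everywhere in
#' this package; GRO input (nm) is converted on read.
#'
#' @param atoms data.frame with columns `element`, `name`, `residue_name`,
#'   `residue_index`, `chain_id`, `x`, `y`, `z` and optionally `radius`.
#' @param label free-text identifier.
#' @return an object of class `pore_structure`.
#' @export
pore_structure <- function(atoms, label = "structure") {
  need <- c("element", "name", "residue_name", "residue_index", "chain_id",
            "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in structure", call. = FALSE)
  }
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  structure(list(atoms = atoms, label = label), class = "pore_structure")
}

#' @export
print.pore_structure <- function(x, ...) {
  r <- x$atoms$radius
  cat("<pore_structure> ", x$label, ": ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain_id)), " chain(s), radii ",
      if (all(is.na(r))) "unassigned" else "assigned", "\n", sep = "")
  invisible(x)
}

# residue names recognised as water
.water_residues <- c("HOH", "SOL", "WAT")

#' Read a channel structure from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d. Water records (HOH/SOL/WAT) are
#' excluded from the structure -- waters belong in trajectories, see
#' [read_water_trajectory()]. Coordinates are kept in Angstrom exactly as
#' printed. Radii are left unassigned; call [assign_radii()] before any
#' geometry.
#'
#' @param path PDB file path.
#' @param model_index which MODEL of a multi-model file to take (default 1).
#' @param water_residues residue names treated as water and dropped.
#' @return a `pore_structure`.
#' @export
read_structure <- function(path, model_index = 1L,
                           water_residues = .water_residues) {
  if (!file.exists(path)) stop("cannot read structure: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ", n_models,
         " model(s))", call. = FALSE)
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  keep <- !(at$resid %in% water_residues)
  if (!any(keep)) stop("no non-water ATOM records in ", path, call. = FALSE)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem)] <- ""
  atoms <- data.frame(
    element = elem,
    name = at$elety,
    residue_name = at$resid,
    residue_index = at$resno,
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  pore_structure(atoms, label = basename(path))
}

#' Write a structure as PDB
#'
#' @param structure a `pore_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "pore_structure"))
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$residue_index,
    resid = at$residue_name,
    elety = at$name,
    chain = at$chain_id,
    elesy = at$element
  )
  invisible(path)
}

#' Construct a water trajectory object
#'
#' Ordered frames of water-oxygen coordinates (Angstrom) with strictly
#' increasing frame times (ns) and an optional periodic box.
#'
#' @param frames list of n x 3 numeric matrices.
#' @param frame_times numeric vector of times in ns, one per frame.
#' @param box optional 3-vector of box lengths in Angstrom.
#' @return an object of class `water_trajectory`.
#' @export
water_trajectory <- function(frames, frame_times = seq_along(frames) - 1,
                             box = NULL) {
  if (length(frames) < 1L) stop("trajectory needs at least one frame", call. = FALSE)
  if (length(frame_times) != length(frames)) {
    stop("frame_times length must match frame count", call. = FALSE)
  }
  if (any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing", call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("each frame must be an n x 3 matrix", call. = FALSE)
    dimnames(f) <- list(NULL, c("x", "y", "z"))
    f
  })
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 box = box),
            class = "water_trajectory")
}

#' @export
print.water_trajectory <- function(x, ...) {
  n <- vapply(x$frames, nrow, 1L)
  cat("<water_trajectory> ", length(x$frames), " frames (",
      round(min(x$frame_times), 3), "-", round(max(x$frame_times), 3),
      " ns), waters/frame ", min(n), "-", max(n), "\n", sep = "")
  invisible(x)
}

#' Read a water-oxygen trajectory
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`xyz-table`}{whitespace table, header `# frame time_ns x y z`,
#'     one row per water; frames grouped by the frame index.}
#'   \item{`pdb-models`}{multi-MODEL PDB; water oxygens are atoms of the
#'     selected residues whose name starts with "O". Frame times default to
#'     the model index (0, 1, ... ns) unless `frame_times` is given.}
#'   \item{`gro-frames`}{concatenated GRO frames (coordinates in nm,
#'     converted to Angstrom); time is taken from a `t=` tag in the title
#'     line when present, in ps, converted to ns.}
#' }
#'
#' @param paths one or more file paths, concatenated in order.
#' @param dialect one of `"xyz-table"`, `"pdb-models"`, `"gro-frames"`.
#' @param water_selection residue names counted as water.
#' @param frame_times optional explicit frame times in ns.
#' @return a `water_trajectory`.
#' @export
read_water_trajectory <- function(paths,
                                  dialect = c("xyz-table", "pdb-models",
                                              "gro-frames"),
                                  water_selection = .water_residues,
                                  frame_times = NULL) {
  dialect <- match.arg(dialect)
  missing_p <- paths[!file.exists(paths)]
  if (length(missing_p)) stop("cannot read: ", missing_p[1], call. = FALSE)
  out <- switch(dialect,
    "xyz-table" = .read_traj_xyz(paths),
    "pdb-models" = .read_traj_pdb(paths, water_selection),
    "gro-frames" = .read_traj_gro(paths, water_selection)
  )
  if (!is.null(frame_times)) out$times <- frame_times
  if (sum(vapply(out$frames, nrow, 1L)) == 0L) {
    stop("no water oxygens matched in any frame", call. = FALSE)
  }
  water_trajectory(out$frames, out$times, box = out$box)
}

.read_traj_xyz <- function(paths) {
  frames <- list(); times <- numeric(0)
  for (p in paths) {
    tab <- read.table(p, comment.char = "#",
                      col.names = c("frame", "time_ns", "x", "y", "z"))
    if (nrow(tab) == 0L) next
    for (fi in unique(tab$frame)) {
      sub <- tab[tab$frame == fi, , drop = FALSE]
      frames[[length(frames) + 1L]] <- as.matrix(sub[, c("x", "y", "z")])
      times <- c(times, sub$time_ns[1])
    }
  }
  if (!length(frames)) stop("no frames in xyz-table input", call. = FALSE)
  list(frames = frames, times = times, box = NULL)
}

.read_traj_pdb <- function(paths, water_selection) {
  frames <- list()
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    sel <- at$resid %in% water_selection & startsWith(at$elety, "O")
    for (m in seq_len(nrow(pdb$xyz))) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      frames[[length(frames) + 1L]] <- xyz[sel, , drop = FALSE]
    }
  }
  list(frames = frames, times = seq_along(frames) - 1, box = NULL)
}

.read_traj_gro <- function(paths, water_selection) {
  frames <- list(); times <- numeric(0); box <- NULL
  for (p in paths) {
    lines <- readLines(p, warn = FALSE)
    i <- 1L
    while (i <= length(lines)) {
      title <- lines[i]
      natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
      if (is.na(natoms)) stop("malformed GRO frame in ", p, call. = FALSE)
      rows <- lines[(i + 2L):(i + 1L + natoms)]
      resname <- trimws(substr(rows, 6, 10))
      atname <- trimws(substr(rows, 11, 15))
      sel <- resname %in% water_selection & startsWith(atname, "O")
      xyz <- cbind(as.numeric(substr(rows, 21, 28)),
                   as.numeric(substr(rows, 29, 36)),
                   as.numeric(substr(rows, 37, 44))) * 10  # nm -> A
      frames[[length(frames) + 1L]] <- xyz[sel, , drop = FALSE]
      tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
      times <- c(times, if (length(tm)) {
        as.numeric(sub("t=\\s*", "", tm)) / 1000  # ps -> ns
      } else length(frames) - 1)
      boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
      box <- as.numeric(boxline[1:3]) * 10
      i <- i + 3L + natoms
    }
  }
  list(frames = frames, times = times, box = box)
}

#' Write a trajectory in the xyz-table dialect
#'
#' @param trajectory a `water_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "water_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame time_ns x y z", con)
  for (i in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[i]]
    if (nrow(f) == 0L) next
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f", i,
                       trajectory$frame_times[i], f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Umbrella-sampling window
#'
#' One biased time series of the restrained coordinate. Force constants are
#' accepted in kJ mol^-1 nm^-2 (the conventional MD unit) and converted
#' internally to kJ mol^-1 A^-2 (factor 0.01).
#'
#' @param center_z restraint centre in Angstrom.
#' @param force_constant harmonic force constant in kJ mol^-1 nm^-2.
#' @param samples z-coordinate samples in Angstrom.
#' @param sample_times times in ns (defaults to sample index).
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center_z, force_constant, samples,
                            sample_times = seq_along(samples)) {
  if (length(samples) == 0L) stop("window has no samples", call. = FALSE)
  if (force_constant <= 0) stop("force_constant must be > 0", call. = FALSE)
  structure(list(center_z = center_z,
                 force_constant = force_constant,
                 force_constant_A2 = force_constant * 0.01,
                 samples = as.numeric(samples),
                 sample_times = as.numeric(sample_times)),
            class = "umbrella_window")
}

#' Read umbrella-sampling window files
#'
#' One file per window: header lines `# center_A <c>` and
#' `# k_kJmol_nm2 <k>`, then whitespace rows `time_ns z_A`.
#'
#' @param paths window file paths.
#' @return list of `umbrella_window`, ordered by centre.
#' @export
read_umbrella_windows <- function(paths) {
  if (length(paths) == 0L) stop("no window files given", call. = FALSE)
  windows <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("cannot read window file: ", p, call. = FALSE)
    lines <- readLines(p, warn = FALSE)
    hdr <- lines[startsWith(lines, "#")]
    get <- function(key) {
      hit <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
      if (!length(hit)) stop("window file ", p, " missing header ", key, call. = FALSE)
      as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][3])
    }
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    tab <- read.table(text = body, col.names = c("time_ns", "z_A"))
    umbrella_window(get("center_A"), get("k_kJmol_nm2"), tab$z_A, tab$time_ns)
  })
  windows[order(vapply(windows, `[[`, 1.0, "center_z"))]
}

#' Write an umbrella window file
#'
#' @param window an `umbrella_window`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_umbrella_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center_A %.6f", window$center_z),
               sprintf("# k_kJmol_nm2 %.6f", window$force_constant)), con)
  writeLines(sprintf("%.6f %.6f", window$sample_times, window$samples), con)
  invisible(path)
}

# Shared tab-separated profile writer: one comment header naming columns
# (with units), then data rows.
write_profile_tsv <- function(df, path, extra_header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in extra_header) writeLines(paste0("# ", h), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_profile_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  cols <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, col.names = cols)
  meta <- hdr[-length(hdr)]
  attr(tab, "meta") <- sub("^#\\s*", "", meta)
  tab
}
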