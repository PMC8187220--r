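#' Read a multi-record XYZ file
#'
#' Each record is an atom-count line, a comment line (preserved verbatim in
#' metadata), and `N_at` lines of `element x y z`.  Scientific notation is
#' accepted; trailing blank lines are ignored.
#'
#' @param path Path to an XYZ file.
#' @return A [mol_dataset()] whose geometries appear in file order.  An empty
#'   file yields a dataset with zero geometries.
#' @export
read_xyz <- function(path) {
  recs <- parse_xyz_records(path, numeric_only = FALSE)
  geoms <- lapply(recs, function(r) mol_geometry(r$elements, r$coords))
  mol_dataset(geoms, metadata = list(comments = vapply(recs, `[[`, "", "comment")))
}

#' Write geometries to a multi-record XYZ file
#'
#' @param dataset A [mol_dataset()] (or list of [mol_geometry()]).
#' @param path Output path.
#' @param comments Optional character vector of per-record comment lines.
#' @param digits Significant digits for coordinates (default 17: full double
#'   precision, so write/read round-trips exactly).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(dataset, path, comments = NULL, digits = 17) {
  geoms <- if (inherits(dataset, "mol_dataset")) dataset$geometries else dataset
  if (is.null(comments)) {
    comments <- if (inherits(dataset, "mol_dataset") &&
                    !is.null(dataset$metadata$comments) &&
                    length(dataset$metadata$comments) == length(geoms)) {
      dataset$metadata$comments
    } else {
      rep("", length(geoms))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    writeLines(c(as.character(n_atoms(g)), comments[[i]]), con)
    writeLines(sprintf("%s %s %s %s", formatC(g$elements, width = 2, flag = "-"),
                       format(g$coordinates[, 1], digits = digits),
                       format(g$coordinates[, 2], digits = digits),
                       format(g$coordinates[, 3], digits = digits)), con)
  }
  invisible(path)
}

#' Read per-geometry Cartesian gradients in XYZ-shaped blocks
#'
#' Record structure matches [read_xyz()] but atom lines hold three numbers
#' (an optional leading element column is tolerated).
#'
#' @param path Path to the gradient file.
#' @return List of `N_at x 3` matrices, one per record.
#' @export
read_xyz_gradients <- function(path) {
  recs <- parse_xyz_records(path, numeric_only = TRUE)
  lapply(recs, `[[`, "coords")
}

#' Write Cartesian gradients as XYZ-shaped blocks
#' @param gradients List of `N_at x 3` matrices.
#' @param path Output path.
#' @param digits Significant digits (default full precision).
#' @return `path`, invisibly.
#' @export
write_xyz_gradients <- function(gradients, path, digits = 17) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in gradients) {
    g <- as.matrix(g)
    writeLines(c(as.character(nrow(g)), ""), con)
    writeLines(paste(format(g[, 1], digits = digits),
                     format(g[, 2], digits = digits),
                     format(g[, 3], digits = digits)), con)
  }
  invisible(path)
}

## Shared XYZ-record parser.  numeric_only: atom lines are numeric triples,
## element column optional (gradient blocks).
parse_xyz_records <- function(path, numeric_only = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blanks inside records are comment lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  recs <- list()
  i <- 1L
  rec_no <- 0L
  while (i <= length(lines)) {
    rec_no <- rec_no + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop("malformed atom-count line in record ", rec_no, " of ", path,
           call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("record ", rec_no, " of ", path, " declares ", nat,
           " atoms but the file ends early", call. = FALSE)
    }
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    elements <- character(nat)
    coords <- matrix(NA_real_, nat, 3)
    for (a in seq_len(nat)) {
      tk <- toks[[a]]
      if (numeric_only && length(tk) == 3L) {
        num <- suppressWarnings(as.numeric(tk))
      } else if (length(tk) >= 4L) {
        elements[a] <- tk[1L]
        num <- suppressWarnings(as.numeric(tk[2:4]))
      } else {
        stop("record ", rec_no, ", atom line ", a, ": expected ",
             if (numeric_only) "3 numbers" else "'element x y z'", call. = FALSE)
      }
      if (anyNA(num)) {
        stop("record ", rec_no, ", atom line ", a, ": non-numeric coordinate",
             call. = FALSE)
      }
      coords[a, ] <- num
    }
    recs[[rec_no]] <- list(elements = elements, coords = coords, comment = comment)
    i <- i + 2L + nat
  }
  recs
}

#' Read a one-number-per-line value file
#'
#' @param path Path to the file.
#' @return Numeric vector in file order (length 0 for an empty file).
#' @export
read_values <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(numeric(0))
  v <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(v)) {
    stop("non-numeric value on line ", which(is.na(v))[1], " of ", path,
         call. = FALSE)
  }
  v
}

#' Write a one-number-per-line value file
#' @param values Numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_values <- function(values, path) {
  writeLines(format(as.double(values), digits = 17), path)
  invisible(path)
}

#' Read split-index files (one 1-based index per line, one file per group)
#'
#' @param paths Named character vector/list of file paths; names become the
#'   group names.
#' @param n Optional total record count for bounds checking.
#' @return A [split_indices()] object.
#' @export
read_split_indices <- function(paths, n = NULL) {
  groups <- lapply(paths, function(p) as.integer(read_values(p)))
  names(groups) <- names(paths)
  split_indices(groups, n = n)
}

#' Write split-index files (one 1-based index per line, one file per group)
#'
#' @param split A [split_indices()] object.
#' @param dir Output directory.
#' @param prefix File-name prefix; files are `<prefix><group>.dat`.
#' @return Named vector of written paths, invisibly.
#' @export
write_split_indices <- function(split, dir, prefix = "indices_") {
  paths <- vapply(names(split), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".dat"))
    writeLines(as.character(split[[nm]]), p)
    p
  }, "")
  invisible(paths)
}

#' Read user-supplied descriptor vectors
#'
#' Whitespace-delimited text, one geometry per line.  Used for external
#' descriptors; such models cannot predict Cartesian gradients (no Jacobian).
#'
#' @param path Path to the file.
#' @return Numeric matrix, one row per geometry.
#' @export
read_descriptor_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty descriptor file: ", path, call. = FALSE)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  nx <- unique(lengths(rows))
  if (length(nx) != 1L) stop("inconsistent descriptor dimensions in ", path, call. = FALSE)
  if (anyNA(unlist(rows))) stop("non-numeric entry in ", path, call. = FALSE)
  do.call(rbind, rows)
}

#' Write descriptor vectors as whitespace-delimited text
#' @param x Numeric matrix, one row per geometry.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_file <- function(x, path) {
  writeLines(apply(x, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
             path)
  invisible(path)
}
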