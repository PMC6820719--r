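## External representations.
##
## Structures: PDB fixed-column ATOM/HETATM records (parsed with bio3d), or a
## pseudo-atom CSV dialect that also carries the box.  Trajectories: a
## '#'-headed TSV with columns frame, time_ps, particle_id, species,
## charge_e, x_A, y_A, z_A.  Traces: two-column time/current TSV with
## '# sampling_hz=' and '# voltage_mv=' metadata.  All writers emit 6
## significant digits; round-trips are lossless to that precision.
## Readers reject, never silently repair, invariant violations.

.parseHeaderMeta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

.metaNum <- function(meta, key, path) {
  if (is.null(meta[[key]]))
    stop(sprintf("header error: missing '# %s=' metadata in %s", key, path),
         call. = FALSE)
  v <- suppressWarnings(as.numeric(strsplit(meta[[key]], "\\s+")[[1]]))
  if (any(is.na(v)))
    stop(sprintf("header error: non-numeric '# %s=' in %s", key, path),
         call. = FALSE)
  v
}

#' Read a pore structure (PDB subset or pseudo-atom CSV)
#'
#' Files ending in `.pdb` are parsed as fixed-column ATOM/HETATM records via
#' \pkg{bio3d}; anything else is read as the pseudo-atom CSV dialect written
#' by [writePoreStructure()] (columns `atom_id, residue_name,
#' residue_number, chain_id, species, x, y, z[, radius]`, with `# box_A=`
#' and optional `# membrane_z=` header lines).  z-coordinates are left
#' untransformed; the pore-bottom convention is applied by the geometry
#' operations.
#'
#' @param path file path.
#' @param box for PDB input without a CRYST1 record: box lengths (Lx, Ly,
#'   Lz) in Angstrom; defaults to the coordinate extent.
#' @return a [PoreStructure-class] with atoms in file order.
#' @export
readPoreStructure <- function(path, box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    .readStructurePdb(path, box)
  } else {
    .readStructureCsv(path)
  }
}

.readStructurePdb <- function(path, box) {
  lines <- readLines(path)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  ## line-numbered validation of the fixed coordinate columns before
  ## delegating the parse to bio3d
  for (i in which(isAtom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("parse error at line %d of %s: truncated ATOM record",
                   i, path), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(
      c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("parse error at line %d of %s: malformed coordinate field",
                   i, path), call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (anyDuplicated(a$eleno))
    stop("validation error: duplicate atom_id in ", path, call. = FALSE)
  species <- ifelse(a$resid %in% c("WAT", "HOH", "SOL", "TIP3"), "WAT",
             ifelse(a$resid %in% c("K", "POT"), "K",
             ifelse(a$resid %in% c("CL", "CLA"), "CL",
             ifelse(a$resid %in% c("PRT", "PROT"), "PROT", "PROT"))))
  atoms <- data.frame(atom_id = a$eleno, residue_name = a$resid,
                      residue_number = a$resno,
                      chain_id = ifelse(is.na(a$chain), "A", a$chain),
                      species = species, x = a$x, y = a$y, z = a$z,
                      radius = NA_real_, stringsAsFactors = FALSE)
  if (is.null(box)) {
    cry <- grep("^CRYST1", lines, value = TRUE)
    if (length(cry)) {
      box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                          substr(cry[1], 25, 33)))
    } else {
      box <- c(max(atoms$x) - min(atoms$x), max(atoms$y) - min(atoms$y),
               max(atoms$z) - min(atoms$z)) + 1
    }
  }
  PoreStructure(atoms, box)
}

.readStructureCsv <- function(path) {
  lines <- readLines(path)
  meta <- .parseHeaderMeta(lines)
  box <- .metaNum(meta, "box_A", path)
  if (length(box) != 3L)
    stop("header error: box_A must give three lengths in ", path,
         call. = FALSE)
  mb <- NULL
  if (!is.null(meta$membrane_z)) mb <- .metaNum(meta, "membrane_z", path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) stop("no atom rows in ", path, call. = FALSE)
  hdrRow <- body[1]
  cols <- strsplit(trimws(lines[hdrRow]), ",")[[1]]
  need <- c("atom_id", "residue_name", "residue_number", "chain_id",
            "species", "x", "y", "z")
  if (!all(need %in% cols))
    stop(sprintf("parse error at line %d of %s: expected columns %s",
                 hdrRow, path, paste(need, collapse = ",")), call. = FALSE)
  atoms <- read.table(text = lines[body[-1]], sep = ",",
                      col.names = cols, stringsAsFactors = FALSE)
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(atoms[[cc]])) {
      bad <- suppressWarnings(is.na(as.numeric(atoms[[cc]])))
      stop(sprintf("parse error at line %d of %s: non-numeric %s field",
                   body[-1][which(bad)[1]], path, cc), call. = FALSE)
    }
  }
  if (anyDuplicated(atoms$atom_id))
    stop("validation error: duplicate atom_id in ", path, call. = FALSE)
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  PoreStructure(atoms, box, mb)
}

#' Write a pore structure
#'
#' `.pdb` paths are written as fixed-column PDB via \pkg{bio3d} (species
#' stored in the residue name; coordinate precision 0.001 Angstrom by
#' format); other paths use the CSV dialect (6 significant digits) that
#' [readPoreStructure()] reads back losslessly.
#'
#' @param x a [PoreStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePoreStructure <- function(x, path) {
  stopifnot(is(x, "PoreStructure"))
  a <- x@atoms
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    resid <- ifelse(a$species == "WAT", "WAT",
             ifelse(a$species == "PROT", "PRT", a$species))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$residue_number, resid = resid,
                     chain = a$chain_id, eleno = a$atom_id,
                     elety = substr(a$species, 1, 1))
  } else {
    out <- c(paste0("# box_A=", paste(fmtNum(x@box), collapse = " ")),
             if (!is.null(x@membraneBounds))
               paste0("# membrane_z=",
                      paste(fmtNum(x@membraneBounds), collapse = " ")),
             "atom_id,residue_name,residue_number,chain_id,species,x,y,z,radius",
             sprintf("%d,%s,%d,%s,%s,%s,%s,%s,%s",
                     a$atom_id, a$residue_name, a$residue_number,
                     a$chain_id, a$species, fmtNum(a$x), fmtNum(a$y),
                     fmtNum(a$z),
                     ifelse(is.na(a$radius), "NA", fmtNum(a$radius))))
    writeLines(out, path)
  }
  invisible(path)
}

#' Read an ion/water trajectory from the '#'-headed TSV dialect
#'
#' Header lines carry `# box_A="Lx Ly Lz"`, `# voltage_mv=`, `# dt_ps=`;
#' body columns are `frame time_ps particle_id species charge_e x_A y_A
#' z_A`, ordered by (frame, particle_id).  The particle set must be
#' identical in every frame (fixed topology) and frame indices strictly
#' increasing; violations raise errors rather than being repaired.
#'
#' @param path file path.
#' @return an [IonTrajectory-class].
#' @export
readTrajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- .parseHeaderMeta(lines)
  box <- .metaNum(meta, "box_A", path)
  volt <- .metaNum(meta, "voltage_mv", path)
  dt <- .metaNum(meta, "dt_ps", path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  d <- read.table(text = body, header = FALSE,
                  col.names = c("frame", "time_ps", "particle_id",
                                "species", "charge_e", "x_A", "y_A", "z_A"),
                  colClasses = c("integer", "numeric", "integer",
                                 "character", "numeric", "numeric",
                                 "numeric", "numeric"))
  frames <- unique(d$frame)
  if (any(diff(frames) <= 0L))
    stop("ordering error: frame index not strictly increasing in ", path,
         call. = FALSE)
  nf <- length(frames)
  first <- d[d$frame == frames[1], ]
  ids <- first$particle_id
  np <- length(ids)
  if (nrow(d) != nf * np)
    stop("topology error: particle set differs across frames in ", path,
         call. = FALSE)
  ## verify fixed topology frame by frame
  idMat <- matrix(d$particle_id, nrow = np)
  if (!all(idMat == ids))
    stop("topology error: particle set differs across frames in ", path,
         call. = FALSE)
  coords <- array(NA_real_, c(np, 3L, nf))
  coords[, 1, ] <- matrix(d$x_A, nrow = np)
  coords[, 2, ] <- matrix(d$y_A, nrow = np)
  coords[, 3, ] <- matrix(d$z_A, nrow = np)
  times <- d$time_ps[seq(1, nrow(d), by = np)]
  IonTrajectory(
    topology = data.frame(particle_id = ids, species = first$species,
                          charge = first$charge_e,
                          stringsAsFactors = FALSE),
    coords = coords, times = times, box = box, voltage = volt, dt = dt,
    frameIndex = frames)
}

#' Write an ion/water trajectory in the TSV dialect
#'
#' @param x an [IonTrajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(x, path) {
  stopifnot(is(x, "IonTrajectory"))
  np <- nParticles(x); nf <- nFrames(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# box_A=", paste(fmtNum(x@box), collapse = " ")),
    paste0("# voltage_mv=", fmtNum(x@voltage)),
    paste0("# dt_ps=", fmtNum(x@dt)),
    "# columns=frame time_ps particle_id species charge_e x_A y_A z_A"),
    con)
  top <- x@topology
  for (k in seq_len(nf)) {
    writeLines(sprintf("%d\t%s\t%d\t%s\t%s\t%s\t%s\t%s",
                       x@frameIndex[k], fmtNum(x@times[k]),
                       top$particle_id, top$species, fmtNum(top$charge),
                       fmtNum(x@coords[, 1, k]), fmtNum(x@coords[, 2, k]),
                       fmtNum(x@coords[, 3, k])), con)
  }
  invisible(path)
}

#' Read a single-channel current trace (two-column TSV)
#'
#' Requires `# sampling_hz=` and `# voltage_mv=` metadata lines; optional
#' `# filter_hz=` and `# label=`.  Body: time (s) and current (pA),
#' tab-separated.  Sampling must be uniform: every timestamp within 1 ppm
#' of `(k-1)/sampling_hz`.
#'
#' @param path file path.
#' @return a [CurrentTrace-class].
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- .parseHeaderMeta(lines)
  fs <- .metaNum(meta, "sampling_hz", path)
  volt <- .metaNum(meta, "voltage_mv", path)
  filt <- if (!is.null(meta$filter_hz)) .metaNum(meta, "filter_hz", path)
          else NA_real_
  label <- if (!is.null(meta$label)) meta$label else ""
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  d <- read.table(text = body, header = FALSE,
                  col.names = c("time_s", "current_pA"),
                  colClasses = c("numeric", "numeric"))
  expected <- (seq_len(nrow(d)) - 1) / fs
  tol <- pmax(abs(expected), 1 / fs) * 1e-6
  if (any(abs(d$time_s - expected) > tol))
    stop("sampling error: non-uniform timestamps in ", path, call. = FALSE)
  CurrentTrace(d$current_pA, samplingRate = fs, voltage = volt,
               filterCutoff = filt, label = label)
}

#' Write a current trace as two-column TSV
#'
#' @param x a [CurrentTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(x, path) {
  stopifnot(is(x, "CurrentTrace"))
  n <- length(x@current)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sampling_hz=", fmtNum(x@samplingRate)),
    paste0("# voltage_mv=", fmtNum(x@voltage)),
    if (!is.na(x@filterCutoff))
      paste0("# filter_hz=", fmtNum(x@filterCutoff)),
    if (nzchar(x@label)) paste0("# label=", x@label)), con)
  t <- (seq_len(n) - 1) / x@samplingRate
  writeLines(sprintf("%.9g\t%s", t, fmtNum(x@current)), con)
  invisible(path)
}

#' Write a results table as CSV with a provenance comment block
#'
#' Every output table carries the operation name, its parameters, input
#' labels and the package version as leading '#' comment lines, so each row
#' is traceable to the computation that produced it.  No timestamps are
#' written: identical inputs give byte-identical files.
#'
#' @param df data.frame of results.
#' @param path output path.
#' @param operation operation name recorded in provenance.
#' @param params named list of parameters recorded in provenance.
#' @param inputs character vector of input labels.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(df, path, operation, params = list(),
                              inputs = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  pv <- as.character(packageVersion("porelab"))
  writeLines(c(
    paste0("# operation=", operation),
    paste0("# package=porelab ", pv),
    if (length(params))
      paste0("# params=", paste(sprintf("%s:%s", names(params),
                                        vapply(params, function(p)
                                          paste(format(p), collapse = " "),
                                          "")), collapse = "; ")),
    if (length(inputs)) paste0("# inputs=", paste(inputs, collapse = "; "))),
    con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [writeResultsTable()]
#'
#' @param path file path.
#' @return data.frame; provenance lines in `attr(, "provenance")`.
#' @export
readResultsTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  d <- read.table(text = lines[!grepl("^#", lines)], sep = ",",
                  header = TRUE, stringsAsFactors = FALSE)
  attr(d, "provenance") <- hdr
  d
}
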