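# PDB v3.3 fixed-width reader/writer and trajectory utilities.
#
# Dialect: ATOM/HETATM/MODEL/ENDMDL records only; altLoc other than blank/'A'
# is skipped; insertion codes are rejected. Coordinates are Angstrom, times
# picoseconds throughout.

.elementFromName <- function(name) {
  # PDB atom-name heuristic: strip digits/primes, first letter wins, except
  # two-letter names left-justified from column 13 (e.g. "FE") — with
  # C-alpha-style names ("CA", "CB") read as carbon when right-padded.
  nm <- gsub("[0-9' ]", "", name)
  ifelse(nchar(nm) == 0L, "X",
         ifelse(substr(nm, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
                substr(nm, 1, 1), toupper(substr(nm, 1, 1))))
}

.parseAtomLine <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  num <- function(from, to, what) {
    s <- trimws(substr(line, from, to))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("malformed PDB record at line %d: bad %s field '%s'",
                               lineno, what, s), call. = FALSE)
    v
  }
  icode <- substr(line, 27, 27)
  if (icode != " ")
    stop(sprintf("insertion codes are not supported (line %d, iCode '%s')",
                 lineno, icode), call. = FALSE)
  alt <- substr(line, 17, 17)
  if (!alt %in% c(" ", "A")) return(NULL)  # alternate location skipped
  el <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (el == "") el <- .elementFromName(name)
  list(serial = as.integer(num(7, 11, "serial")),
       name = name,
       element = el,
       chain = substr(line, 22, 22),
       resno = as.integer(num(23, 26, "residue number")),
       resname = trimws(substr(line, 18, 20)),
       record = if (startsWith(line, "HETATM")) "hetero" else "protein",
       x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"))
}

#' Read a PDB file or string
#'
#' Parses ATOM/HETATM records (fixed-width v3.3 columns). A multi-MODEL file
#' yields a \code{TrajectoryEnsemble} with one snapshot per MODEL and times
#' \code{interval, 2*interval, ...}; a single-model file yields a
#' \code{Structure}. Elements come from columns 77-78, falling back to an
#' atom-name heuristic.
#'
#' @param con path to a PDB file, or a character vector of PDB lines (length
#'   > 1 or containing newlines).
#' @param interval snapshot spacing in ps used to assign times to MODELs.
#' @param times optional explicit snapshot times (overrides \code{interval}).
#' @return \code{Structure} or \code{TrajectoryEnsemble}.
#' @export
readPDB <- function(con, interval = 10, times = NULL) {
  lines <- if (length(con) == 1L && !grepl("\n", con) && file.exists(con))
    readLines(con) else unlist(strsplit(con, "\n", fixed = TRUE))
  recs <- substr(lines, 1, 6)
  isAtom <- recs %in% c("ATOM  ", "HETATM")
  if (!any(isAtom)) stop("no ATOM/HETATM records found")
  models <- list(); cur <- list()
  for (i in seq_along(lines)) {
    r <- trimws(recs[i])
    if (r %in% c("ATOM", "HETATM")) {
      a <- .parseAtomLine(lines[i], i)
      if (!is.null(a)) cur[[length(cur) + 1L]] <- a
    } else if (r == "ENDMDL") {
      models[[length(models) + 1L]] <- cur; cur <- list()
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- cur
  models <- Filter(length, models)
  toDF <- function(m) do.call(rbind, lapply(m, function(a)
    as.data.frame(a, stringsAsFactors = FALSE)))
  if (length(models) == 1L)
    return(new("Structure", atoms = toDF(models[[1]])))
  dfs <- lapply(models, toDF)
  ref <- dfs[[1]]
  key <- function(d) paste(d$chain, d$resno, d$name)
  for (k in seq_along(dfs)[-1])
    if (nrow(dfs[[k]]) != nrow(ref) || !all(key(dfs[[k]]) == key(ref)))
      stop(sprintf("inconsistent atom roster in MODEL %d", k))
  if (is.null(times)) times <- interval * seq_along(dfs)
  new("TrajectoryEnsemble",
      roster = ref[, setdiff(names(ref), c("x", "y", "z"))],
      coords = lapply(dfs, function(d) unname(as.matrix(d[, c("x", "y", "z")]))),
      times = times)
}

.formatAtomLine <- function(a, x, y, z) {
  rec <- if (a$record == "hetero") "HETATM" else "ATOM  "
  name <- a$name
  # v3.3 alignment: 1-3 character names start in column 14
  name <- if (nchar(name) < 4L && nchar(a$element) == 1L)
    formatC(paste0(" ", name), width = -4) else formatC(name, width = -4)
  sprintf("%s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, name, " ", a$resname, a$chain, a$resno, " ",
          x, y, z, 1, 0, a$element)
}

#' Write a Structure or TrajectoryEnsemble as PDB text
#'
#' @param x Structure, ComplexModel or TrajectoryEnsemble.
#' @param path optional output file; when NULL the lines are returned.
#' @return invisibly (or visibly when \code{path} is NULL) the PDB lines.
#' @export
writePDB <- function(x, path = NULL) {
  lines <- character(0)
  emit <- function(df, xyz) {
    vapply(seq_len(nrow(df)), function(i)
      .formatAtomLine(df[i, ], xyz[i, 1], xyz[i, 2], xyz[i, 3]), character(1))
  }
  if (is(x, "ComplexModel"))
    x <- new("Structure", atoms = rbind(x@receptor@atoms, x@ligand@atoms))
  if (is(x, "Structure")) {
    lines <- c(emit(x@atoms, coordMatrix(x)), "END")
  } else if (is(x, "TrajectoryEnsemble")) {
    for (k in seq_len(nSnapshots(x)))
      lines <- c(lines, sprintf("MODEL %8d", k),
                 emit(x@roster, x@coords[[k]]), "ENDMDL")
    lines <- c(lines, "END")
  } else stop("cannot write object of class ", class(x))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Split a structure into receptor and ligand
#'
#' Selects the ligand by hetero residue name (optionally disambiguated by
#' chain as \code{"name:chain"}); the receptor keeps the protein atoms.
#' Waters (HOH/WAT) and single-atom hetero ions are dropped from both sides.
#'
#' @param s Structure.
#' @param ligandSelector residue name, e.g. \code{"LIG"}, or
#'   \code{"LIG:A"} to pin the chain.
#' @return ComplexModel.
#' @export
splitComplex <- function(s, ligandSelector) {
  a <- s@atoms
  parts <- strsplit(ligandSelector, ":", fixed = TRUE)[[1]]
  rn <- parts[1]; ch <- if (length(parts) > 1L) parts[2] else NA
  sel <- a$record == "hetero" & a$resname == rn
  if (!is.na(ch)) sel <- sel & a$chain == ch
  if (!any(sel)) stop(sprintf("ligand selector '%s' matches no hetero residue",
                              ligandSelector))
  copies <- unique(paste(a$chain[sel], a$resno[sel]))
  if (length(copies) > 1L)
    stop(sprintf("selector '%s' matches %d residue copies (%s); disambiguate by chain",
                 ligandSelector, length(copies), paste(copies, collapse = "; ")))
  lig <- a[sel, , drop = FALSE]
  rec <- a[a$record == "protein", , drop = FALSE]
  if (!nrow(rec)) stop("no protein atoms remain for the receptor")
  new("ComplexModel",
      receptor = new("Structure", atoms = rec),
      ligand = new("Structure", atoms = lig))
}

#' Select snapshots from a time window
#'
#' Keeps snapshots with time in the half-open window \code{(start, end]} at
#' the given spacing, earliest first, so that e.g. the last 2 ns of an 8 ns
#' run sampled every 10 ps yields exactly 200 frames.
#'
#' @param t TrajectoryEnsemble.
#' @param window numeric length-2: (start, end] in ps.
#' @param interval required spacing in ps (> 0).
#' @return TrajectoryEnsemble.
#' @export
selectSnapshots <- function(t, window, interval) {
  stopifnot(interval > 0, length(window) == 2L)
  tm <- t@times
  if (window[1] >= window[2]) stop("window start must precede window end")
  if (window[2] > max(tm) + 1e-9)
    stop("selection window extends beyond the trajectory end")
  keep <- which(tm > window[1] + 1e-9 & tm <= window[2] + 1e-9)
  # thin to the requested spacing relative to the window start
  phase <- (tm[keep] - window[1]) / interval
  keep <- keep[abs(phase - round(phase)) < 1e-6]
  if (!length(keep)) stop("empty snapshot selection")
  new("TrajectoryEnsemble", roster = t@roster,
      coords = t@coords[keep], times = tm[keep])
}

.selectionIdx <- function(roster, selection) {
  if (is.function(selection)) which(vapply(seq_len(nrow(roster)), function(i)
    isTRUE(selection(roster[i, ])), logical(1)))
  else which(roster$name %in% selection)
}

#' Superpose every snapshot onto the first
#'
#' Rigidly fits each snapshot to snapshot 1, minimizing the RMSD of the
#' selected atoms (default protein backbone N, CA, C, O). Snapshot 1 is
#' unchanged; the whole coordinate set moves with the fit.
#'
#' @param t TrajectoryEnsemble.
#' @param selection atom names (character) or a predicate over roster rows.
#' @return TrajectoryEnsemble, superposed.
#' @export
superposeToFirst <- function(t, selection = c("N", "CA", "C", "O")) {
  idx <- .selectionIdx(t@roster, selection)
  if (length(idx) < 3L) stop("degenerate fit: selection must match >= 3 atoms")
  ref <- t@coords[[1]][idx, , drop = FALSE]
  out <- t@coords
  for (k in seq_along(out)[-1]) {
    fit <- superposePoints(ref, out[[k]][idx, , drop = FALSE])
    out[[k]] <- .applyTransform(out[[k]], fit$rotation, fit$translation)
  }
  new("TrajectoryEnsemble", roster = t@roster, coords = out, times = t@times)
}

#' Per-snapshot RMSD against the first frame
#'
#' The caller is responsible for superposing the ensemble first (see
#' \code{\link{superposeToFirst}}); this function measures displacement only.
#'
#' @param t TrajectoryEnsemble.
#' @param selection atom names or predicate (see
#'   \code{\link{superposeToFirst}}).
#' @return data.frame with columns \code{time} and \code{rmsd} (Angstrom);
#'   the first entry is 0.
#' @export
rmsdSeries <- function(t, selection) {
  idx <- .selectionIdx(t@roster, selection)
  if (!length(idx)) stop("empty selection")
  ref <- t@coords[[1]][idx, , drop = FALSE]
  data.frame(time = t@times,
             rmsd = vapply(t@coords, function(m)
               .rmsd(ref, m[idx, , drop = FALSE]), numeric(1)))
}
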